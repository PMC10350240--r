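test_that("generated tables validate and are seed-deterministic", {
  spec <- synthetic_spec(seed = 3)
  for (cl in 1:2) for (s in c(10, 20)) {
    tab <- generate_patch(spec, cl, seed = s)
    expect_s3_class(validate_cell_table(tab), "cell_table")
  }
  t1 <- generate_patch(spec, 1, seed = 42)
  t2 <- generate_patch(spec, 1, seed = 42)
  expect_identical(t1$cells, t2$cells)
  expect_false(identical(generate_patch(spec, 1, seed = 43)$cells, t1$cells))

  spec_small <- synthetic_spec(cells_per_patch = c(1L, 1L))
  expect_error(generate_patch(spec_small, 1, 1), "infeasible")
})

test_that("datasets are bit-identical under a fixed spec and patient-disjoint", {
  spec <- synthetic_spec(n_patients_per_class = 4, patches_per_patient = 2,
                         cells_per_patch = c(60L, 80L), seed = 5)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$train, d2$train)
  expect_identical(d1$test, d2$test)

  pts <- lapply(d1[c("train", "val", "test")], function(gs)
    unique(vapply(gs, function(g) g$patient_id, character(1))))
  expect_length(intersect(pts$train, pts$val), 0L)
  expect_length(intersect(pts$train, pts$test), 0L)
  expect_length(intersect(pts$val, pts$test), 0L)
  # labels present and both classes represented
  labs <- vapply(d1$train, function(g) g$label, integer(1))
  expect_setequal(unique(labs), 1:2)
})

test_that("manifest lists exactly the planted (non-neutral) effects", {
  spec0 <- synthetic_spec(n_patients_per_class = 3, patches_per_patient = 1,
                          seed = 1)
  expect_length(generate_dataset(spec0)$manifest$planted_effects, 0L)

  spec1 <- synthetic_spec(n_patients_per_class = 3, patches_per_patient = 1,
                          effect_sizes = list(tumor_eccentricity_shift = 0.2,
                                              stroma_spacing_scale = 1.5),
                          seed = 1)
  mf <- generate_dataset(spec1)$manifest
  expect_setequal(names(mf$planted_effects),
                  c("tumor_eccentricity_shift", "stroma_spacing_scale"))
  expect_equal(mf$expected_discriminative_features, "eccentricity")
  expect_error(synthetic_spec(effect_sizes = list(bogus = 1)), "unknown effect")
})

test_that("perfect local alignment yields parallelism 1 on every kNN edge", {
  spec <- synthetic_spec(effect_sizes = list(alignment_strength = 1),
                         cells_per_patch = c(60L, 60L), seed = 9)
  tab <- generate_patch(spec, 2L, seed = 4)
  g <- build_graph(tab, k = 8, coincident = "clamp")
  expect_equal(g$edges$a, rep(1, length(g$edges$a)), tolerance = 1e-9)
  # baseline class is unaligned
  tab1 <- generate_patch(spec, 1L, seed = 4)
  g1 <- build_graph(tab1, k = 8, coincident = "clamp")
  expect_lt(mean(g1$edges$a), 0.9)
})

test_that("null effect sizes give indistinguishable class distributions", {
  spec <- synthetic_spec(seed = 17)
  draw <- function(cl) {
    cells <- do.call(rbind, lapply(1:90, function(i)
      generate_patch(spec, cl, seed = 1000 * cl + i)$cells))
    cells[1:9000, ]
  }
  c1 <- draw(1); c2 <- draw(2)
  feats <- c("confidence", "orientation", MORPHOLOGY_FEATURES)
  for (f in feats) {
    p <- suppressWarnings(stats::ks.test(c1[[f]], c2[[f]])$p.value)
    expect_gt(p, 0.001, label = paste("KS", f))
  }
})

test_that("planted eccentricity shift is recovered at the stated magnitude", {
  delta <- 0.2
  spec <- synthetic_spec(effect_sizes = list(tumor_eccentricity_shift = delta),
                         seed = 23)
  tumor_ecc <- function(cl) {
    unlist(lapply(1:60, function(i) {
      cells <- generate_patch(spec, cl, seed = 5000 * cl + i)$cells
      cells$eccentricity[cells$cell_type == "tumor"]
    }))
  }
  e1 <- tumor_ecc(1); e2 <- tumor_ecc(2)
  expect_gt(length(e1), 2000)
  diff <- mean(e2) - mean(e1)
  se <- sqrt(var(e1) / length(e1) + var(e2) / length(e2))
  expect_lt(abs(diff - delta), 3 * se + 0.01)
})

test_that("stroma spacing scale lowers stroma-stroma closeness", {
  spec <- synthetic_spec(effect_sizes = list(stroma_spacing_scale = 1.5),
                         cells_per_patch = c(100L, 100L), seed = 31)
  pooled_ss_w <- function(cl) {
    unlist(lapply(1:10, function(s) {
      g <- build_graph(generate_patch(spec, cl, seed = 100 * cl + s),
                       k = 8, coincident = "clamp")
      g$edges$w[g$edges$type == edge_type_code(1, 1, 6)]  # stroma->stroma
    }))
  }
  w1 <- pooled_ss_w(1); w2 <- pooled_ss_w(2)
  expect_lt(length(w2), length(w1))   # thinned: fewer stroma-stroma edges
  expect_lt(mean(w2), mean(w1))       # and larger spacing among survivors
})

test_that("held-out accuracy is monotone in planted effect size", {
  # scaled-down sweep: 3 magnitudes x 3 seeds, small cohorts and few
  # epochs (see methods vignette on benchmark scaling)
  acc_for <- function(mag, seed) {
    spec <- synthetic_spec(
      n_patients_per_class = 6L, patches_per_patient = 3L,
      cells_per_patch = c(60L, 90L),
      effect_sizes = if (mag > 0)
        list(tumor_eccentricity_shift = mag, alignment_strength = mag * 3)
      else list(),
      split = c(train = 0.5, val = 1 / 6, test = 1 / 3),
      seed = seed)
    ds <- generate_dataset(spec)
    set.seed(seed)
    model <- ceograph_model(scheme_lung6(), channels = c(8L, 8L, 2L))
    fit <- train_model(ds$train, ds$val, model,
                       make_optimizer("sgd_momentum", lr = 0.05),
                       epochs = 8, batch_size = 8, seed = seed)
    evaluate_graphs(fit$model, ds$test)$accuracy
  }
  mags <- c(0, 0.1, 0.3)
  acc <- vapply(mags, function(m)
    mean(vapply(1:3, function(s) acc_for(m, s), numeric(1))), numeric(1))
  expect_true(all(diff(acc) > -0.05))   # non-decreasing up to sampling noise
  expect_gt(acc[3], acc[1])
})
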