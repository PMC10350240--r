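test_that("edge feature primitives match their closed forms", {
  expect_equal(edge_parallelism(30, 30), 1.0)
  expect_equal(edge_parallelism(0, 90), 0.0, tolerance = 1e-12)
  expect_equal(edge_parallelism(10, 190), 1.0)

  expect_equal(edge_closeness(c(0, 0), c(0, 4)), 0.25)
  expect_equal(edge_closeness(c(0, 0), c(3, 4)), 0.2)
  expect_error(edge_closeness(c(1, 1), c(1, 1)), "coincident")

  withr::with_seed(9, {
    for (i in 1:50) {
      p <- runif(2, 0, 100); q <- runif(2, 0, 100)
      expect_equal(edge_closeness(p, q), 1 / sqrt(sum((p - q)^2)),
                   tolerance = 1e-12)
    }
    # parallelism: symmetric, axial, bounded
    th <- runif(40, -400, 400)
    ph <- runif(40, -400, 400)
    expect_equal(edge_parallelism(th, ph), edge_parallelism(ph, th))
    expect_equal(edge_parallelism(th, ph), edge_parallelism(th + 180, ph))
    expect_true(all(edge_parallelism(th, ph) >= 0 & edge_parallelism(th, ph) <= 1))
  })
})

test_that("edge_type_code is the declared bijection", {
  expect_equal(edge_type_code(0, 0, 6), 0L)
  expect_equal(edge_type_code(2, 5, 6), 17L)
  expect_error(edge_type_code(6, 0, 6), "out of range")
  for (T in c(4L, 6L)) {
    grid <- expand.grid(s = 0:(T - 1), d = 0:(T - 1))
    codes <- edge_type_code(grid$s, grid$d, T)
    expect_setequal(codes, 0:(T^2 - 1))
  }
})

test_that("kNN construction: degree law, cap at N-1, brute-force equality", {
  g2 <- rand_graph(2, seed = 1, k = 8)
  expect_equal(tabulate(g2$edges$src, 2), c(1L, 1L))

  g <- rand_graph(60, seed = 4, k = 8)
  deg <- tabulate(g$edges$src, 60)
  expect_true(all(deg == 8L))
  expect_true(all(g$edges$src != g$edges$dst))

  # independent oracle: per-node full sort with ascending-index ties
  tab <- rand_table(20, seed = 7)
  g3 <- build_graph(tab, k = 3)
  co <- cbind(tab$cells$x, tab$cells$y)
  for (n in 1:20) {
    d <- sqrt(colSums((t(co) - co[n, ])^2))
    d[n] <- Inf
    expected <- order(d)[1:3]
    got <- g3$edges$dst[g3$edges$src == n]
    expect_equal(got, expected)
  }
  expect_error(build_graph(rand_table(1, seed = 1)), "at least 2")
})

test_that("coincident centroids error by default, clamp on request", {
  tab <- rand_table(5, seed = 8)
  tab$cells$x[2] <- tab$cells$x[1]
  tab$cells$y[2] <- tab$cells$y[1]
  expect_error(build_graph(tab, k = 2), "coincident")
  g <- build_graph(tab, k = 2, coincident = "clamp")
  expect_true(all(g$edges$w <= 1))
})

test_that("graph edge features agree with direct recomputation", {
  tab <- rand_table(30, seed = 12)
  g <- build_graph(tab, k = 4)
  co <- cbind(tab$cells$x, tab$cells$y)
  d <- sqrt(rowSums((co[g$edges$src, ] - co[g$edges$dst, ])^2))
  expect_equal(g$edges$w, 1 / d, tolerance = 1e-12)
  expect_equal(g$edges$a,
               abs(cos((tab$cells$orientation[g$edges$src] -
                        tab$cells$orientation[g$edges$dst]) * pi / 180)),
               tolerance = 1e-12)
  ti <- match(tab$cells$cell_type, g$scheme$names) - 1L
  expect_equal(g$edges$type, ti[g$edges$src] * 6L + ti[g$edges$dst])
})

test_that("normalization fits, applies, guards and persists", {
  graphs <- lapply(1:50, function(s) rand_graph(30, seed = s, k = 3))
  st <- fit_normalization(graphs)
  normed <- lapply(graphs, apply_normalization, stats = st)
  Xall <- do.call(rbind, lapply(normed, `[[`, "X"))
  expect_true(all(abs(colMeans(Xall)) < 1e-9))
  expect_equal(unname(apply(Xall, 2, sd)), rep(1, 11), tolerance = 1e-9)

  # stats frozen: applying to an unseen graph uses the same moments
  g_new <- rand_graph(25, seed = 999, k = 3)
  gn <- apply_normalization(g_new, st)
  expect_equal(gn$X, sweep(sweep(g_new$X, 2, st$mean), 2, st$sd, "/"))
  expect_error(apply_normalization(gn, st), "already normalized")

  # constant column: guarded, transformed to zeros
  g_const <- rand_graph(40, seed = 5, k = 3)
  g_const$X[, "confidence"] <- 1.0
  expect_warning(st2 <- fit_normalization(list(g_const)), "confidence")
  expect_equal(unname(st2$sd[["confidence"]]), 1)
  g2 <- apply_normalization(g_const, st2)
  expect_true(all(g2$X[, "confidence"] == 0))
})

test_that("merge_slide_graphs is a disjoint union", {
  sc <- scheme_lung6()
  g1 <- build_graph(rand_table(5, sc, seed = 1, patch_id = "a",
                               slide_id = "s1"), sc, k = 2)
  g2 <- build_graph(rand_table(7, sc, seed = 2, patch_id = "b",
                               slide_id = "s1"), sc, k = 2)
  m <- merge_slide_graphs(list(g1, g2))
  expect_equal(nrow(m$X), 12L)
  expect_length(m$edges$src, length(g1$edges$src) + length(g2$edges$src))

  # no cross-component edges: verified by component labels
  expect_true(all(m$component[m$edges$src] == m$component[m$edges$dst]))

  single <- merge_slide_graphs(list(g1))
  expect_identical(single, g1)

  g3 <- build_graph(rand_table(4, sc, seed = 3, slide_id = "s2"), sc, k = 2)
  expect_error(merge_slide_graphs(list(g1, g3)), "different slides")
})

test_that("graph bundles round-trip through disk", {
  graphs <- lapply(1:3, function(s)
    build_graph(rand_table(15, seed = s, patch_id = paste0("p", s)),
                k = 4, label = 1L + s %% 2L))
  dir <- withr::local_tempdir()
  write_graph_bundle(graphs, dir)
  back <- read_graph_bundle(dir)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_equal(back[[i]]$X, graphs[[i]]$X, tolerance = 1e-12)
    expect_equal(back[[i]]$edges$w, graphs[[i]]$edges$w, tolerance = 1e-12)
    expect_identical(back[[i]]$edges$type, graphs[[i]]$edges$type)
    expect_identical(back[[i]]$label, graphs[[i]]$label)
    expect_identical(back[[i]]$patch_id, graphs[[i]]$patch_id)
  }
})
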