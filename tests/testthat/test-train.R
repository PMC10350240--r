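test_that("outcome labelers apply the published thresholds inclusively", {
  opmd <- outcome_labeler("opmd_risk")
  clin <- data.frame(patient_id = c("a", "b", "c", "d"),
                     time = c(42.3, 50, 68.5, 70))
  lab <- make_labels(clin, opmd)
  expect_equal(lab$label_name[lab$patient_id == "a"], "high_risk")
  expect_false("b" %in% lab$patient_id)      # in the exclusion gap
  expect_false("c" %in% lab$patient_id)      # 68.5 is still in the gap (> rule)
  expect_equal(lab$label_name[lab$patient_id == "d"], "low_risk")
  expect_setequal(attr(lab, "excluded"), c("b", "c"))

  tki <- outcome_labeler("tki_response")
  lab2 <- make_labels(data.frame(patient_id = c("x", "y"), time = c(31, 31.1)),
                      tki)
  expect_equal(lab2$label_name, c("non_benefitting", "benefitting"))
  expect_error(make_labels(data.frame(patient_id = "z", time = -1), tki),
               "negative")
})

test_that("parameter gradients match central finite differences", {
  g <- rand_graph(5, seed = 21, k = 2)
  gn <- apply_normalization(g, fit_normalization(list(g)))
  m <- rand_model(seed = 22, channels = c(4, 2), sd = 0.4)
  bk <- ceograph:::model_backward(m, gn, 1)
  eps <- 1e-5
  probe <- function(layer, slot, idx) {
    fd <- {
      mp <- m; mp$layers[[layer]][[slot]][idx] <-
        mp$layers[[layer]][[slot]][idx] + eps
      mm <- m; mm$layers[[layer]][[slot]][idx] <-
        mm$layers[[layer]][[slot]][idx] - eps
      (-log(model_forward(mp, gn)$p_graph[1]) +
         log(model_forward(mm, gn)$p_graph[1])) / (2 * eps)
    }
    an <- bk$grads[[layer]][[slot]][idx]
    expect_equal(an, fd, tolerance = 1e-4,
                 label = paste("layer", layer, slot, idx))
  }
  withr::with_seed(23, {
    for (layer in 1:2) {
      for (slot in c("EM", "theta", "Wg", "bg", "Wb", "bb")) {
        sz <- length(m$layers[[layer]][[slot]])
        for (idx in sample(sz, min(4, sz))) probe(layer, slot, idx)
      }
    }
  })
})

test_that("optimizers: zero-lr SGD freezes, AdaDelta moves, both stateful", {
  g <- rand_graph(10, seed = 30)
  ds <- lapply(1:6, function(i) {
    gi <- rand_graph(10, seed = 30 + i, patch_id = paste0("t", i),
                     slide_id = paste0("s", i))
    gi$label <- 1L + i %% 2L
    gi
  })
  m <- rand_model(seed = 31)
  before <- ceograph:::model_param_list(m)

  # SGD with vanishing lr: one epoch leaves parameters unchanged (limit)
  fit0 <- train_model(ds[1:4], ds[5:6], m,
                      make_optimizer("sgd_momentum", lr = 1e-300),
                      epochs = 1, batch_size = 2, seed = 1)
  expect_equal(ceograph:::model_param_list(fit0$model), before,
               tolerance = 1e-12)

  fit1 <- train_model(ds[1:4], ds[5:6], m, make_optimizer("adadelta"),
                      epochs = 1, batch_size = 2, seed = 1)
  expect_false(isTRUE(all.equal(ceograph:::model_param_list(fit1$model),
                                before)))
  expect_error(make_optimizer("sgd_momentum", lr = 0), "learning_rate")
})

test_that("training is seed-reproducible and rejects slide leakage", {
  ds <- lapply(1:8, function(i) {
    g <- rand_graph(12, seed = 40 + i, patch_id = paste0("p", i),
                    slide_id = paste0("s", (i + 1) %/% 2))
    g$label <- 1L + i %% 2L
    g
  })
  m <- rand_model(seed = 41)
  opt <- function() make_optimizer("sgd_momentum", lr = 0.01)
  f1 <- train_model(ds[1:6], ds[7:8], m, opt(), epochs = 3, batch_size = 2,
                    seed = 99)
  f2 <- train_model(ds[1:6], ds[7:8], m, opt(), epochs = 3, batch_size = 2,
                    seed = 99)
  expect_identical(f1$history, f2$history)

  leaky <- ds[c(1, 2, 3)]
  leaky[[3]]$slide_id <- ds[[7]]$slide_id
  expect_error(train_model(leaky, ds[7:8], m, opt(), epochs = 1, seed = 1),
               "leakage")
})

test_that("loss decreases in expectation on a fixed tiny dataset", {
  ds <- lapply(1:10, function(i) {
    g <- rand_graph(15, seed = 50 + i, patch_id = paste0("p", i),
                    slide_id = paste0("s", i))
    g$label <- 1L + i %% 2L
    g
  })
  first <- numeric(5); last <- numeric(5)
  for (s in 1:5) {
    m <- rand_model(seed = 60 + s)
    fit <- train_model(ds[1:8], ds[9:10], m,
                       make_optimizer("sgd_momentum", lr = 0.02),
                       epochs = 5, batch_size = 4, seed = s)
    first[s] <- fit$history$loss[1]
    last[s] <- fit$history$loss[5]
  }
  expect_lt(mean(last), mean(first))
})

test_that("checkpoint selection takes the best validation epoch", {
  ds <- lapply(1:6, function(i) {
    g <- rand_graph(12, seed = 70 + i, patch_id = paste0("p", i),
                    slide_id = paste0("s", i))
    g$label <- 1L + i %% 2L
    g
  })
  m <- rand_model(seed = 71)
  fit <- train_model(ds[1:4], ds[5:6], m,
                     make_optimizer("sgd_momentum", lr = 0.05),
                     epochs = 4, batch_size = 2, seed = 3)
  expect_equal(fit$best_epoch,
               which.max(fit$history$val_accuracy))  # earliest on ties
})

test_that("per-epoch resampling is deterministic and varies across epochs", {
  pools1 <- list(a = list("only"))
  expect_identical(resample_epoch_patches(pools1, 5, 1)$a, "only")
  expect_identical(resample_epoch_patches(pools1, 5, 9)$a, "only")

  pools <- stats::setNames(
    lapply(1:100, function(i) as.list(seq_len(100))),
    paste0("pt", 1:100))
  e1 <- resample_epoch_patches(pools, seed = 7, epoch = 1)
  e1b <- resample_epoch_patches(pools, seed = 7, epoch = 1)
  e2 <- resample_epoch_patches(pools, seed = 7, epoch = 2)
  expect_identical(e1, e1b)
  expect_false(identical(e1, e2))  # collision prob ~ (1/100)^100

  expect_error(resample_epoch_patches(list(a = list()), 1, 1), "empty")
})
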