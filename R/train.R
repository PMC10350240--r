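#' Outcome labeler presets
#'
#' Turns survival times into the binary training labels of the two
#' prognostic tasks:
#' * `opmd_risk`: cancer-free survival (CFS) <= 42.3 months is
#'   high-risk, CFS > 68.5 months is low-risk; times in the gap are
#'   excluded from training.
#' * `tki_response`: overall survival (OS) <= 31 months is
#'   non-benefitting, otherwise benefitting.
#'
#' Class index 1 is the "positive"/adverse group (high-risk,
#' non-benefitting) and index 2 the favorable group; the mapping is
#' carried in `$classes`.
#'
#' @param task `"opmd_risk"` or `"tki_response"`.
#' @param low,high Threshold overrides in months (for `tki_response`
#'   only `low` is used).
#' @return An `outcome_labeler`.
#' @export
outcome_labeler <- function(task = c("opmd_risk", "tki_response"),
                            low = NULL, high = NULL) {
  task <- match.arg(task)
  if (task == "opmd_risk") {
    low <- low %||% 42.3; high <- high %||% 68.5
    classes <- c("high_risk", "low_risk")
  } else {
    low <- low %||% 31; high <- high %||% low
    classes <- c("non_benefitting", "benefitting")
  }
  structure(list(task = task, low = low, high = high, classes = classes),
            class = "outcome_labeler")
}

#' Label patients from survival times
#'
#' @param clinical data.frame with columns `patient_id` and `time`
#'   (months, >= 0).
#' @param labeler An [outcome_labeler()].
#' @return data.frame `patient_id`, `time`, `label` (1-based class
#'   index), `label_name`; rows falling in the OPMD exclusion gap are
#'   dropped and reported in the `"excluded"` attribute.
#' @export
make_labels <- function(clinical, labeler) {
  stopifnot(all(c("patient_id", "time") %in% names(clinical)))
  if (any(clinical$time < 0)) stop("negative survival time")
  t <- clinical$time
  if (labeler$task == "opmd_risk") {
    lab <- ifelse(t <= labeler$low, 1L, ifelse(t > labeler$high, 2L, NA_integer_))
  } else {
    lab <- ifelse(t <= labeler$low, 1L, 2L)
  }
  out <- data.frame(patient_id = clinical$patient_id, time = t,
                    label = lab,
                    label_name = labeler$classes[lab],
                    stringsAsFactors = FALSE)
  excluded <- out[is.na(out$label), , drop = FALSE]
  out <- out[!is.na(out$label), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded$patient_id
  out
}

# ---- optimizers -----------------------------------------------------------

# Parameter containers are nested lists of numeric arrays; these helpers
# apply a function elementwise across the nesting.
map_params <- function(f, ...) {
  args <- list(...)
  out <- args[[1L]]
  for (i in seq_along(out)) {
    if (is.list(out[[i]])) {
      out[[i]] <- do.call(map_params, c(list(f), lapply(args, `[[`, i)))
    } else if (is.numeric(out[[i]])) {
      out[[i]] <- do.call(f, lapply(args, `[[`, i))
    }
  }
  out
}

zero_params <- function(p) map_params(function(x) x * 0, p)

model_param_list <- function(model) {
  lapply(model$layers, function(l) l[c("EM", "theta", "Wg", "bg", "Wb", "bb")])
}

set_model_params <- function(model, plist) {
  for (i in seq_along(model$layers))
    model$layers[[i]][c("EM", "theta", "Wg", "bg", "Wb", "bb")] <- plist[[i]]
  model
}

#' Create an optimizer
#'
#' `sgd_momentum` follows the usual velocity form
#' `v <- momentum * v + g; p <- p - lr * v`. `adadelta` is the
#' accumulator scheme (decay `rho`, guard `eps`) with the update scaled
#' by `scale` — the "scaling factor" knob is mapped to this
#' learning-rate multiplier (the published description does not define
#' the term; see the methods vignette).
#'
#' @param kind `"sgd_momentum"` or `"adadelta"`.
#' @param lr Learning rate (SGD; must be > 0).
#' @param momentum SGD momentum.
#' @param scale AdaDelta update multiplier (default 2).
#' @param rho,eps AdaDelta decay and guard.
#' @return An `optimizer` with a `$step(params, grads)` closure.
#' @export
make_optimizer <- function(kind = c("sgd_momentum", "adadelta"),
                           lr = 1e-4, momentum = 0.9, scale = 2,
                           rho = 0.9, eps = 1e-6) {
  kind <- match.arg(kind)
  state <- new.env(parent = emptyenv())
  if (kind == "sgd_momentum") {
    if (lr <= 0) stop("learning_rate must be > 0 for SGD")
    step <- function(params, grads) {
      if (is.null(state$v)) state$v <- zero_params(params)
      state$v <- map_params(function(v, g) momentum * v + g, state$v, grads)
      map_params(function(p, v) p - lr * v, params, state$v)
    }
  } else {
    step <- function(params, grads) {
      if (is.null(state$eg)) {
        state$eg <- zero_params(params)
        state$ed <- zero_params(params)
      }
      state$eg <- map_params(function(a, g) rho * a + (1 - rho) * g^2,
                             state$eg, grads)
      delta <- map_params(function(g, eg, ed)
        -sqrt(ed + eps) / sqrt(eg + eps) * g, grads, state$eg, state$ed)
      state$ed <- map_params(function(a, d) rho * a + (1 - rho) * d^2,
                             state$ed, delta)
      map_params(function(p, d) p + scale * d, params, delta)
    }
  }
  structure(list(kind = kind, step = step), class = "optimizer")
}

#' Deterministic per-epoch patch resampling
#'
#' For cohorts too small for a fixed patch set, one patch per patient is
#' redrawn each epoch. The draw is a pure function of `(seed, epoch)`:
#' identical calls repeat exactly, different epochs differ with high
#' probability.
#'
#' @param pools Named list (by patient) of non-empty lists of graphs or
#'   tables.
#' @param seed Integer base seed.
#' @param epoch Epoch number (>= 1).
#' @return Named list with one element drawn per patient.
#' @export
resample_epoch_patches <- function(pools, seed, epoch) {
  sizes <- lengths(pools)
  if (any(sizes == 0L))
    stop("empty patch pool for patient(s): ",
         paste(names(pools)[sizes == 0L], collapse = ", "))
  picks <- withr_seed(as.integer((seed + 1000003 * epoch) %% 2147483647L), {
    vapply(sizes, function(s) sample.int(s, 1L), integer(1))
  })
  Map(function(pool, i) pool[[i]], pools, picks)
}

# run expr under a temporary RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

check_split_integrity <- function(splits) {
  slide_sets <- lapply(splits, function(gs)
    unique(vapply(gs, function(g) g$slide_id, character(1))))
  nm <- names(slide_sets)
  for (i in seq_along(slide_sets)) for (j in seq_len(i - 1L)) {
    leak <- intersect(slide_sets[[i]], slide_sets[[j]])
    if (length(leak))
      stop("slide leakage between ", nm[j], " and ", nm[i], ": ",
           paste(leak, collapse = ", "))
  }
  invisible(TRUE)
}

#' Evaluate a model on labeled graphs
#'
#' @param model A `ceograph_model`.
#' @param graphs List of labeled `spatial_graph`s.
#' @return List `loss` (mean cross-entropy), `accuracy` (graph-level),
#'   `scores` data.frame of per-graph probabilities and predictions.
#' @export
evaluate_graphs <- function(model, graphs) {
  K <- model$K
  probs <- matrix(NA_real_, length(graphs), K)
  labels <- integer(length(graphs))
  for (i in seq_along(graphs)) {
    probs[i, ] <- model_forward(model, graphs[[i]])$p_graph
    labels[i] <- graphs[[i]]$label %||% NA_integer_
  }
  pred <- max.col(probs, ties.method = "first")
  loss <- mean(-log(pmax(probs[cbind(seq_along(graphs), labels)], 1e-300)))
  scores <- data.frame(
    patch_id = vapply(graphs, function(g) g$patch_id, character(1)),
    slide_id = vapply(graphs, function(g) g$slide_id, character(1)),
    patient_id = vapply(graphs, function(g) g$patient_id, character(1)),
    label = labels, predicted = pred, stringsAsFactors = FALSE
  )
  colnames(probs) <- paste0("p", seq_len(K))
  scores <- cbind(scores, probs)
  list(loss = loss, accuracy = mean(pred == labels), scores = scores)
}

#' Train a Ceograph model
#'
#' Minimizes graph-level cross-entropy with exact hand-derived
#' gradients, averaged over mini-batches. Normalization statistics are
#' fitted on the training graphs and frozen into the model. Each epoch
#' the training order is reshuffled; with
#' `resample_per_epoch = TRUE`, `train_graphs` must be a named list of
#' per-patient graph pools and one graph per patient is redrawn per
#' epoch. The checkpoint returned is the epoch with the highest
#' validation accuracy (earliest epoch on ties). All randomness (init
#' is the caller's, shuffling, dropout, resampling) flows from `seed`.
#'
#' @param train_graphs Labeled graphs (raw features), or per-patient
#'   pools when resampling.
#' @param val_graphs Labeled validation graphs; slides must not overlap
#'   the training slides.
#' @param model A freshly built `ceograph_model`.
#' @param optimizer From [make_optimizer()].
#' @param epochs Number of epochs (never stated upstream; configure).
#' @param batch_size Graphs per gradient step.
#' @param seed Integer seed.
#' @param resample_per_epoch Per-epoch patient resampling mode.
#' @param tie_break How to choose among epochs with equal (highest)
#'   validation accuracy: `"earliest"` (default) keeps the first such
#'   epoch; `"val_loss"` keeps the one with the lowest validation loss.
#'   The latter matters on small corpora where accuracy saturates early
#'   while the model is still far from converged.
#' @param verbose Print per-epoch lines.
#' @return List `model` (best checkpoint, normalization attached),
#'   `history` data.frame (epoch, loss, train_accuracy, val_accuracy),
#'   `best_epoch`.
#' @export
train_model <- function(train_graphs, val_graphs, model, optimizer,
                        epochs = 30L, batch_size = 32L, seed = 1L,
                        resample_per_epoch = FALSE,
                        tie_break = c("earliest", "val_loss"),
                        verbose = FALSE) {
  stopifnot(epochs >= 1L, length(val_graphs) > 0L)
  tie_break <- match.arg(tie_break)
  pools <- NULL
  if (resample_per_epoch) {
    pools <- train_graphs
    if (is.null(names(pools))) stop("resampling needs per-patient named pools")
    flat <- unlist(pools, recursive = FALSE)
  } else {
    flat <- train_graphs
  }
  if (!length(flat)) stop("empty training set")
  check_split_integrity(list(train = flat, validation = val_graphs))

  norm <- fit_normalization(flat)
  model$norm <- norm
  norm_all <- function(gs) lapply(gs, function(g)
    if (isTRUE(g$normalized)) g else apply_normalization(g, norm))
  val_n <- norm_all(val_graphs)
  if (!resample_per_epoch) train_n <- norm_all(flat)

  best <- list(acc = -Inf, loss = Inf, epoch = NA_integer_, params = NULL)
  history <- data.frame()
  set.seed(seed)

  for (ep in seq_len(epochs)) {
    if (resample_per_epoch) {
      train_ep <- norm_all(resample_epoch_patches(pools, seed, ep))
    } else {
      train_ep <- train_n
    }
    ord <- sample.int(length(train_ep))
    losses <- numeric(0)
    for (start in seq(1L, length(ord), by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, length(ord))]
      acc_g <- NULL
      bl <- 0
      for (i in idx) {
        g <- train_ep[[i]]
        bk <- model_backward(model, g, g$label, training = TRUE)
        bl <- bl + bk$loss
        acc_g <- if (is.null(acc_g)) bk$grads
                 else map_params(`+`, acc_g, bk$grads)
      }
      acc_g <- map_params(function(x) x / length(idx), acc_g)
      params <- optimizer$step(model_param_list(model), acc_g)
      model <- set_model_params(model, params)
      losses <- c(losses, bl / length(idx))
    }
    tr_eval <- evaluate_graphs(model, train_ep)
    va_eval <- evaluate_graphs(model, val_n)
    history <- rbind(history, data.frame(
      epoch = ep, loss = mean(losses), train_accuracy = tr_eval$accuracy,
      val_accuracy = va_eval$accuracy))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  train %.3f  val %.3f",
                      ep, mean(losses), tr_eval$accuracy, va_eval$accuracy))
    better <- va_eval$accuracy > best$acc ||
      (tie_break == "val_loss" && va_eval$accuracy == best$acc &&
         va_eval$loss < best$loss)
    if (better) {
      best <- list(acc = va_eval$accuracy, loss = va_eval$loss, epoch = ep,
                   params = model_param_list(model))
    }
  }
  model <- set_model_params(model, best$params)
  list(model = model, history = history, best_epoch = best$epoch)
}
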