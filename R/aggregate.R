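#' Score graphs with a trained model
#'
#' @param model Trained `ceograph_model` (normalization attached).
#' @param graphs List of `spatial_graph`s (raw or normalized).
#' @return data.frame with ids, per-class probabilities `p1..pK` and the
#'   argmax `predicted` class index.
#' @export
score_graphs <- function(model, graphs) {
  K <- model$K
  probs <- t(vapply(graphs, function(g) model_forward(model, g)$p_graph,
                    numeric(K)))
  out <- data.frame(
    patch_id = vapply(graphs, function(g) g$patch_id, character(1)),
    slide_id = vapply(graphs, function(g) g$slide_id, character(1)),
    patient_id = vapply(graphs, function(g) g$patient_id, character(1)),
    stringsAsFactors = FALSE
  )
  colnames(probs) <- paste0("p", seq_len(K))
  out <- cbind(out, probs)
  out$predicted <- max.col(probs, ties.method = "first")
  out
}

#' Majority vote over patch predictions of one slide
#'
#' The slide call is the most frequent patch-level class. Ties are
#' broken by the higher mean probability of the tied classes, then by
#' the lower class index (documented deterministic convention).
#'
#' @param predicted Integer vector of patch class indices.
#' @param probs Optional matrix of patch probabilities (columns =
#'   classes) used for tie-breaking.
#' @return Single class index.
#' @export
majority_vote <- function(predicted, probs = NULL) {
  stopifnot(length(predicted) >= 1L)
  counts <- table(predicted)
  topc <- as.integer(names(counts)[counts == max(counts)])
  if (length(topc) == 1L) return(topc)
  if (!is.null(probs)) {
    mp <- vapply(topc, function(k) mean(probs[, k]), numeric(1))
    topc <- topc[mp == max(mp)]
  }
  min(topc)
}

#' Slide-level class by majority vote
#'
#' @param scores A [score_graphs()] data.frame.
#' @return data.frame `slide_id`, `n_patches`, `predicted`.
#' @export
slide_majority_vote <- function(scores) {
  K <- sum(grepl("^p[0-9]+$", names(scores)))
  pm <- as.matrix(scores[, paste0("p", seq_len(K)), drop = FALSE])
  res <- lapply(split(seq_len(nrow(scores)), scores$slide_id), function(i)
    data.frame(slide_id = scores$slide_id[i[1L]], n_patches = length(i),
               predicted = majority_vote(scores$predicted[i],
                                         pm[i, , drop = FALSE]),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Patient-level mean score
#'
#' Arithmetic mean of the positive-class probability over all of a
#' patient's patches (pooled across slides when a patient has several).
#'
#' @param scores A [score_graphs()] data.frame.
#' @param positive_class 1-based class column to average.
#' @return data.frame `patient_id`, `n_patches`, `score`.
#' @export
patient_mean_score <- function(scores, positive_class = 1L) {
  col <- paste0("p", positive_class)
  stopifnot(col %in% names(scores))
  agg <- stats::aggregate(scores[[col]], by = list(patient_id = scores$patient_id),
                          FUN = mean)
  n <- stats::aggregate(scores[[col]], by = list(patient_id = scores$patient_id),
                        FUN = length)
  data.frame(patient_id = agg$patient_id, n_patches = n$x, score = agg$x,
             stringsAsFactors = FALSE)
}

#' Dichotomize patient scores into two groups
#'
#' * `fixed_cutoff`: score strictly greater than `cutoff` (default 0.5)
#'   is positive; a score exactly at the cutoff goes to the negative
#'   group (documented boundary convention).
#' * `cohort_median`: score strictly greater than the cohort median is
#'   positive; ties at the median are negative. With the midpoint
#'   convention an even cohort splits in half. All-identical scores
#'   produce a warning and an all-negative grouping.
#'
#' @param scores Named numeric vector (names = patient ids) or the
#'   data.frame from [patient_mean_score()].
#' @param rule `"fixed_cutoff"` or `"cohort_median"`.
#' @param cutoff Cutoff for the fixed rule.
#' @return data.frame `patient_id`, `score`, `group` (`"positive"` /
#'   `"negative"`), with the cutoff used in attribute `"cutoff"`.
#' @export
dichotomize <- function(scores, rule = c("fixed_cutoff", "cohort_median"),
                        cutoff = 0.5) {
  rule <- match.arg(rule)
  if (is.data.frame(scores)) {
    ids <- scores$patient_id; s <- scores$score
  } else {
    ids <- names(scores) %||% as.character(seq_along(scores))
    s <- as.numeric(scores)
  }
  stopifnot(length(s) >= 1L)
  if (rule == "cohort_median") {
    if (length(s) < 2L) stop("median rule needs at least 2 patients")
    cutoff <- stats::median(s)
    if (all(s == s[1L]))
      warning("all patient scores identical; everyone in the negative group")
  }
  data.frame(patient_id = ids, score = s,
             group = ifelse(s > cutoff, "positive", "negative"),
             stringsAsFactors = FALSE) -> out
  attr(out, "cutoff") <- cutoff
  out
}
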