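#' Per-feature contribution gradients for one graph
#'
#' Computes the exact partial derivative of the cross-entropy objective
#' `L = CE(P_graph, reference_class)` with respect to every continuous
#' input feature — each node's 11 features and each edge's closeness and
#' parallelism (the categorical type code has no derivative and serves
#' only as a grouping key) — in one backward pass. Sign convention: a
#' positive `dL/df` means increasing the feature increases the loss of
#' being called `reference_class`, i.e. pushes the prediction toward the
#' other class(es).
#'
#' Node-feature gradients are reported on the raw measurement scale by
#' default (chain rule through the persisted normalization: division by
#' the fitted per-column sd), so contributions read in the units of the
#' named features. Dropout is off: the report is deterministic.
#'
#' @param model Trained `ceograph_model` with normalization attached (or
#'   an already-normalized graph).
#' @param graph A `spatial_graph`.
#' @param reference_class 1-based presumptive category k.
#' @param raw_scale Report node gradients on the raw feature scale
#'   (`TRUE`, default) or the normalized scale.
#' @return A `contribution_report`: list with `node_probabilities`
#'   (N x K), `node_gradients` (N x 11, named columns),
#'   `edge_gradients` (data.frame src, dst, edge_type, closeness,
#'   parallelism), `node_type`, `p_graph`, `loss`, `reference_class`,
#'   ids, `coords`, `scheme`.
#' @export
feature_contributions <- function(model, graph, reference_class = 1L,
                                  raw_scale = TRUE) {
  if (reference_class < 1L || reference_class > model$K)
    stop("reference_class out of range")
  bk <- model_backward(model, graph, reference_class, training = FALSE)
  dX <- bk$dX
  if (raw_scale) {
    stats <- graph$norm %||% model$norm
    if (is.null(stats))
      stop("raw-scale gradients need fitted normalization statistics")
    dX <- sweep(dX, 2L, stats$sd, "/")
  }
  colnames(dX) <- NODE_FEATURES
  structure(
    list(
      node_probabilities = node_probabilities(bk$node_outputs),
      node_gradients = dX,
      edge_gradients = data.frame(
        src = graph$edges$src, dst = graph$edges$dst,
        edge_type = graph$edges$type,
        closeness = bk$dw, parallelism = bk$da),
      node_type = graph$node_type,
      p_graph = bk$p_graph, loss = bk$loss,
      reference_class = as.integer(reference_class),
      patch_id = graph$patch_id, slide_id = graph$slide_id,
      patient_id = graph$patient_id,
      coords = graph$coords, scheme = graph$scheme
    ),
    class = "contribution_report"
  )
}

#' @export
print.contribution_report <- function(x, ...) {
  cat("<contribution_report> patch ", x$patch_id, ": ",
      nrow(x$node_gradients), " nodes, ", nrow(x$edge_gradients),
      " edges; reference class ", x$reference_class,
      " (loss ", signif(x$loss, 4), ")\n", sep = "")
  invisible(x)
}

#' Summarize contributions across a corpus of reports
#'
#' Pools one feature's contributions over many graphs and summarizes
#' them per group — per cell type for node features, per directed
#' edge-type pair for edge features — the tabular form behind the
#' dataset-level contribution boxplots.
#'
#' @param reports List of `contribution_report`s.
#' @param feature One of the 11 node feature names, or `"closeness"` /
#'   `"parallelism"`.
#' @param group_by `"cell_type"` (node features) or `"edge_type"` (edge
#'   features); inferred from the feature when `NULL`.
#' @return data.frame `group`, `n`, `q1`, `median`, `q3`, `mean`.
#' @export
summarize_contributions <- function(reports, feature,
                                    group_by = NULL) {
  stopifnot(length(reports) > 0L)
  edge_feats <- c("closeness", "parallelism")
  if (is.null(group_by))
    group_by <- if (feature %in% edge_feats) "edge_type" else "cell_type"
  if (!group_by %in% c("cell_type", "edge_type"))
    stop("unknown group key: ", group_by)
  scheme <- reports[[1L]]$scheme
  if (group_by == "cell_type") {
    if (!feature %in% NODE_FEATURES) stop("unknown node feature: ", feature)
    vals <- unlist(lapply(reports, function(r) r$node_gradients[, feature]))
    grp <- unlist(lapply(reports, function(r) scheme$names[r$node_type]))
  } else {
    if (!feature %in% edge_feats) stop("unknown edge feature: ", feature)
    vals <- unlist(lapply(reports, function(r) r$edge_gradients[[feature]]))
    grp <- unlist(lapply(reports, function(r) {
      code <- r$edge_gradients$edge_type
      paste0(scheme$names[code %/% scheme$n_types + 1L], "->",
             scheme$names[code %% scheme$n_types + 1L])
    }))
  }
  res <- lapply(split(vals, grp), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(v), q1 = q[1L], median = q[2L], q3 = q[3L],
               mean = mean(v))
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(group = names(res), stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Spatial contribution map
#'
#' Plots every nucleus at its patch coordinates colored by a signed
#' per-node score on a diverging blue-white-red scale: either the
#' node-probability margin `P_nucleus[k] - 1/K` (how strongly the cell
#' votes for the reference class) or the summed node-feature gradient.
#' Optionally writes the figure (PNG or SVG by extension) and always
#' returns the per-node table.
#'
#' @param graph The `spatial_graph` the report was computed on.
#' @param report Its `contribution_report`.
#' @param color_by `"probability"` or `"gradient"`.
#' @param file Optional output figure path (`.png` or `.svg`).
#' @param table_file Optional output path for the per-node TSV.
#' @param point_cex Marker size.
#' @return Invisibly, a data.frame `x`, `y`, `cell_type`, `score`.
#' @export
spatial_contribution_map <- function(graph, report,
                                     color_by = c("probability", "gradient"),
                                     file = NULL, table_file = NULL,
                                     point_cex = 0.8) {
  color_by <- match.arg(color_by)
  k <- report$reference_class
  score <- if (color_by == "probability") {
    report$node_probabilities[, k] - 1 / ncol(report$node_probabilities)
  } else {
    rowSums(report$node_gradients)
  }
  tab <- data.frame(x = graph$coords[, 1L], y = graph$coords[, 2L],
                    cell_type = graph$scheme$names[graph$node_type],
                    score = score, stringsAsFactors = FALSE)
  if (!is.null(table_file))
    utils::write.table(tab, table_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)

  lim <- max(abs(score), 1e-12)
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(256)
  ci <- pmin(pmax(round((score / lim + 1) / 2 * 255) + 1, 1), 256)
  draw <- function() {
    graphics::plot(tab$x, tab$y, col = pal[ci], pch = 16, cex = point_cex,
                   asp = 1, ylim = rev(range(tab$y)),
                   xlab = "x (px)", ylab = "y (px)",
                   main = sprintf("contribution map (%s, class %d)",
                                  color_by, k))
  }
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file, width = 7, height = 7)
    else grDevices::png(file, width = 900, height = 900)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
  } else {
    draw()
  }
  invisible(tab)
}
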