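#' Nuclear parallelism between two orientations
#'
#' Absolute cosine of the angle between the major axes of two nuclei:
#' 1 means parallel, 0 perpendicular. Orientations are axial, so the
#' result is invariant to adding 180 degrees to either angle.
#'
#' @param theta_n,theta_m Orientations in degrees (any real; wrapped).
#' @return Value(s) in \[0, 1\]; vectorized.
#' @export
edge_parallelism <- function(theta_n, theta_m) {
  v <- abs(cos((theta_n - theta_m) * pi / 180))
  pmin(pmax(v, 0), 1)
}

#' Nuclear closeness between two centroids
#'
#' Reciprocal of the Euclidean distance in pixels between two nuclei
#' centroids.
#'
#' @param p_n,p_m Numeric length-2 points `c(x, y)`.
#' @return Positive scalar `1 / ||p_n - p_m||`.
#' @export
edge_closeness <- function(p_n, p_m) {
  d <- sqrt(sum((p_n - p_m)^2))
  if (d == 0) stop("coincident centroids: closeness undefined")
  1 / d
}

#' Categorical edge-type code for an ordered cell-type pair
#'
#' `code = src * T + dst` over 0-based type indices: a bijection from the
#' T x T ordered pairs onto `[0, T^2)` (36 codes for the 6-type lung
#' scheme, 16 for the 4-type oral scheme).
#'
#' @param src_type,dst_type 0-based type indices; vectorized.
#' @param n_types Number of types T.
#' @return Integer code(s) in `[0, n_types^2)`.
#' @export
edge_type_code <- function(src_type, dst_type, n_types) {
  if (any(src_type < 0 | src_type >= n_types | dst_type < 0 | dst_type >= n_types))
    stop("type index out of range [0, ", n_types, ")")
  as.integer(src_type) * as.integer(n_types) + as.integer(dst_type)
}

#' Build a directed kNN cell spatial graph from a cell table
#'
#' Each nucleus becomes a node with 11 features (prediction confidence
#' followed by the ten [MORPHOLOGY_FEATURES]); each node emits directed
#' edges to its `min(k, N-1)` nearest other nuclei by Euclidean centroid
#' distance (direction pointing from a cell to its neighbors). Each edge
#' carries three features: the categorical [edge_type_code()], nuclear
#' closeness and nuclear parallelism. Distance ties are broken by
#' ascending cell index for determinism.
#'
#' @param table A `cell_table` with at least 2 cells.
#' @param scheme A [cell_scheme()]; defaults to the table's own.
#' @param k Out-degree (default 8, covering the adjacent neighbors of a
#'   nucleus).
#' @param coincident Either `"error"` (default; 1/0 closeness is
#'   undefined) or `"clamp"` (coincident centroids treated as 1px apart).
#' @param label Optional 1-based class index attached to the graph.
#' @return A `spatial_graph`: list with `X` (N x 11 raw feature matrix),
#'   `node_type` (1-based indices into `scheme$names`), `coords`,
#'   `orientation`, `edges` (list of vectors `src`, `dst`, `type`, `w`
#'   closeness, `a` parallelism), ids, `k`, `scheme`, `label`,
#'   `normalized` flag.
#' @export
build_graph <- function(table, scheme = table$scheme, k = 8L,
                        coincident = c("error", "clamp"), label = NULL) {
  coincident <- match.arg(coincident)
  cells <- table$cells
  N <- nrow(cells)
  if (N < 2L) stop("degenerate input: need at least 2 cells to build a graph")
  if (k < 1L) stop("k must be >= 1")
  kk <- min(as.integer(k), N - 1L)

  co <- cbind(cells$x, cells$y)
  D <- as.matrix(stats::dist(co))
  diag(D) <- Inf
  # per-row partial order; order() is stable with ascending-index tie-break
  nn <- t(apply(D, 1L, function(d) order(d)[seq_len(kk)]))
  src <- rep(seq_len(N), each = kk)
  dst <- as.integer(t(nn))

  dists <- D[cbind(src, dst)]
  if (any(dists == 0)) {
    if (coincident == "error")
      stop("coincident centroids: closeness undefined (set coincident = \"clamp\")")
    dists[dists == 0] <- 1
  }

  ti <- type_index(scheme, cells$cell_type)
  edges <- list(
    src = src,
    dst = dst,
    type = edge_type_code(ti[src] - 1L, ti[dst] - 1L, scheme$n_types),
    w = 1 / dists,
    a = edge_parallelism(cells$orientation[src], cells$orientation[dst])
  )

  X <- as.matrix(cells[, NODE_FEATURES])
  dimnames(X) <- list(NULL, NODE_FEATURES)

  structure(
    list(X = X, node_type = ti, coords = co, orientation = cells$orientation,
         edges = edges, k = as.integer(k), scheme = scheme, label = label,
         patch_id = table$patch_id, slide_id = table$slide_id,
         patient_id = table$patient_id, normalized = FALSE, norm = NULL),
    class = "spatial_graph"
  )
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat("<spatial_graph> ", nrow(x$X), " nodes, ", length(x$edges$src),
      " edges (k = ", x$k, ")", if (isTRUE(x$normalized)) ", normalized",
      "\n  patch ", x$patch_id, " / slide ", x$slide_id, " / patient ",
      x$patient_id, if (!is.null(x$label)) paste0(", label ", x$label),
      "\n", sep = "")
  invisible(x)
}

n_nodes <- function(g) nrow(g$X)

out_degrees <- function(g) tabulate(g$edges$src, n_nodes(g))

#' Fit global centering/scaling statistics for node features
#'
#' Node features are globally centered and scaled before entering the
#' model: the mean and standard deviation of each of the 11 feature
#' columns are pooled over every node of every training graph. Columns
#' with standard deviation below `eps` (constants) have their scale
#' guarded to 1 with a warning, so the transformed column is all zeros.
#'
#' @param graphs Non-empty list of `spatial_graph`s (raw features).
#' @param eps Guard threshold for near-constant columns.
#' @return A `norm_stats` object with `mean`, `sd`, `guarded`, `eps`.
#' @export
fit_normalization <- function(graphs, eps = 1e-8) {
  stopifnot(length(graphs) > 0)
  Xall <- do.call(rbind, lapply(graphs, function(g) g$X))
  mu <- colMeans(Xall)
  sd <- apply(Xall, 2L, stats::sd)
  sd[is.na(sd)] <- 0
  guarded <- sd < eps
  if (any(guarded)) {
    warning("near-constant node feature column(s) guarded: ",
            paste(colnames(Xall)[guarded], collapse = ", "))
    sd[guarded] <- 1
  }
  structure(list(mean = mu, sd = sd, guarded = guarded, eps = eps),
            class = "norm_stats")
}

#' Apply fitted normalization statistics to a graph
#'
#' @param graph A raw `spatial_graph`.
#' @param stats A `norm_stats` from [fit_normalization()]; persisted and
#'   re-applied unchanged to validation/test graphs.
#' @return The graph with standardized `X` and `normalized = TRUE`; the
#'   stats are kept on the graph for the raw-scale gradient chain rule.
#' @export
apply_normalization <- function(graph, stats) {
  stopifnot(inherits(graph, "spatial_graph"), inherits(stats, "norm_stats"))
  if (isTRUE(graph$normalized)) stop("graph is already normalized")
  graph$X <- sweep(sweep(graph$X, 2L, stats$mean, "-"), 2L, stats$sd, "/")
  graph$normalized <- TRUE
  graph$norm <- stats
  graph
}

#' Merge all graphs of one slide into a single disconnected graph
#'
#' Node and edge sets become disjoint unions with node indices
#' reindexed; no edge crosses the original patch components. Used for
#' slide-level prediction with global mean pooling.
#'
#' @param graphs Non-empty list of `spatial_graph`s sharing a `slide_id`.
#' @return One `spatial_graph` with `patch_id` set to
#'   `"<slide_id>:merged"` and a `component` vector mapping nodes to
#'   their source patch.
#' @export
merge_slide_graphs <- function(graphs) {
  stopifnot(length(graphs) > 0)
  sid <- unique(vapply(graphs, function(g) g$slide_id, character(1)))
  if (length(sid) != 1L)
    stop("cannot merge graphs from different slides: ",
         paste(sid, collapse = ", "))
  if (length(graphs) == 1L) return(graphs[[1L]])
  offs <- cumsum(c(0L, vapply(graphs, n_nodes, integer(1))))
  g1 <- graphs[[1L]]
  merged <- structure(
    list(
      X = do.call(rbind, lapply(graphs, function(g) g$X)),
      node_type = unlist(lapply(graphs, function(g) g$node_type)),
      coords = do.call(rbind, lapply(graphs, function(g) g$coords)),
      orientation = unlist(lapply(graphs, function(g) g$orientation)),
      edges = list(
        src = unlist(lapply(seq_along(graphs),
                            function(i) graphs[[i]]$edges$src + offs[i])),
        dst = unlist(lapply(seq_along(graphs),
                            function(i) graphs[[i]]$edges$dst + offs[i])),
        type = unlist(lapply(graphs, function(g) g$edges$type)),
        w = unlist(lapply(graphs, function(g) g$edges$w)),
        a = unlist(lapply(graphs, function(g) g$edges$a))
      ),
      k = g1$k, scheme = g1$scheme, label = g1$label,
      patch_id = paste0(sid, ":merged"), slide_id = sid,
      patient_id = g1$patient_id,
      normalized = isTRUE(g1$normalized), norm = g1$norm,
      component = rep(seq_along(graphs),
                      vapply(graphs, n_nodes, integer(1)))
    ),
    class = "spatial_graph"
  )
  merged
}
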