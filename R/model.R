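softmax_vec <- function(x) {
  if (any(!is.finite(x))) stop("non-finite logits")
  z <- exp(x - max(x))
  z / sum(z)
}

softmax_rows <- function(m) {
  if (any(!is.finite(m))) stop("non-finite logits")
  z <- exp(m - apply(m, 1L, max))
  z / rowSums(z)
}

#' Subgroup mean pooling
#'
#' Graph readout averaging the last-layer outputs of nodes whose type is
#' in the pooling subgroup (e.g. tumor nuclei); global mean pooling is
#' the subgroup = all-types case.
#'
#' @param node_outputs N x K matrix of last-layer node outputs.
#' @param node_types Length-N 1-based type indices.
#' @param scheme The graph's [cell_scheme()].
#' @param subgroup Character subset of type names to average; `NULL`
#'   means all types (global pooling).
#' @return Length-K pooled vector `x_graph`.
#' @export
subgroup_mean_pool <- function(node_outputs, node_types, scheme,
                               subgroup = scheme$subgroup) {
  if (is.null(subgroup)) subgroup <- scheme$names
  keep <- node_types %in% type_index(scheme, subgroup)
  if (!any(keep))
    stop("no nodes of pooling subgroup (", paste(subgroup, collapse = ", "),
         ") present; was the patch filter applied?")
  colMeans(node_outputs[keep, , drop = FALSE])
}

#' Graph-level class probabilities
#'
#' Softmax over the pooled graph logits.
#'
#' @param x_graph Length-K finite logit vector.
#' @return Probability vector (entries in (0,1), summing to 1).
#' @export
graph_probability <- function(x_graph) softmax_vec(x_graph)

#' Per-node class probabilities
#'
#' Row-wise softmax of the last-layer node outputs: the cellular-level
#' prediction that localizes the graph-level call.
#'
#' @param node_outputs N x K matrix.
#' @return N x K matrix of row-stochastic probabilities.
#' @export
node_probabilities <- function(node_outputs) softmax_rows(node_outputs)

#' Assemble a Ceograph model
#'
#' Stacks `n_layers` CSIGC layers whose final width equals the number of
#' prediction categories K, followed by subgroup (or global) mean
#' pooling and a softmax. There is no dense head: pooled channel k is
#' the class-k logit, which is what makes per-node probabilities
#' meaningful. By default the last layer passes through un-activated so
#' pooled values act as signed logits; `final_activation = TRUE`
#' restores a literal per-layer ReLU.
#'
#' @param scheme A [cell_scheme()].
#' @param channels Integer vector of per-layer output widths; the last
#'   entry is K.
#' @param pooling `"subgroup"` or `"global"`.
#' @param subgroup Types pooled when `pooling = "subgroup"`; defaults to
#'   the scheme's subgroup.
#' @param f_in Input node-feature width (11).
#' @param dropout_rate Dropout probability used in training mode.
#' @param film FiLM granularity, see [csigc_params()].
#' @param message_source See [csigc_forward()].
#' @param final_activation Apply ReLU/dropout after the last layer too.
#' @param init_sd Parameter init scale (uses the current RNG state).
#' @param task Optional preset tag carried for bookkeeping.
#' @return A `ceograph_model`.
#' @export
ceograph_model <- function(scheme, channels = c(16L, 16L, 2L),
                           pooling = c("subgroup", "global"),
                           subgroup = scheme$subgroup,
                           f_in = length(NODE_FEATURES),
                           dropout_rate = 0.2,
                           film = c("channel", "element"),
                           message_source = c("neighbor", "self_as_printed"),
                           final_activation = FALSE, init_sd = 0.1,
                           task = NULL) {
  pooling <- match.arg(pooling)
  film <- match.arg(film)
  message_source <- match.arg(message_source)
  if (pooling == "subgroup" && is.null(subgroup))
    stop("subgroup pooling needs a non-empty subgroup")
  L <- length(channels)
  widths <- c(f_in, as.integer(channels))
  layers <- lapply(seq_len(L), function(i)
    csigc_params(scheme$n_types, widths[i], widths[i + 1L], film = film,
                 init_sd = init_sd))
  structure(
    list(layers = layers, channels = as.integer(channels),
         K = as.integer(channels[L]), scheme = scheme, pooling = pooling,
         subgroup = if (pooling == "global") NULL else subgroup,
         dropout_rate = dropout_rate, message_source = message_source,
         final_activation = final_activation, norm = NULL, task = task),
    class = "ceograph_model"
  )
}

#' @export
print.ceograph_model <- function(x, ...) {
  cat("<ceograph_model>", if (!is.null(x$task)) paste0(" [", x$task, "]"),
      "\n  layers: ", length(x$layers), " CSIGC (widths ",
      paste(x$channels, collapse = " -> "), "), K = ", x$K,
      "\n  pooling: ", x$pooling,
      if (x$pooling == "subgroup")
        paste0(" over {", paste(x$subgroup, collapse = ", "), "}"),
      "\n  parameters: ", sum(vapply(x$layers, count_parameters, numeric(1))),
      "\n  normalization: ", if (is.null(x$norm)) "not fitted" else "fitted",
      "\n", sep = "")
  invisible(x)
}

#' Task presets
#'
#' * `lung_subtype`: 6-type lung scheme, 3 CSIGC layers (16, 16, 2),
#'   tumor-subgroup mean pooling; patch filter >= 20 tumor cells.
#' * `opmd_risk`: 4-type oral scheme, 4 layers (16, 16, 16, 2),
#'   epithelial-strata pooling; patch filter >= 50 epithelial nuclei.
#' * `tki_response`: 6-type lung scheme, 3 layers, global mean pooling
#'   on merged per-slide graphs.
#'
#' Hidden widths are package defaults (the published architecture states
#' layer counts and pooling, not widths); override via `channels`.
#'
#' @param task One of `"lung_subtype"`, `"opmd_risk"`, `"tki_response"`.
#' @param channels Optional width override.
#' @param ... Further arguments to [ceograph_model()].
#' @return A `ceograph_model` with a `min_subgroup_cells` attribute
#'   giving the preset patch filter.
#' @export
task_preset <- function(task = c("lung_subtype", "opmd_risk", "tki_response"),
                        channels = NULL, ...) {
  task <- match.arg(task)
  cfg <- switch(task,
    lung_subtype = list(scheme = scheme_lung6(), channels = c(16L, 16L, 2L),
                        pooling = "subgroup", min_cells = 20L),
    opmd_risk = list(scheme = scheme_oral4(), channels = c(16L, 16L, 16L, 2L),
                     pooling = "subgroup", min_cells = 50L),
    tki_response = list(scheme = scheme_lung6(), channels = c(16L, 16L, 2L),
                        pooling = "global", min_cells = 20L)
  )
  m <- ceograph_model(cfg$scheme, channels = channels %||% cfg$channels,
                      pooling = cfg$pooling, task = task, ...)
  attr(m, "min_subgroup_cells") <- cfg$min_cells
  m
}

model_graph_ready <- function(model, graph) {
  if (!isTRUE(graph$normalized) && !is.null(model$norm))
    graph <- apply_normalization(graph, model$norm)
  graph
}

# Forward through all layers keeping per-layer caches when requested.
model_forward_internal <- function(model, graph, training = FALSE,
                                   keep_cache = FALSE) {
  graph <- model_graph_ready(model, graph)
  X <- graph$X
  L <- length(model$layers)
  caches <- if (keep_cache) vector("list", L) else NULL
  for (i in seq_len(L)) {
    act <- i < L || model$final_activation
    cache <- csigc_forward_cache(X, graph$edges, model$layers[[i]],
                                 activation = act,
                                 dropout_rate = model$dropout_rate,
                                 training = training,
                                 message_source = model$message_source)
    if (keep_cache) caches[[i]] <- cache
    X <- cache$out
  }
  x_graph <- subgroup_mean_pool(X, graph$node_type, graph$scheme,
                                if (model$pooling == "global") NULL
                                else model$subgroup)
  list(node_outputs = X, x_graph = x_graph,
       p_graph = graph_probability(x_graph), caches = caches,
       graph = graph)
}

#' Run a model on a graph
#'
#' @param model A `ceograph_model`; if it carries fitted normalization
#'   statistics, raw graphs are standardized on the fly.
#' @param graph A `spatial_graph`.
#' @param training Enable dropout.
#' @return List with `p_graph` (length-K probability vector),
#'   `node_outputs` (N x K last-layer matrix, input to
#'   [node_probabilities()]) and `x_graph` (pooled logits).
#' @export
model_forward <- function(model, graph, training = FALSE) {
  r <- model_forward_internal(model, graph, training = training)
  r[c("p_graph", "node_outputs", "x_graph")]
}

# Cross-entropy loss + full backward pass for one graph.
# target: 1-based class index. Returns loss, per-layer parameter
# gradients, gradient on the (normalized) input features, and
# accumulated gradients on the continuous edge features.
model_backward <- function(model, graph, target, training = FALSE) {
  fw <- model_forward_internal(model, graph, training = training,
                               keep_cache = TRUE)
  K <- model$K
  if (target < 1L || target > K) stop("target class out of range")
  p <- fw$p_graph
  loss <- -log(max(p[target], 1e-300))

  g <- fw$graph
  sub <- if (model$pooling == "global") g$scheme$names else model$subgroup
  keep <- g$node_type %in% type_index(g$scheme, sub)
  nS <- sum(keep)
  d_pool <- p
  d_pool[target] <- d_pool[target] - 1          # dL/dx_graph = P - onehot
  d_nodes <- matrix(0, nrow(g$X), K)
  d_nodes[keep, ] <- matrix(d_pool / nS, nS, K, byrow = TRUE)

  L <- length(model$layers)
  layer_grads <- vector("list", L)
  E <- length(g$edges$src)
  dw <- numeric(E); da <- numeric(E)
  d_out <- d_nodes
  for (i in rev(seq_len(L))) {
    bk <- csigc_backward(fw$caches[[i]], d_out)
    layer_grads[[i]] <- bk$grads
    dw <- dw + bk$dw
    da <- da + bk$da
    d_out <- bk$dX
  }
  list(loss = loss, p_graph = p, grads = layer_grads, dX = d_out,
       dw = dw, da = da, node_outputs = fw$node_outputs)
}
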