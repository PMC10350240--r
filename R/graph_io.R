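#' Write a list of graphs as an on-disk bundle
#'
#' A bundle is a directory holding one JSON manifest plus, per graph,
#' a `<id>.nodes.tsv` (coordinates, type, orientation, 11 features) and
#' a `<id>.edges.tsv` (src, dst, type code, closeness, parallelism),
#' so graphs remain inspectable with plain text tools.
#'
#' @param graphs List of `spatial_graph`s (raw, unnormalized).
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_graph_bundle <- function(graphs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g1 <- graphs[[1L]]
  entries <- lapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]
    id <- sprintf("g%04d", i)
    nodes <- data.frame(x = g$coords[, 1L], y = g$coords[, 2L],
                        cell_type = g$scheme$names[g$node_type],
                        orientation = g$orientation,
                        as.data.frame(g$X), check.names = FALSE)
    ed <- as.data.frame(g$edges)
    for (d in list(nodes, ed)) NULL
    write_full <- function(df, path) {
      num <- vapply(df, is.numeric, logical(1))
      df[num] <- lapply(df[num], function(v)
        format(v, digits = 17, trim = TRUE, scientific = FALSE))
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    write_full(nodes, file.path(dir, paste0(id, ".nodes.tsv")))
    write_full(ed, file.path(dir, paste0(id, ".edges.tsv")))
    list(id = id, patch_id = g$patch_id, slide_id = g$slide_id,
         patient_id = g$patient_id, label = g$label, k = g$k)
  })
  manifest <- list(
    format = "ceograph-graph-bundle-v1",
    scheme = list(names = g1$scheme$names, subgroup = g1$scheme$subgroup),
    graphs = entries
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a graph bundle written by [write_graph_bundle()]
#'
#' @param dir Bundle directory.
#' @return List of `spatial_graph`s.
#' @export
read_graph_bundle <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json under ", dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  scheme <- cell_scheme(mf$scheme$names, mf$scheme$subgroup)
  entries <- mf$graphs
  lapply(seq_len(nrow(entries)), function(i) {
    e <- entries[i, ]
    nodes <- utils::read.table(file.path(dir, paste0(e$id, ".nodes.tsv")),
                               header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE, check.names = FALSE)
    ed <- utils::read.table(file.path(dir, paste0(e$id, ".edges.tsv")),
                            header = TRUE, sep = "\t")
    X <- as.matrix(nodes[, NODE_FEATURES])
    dimnames(X) <- list(NULL, NODE_FEATURES)
    structure(
      list(X = X, node_type = type_index(scheme, nodes$cell_type),
           coords = cbind(nodes$x, nodes$y), orientation = nodes$orientation,
           edges = list(src = as.integer(ed$src), dst = as.integer(ed$dst),
                        type = as.integer(ed$type), w = ed$w, a = ed$a),
           k = as.integer(e$k), scheme = scheme,
           label = if (is.na(e$label %||% NA)) NULL else as.integer(e$label),
           patch_id = e$patch_id, slide_id = e$slide_id,
           patient_id = e$patient_id, normalized = FALSE, norm = NULL),
      class = "spatial_graph"
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
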