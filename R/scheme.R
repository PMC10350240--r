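#' Nuclear morphology feature names, in canonical column order
#'
#' The ten morphology descriptors emitted per nucleus by upstream
#' segmentation, in the fixed order used throughout the package (node
#' feature matrix columns 2..11; column 1 is `confidence`).
#'
#' @format Character vector of length 10.
#' @export
MORPHOLOGY_FEATURES <- c(
  "area", "convex_area", "eccentricity", "extent", "filled_area",
  "major_axis_length", "minor_axis_length", "perimeter_sq_over_area",
  "perimeter", "solidity"
)

#' Node feature names (confidence + morphology), width 11
#' @format Character vector of length 11.
#' @export
NODE_FEATURES <- c("confidence", MORPHOLOGY_FEATURES)

#' Define a cell-type scheme
#'
#' A scheme declares the ordered set of cell-type labels a dataset may use
#' and, optionally, the subset of types averaged by subgroup mean pooling
#' (e.g. tumor nuclei only).
#'
#' @param names Character vector of unique type labels (length T >= 1).
#' @param subgroup Optional character subset of `names` used for pooling.
#' @return An object of class `cell_scheme` with fields `names`, `subgroup`
#'   and `n_types`.
#' @examples
#' sc <- cell_scheme(c("tumor", "stroma"), subgroup = "tumor")
#' sc$n_types
#' @export
cell_scheme <- function(names, subgroup = NULL) {
  if (!is.character(names) || length(names) < 1L || anyDuplicated(names))
    stop("scheme 'names' must be a non-empty character vector without duplicates")
  if (!is.null(subgroup)) {
    bad <- setdiff(subgroup, names)
    if (length(bad))
      stop("subgroup types not in scheme: ", paste(bad, collapse = ", "))
  }
  structure(
    list(names = names, subgroup = subgroup, n_types = length(names)),
    class = "cell_scheme"
  )
}

#' @export
print.cell_scheme <- function(x, ...) {
  cat("<cell_scheme> ", x$n_types, " types: ",
      paste(x$names, collapse = ", "), "\n", sep = "")
  if (!is.null(x$subgroup))
    cat("  pooling subgroup: ", paste(x$subgroup, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Six-type lung tumor microenvironment scheme
#'
#' Tumor, stromal, lymphocyte, red blood cell, macrophage and karyorrhexis
#' nuclei; pooling subgroup is the tumor nuclei. Yields 36 directed edge
#' types.
#' @return A `cell_scheme`.
#' @export
scheme_lung6 <- function() {
  cell_scheme(
    c("tumor", "stroma", "lymphocyte", "red_blood_cell", "macrophage",
      "karyorrhexis"),
    subgroup = "tumor"
  )
}

#' Four-type oral epithelium scheme
#'
#' Stratum corneum, stratum basale, other strata and non-epithelium;
#' pooling subgroup is the three epithelial strata. Yields 16 directed
#' edge types.
#' @return A `cell_scheme`.
#' @export
scheme_oral4 <- function() {
  cell_scheme(
    c("stratum_corneum", "stratum_basale", "other_strata", "non_epithelium"),
    subgroup = c("stratum_corneum", "stratum_basale", "other_strata")
  )
}

type_index <- function(scheme, types) {
  idx <- match(types, scheme$names)
  if (anyNA(idx))
    stop("cell types outside scheme: ",
         paste(unique(types[is.na(idx)]), collapse = ", "))
  idx
}
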