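#' Construct a per-patch cell table
#'
#' Bundles per-nucleus measurements for one image patch together with its
#' provenance (patch / slide / patient identifiers) and acquisition
#' metadata. Coordinates are 0-based pixel positions, x rightward and y
#' downward (image convention); orientation is the angle in degrees in
#' [0, 180) between the x-axis and the nuclear major axis, and values
#' outside that range are wrapped modulo 180 with a warning (an ellipse
#' axis is axial, so 190 degrees and 10 degrees are the same posture).
#'
#' @param cells data.frame with columns `x`, `y`, `cell_type`,
#'   `confidence`, `orientation` and the ten [MORPHOLOGY_FEATURES].
#' @param scheme A [cell_scheme()] declaring admissible `cell_type` values.
#' @param patch_id,slide_id,patient_id Non-empty identifier strings.
#' @param patch_size_px Patch edge length in pixels; all cells must lie in
#'   `[0, patch_size_px)^2`.
#' @param mpp Microns per pixel (informational; 0.25 for 40X scans).
#' @return An object of class `cell_table`.
#' @export
cell_table <- function(cells, scheme, patch_id, slide_id = patch_id,
                       patient_id = slide_id, patch_size_px = 1024L,
                       mpp = 0.25) {
  stopifnot(is.data.frame(cells))
  required <- c("x", "y", "cell_type", "confidence", "orientation",
                MORPHOLOGY_FEATURES)
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols))
    stop("cell table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (id in c(patch_id, slide_id, patient_id))
    if (!is.character(id) || length(id) != 1L || !nzchar(id))
      stop("identifiers must be non-empty strings")
  cells <- cells[, required, drop = FALSE]
  cells$cell_type <- as.character(cells$cell_type)

  out_of_range <- cells$orientation < 0 | cells$orientation >= 180
  if (any(out_of_range, na.rm = TRUE)) {
    warning(sum(out_of_range), " orientation value(s) outside [0,180) wrapped modulo 180")
    cells$orientation <- cells$orientation %% 180
  }

  tab <- structure(
    list(cells = cells, patch_id = patch_id, slide_id = slide_id,
         patient_id = patient_id, patch_size_px = as.integer(patch_size_px),
         mpp = mpp, scheme = scheme),
    class = "cell_table"
  )
  validate_cell_table(tab)
  tab
}

#' Validate a cell table against the per-record invariants
#'
#' Checks ranges (confidence and eccentricity in \[0,1\], extent and
#' solidity in (0,1\]), ordering constraints (minor <= major axis,
#' area <= convex area), non-negativity of all morphology features,
#' coordinates inside the patch, and membership of every `cell_type` in
#' the scheme. Errors name the offending column and 1-based row index.
#'
#' @param tab A `cell_table`.
#' @return `tab`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_cell_table <- function(tab) {
  stopifnot(inherits(tab, "cell_table"))
  cells <- tab$cells
  fail <- function(col, rows) {
    stop("validation error in column '", col, "' at row(s) ",
         paste(utils::head(rows, 5L), collapse = ", "),
         if (length(rows) > 5L) " ..." else "", call. = FALSE)
  }
  chk <- function(ok, col) {
    bad <- which(!ok | is.na(ok))
    if (length(bad)) fail(col, bad)
  }
  if (nrow(cells)) {
    bad_type <- !(cells$cell_type %in% tab$scheme$names)
    if (any(bad_type)) fail("cell_type", which(bad_type))
    chk(cells$x >= 0 & cells$x < tab$patch_size_px, "x")
    chk(cells$y >= 0 & cells$y < tab$patch_size_px, "y")
    chk(cells$confidence >= 0 & cells$confidence <= 1, "confidence")
    chk(cells$orientation >= 0 & cells$orientation < 180, "orientation")
    chk(cells$eccentricity >= 0 & cells$eccentricity <= 1, "eccentricity")
    chk(cells$extent > 0 & cells$extent <= 1, "extent")
    chk(cells$solidity > 0 & cells$solidity <= 1, "solidity")
    chk(cells$minor_axis_length <= cells$major_axis_length + 1e-9,
        "minor_axis_length")
    chk(cells$area <= cells$convex_area + 1e-9, "area")
    for (f in MORPHOLOGY_FEATURES) chk(cells[[f]] >= 0, f)
  }
  invisible(tab)
}

#' Number of cells in a table
#' @param x A `cell_table`.
#' @export
n_cells <- function(x) nrow(x$cells)

#' @export
print.cell_table <- function(x, ...) {
  cat("<cell_table> patch ", x$patch_id, " (slide ", x$slide_id,
      ", patient ", x$patient_id, "): ", n_cells(x), " cells, ",
      x$patch_size_px, "px, ", x$mpp, " mpp\n", sep = "")
  print(table(x$cells$cell_type))
  invisible(x)
}

#' Read a per-cell table from delimited text
#'
#' The expected header uses the documented snake_case names (`x`, `y`,
#' `cell_type`, `confidence`, `orientation`, then the ten
#' [MORPHOLOGY_FEATURES]); `column_map` renames dialects from other
#' upstream tools, as `c(theirs = "ours")`.
#'
#' @param path Path to a CSV (default) or TSV file with a header row.
#' @param scheme A [cell_scheme()]; rows whose type is outside the scheme
#'   cause a validation error.
#' @param patch_id,slide_id,patient_id Identifiers; default to the file
#'   basename.
#' @param patch_size_px,mpp Patch metadata.
#' @param sep Field separator; inferred from the extension when `NULL`.
#' @param column_map Optional named character vector renaming input
#'   columns to the canonical names.
#' @return A validated `cell_table`.
#' @export
read_cell_table <- function(path, scheme, patch_id = NULL, slide_id = NULL,
                            patient_id = NULL, patch_size_px = 1024L,
                            mpp = 0.25, sep = NULL, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    hit <- match(names(df), names(column_map))
    names(df)[!is.na(hit)] <- unname(column_map[hit[!is.na(hit)]])
  }
  base <- sub("\\.[^.]+$", "", basename(path))
  if (is.null(patch_id)) patch_id <- base
  if (is.null(slide_id)) slide_id <- patch_id
  if (is.null(patient_id)) patient_id <- slide_id
  cell_table(df, scheme, patch_id = patch_id, slide_id = slide_id,
             patient_id = patient_id, patch_size_px = patch_size_px,
             mpp = mpp)
}

#' Write a cell table to delimited text
#'
#' Round-trips losslessly with [read_cell_table()] (full double
#' precision via 17 significant digits).
#'
#' @param tab A `cell_table`.
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(tab, path) {
  stopifnot(inherits(tab, "cell_table"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  cells <- tab$cells
  num <- vapply(cells, is.numeric, logical(1))
  cells[num] <- lapply(cells[num], function(v) format(v, digits = 17, trim = TRUE,
                                                      scientific = FALSE))
  utils::write.table(cells, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Count cells of the pooling subgroup
#'
#' @param tab A `cell_table`.
#' @param scheme Scheme whose `subgroup` defines the count; defaults to
#'   the table's own scheme.
#' @return Integer count.
#' @export
count_subgroup_cells <- function(tab, scheme = tab$scheme) {
  sub <- scheme$subgroup
  if (is.null(sub)) sub <- scheme$names
  sum(tab$cells$cell_type %in% sub)
}

#' Keep only informative patches
#'
#' Retains tables with at least `min_subgroup_cells` cells of the
#' scheme's pooling subgroup ("at least" is inclusive: a patch exactly at
#' the threshold is kept). Order is preserved; an empty result is not an
#' error. The published presets use 20 tumor cells (lung subtyping,
#' 1024px patches) and 50 epithelial nuclei (oral epithelium, 2048px
#' patches).
#'
#' @param tables List of `cell_table`s.
#' @param scheme Scheme supplying the subgroup.
#' @param min_subgroup_cells Non-negative integer threshold.
#' @return Filtered list of `cell_table`s.
#' @export
filter_patches <- function(tables, scheme, min_subgroup_cells = 20L) {
  stopifnot(min_subgroup_cells >= 0)
  keep <- vapply(tables, function(t)
    count_subgroup_cells(t, scheme) >= min_subgroup_cells, logical(1))
  tables[keep]
}
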