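# class-conditional baselines for the generator: per-type mean nuclear
# eccentricity, mean log area (px^2 at 0.25 mpp) and mean solidity.
synthetic_type_baselines <- function(names) {
  defaults <- list(
    tumor           = list(ecc = 0.55, logarea = log(900), solidity = 0.92),
    stroma          = list(ecc = 0.78, logarea = log(420), solidity = 0.90),
    lymphocyte      = list(ecc = 0.35, logarea = log(300), solidity = 0.95),
    red_blood_cell  = list(ecc = 0.40, logarea = log(250), solidity = 0.94),
    macrophage      = list(ecc = 0.45, logarea = log(700), solidity = 0.90),
    karyorrhexis    = list(ecc = 0.50, logarea = log(200), solidity = 0.88),
    stratum_corneum = list(ecc = 0.70, logarea = log(500), solidity = 0.90),
    stratum_basale  = list(ecc = 0.45, logarea = log(600), solidity = 0.93),
    other_strata    = list(ecc = 0.55, logarea = log(550), solidity = 0.92),
    non_epithelium  = list(ecc = 0.60, logarea = log(350), solidity = 0.91)
  )
  out <- lapply(names, function(nm)
    defaults[[nm]] %||% list(ecc = 0.5, logarea = log(500), solidity = 0.92))
  names(out) <- names
  out
}

neutral_effects <- function() {
  list(tumor_eccentricity_shift = 0, tumor_solidity_shift = 0,
       alignment_strength = 0, stroma_spacing_scale = 1)
}

#' Declare a synthetic dataset specification
#'
#' Describes a two-class population of simulated cell tables with
#' controllable, fully documented class-discriminative structure. Class
#' 1 is the baseline tissue; class 2 additionally receives the planted
#' `effect_sizes`:
#'
#' * `tumor_eccentricity_shift`: added to the mean eccentricity of the
#'   scheme's first subgroup type (tumor nuclei) — mimics the more
#'   elongated tumor nuclei of one histology subtype.
#' * `tumor_solidity_shift`: likewise for solidity.
#' * `alignment_strength` in \[0, 1\]: class 2 nuclei follow a locally
#'   aligned orientation field with wrapped-normal noise
#'   `sd = 45 * (1 - strength)` degrees (1 = perfectly shared
#'   orientation, hence kNN edge parallelism 1) — mimics structured
#'   architecture.
#' * `stroma_spacing_scale` (neutral 1): class 2 stroma density is
#'   thinned by `1 / scale^2`, so typical stroma-stroma spacing grows by
#'   ~`scale` and stroma-stroma closeness drops (activated-fibroblast
#'   phenotype: fewer, larger, sparser stromal nuclei).
#'
#' @param scheme A [cell_scheme()]; defaults to [scheme_lung6()].
#' @param n_patients_per_class,patches_per_patient Cohort shape.
#' @param cells_per_patch Integer range (min, max), uniform per patch.
#' @param patch_size_px Patch edge (1024 for the lung presets, 2048 for
#'   oral epithelium).
#' @param type_mixture Named proportions over `scheme$names` (sum 1).
#' @param orientation_model Baseline orientation model:
#'   `list(kind = "uniform")` or `list(kind = "locally_aligned",
#'   correlation_length = <px>, noise_sd = <deg>)`.
#' @param density_model `"uniform"` (homogeneous) or `"clustered"`
#'   (parent-offspring clusters).
#' @param effect_sizes Named list overriding entries of the neutral set.
#' @param k kNN out-degree used when building graphs.
#' @param min_subgroup_cells Patch filter applied to generated tables.
#' @param split Named train/val/test patient fractions.
#' @param seed Base seed; every patch seed derives from it.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(scheme = scheme_lung6(),
                           n_patients_per_class = 12L,
                           patches_per_patient = 5L,
                           cells_per_patch = c(80L, 120L),
                           patch_size_px = 1024L,
                           type_mixture = NULL,
                           orientation_model = list(kind = "uniform"),
                           density_model = c("uniform", "clustered"),
                           effect_sizes = list(),
                           k = 8L, min_subgroup_cells = 20L,
                           split = c(train = 0.6, val = 0.2, test = 0.2),
                           seed = 1L) {
  density_model <- match.arg(density_model)
  if (is.null(type_mixture)) {
    type_mixture <- if (identical(scheme$names, scheme_lung6()$names)) {
      c(tumor = 0.40, stroma = 0.25, lymphocyte = 0.20, red_blood_cell = 0.05,
        macrophage = 0.05, karyorrhexis = 0.05)
    } else if (identical(scheme$names, scheme_oral4()$names)) {
      c(stratum_corneum = 0.25, stratum_basale = 0.30, other_strata = 0.30,
        non_epithelium = 0.15)
    } else {
      stats::setNames(rep(1 / scheme$n_types, scheme$n_types), scheme$names)
    }
  }
  if (!setequal(names(type_mixture), scheme$names))
    stop("type_mixture names must match the scheme")
  if (abs(sum(type_mixture) - 1) > 1e-8)
    stop("type_mixture must sum to 1")
  eff <- neutral_effects()
  unknown <- setdiff(names(effect_sizes), names(eff))
  if (length(unknown)) stop("unknown effect(s): ", paste(unknown, collapse = ", "))
  eff[names(effect_sizes)] <- effect_sizes
  if (is.null(orientation_model$correlation_length))
    orientation_model$correlation_length <- patch_size_px
  if (is.null(orientation_model$noise_sd)) orientation_model$noise_sd <- 0

  structure(
    list(scheme = scheme, n_patients_per_class = as.integer(n_patients_per_class),
         patches_per_patient = as.integer(patches_per_patient),
         cells_per_patch = as.integer(cells_per_patch),
         patch_size_px = as.integer(patch_size_px),
         type_mixture = type_mixture[scheme$names],
         orientation_model = orientation_model,
         density_model = density_model, effect_sizes = eff,
         k = as.integer(k), min_subgroup_cells = as.integer(min_subgroup_cells),
         split = split, seed = as.integer(seed),
         baselines = synthetic_type_baselines(scheme$names)),
    class = "synthetic_spec"
  )
}

rbeta_mean <- function(n, mean, conc = 12) {
  mean <- pmin(pmax(mean, 0.02), 0.98)
  stats::rbeta(n, mean * conc, (1 - mean) * conc)
}

# orientation field: piecewise-constant direction per grid cell of edge
# `correlation_length`, plus wrapped-normal noise.
aligned_orientations <- function(x, y, size, correlation_length, noise_sd) {
  ncell <- max(1L, ceiling(size / correlation_length))
  gx <- pmin(floor(x / correlation_length), ncell - 1L)
  gy <- pmin(floor(y / correlation_length), ncell - 1L)
  field <- matrix(stats::runif(ncell^2, 0, 180), ncell, ncell)
  base <- field[cbind(gx + 1L, gy + 1L)]
  (base + stats::rnorm(length(x), 0, noise_sd)) %% 180
}

#' Generate one synthetic cell table
#'
#' Deterministic given `seed`; the caller's RNG state is untouched.
#'
#' @param spec A [synthetic_spec()].
#' @param class_label 1 (baseline) or 2 (planted effects applied).
#' @param seed Integer seed for this patch.
#' @param patch_id,slide_id,patient_id Identifiers.
#' @return A validated `cell_table`.
#' @export
generate_patch <- function(spec, class_label, seed, patch_id = "patch1",
                           slide_id = patch_id, patient_id = slide_id) {
  stopifnot(inherits(spec, "synthetic_spec"), class_label %in% c(1L, 2L))
  eff <- spec$effect_sizes
  size <- spec$patch_size_px
  withr_seed(as.integer(seed), {
    n <- sample(spec$cells_per_patch[1L]:spec$cells_per_patch[2L], 1L)
    if (n < 2L) stop("infeasible spec: fewer than 2 cells per patch")
    types <- sample(spec$scheme$names, n, replace = TRUE,
                    prob = spec$type_mixture)
    if (class_label == 2L && eff$stroma_spacing_scale != 1) {
      st <- which(types == "stroma")
      drop <- st[stats::runif(length(st)) > 1 / eff$stroma_spacing_scale^2]
      if (length(drop) && n - length(drop) >= 2L) {
        types <- types[-drop]
        n <- length(types)
      }
    }

    if (spec$density_model == "uniform") {
      x <- stats::runif(n, 0, size); y <- stats::runif(n, 0, size)
    } else {
      npar <- max(1L, round(n / 15))
      px <- stats::runif(npar, 0, size); py <- stats::runif(npar, 0, size)
      pa <- sample.int(npar, n, replace = TRUE)
      x <- px[pa] + stats::rnorm(n, 0, size / 12)
      y <- py[pa] + stats::rnorm(n, 0, size / 12)
    }
    x <- pmin(pmax(x, 0), size - 1e-3)
    y <- pmin(pmax(y, 0), size - 1e-3)

    om <- spec$orientation_model
    if (class_label == 2L && eff$alignment_strength > 0) {
      orientation <- aligned_orientations(
        x, y, size, om$correlation_length,
        noise_sd = 45 * (1 - eff$alignment_strength))
    } else if (om$kind == "locally_aligned") {
      orientation <- aligned_orientations(x, y, size,
                                          om$correlation_length, om$noise_sd)
    } else {
      orientation <- stats::runif(n, 0, 180)
    }

    base <- spec$baselines[types]
    ecc_mean <- vapply(base, `[[`, numeric(1), "ecc")
    sol_mean <- vapply(base, `[[`, numeric(1), "solidity")
    logarea <- vapply(base, `[[`, numeric(1), "logarea")
    if (class_label == 2L) {
      tum <- types == (spec$scheme$subgroup[1L] %||% spec$scheme$names[1L])
      ecc_mean[tum] <- ecc_mean[tum] + eff$tumor_eccentricity_shift
      sol_mean[tum] <- sol_mean[tum] + eff$tumor_solidity_shift
    }

    ecc <- rbeta_mean(n, ecc_mean, conc = 12)
    solidity <- rbeta_mean(n, sol_mean, conc = 40)
    area <- stats::rlnorm(n, logarea, 0.25)
    # consistent ellipse-derived lengths: area = pi * a * b (semi-axes)
    a <- sqrt(area / (pi * sqrt(1 - ecc^2)))
    b <- a * sqrt(1 - ecc^2)
    # Ramanujan ellipse perimeter, degraded by multiplicative measurement
    # noise: boundary tracing on segmentation masks is much noisier than
    # moment-based quantities, and without this noise perimeter^2/area
    # would be a deterministic monotone proxy of eccentricity
    perim <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b))) *
      stats::rlnorm(n, 0.05, 0.08)

    cells <- data.frame(
      x = x, y = y, cell_type = types,
      confidence = stats::rbeta(n, 20, 2.5),
      orientation = orientation,
      area = area,
      convex_area = area / solidity,
      eccentricity = ecc,
      extent = rbeta_mean(n, 0.72, conc = 30),
      filled_area = area * stats::runif(n, 1.0, 1.03),
      major_axis_length = 2 * a,
      minor_axis_length = 2 * b,
      perimeter_sq_over_area = perim^2 / area,
      perimeter = perim,
      solidity = solidity,
      stringsAsFactors = FALSE
    )
    cell_table(cells, spec$scheme, patch_id = patch_id, slide_id = slide_id,
               patient_id = patient_id, patch_size_px = size, mpp = 0.25)
  })
}

patch_seed <- function(base, i) as.integer((base + 97561 * i) %% 2147483629)

#' Generate a labeled, patient-disjoint synthetic graph dataset
#'
#' Simulates `n_patients_per_class` patients per class with
#' `patches_per_patient` patches each, builds kNN graphs, applies the
#' subgroup patch filter and splits patients into train/val/test
#' (patient- and slide-disjoint by construction). Bit-identical for a
#' given spec + seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `train`, `val`, `test` (lists of labeled raw
#'   `spatial_graph`s), `pools` (named per-patient training pools for
#'   resampling mode) and `manifest` (seed, planted effects, the node
#'   feature(s) expected to discriminate, and the planted direction:
#'   class 2 is the shifted class).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_pat <- spec$n_patients_per_class
  if (n_pat < 3L)
    stop("need at least 3 patients per class for a patient-disjoint split")
  counts <- pmax(round(spec$split * n_pat), 1L)
  while (sum(counts) > n_pat) counts[which.max(counts)] <-
    counts[which.max(counts)] - 1L
  counts[1L] <- n_pat - sum(counts[-1L])

  graphs <- list(train = list(), val = list(), test = list())
  pools <- list()
  gi <- 0L
  for (cl in 1:2) for (p in seq_len(n_pat)) {
    pid <- sprintf("c%dp%02d", cl, p)
    sid <- paste0(pid, "s1")
    assignment <- rep(c("train", "val", "test"), counts)[p]
    patient_graphs <- list()
    for (j in seq_len(spec$patches_per_patient)) {
      gi <- gi + 1L
      tab <- generate_patch(spec, cl, patch_seed(spec$seed, gi),
                            patch_id = sprintf("%s_patch%02d", pid, j),
                            slide_id = sid, patient_id = pid)
      if (count_subgroup_cells(tab, spec$scheme) < spec$min_subgroup_cells)
        next
      patient_graphs[[length(patient_graphs) + 1L]] <-
        build_graph(tab, spec$scheme, k = spec$k, coincident = "clamp",
                    label = cl)
    }
    graphs[[assignment]] <- c(graphs[[assignment]], patient_graphs)
    if (assignment == "train") pools[[pid]] <- patient_graphs
  }

  eff <- spec$effect_sizes
  neutral <- neutral_effects()
  planted <- eff[vapply(names(eff), function(nm)
    !isTRUE(all.equal(eff[[nm]], neutral[[nm]])), logical(1))]
  feature_map <- c(tumor_eccentricity_shift = "eccentricity",
                   tumor_solidity_shift = "solidity")
  disc <- unname(feature_map[intersect(names(planted), names(feature_map))])
  manifest <- list(
    seed = spec$seed, scheme = spec$scheme$names,
    n_patients_per_class = n_pat,
    planted_effects = planted,
    expected_discriminative_features = disc,
    planted_direction = "class 2 carries the positive shift"
  )
  list(train = graphs$train, val = graphs$val, test = graphs$test,
       pools = pools, manifest = manifest)
}
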