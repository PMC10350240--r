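# Programmatic fixtures: every dataset used in tests is built in code.

# A random valid cell table, built directly (independent of the synthetic
# generator) so cell_io/graph tests don't depend on that module.
rand_table <- function(n, scheme = scheme_lung6(), seed = 1,
                       size = 1024L, patch_id = "p1", slide_id = patch_id,
                       patient_id = slide_id, types = NULL) {
  withr::with_seed(seed, {
    ecc <- runif(n, 0.05, 0.95)
    area <- runif(n, 200, 1500)
    a <- sqrt(area / (pi * sqrt(1 - ecc^2)))
    b <- a * sqrt(1 - ecc^2)
    perim <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
    df <- data.frame(
      x = runif(n, 0, size - 1), y = runif(n, 0, size - 1),
      cell_type = types %||% {
        # guarantee subgroup presence so pooling never degenerates
        t <- sample(scheme$names, n, replace = TRUE)
        if (!is.null(scheme$subgroup))
          t[seq_len(min(2L, n))] <- scheme$subgroup[1L]
        t
      },
      confidence = runif(n, 0.5, 1), orientation = runif(n, 0, 180),
      area = area, convex_area = area * runif(n, 1.0, 1.15),
      eccentricity = ecc, extent = runif(n, 0.4, 0.9),
      filled_area = area * runif(n, 1, 1.02),
      major_axis_length = 2 * a, minor_axis_length = 2 * b,
      perimeter_sq_over_area = perim^2 / area, perimeter = perim,
      solidity = runif(n, 0.7, 0.99), stringsAsFactors = FALSE)
    cell_table(df, scheme, patch_id = patch_id, slide_id = slide_id,
               patient_id = patient_id, patch_size_px = size)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_graph <- function(n, seed = 1, k = 8, scheme = scheme_lung6(), ...) {
  build_graph(rand_table(n, scheme, seed, ...), scheme, k = k)
}

# CSIGC params with every block (including FiLM) randomized, so edge
# modulation is active.
rand_params <- function(n_types, f_in, c_out, seed = 1,
                        film = "channel", sd = 0.3) {
  withr::with_seed(seed, {
    p <- csigc_params(n_types, f_in, c_out, film = film, init_sd = sd)
    p$Wg <- matrix(rnorm(length(p$Wg), sd = sd), nrow(p$Wg))
    p$bg <- rnorm(length(p$bg), sd = sd)
    p$Wb <- matrix(rnorm(length(p$Wb), sd = sd), nrow(p$Wb))
    p$bb <- rnorm(length(p$bb), sd = sd)
    p
  })
}

# model with randomized FiLM blocks everywhere
rand_model <- function(scheme = scheme_lung6(), channels = c(8, 8, 2),
                       seed = 1, sd = 0.3, ...) {
  withr::with_seed(seed, {
    m <- ceograph_model(scheme, channels = channels, init_sd = sd, ...)
    for (i in seq_along(m$layers)) {
      l <- m$layers[[i]]
      m$layers[[i]]$Wg <- matrix(rnorm(length(l$Wg), sd = sd), nrow(l$Wg))
      m$layers[[i]]$bg <- rnorm(length(l$bg), sd = sd)
      m$layers[[i]]$Wb <- matrix(rnorm(length(l$Wb), sd = sd), nrow(l$Wb))
      m$layers[[i]]$bb <- rnorm(length(l$bb), sd = sd)
    }
    m
  })
}

# a hand-specified spatial_graph (for degenerate / locality constructions)
manual_graph <- function(X, node_type, edges, scheme = scheme_lung6(),
                         coords = NULL, orientation = NULL, label = NULL,
                         ids = "manual") {
  structure(
    list(X = X, node_type = node_type,
         coords = coords %||% cbind(seq_len(nrow(X)) * 10, 0),
         orientation = orientation %||% rep(0, nrow(X)),
         edges = edges, k = NA_integer_, scheme = scheme, label = label,
         patch_id = ids, slide_id = ids, patient_id = ids,
         normalized = TRUE, norm = NULL),
    class = "spatial_graph")
}

# central finite difference of the reference-class cross-entropy wrt one
# input entry; mutate is a function(graph, delta) -> graph
fd_loss <- function(model, graph, ref, mutate, eps = 1e-4) {
  lp <- -log(model_forward(model, mutate(graph, eps))$p_graph[ref])
  lm <- -log(model_forward(model, mutate(graph, -eps))$p_graph[ref])
  (lp - lm) / (2 * eps)
}

# cached heavy benchmark runs shared between acceptance criteria
.bench_cache <- new.env(parent = emptyenv())
bench_run <- function(seed, effect) {
  key <- paste0(effect, seed)
  if (is.null(.bench_cache[[key]]))
    .bench_cache[[key]] <- run_synthetic_benchmark(seed, effect)
  .bench_cache[[key]]
}
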