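#' Initialize parameters of one CSIGC layer
#'
#' One cell spatial interaction-conditioned graph convolution holds:
#' an edge-type embedding table `EM` (T^2 rows, each a flattened
#' `f_in x c` message modulator), a self-transform `theta` (`f_in x c`),
#' and two linear FiLM maps taking the continuous edge features
#' (closeness w, parallelism a) to per-channel scale `gamma` and shift
#' `beta`. The modulator is applied as `mo * (1 + gamma) + beta`, so
#' zero-initialized FiLM weights leave the embedding untouched.
#'
#' `film = "channel"` (default) emits one scale/shift per output channel
#' (broadcast over the input-feature axis); `film = "element"` emits a
#' full `f_in x c` scale/shift per edge.
#'
#' @param n_types Number of cell types T (edge-type table has T^2 rows).
#' @param f_in Input feature width x.
#' @param c_out Output channel count c (> 0).
#' @param film `"channel"` or `"element"` modulation granularity.
#' @param init_sd Standard deviation of the normal init for `EM` and
#'   `theta`; FiLM weights start at zero (identity modulation). Uses the
#'   current RNG state.
#' @return A `csigc_params` object.
#' @export
csigc_params <- function(n_types, f_in, c_out, film = c("channel", "element"),
                         init_sd = 0.1) {
  film <- match.arg(film)
  if (c_out < 1L) stop("c_out must be a positive channel count")
  if (f_in < 1L || n_types < 1L) stop("invalid shape")
  d <- if (film == "channel") c_out else f_in * c_out
  structure(
    list(
      EM = matrix(stats::rnorm(n_types^2 * f_in * c_out, sd = init_sd),
                  n_types^2, f_in * c_out),
      theta = matrix(stats::rnorm(f_in * c_out, sd = init_sd), f_in, c_out),
      Wg = matrix(0, d, 2L), bg = numeric(d),
      Wb = matrix(0, d, 2L), bb = numeric(d),
      n_types = as.integer(n_types), f_in = as.integer(f_in),
      c_out = as.integer(c_out), film = film
    ),
    class = "csigc_params"
  )
}

#' Stored parameter count of a CSIGC layer
#'
#' `T^2 * f_in * c + f_in * c + 3 * d * 2` where `d = c` for per-channel
#' FiLM (each of the two FiLM maps stores a `d x 2` weight plus a length-d
#' bias) and `d = f_in * c` for per-element FiLM.
#'
#' @param params A `csigc_params`.
#' @return Integer count, equal to an element-by-element enumeration of
#'   the stored arrays.
#' @export
count_parameters <- function(params) {
  UseMethod("count_parameters")
}

#' @export
count_parameters.csigc_params <- function(params) {
  length(params$EM) + length(params$theta) +
    length(params$Wg) + length(params$bg) +
    length(params$Wb) + length(params$bb)
}

# zero-filled gradient container with the same shapes as params
zero_like_params <- function(p) {
  list(EM = matrix(0, nrow(p$EM), ncol(p$EM)),
       theta = matrix(0, nrow(p$theta), ncol(p$theta)),
       Wg = matrix(0, nrow(p$Wg), 2L), bg = numeric(length(p$bg)),
       Wb = matrix(0, nrow(p$Wb), 2L), bb = numeric(length(p$bb)))
}

# rowsum over all N groups (rowsum() drops absent groups)
rowsum_full <- function(m, group, n) {
  out <- matrix(0, n, ncol(m))
  r <- rowsum(m, group)
  out[as.integer(rownames(r)), ] <- r
  out
}

#' CSIGC layer forward pass (vectorized)
#'
#' For every node n and each of its out-neighbors m: the categorical
#' edge type indexes the embedding table to give a modulator
#' `mo (f_in x c)`; FiLM conditioned on (closeness, parallelism) rescales
#' and shifts it; the message is `x_src %*% mo`, where the feature source
#' is the neighbor m by default (`message_source = "neighbor"`) or the
#' node n itself (`"self_as_printed"`). The node output is the self
#' message `x_n %*% theta` plus the average of its edge messages
#' (zero-edge nodes keep the self message alone), optionally followed by
#' ReLU and inverted dropout when `training`.
#'
#' @param graph A `spatial_graph` (normally normalized).
#' @param params A `csigc_params` with `f_in == ncol(graph$X)`.
#' @param activation Apply ReLU + dropout (`TRUE`) or pass through.
#' @param dropout_rate Dropout probability in \[0, 1); active only when
#'   `training` and `activation`.
#' @param training Training-mode flag.
#' @param message_source `"neighbor"` or `"self_as_printed"`.
#' @return N x c output matrix.
#' @export
csigc_forward <- function(graph, params, activation = TRUE,
                          dropout_rate = 0, training = FALSE,
                          message_source = c("neighbor", "self_as_printed")) {
  message_source <- match.arg(message_source)
  csigc_forward_cache(graph$X, graph$edges, params, activation,
                      dropout_rate, training, message_source)$out
}

# Core forward with cache for backprop. X: N x f_in, edges: list(src, dst,
# type, w, a). Message algebra, with Xs the per-edge feature source rows,
# EMr the per-edge embedding rows, G/B the FiLM outputs:
#   channel: me[e, j] = (1 + G[e, j]) * sum_f Xs[e, f] EMr[e, (j-1)F + f]
#                        + B[e, j] * sum_f Xs[e, f]
#   element: me[e, j] = sum_f Xs[e, f] * (EMr * (1+G) + B)[e, (j-1)F + f]
csigc_forward_cache <- function(X, edges, params, activation, dropout_rate,
                                training, message_source) {
  N <- nrow(X); Fi <- params$f_in; cc <- params$c_out
  if (ncol(X) != Fi) stop("feature width ", ncol(X), " != layer f_in ", Fi)
  E <- length(edges$src)
  if (E && (min(edges$type) < 0 || max(edges$type) >= nrow(params$EM)))
    stop("unknown edge-type code")

  self_out <- X %*% params$theta
  cache <- list(X = X, edges = edges, params = params,
                activation = activation, training = training,
                dropout_rate = dropout_rate,
                message_source = message_source, N = N, E = E)

  if (E > 0L) {
    fsrc <- if (message_source == "neighbor") edges$dst else edges$src
    Xs <- X[fsrc, , drop = FALSE]
    EMr <- params$EM[edges$type + 1L, , drop = FALSE]
    WA <- cbind(edges$w, edges$a)
    G <- WA %*% t(params$Wg) + rep(params$bg, each = E)
    B <- WA %*% t(params$Wb) + rep(params$bb, each = E)
    me <- matrix(0, E, cc)
    if (params$film == "channel") {
      sx <- rowSums(Xs)
      base <- matrix(0, E, cc)
      for (j in seq_len(cc)) {
        cols <- ((j - 1L) * Fi + 1L):(j * Fi)
        base[, j] <- rowSums(Xs * EMr[, cols, drop = FALSE])
      }
      me <- base * (1 + G) + sx * B
      cache[c("sx", "base")] <- list(sx, base)
    } else {
      MOD <- EMr * (1 + G) + B
      for (j in seq_len(cc)) {
        cols <- ((j - 1L) * Fi + 1L):(j * Fi)
        me[, j] <- rowSums(Xs * MOD[, cols, drop = FALSE])
      }
      cache$MOD <- MOD
    }
    cnt <- tabulate(edges$src, N)
    agg <- rowsum_full(me, edges$src, N) / pmax(cnt, 1L)
    pre <- self_out + agg
    cache[c("fsrc", "Xs", "EMr", "WA", "G", "B", "cnt")] <-
      list(fsrc, Xs, EMr, WA, G, B, cnt)
  } else {
    pre <- self_out
  }
  cache$pre <- pre

  out <- pre
  if (activation) {
    out <- pmax(out, 0)
    if (training && dropout_rate > 0) {
      mask <- matrix(stats::runif(length(out)) >= dropout_rate,
                     nrow(out), ncol(out)) / (1 - dropout_rate)
      out <- out * mask
      cache$drop_mask <- mask
    }
  }
  cache$out <- out
  cache
}

# Backward pass of one layer. d_out: N x c gradient at the layer output.
# Returns gradients for the inputs (dX), the stored parameters, and the
# continuous edge features (dw, da; the categorical type code has no
# derivative).
csigc_backward <- function(cache, d_out) {
  p <- cache$params
  Fi <- p$f_in; cc <- p$c_out; N <- cache$N; E <- cache$E
  d_pre <- d_out
  if (cache$activation) {
    if (!is.null(cache$drop_mask)) d_pre <- d_pre * cache$drop_mask
    d_pre <- d_pre * (cache$pre > 0)
  }

  grads <- zero_like_params(p)
  grads$theta <- unname(crossprod(cache$X, d_pre))
  dX <- d_pre %*% t(p$theta)
  dw <- numeric(E); da <- numeric(E)

  if (E > 0L) {
    ed <- cache$edges
    d_me <- d_pre[ed$src, , drop = FALSE] / cache$cnt[ed$src]
    Xs <- cache$Xs; EMr <- cache$EMr; G <- cache$G; B <- cache$B
    dXs <- matrix(0, E, Fi)
    dEMr <- matrix(0, E, Fi * cc)
    if (p$film == "channel") {
      d_base <- d_me * (1 + G)
      dG <- d_me * cache$base
      dB <- d_me * cache$sx
      d_sx <- rowSums(d_me * B)
      for (j in seq_len(cc)) {
        cols <- ((j - 1L) * Fi + 1L):(j * Fi)
        dXs <- dXs + d_base[, j] * EMr[, cols, drop = FALSE]
        dEMr[, cols] <- d_base[, j] * Xs
      }
      dXs <- dXs + d_sx
    } else {
      dMOD <- matrix(0, E, Fi * cc)
      for (j in seq_len(cc)) {
        cols <- ((j - 1L) * Fi + 1L):(j * Fi)
        dMOD[, cols] <- d_me[, j] * Xs
        dXs <- dXs + d_me[, j] * cache$MOD[, cols, drop = FALSE]
      }
      dEMr <- dMOD * (1 + G)
      dG <- dMOD * EMr
      dB <- dMOD
    }
    grads$EM <- rowsum_full(dEMr, ed$type + 1L, nrow(p$EM))
    grads$Wg <- crossprod(dG, cache$WA)
    grads$bg <- colSums(dG)
    grads$Wb <- crossprod(dB, cache$WA)
    grads$bb <- colSums(dB)
    dWA <- dG %*% p$Wg + dB %*% p$Wb
    dw <- dWA[, 1L]; da <- dWA[, 2L]
    dX <- dX + rowsum_full(dXs, cache$fsrc, N)
  }
  list(dX = dX, grads = grads, dw = dw, da = da)
}

#' CSIGC layer forward pass, naive per-node reference
#'
#' Literal transcription of the layer's per-node / per-edge loop with no
#' batching; same contract as [csigc_forward()]. Kept as an independent
#' testing oracle — do not use it for work.
#'
#' @inheritParams csigc_forward
#' @return N x c output matrix.
#' @export
csigc_forward_naive <- function(graph, params, activation = TRUE,
                                dropout_rate = 0, training = FALSE,
                                message_source = c("neighbor", "self_as_printed")) {
  message_source <- match.arg(message_source)
  X <- graph$X; ed <- graph$edges
  N <- nrow(X); Fi <- params$f_in; cc <- params$c_out
  out <- matrix(0, N, cc)
  for (n in seq_len(N)) {
    eidx <- which(ed$src == n)
    msgs <- matrix(0, length(eidx), cc)
    for (i in seq_along(eidx)) {
      e <- eidx[i]
      m <- ed$dst[e]
      mo <- matrix(params$EM[ed$type[e] + 1L, ], Fi, cc)
      wa <- c(ed$w[e], ed$a[e])
      gam <- as.numeric(params$Wg %*% wa) + params$bg
      bet <- as.numeric(params$Wb %*% wa) + params$bb
      if (params$film == "channel") {
        for (j in seq_len(cc)) mo[, j] <- mo[, j] * (1 + gam[j]) + bet[j]
      } else {
        mo <- matrix(as.numeric(mo) * (1 + gam) + bet, Fi, cc)
      }
      xsrc <- if (message_source == "neighbor") X[m, ] else X[n, ]
      msgs[i, ] <- as.numeric(matrix(xsrc, 1L, Fi) %*% mo)
    }
    me_self <- as.numeric(matrix(X[n, ], 1L, Fi) %*% params$theta)
    nbr <- if (length(eidx)) colMeans(msgs) else numeric(cc)
    out[n, ] <- me_self + nbr
  }
  if (activation) {
    out <- pmax(out, 0)
    if (training && dropout_rate > 0) {
      mask <- matrix(stats::runif(length(out)) >= dropout_rate,
                     N, cc) / (1 - dropout_rate)
      out <- out * mask
    }
  }
  out
}
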