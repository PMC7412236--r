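#' Embedding configuration for recurrence-plot construction
#'
#' Bundles the delay-embedding and distance parameters that govern how a
#' series is turned into a recurrence image: the phase-space dimension `m`
#' (how many delayed samples form one state), the embedding delay `tau`
#' (the stride between those samples), the state-to-state distance norm,
#' and the optional Heaviside binarization against a threshold `epsilon`.
#'
#' The default norm is `"l2sq"` (squared Euclidean). The recurrence-plot
#' literature usually speaks of the L2 norm, but the worked two-state
#' example that motivates the sign rule (`[1,2,3]` giving off-diagonal
#' pixel value 2) only reproduces under L1 or squared-L2 distance — plain
#' L2 gives sqrt(2). Squared L2 is therefore the package default; `"l1"`,
#' `"l2"` and `"linf"` are available for users who want the classical
#' distances.
#'
#' Binarization (the classical thresholded recurrence plot) is off by
#' default: for classification the raw distance texture is what the
#' networks consume, and thresholding discards it.
#'
#' @param m Phase-space dimension, integer >= 1.
#' @param tau Embedding delay, integer >= 1.
#' @param norm One of `"l1"`, `"l2"`, `"l2sq"`, `"linf"`.
#' @param epsilon Optional non-negative threshold; required when
#'   `binarize = TRUE`.
#' @param binarize If `TRUE`, pixels are Heaviside(epsilon - distance),
#'   i.e. 1 where the two states recur within `epsilon` and 0 elsewhere.
#' @param normalize If `TRUE` (default), series are z-normalized before
#'   embedding (UCR convention); constant series are centered to zero.
#' @return An object of class `embed_config`.
#' @examples
#' embed_config(2, 1)
#' embed_config(3, 4, norm = "l2")
#' @export
embed_config <- function(m = 2L, tau = 1L, norm = c("l2sq", "l1", "l2", "linf"),
                         epsilon = NULL, binarize = FALSE, normalize = TRUE) {
  m <- as.integer(m); tau <- as.integer(tau)
  if (is.na(m) || m < 1L) stop("m must be an integer >= 1")
  if (is.na(tau) || tau < 1L) stop("tau must be an integer >= 1")
  norm <- match.arg(norm)
  if (binarize && is.null(epsilon))
    stop("binarize = TRUE requires a threshold epsilon (the Heaviside step needs it)")
  if (!is.null(epsilon) && (!is.numeric(epsilon) || epsilon < 0))
    stop("epsilon must be a non-negative number")
  structure(list(m = m, tau = tau, norm = norm, epsilon = epsilon,
                 binarize = isTRUE(binarize), normalize = isTRUE(normalize)),
            class = "embed_config")
}

#' @export
print.embed_config <- function(x, ...) {
  cat("<embed_config> m =", x$m, " tau =", x$tau, " norm =", x$norm,
      if (x$binarize) paste0(" binarized at eps = ", x$epsilon) else "",
      if (x$normalize) " (z-normalized)" else "", "\n")
  invisible(x)
}

#' Delay embedding of a series into phase space
#'
#' Maps a series s(1..L) to its N = L - (m-1) tau delayed states; state i
#' is the subsequence `[s(i), s(i+tau), ..., s(i+(m-1) tau)]`. Any
#' z-normalization requested by the config is applied to the series first.
#'
#' @param series Numeric vector or `time_series`.
#' @param config An [embed_config()].
#' @return An object of class `phase_states`: an N x m matrix whose row i
#'   is the i-th state, with the config attached as attribute `config`.
#' @examples
#' embed_series(c(1, 2, 3), embed_config(2, 1, normalize = FALSE))
#' @export
embed_series <- function(series, config = embed_config()) {
  v <- as.numeric(series)
  L <- length(v)
  span <- (config$m - 1L) * config$tau
  if (L < span + 1L)
    stop("embedding infeasible: length L = ", L,
         " is too short for m = ", config$m, ", tau = ", config$tau,
         " (needs L >= ", span + 1L, ")")
  if (config$normalize) v <- znorm(v)
  n <- L - span
  states <- matrix(0, n, config$m)
  for (k in seq_len(config$m))
    states[, k] <- v[seq.int(1L + (k - 1L) * config$tau, length.out = n)]
  structure(states, config = config, source_length = L,
            class = c("phase_states", "matrix", "array"))
}

#' @export
print.phase_states <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<phase_states>", nrow(x), "states in R^", ncol(x),
      " (m =", cfg$m, ", tau =", cfg$tau, ")\n", sep = "")
  print(unclass(x)[seq_len(min(6L, nrow(x))), , drop = FALSE])
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

pairwise_state_distance <- function(states, norm) {
  n <- nrow(states)
  switch(norm,
    # accumulated squared differences (not the polarization identity), so
    # the result is bit-identical to a per-pair loop
    l2sq = {
      dm <- matrix(0, n, n)
      for (k in seq_len(ncol(states)))
        dm <- dm + outer(states[, k], states[, k], "-")^2
      dm
    },
    l2 = sqrt(pairwise_state_distance(states, "l2sq")),
    l1 = {
      dm <- matrix(0, n, n)
      for (k in seq_len(ncol(states)))
        dm <- dm + abs(outer(states[, k], states[, k], "-"))
      dm
    },
    linf = {
      dm <- matrix(0, n, n)
      for (k in seq_len(ncol(states)))
        dm <- pmax(dm, abs(outer(states[, k], states[, k], "-")))
      dm
    },
    stop("unknown norm: ", norm))
}

new_rp_image <- function(pixels, signed, asymmetric, config, source_length) {
  # distance images have a zero diagonal; a binarized plot keeps its line
  # of identity (Heaviside(eps - 0) = 1)
  if (!isTRUE(config$binarize)) diag(pixels) <- 0
  structure(pixels,
            signed = isTRUE(signed), asymmetric = isTRUE(asymmetric),
            meta = list(m = config$m, tau = config$tau, norm = config$norm,
                        source_length = source_length,
                        binarized = isTRUE(config$binarize)),
            class = c("rp_image", "matrix", "array"))
}

#' @export
print.rp_image <- function(x, ...) {
  m <- attr(x, "meta")
  cat("<rp_image> ", nrow(x), "x", ncol(x),
      if (attr(x, "signed")) " signed" else " unsigned",
      if (attr(x, "asymmetric")) " asymmetric" else "",
      if (isTRUE(m$binarized)) " binarized" else "",
      "  (m=", m$m, ", tau=", m$tau, ", norm=", m$norm,
      ", L=", m$source_length, ")\n", sep = "")
  cat("  pixel range [", signif(min(x), 4), ", ", signif(max(x), 4), "]\n",
      sep = "")
  invisible(x)
}

#' Accessors for recurrence-plot images
#'
#' @param x An `rp_image`.
#' @return `rp_pixels` the bare numeric matrix; `rp_meta` the provenance
#'   list (m, tau, norm, source length, binarized flag); `is_signed` /
#'   `is_asymmetric` logical flags.
#' @export
rp_pixels <- function(x) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(x))
  y
}

#' @rdname rp_pixels
#' @export
rp_meta <- function(x) attr(x, "meta")

#' @rdname rp_pixels
#' @export
is_signed <- function(x) isTRUE(attr(x, "signed"))

#' @rdname rp_pixels
#' @export
is_asymmetric <- function(x) isTRUE(attr(x, "asymmetric"))

#' Unsigned recurrence matrix of embedded states
#'
#' The unthresholded recurrence plot: pixel (i, j) is the distance between
#' states i and j under the configured norm, giving a symmetric,
#' non-negative image with a zero diagonal. With `binarize = TRUE` in the
#' config, the classical thresholded plot is returned instead: pixel
#' (i, j) is 1 where the distance is below `epsilon` (a recurrence) and 0
#' elsewhere, the Heaviside step applied to epsilon minus distance.
#'
#' @param states A `phase_states` object from [embed_series()].
#' @param config The [embed_config()]; defaults to the one the states were
#'   embedded with.
#' @return An unsigned `rp_image`.
#' @examples
#' st <- embed_series(c(1, 2, 3), embed_config(2, 1, normalize = FALSE))
#' recurrence_matrix(st)   # [[0, 2], [2, 0]] under the default norm
#' @export
recurrence_matrix <- function(states, config = attr(states, "config")) {
  stopifnot(inherits(states, "phase_states"), nrow(states) >= 1L)
  if (config$binarize && is.null(config$epsilon))
    stop("binarize = TRUE requires epsilon")
  dm <- pairwise_state_distance(unclass(states), config$norm)
  if (config$binarize) {
    # Heaviside(eps - d): 1 for positive argument, 0 for negative; the
    # boundary d == eps counts as a recurrence.
    dm <- (config$epsilon - dm >= 0) + 0
  }
  new_rp_image(dm, signed = FALSE, asymmetric = FALSE, config = config,
               source_length = attr(states, "source_length"))
}

#' Sign mask of embedded states
#'
#' For each pair of states the componentwise difference x(i) - x(j) is
#' summed; the sign of that sum (+1 rising, -1 falling) fills the mask.
#' Multiplying the mask into the distance matrix is what disambiguates
#' rising from falling trends, which the norm alone erases. Pairs whose
#' difference sum is exactly zero (including the diagonal) take the fill
#' value +1, preserving the distance magnitude where opposite component
#' movements cancel.
#'
#' @param states A `phase_states` object.
#' @return A `sign_mask`: an N x N matrix of +1/-1.
#' @examples
#' st <- embed_series(c(1, 2, 3), embed_config(2, 1, normalize = FALSE))
#' sign_mask(st)
#' @export
sign_mask <- function(states) {
  stopifnot(inherits(states, "phase_states"), nrow(states) >= 1L)
  s <- rowSums(unclass(states))
  mask <- sign(outer(s, s, "-"))
  mask[mask == 0] <- 1
  structure(mask, class = c("sign_mask", "matrix", "array"))
}

#' @export
print.sign_mask <- function(x, ...) {
  cat("<sign_mask>", nrow(x), "x", ncol(x), "(",
      sum(x > 0), "positive /", sum(x < 0), "negative )\n")
  invisible(x)
}

#' Signed recurrence matrix
#'
#' Entrywise product of the sign mask and the unsigned recurrence matrix:
#' pixel (i, j) keeps the state distance as magnitude but carries the sign
#' of sum(x(i) - x(j)). Two series with opposite monotone trends, whose
#' unsigned plots are identical, get sign-flipped — hence distinguishable —
#' signed plots. Signing a binarized plot is refused: the 0/1 recurrence
#' texture has no magnitude for the sign to modulate.
#'
#' @inheritParams recurrence_matrix
#' @return A signed `rp_image` with `abs(pixels)` equal to the unsigned
#'   matrix and antisymmetric entries wherever the difference sum is
#'   nonzero.
#' @examples
#' st <- embed_series(c(1, 2, 3), embed_config(2, 1, normalize = FALSE))
#' signed_recurrence_matrix(st)   # [[0, -2], [2, 0]]
#' @export
signed_recurrence_matrix <- function(states, config = attr(states, "config")) {
  if (isTRUE(config$binarize))
    stop("signed RP undefined for binarized images")
  rp <- recurrence_matrix(states, config)
  mask <- sign_mask(states)
  new_rp_image(unclass(rp) * unclass(mask), signed = TRUE, asymmetric = FALSE,
               config = config, source_length = attr(states, "source_length"))
}

#' One-call recurrence-plot encoder
#'
#' Composes delay embedding, distance computation and (optionally) the
#' sign mask into a single call: the image a classifier consumes, before
#' any multi-scale resizing.
#'
#' @param series Numeric vector or `time_series`.
#' @param config An [embed_config()].
#' @param signed If `TRUE`, return the signed recurrence matrix.
#' @return An `rp_image` with provenance (m, tau, norm, source length)
#'   in `rp_meta()`.
#' @examples
#' rp_encode(c(1, 2, 3), embed_config(2, 1, normalize = FALSE))
#' @export
rp_encode <- function(series, config = embed_config(), signed = FALSE) {
  states <- embed_series(series, config)
  if (signed) signed_recurrence_matrix(states, config)
  else recurrence_matrix(states, config)
}
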