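#' Halve a long series into two equal-length pieces
#'
#' Very long sequences are encoded piecewise: the series is split into a
#' first and a second half, each of which is embedded like a short series.
#' Both halves have ceiling(L/2) points; when L is odd the middle point is
#' shared, so the two halves — and hence the two half-images — have equal
#' state counts.
#'
#' @param series Numeric vector or `time_series`, length > 1.
#' @return List with elements `first` and `second` (both `time_series`),
#'   and `overlap` (0 or 1 shared points).
#' @export
split_halves <- function(series) {
  v <- as.numeric(series)
  L <- length(v)
  if (L < 2L) stop("cannot halve a series of length ", L)
  h <- ceiling(L / 2)
  lab <- attr(series, "label")
  list(first = time_series(v[seq_len(h)], label = lab),
       second = time_series(v[seq.int(L - h + 1L, L)], label = lab),
       overlap = 2L * h - L)
}

#' Asymmetric recurrence image for long sequences
#'
#' A sequence longer than the long-series threshold would give an
#' impractically large recurrence image whose downsampling destroys
#' detail. Instead the series is halved, each half is encoded exactly like
#' a short sequence (including the sign mask when `signed = TRUE`), and —
#' because each half-image is redundant across its diagonal — the strict
#' upper triangle of the first half's image and the strict lower triangle
#' of the second half's image are reassembled into one image of half the
#' side length. The diagonal, zero in both halves, stays zero.
#'
#' When the config requests z-normalization it is applied to the full
#' series before splitting, so both halves live on one amplitude scale.
#'
#' @param series Numeric vector or `time_series`.
#' @param config An [embed_config()].
#' @param signed Apply the sign rule to each half.
#' @return An `rp_image` with the `asymmetric` flag set.
#' @export
asymmetric_rp <- function(series, config = embed_config(), signed = FALSE) {
  v <- as.numeric(series)
  if (config$normalize) v <- znorm(v)
  cfg_half <- config
  cfg_half$normalize <- FALSE
  halves <- split_halves(v)
  enc <- function(h) rp_encode(h, cfg_half, signed = signed)
  rp1 <- enc(halves$first)
  rp2 <- enc(halves$second)
  px <- unclass(rp2)
  up <- upper.tri(px)
  px[up] <- unclass(rp1)[up]
  img <- new_rp_image(px, signed = signed, asymmetric = TRUE,
                      config = config, source_length = length(v))
  img
}

# 1D linear-interpolation operator from n input samples to s output
# samples, on the half-pixel-center grid: output center k maps to input
# coordinate (k - 0.5) * n / s + 0.5, clamped at the borders. At s == n
# this is the identity matrix exactly.
interp_operator <- function(n, s) {
  W <- matrix(0, s, n)
  p <- (seq_len(s) - 0.5) * n / s + 0.5
  p <- pmin(pmax(p, 1), n)
  i0 <- pmin(floor(p), n - 1L)
  if (n == 1L) i0 <- rep(1, s)
  frac <- p - i0
  for (k in seq_len(s)) {
    W[k, i0[k]] <- W[k, i0[k]] + (1 - frac[k])
    if (i0[k] < n) W[k, i0[k] + 1L] <- W[k, i0[k] + 1L] + frac[k]
  }
  W
}

#' Bilinear resizing of a recurrence image
#'
#' Resamples an N x N image to `size` x `size` by separable linear
#' interpolation on a transpose-symmetric half-pixel grid: the same 1D
#' operator W is applied to rows and columns (out = W X W'). Because one
#' operator acts on both axes, symmetric inputs stay symmetric and
#' antisymmetric (signed) inputs stay antisymmetric to float precision;
#' at the native size the operator is the identity.
#'
#' @param image An `rp_image` (any numeric matrix is accepted).
#' @param size Target side length, integer >= 2.
#' @return The resized image; `rp_image` provenance is preserved and the
#'   resize recorded in `rp_meta()$resized_from`.
#' @export
resize_image <- function(image, size) {
  size <- as.integer(size)
  if (is.na(size) || size < 2L) stop("target size must be an integer >= 2")
  n <- nrow(image)
  if (n != ncol(image)) stop("recurrence images are square; got ",
                             n, " x ", ncol(image))
  W <- interp_operator(n, size)
  out <- W %*% unclass(image) %*% t(W)
  if (inherits(image, "rp_image")) {
    meta <- attr(image, "meta")
    meta$resized_from <- n
    out <- structure(out, signed = attr(image, "signed"),
                     asymmetric = attr(image, "asymmetric"),
                     meta = meta, class = class(image))
  }
  out
}

#' The multi-scale candidate grid
#'
#' The scale axes of the encoder: the embedding pairs (m, tau), the image
#' side lengths the resized plots may take, whether images are signed, and
#' the series length above which the asymmetric construction is used.
#' Defaults follow the benchmark setup: (m, tau) in {(2,1), (3,4)}, sizes
#' in {16, 48, 64, 80, 96, 112, 128}, signed images, long-series
#' threshold 700.
#'
#' @param mt_pairs List of length-2 integer vectors (m, tau).
#' @param sizes Integer vector of target image side lengths.
#' @param signed Encode signed images.
#' @param long_threshold Series length above which the asymmetric path is
#'   taken.
#' @param norm Distance norm passed through to [embed_config()].
#' @param normalize Per-series z-normalization flag passed through.
#' @return An object of class `scale_grid`.
#' @export
scale_grid <- function(mt_pairs = list(c(2L, 1L), c(3L, 4L)),
                       sizes = c(16L, 48L, 64L, 80L, 96L, 112L, 128L),
                       signed = TRUE, long_threshold = 700L,
                       norm = "l2sq", normalize = TRUE) {
  if (!length(mt_pairs)) stop("mt_pairs must be nonempty")
  mt_pairs <- lapply(mt_pairs, function(p) {
    p <- as.integer(p)
    if (length(p) != 2L || anyNA(p) || any(p < 1L))
      stop("each mt pair must be two positive integers (m, tau)")
    p
  })
  sizes <- sort(unique(as.integer(sizes)))
  if (!length(sizes) || any(sizes < 2L)) stop("sizes must be integers >= 2")
  structure(list(mt_pairs = mt_pairs, sizes = sizes, signed = isTRUE(signed),
                 long_threshold = as.integer(long_threshold),
                 norm = norm, normalize = isTRUE(normalize)),
            class = "scale_grid")
}

#' @export
print.scale_grid <- function(x, ...) {
  cat("<scale_grid> (m,tau):",
      paste(vapply(x$mt_pairs, paste, "", collapse = ","), collapse = " "),
      "| sizes:", paste(x$sizes, collapse = ","),
      "|", if (x$signed) "signed" else "unsigned",
      "| long threshold", x$long_threshold, "\n")
  invisible(x)
}

grid_config <- function(grid, m, tau) {
  embed_config(m, tau, norm = grid$norm, normalize = grid$normalize)
}

#' Encode one series at one scale
#'
#' The canonical per-series pipeline: asymmetric construction when the
#' series exceeds `long_threshold`, plain encoding otherwise; sign mask
#' applied before resizing; bilinear resize to the requested side length.
#'
#' @param series Numeric vector or `time_series`.
#' @param config An [embed_config()].
#' @param signed Apply the sign rule.
#' @param size Target image side length, or `NULL` to keep the native
#'   state count.
#' @param long_threshold Length above which the asymmetric path is taken.
#' @return An `rp_image`.
#' @export
msrp_encode <- function(series, config = embed_config(), signed = TRUE,
                        size = NULL, long_threshold = 700L) {
  L <- length(as.numeric(series))
  img <- if (L > long_threshold) asymmetric_rp(series, config, signed = signed)
         else rp_encode(series, config, signed = signed)
  if (!is.null(size)) img <- resize_image(img, size)
  img
}

#' All candidate images of one series under a scale grid
#'
#' One image per (m, tau, size) triple, in deterministic order (by m, then
#' tau, then size). Combinations whose embedding is infeasible for the
#' series length are skipped and reported via the `failed` attribute
#' rather than aborting the whole grid.
#'
#' @param series Numeric vector or `time_series`.
#' @param grid A [scale_grid()].
#' @return Named list of `rp_image`s (names like `"m2_tau1_s64"`), with
#'   attribute `failed`: a character vector of per-combination error
#'   messages (empty when all succeeded).
#' @export
generate_scales <- function(series, grid = scale_grid()) {
  ord <- order(vapply(grid$mt_pairs, `[`, 0L, 1L),
               vapply(grid$mt_pairs, `[`, 0L, 2L))
  out <- list()
  failed <- character()
  for (p in grid$mt_pairs[ord]) {
    cfg <- grid_config(grid, p[1], p[2])
    base <- tryCatch(
      msrp_encode(series, cfg, signed = grid$signed, size = NULL,
                  long_threshold = grid$long_threshold),
      error = function(e) e)
    if (inherits(base, "error")) {
      failed <- c(failed, sprintf("(m=%d,tau=%d): %s", p[1], p[2],
                                  conditionMessage(base)))
      next
    }
    for (s in grid$sizes)
      out[[sprintf("m%d_tau%d_s%d", p[1], p[2], s)]] <- resize_image(base, s)
  }
  attr(out, "failed") <- failed
  out
}

#' Encode a whole dataset at one scale
#'
#' @param dataset A [ts_dataset()].
#' @param config An [embed_config()].
#' @param signed Apply the sign rule.
#' @param size Target image side length.
#' @param long_threshold Length above which the asymmetric path is taken.
#' @return List with `images` (size x size x n array), `class_id`
#'   (integer labels 1..K), `n_classes`, and `meta`.
#' @export
encode_dataset <- function(dataset, config = embed_config(), signed = TRUE,
                           size = 64L, long_threshold = 700L) {
  n <- n_series(dataset)
  first <- msrp_encode(dataset$values[1L, ], config, signed, size,
                       long_threshold)
  imgs <- array(0, c(nrow(first), ncol(first), n))
  imgs[, , 1L] <- unclass(first)
  if (n > 1L) for (i in 2:n)
    imgs[, , i] <- unclass(msrp_encode(dataset$values[i, ], config, signed,
                                       size, long_threshold))
  list(images = imgs, class_id = dataset$class_id,
       n_classes = dataset$n_classes,
       meta = list(m = config$m, tau = config$tau, norm = config$norm,
                   signed = signed, size = size,
                   asymmetric = ncol(dataset$values) > long_threshold,
                   long_threshold = long_threshold,
                   name = dataset$name, split = dataset$split,
                   label_levels = dataset$label_levels))
}

# Stratified train/validation split: indices of the validation part.
# Every class keeps at least one sample on each side.
stratified_validation_split <- function(class_id, fraction, seed) {
  counts <- table(class_id)
  if (any(counts < 2L))
    stop("stratification error: class ",
         names(counts)[which(counts < 2L)[1]],
         " has fewer than 2 samples, cannot split")
  val <- integer()
  with_seed(seed, {
    for (k in unique(class_id)) {
      idx <- which(class_id == k)
      n_val <- max(1L, min(length(idx) - 1L, round(length(idx) * fraction)))
      val <- c(val, sample(idx, n_val))
    }
  })
  sort(val)
}

#' Validation-driven scale selection
#'
#' Two-stage search over the grid: first the image size is fixed at a
#' pilot value and each (m, tau) pair is scored by validation error of a
#' classifier trained on an internal stratified split of the training
#' set; then the winning (m, tau) is fixed and the remaining sizes are
#' scored, reusing the pilot result. The search therefore trains exactly
#' `length(mt_pairs) + length(sizes) - 1` candidate models. Ties break
#' toward the smaller size and toward the earlier (m, tau) pair in the
#' grid (so (2,1) beats (3,4) under the default grid).
#'
#' @param train A [ts_dataset()] with at least 2 classes.
#' @param grid A [scale_grid()]; the pilot size must be one of its sizes.
#' @param trainer A [trainer_config()]: which network to train, its
#'   training configuration, the pilot size, validation fraction and seed.
#' @return An object of class `scale_choice`: `m`, `tau`, `size`, the
#'   winning `validation_error`, `n_evaluated` (number of trainings), and
#'   `candidates` (a data.frame of every evaluated combination).
#' @export
select_scale <- function(train, grid = scale_grid(), trainer = trainer_config()) {
  if (train$n_classes < 2L)
    stop("scale selection needs at least 2 classes")
  pilot <- trainer$pilot_size
  if (is.null(pilot)) pilot <- if (64L %in% grid$sizes) 64L
                               else grid$sizes[ceiling(length(grid$sizes) / 2)]
  if (!pilot %in% grid$sizes)
    stop("pilot size ", pilot, " is not in the grid sizes")
  val_idx <- stratified_validation_split(train$class_id,
                                         trainer$val_fraction, trainer$seed)
  tr_idx <- setdiff(seq_len(n_series(train)), val_idx)

  eval_candidate <- function(m, tau, size) {
    cfg <- grid_config(grid, m, tau)
    enc <- encode_dataset(train, cfg, signed = grid$signed, size = size,
                          long_threshold = grid$long_threshold)
    spec <- network_spec(trainer$kind, input_size = size,
                         n_classes = train$n_classes)
    model <- train_network(spec, enc$images[, , tr_idx, drop = FALSE],
                           enc$class_id[tr_idx], trainer$train_config)
    pred <- classify_images(model, enc$images[, , val_idx, drop = FALSE])
    error_rate(pred, enc$class_id[val_idx])
  }

  cand <- data.frame(m = integer(), tau = integer(), size = integer(),
                     validation_error = numeric())
  ord <- order(vapply(grid$mt_pairs, `[`, 0L, 1L),
               vapply(grid$mt_pairs, `[`, 0L, 2L))
  # stage 1: fix the pilot size, search (m, tau); first-listed pair wins ties
  best_mt <- NULL; best_err <- Inf
  for (p in grid$mt_pairs[ord]) {
    err <- eval_candidate(p[1], p[2], pilot)
    cand <- rbind(cand, data.frame(m = p[1], tau = p[2], size = pilot,
                                   validation_error = err))
    if (err < best_err) { best_err <- err; best_mt <- p }
  }
  # stage 2: fix (m, tau), search the sizes; smaller size wins ties
  best_size <- pilot
  for (s in grid$sizes) {
    if (s == pilot) next
    err <- eval_candidate(best_mt[1], best_mt[2], s)
    cand <- rbind(cand, data.frame(m = best_mt[1], tau = best_mt[2], size = s,
                                   validation_error = err))
    if (err < best_err || (err == best_err && s < best_size)) {
      best_err <- err; best_size <- s
    }
  }
  structure(list(m = best_mt[1], tau = best_mt[2], size = best_size,
                 validation_error = best_err, n_evaluated = nrow(cand),
                 candidates = cand),
            class = "scale_choice")
}

#' @export
print.scale_choice <- function(x, ...) {
  cat("<scale_choice> (m,tau) = (", x$m, ",", x$tau, "), size = ", x$size,
      "  validation error ", signif(x$validation_error, 4),
      "  [", x$n_evaluated, " candidates trained]\n", sep = "")
  invisible(x)
}

#' Trainer settings used during scale selection
#'
#' @param kind Network architecture, see [network_spec()].
#' @param train_config A [train_config()].
#' @param pilot_size Image size for the stage-1 (m, tau) search; defaults
#'   to 64 when the grid contains it, otherwise the middle grid size.
#' @param val_fraction Fraction of the training set held out, per class.
#' @param seed Seed controlling the stratified split (training seeds come
#'   from `train_config`).
#' @return An object of class `trainer_config`.
#' @export
trainer_config <- function(kind = "fcn", train_config = msrp::train_config(),
                           pilot_size = NULL, val_fraction = 0.2, seed = 1L) {
  structure(list(kind = kind, train_config = train_config,
                 pilot_size = if (is.null(pilot_size)) NULL
                              else as.integer(pilot_size),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "trainer_config")
}
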