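#' Construct a labeled univariate time series
#'
#' The elementary object of the package: a finite univariate sequence of
#' amplitudes, optionally carrying a class label and an identifier.
#'
#' @param values Numeric vector of amplitudes, length at least 2, all finite.
#' @param label Optional class label (kept as-is; coerced to character).
#' @param id Optional identifier string.
#' @return An object of class `time_series`: the numeric vector with
#'   `label` and `id` attributes.
#' @examples
#' s <- time_series(c(1, 2, 3), label = "up")
#' ts_label(s)
#' @export
time_series <- function(values, label = NULL, id = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a time series needs at least 2 points, got ", length(values))
  if (!all(is.finite(values)))
    stop("time series contains non-finite values")
  structure(values,
            label = if (is.null(label)) NULL else as.character(label),
            id = id,
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat("<time_series> length", length(x))
  if (!is.null(attr(x, "label"))) cat(", label", attr(x, "label"))
  if (!is.null(attr(x, "id"))) cat(", id", attr(x, "id"))
  cat("\n")
  utils::str(as.numeric(x))
  invisible(x)
}

#' @rdname time_series
#' @param x A `time_series`.
#' @export
ts_label <- function(x) attr(x, "label")

#' Per-series z-normalization
#'
#' Centers a series to mean zero and scales it to unit standard deviation,
#' the usual preprocessing convention for UCR-style benchmark series. A
#' constant series has zero standard deviation; it is centered to all zeros
#' and left unscaled.
#'
#' @param values Numeric vector or `time_series`.
#' @return The normalized vector, preserving `time_series` attributes.
#' @export
znorm <- function(values) {
  v <- as.numeric(values)
  s <- stats::sd(v)
  out <- if (s > 0) (v - mean(v)) / s else v - mean(v)
  attributes(out) <- attributes(values)
  out
}

#' A labeled collection of equal-length series
#'
#' Container for one split (train or test) of a classification dataset,
#' following the UCR archive convention that all series in a dataset share
#' one length. Labels are stored both as given and remapped to contiguous
#' integer classes 1..K.
#'
#' @param values Numeric matrix, one series per row, or a list of
#'   equal-length numeric vectors.
#' @param labels Vector of class labels, one per series.
#' @param name Optional dataset name.
#' @param split Optional split tag, `"train"` or `"test"`.
#' @param label_levels Optional explicit label universe; defaults to the
#'   sorted unique labels. Supply it to keep train/test integer codings
#'   consistent when a split is missing some class.
#' @return An object of class `ts_dataset` with elements `values` (n x L
#'   matrix), `labels` (original, character), `class_id` (integer 1..K),
#'   `label_levels`, `n_classes`, `name`, `split`.
#' @export
ts_dataset <- function(values, labels, name = NULL, split = NULL,
                       label_levels = NULL) {
  if (is.list(values) && !is.matrix(values)) {
    len <- unique(lengths(values))
    if (length(len) != 1L)
      stop("series have inconsistent lengths: ", paste(len, collapse = ", "))
    values <- do.call(rbind, lapply(values, as.numeric))
  }
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(labels))
    stop("got ", nrow(values), " series but ", length(labels), " labels")
  if (!all(is.finite(values)))
    stop("dataset contains non-finite values")
  labels <- as.character(labels)
  if (is.null(label_levels)) {
    lv <- unique(labels)
    num <- suppressWarnings(as.numeric(lv))
    label_levels <- if (!anyNA(num)) lv[order(num)] else sort(lv)
  }
  if (!all(labels %in% label_levels))
    stop("labels outside the supplied label universe")
  structure(list(values = values,
                 labels = labels,
                 class_id = match(labels, label_levels),
                 label_levels = label_levels,
                 n_classes = length(label_levels),
                 name = name, split = split),
            class = "ts_dataset")
}

#' @export
print.ts_dataset <- function(x, ...) {
  cat("<ts_dataset>", if (!is.null(x$name)) x$name else "",
      if (!is.null(x$split)) paste0("[", x$split, "]") else "", "\n")
  cat("  ", nrow(x$values), "series of length", ncol(x$values),
      "|", x$n_classes, "classes\n")
  tab <- table(x$labels)
  cat("  per class:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @rdname ts_dataset
#' @param x A `ts_dataset`.
#' @param i Series index.
#' @export
ts_get <- function(x, i) {
  time_series(x$values[i, ], label = x$labels[i],
              id = if (!is.null(x$name)) paste0(x$name, "#", i) else NULL)
}

#' @rdname ts_dataset
#' @export
ts_length <- function(x) ncol(x$values)

#' @rdname ts_dataset
#' @export
n_series <- function(x) nrow(x$values)
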