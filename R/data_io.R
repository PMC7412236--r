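#' Read a UCR-style delimited time-series file
#'
#' One record per row: the class label followed by the amplitude values,
#' tab- or comma-separated (auto-detected from the first line). All rows
#' must have the same length; labels are remapped to contiguous integer
#' classes with the mapping recorded on the returned dataset.
#'
#' @param path Path to the file.
#' @param name Dataset name; defaults to the file name stem.
#' @param split Optional `"train"`/`"test"` tag.
#' @param label_levels Optional explicit label universe (to align the
#'   integer coding across a TRAIN/TEST pair).
#' @return A [ts_dataset()].
#' @export
read_ucr <- function(path, name = NULL, split = NULL, label_levels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path)
  sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  lens <- lengths(parts)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1])[1]
    stop("inconsistent length at row ", bad, ": ", lens[bad],
         " fields vs ", lens[1], " in row 1")
  }
  if (lens[1] < 3L)
    stop("rows need a label plus at least 2 values, got ", lens[1], " fields")
  cells <- suppressWarnings(
    vapply(parts, function(p) as.numeric(trimws(p)), numeric(lens[1])))
  if (anyNA(cells)) {
    bad <- which(apply(cells, 2, anyNA))[1]
    stop("non-numeric cell in row ", bad)
  }
  labels <- cells[1, ]
  # integer-valued labels print without decimals (UCR convention)
  labels <- ifelse(labels == round(labels),
                   format(as.integer(round(labels))), format(labels))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  ts_dataset(t(cells[-1, , drop = FALSE]), trimws(labels), name = name,
             split = split, label_levels = label_levels)
}

#' Write a dataset in UCR delimited format
#'
#' @param dataset A [ts_dataset()].
#' @param path Output path.
#' @param sep Field separator, `"\t"` (default) or `","`.
#' @return `path`, invisibly.
#' @export
write_ucr <- function(dataset, path, sep = "\t") {
  stopifnot(inherits(dataset, "ts_dataset"), sep %in% c("\t", ","))
  m <- cbind(dataset$labels,
             format(dataset$values, digits = 17, trim = TRUE,
                    scientific = FALSE))
  writeLines(apply(m, 1, paste, collapse = sep), path)
  invisible(path)
}

#' The packaged 45-dataset benchmark error-rate table
#'
#' The published comparison of nine classifiers on 45 UCR benchmark
#' datasets, shipped as a plain-text fixture: one error rate per dataset
#' and method, plus the per-dataset image size and (m, tau) annotation
#' parsed into metadata, and the standard UCR class counts (needed for
#' the mean per-class error) joined from a companion metadata file.
#'
#' @return A [result_table()] with 45 rows and 9 methods; the annotation
#'   metadata is attached as attribute `scales` (data.frame with columns
#'   `dataset`, `size`, `m`, `tau`).
#' @export
load_table2 <- function() {
  path <- system.file("extdata", "table2_error_rates.tsv", package = "msrp",
                      mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, "220733bdd5208937e05dda6a20a883e4"))
    stop("fixture corruption: table2_error_rates.tsv md5 ", md5,
         " does not match the packaged checksum")
  df <- utils::read.delim(path, check.names = FALSE)
  keys <- df$dataset
  base <- sub("\\(.*", "", keys)
  ann <- regmatches(keys, regexec("\\((\\d+),(\\d+),(\\d+)\\)", keys))
  scales <- data.frame(dataset = base,
                       size = as.integer(vapply(ann, `[`, "", 2)),
                       m = as.integer(vapply(ann, `[`, "", 3)),
                       tau = as.integer(vapply(ann, `[`, "", 4)))
  cc_path <- system.file("extdata", "ucr_class_counts.csv", package = "msrp",
                         mustWork = TRUE)
  cc <- utils::read.csv(cc_path)
  n_classes <- cc$n_classes[match(base, cc$dataset)]
  errors <- as.matrix(df[, -1])
  rownames(errors) <- keys
  tbl <- result_table(errors, dataset_names = keys,
                      method_names = colnames(errors),
                      n_classes = n_classes)
  attr(tbl, "scales") <- scales
  tbl
}

#' Seeded synthetic benchmark generators
#'
#' Reproducible datasets emulating the regimes the encoder is built for:
#'
#' * `"triangle_wave"`: periodic triangle waves with random phase — the
#'   texture used to illustrate how different (m, tau) change the scale
#'   of a recurrence image. Single class.
#' * `"trend_pair"`: two classes with opposite monotone tendencies — a
#'   linearly rising vs falling base plus Gaussian noise. The canonical
#'   showcase for the sign rule: the class prototypes have identical
#'   unsigned recurrence plots.
#' * `"multiclass"`: four classes differing in trend sign, frequency, or
#'   a localized bump (rising, falling, fast sinusoid, Gaussian bump).
#' * `"long"`: the trend pair stretched past the long-series threshold
#'   (length > 700) to exercise the asymmetric path.
#'
#' @param kind One of `"triangle_wave"`, `"trend_pair"`, `"multiclass"`,
#'   `"long"`.
#' @param n_per_class Series per class.
#' @param length Series length; `"long"` requires > 700 (default 720).
#' @param noise_sd Gaussian noise standard deviation (on the unit-range
#'   base signals), >= 0.
#' @param seed RNG seed; the same spec and seed always give the same
#'   dataset.
#' @param name,split Passed to [ts_dataset()].
#' @return A [ts_dataset()].
#' @export
generate_synthetic <- function(kind = c("trend_pair", "triangle_wave",
                                        "multiclass", "long"),
                               n_per_class = 30L, length = 60L,
                               noise_sd = 0.2, seed = 1L,
                               name = NULL, split = NULL) {
  kind <- match.arg(kind)
  n_per_class <- as.integer(n_per_class)
  L <- as.integer(length)
  if (kind == "long" && missing(length)) L <- 720L
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  if (L < 2L) stop("length must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (kind == "long" && L <= 700L)
    stop("kind = 'long' requires length > 700, got ", L)
  t01 <- seq(0, 1, length.out = L)
  # phase grid for periodic kinds: 4 (or 6) whole periods fit exactly
  tper <- (seq_len(L) - 1) / L
  gen <- switch(kind,
    triangle_wave = list("tri" = function() {
      phase <- stats::runif(1)
      # triangle wave with 4 periods over the series
      x <- (tper * 4 + phase) %% 1
      2 * abs(2 * x - 1) - 1
    }),
    trend_pair = ,
    long = list(
      "up"   = function() t01,
      "down" = function() rev(t01)),
    multiclass = list(
      "up"   = function() t01,
      "down" = function() rev(t01),
      "sine" = function() 0.5 * sin(2 * pi * (6 * tper + stats::runif(1))) + 0.5,
      "bump" = function() exp(-0.5 * ((t01 - 0.35) / 0.08)^2)))
  with_seed(seed, {
    vals <- list(); labs <- character()
    for (cls in names(gen)) for (i in seq_len(n_per_class)) {
      vals[[length(vals) + 1L]] <- gen[[cls]]() +
        if (noise_sd > 0) stats::rnorm(L, sd = noise_sd) else 0
      labs <- c(labs, cls)
    }
    ts_dataset(vals, labs, label_levels = names(gen),
               name = if (is.null(name)) paste0("synthetic_", kind) else name,
               split = split)
  })
}

#' Save / load an encoded image stack
#'
#' Serializes the output of [encode_dataset()] (image array, integer
#' labels, scale metadata) to a single-file R container. These are run
#' artifacts, written next to a run's results; they are not a shipped
#' data format.
#'
#' @param stack A list as returned by [encode_dataset()].
#' @param path Output path (conventionally `.rds`).
#' @return `path` invisibly; `load_image_stack` returns the list.
#' @export
save_image_stack <- function(stack, path) {
  stopifnot(is.list(stack), !is.null(stack$images), !is.null(stack$class_id))
  saveRDS(stack, path)
  invisible(path)
}

#' @rdname save_image_stack
#' @export
load_image_stack <- function(path) {
  if (!file.exists(path)) stop("image stack not found: ", path)
  readRDS(path)
}
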