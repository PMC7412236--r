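#' A datasets-by-methods error-rate table
#'
#' The container behind benchmark comparison: an error-rate matrix with
#' one row per dataset and one column per method, optionally carrying
#' per-dataset class counts (needed for the mean per-class error).
#'
#' @param errors Numeric matrix of error rates in \[0, 1\].
#' @param dataset_names,method_names Row/column names; default to the
#'   matrix dimnames.
#' @param n_classes Optional integer vector of per-dataset class counts.
#' @return An object of class `result_table`.
#' @export
result_table <- function(errors, dataset_names = rownames(errors),
                         method_names = colnames(errors), n_classes = NULL) {
  errors <- as.matrix(errors)
  if (is.null(dataset_names))
    dataset_names <- paste0("dataset", seq_len(nrow(errors)))
  if (is.null(method_names))
    method_names <- paste0("method", seq_len(ncol(errors)))
  if (anyNA(errors)) stop("error matrix has missing cells")
  if (any(errors < 0 | errors > 1)) stop("error rates must lie in [0, 1]")
  if (!is.null(n_classes)) {
    n_classes <- as.integer(n_classes)
    if (length(n_classes) != nrow(errors) || anyNA(n_classes) ||
        any(n_classes < 2L))
      stop("n_classes must give one class count (>= 2) per dataset")
  }
  dimnames(errors) <- list(dataset_names, method_names)
  structure(list(errors = errors, dataset_names = dataset_names,
                 method_names = method_names, n_classes = n_classes),
            class = "result_table")
}

#' @export
print.result_table <- function(x, ...) {
  cat("<result_table>", nrow(x$errors), "datasets x", ncol(x$errors),
      "methods", if (!is.null(x$n_classes)) "(with class counts)" else "",
      "\n")
  print(utils::head(x$errors, 4))
  if (nrow(x$errors) > 4) cat("  ...\n")
  invisible(x)
}

check_method <- function(table, method) {
  if (is.null(method)) return(table$method_names)
  miss <- setdiff(method, table$method_names)
  if (length(miss)) stop("unknown method: ", paste(miss, collapse = ", "))
  method
}

#' Number of wins of a method
#'
#' The number of datasets on which a method attains the row-minimum error;
#' every method tied at the minimum counts a win, so ties inflate the
#' column total beyond the number of datasets.
#'
#' @param table A [result_table()].
#' @param method Method name(s); `NULL` (default) for all methods.
#' @return Named integer vector of win counts (a scalar for one method).
#' @export
win_count <- function(table, method = NULL) {
  method <- check_method(table, method)
  mins <- apply(table$errors, 1, min)
  out <- colSums(table$errors[, method, drop = FALSE] == mins)
  if (length(method) == 1L) unname(out) else out
}

#' Mean rank of a method across datasets
#'
#' Methods are ranked 1..M per dataset, ascending by error. Tied errors
#' share the best rank of the tie group under the default `"competition"`
#' convention (1, 1, 3, ...), which is the convention the packaged
#' benchmark table's printed summary rows follow; `"average"` ranks
#' (1.5, 1.5, 3, ...) are also available. The arithmetic mean rank is the
#' plain mean; the geometric mean rank is exp(mean(log(rank))), which is
#' never larger (AM-GM).
#'
#' @param table A [result_table()].
#' @param method Method name(s); `NULL` for all.
#' @param kind `"arithmetic"` or `"geometric"`.
#' @param ties `"competition"` (default) or `"average"`.
#' @return Named numeric vector of mean ranks (a scalar for one method).
#' @export
mean_rank <- function(table, method = NULL,
                      kind = c("arithmetic", "geometric"),
                      ties = c("competition", "average")) {
  method <- check_method(table, method)
  kind <- match.arg(kind)
  ties <- match.arg(ties)
  tm <- if (ties == "competition") "min" else "average"
  ranks <- table$errors
  for (i in seq_len(nrow(ranks)))
    ranks[i, ] <- rank(table$errors[i, ], ties.method = tm)
  ranks <- ranks[, method, drop = FALSE]
  out <- if (kind == "arithmetic") colMeans(ranks)
         else exp(colMeans(log(ranks)))
  if (length(method) == 1L) unname(out) else out
}

#' Mean per-class error of a method
#'
#' The mean over datasets of (error rate / number of classes): dividing
#' by the class count discounts the error a random guesser would make on
#' many-class datasets, making the average comparable across benchmarks
#' with very different class counts.
#'
#' @inheritParams win_count
#' @return Named numeric vector (a scalar for one method).
#' @export
mpce <- function(table, method = NULL) {
  if (is.null(table$n_classes))
    stop("MPCE needs per-dataset class counts; supply n_classes to result_table()")
  method <- check_method(table, method)
  out <- colMeans(table$errors[, method, drop = FALSE] / table$n_classes)
  if (length(method) == 1L) unname(out) else out
}

#' Classification error rate
#'
#' @param predictions Predicted labels.
#' @param labels True labels, same length.
#' @return Fraction misclassified, in \[0, 1\].
#' @export
error_rate <- function(predictions, labels) {
  if (!length(labels)) stop("empty label vector")
  if (length(predictions) != length(labels))
    stop("got ", length(predictions), " predictions for ",
         length(labels), " labels")
  mean(as.character(predictions) != as.character(labels))
}

#' Summary metrics for every method of a result table
#'
#' @param table A [result_table()].
#' @param ties Tie-rank convention for [mean_rank()].
#' @return A data.frame with one row per method: wins, arithmetic and
#'   geometric mean rank, and MPCE when class counts are available.
#' @export
summarize_results <- function(table, ties = "competition") {
  out <- data.frame(method = table$method_names,
                    wins = as.integer(win_count(table)),
                    arithmetic_rank = unname(mean_rank(table, kind = "arithmetic",
                                                       ties = ties)),
                    geometric_rank = unname(mean_rank(table, kind = "geometric",
                                                      ties = ties)))
  if (!is.null(table$n_classes)) out$mpce <- unname(mpce(table))
  out
}

#' Significance tests across methods (thin wrappers)
#'
#' Standard multi-classifier comparison machinery over an error-rate
#' table: a Friedman rank test of the global null that all methods
#' perform alike, and paired Wilcoxon signed-rank tests of one reference
#' method against every other with Holm correction.
#'
#' @param table A [result_table()].
#' @return `friedman_errors`: the `htest` from [stats::friedman.test()].
#' @export
friedman_errors <- function(table) {
  stats::friedman.test(table$errors)
}

#' @rdname friedman_errors
#' @param reference Method to compare against all others.
#' @param alpha Significance level after Holm correction.
#' @return `pairwise_wilcoxon_holm`: data.frame with raw and
#'   Holm-adjusted p-values and a significance flag per competitor.
#' @export
pairwise_wilcoxon_holm <- function(table, reference, alpha = 0.05) {
  reference <- check_method(table, reference)
  others <- setdiff(table$method_names, reference)
  p <- vapply(others, function(mth) {
    suppressWarnings(stats::wilcox.test(table$errors[, reference],
                                        table$errors[, mth],
                                        paired = TRUE, exact = FALSE))$p.value
  }, 0)
  adj <- stats::p.adjust(p, method = "holm")
  data.frame(method = others, p_value = unname(p),
             p_holm = unname(adj), significant = unname(adj < alpha))
}
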