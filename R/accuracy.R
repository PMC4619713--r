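#' Build an error (confusion) matrix
#'
#' Cross-tabulates predicted against ground-truth class labels.
#' Orientation: **rows are predicted classes, columns are ground truth** —
#' both axes are labelled in all outputs to prevent transposition mistakes.
#'
#' @param predicted,truth character vectors of class labels, or pass a
#'   pre-built square count matrix as `predicted` (with `truth` missing).
#' @param labels optional class ordering; defaults to the sorted union.
#' @return An `error_matrix`: an integer matrix with dimnames
#'   `predicted` x `truth`.
#' @export
error_matrix <- function(predicted, truth = NULL, labels = NULL) {
  if (is.matrix(predicted) && is.null(truth)) {
    m <- predicted
    if (nrow(m) != ncol(m)) stop("matrix must be square", call. = FALSE)
    if (any(m < 0) || any(m != round(m)))
      stop("counts must be non-negative integers", call. = FALSE)
    if (sum(m) == 0) stop("all-zero error matrix", call. = FALSE)
    if (is.null(dimnames(m))) {
      lb <- if (is.null(labels)) paste0("class", seq_len(nrow(m))) else labels
      dimnames(m) <- list(lb, lb)
    }
  } else {
    if (length(predicted) != length(truth))
      stop("predicted and truth must have equal length", call. = FALSE)
    if (is.null(labels)) labels <- sort(union(unique(predicted), unique(truth)))
    m <- table(factor(predicted, levels = labels),
               factor(truth, levels = labels))
    m <- matrix(as.integer(m), length(labels), length(labels),
                dimnames = list(labels, labels))
  }
  names(dimnames(m)) <- c("predicted", "truth")
  structure(m, class = c("error_matrix", class(matrix())))
}

#' Accuracy statistics from an error matrix
#'
#' Overall accuracy is the proportion of correctly classified samples (the
#' diagonal) over all samples. Producer's accuracy for a class is the
#' fraction of that class's ground-truth samples that were classified
#' correctly (column-wise recall); user's accuracy is the fraction of the
#' samples *predicted* as that class that are correct (row-wise precision).
#' A class with a zero margin yields `NA` (reported missing, never 0).
#'
#' @param m an [error_matrix()] (or square count matrix).
#' @return List with `overall_pct` and a data.frame `per_class`
#'   (`class`, `producers_pct`, `users_pct`).
#' @export
matrix_stats <- function(m) {
  m <- as_error_matrix(m)
  tot <- sum(m)
  overall <- 100 * sum(diag(m)) / tot
  col_tot <- colSums(m)
  row_tot <- rowSums(m)
  producers <- ifelse(col_tot > 0, 100 * diag(m) / col_tot, NA_real_)
  users <- ifelse(row_tot > 0, 100 * diag(m) / row_tot, NA_real_)
  list(overall_pct = overall,
       per_class = data.frame(class = rownames(m),
                              producers_pct = as.vector(producers),
                              users_pct = as.vector(users)))
}

#' Cohen's kappa with interpretation band
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with
#' observed agreement `p_o = trace/total` and expected agreement under
#' independence `p_e = sum(row_c * col_c) / total^2`. Interpretation bands:
#' below 0.20 poor, 0.20-0.40 fair, 0.40-0.60 moderate, 0.60-0.80 good,
#' 0.80-1 very good (half-open on the left; negative values are labelled
#' "worse than chance"). When `p_e = 1` (all mass in a single class on both
#' axes) kappa is undefined and reported as `NA`.
#'
#' @param m an [error_matrix()] (or square count matrix).
#' @return List with `kappa` and `band`.
#' @export
cohen_kappa <- function(m) {
  m <- as_error_matrix(m)
  tot <- sum(m)
  po <- sum(diag(m)) / tot
  pe <- sum(rowSums(m) * colSums(m)) / tot^2
  if (abs(1 - pe) < 1e-12)
    return(list(kappa = NA_real_, band = NA_character_))
  k <- (po - pe) / (1 - pe)
  list(kappa = k, band = kappa_band(k))
}

#' Interpretation band for a kappa value
#'
#' @param kappa numeric kappa value(s).
#' @return Character band label(s).
#' @export
kappa_band <- function(kappa) {
  vapply(kappa, function(k) {
    if (is.na(k)) return(NA_character_)
    if (k < 0) "worse than chance"
    else if (k < 0.20) "poor"
    else if (k < 0.40) "fair"
    else if (k < 0.60) "moderate"
    else if (k < 0.80) "good"
    else "very good"
  }, character(1))
}

as_error_matrix <- function(m) {
  if (!inherits(m, "error_matrix")) m <- error_matrix(m)
  m
}

#' @export
print.error_matrix <- function(x, ...) {
  cat("Error matrix (rows = predicted, columns = truth)\n")
  print(unclass(x))
  st <- matrix_stats(x)
  kp <- cohen_kappa(x)
  cat(sprintf("Overall accuracy %.2f%%; kappa %.3f (%s)\n", st$overall_pct,
              kp$kappa, kp$band))
  invisible(x)
}
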