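#' Pearson product-moment correlation with explicit undefined handling
#'
#' On 0/1 indicator vectors this is the phi coefficient; on 0/1/2 ordinal
#' item codes it is the plain product-moment correlation the same way a
#' correlation matrix over questionnaire items is usually computed. A
#' constant vector has no defined correlation and yields `NA` (flagged via
#' attribute `"undefined"`), never a silent 0.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in [-1, 1], or flagged `NA` if either input is
#'   constant.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  stats::cor(x, y, method = "pearson")
}

#' Fisher z-transform confidence interval for a correlation
#'
#' tanh(atanh(r) +/- z_{level} / sqrt(n - 3)). With |r| = 1 the transform
#' diverges and the interval is returned degenerate at r with a flag.
#'
#' @param r Sample correlation, |r| <= 1.
#' @param n Sample size, n >= 4.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' pearson_ci(0.81, 102)  # about [0.73, 0.87]
#' @export
pearson_ci <- function(r, n, level = 0.95) {
  stopifnot(abs(r) <= 1, n >= 4, level > 0, level < 1)
  if (abs(r) == 1) {
    return(structure(c(lower = r, upper = r), degenerate = TRUE))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z / sqrt(n - 3)
  c(lower = tanh(atanh(r) - half), upper = tanh(atanh(r) + half))
}

#' Cross-scale item correlation matrix
#'
#' Pearson correlations of every binary screening item (0/1) against every
#' ordinal reference item (0/1/2), with the correlation between the two
#' total scores (and its Fisher-z interval) attached as attributes.
#' Constant columns produce flagged `NA` entries; the matrix is still
#' returned so one degenerate item never aborts a batch report.
#'
#' @param cohort Cohort data frame with `zfs_*` and `msega_*` columns
#'   (see [read_cohort()]).
#' @param level Confidence level for the totals-correlation interval.
#' @return A 6 x 13 numeric matrix (rows = ZFS items, columns = mSEGA
#'   items) of class `item_matrix`, with attributes `totals_r`,
#'   `totals_ci`, `n`.
#' @export
item_matrix <- function(cohort, level = 0.95) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 3)
  zcols <- paste0("zfs_", zfs_items())
  mcols <- paste0("msega_", msega_items())
  missing_cols <- setdiff(c(zcols, mcols), names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  zmat <- sapply(cohort[zcols], normalize_binary)
  mmat <- as.matrix(cohort[mcols])
  m <- matrix(NA_real_, length(zcols), length(mcols),
              dimnames = list(zfs_items(), msega_items()))
  for (i in seq_along(zcols)) {
    for (j in seq_along(mcols)) {
      m[i, j] <- as.numeric(pearson_r(zmat[, i], mmat[, j]))
    }
  }
  totals_z <- rowSums(zmat)
  totals_m <- rowSums(mmat)
  r <- pearson_r(totals_z, totals_m)
  attr(m, "totals_r") <- as.numeric(r)
  attr(m, "totals_ci") <- if (is.na(r)) c(lower = NA_real_, upper = NA_real_)
                          else pearson_ci(as.numeric(r), nrow(cohort), level)
  attr(m, "n") <- nrow(cohort)
  class(m) <- c("item_matrix", "matrix", "array")
  m
}

#' @export
print.item_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("item correlation matrix (n = %d patients)\n", attr(x, "n")))
  print(round(unclass(x), digits))
  r <- attr(x, "totals_r"); ci <- attr(x, "totals_ci")
  if (!is.na(r)) {
    cat(sprintf("total-score correlation r = %.2f [%.2f; %.2f]\n",
                r, ci[["lower"]], ci[["upper"]]))
  } else {
    cat("total-score correlation undefined (constant totals)\n")
  }
  invisible(x)
}

#' Write an item correlation matrix as delimited text
#'
#' @param matrix An [item_matrix()].
#' @param path Output file path.
#' @param na_token Sentinel written for undefined entries (default
#'   `"undefined"`), so a missing correlation is never mistaken for 0.
#' @return `path`, invisibly.
#' @export
write_item_matrix <- function(matrix, path, na_token = "undefined") {
  stopifnot(inherits(matrix, "item_matrix"))
  df <- as.data.frame(unclass(matrix))
  df <- cbind(item = rownames(matrix), df)
  utils::write.csv(df, path, row.names = FALSE, na = na_token)
  invisible(path)
}
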