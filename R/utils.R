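#' Counts per million
#'
#' Library-size normalization: each column is scaled to sum to one million.
#'
#' @param counts Numeric matrix, features x samples. Column sums must be
#'   positive.
#' @return Matrix of the same dimensions with \code{cpm(g, s) = 1e6 *
#'   counts[g, s] / sum(counts[, s])}.
#' @export
cpm <- function(counts) {
  counts <- as.matrix(counts)
  cs <- colSums(counts)
  if (any(cs <= 0)) {
    stop("zero or negative column sum in sample(s): ",
         paste(colnames(counts)[cs <= 0], collapse = ", "))
  }
  sweep(counts, 2L, cs, "/") * 1e6
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment via \code{stats::p.adjust}. \code{NA} values are
#' ignored (they do not enter the denominator) and propagated.
#'
#' @param p Numeric vector of p-values in \[0, 1\], \code{NA} allowed.
#' @return Adjusted p-values, same length and order as \code{p}.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Simes combination of p-values
#'
#' \code{min_i p_(i) * m / i} over the sorted p-values: the region-level
#' combination used before region FDR correction. \code{NA}s are dropped;
#' all-\code{NA} input returns \code{NA}.
#'
#' @param p Numeric vector of p-values.
#' @return A single combined p-value.
#' @export
simes_p <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0L) return(NA_real_)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  min(sort(p) * m / seq_len(m))
}

#' Spurious-spike pass threshold
#'
#' Maximum tolerated within-group count proportion for a single replicate,
#' \code{coef * n^(-exp)} with defaults 1.4 and 0.66. A gene whose largest
#' replicate proportion reaches or exceeds this value in a group is flagged
#' as a potential single-replicate artifact.
#'
#' @param n Number of replicates in the group.
#' @param coef,exp Threshold constants.
#' @return Numeric threshold, strictly decreasing in \code{n}.
#' @export
spike_threshold <- function(n, coef = 1.4, exp = 0.66) {
  stopifnot(n >= 1, coef > 0, exp > 0)
  coef * n^(-exp)
}

## internal: write a data.frame as TSV with stable formatting
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
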