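#' Per-sample biotype composition
#'
#' Percentage of counted reads attributed to each gene biotype, per sample.
#' Genes missing from the biotype map fall into an "unannotated" bucket so
#' that rows always sum to 100.
#'
#' @param counts Integer matrix, genes x samples (rownames = gene ids).
#' @param biotype_map data.frame with columns \code{gene}, \code{biotype}.
#' @return Matrix samples x biotypes of percentages (rows sum to 100).
#' @export
biotype_fractions <- function(counts, biotype_map) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  bt <- biotype_map$biotype[match(rownames(counts), biotype_map$gene)]
  bt[is.na(bt)] <- "unannotated"
  by_bt <- rowsum(counts, group = bt)
  frac <- t(sweep(by_bt, 2L, tot, "/")) * 100
  frac[, order(colnames(frac)), drop = FALSE]
}

#' Retain biotypes above a prevalence floor
#'
#' A biotype is kept iff it reaches at least \code{min_pct} percent of reads
#' in at least one sample (boundary inclusive).
#'
#' @param fractions Samples x biotypes percentage matrix from
#'   \code{\link{biotype_fractions}}.
#' @param min_pct Retention threshold in percent.
#' @return Character vector of retained biotype names.
#' @export
retain_major_biotypes <- function(fractions, min_pct = 1) {
  keep <- apply(fractions, 2L, max) >= min_pct
  colnames(fractions)[keep]
}

#' Flag per-group biotype outliers by the 1.5 x IQR rule
#'
#' Within each treatment group and biotype, a sample is flagged when its
#' percentage lies strictly below Q1 - multiplier * IQR or strictly above
#' Q3 + multiplier * IQR (quartiles by linear interpolation, type 7).
#' Groups with fewer than 3 samples are skipped with a warning.
#'
#' @param fractions Samples x biotypes percentage matrix.
#' @param groups Character vector of group labels, one per sample (in the
#'   row order of \code{fractions}).
#' @param multiplier Fence multiplier on the IQR.
#' @return List with \code{flags} (data.frame sample, biotype, group, side,
#'   value) and \code{fences} (data.frame group, biotype, lower, upper).
#' @export
flag_outliers_iqr <- function(fractions, groups, multiplier = 1.5) {
  stopifnot(nrow(fractions) == length(groups))
  flags <- list(); fences <- list()
  for (grp in unique(groups)) {
    idx <- which(groups == grp)
    if (length(idx) < 3L) {
      warning("group '", grp, "' has fewer than 3 samples; skipped")
      next
    }
    for (bt in colnames(fractions)) {
      v <- fractions[idx, bt]
      q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
      iqr <- q[2] - q[1]
      lo <- q[1] - multiplier * iqr
      hi <- q[2] + multiplier * iqr
      fences[[length(fences) + 1L]] <-
        data.frame(group = grp, biotype = bt, lower = lo, upper = hi)
      out_lo <- v < lo
      out_hi <- v > hi
      if (any(out_lo | out_hi)) {
        flags[[length(flags) + 1L]] <- data.frame(
          sample = rownames(fractions)[idx][out_lo | out_hi],
          biotype = bt, group = grp,
          side = ifelse(out_lo[out_lo | out_hi], "low", "high"),
          value = v[out_lo | out_hi])
      }
    }
  }
  empty <- data.frame(sample = character(0), biotype = character(0),
                      group = character(0), side = character(0),
                      value = numeric(0))
  list(flags = if (length(flags)) do.call(rbind, flags) else empty,
       fences = if (length(fences)) do.call(rbind, fences) else
         data.frame(group = character(0), biotype = character(0),
                    lower = numeric(0), upper = numeric(0)))
}

#' Split one biotype out of a count matrix
#'
#' Exact partition of the genes: the named biotype's genes go to the second
#' matrix, all remaining genes to the first. Used to analyze snoRNA genes
#' separately when variable-PCR-cycle libraries inflate their share and
#' would bias library-size normalization of the main dataset.
#'
#' @param counts Genes x samples matrix.
#' @param biotype_map data.frame gene/biotype.
#' @param biotype Biotype to split off (default "snoRNA").
#' @return List with \code{main} and \code{split} count matrices.
#' @export
split_biotype <- function(counts, biotype_map, biotype = "snoRNA") {
  bt <- biotype_map$biotype[match(rownames(counts), biotype_map$gene)]
  sel <- !is.na(bt) & bt == biotype
  if (!any(sel))
    warning("no genes of biotype '", biotype, "' present")
  list(main = counts[!sel, , drop = FALSE],
       split = counts[sel, , drop = FALSE])
}

#' Drop samples flagged as outliers in key biotypes
#'
#' Pipeline-level consequence of \code{\link{flag_outliers_iqr}}: samples
#' flagged (either side) in any of the listed biotypes are removed; flags in
#' other biotypes are reported but not acted on.
#'
#' @param counts Genes x samples matrix.
#' @param design Sample sheet (data.frame with a \code{sample} column).
#' @param outliers Result of \code{\link{flag_outliers_iqr}}.
#' @param drop_biotypes Biotypes whose flags trigger removal.
#' @return List with filtered \code{counts}, \code{design}, and
#'   \code{removed} sample names.
#' @export
drop_flagged_samples <- function(counts, design, outliers,
                                 drop_biotypes = c("protein_coding",
                                                   "miRNA")) {
  bad <- unique(outliers$flags$sample[
    outliers$flags$biotype %in% drop_biotypes])
  keep <- !(colnames(counts) %in% bad)
  list(counts = counts[, keep, drop = FALSE],
       design = design[design$sample %in% colnames(counts)[keep], ,
                       drop = FALSE],
       removed = bad)
}
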