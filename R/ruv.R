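#' Unwanted-variation factors from negative-control genes
#'
#' Factor analysis of technical variation: the first \code{k} left singular
#' vectors (sample space) of the per-gene-centered log(count + pseudocount)
#' matrix restricted to control genes — genes assumed unaffected by the
#' condition, so shared variation among them is nuisance. The factors are
#' meant to be used as covariates in downstream GLMs, not to produce
#' "corrected" counts.
#'
#' @param counts Genes x samples count matrix.
#' @param control_genes Gene ids assumed unaffected by condition. If
#'   \code{NULL}, empirical controls are used: the least-significant half of
#'   genes from \code{first_pass_p} (required in that case).
#' @param k Number of factors (>= 1, less than the number of samples).
#' @param pseudocount Added before the log.
#' @param first_pass_p Optional per-gene p-values from an unadjusted
#'   first-pass test, used to pick empirical controls.
#' @return List of class \code{nuisance_factors}: \code{W} (samples x k,
#'   orthonormal columns), \code{explained_variance} (fraction per factor),
#'   \code{control_genes}.
#' @export
ruv_control_genes <- function(counts, control_genes = NULL, k = 2,
                              pseudocount = 1, first_pass_p = NULL) {
  counts <- as.matrix(counts)
  stopifnot(k >= 1, k < ncol(counts))
  if (is.null(control_genes)) {
    if (is.null(first_pass_p))
      stop("either control_genes or first_pass_p must be given")
    stopifnot(length(first_pass_p) == nrow(counts))
    ord <- order(first_pass_p, decreasing = TRUE)
    control_genes <- rownames(counts)[ord[seq_len(ceiling(nrow(counts) / 2))]]
  }
  if (!all(control_genes %in% rownames(counts)))
    stop("control genes absent from the count matrix")
  z <- t(log(counts[control_genes, , drop = FALSE] + pseudocount))
  z <- scale(z, center = TRUE, scale = FALSE)   # center each gene
  sv <- svd(z)
  r <- sum(sv$d > max(dim(z)) * .Machine$double.eps * sv$d[1])
  if (k > r) stop("k = ", k, " exceeds the rank (", r,
                  ") of the control-gene submatrix")
  W <- sv$u[, seq_len(k), drop = FALSE]
  rownames(W) <- colnames(counts)
  colnames(W) <- paste0("W", seq_len(k))
  structure(list(W = W,
                 explained_variance = sv$d[seq_len(k)]^2 / sum(sv$d^2),
                 control_genes = control_genes),
            class = "nuisance_factors")
}

#' Unwanted-variation factors from replicate sets
#'
#' Variant for designs with replicate structure: log counts are centered
#' within each replicate set, and the first \code{k} left singular vectors
#' of the stacked centered matrix give the nuisance directions in sample
#' space. Replicate sets must be condition-homogeneous (samples within a
#' set share the biology), so that centering removes the signal and leaves
#' only unwanted variation; a set that mixes conditions would absorb the
#' condition effect into the factors. Singleton replicate sets carry no
#' information and are excluded from the SVD with a warning (their factor
#' rows are zero).
#'
#' @param counts Features x samples matrix.
#' @param replicate_sets Character/factor vector, one set id per sample.
#' @param k Number of factors.
#' @param pseudocount Added before the log.
#' @return A \code{nuisance_factors} list as in
#'   \code{\link{ruv_control_genes}}.
#' @export
ruv_replicates <- function(counts, replicate_sets, k = 5, pseudocount = 1) {
  counts <- as.matrix(counts)
  stopifnot(length(replicate_sets) == ncol(counts), k >= 1,
            k < ncol(counts))
  z <- t(log(counts + pseudocount))   # samples x features
  sets <- as.character(replicate_sets)
  sizes <- table(sets)
  if (any(sizes < 2))
    warning("singleton replicate set(s) excluded: ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
  zc <- z * 0
  for (s in names(sizes)[sizes >= 2]) {
    idx <- which(sets == s)
    zc[idx, ] <- scale(z[idx, , drop = FALSE], center = TRUE, scale = FALSE)
  }
  sv <- svd(zc)
  r <- sum(sv$d > max(dim(zc)) * .Machine$double.eps * max(sv$d, 1e-300))
  if (k > r) stop("k = ", k, " exceeds the rank (", r,
                  ") of the replicate-centered matrix")
  W <- sv$u[, seq_len(k), drop = FALSE]
  rownames(W) <- colnames(counts)
  colnames(W) <- paste0("W", seq_len(k))
  structure(list(W = W,
                 explained_variance = sv$d[seq_len(k)]^2 / sum(sv$d^2),
                 control_genes = NULL),
            class = "nuisance_factors")
}
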