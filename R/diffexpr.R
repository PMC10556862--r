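#' Configuration for the differential expression stage
#'
#' Relevance filtering at \code{min_cpm} in at least \code{min_frac} of the
#' samples of either group, BH FDR threshold, the spurious-spike constants,
#' and the dose codes pooled into "treatment" (the top code is excluded by
#' default because its response diverges from the rest of the series).
#'
#' @param min_cpm CPM floor for the relevance filter.
#' @param min_frac Minimum fraction of samples at or above \code{min_cpm}.
#' @param fdr BH threshold for calling differential expression.
#' @param spike_coef,spike_exp Constants of the spike threshold
#'   \code{coef * n^(-exp)}.
#' @param pool_doses Dose codes pooled as treatment.
#' @return List of class \code{de_config}.
#' @export
de_config <- function(min_cpm = 1, min_frac = 0.75, fdr = 0.01,
                      spike_coef = 1.4, spike_exp = 0.66,
                      pool_doses = 1:4) {
  stopifnot(min_frac > 0, min_frac <= 1, fdr > 0, fdr < 1,
            spike_coef > 0, spike_exp > 0)
  structure(list(min_cpm = min_cpm, min_frac = min_frac, fdr = fdr,
                 spike_coef = spike_coef, spike_exp = spike_exp,
                 pool_doses = pool_doses),
            class = "de_config")
}

#' Relevance filter: expressed in at least one group
#'
#' A gene is retained iff its CPM reaches \code{min_cpm} in at least
#' \code{min_frac} of the samples of group A, or of group B (both
#' boundaries inclusive).
#'
#' @param counts Genes x samples count matrix (CPM computed on these
#'   columns).
#' @param group_a,group_b Disjoint, non-empty sample name (or index)
#'   vectors.
#' @param cfg A \code{\link{de_config}}.
#' @return Character vector of retained gene ids.
#' @export
relevance_filter <- function(counts, group_a, group_b, cfg = de_config()) {
  stopifnot(length(group_a) > 0, length(group_b) > 0,
            length(intersect(group_a, group_b)) == 0)
  x <- cpm(counts)
  frac_a <- rowMeans(x[, group_a, drop = FALSE] >= cfg$min_cpm)
  frac_b <- rowMeans(x[, group_b, drop = FALSE] >= cfg$min_cpm)
  rownames(counts)[frac_a >= cfg$min_frac | frac_b >= cfg$min_frac]
}

#' Median-of-ratios size factors
#'
#' For each sample, the median ratio of its counts to the per-gene
#' geometric mean, over genes expressed in all samples; factors are
#' rescaled to geometric mean 1. If no gene is expressed in every sample,
#' total-count ratios are used with a warning.
#'
#' @param counts Genes x samples count matrix.
#' @return Named numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  use <- rowSums(counts > 0) == ncol(counts)
  if (!any(use)) {
    warning("no gene expressed in all samples; using total-count ratios")
    sf <- colSums(counts)
  } else {
    lgm <- rowMeans(log(counts[use, , drop = FALSE]))
    sf <- apply(counts[use, , drop = FALSE], 2L,
                function(col) exp(stats::median(log(col) - lgm)))
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

nb_loglik <- function(y, mu, alpha) {
  size <- 1 / alpha
  sum(lgamma(y + size) - lgamma(size) - lgamma(y + 1) +
        y * log(mu / (mu + size)) + size * log(size / (mu + size)))
}

## Cox-Reid adjusted profile likelihood: penalizes the fitted-mean degrees
## of freedom so gene-wise dispersion is not biased low at small n
nb_apl <- function(y, mu, alpha, design) {
  w <- mu / (1 + alpha * mu)           # working weights, log link
  xtwx <- crossprod(design * sqrt(w))
  nb_loglik(y, mu, alpha) -
    0.5 * determinant(xtwx, logarithm = TRUE)$modulus
}

#' Estimate per-gene NB dispersions with trend shrinkage
#'
#' Gene-wise Cox-Reid adjusted-profile-likelihood dispersion (given
#' design-fitted means; the adjustment removes the downward bias of plain
#' ML at small sample sizes),
#' a mean-dispersion trend \code{alpha_tr(mu) = a0 + a1 / mu} fitted across
#' genes, and shrinkage of the gene-wise estimate toward the trend by a
#' weighted geometric mean (weight \code{trend_weight} on the trend).
#' Estimates are clipped to \[1e-8, 10\]. With a single gene the trend is
#' skipped and the gene-wise estimate returned.
#'
#' @param counts Genes x samples count matrix.
#' @param design Model matrix (samples x coefficients), full rank.
#' @param size_factors Per-sample normalization factors.
#' @param trend_weight Shrinkage weight on the trend, in \[0, 1\].
#' @return List: \code{alpha} (final per-gene dispersion), \code{genewise},
#'   \code{trend} (per-gene trend value), \code{trend_coef} (a0, a1),
#'   \code{mean_norm} (per-gene mean normalized count).
#' @export
estimate_dispersions <- function(counts, design,
                                 size_factors = toxseq::size_factors(counts),
                                 trend_weight = 0.5) {
  counts <- as.matrix(counts)
  n <- ncol(counts)
  stopifnot(nrow(design) == n, n - ncol(design) >= 1)
  off <- log(size_factors)

  genewise <- numeric(nrow(counts))
  mu_mean <- numeric(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    y <- counts[i, ]
    if (all(y == 0)) { genewise[i] <- 1e-8; mu_mean[i] <- 0; next }
    pf <- suppressWarnings(
      stats::glm.fit(design, y, family = stats::poisson(), offset = off))
    mu <- pmax(pf$fitted.values, 1e-8)
    mu_mean[i] <- mean(y / exp(off))
    opt <- stats::optimize(function(la) -nb_apl(y, mu, exp(la), design),
                           interval = log(c(1e-8, 10)))
    genewise[i] <- exp(opt$minimum)
  }
  genewise <- pmin(pmax(genewise, 1e-8), 10)

  if (nrow(counts) < 10L) {
    return(list(alpha = genewise, genewise = genewise, trend = genewise,
                trend_coef = c(a0 = NA_real_, a1 = NA_real_),
                mean_norm = mu_mean))
  }
  use <- mu_mean > 0
  tf <- tryCatch(
    stats::lm(genewise[use] ~ I(1 / mu_mean[use])),
    error = function(e) NULL)
  if (is.null(tf)) {
    warning("dispersion trend fit failed; using gene-wise estimates")
    return(list(alpha = genewise, genewise = genewise, trend = genewise,
                trend_coef = c(a0 = NA_real_, a1 = NA_real_),
                mean_norm = mu_mean))
  }
  a0 <- max(stats::coef(tf)[1], 1e-8)
  a1 <- max(stats::coef(tf)[2], 0)
  trend <- pmin(pmax(a0 + a1 / pmax(mu_mean, 1e-8), 1e-8), 10)
  alpha <- exp((1 - trend_weight) * log(genewise) +
                 trend_weight * log(trend))
  alpha <- pmin(pmax(alpha, 1e-8), 10)
  list(alpha = alpha, genewise = genewise, trend = trend,
       trend_coef = c(a0 = a0, a1 = a1), mean_norm = mu_mean)
}

#' Per-gene NB Wald test
#'
#' Log-link NB GLM per gene with log size-factor offsets and fixed per-gene
#' dispersion; the Wald statistic is the condition coefficient divided by
#' its standard error. The two-sided p-value uses a t reference with
#' residual degrees of freedom (samples minus design columns): with a
#' dozen samples and estimated dispersions the large-sample normal
#' reference is anti-conservative in the extreme tail, which is exactly
#' where FDR-level calls are decided. BH adjustment runs across the genes
#' that converged. log2 fold change is the condition coefficient converted
#' from natural to base-2 logarithm.
#'
#' @param counts Genes x samples count matrix.
#' @param design Model matrix including the condition column and any
#'   nuisance covariates; must be full rank.
#' @param coef Name or index of the condition column of \code{design}.
#' @param alpha Per-gene dispersion vector (recycled if length 1).
#' @param size_factors Per-sample factors.
#' @return data.frame: gene, log2fc, wald_stat, p, fdr_adj, converged.
#' @export
nb_wald <- function(counts, design, coef = "condition",
                    alpha = 0.05, size_factors = toxseq::size_factors(counts)) {
  counts <- as.matrix(counts)
  stopifnot(nrow(design) == ncol(counts))
  if (qr(design)$rank < ncol(design)) stop("design matrix is not full rank")
  if (is.character(coef)) coef <- match(coef, colnames(design))
  stopifnot(!is.na(coef), coef >= 1, coef <= ncol(design))
  alpha <- rep_len(alpha, nrow(counts))
  off <- log(size_factors)
  df_resid <- max(ncol(counts) - ncol(design), 1L)

  res <- vapply(seq_len(nrow(counts)), function(i) {
    y <- counts[i, ]
    if (all(y == 0)) return(c(0, 0, NA_real_, 0))
    fam <- MASS::negative.binomial(theta = 1 / alpha[i])
    f <- tryCatch(
      suppressWarnings(stats::glm.fit(design, y, family = fam, offset = off)),
      error = function(e) NULL)
    if (is.null(f) || !f$converged || any(!is.finite(f$coefficients)))
      return(c(NA_real_, NA_real_, NA_real_, 0))
    cov <- tryCatch(chol2inv(qr.R(f$qr)), error = function(e) NULL)
    if (is.null(cov) || !all(is.finite(diag(cov))) || any(diag(cov) <= 0))
      return(c(NA_real_, NA_real_, NA_real_, 0))
    b <- f$coefficients[coef]
    se <- sqrt(diag(cov))[coef]
    z <- b / se
    c(b / log(2), z, 2 * stats::pt(-abs(z), df = df_resid), 1)
  }, numeric(4))

  out <- data.frame(gene = rownames(counts),
                    log2fc = res[1, ], wald_stat = res[2, ], p = res[3, ],
                    converged = res[4, ] == 1,
                    stringsAsFactors = FALSE)
  out$fdr_adj <- bh_adjust(out$p)
  out
}

#' Spurious single-replicate spike filter
#'
#' For each gene and group, the largest single-replicate share of the
#' group's total count is compared with the threshold
#' \code{spike_coef * n^(-spike_exp)}; the gene passes for that group iff
#' the share is strictly below the threshold. Genes with zero group total
#' pass trivially. Failing genes are flagged for manual review, not
#' dropped.
#'
#' @param counts Genes x samples count matrix.
#' @param genes Genes to evaluate (typically the DE calls).
#' @param group_samples Sample names/indices of one group.
#' @param cfg A \code{\link{de_config}}.
#' @return data.frame: gene, max_prop, threshold, flagged.
#' @export
spurious_spike_filter <- function(counts, genes, group_samples,
                                  cfg = de_config()) {
  stopifnot(length(group_samples) > 0)
  x <- as.matrix(counts)[genes, group_samples, drop = FALSE]
  tot <- rowSums(x)
  mx <- apply(x, 1L, max)
  prop <- ifelse(tot > 0, mx / tot, 0)
  thr <- spike_threshold(length(group_samples), cfg$spike_coef,
                         cfg$spike_exp)
  data.frame(gene = genes, max_prop = as.numeric(prop),
             threshold = rep(thr, length(genes)),
             flagged = as.numeric(prop) >= thr, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Full differential expression contrast for one compound
#'
#' The complete stage: pool the configured dose codes of \code{compound} as
#' treatment versus the solvent control group, apply the relevance filter,
#' compute size factors and dispersions, estimate \code{ruv_k} nuisance
#' factors from empirical control genes (least-significant half of a
#' first-pass unadjusted test), run the NB Wald test with those covariates,
#' BH-adjust, and flag spurious spikes in both groups.
#'
#' @param counts Genes x samples count matrix.
#' @param design Sample sheet (columns sample, compound, dose_code).
#' @param compound Treatment compound name.
#' @param control Control group compound name.
#' @param cfg A \code{\link{de_config}}.
#' @param ruv_k Nuisance factors to estimate (0 disables RUV).
#' @return data.frame with DEResult fields: gene, log2fc, wald_stat, p,
#'   fdr_adj, relevance_pass (all TRUE: failing genes are absent),
#'   spike_flag_treatment, spike_flag_control, final_call in
#'   \{up, down, not_significant, spike_filtered\}. The filter ledger
#'   (rows in/out per step) is in \code{attr(, "ledger")}.
#' @export
run_de_contrast <- function(counts, design, compound, control = "DMSO",
                            cfg = de_config(), ruv_k = 2) {
  trt <- design$sample[design$compound == compound &
                         design$dose_code %in% cfg$pool_doses]
  ctl <- design$sample[design$compound == control]
  if (length(trt) == 0 || length(ctl) == 0)
    stop("empty treatment or control group for ", compound)
  sub <- as.matrix(counts)[, c(ctl, trt), drop = FALSE]

  keep <- relevance_filter(sub, ctl, trt, cfg)
  ledger <- data.frame(step = "relevance_filter", n_in = nrow(sub),
                       n_out = length(keep))
  sub <- sub[keep, , drop = FALSE]

  sf <- size_factors(sub)
  condition <- as.numeric(colnames(sub) %in% trt)
  X0 <- cbind("(Intercept)" = 1, condition = condition)
  disp <- estimate_dispersions(sub, X0, sf)

  if (ruv_k > 0) {
    first <- nb_wald(sub, X0, "condition", disp$alpha, sf)
    ruv <- ruv_control_genes(sub, k = ruv_k, first_pass_p = first$p)
    X <- cbind(X0, ruv$W)
  } else {
    ruv <- NULL
    X <- X0
  }

  res <- nb_wald(sub, X, "condition", disp$alpha, sf)
  ledger <- rbind(ledger,
                  data.frame(step = "nb_wald", n_in = nrow(sub),
                             n_out = sum(res$converged)))

  de <- res$gene[!is.na(res$fdr_adj) & res$fdr_adj < cfg$fdr]
  spike_t <- spurious_spike_filter(sub, de, trt, cfg)
  spike_c <- spurious_spike_filter(sub, de, ctl, cfg)
  res$relevance_pass <- TRUE
  res$spike_flag_treatment <- res$gene %in% spike_t$gene[spike_t$flagged]
  res$spike_flag_control <- res$gene %in% spike_c$gene[spike_c$flagged]

  sig <- res$gene %in% de
  spiked <- res$spike_flag_treatment | res$spike_flag_control
  res$final_call <- ifelse(!sig, "not_significant",
                    ifelse(spiked, "spike_filtered",
                    ifelse(res$log2fc > 0, "up", "down")))
  ledger <- rbind(ledger,
                  data.frame(step = "fdr_and_spike", n_in = length(de),
                             n_out = sum(res$final_call %in% c("up", "down"))))
  attr(res, "ledger") <- ledger
  attr(res, "ruv") <- ruv
  res
}
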