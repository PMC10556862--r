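#' Configuration for dose-series polynomial regression
#'
#' NB GLM with fixed size parameter \code{theta} (dispersion alpha = 1 /
#' theta), polynomial in the ordinal dose code up to \code{degree}, gene
#' selection by BH FDR, and hierarchical clustering of the significant
#' fitted profiles into \code{n_clusters} groups.
#'
#' @param theta NB size (variance mu + mu^2 / theta).
#' @param degree Polynomial degree of the dose term.
#' @param fdr BH threshold for selecting dose-responsive genes.
#' @param n_clusters Number of profile clusters.
#' @param dose_codes Ordered dose codes used for fitted-profile prediction.
#' @return List of class \code{dose_series_config}.
#' @export
dose_series_config <- function(theta = 10, degree = 3, fdr = 0.05,
                               n_clusters = 9, dose_codes = 0:5) {
  stopifnot(theta > 0, degree >= 1, fdr > 0, fdr < 1, n_clusters >= 1)
  structure(list(theta = theta, degree = as.integer(degree), fdr = fdr,
                 n_clusters = as.integer(n_clusters),
                 dose_codes = dose_codes),
            class = "dose_series_config")
}

#' Fit a polynomial dose-response NB GLM for one gene
#'
#' Log-link NB regression of counts on 1, d, d^2, ..., d^degree where d is
#' the ordinal dose code, with log size-factor offsets and dispersion fixed
#' at 1/theta. Significance is a likelihood-ratio test against the
#' intercept-only model, chi-squared with \code{degree} degrees of freedom.
#' Non-convergence falls back to successively lower degrees (flagged);
#' all-zero genes return p = 1 with zero coefficients.
#'
#' @param y Integer count vector (one gene, all samples).
#' @param dose Numeric dose codes per sample.
#' @param cfg A \code{\link{dose_series_config}}.
#' @param size_factors Per-sample normalization factors (offsets =
#'   \code{log(size_factors)}).
#' @return List: coefficients (length degree + 1), lrt_stat, df, p,
#'   fitted_profile (predicted mean per \code{cfg$dose_codes} at unit size
#'   factor), wald_z (per-coefficient z), degree_used, converged.
#' @export
fit_dose_polynomial <- function(y, dose, cfg = dose_series_config(),
                                size_factors = rep(1, length(y))) {
  stopifnot(length(y) == length(dose),
            length(y) >= cfg$degree + 2)
  coefs <- rep(0, cfg$degree + 1L)
  names(coefs) <- paste0("beta", 0:cfg$degree)
  if (all(y == 0)) {
    return(list(coefficients = coefs, lrt_stat = 0, df = cfg$degree, p = 1,
                fitted_profile = rep(0, length(cfg$dose_codes)),
                wald_z = rep(0, cfg$degree + 1L),
                degree_used = cfg$degree, converged = TRUE))
  }
  off <- log(size_factors)
  fam <- MASS::negative.binomial(theta = cfg$theta)

  fit_deg <- function(deg) {
    X <- stats::poly(dose, degree = deg, raw = TRUE)
    X <- cbind("(Intercept)" = 1, X)
    f <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y, family = fam, offset = off)),
      error = function(e) NULL)
    if (is.null(f) || !f$converged || any(!is.finite(f$coefficients)))
      return(NULL)
    f$X <- X
    f
  }

  deg <- cfg$degree
  fit <- fit_deg(deg)
  while (is.null(fit) && deg > 1L) {
    deg <- deg - 1L
    fit <- fit_deg(deg)
  }
  null_fit <- suppressWarnings(
    stats::glm.fit(matrix(1, length(y)), y, family = fam, offset = off))
  if (is.null(fit)) {
    return(list(coefficients = coefs, lrt_stat = 0, df = cfg$degree, p = 1,
                fitted_profile = rep(exp(null_fit$coefficients[1]),
                                     length(cfg$dose_codes)),
                wald_z = rep(0, cfg$degree + 1L),
                degree_used = 0L, converged = FALSE))
  }

  lrt <- max(0, null_fit$deviance - fit$deviance)
  p <- stats::pchisq(lrt, df = deg, lower.tail = FALSE)
  coefs[seq_len(deg + 1L)] <- fit$coefficients

  ## per-coefficient Wald z from the unscaled covariance (dispersion fixed)
  R <- qr.R(fit$qr)
  cov <- tryCatch(chol2inv(R), error = function(e) NULL)
  wz <- rep(NA_real_, cfg$degree + 1L)
  if (!is.null(cov))
    wz[seq_len(deg + 1L)] <- fit$coefficients / sqrt(diag(cov))

  Xp <- cbind(1, stats::poly(cfg$dose_codes, degree = deg, raw = TRUE))
  profile <- as.numeric(exp(Xp %*% fit$coefficients))

  list(coefficients = coefs, lrt_stat = lrt, df = deg, p = p,
       fitted_profile = profile, wald_z = wz,
       degree_used = deg, converged = deg == cfg$degree)
}

#' Fit the dose-response model for every gene of one compound series
#'
#' @param counts Genes x samples count matrix (one compound's dose series
#'   plus its dose-0 control samples).
#' @param dose Dose codes per sample (0 = control).
#' @param cfg A \code{\link{dose_series_config}}.
#' @param size_factors Per-sample factors; default median-of-ratios via
#'   \code{\link{size_factors}}.
#' @return data.frame of class \code{dose_fit_table}: gene, beta0..beta_k,
#'   lrt_stat, df, p, q (BH), converged; fitted profiles in
#'   \code{attr(, "profiles")} (genes x dose codes matrix).
#' @export
fit_dose_series <- function(counts, dose, cfg = dose_series_config(),
                            size_factors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(size_factors)) size_factors <- toxseq::size_factors(counts)
  fits <- lapply(seq_len(nrow(counts)), function(i)
    fit_dose_polynomial(counts[i, ], dose, cfg, size_factors))
  tab <- data.frame(
    gene = rownames(counts),
    do.call(rbind, lapply(fits, function(f) t(f$coefficients))),
    lrt_stat = vapply(fits, `[[`, 0, "lrt_stat"),
    df = vapply(fits, `[[`, 0L, "df"),
    p = vapply(fits, `[[`, 0, "p"),
    converged = vapply(fits, `[[`, TRUE, "converged"),
    stringsAsFactors = FALSE)
  tab$q <- bh_adjust(tab$p)
  profiles <- do.call(rbind, lapply(fits, `[[`, "fitted_profile"))
  dimnames(profiles) <- list(rownames(counts),
                             paste0("dose", cfg$dose_codes))
  attr(tab, "profiles") <- profiles
  class(tab) <- c("dose_fit_table", "data.frame")
  tab
}

#' Select dose-responsive genes at a BH FDR threshold
#'
#' @param fits A \code{dose_fit_table} from \code{\link{fit_dose_series}}.
#' @param fdr FDR threshold (keep q <= fdr).
#' @return Character vector of selected gene ids.
#' @export
select_significant <- function(fits, fdr = 0.05) {
  if (nrow(fits) == 0L) return(character(0))
  fits$gene[fits$q <= fdr]
}

#' Cluster significant dose profiles
#'
#' Fitted mean profiles are standardized per gene (zero mean, unit variance
#' across dose codes), then clustered hierarchically with correlation
#' distance and average linkage, cut into \code{min(n_clusters, n_genes)}
#' groups. Constant profiles (zero variance) get correlation 0 to
#' everything and end up in their own cluster(s).
#'
#' @param fits A \code{dose_fit_table} (with its \code{profiles} attribute).
#' @param genes Genes to cluster (typically \code{\link{select_significant}}
#'   output).
#' @param n_clusters Maximum number of clusters.
#' @return List: \code{assignment} (named integer vector gene -> cluster),
#'   \code{centers} (cluster x dose matrix of mean standardized profiles).
#' @export
cluster_profiles <- function(fits, genes, n_clusters = 9) {
  profiles <- attr(fits, "profiles")
  stopifnot(!is.null(profiles), all(genes %in% rownames(profiles)))
  if (length(genes) == 0L)
    return(list(assignment = stats::setNames(integer(0), character(0)),
                centers = NULL))
  prof <- profiles[genes, , drop = FALSE]
  sdv <- apply(prof, 1L, stats::sd)
  z <- (prof - rowMeans(prof)) / ifelse(sdv > 0, sdv, 1)
  k <- min(n_clusters, length(genes))
  if (length(genes) == 1L) {
    assignment <- stats::setNames(1L, genes)
  } else {
    cc <- suppressWarnings(stats::cor(t(z)))
    cc[!is.finite(cc)] <- 0
    d <- stats::as.dist(1 - cc)
    hc <- stats::hclust(d, method = "average")
    assignment <- stats::cutree(hc, k = k)
  }
  centers <- rowsum(z, assignment) / as.vector(table(assignment))
  list(assignment = assignment, centers = centers)
}
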