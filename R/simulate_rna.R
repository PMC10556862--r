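#' Parameters for the RNA count simulator
#'
#' Constructs and validates the parameter set for
#' \code{\link{simulate_rna_counts}}. Defaults emulate a low-dose in vitro
#' exposure screen: six treatment groups (four compounds x five-dose series
#' coded 1..5 plus solvent and untreated controls at code 0), a biotype mix
#' dominated by protein-coding genes, hidden technical confounders, and rare
#' single-replicate expression spikes.
#'
#' The negative binomial is parameterized by mean \eqn{\mu} and dispersion
#' \eqn{\alpha} with variance \eqn{\mu + \alpha \mu^2} throughout the package
#' (\eqn{\theta = 1/\alpha}). Planted effect profiles are polynomials in the
#' raw dose code (the same covariates the dose-series model fits), so the
#' default cubic coefficient 0.008 gives a one-log2 shift at dose code 5.
#' A profile may also be a function(dose_code) returning the log2 shift,
#' for non-polynomial shapes such as step effects. Gene means are the
#' library-size-scaled \code{2^(baseline + profile + confounders)} against
#' a fixed baseline normalizer, so planted effects never distort other
#' genes; each mean is capped at the sample's library size to keep extreme
#' planted effects finite.
#'
#' @param n_genes Number of genes.
#' @param biotype_proportions Named fractions summing to 1.
#' @param groups data.frame with columns \code{compound}, \code{dose_code},
#'   \code{n_replicates}. Dose code 0 denotes control.
#' @param baseline_mean_log2,baseline_sd_log2 Gene baseline log2 abundance
#'   distribution (relative expression before library scaling).
#' @param dispersion NB dispersion alpha (> 0).
#' @param de_fraction Fraction of genes given a dose effect.
#' @param effect_profiles List of polynomial coefficient vectors
#'   (beta1..beta_degree on the raw dose code, log2 scale, no intercept) or
#'   functions of the dose code, sampled for affected genes.
#' @param n_confounders,confounder_sd Hidden additive log2 factors: per-sample
#'   scores ~ N(0, 1), per-gene loadings ~ N(0, confounder_sd).
#' @param spike_rate Fraction of gene x group cells given a single-replicate
#'   spike.
#' @param spike_multiplier Multiplier (> 1) applied to the spiked count.
#' @param library_size_range Min/max expected total counts per sample.
#' @param seed Integer seed; identical parameters and seed give identical
#'   output.
#' @return A validated list of class \code{rna_sim_params}.
#' @export
rna_sim_params <- function(n_genes = 2000,
                           biotype_proportions = c(protein_coding = 0.70,
                                                   miRNA = 0.10,
                                                   snoRNA = 0.08,
                                                   pseudogene = 0.08,
                                                   rRNA = 0.04),
                           groups = default_rna_groups(),
                           baseline_mean_log2 = 5,
                           baseline_sd_log2 = 2,
                           dispersion = 0.05,
                           de_fraction = 0.1,
                           effect_profiles = list(c(0, 0, 0.008),
                                                  c(0.2, 0, 0),
                                                  c(0, 0, -0.008),
                                                  c(-0.2, 0, 0)),
                           n_confounders = 0,
                           confounder_sd = 0.5,
                           spike_rate = 0,
                           spike_multiplier = 20,
                           library_size_range = c(1e6, 2e6),
                           seed = 1L) {
  p <- list(n_genes = as.integer(n_genes),
            biotype_proportions = biotype_proportions,
            groups = as.data.frame(groups),
            baseline_mean_log2 = baseline_mean_log2,
            baseline_sd_log2 = baseline_sd_log2,
            dispersion = dispersion,
            de_fraction = de_fraction,
            effect_profiles = effect_profiles,
            n_confounders = as.integer(n_confounders),
            confounder_sd = confounder_sd,
            spike_rate = spike_rate,
            spike_multiplier = spike_multiplier,
            library_size_range = library_size_range,
            seed = as.integer(seed))
  validate_rna_sim_params(p)
  class(p) <- "rna_sim_params"
  p
}

#' Default exposure design: four compounds x doses 1..5 in triplicate,
#' solvent control (n = 5) and untreated control (n = 3) at dose 0.
#' @return data.frame with columns compound, dose_code, n_replicates.
#' @export
default_rna_groups <- function() {
  compounds <- c("DEHP", "DIDP", "DINP", "DnOP")
  rbind(
    data.frame(compound = rep(compounds, each = 5),
               dose_code = rep(1:5, times = 4),
               n_replicates = 3L),
    data.frame(compound = c("DMSO", "untreated"),
               dose_code = 0L,
               n_replicates = c(5L, 3L))
  )
}

validate_rna_sim_params <- function(p) {
  stopifnot(p$n_genes >= 1)
  if (abs(sum(p$biotype_proportions) - 1) > 1e-9)
    stop("biotype_proportions must sum to 1")
  if (any(p$biotype_proportions < 0 | p$biotype_proportions > 1))
    stop("biotype_proportions must lie in [0, 1]")
  stopifnot(p$dispersion > 0,
            p$de_fraction >= 0, p$de_fraction <= 1,
            p$spike_rate >= 0, p$spike_rate <= 1,
            p$spike_multiplier > 1 || p$spike_rate == 0,
            all(p$library_size_range > 0),
            length(p$library_size_range) == 2L)
  if (any(p$groups$n_replicates < 1))
    stop("every group must have at least one replicate")
  ok <- vapply(p$effect_profiles, function(e)
    is.function(e) || (is.numeric(e) && length(e) >= 1), TRUE)
  if (!all(ok))
    stop("effect profiles must be coefficient vectors or functions")
  invisible(TRUE)
}

#' Simulate an RNA-seq count matrix with planted structure
#'
#' Draws NB counts for a multi-group dose design. The log2 mean of gene g in
#' sample s is \code{baseline_g + profile_g(dose_s / max_dose) +
#' sum_k loading_gk * score_ks}; relative expressions are renormalized per
#' sample so the expected column total equals the drawn library size. A
#' seeded subset of gene x group cells has one replicate's count multiplied
#' by \code{spike_multiplier} (a single-replicate technical artifact).
#'
#' @param params An \code{\link{rna_sim_params}} object.
#' @return List with elements \code{counts} (integer matrix genes x samples),
#'   \code{biotype} (data.frame gene/biotype), \code{design} (data.frame
#'   sample, compound, dose_code, group, replicate_set), and \code{truth}
#'   (list: de_genes data.frame with profiles, confounder loadings and
#'   scores, spiked cells, library sizes).
#' @export
simulate_rna_counts <- function(params) {
  p <- params
  validate_rna_sim_params(p)
  set.seed(p$seed)

  genes <- sprintf("gene_%05d", seq_len(p$n_genes))
  biotype <- sample(names(p$biotype_proportions), p$n_genes, replace = TRUE,
                    prob = p$biotype_proportions)

  g <- p$groups
  design <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    reps <- seq_len(g$n_replicates[i])
    data.frame(
      sample = sprintf("%s_d%d_r%d", g$compound[i], g$dose_code[i], reps),
      compound = g$compound[i],
      dose_code = g$dose_code[i],
      group = g$compound[i],
      replicate_set = sprintf("rs%d", reps),
      stringsAsFactors = FALSE)
  }))
  n_samples <- nrow(design)

  baseline <- stats::rnorm(p$n_genes, p$baseline_mean_log2, p$baseline_sd_log2)

  ## planted dose effects
  n_de <- round(p$de_fraction * p$n_genes)
  de_idx <- if (n_de > 0) sort(sample.int(p$n_genes, n_de)) else integer(0)
  profile_id <- if (n_de > 0)
    sample.int(length(p$effect_profiles), n_de, replace = TRUE) else integer(0)

  log2mu <- matrix(baseline, p$n_genes, n_samples)
  x <- design$dose_code
  if (n_de > 0) {
    for (j in seq_along(de_idx)) {
      cf <- p$effect_profiles[[profile_id[j]]]
      shift <- if (is.function(cf)) cf(x)
        else rowSums(vapply(seq_along(cf),
                            function(d) cf[d] * x^d, numeric(n_samples)))
      log2mu[de_idx[j], ] <- log2mu[de_idx[j], ] + shift
    }
  }

  ## hidden confounders: additive on log2 mean
  loadings <- scores <- NULL
  if (p$n_confounders > 0) {
    loadings <- matrix(stats::rnorm(p$n_genes * p$n_confounders,
                                    0, p$confounder_sd),
                       p$n_genes, p$n_confounders)
    scores <- matrix(stats::rnorm(n_samples * p$n_confounders),
                     n_samples, p$n_confounders)
    log2mu <- log2mu + loadings %*% t(scores)
  }

  libsize <- stats::runif(n_samples, p$library_size_range[1],
                          p$library_size_range[2])
  baseline_total <- sum(2^baseline)   # fixed normalizer: no compositional
  mu <- sweep(2^log2mu / baseline_total, 2L, libsize, "*")
  mu <- pmin(mu, rep(libsize, each = p$n_genes))

  counts <- matrix(
    stats::rnbinom(p$n_genes * n_samples, mu = mu, size = 1 / p$dispersion),
    p$n_genes, n_samples)

  ## single-replicate spikes: one replicate per selected gene x group cell
  spiked <- data.frame(gene = character(0), sample = character(0))
  if (p$spike_rate > 0) {
    grp_levels <- unique(design$group)
    cells <- expand.grid(gene = seq_len(p$n_genes),
                         group = grp_levels, stringsAsFactors = FALSE)
    pick <- which(stats::runif(nrow(cells)) < p$spike_rate)
    for (i in pick) {
      s_idx <- which(design$group == cells$group[i])
      hit <- s_idx[sample.int(length(s_idx), 1L)]
      gi <- cells$gene[i]
      counts[gi, hit] <- max(1L, counts[gi, hit]) * p$spike_multiplier
      spiked <- rbind(spiked, data.frame(gene = genes[gi],
                                         sample = design$sample[hit]))
    }
  }

  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(genes, design$sample)

  truth <- list(
    de_genes = data.frame(gene = genes[de_idx],
                          profile = I(p$effect_profiles[profile_id])),
    confounder_loadings = loadings,
    confounder_scores = scores,
    spiked_cells = spiked,
    library_sizes = stats::setNames(libsize, design$sample))

  list(counts = counts,
       biotype = data.frame(gene = genes, biotype = biotype,
                            stringsAsFactors = FALSE),
       design = design,
       truth = truth)
}

#' Write a simulated RNA dataset as the package's TSV interchange files
#'
#' Emits counts (first column \code{gene}, then one column per sample), the
#' gene -> biotype map, the sample sheet, and a JSON ground-truth sidecar.
#'
#' @param sim Result of \code{\link{simulate_rna_counts}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_rna_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             biotype = file.path(dir, "biotypes.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.json"))
  write_tsv(data.frame(gene = rownames(sim$counts), sim$counts,
                       check.names = FALSE), paths["counts"])
  write_tsv(sim$biotype, paths["biotype"])
  write_tsv(sim$design, paths["samples"])
  truth <- sim$truth
  truth$confounder_loadings <- NULL   # matrices audited in-session, not on disk
  truth$confounder_scores <- NULL
  truth$de_genes$profile <- vapply(truth$de_genes$profile, function(e)
    if (is.function(e)) paste(deparse(e), collapse = " ")
    else paste(e, collapse = ","), "")
  jsonlite::write_json(truth, paths["truth"], dataframe = "columns",
                       auto_unbox = FALSE, digits = NA)
  invisible(paths)
}
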