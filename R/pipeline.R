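#' Default pipeline configuration
#'
#' All stage configurations with their standard defaults, plus the seed and
#' synthetic-data parameters, as one declarative list. Every numeric
#' threshold used by the pipeline stages is reachable from here.
#'
#' @param seed Integer master seed.
#' @return Nested list: rna_sim, atac_sim, qc (retention/outlier settings),
#'   dose (dose_series_config), de (de_config), ruv (k per variant), gsea
#'   (n_perm, q threshold, size bounds), atac (atac_config), seed.
#' @export
default_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       rna_sim = rna_sim_params(seed = seed),
       atac_sim = atac_sim_params(seed = seed + 1000L),
       qc = list(min_pct = 1, iqr_multiplier = 1.5,
                 split_biotype = "snoRNA",
                 drop_biotypes = c("protein_coding", "miRNA")),
       dose = dose_series_config(),
       de = de_config(),
       ruv = list(k_genes = 2L, k_replicates = 5L),
       gsea = list(n_perm = 1000L, q_threshold = 0.05,
                   min_size = 5L, max_size = 500L),
       atac = atac_config())
}

#' Run the full synthetic pipeline
#'
#' Simulate an RNA dataset and ATAC fragment files, then run biotype QC,
#' dose-series fitting and clustering for one compound, the pooled-dose
#' differential expression contrast for every compound, preranked GSEA on
#' one contrast against synthetic gene sets, and the window-based
#' accessibility stage; write all result tables under \code{outdir}. Fully
#' deterministic for a fixed config seed.
#'
#' @param config A \code{\link{default_config}} list.
#' @param outdir Output directory.
#' @return Invisibly, the list of in-memory results.
#' @export
run_synthetic_pipeline <- function(config = default_config(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config

  ## --- simulate RNA
  sim <- simulate_rna_counts(cfg$rna_sim)
  write_rna_dataset(sim, file.path(outdir, "rna"))

  ## --- QC: biotype fractions, retention, outliers, snoRNA split
  frac <- biotype_fractions(sim$counts, sim$biotype)
  retained <- retain_major_biotypes(frac, cfg$qc$min_pct)
  split <- split_biotype(sim$counts, sim$biotype, cfg$qc$split_biotype)
  frac_main <- biotype_fractions(split$main, sim$biotype)
  outliers <- flag_outliers_iqr(frac_main, sim$design$group,
                                cfg$qc$iqr_multiplier)
  kept <- drop_flagged_samples(split$main, sim$design, outliers,
                               cfg$qc$drop_biotypes)
  write_tsv(data.frame(sample = rownames(frac), frac, check.names = FALSE),
            file.path(outdir, "biotype_fractions.tsv"))
  jsonlite::write_json(outliers$flags, file.path(outdir, "outliers.json"),
                       dataframe = "rows")

  ## --- dose series for the first compound
  comp1 <- setdiff(unique(kept$design$compound), c("DMSO", "untreated"))[1]
  ds_samples <- kept$design$sample[kept$design$compound %in%
                                     c(comp1, "DMSO")]
  ds_design <- kept$design[kept$design$sample %in% ds_samples, ]
  ds_counts <- kept$counts[, ds_design$sample, drop = FALSE]
  expressed <- rowMeans(cpm(ds_counts) >= 1) >= 0.5
  fits <- fit_dose_series(ds_counts[expressed, , drop = FALSE],
                          ds_design$dose_code, cfg$dose)
  sig <- select_significant(fits, cfg$dose$fdr)
  clust <- cluster_profiles(fits, sig, cfg$dose$n_clusters)
  ds_out <- fits
  ds_out$cluster <- clust$assignment[match(ds_out$gene,
                                           names(clust$assignment))]
  attr(ds_out, "profiles") <- NULL
  write_tsv(as.data.frame(ds_out), file.path(outdir, "dose_series.tsv"))

  ## --- DE contrast per compound (pooled doses, RUVg covariates)
  compounds <- setdiff(unique(kept$design$compound), c("DMSO", "untreated"))
  de <- lapply(compounds, function(cp)
    run_de_contrast(kept$counts, kept$design, cp, "DMSO", cfg$de,
                    cfg$ruv$k_genes))
  names(de) <- compounds
  for (cp in compounds)
    write_tsv(de[[cp]], file.path(outdir, paste0("de_", cp, ".tsv")))
  summary_tab <- data.frame(
    compound = compounds,
    n_deg = vapply(de, function(r)
      sum(r$final_call %in% c("up", "down")), 0L),
    n_spike_filtered = vapply(de, function(r)
      sum(r$final_call == "spike_filtered"), 0L))
  write_tsv(summary_tab, file.path(outdir, "de_summary.tsv"))

  ## --- GSEA on the first contrast, synthetic sets over the universe
  ranked <- rank_genes(de[[1]][de[[1]]$converged, ])
  set.seed(cfg$seed + 2000L)
  sets <- replicate(10, sample(ranked$gene, 40), simplify = FALSE)
  names(sets) <- sprintf("random_set_%02d", 1:10)
  gsea <- gsea_preranked(ranked, sets, n_perm = cfg$gsea$n_perm,
                         seed = cfg$seed + 3000L,
                         min_size = cfg$gsea$min_size,
                         max_size = cfg$gsea$max_size)
  write_tsv(gsea, file.path(outdir, "gsea.tsv"))

  ## --- ATAC stage
  atac_sim <- simulate_atac_fragments(cfg$atac_sim,
                                      file.path(outdir, "fragments"))
  ref <- cfg$atac_sim$groups$condition[1]
  da <- run_atac_da(atac_sim$files, atac_sim$chrom_sizes,
                    condition = as.numeric(atac_sim$design$condition != ref),
                    ruv_k = cfg$ruv$k_replicates, cfg = cfg$atac)
  reg_out <- da$regions
  attr(reg_out, "members") <- NULL
  write_tsv(reg_out, file.path(outdir, "atac_regions.tsv"))
  write_tsv(da$report, file.path(outdir, "atac_report.tsv"))

  invisible(list(sim = sim, fractions = frac, retained = retained,
                 outliers = outliers, dose = ds_out, de = de,
                 de_summary = summary_tab, gsea = gsea, atac = da,
                 atac_truth = atac_sim$truth))
}
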