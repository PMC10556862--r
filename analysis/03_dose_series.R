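#!/usr/bin/env Rscript

# Stage 3 — dose-response profiling per compound.
#
# For every compound: NB polynomial regression (theta = 10, cubic) of each
# expressed gene on the ordinal dose code (0 = control, 1..5 = doses), BH
# selection at FDR 0.05, and hierarchical clustering of the significant
# fitted profiles into up to nine groups. The per-cluster mean standardized
# profiles show which response shapes dominate — in particular whether
# divergence is confined to the top dose.

library(toxseq)

outdir <- "results"
counts <- as.matrix(read.table(file.path(outdir, "counts_main_qc.tsv"),
                               header = TRUE, sep = "\t", row.names = 1,
                               check.names = FALSE))
design <- read.table(file.path(outdir, "samples_qc.tsv"),
                     header = TRUE, sep = "\t")
cfg <- dose_series_config()          # theta 10, degree 3, FDR 0.05, 9 clusters

compounds <- setdiff(unique(design$compound), c("DMSO", "untreated"))
all_fits <- list()
for (cp in compounds) {
  d <- design[design$compound %in% c(cp, "DMSO"), ]
  cts <- counts[, d$sample, drop = FALSE]
  expressed <- rowMeans(cpm(cts) >= 1) >= 0.5
  fits <- fit_dose_series(cts[expressed, , drop = FALSE], d$dose_code, cfg)
  sig <- select_significant(fits, cfg$fdr)
  cl <- cluster_profiles(fits, sig, cfg$n_clusters)
  cat(sprintf("%s: %d genes fit, %d significant at FDR %.2f, %d clusters\n",
              cp, nrow(fits), length(sig), cfg$fdr,
              length(unique(cl$assignment))))
  tab <- as.data.frame(fits)
  tab$cluster <- cl$assignment[match(tab$gene, names(cl$assignment))]
  tab$compound <- cp
  all_fits[[cp]] <- tab
  if (!is.null(cl$centers)) {
    write.table(data.frame(cluster = rownames(cl$centers), cl$centers,
                           check.names = FALSE),
                file.path(outdir, paste0("dose_clusters_", cp, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
}
write.table(do.call(rbind, all_fits),
            file.path(outdir, "dose_series_fits.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
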