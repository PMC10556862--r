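#!/usr/bin/env Rscript

# Stage 4 — pooled-dose differential expression per compound.
#
# Dose codes 1..4 of each compound are pooled as treatment (the top code
# is excluded: the dose-series stage shows its response diverges from the
# rest of the series) and compared to the DMSO solvent control with the NB
# Wald test at FDR 0.01, after the CPM relevance filter and with two
# control-gene RUV factors as covariates; DE calls failing the
# single-replicate spurious-spike rule in either group are flagged, not
# dropped. The snoRNA matrix runs through the identical machinery as a
# separate dataset with its own BH family.

library(toxseq)

outdir <- "results"
design <- read.table(file.path(outdir, "samples_qc.tsv"),
                     header = TRUE, sep = "\t")
cfg <- de_config()     # >=1 CPM in >=75%, FDR 0.01, 1.4*n^-0.66, doses 1-4

run_dataset <- function(label, counts_file) {
  counts <- as.matrix(read.table(counts_file, header = TRUE, sep = "\t",
                                 row.names = 1, check.names = FALSE))
  counts <- counts[, intersect(colnames(counts), design$sample),
                   drop = FALSE]
  compounds <- setdiff(unique(design$compound), c("DMSO", "untreated"))
  summary_rows <- list()
  for (cp in compounds) {
    de <- run_de_contrast(counts, design, cp, "DMSO", cfg, ruv_k = 2)
    calls <- table(factor(de$final_call,
                          c("up", "down", "spike_filtered",
                            "not_significant")))
    cat(sprintf("%s %s vs DMSO: %d tested, %d up, %d down, %d spike-flagged\n",
                label, cp, sum(de$converged), calls[["up"]],
                calls[["down"]], calls[["spike_filtered"]]))
    write.table(de, file.path(outdir, sprintf("de_%s_%s.tsv", label, cp)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    # volcano-ready companion table
    volcano <- data.frame(gene = de$gene, log2fc = de$log2fc,
                          neg_log10_fdr = -log10(de$fdr_adj),
                          final_call = de$final_call)
    write.table(volcano,
                file.path(outdir, sprintf("volcano_%s_%s.tsv", label, cp)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summary_rows[[cp]] <- data.frame(
      dataset = label, compound = cp, n_tested = sum(de$converged),
      n_up = calls[["up"]], n_down = calls[["down"]],
      n_spike_filtered = calls[["spike_filtered"]])
  }
  do.call(rbind, summary_rows)
}

summary_tab <- rbind(
  run_dataset("genes", file.path(outdir, "counts_main_qc.tsv")),
  run_dataset("snoRNA", file.path(outdir, "counts_snoRNA.tsv")))
write.table(summary_tab, file.path(outdir, "de_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("summary written to", file.path(outdir, "de_summary.tsv"), "\n")
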