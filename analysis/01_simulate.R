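#!/usr/bin/env Rscript

# Stage 1 — generate the synthetic study data.
#
# Emulates the study design: four high-molecular-weight phthalates (DEHP,
# DIDP, DINP, DnOP) at five ordinal dose codes (1..5) in triplicate, a
# solvent control (DMSO, n = 5) and an untreated control (n = 3), plus an
# ATAC experiment (DMSO vs DEHP, 6 vs 6, with replicate-set batch
# structure). Ground truth for every planted effect is written alongside.

library(toxseq)

seed <- 1L
outdir <- "results"
dir.create(file.path(outdir, "data"), recursive = TRUE, showWarnings = FALSE)

rna_params <- rna_sim_params(
  n_genes = 4000, de_fraction = 0.05, n_confounders = 2,
  confounder_sd = 0.3, spike_rate = 0.001, spike_multiplier = 20,
  seed = seed)
rna <- simulate_rna_counts(rna_params)
paths <- write_rna_dataset(rna, file.path(outdir, "data", "rna"))

atac_params <- atac_sim_params(
  batch_shift = c(0.4, -0.4, 0.2, -0.2, 0.1, -0.1), seed = seed + 1000L)
atac <- simulate_atac_fragments(atac_params,
                                file.path(outdir, "data", "fragments"))
write.table(atac$design, file.path(outdir, "data", "atac_samples.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(atac$truth$peaks, file.path(outdir, "data", "atac_peaks.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(chrom = names(atac$chrom_sizes),
                       size = as.integer(atac$chrom_sizes)),
            file.path(outdir, "data", "chrom_sizes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("RNA: ", nrow(rna$counts), "genes x", ncol(rna$counts), "samples;",
    nrow(rna$truth$de_genes), "genes with planted dose effects,",
    nrow(rna$truth$spiked_cells), "planted single-replicate spikes\n")
cat("ATAC:", length(atac$files), "fragment files;",
    sum(atac$truth$peaks$differential), "of", nrow(atac$truth$peaks),
    "peaks differential\n")
cat("written under", file.path(outdir, "data"), "\n")
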