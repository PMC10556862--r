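#!/usr/bin/env Rscript

# Stage 7 — cross-stage report.
#
# Aggregates the per-contrast DEG counts, the GSEA intersection across
# contrasts, the ATAC DA count table, and a recovery audit against the
# generator's ground truth (how many planted effects each stage found).

library(toxseq)

outdir <- "results"
de <- read.table(file.path(outdir, "de_summary.tsv"), header = TRUE,
                 sep = "\t")
cat("== differential expression (FDR < 0.01, spike-filtered) ==\n")
print(de, row.names = FALSE)

common <- read.table(file.path(outdir, "gsea_common.tsv"), header = TRUE,
                     sep = "\t")
cat("\n== gene sets significant in every contrast ==\n")
print(common, row.names = FALSE)

atac <- read.table(file.path(outdir, "atac_report.tsv"), header = TRUE,
                   sep = "\t")
cat("\n== differentially accessible regions ==\n")
print(atac, row.names = FALSE)

## ground-truth audit
truth <- jsonlite::read_json(file.path(outdir, "data/rna/truth.json"),
                             simplifyVector = TRUE)
fits <- read.table(file.path(outdir, "dose_series_fits.tsv"),
                   header = TRUE, sep = "\t")
planted <- truth$de_genes$gene
sig <- unique(fits$gene[fits$q <= 0.05])
cat(sprintf("\ndose series: %d/%d planted dose-responsive genes recovered\n",
            sum(planted %in% sig), length(planted)))

peaks <- read.table(file.path(outdir, "data/atac_peaks.tsv"), header = TRUE,
                    sep = "\t")
regions <- read.table(file.path(outdir, "atac_regions.tsv"), header = TRUE,
                      sep = "\t")
diff_peaks <- peaks[peaks$differential, ]
hit <- vapply(seq_len(nrow(diff_peaks)), function(i) {
  ov <- regions$chrom == diff_peaks$chrom[i] &
    regions$start < diff_peaks$end[i] & regions$end > diff_peaks$start[i] &
    !is.na(regions$p)
  any(ov & regions$p < 0.01 &
        sign(regions$logFC) == diff_peaks$direction[i])
}, TRUE)
cat(sprintf("accessibility: %d/%d planted differential peaks recovered at p < 0.01\n",
            sum(hit), nrow(diff_peaks)))
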