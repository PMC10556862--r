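#!/usr/bin/env Rscript

# Stage 2 — biotype composition QC.
#
# Percentages of counted reads per biotype and sample; biotypes below 1%
# everywhere are set aside; snoRNA genes are split into their own matrix
# (their library share varies with PCR cycle count and would bias the
# main dataset's normalization); per-group 1.5 x IQR outlier flags; samples
# flagged in the protein-coding or miRNA biotypes are removed.

library(toxseq)

outdir <- "results"
counts <- as.matrix(read.table(file.path(outdir, "data/rna/counts.tsv"),
                               header = TRUE, sep = "\t", row.names = 1,
                               check.names = FALSE))
biotype <- read.table(file.path(outdir, "data/rna/biotypes.tsv"),
                      header = TRUE, sep = "\t")
design <- read.table(file.path(outdir, "data/rna/samples.tsv"),
                     header = TRUE, sep = "\t")

frac <- biotype_fractions(counts, biotype)
retained <- retain_major_biotypes(frac, min_pct = 1)
cat("biotypes at >= 1% in some sample:", paste(retained, collapse = ", "),
    "\n")

split <- split_biotype(counts, biotype, "snoRNA")
cat("snoRNA genes split off:", nrow(split$split), "\n")

frac_main <- biotype_fractions(split$main, biotype)
outliers <- flag_outliers_iqr(frac_main, design$group)
cat("outlier flags:", nrow(outliers$flags), "\n")
if (nrow(outliers$flags) > 0) print(outliers$flags, row.names = FALSE)

kept <- drop_flagged_samples(split$main, design, outliers)
cat("samples removed:", if (length(kept$removed)) kept$removed else "none",
    "\n")

write.table(data.frame(sample = rownames(frac), frac, check.names = FALSE),
            file.path(outdir, "biotype_fractions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(outliers, file.path(outdir, "outlier_report.json"),
                     dataframe = "rows", auto_unbox = TRUE, digits = NA)
write.table(data.frame(gene = rownames(kept$counts), kept$counts,
                       check.names = FALSE),
            file.path(outdir, "counts_main_qc.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(gene = rownames(split$split), split$split,
                       check.names = FALSE),
            file.path(outdir, "counts_snoRNA.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(kept$design, file.path(outdir, "samples_qc.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
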