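chr <- c(chrT = 10000L)

frag_df <- function(start, end, strand = "+") {
  data.frame(chrom = "chrT", start = start, end = end,
             name = paste0("f", seq_along(start)), score = 0L,
             strand = strand, stringsAsFactors = FALSE)
}

test_that("cut-site shifting follows the +4/-5 convention", {
  f <- frag_df(100L, 200L)
  cs <- shift_cut_sites(f, chr, mode = "both_ends")
  expect_setequal(cs$pos, c(104L, 195L))
  cs_plus <- shift_cut_sites(frag_df(100L, 200L, "+"), chr, mode = "single")
  expect_equal(cs_plus$pos, 104L)
  cs_minus <- shift_cut_sites(frag_df(100L, 200L, "-"), chr, mode = "single")
  expect_equal(cs_minus$pos, 195L)
  cfg0 <- atac_config(shift_plus = 0L, shift_minus = 0L)
  cs0 <- shift_cut_sites(f, chr, cfg0, mode = "both_ends")
  expect_setequal(cs0$pos, c(100L, 200L))
  # off-chromosome sites are clipped with a warning
  expect_warning(
    csc <- shift_cut_sites(frag_df(0L, 9999L), chr,
                           atac_config(shift_plus = -10L, shift_minus = 5L)),
    "clipped")
  expect_true(all(csc$pos >= 0 & csc$pos < 10000))
})

test_that("window counting partitions cut sites exactly", {
  cs <- list(s1 = data.frame(chrom = "chrT", pos = c(3L, 49L, 50L)))
  w <- count_windows(cs, chr, atac_config(min_window_count = 0L))
  expect_equal(w$start[1:2], c(0L, 50L))
  expect_equal(w$s1[1:2], c(2L, 1L))
  expect_equal(sum(w$s1), 3L)
  # retention threshold drops sparse windows but conservation is tracked
  w2 <- count_windows(cs, chr, atac_config(min_window_count = 2L))
  expect_equal(nrow(w2), 1L)
  expect_equal(attr(w2, "all_windows_total"), 3L)
  # empty input
  e <- count_windows(list(s1 = data.frame(chrom = character(0),
                                          pos = integer(0))), chr)
  expect_equal(nrow(e), 0L)
})

test_that("uniform cut sites give a background near window abundance", {
  set.seed(61)
  cs <- list(s1 = data.frame(chrom = "chrT",
                             pos = sample.int(10000L, 5000L) - 1L))
  cfg <- atac_config(min_window_count = 0L, background_bin_bp = 1000L)
  w <- count_windows(cs, chr, cfg)
  bg <- background_abundance(cs, chr, cfg)
  ab <- log2((rowSums(as.matrix(w[, "s1", drop = FALSE])) + 0.5) /
               (5000 + 1) * 1e6)
  expect_lt(abs(bg$background - median(ab)), 0.5)
  # at fold-change 3 above background, a uniform profile keeps ~nothing
  sig <- filter_signal_windows(w, bg$background, lib_sizes = 5000L,
                               cfg = cfg)
  expect_lt(nrow(sig) / nrow(w), 0.01)
})

test_that("signal filter boundary is inclusive and monotone in the cutoff", {
  w <- data.frame(chrom = "chrT", start = c(0L, 50L), end = c(50L, 100L),
                  s1 = c(100L, 10L))
  lib <- 1000L
  ab <- log2((w$s1 + 0.5) / (lib + 1) * 1e6)
  cfg3 <- atac_config(signal_fc = 3)
  # choose a background so window 1 sits exactly at 3x background
  bg <- ab[1] - log2(3)
  keep <- filter_signal_windows(w, bg, lib_sizes = lib, cfg = cfg3)
  expect_equal(keep$start, 0L)     # boundary window kept, weak one dropped
  cfg4 <- atac_config(signal_fc = 4)
  keep4 <- filter_signal_windows(w, bg, lib_sizes = lib, cfg = cfg4)
  expect_true(all(keep4$start %in% keep$start))
})

test_that("region merging respects the gap rule and the width cap", {
  mkw <- function(starts, width = 50L)
    data.frame(chrom = "chrT", start = starts, end = starts + width,
               s1 = 1L)
  # gaps: 50 (merge) then 550 (break)
  r <- merge_regions(mkw(c(0L, 100L, 700L)))
  expect_equal(nrow(r), 2L)
  expect_equal(r$start, c(0L, 700L))
  expect_equal(r$end, c(150L, 750L))
  # 120 adjacent windows spanning 6000 bp split into 2 regions <= 5000
  r2 <- merge_regions(mkw(seq(0L, 5950L, by = 50L)))
  expect_equal(nrow(r2), 2L)
  expect_true(all(r2$end - r2$start <= 5000))
  expect_equal(sum(r2$n_windows), 120L)
  # single window: region equals it
  r3 <- merge_regions(mkw(400L))
  expect_equal(r3[, c("start", "end")],
               data.frame(start = 400L, end = 450L))
  # idempotence: merging merged regions changes nothing
  as_windows <- data.frame(chrom = r2$chrom, start = r2$start,
                           end = r2$end, s1 = 1L)
  r4 <- merge_regions(as_windows)
  expect_equal(r4[, c("start", "end")], r2[, c("start", "end")])
  # adversarial: sparse chain (gaps just under the limit) still capped
  r5 <- merge_regions(mkw(seq(0L, 27000L, by = 540L)))
  expect_true(all(r5$end - r5$start <= 5000))
  expect_equal(sum(r5$n_windows), 51L)
})

test_that("region p-values are Simes combinations with BH across regions", {
  w <- data.frame(chrom = "chrT",
                  start = c(0L, 100L, 5000L), end = c(50L, 150L, 5050L),
                  s1 = 1L, p = c(0.01, 0.2, 0.5), logFC = c(2, 1, -1))
  r <- merge_regions(w)
  rc <- combine_and_correct(r, w)
  expect_equal(rc$p[1], 0.02)          # min(0.01 * 2/1, 0.2 * 2/2)
  expect_equal(rc$p[2], 0.5)           # single-window region
  expect_equal(rc$logFC[1], 2)         # most significant window's logFC
  expect_equal(rc$fdr_adj, bh_adjust(rc$p))
  expect_true(all(rc$p >= c(0.01, 0.5) - 1e-12))
  # all-NA regions are excluded and reported
  w$p <- c(NA, NA, 0.1)
  rc2 <- combine_and_correct(merge_regions(w), w)
  expect_equal(nrow(rc2), 1L)
  expect_equal(length(attr(rc2, "excluded")), 1L)
})

test_that("DA count report tabulates thresholds and directions", {
  reg <- data.frame(p = c(5e-4, 5e-3, 0.5), logFC = c(2, -3, 4),
                    fdr_adj = c(0.002, 0.5, 0.9))
  rep_tab <- report_da_counts(reg)
  expect_equal(rep_tab$n[rep_tab$threshold == "p<0.001" &
                           rep_tab$direction == "up"], 1L)
  expect_equal(rep_tab$n[rep_tab$threshold == "p<0.01" &
                           rep_tab$direction == "down"], 1L)
  expect_equal(rep_tab$n[rep_tab$threshold == "fdr<0.01"], 1L)
  empty <- report_da_counts(data.frame(p = numeric(0), logFC = numeric(0),
                                       fdr_adj = numeric(0)))
  expect_true(all(empty$n == 0L))
})

test_that("annotation assigns nearest gene, feature class and overlap", {
  # gene bodies much wider than the 1 kb site flanks, so body-interior
  # regions are not captured by the TSS/TTS windows
  genes <- data.frame(chrom = "chrT",
                      start = c(1000L, 20000L), end = c(12000L, 30001L),
                      name = c("geneA", "geneB"), strand = c("+", "-"))
  regulatory <- data.frame(chrom = "chrT", start = 4000L, end = 4200L)
  regions <- data.frame(chrom = "chrT",
                        start = c(900L, 4050L, 2400L, 16000L),
                        end = c(1100L, 4150L, 2600L, 16100L))
  ann <- annotate_regions(regions, genes, regulatory = regulatory)
  expect_equal(ann$feature_class[1], "TSS")        # overlaps geneA TSS
  expect_equal(ann$nearest_gene[1], "geneA")
  expect_true(ann$regulatory[2])
  expect_false(ann$regulatory[1])
  expect_equal(ann$feature_class[3], "intron")     # body, no exon map
  expect_equal(ann$feature_class[4], "intergenic")
  # midway tie breaks toward the smaller TSS coordinate
  # TSSs: geneA at 1000 (+), geneB at 30000 (-); midpoint 15500 is a tie
  tie <- data.frame(chrom = "chrT", start = 15450L, end = 15550L)
  ann_tie <- annotate_regions(tie, genes)
  mid <- (15450 + 15550) %/% 2
  expect_equal(abs(1000 - mid), abs(30000 - mid))
  expect_equal(ann_tie$nearest_gene, "geneA")
  # exon classification when exon intervals are given
  exons <- data.frame(chrom = "chrT", start = 2300L, end = 2700L)
  ann_ex <- annotate_regions(regions, genes, exons = exons)
  expect_equal(ann_ex$feature_class[3], "exon")
})

test_that("null window tests are calibrated and identical conditions give
           symmetric logFC", {
  p <- atac_sim_params(chrom_sizes = c(chrS1 = 4e5), n_peaks = 50,
                       fragments_per_sample = 4e4, frac_differential = 0,
                       groups = data.frame(condition = c("DMSO", "DEHP"),
                                           n_replicates = c(3L, 3L)),
                       seed = 62)
  s <- simulate_atac_fragments(p, tempfile())
  da <- run_atac_da(s$files, s$chrom_sizes,
                    condition = as.numeric(s$design$condition != "DMSO"),
                    ruv_k = 2)
  frac <- mean(da$windows$p < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.08)
  expect_lt(abs(median(da$windows$logFC, na.rm = TRUE)), 0.1)
  expect_equal(sum(da$regions$fdr_adj < 0.01, na.rm = TRUE), 0L)
})
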