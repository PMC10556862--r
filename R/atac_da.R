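#' Configuration for window-based differential accessibility
#'
#' Non-overlapping fixed windows over the genome, a minimum total cut-site
#' count per window, a global background estimated from large genomic bins,
#' a fold-change-over-background signal filter, gap/width-constrained
#' region merging, and region-level BH FDR. Tn5 cut sites are inferred from
#' fragment ends with the +4/-5 shift convention.
#'
#' @param window_bp Window width (bp), non-overlapping.
#' @param min_window_count Minimum total count (across samples) to retain a
#'   window.
#' @param background_bin_bp Bin width for the global background.
#' @param signal_fc Minimum fold change over background (on CPM scale) for
#'   a window to count as signal.
#' @param merge_gap_bp Maximum gap between signal windows merged into one
#'   region.
#' @param max_region_bp Maximum merged region width.
#' @param fdr Region-level BH threshold.
#' @param report_p Unadjusted p thresholds for the descriptive DA report.
#' @param report_lfc |log2 fold change| threshold for the report.
#' @param shift_plus,shift_minus Cut-site shifts for plus-/minus-strand
#'   fragment ends.
#' @param pseudocount Added in all log2 CPM computations.
#' @return List of class \code{atac_config}.
#' @export
atac_config <- function(window_bp = 50L, min_window_count = 50L,
                        background_bin_bp = 10000L, signal_fc = 3,
                        merge_gap_bp = 500L, max_region_bp = 5000L,
                        fdr = 0.01, report_p = c(0.001, 0.01),
                        report_lfc = 1, shift_plus = 4L, shift_minus = -5L,
                        pseudocount = 0.5) {
  stopifnot(window_bp > 0, merge_gap_bp >= 0, max_region_bp >= window_bp,
            signal_fc > 1, min_window_count >= 0)
  structure(list(window_bp = as.integer(window_bp),
                 min_window_count = as.integer(min_window_count),
                 background_bin_bp = as.integer(background_bin_bp),
                 signal_fc = signal_fc,
                 merge_gap_bp = as.integer(merge_gap_bp),
                 max_region_bp = as.integer(max_region_bp),
                 fdr = fdr, report_p = report_p, report_lfc = report_lfc,
                 shift_plus = as.integer(shift_plus),
                 shift_minus = as.integer(shift_minus),
                 pseudocount = pseudocount),
            class = "atac_config")
}

#' Tn5 cut sites from fragment intervals
#'
#' Each fragment end marks a transposase insertion: the plus-strand end is
#' \code{start + shift_plus}, the minus-strand end \code{end +
#' shift_minus}. In \code{mode = "both_ends"} (whole fragments, the
#' default) every record yields both cut sites; in \code{mode = "single"}
#' the record's strand field selects one. Sites falling off the chromosome
#' are clipped into range, with a count of clipped sites reported.
#'
#' @param fragments data.frame chrom/start/end/strand (0-based half-open).
#' @param chrom_sizes Named chromosome lengths.
#' @param cfg An \code{\link{atac_config}}.
#' @param mode "both_ends" or "single".
#' @return data.frame chrom, pos (0-based cut positions);
#'   \code{attr(, "n_clipped")} counts clipped sites.
#' @export
shift_cut_sites <- function(fragments, chrom_sizes, cfg = atac_config(),
                            mode = c("both_ends", "single")) {
  mode <- match.arg(mode)
  missing <- setdiff(unique(fragments$chrom), names(chrom_sizes))
  if (length(missing))
    stop("chromosome(s) absent from chrom_sizes: ",
         paste(missing, collapse = ", "))
  if (mode == "both_ends") {
    chrom <- rep(fragments$chrom, 2L)
    pos <- c(fragments$start + cfg$shift_plus,
             fragments$end + cfg$shift_minus)
  } else {
    stopifnot(all(fragments$strand %in% c("+", "-")))
    plus <- fragments$strand == "+"
    chrom <- fragments$chrom
    pos <- ifelse(plus, fragments$start + cfg$shift_plus,
                  fragments$end + cfg$shift_minus)
  }
  lim <- unname(chrom_sizes[chrom])
  clipped <- pos < 0 | pos >= lim
  if (any(clipped)) {
    warning(sum(clipped), " cut site(s) clipped to chromosome bounds")
    pos <- pmin(pmax(pos, 0L), lim - 1L)
  }
  out <- data.frame(chrom = chrom, pos = as.integer(pos),
                    stringsAsFactors = FALSE)
  attr(out, "n_clipped") <- sum(clipped)
  out
}

## internal: counts of positions per fixed-width tile, one column per sample
tile_counts <- function(cut_sites_list, chrom_sizes, tile_bp,
                        keep_empty = FALSE) {
  per_chrom <- lapply(names(chrom_sizes), function(ch) {
    n_tiles <- as.integer(ceiling(chrom_sizes[[ch]] / tile_bp))
    m <- vapply(cut_sites_list, function(cs) {
      p <- cs$pos[cs$chrom == ch]
      tabulate(p %/% tile_bp + 1L, nbins = n_tiles)
    }, integer(n_tiles))
    if (n_tiles == 1L) m <- matrix(m, nrow = 1L)
    keep <- if (keep_empty) rep(TRUE, n_tiles) else rowSums(m) > 0
    data.frame(chrom = rep(ch, sum(keep)),
               start = (which(keep) - 1L) * tile_bp,
               end = pmin(which(keep) * tile_bp,
                          as.integer(chrom_sizes[[ch]])),
               m[keep, , drop = FALSE],
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, per_chrom)
}

#' Count cut sites in non-overlapping fixed windows
#'
#' Window k of a chromosome covers \[k * window_bp, (k + 1) * window_bp).
#' Windows whose total count across all samples is below
#' \code{min_window_count} are discarded (the full partition is available
#' as \code{attr(, "all_windows_total")} for conservation checks).
#'
#' @param cut_sites_list Named list (per sample) of
#'   \code{\link{shift_cut_sites}} results.
#' @param chrom_sizes Named chromosome lengths.
#' @param cfg An \code{\link{atac_config}}.
#' @return data.frame: chrom, start, end, one count column per sample.
#' @export
count_windows <- function(cut_sites_list, chrom_sizes, cfg = atac_config()) {
  w <- tile_counts(cut_sites_list, chrom_sizes, cfg$window_bp)
  counts <- as.matrix(w[, -(1:3), drop = FALSE])
  total <- rowSums(counts)
  out <- w[total >= cfg$min_window_count, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_windows_total") <- sum(total)
  attr(out, "lib_sizes") <- vapply(cut_sites_list, nrow, 0L)
  out
}

## internal: summed-count log2 CPM abundance of interval rows
interval_abundance <- function(tab, lib_sizes, pseudocount) {
  counts <- as.matrix(tab[, -(1:3), drop = FALSE])
  log2((rowSums(counts) + pseudocount) / (sum(lib_sizes) + 1) * 1e6)
}

#' Global background abundance from large genomic bins
#'
#' The genome (all of it, including empty stretches) is binned at
#' \code{background_bin_bp}; the background is the median bin log2 CPM
#' rescaled to window width by subtracting
#' \code{log2(background_bin_bp / window_bp)}.
#'
#' @inheritParams count_windows
#' @return List: \code{background} (log2 CPM per window-width equivalent),
#'   \code{bins} (per-bin table with abundance).
#' @export
background_abundance <- function(cut_sites_list, chrom_sizes,
                                 cfg = atac_config()) {
  bins <- tile_counts(cut_sites_list, chrom_sizes, cfg$background_bin_bp,
                      keep_empty = TRUE)
  lib <- vapply(cut_sites_list, nrow, 0L)
  bins$abundance <- interval_abundance(bins, lib, cfg$pseudocount)
  bg <- stats::median(bins$abundance) -
    log2(cfg$background_bin_bp / cfg$window_bp)
  list(background = bg, bins = bins)
}

#' Keep windows well above background
#'
#' Retains windows whose summed-count log2 CPM abundance exceeds the global
#' background by at least \code{log2(signal_fc)} (boundary inclusive).
#'
#' @param windows A \code{\link{count_windows}} table.
#' @param background Scalar from \code{\link{background_abundance}}.
#' @param lib_sizes Per-sample totals (defaults to the attribute stored by
#'   \code{count_windows}).
#' @param cfg An \code{\link{atac_config}}.
#' @return Filtered window table with an \code{abundance} column.
#' @export
filter_signal_windows <- function(windows, background, lib_sizes = NULL,
                                  cfg = atac_config()) {
  if (is.null(lib_sizes)) lib_sizes <- attr(windows, "lib_sizes")
  ab <- interval_abundance(windows, lib_sizes, cfg$pseudocount)
  keep <- ab - background >= log2(cfg$signal_fc)
  out <- windows[keep, , drop = FALSE]
  out$abundance <- ab[keep]
  rownames(out) <- NULL
  out
}

#' NB likelihood-ratio test per window
#'
#' Shares the count-model machinery of the expression stage: per-window NB
#' GLM (log link, log size-factor offsets, trend-shrunk dispersions) with
#' condition plus nuisance covariates, tested by likelihood ratio against
#' the design without the condition column (chi-squared, 1 df).
#'
#' @param windows Window table (chrom, start, end, counts...).
#' @param condition 0/1 vector per sample.
#' @param W Optional nuisance covariate matrix (samples x k).
#' @param size_factors Per-sample factors; default library-size based
#'   (total counts normalized to geometric mean 1).
#' @param lib_sizes Per-sample cut-site totals used for the default size
#'   factors.
#' @return Window table with added logFC (log2), p, converged.
#' @export
test_windows <- function(windows, condition, W = NULL, size_factors = NULL,
                         lib_sizes = attr(windows, "lib_sizes")) {
  counts <- as.matrix(windows[, !(names(windows) %in%
                                    c("chrom", "start", "end",
                                      "abundance")), drop = FALSE])
  stopifnot(length(condition) == ncol(counts))
  if (is.null(size_factors)) {
    stopifnot(!is.null(lib_sizes))
    size_factors <- lib_sizes / exp(mean(log(lib_sizes)))
  }
  X <- cbind("(Intercept)" = 1, condition = condition)
  if (!is.null(W)) X <- cbind(X, W)
  X0 <- X[, colnames(X) != "condition", drop = FALSE]
  if (qr(X)$rank < ncol(X)) stop("design matrix is not full rank")
  stopifnot(table(condition)["0"] >= 2, table(condition)["1"] >= 2)

  disp <- estimate_dispersions(counts, X, size_factors)
  off <- log(size_factors)

  res <- vapply(seq_len(nrow(counts)), function(i) {
    y <- counts[i, ]
    fam <- MASS::negative.binomial(theta = 1 / disp$alpha[i])
    full <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y, family = fam, offset = off)),
      error = function(e) NULL)
    red <- tryCatch(
      suppressWarnings(stats::glm.fit(X0, y, family = fam, offset = off)),
      error = function(e) NULL)
    if (is.null(full) || is.null(red) || !full$converged ||
        any(!is.finite(full$coefficients)))
      return(c(NA_real_, NA_real_, 0))
    lrt <- max(0, red$deviance - full$deviance)
    c(full$coefficients["condition"] / log(2),
      stats::pchisq(lrt, df = 1, lower.tail = FALSE), 1)
  }, numeric(3))

  out <- windows
  out$logFC <- res[1, ]
  out$p <- res[2, ]
  out$converged <- res[3, ] == 1
  attr(out, "lib_sizes") <- lib_sizes
  attr(out, "dispersion") <- disp
  out
}

#' Merge signal windows into candidate regions
#'
#' Windows sorted by position are chained while the gap to the previous
#' window is at most \code{merge_gap_bp}; a chain whose span exceeds
#' \code{max_region_bp} is split into ceiling(span / max) contiguous
#' sub-chains of near-equal window count (recursively, so no region ever
#' exceeds the cap). Merging its own output changes nothing.
#'
#' @param windows Window table (rows become region members).
#' @param cfg An \code{\link{atac_config}}.
#' @return data.frame: region, chrom, start, end, n_windows; member row
#'   indices in \code{attr(, "members")}.
#' @export
merge_regions <- function(windows, cfg = atac_config()) {
  if (nrow(windows) == 0L)
    return(structure(data.frame(region = character(0), chrom = character(0),
                                start = integer(0), end = integer(0),
                                n_windows = integer(0)),
                     members = list()))
  ord <- order(windows$chrom, windows$start)
  w <- windows[ord, ]
  gap_prev <- c(Inf, w$start[-1] - w$end[-nrow(w)])
  new_chain <- gap_prev > cfg$merge_gap_bp |
    c(TRUE, w$chrom[-1] != w$chrom[-nrow(w)])
  chain <- cumsum(new_chain)

  split_chain <- function(idx) {
    span <- w$end[idx[length(idx)]] - w$start[idx[1]]
    if (span <= cfg$max_region_bp) return(list(idx))
    k <- ceiling(span / cfg$max_region_bp)
    parts <- split(idx, cut(seq_along(idx), k, labels = FALSE))
    unlist(lapply(parts, split_chain), recursive = FALSE)
  }
  members <- unlist(lapply(split(seq_len(nrow(w)), chain), split_chain),
                    recursive = FALSE)
  out <- data.frame(
    region = sprintf("region_%04d", seq_along(members)),
    chrom = vapply(members, function(i) w$chrom[i[1]], ""),
    start = vapply(members, function(i) w$start[i[1]], 0L),
    end = vapply(members, function(i) w$end[i[length(i)]], 0L),
    n_windows = lengths(members),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "members") <- lapply(members, function(i) ord[i])
  out
}

#' Region-level combined p-values and FDR
#'
#' Each region's p-value is the Simes combination of its member windows'
#' p-values; BH correction is applied across regions (never windows). The
#' region's logFC and direction come from its most significant window.
#' Regions whose windows are all NA are excluded (reported in
#' \code{attr(, "excluded")}).
#'
#' @param regions A \code{\link{merge_regions}} table.
#' @param windows The tested window table the regions were built from.
#' @param cfg An \code{\link{atac_config}}.
#' @return Region table with p, fdr_adj, logFC, direction.
#' @export
combine_and_correct <- function(regions, windows, cfg = atac_config()) {
  members <- attr(regions, "members")
  stats_list <- lapply(members, function(idx) {
    pv <- windows$p[idx]
    if (all(is.na(pv))) return(c(NA_real_, NA_real_))
    best <- idx[which.min(pv)]
    c(simes_p(pv), windows$logFC[best])
  })
  regions$p <- vapply(stats_list, `[`, 0, 1L)
  regions$logFC <- vapply(stats_list, `[`, 0, 2L)
  excluded <- regions$region[is.na(regions$p)]
  keep <- !is.na(regions$p)
  members <- members[keep]
  regions <- regions[keep, , drop = FALSE]
  regions$fdr_adj <- bh_adjust(regions$p)
  regions$direction <- sign(regions$logFC)
  attr(regions, "members") <- members
  attr(regions, "excluded") <- excluded
  regions
}

#' Descriptive differential accessibility report
#'
#' Counts of regions below each unadjusted p threshold with
#' |logFC| > \code{report_lfc}, split by direction, plus the count passing
#' region-level FDR.
#'
#' @param regions A \code{\link{combine_and_correct}} table.
#' @param cfg An \code{\link{atac_config}}.
#' @return data.frame: threshold, direction, n.
#' @export
report_da_counts <- function(regions, cfg = atac_config()) {
  rows <- list()
  for (thr in cfg$report_p) {
    for (dir in c("up", "down")) {
      sel <- !is.na(regions$p) & regions$p < thr &
        abs(regions$logFC) > cfg$report_lfc &
        (if (dir == "up") regions$logFC > 0 else regions$logFC < 0)
      rows[[length(rows) + 1L]] <-
        data.frame(threshold = paste0("p<", thr), direction = dir,
                   n = sum(sel))
    }
  }
  rows[[length(rows) + 1L]] <-
    data.frame(threshold = paste0("fdr<", cfg$fdr), direction = "any",
               n = sum(!is.na(regions$fdr_adj) & regions$fdr_adj < cfg$fdr))
  do.call(rbind, rows)
}

#' Annotate regions with the nearest gene and feature class
#'
#' The nearest gene is chosen by distance from the region midpoint to the
#' gene's transcription start site (ties broken toward the smaller TSS
#' coordinate). The feature class is TSS or TTS when the region overlaps
#' the site +- \code{site_flank_bp}; otherwise exon (if exon intervals are
#' supplied and overlapped), intron (overlapping the gene body), or
#' intergenic. Regulatory overlap is any-bp intersection with the
#' regulatory interval set.
#'
#' @param regions Region table (chrom, start, end, 0-based half-open).
#' @param genes data.frame chrom, start, end, name, strand (gene bodies;
#'   TSS = start on "+", end on "-").
#' @param exons Optional data.frame chrom, start, end of exon intervals.
#' @param regulatory Optional data.frame chrom, start, end of regulatory
#'   elements.
#' @param site_flank_bp Flank around TSS/TTS sites for classification.
#' @return Region table with nearest_gene, tss_distance, feature_class,
#'   regulatory columns.
#' @export
annotate_regions <- function(regions, genes, exons = NULL,
                             regulatory = NULL, site_flank_bp = 1000L) {
  stopifnot(all(genes$strand %in% c("+", "-")))
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  tts <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
  mid <- (regions$start + regions$end) %/% 2L

  nearest_gene <- rep(NA_character_, nrow(regions))
  tss_dist <- rep(NA_real_, nrow(regions))
  for (i in seq_len(nrow(regions))) {
    j <- which(genes$chrom == regions$chrom[i])
    if (length(j) == 0L) next
    d <- abs(tss[j] - mid[i])
    best <- j[d == min(d)]
    if (length(best) > 1L) best <- best[which.min(tss[best])]
    nearest_gene[i] <- genes$name[best]
    tss_dist[i] <- mid[i] - tss[best]
  }

  gr_regions <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end))
  gr_of <- function(chrom, start, end)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  hits_any <- function(gr_b) {
    GenomicRanges::countOverlaps(gr_regions, gr_b) > 0
  }

  ov_tss <- hits_any(gr_of(genes$chrom, pmax(tss - site_flank_bp, 0L),
                           tss + site_flank_bp + 1L))
  ov_tts <- hits_any(gr_of(genes$chrom, pmax(tts - site_flank_bp, 0L),
                           tts + site_flank_bp + 1L))
  ov_gene <- hits_any(gr_of(genes$chrom, genes$start, genes$end))
  ov_exon <- if (!is.null(exons) && nrow(exons) > 0)
    hits_any(gr_of(exons$chrom, exons$start, exons$end))
  else rep(FALSE, nrow(regions))

  cls <- ifelse(ov_tss, "TSS",
         ifelse(ov_tts, "TTS",
         ifelse(ov_exon, "exon",
         ifelse(ov_gene, "intron", "intergenic"))))
  cls[is.na(nearest_gene)] <- "intergenic"

  regions$nearest_gene <- nearest_gene
  regions$tss_distance <- tss_dist
  regions$feature_class <- cls
  regions$regulatory <- if (!is.null(regulatory) && nrow(regulatory) > 0)
    hits_any(gr_of(regulatory$chrom, regulatory$start, regulatory$end))
  else FALSE
  regions
}

#' Run the full window-based differential accessibility stage
#'
#' Fragment BEDs to annotated, FDR-corrected regions: cut-site shifting,
#' window counting, background estimation, signal filtering, replicate-set
#' RUV (k factors), per-window NB LRT, merging, Simes + BH, and the
#' descriptive report. A filter ledger (window/region counts in and out of
#' every step) is attached.
#'
#' @param fragment_files Named vector of per-sample fragment BED paths.
#' @param chrom_sizes Named chromosome lengths.
#' @param condition 0/1 per sample (order of \code{fragment_files}).
#' @param ruv_sets Condition-homogeneous replicate sets for factor
#'   estimation; defaults to the condition groups themselves.
#' @param ruv_k Number of nuisance factors (0 disables RUV).
#' @param cfg An \code{\link{atac_config}}.
#' @param mode Cut-site mode, see \code{\link{shift_cut_sites}}.
#' @return List: windows (tested), regions (corrected), report, background,
#'   ledger.
#' @export
run_atac_da <- function(fragment_files, chrom_sizes, condition,
                        ruv_sets = as.character(condition), ruv_k = 5,
                        cfg = atac_config(), mode = "both_ends") {
  cuts <- lapply(fragment_files, function(f)
    shift_cut_sites(read_bed(f), chrom_sizes, cfg, mode))
  windows <- count_windows(cuts, chrom_sizes, cfg)
  ledger <- data.frame(step = "count_windows",
                       n_in = NA_integer_, n_out = nrow(windows))
  bg <- background_abundance(cuts, chrom_sizes, cfg)
  signal <- filter_signal_windows(windows, bg$background, cfg = cfg)
  ledger <- rbind(ledger, data.frame(step = "filter_signal_windows",
                                     n_in = nrow(windows),
                                     n_out = nrow(signal)))
  W <- NULL
  if (!is.null(ruv_sets) && ruv_k > 0) {
    if (any(tapply(condition, ruv_sets, function(x) length(unique(x))) > 1))
      warning("ruv_sets mix conditions; factors may absorb the signal")
    counts <- as.matrix(signal[, names(fragment_files), drop = FALSE])
    W <- ruv_replicates(counts, ruv_sets, k = ruv_k)$W
  }
  tested <- test_windows(signal, condition, W = W,
                         lib_sizes = attr(windows, "lib_sizes"))
  regions <- merge_regions(tested, cfg)
  ledger <- rbind(ledger, data.frame(step = "merge_regions",
                                     n_in = nrow(tested),
                                     n_out = nrow(regions)))
  regions <- combine_and_correct(regions, tested, cfg)
  ledger <- rbind(ledger, data.frame(step = "combine_and_correct",
                                     n_in = nrow(regions) +
                                       length(attr(regions, "excluded")),
                                     n_out = nrow(regions)))
  list(windows = tested, regions = regions,
       report = report_da_counts(regions, cfg),
       background = bg$background, ledger = ledger)
}
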