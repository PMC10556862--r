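#' Parameters for the ATAC fragment simulator
#'
#' Describes a small synthetic genome with planted accessible peaks, a
#' fraction of which differ between two conditions, plus replicate-set batch
#' structure. Fragment lengths follow a two-component normal mixture
#' (sub-nucleosomal ~60 bp, mono-nucleosomal ~200 bp), mimicking the insert
#' length profile of ATAC libraries.
#'
#' @param chrom_sizes Named integer vector, chromosome -> length (bp).
#' @param n_peaks Number of accessible peaks planted (non-overlapping).
#' @param peak_width_range Min/max peak width (bp).
#' @param frac_differential Fraction of peaks with a condition effect.
#' @param effect_log2fc Log2 fold change of differential peaks (sign drawn
#'   per peak; recorded in the ground truth).
#' @param fragments_per_sample Expected fragments per sample.
#' @param background_fraction Fraction of fragments placed uniformly on the
#'   genome rather than in peaks.
#' @param groups data.frame with columns \code{condition},
#'   \code{n_replicates}; replicate i of every condition belongs to
#'   replicate set \code{rs<i>} (paired processing batches).
#' @param batch_shift Numeric vector, one log2 offset per replicate set,
#'   applied to a seeded half of the peaks (batch-sensitive peaks); recycled.
#' @param frag_len_mix Mixture weight, mean and sd for the two fragment
#'   length components: list(w, mean, sd) with two entries each.
#' @param seed Integer seed.
#' @return Validated list of class \code{atac_sim_params}.
#' @export
atac_sim_params <- function(chrom_sizes = c(chrS1 = 1e6, chrS2 = 1e6),
                            n_peaks = 200,
                            peak_width_range = c(300, 800),
                            frac_differential = 0.1,
                            effect_log2fc = 2,
                            fragments_per_sample = 2e5,
                            background_fraction = 0.3,
                            groups = data.frame(
                              condition = c("DMSO", "DEHP"),
                              n_replicates = c(6L, 6L)),
                            batch_shift = c(0, 0, 0, 0, 0, 0),
                            frag_len_mix = list(w = c(0.5, 0.5),
                                                mean = c(60, 200),
                                                sd = c(10, 25)),
                            seed = 1L) {
  p <- list(chrom_sizes = chrom_sizes, n_peaks = as.integer(n_peaks),
            peak_width_range = peak_width_range,
            frac_differential = frac_differential,
            effect_log2fc = effect_log2fc,
            fragments_per_sample = as.integer(fragments_per_sample),
            background_fraction = background_fraction,
            groups = as.data.frame(groups),
            batch_shift = batch_shift,
            frag_len_mix = frag_len_mix,
            seed = as.integer(seed))
  stopifnot(all(p$chrom_sizes > 0), !is.null(names(p$chrom_sizes)),
            p$frac_differential >= 0, p$frac_differential <= 1,
            p$background_fraction >= 0, p$background_fraction <= 1,
            p$peak_width_range[2] >= p$peak_width_range[1],
            all(p$groups$n_replicates >= 1))
  if (p$n_peaks > 0 &&
      p$peak_width_range[2] > min(p$chrom_sizes))
    stop("peaks wider than the smallest chromosome")
  class(p) <- "atac_sim_params"
  p
}

#' Simulate per-sample ATAC fragment BED files with planted peaks
#'
#' Peaks are placed without overlap on the synthetic genome; each sample's
#' fragments are split between uniform background and peak-derived reads.
#' Differential peaks have their expected fragment share scaled by
#' \code{2^(+-effect_log2fc)} in the non-reference condition; batch-sensitive
#' peaks are scaled by \code{2^batch_shift\[replicate set\]} in every sample
#' of that replicate set. Fragment centers are uniform within the peak.
#'
#' @param params An \code{\link{atac_sim_params}} object.
#' @param dir Directory for the 6-column BED files (one per sample).
#' @return List with \code{files} (named vector of BED paths),
#'   \code{design} (sample sheet: sample, condition, replicate_set),
#'   \code{truth} (peaks data.frame with chrom, start, end, differential,
#'   direction, batch_sensitive), and \code{chrom_sizes}.
#' @export
simulate_atac_fragments <- function(params, dir) {
  p <- params
  set.seed(p$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  ## non-overlapping peak placement: sample starts, retry on overlap
  peaks <- place_peaks(p$chrom_sizes, p$n_peaks, p$peak_width_range)
  n_diff <- round(p$frac_differential * p$n_peaks)
  diff_idx <- if (n_diff > 0) sort(sample.int(p$n_peaks, n_diff)) else integer(0)
  peaks$differential <- seq_len(max(p$n_peaks, 0L)) %in% diff_idx
  peaks$direction <- 0
  if (n_diff > 0)
    peaks$direction[diff_idx] <- sample(c(-1, 1), n_diff, replace = TRUE)
  peaks$batch_sensitive <- FALSE
  if (p$n_peaks > 0)
    peaks$batch_sensitive[sample.int(p$n_peaks, floor(p$n_peaks / 2))] <- TRUE
  ## baseline peak strength varies ~4-fold
  peaks$weight <- 2^stats::rnorm(p$n_peaks, 0, 0.5)

  g <- p$groups
  design <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    reps <- seq_len(g$n_replicates[i])
    data.frame(sample = sprintf("%s_r%d", g$condition[i], reps),
               condition = g$condition[i],
               replicate_set = sprintf("rs%d", reps),
               stringsAsFactors = FALSE)
  }))
  ref_condition <- g$condition[1]
  shift_of_set <- function(rs) {
    i <- as.integer(sub("^rs", "", rs))
    p$batch_shift[((i - 1L) %% length(p$batch_shift)) + 1L]
  }

  genome_len <- sum(p$chrom_sizes)
  chrom_offsets <- cumsum(c(0, p$chrom_sizes))[seq_along(p$chrom_sizes)]
  names(chrom_offsets) <- names(p$chrom_sizes)

  files <- character(nrow(design))
  names(files) <- design$sample
  for (s in seq_len(nrow(design))) {
    n_frag <- p$fragments_per_sample
    n_bg <- stats::rbinom(1L, n_frag, p$background_fraction)
    n_pk <- n_frag - n_bg

    ## per-peak expected share for this sample
    if (p$n_peaks > 0 && n_pk > 0) {
      w <- peaks$weight
      treated <- design$condition[s] != ref_condition
      if (treated && n_diff > 0) {
        w[diff_idx] <- w[diff_idx] * 2^(peaks$direction[diff_idx] *
                                          p$effect_log2fc)
      }
      bs <- shift_of_set(design$replicate_set[s])
      w[peaks$batch_sensitive] <- w[peaks$batch_sensitive] * 2^bs
      pk_of_frag <- sample.int(p$n_peaks, n_pk, replace = TRUE,
                               prob = w / sum(w))
      centers_pk <- peaks$start[pk_of_frag] +
        floor(stats::runif(n_pk) * (peaks$end[pk_of_frag] -
                                      peaks$start[pk_of_frag]))
      chrom_pk <- peaks$chrom[pk_of_frag]
    } else {
      centers_pk <- integer(0); chrom_pk <- character(0)
    }

    if (n_bg > 0) {
      pos <- floor(stats::runif(n_bg) * genome_len)
      ci <- findInterval(pos, cumsum(p$chrom_sizes), left.open = TRUE) + 1L
      chrom_bg <- names(p$chrom_sizes)[ci]
      centers_bg <- as.integer(pos - chrom_offsets[ci])
    } else {
      centers_bg <- integer(0); chrom_bg <- character(0)
    }

    chrom <- c(chrom_pk, chrom_bg)
    center <- c(centers_pk, centers_bg)
    n <- length(center)

    comp <- sample.int(2L, n, replace = TRUE, prob = p$frag_len_mix$w)
    len <- pmax(20L, round(stats::rnorm(n, p$frag_len_mix$mean[comp],
                                        p$frag_len_mix$sd[comp])))
    start <- as.integer(pmax(0, center - len %/% 2))
    end <- as.integer(pmin(p$chrom_sizes[chrom], start + len))
    strand <- sample(c("+", "-"), n, replace = TRUE)

    frag <- data.frame(chrom = chrom, start = start, end = end,
                       name = sprintf("frag_%d", seq_len(n)),
                       score = 0L, strand = strand,
                       stringsAsFactors = FALSE)
    frag <- frag[order(frag$chrom, frag$start, frag$end), ]
    files[s] <- file.path(dir, paste0(design$sample[s], ".bed"))
    write_bed(frag, files[s])
  }

  list(files = files, design = design, truth = list(peaks = peaks),
       chrom_sizes = p$chrom_sizes)
}

place_peaks <- function(chrom_sizes, n_peaks, width_range) {
  if (n_peaks == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  out <- vector("list", n_peaks)
  placed <- list()   # per-chrom IRanges of occupied space
  for (ch in names(chrom_sizes)) placed[[ch]] <- IRanges::IRanges()
  i <- 1L; tries <- 0L
  while (i <= n_peaks) {
    tries <- tries + 1L
    if (tries > 50L * n_peaks) stop("cannot place non-overlapping peaks; ",
                                    "genome too small for n_peaks")
    ch <- sample(names(chrom_sizes), 1L,
                 prob = chrom_sizes / sum(chrom_sizes))
    w <- sample(seq(width_range[1], width_range[2]), 1L)
    st <- sample.int(chrom_sizes[[ch]] - w, 1L) - 1L
    cand <- IRanges::IRanges(st + 1L, st + w)   # 1-based closed for IRanges
    if (length(IRanges::findOverlaps(cand, placed[[ch]])) > 0) next
    placed[[ch]] <- c(placed[[ch]], cand)
    out[[i]] <- data.frame(chrom = ch, start = st, end = st + w)
    i <- i + 1L
  }
  peaks <- do.call(rbind, out)
  peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
}

#' Read / write 6-column BED (0-based half-open)
#'
#' Minimal tab-separated interchange for fragment and annotation intervals:
#' chrom, start, end, name, score, strand, no header. Writing then reading
#' is the identity; the text round-trips byte-identically.
#'
#' @param path File path.
#' @param x data.frame with columns chrom, start, end, name, score, strand.
#' @return \code{read_bed}: data.frame with those six columns.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end",
                                       "name", "score", "strand"),
                         colClasses = c("character", "integer", "integer",
                                        "character", "integer", "character"))
  x
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end", "name", "score", "strand")
                %in% names(x)))
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  utils::write.table(x[, c("chrom", "start", "end", "name", "score",
                           "strand")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
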