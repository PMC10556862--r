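#' Read / write GMT gene-set files
#'
#' Tab-separated, one set per line: set id, description, member genes.
#'
#' @param path File path.
#' @param sets Named list of character vectors (member genes); descriptions
#'   taken from \code{attr(sets, "description")} or set to the id.
#' @return \code{read_gmt}: named list of gene vectors with a
#'   \code{description} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate set ids in GMT")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[`, "", 2L), ids)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id)
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Rank genes for preranked enrichment
#'
#' Descending by the per-gene test statistic (the Wald statistic of the
#' differential expression stage); ties broken by gene id so the order is
#' deterministic. NA statistics are excluded with a message.
#'
#' @param de_results data.frame with columns \code{gene} and
#'   \code{wald_stat} (or a named numeric vector of statistics).
#' @return data.frame of class \code{ranked_list}: gene, score, in
#'   descending score order.
#' @export
rank_genes <- function(de_results) {
  if (is.numeric(de_results)) {
    de_results <- data.frame(gene = names(de_results),
                             wald_stat = unname(de_results))
  }
  if (anyDuplicated(de_results$gene)) stop("duplicate gene ids")
  drop <- is.na(de_results$wald_stat)
  if (any(drop)) message(sum(drop), " gene(s) with NA statistic excluded")
  x <- de_results[!drop, c("gene", "wald_stat")]
  x <- x[order(-x$wald_stat, x$gene), ]
  out <- data.frame(gene = x$gene, score = x$wald_stat,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Weighted running-sum enrichment score
#'
#' Classic weighted Kolmogorov-Smirnov statistic: walking down the ranked
#' list, set members ("hits") increment the running sum by
#' \code{|score|^p / sum_hits |score|^p} and non-members decrement it by
#' \code{1 / (N - N_hits)}; the enrichment score is the signed maximum
#' deviation from zero. The sum starts and ends at zero.
#'
#' @param ranked A \code{\link{rank_genes}} result.
#' @param gene_set Character vector of member genes.
#' @param p Weight exponent (1 = classic weighted).
#' @return List: \code{es}, \code{running} (running sum after each gene),
#'   \code{hits} (logical per position), \code{leading_edge} (genes up to
#'   and including the extremum, restricted to hits).
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  hits <- ranked$gene %in% gene_set
  n <- nrow(ranked)
  nh <- sum(hits)
  if (nh == 0 || nh == n)
    stop("gene set must intersect, and not exhaust, the ranked universe")
  w <- abs(ranked$score)^p
  inc <- numeric(n)
  inc[hits] <- w[hits] / sum(w[hits])
  inc[!hits] <- -1 / (n - nh)
  running <- cumsum(inc)
  i_max <- which.max(abs(running))
  es <- running[i_max]
  le <- if (es >= 0) ranked$gene[seq_len(i_max)][hits[seq_len(i_max)]]
        else ranked$gene[i_max:n][hits[i_max:n]]
  list(es = es, running = running, hits = hits, leading_edge = le)
}

## ES from hit positions only (O(nh log nh)); used for permutations
es_from_positions <- function(pos, w, n) {
  pos <- sort(pos)
  nh <- length(pos)
  wh <- w[pos]
  cw <- cumsum(wh) / sum(wh)
  miss_before <- (pos - seq_len(nh)) / (n - nh)   # misses up to each hit
  top <- cw - miss_before                         # running sum at each hit
  bottom <- c(0, cw[-nh]) - miss_before           # just before each hit
  m <- c(top, bottom)
  m[which.max(abs(m))]
}

#' Preranked GSEA with a permutation null
#'
#' For each gene set, the enrichment score against the observed ranking,
#' and a gene-label permutation null (random positions in the list, same
#' set size). NES is the ES divided by the mean |null ES| of matching sign;
#' the permutation p-value is the +1-smoothed sign-matched exceedance
#' fraction; q-values are BH-adjusted within sign strata. Deterministic for
#' a fixed seed.
#'
#' @param ranked A \code{\link{rank_genes}} result.
#' @param gene_sets Named list of gene vectors (e.g. \code{read_gmt}).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param min_size,max_size Set size bounds (after intersection with the
#'   universe); sets outside are skipped and listed in
#'   \code{attr(, "skipped")}.
#' @param p Weight exponent.
#' @return data.frame: set, size, es, nes, p_perm, q, leading_edge
#'   (semicolon-joined).
#' @export
gsea_preranked <- function(ranked, gene_sets, n_perm = 10000, seed = 1L,
                           min_size = 5, max_size = 500, p = 1) {
  stopifnot(n_perm >= 100)
  set.seed(seed)
  n <- nrow(ranked)
  w <- abs(ranked$score)^p

  sizes <- vapply(gene_sets, function(s) sum(ranked$gene %in% s), 0L)
  use <- sizes >= min_size & sizes <= max_size & sizes < n
  skipped <- names(gene_sets)[!use]

  ## share permutation nulls across sets of equal size
  null_cache <- new.env(parent = emptyenv())
  null_for_size <- function(sz) {
    key <- as.character(sz)
    if (!is.null(null_cache[[key]])) return(null_cache[[key]])
    es0 <- vapply(seq_len(n_perm), function(b)
      es_from_positions(sample.int(n, sz), w, n), 0)
    null_cache[[key]] <- es0
    es0
  }

  rows <- lapply(names(gene_sets)[use], function(id) {
    obs <- enrichment_score(ranked, gene_sets[[id]], p)
    es0 <- null_for_size(sizes[[id]])
    same <- if (obs$es >= 0) es0[es0 >= 0] else es0[es0 < 0]
    denom <- mean(abs(same))
    nes <- if (length(same) > 0 && denom > 0) obs$es / denom else NA_real_
    p_perm <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
    data.frame(set = id, size = sizes[[id]], es = obs$es, nes = nes,
               p_perm = p_perm,
               leading_edge = paste(obs$leading_edge, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(0), size = integer(0), es = numeric(0),
               nes = numeric(0), p_perm = numeric(0),
               leading_edge = character(0))
  out$q <- rep(NA_real_, nrow(out))
  if (nrow(out) > 0) {
    pos <- !is.na(out$es) & out$es >= 0
    out$q[pos] <- bh_adjust(out$p_perm[pos])
    out$q[!pos] <- bh_adjust(out$p_perm[!pos])
  }
  attr(out, "skipped") <- skipped
  out
}

#' Gene sets significant in every contrast
#'
#' Simple intersection reporting across multiple GSEA result tables: sets
#' with q below the threshold in all of them, with their NES signs.
#'
#' @param results Named list of \code{\link{gsea_preranked}} tables.
#' @param q_threshold Significance threshold on q.
#' @return data.frame: set, one NES column per contrast.
#' @export
gsea_intersection <- function(results, q_threshold = 0.05) {
  sig <- lapply(results, function(r) r$set[!is.na(r$q) & r$q < q_threshold])
  common <- Reduce(intersect, sig)
  out <- data.frame(set = common, stringsAsFactors = FALSE)
  for (nm in names(results)) {
    out[[paste0("nes_", nm)]] <-
      results[[nm]]$nes[match(common, results[[nm]]$set)]
  }
  out
}
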