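test_that("relevance filter reproduces hand-enumerated keep/drop sets", {
  # 4 + 4 samples; CPM equals raw counts when columns sum to 1e6
  mk <- function(...) matrix(c(...), nrow = 1)
  base <- matrix(0, 5, 8,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  base["g1", ] <- c(2, 2, 2, 0, 0, 0, 0, 0)   # 3/4 = 75% of group A
  base["g2", ] <- c(0, 0, 0, 0, 2, 2, 2, 2)   # only group B
  base["g3", ] <- c(2, 2, 0, 0, 2, 2, 0, 0)   # 50% in both: drop
  base["g4", ] <- c(1, 1, 1, 1, 0, 0, 0, 0)   # exactly 1 CPM everywhere in A
  # filler gene to fix library sizes at 1e6 so counts are CPM
  fill <- 1e6 - colSums(base)
  counts <- rbind(base, filler = fill)
  keep <- relevance_filter(counts, paste0("s", 1:4), paste0("s", 5:8))
  expect_true(all(c("g1", "g2", "g4") %in% keep))
  expect_false("g3" %in% keep)
  # g4 at exactly min_cpm counts as expressed (boundary inclusive)
  expect_true("g4" %in% keep)
})

test_that("size factors match construction and the DESeq2 reference", {
  counts <- tiny_counts(100, 4, seed = 31, mu = 200)
  twoX <- cbind(counts[, 1, drop = FALSE], counts[, 1, drop = FALSE] * 2L)
  colnames(twoX) <- c("a", "b")
  sf <- size_factors(twoX)
  expect_equal(unname(sf["b"] / sf["a"]), 2, tolerance = 1e-12)
  expect_equal(exp(mean(log(size_factors(counts)))), 1, tolerance = 1e-12)
  skip_if_not_installed("DESeq2")
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(size_factors(counts), ref / exp(mean(log(ref))),
               tolerance = 1e-8)
})

test_that("dispersion estimation is calibrated on Poisson and NB data", {
  X <- cbind(1, rep(0:1, each = 6))
  set.seed(32)
  cts_p <- matrix(rpois(200 * 12, 100), 200,
                  dimnames = list(paste0("g", 1:200), NULL))
  dp <- estimate_dispersions(cts_p, X, rep(1, 12))
  expect_lte(median(dp$alpha), 0.01)
  cts_nb <- matrix(rnbinom(200 * 12, mu = 100, size = 10), 200,
                   dimnames = list(paste0("g", 1:200), NULL))
  dn <- estimate_dispersions(cts_nb, X, rep(1, 12))
  expect_gte(median(dn$alpha), 0.05)
  expect_lte(median(dn$alpha), 0.2)
  # single gene: no trend, gene-wise estimate returned
  one <- estimate_dispersions(cts_nb[1, , drop = FALSE], X, rep(1, 12))
  expect_equal(one$alpha, one$genewise)
})

test_that("Wald test gives zero effect for identical groups and recovers
           planted fold changes", {
  counts <- tiny_counts(50, 4, seed = 33, mu = 300)
  both <- cbind(counts, counts)
  colnames(both) <- paste0("s", 1:8)
  X <- cbind("(Intercept)" = 1, condition = rep(0:1, each = 4))
  r <- nb_wald(both, X, "condition", alpha = 0.1,
               size_factors = rep(1, 8))
  expect_equal(max(abs(r$log2fc)), 0, tolerance = 1e-8)
  expect_equal(max(abs(r$wald_stat)), 0, tolerance = 1e-6)

  p <- rna_sim_params(
    n_genes = 600, de_fraction = 0.1,
    effect_profiles = list(function(d) ifelse(d >= 1 & d <= 4, 1, 0)),
    groups = pooled_groups(), seed = 34)
  sim <- simulate_rna_counts(p)
  de <- run_de_contrast(sim$counts, sim$design, "DEHP", ruv_k = 2)
  planted <- de[de$gene %in% sim$truth$de_genes$gene, ]
  expect_lte(abs(mean(planted$log2fc) - 1), 0.2)
})

test_that("design rank is checked", {
  counts <- tiny_counts(5, 4)
  X <- cbind(1, c(0, 0, 1, 1), c(0, 0, 2, 2))
  expect_error(nb_wald(counts, X, 2), "full rank")
})

test_that("spike filter follows the displayed pass rule", {
  counts <- rbind(even = c(10, 10, 10), spiked = c(100, 1, 1))
  colnames(counts) <- paste0("s", 1:3)
  r <- spurious_spike_filter(counts, c("even", "spiked"), paste0("s", 1:3))
  expect_equal(r$threshold[1], 1.4 * 3^(-0.66))
  expect_false(r$flagged[r$gene == "even"])    # 0.333 < 0.678
  expect_true(r$flagged[r$gene == "spiked"])   # 0.980 >= 0.678
  # n = 1: threshold 1.4 > any proportion, always passes
  r1 <- spurious_spike_filter(counts, "spiked", "s1")
  expect_false(r1$flagged)
  # zero-total gene passes trivially
  z <- rbind(zero = c(0, 0, 0)); colnames(z) <- paste0("s", 1:3)
  expect_false(spurious_spike_filter(z, "zero", paste0("s", 1:3))$flagged)
})

test_that("planted single-replicate spikes are flagged at high rate", {
  p <- rna_sim_params(n_genes = 500, de_fraction = 0, spike_rate = 0.02,
                      spike_multiplier = 20, groups = pooled_groups(),
                      seed = 35)
  sim <- simulate_rna_counts(p)
  sp <- sim$truth$spiked_cells
  smp_grp <- setNames(sim$design$group, sim$design$sample)
  flagged <- mapply(function(g, s) {
    grp_samples <- sim$design$sample[sim$design$group == smp_grp[s]]
    spurious_spike_filter(sim$counts, g, grp_samples)$flagged
  }, sp$gene, sp$sample)
  expect_gte(mean(flagged), 0.9)
})

test_that("relevance filter is invariant to permuting samples in groups", {
  counts <- tiny_counts(80, 8, seed = 36, mu = 20)
  a <- paste0("s", 1:4); b <- paste0("s", 5:8)
  k1 <- relevance_filter(counts, a, b)
  k2 <- relevance_filter(counts[, c(2, 4, 1, 3, 8, 5, 7, 6)],
                         a[c(2, 4, 1, 3)], b[c(4, 1, 3, 2)])
  expect_equal(sort(k1), sort(k2))
})

test_that("final calls respect the FDR and spike-flag contract", {
  p <- rna_sim_params(
    n_genes = 500, de_fraction = 0.1,
    effect_profiles = list(function(d) ifelse(d >= 1 & d <= 4, 1.5, 0)),
    spike_rate = 0.005, spike_multiplier = 30,
    groups = pooled_groups(), seed = 37)
  sim <- simulate_rna_counts(p)
  de <- run_de_contrast(sim$counts, sim$design, "DEHP", ruv_k = 2)
  called <- de$final_call %in% c("up", "down")
  expect_true(all(de$fdr_adj[called] < 0.01))
  expect_true(all(!de$spike_flag_treatment[called]))
  expect_true(all(!de$spike_flag_control[called]))
  expect_true(all(de$log2fc[de$final_call == "up"] > 0))
  expect_true(all(de$log2fc[de$final_call == "down"] < 0))
  led <- attr(de, "ledger")
  expect_true(all(led$n_out <= led$n_in | is.na(led$n_in)))
})
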