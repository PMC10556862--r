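test_that("biotype fractions are direct percentages summing to 100", {
  counts <- matrix(c(3, 1), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  map <- data.frame(gene = c("g1", "g2"), biotype = c("A", "B"))
  f <- biotype_fractions(counts, map)
  expect_equal(f["s1", "A"], 75)
  expect_equal(f["s1", "B"], 25)

  map1 <- data.frame(gene = c("g1", "g2"), biotype = c("A", "A"))
  expect_equal(unname(biotype_fractions(counts, map1)[1, "A"]), 100)

  # unmapped genes go to an explicit bucket; rows still sum to 100
  map2 <- data.frame(gene = "g1", biotype = "A")
  f2 <- biotype_fractions(counts, map2)
  expect_equal(unname(rowSums(f2)), 100)
  expect_true("unannotated" %in% colnames(f2))

  zero <- cbind(counts, s2 = c(0, 0))
  expect_error(biotype_fractions(zero, map), "s2")
})

test_that("planted biotype proportions are recovered within tolerance", {
  p <- rna_sim_params(n_genes = 3000, seed = 12)
  sim <- simulate_rna_counts(p)
  f <- biotype_fractions(sim$counts, sim$biotype)
  # gene-count proportions match the multinomial draw; read fractions are
  # weighted by expression, so compare gene tallies instead
  tab <- table(sim$biotype$biotype) / nrow(sim$biotype)
  expect_lt(max(abs(tab[names(p$biotype_proportions)] -
                      p$biotype_proportions)), 0.03)
  expect_true(all(colnames(f) %in% c(names(p$biotype_proportions),
                                     "unannotated")))
})

test_that("biotype retention keeps >= min_pct in any sample, inclusively", {
  f <- rbind(s1 = c(A = 99, B = 1.0, C = 0),
             s2 = c(A = 99.01, B = 0.99, C = 0))
  expect_equal(retain_major_biotypes(f, 1), c("A", "B"))  # B: exactly 1.0
  f2 <- rbind(s1 = c(A = 99.01, B = 0.99), s2 = c(A = 99.01, B = 0.99))
  expect_equal(retain_major_biotypes(f2, 1), "A")
  expect_equal(retain_major_biotypes(f2, 0), c("A", "B"))
  # monotone: raising the floor never enlarges the kept set
  for (cut in c(0, 0.5, 1, 2, 50)) {
    expect_true(all(retain_major_biotypes(f, cut + 0.5) %in%
                      retain_major_biotypes(f, cut)))
  }
})

test_that("IQR outlier rule matches hand-computed type-7 fences", {
  f <- matrix(c(10, 10, 10, 100), 4, 1,
              dimnames = list(paste0("s", 1:4), "A"))
  r <- flag_outliers_iqr(f, rep("g", 4))
  # type 7 quartiles of [10,10,10,100]: Q1 = 10, Q3 = 32.5, IQR = 22.5
  fen <- r$fences
  expect_equal(fen$lower, 10 - 1.5 * 22.5)
  expect_equal(fen$upper, 32.5 + 1.5 * 22.5)   # 66.25
  expect_equal(r$flags$sample, "s4")
  expect_equal(r$flags$side, "high")

  # equal values: IQR 0, nothing flagged
  f2 <- matrix(rep(5, 4), 4, 1, dimnames = list(paste0("s", 1:4), "A"))
  expect_equal(nrow(flag_outliers_iqr(f2, rep("g", 4))$flags), 0L)

  # a value exactly on the fence is not flagged (strict inequality)
  v <- c(10, 20, 30, 40)
  q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  up <- q[2] + 1.5 * (q[2] - q[1])
  f4 <- matrix(c(v[1:3], up), 4, 1,
               dimnames = list(paste0("s", 1:4), "A"))
  expect_equal(nrow(flag_outliers_iqr(f4, rep("g", 4))$flags), 0L)

  expect_warning(flag_outliers_iqr(f[1:2, , drop = FALSE], rep("g", 2)),
                 "fewer than 3")
})

test_that("negating values swaps low and high flags", {
  set.seed(13)
  f <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10),
                                                c("A", "B")))
  r1 <- flag_outliers_iqr(f, rep("g", 10))
  r2 <- flag_outliers_iqr(-f, rep("g", 10))
  key <- function(r) r$flags[order(r$flags$sample, r$flags$biotype),
                             c("sample", "biotype")]
  expect_equal(key(r1), key(r2))
  side1 <- r1$flags$side[order(r1$flags$sample, r1$flags$biotype)]
  side2 <- r2$flags$side[order(r2$flags$sample, r2$flags$biotype)]
  expect_equal(side1, rev(c("low", "high"))[match(side2, c("low", "high"))])
})

test_that("split_biotype partitions exactly and conserves totals", {
  counts <- tiny_counts(10, 4)
  map <- data.frame(gene = rownames(counts),
                    biotype = c(rep("protein_coding", 8), rep("snoRNA", 2)))
  sp <- split_biotype(counts, map)
  expect_equal(nrow(sp$main), 8)
  expect_equal(nrow(sp$split), 2)
  expect_equal(length(intersect(rownames(sp$main), rownames(sp$split))), 0L)
  expect_equal(colSums(sp$main) + colSums(sp$split), colSums(counts))

  map2 <- data.frame(gene = rownames(counts),
                     biotype = rep("protein_coding", 10))
  expect_warning(sp2 <- split_biotype(counts, map2), "no genes")
  expect_equal(nrow(sp2$split), 0L)
  expect_equal(sp2$main, counts)
})

test_that("flagged samples in key biotypes are dropped, others kept", {
  counts <- tiny_counts(10, 4)
  design <- data.frame(sample = colnames(counts))
  out <- list(flags = data.frame(sample = c("s1", "s2"),
                                 biotype = c("protein_coding", "rRNA"),
                                 group = "g", side = "high",
                                 value = c(9, 9)))
  kept <- drop_flagged_samples(counts, design, out)
  expect_equal(kept$removed, "s1")
  expect_false("s1" %in% colnames(kept$counts))
  expect_true("s2" %in% colnames(kept$counts))
})
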