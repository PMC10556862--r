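test_that("ranking is descending with deterministic tie-breaks", {
  r <- rank_genes(c(a = 2, b = -1, c = 3))
  expect_equal(r$gene, c("c", "a", "b"))
  r2 <- rank_genes(c(z = 1, a = 1, m = 1))
  expect_equal(r2$gene, c("a", "m", "z"))   # lexicographic on ties
  expect_message(r3 <- rank_genes(c(a = 1, b = NA)), "1 gene")
  expect_equal(r3$gene, "a")
  expect_error(rank_genes(data.frame(gene = c("a", "a"),
                                     wald_stat = c(1, 2))), "duplicate")
})

test_that("enrichment score matches hand-computed running sums", {
  rk <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                   score = c(3, 2, 1, -1))
  top <- enrichment_score(rk, "g1")
  expect_equal(top$es, 1)                       # full increment at pos 1
  expect_equal(top$running[4], 0, tolerance = 1e-9)
  bottom <- enrichment_score(rk, "g4")
  expect_equal(bottom$es, -1)                   # mirror case
  # scale invariance in the scores
  rk2 <- rk; rk2$score <- rk$score * 10
  expect_equal(enrichment_score(rk2, "g1")$es, top$es)
  # reversal negates ES
  rkr <- data.frame(gene = rev(rk$gene), score = rev(-rk$score))
  expect_equal(enrichment_score(rkr, "g1")$es, -top$es, tolerance = 1e-9)
  expect_error(enrichment_score(rk, "absent"), "intersect")
})

test_that("running sum conservation holds on random inputs", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(20:100, 1)
    rk <- rank_genes(setNames(rnorm(n), paste0("g", 1:n)))
    set <- sample(rk$gene, sample(2:10, 1))
    es <- enrichment_score(rk, set)
    expect_equal(es$running[n], 0, tolerance = 1e-9)
    expect_lte(abs(es$es), 1)
  }
})

test_that("ES agrees with the fgsea reference implementation", {
  skip_if_not_installed("fgsea")
  set.seed(52)
  stats <- sort(rnorm(200), decreasing = TRUE)
  names(stats) <- sprintf("g%03d", 1:200)
  rk <- rank_genes(stats)
  for (i in 1:5) {
    set <- sample(names(stats), 15)
    mine <- enrichment_score(rk, set)$es
    ref <- fgsea::calcGseaStat(stats, selectedStats = match(set, names(stats)),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-6)
  }
})

test_that("preranked GSEA separates planted from random sets", {
  set.seed(53)
  n <- 1000
  scores <- rnorm(n)
  names(scores) <- sprintf("g%04d", 1:n)
  # plant: top-ranked genes get inflated scores
  scores[1:30] <- scores[1:30] + 3
  rk <- rank_genes(scores)
  sets <- list(planted = names(scores)[1:30],
               random = sample(names(scores), 30))
  res <- gsea_preranked(rk, sets, n_perm = 500, seed = 54)
  expect_gt(res$nes[res$set == "planted"], 0)
  expect_lt(res$q[res$set == "planted"], 0.05)
  expect_gt(res$q[res$set == "random"], 0.05)
  expect_equal(sign(res$nes), sign(res$es))
})

test_that("random sets are rarely significant under the null", {
  set.seed(55)
  scores <- setNames(rnorm(500), sprintf("g%03d", 1:500))
  rk <- rank_genes(scores)
  sets <- lapply(1:20, function(i) sample(rk$gene, 25))
  names(sets) <- paste0("set", 1:20)
  res <- gsea_preranked(rk, sets, n_perm = 200, seed = 56)
  expect_gte(mean(res$q > 0.05), 0.9)
})

test_that("results are identical under an identical seed", {
  set.seed(57)
  scores <- setNames(rnorm(300), sprintf("g%03d", 1:300))
  rk <- rank_genes(scores)
  sets <- list(s1 = sample(rk$gene, 20), s2 = sample(rk$gene, 40))
  r1 <- gsea_preranked(rk, sets, n_perm = 200, seed = 99)
  r2 <- gsea_preranked(rk, sets, n_perm = 200, seed = 99)
  expect_identical(r1, r2)
})

test_that("GMT round-trips and size bounds are enforced", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g4", "g5"))
  attr(sets, "description") <- c(alpha = "first", beta = "second")
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back$alpha, sets$alpha)
  expect_equal(attr(back, "description")[["beta"]], "second")

  set.seed(58)
  scores <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  rk <- rank_genes(scores)
  res <- gsea_preranked(rk, list(tiny = rk$gene[1:2]), n_perm = 100,
                        seed = 1, min_size = 5)
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "skipped"), "tiny")
})

test_that("intersection reporting returns sets significant everywhere", {
  r1 <- data.frame(set = c("a", "b"), nes = c(2, -2), q = c(0.01, 0.2))
  r2 <- data.frame(set = c("a", "b"), nes = c(1.5, -1), q = c(0.02, 0.01))
  out <- gsea_intersection(list(x = r1, y = r2))
  expect_equal(out$set, "a")
  expect_equal(out$nes_x, 2)
})
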