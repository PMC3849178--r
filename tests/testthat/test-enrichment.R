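test_that("enrichment score equals the loop oracle on random instances", {
  set.seed(1)
  for (i in 1:10) {
    scores <- setNames(rnorm(20), sprintf("g%02d", 1:20))
    gene_set <- sample(names(scores), 5)
    for (p in c(0, 1)) {
      expect_equal(es_score(scores, gene_set, weight_p = p)$es,
                   es_oracle(scores, gene_set, weight_p = p),
                   tolerance = 1e-12)
    }
  }
})

test_that("a set occupying the top ranks attains ES = 1", {
  scores <- setNames(seq(10, 0.5, length.out = 20), sprintf("g%02d", 1:20))
  expect_equal(es_score(scores, names(scores)[1:5])$es, 1)
})

test_that("a bottom-ranked set is maximally depleted (all misses walk to -1)", {
  scores <- setNames(seq(10, 0.5, length.out = 20), sprintf("g%02d", 1:20))
  bottom <- names(scores)[16:20]
  es <- es_score(scores, bottom, weight_p = 0)$es
  expect_equal(es, es_oracle(scores, bottom, weight_p = 0))
  expect_equal(es, -1)   # 15 misses at 1/15 each before the first hit
})

test_that("degenerate sets are rejected", {
  scores <- setNames(1:10, paste0("g", 1:10))
  expect_error(es_score(scores, paste0("g", 1:10)), "whole")
  expect_error(es_score(scores, "nope"), "no member")
})

test_that("the internal fast ES agrees with the full running sum", {
  set.seed(2)
  for (i in 1:20) {
    n <- sample(15:60, 1)
    scores <- setNames(rnorm(n), sprintf("x%03d", seq_len(n)))
    gs <- sample(names(scores), sample(3:(n - 3), 1))
    ord <- order(-scores, names(scores))
    w <- abs(scores[ord])
    pos <- match(intersect(names(scores)[ord], gs), names(scores)[ord])
    pos <- which(names(scores)[ord] %in% gs)
    expect_equal(coopnet:::es_fast(pos, w, n), es_score(scores, gs)$es,
                 tolerance = 1e-12)
  }
})

test_that("preranked GSEA flags a constructed top-decile set", {
  set.seed(3)
  n <- 200
  scores <- setNames(sort(rnorm(n, sd = 3), decreasing = TRUE),
                     sprintf("g%03d", 1:n))
  sets <- list(top = names(scores)[1:20],
               rand1 = sample(names(scores), 20),
               rand2 = sample(names(scores), 20))
  res <- gsea_preranked(scores, sets, n_perm = 500, seed = 7)
  expect_lt(res$fwer[res$set_id == "top"], 0.05)
  expect_true(all(abs(res$es) <= 1))
  # FWER is monotone non-increasing in |nes|
  o <- order(-abs(res$nes))
  expect_true(all(diff(res$fwer[o]) >= 0))
})

test_that("with a single set the FWER equals the max-rule nominal rate", {
  set.seed(4)
  scores <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  res <- gsea_preranked(scores, list(s = sample(names(scores), 10)),
                        n_perm = 300, seed = 1)
  # one set: the max over the collection is the set itself, so the FWER is
  # the two-sided |nes| exceedance rate, which matches the sign-stratified
  # nominal rate up to the sign-conditioning of the denominator
  expect_lt(abs(res$fwer - res$p_nominal), 0.05)
})

test_that("gsea results agree with fgsea on direction and strength", {
  skip_if_not_installed("fgsea")
  set.seed(5)
  n <- 300
  scores <- setNames(rnorm(n), sprintf("g%03d", 1:n))
  scores[1:25] <- scores[1:25] + 3
  sets <- list(enriched = names(scores)[1:25],
               random = sample(names(scores)[26:n], 25))
  res <- gsea_preranked(scores, sets, n_perm = 500, seed = 2)
  fg <- suppressWarnings(
    fgsea::fgsea(sets, sort(scores, decreasing = TRUE), nPermSimple = 2000,
                 scoreType = "std"))
  expect_equal(sign(res$es[match(fg$pathway, res$set_id)]), sign(fg$ES))
  expect_lt(res$fwer[res$set_id == "enriched"], 0.05)
  expect_gt(fg$ES[fg$pathway == "enriched"], 0.5)
})

test_that("fisher over-representation matches the closed form", {
  universe <- sprintf("u%02d", 1:20)
  gs <- universe[1:5]
  de <- universe[1:5]
  res <- fisher_overrep(gs, de, universe, "up")
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$k_overlap, 5L)
  res0 <- fisher_overrep(gs, universe[6:10], universe, "down")
  expect_equal(res0$p, 1)
  expect_error(fisher_overrep(gs, de, character(), "up"), "empty")
})

test_that("fisher tail matches brute-force enumeration on small universes", {
  set.seed(6)
  universe <- sprintf("u%02d", 1:12)
  for (i in 1:8) {
    gs <- sample(universe, sample(2:6, 1))
    nd <- sample(2:6, 1)
    de <- sample(universe, nd)
    res <- fisher_overrep(gs, de, universe, "up")
    draws <- utils::combn(12, nd)
    hits <- colSums(matrix(universe[draws] %in% gs, nrow = nd))
    expect_equal(res$p, mean(hits >= res$k_overlap), tolerance = 1e-12)
  }
})

test_that("odds ratio uses the Haldane correction only when needed", {
  universe <- sprintf("u%02d", 1:20)
  r <- fisher_overrep(universe[1:5], universe[3:8], universe, "up")
  a <- 3; b <- 2; cc <- 3; d <- 12
  expect_equal(r$odds_ratio, (a * d) / (b * cc))
  r2 <- fisher_overrep(universe[1:5], universe[1:5], universe, "up")
  expect_equal(r2$odds_ratio, (5.5 * 15.5) / (0.5 * 0.5))
})
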