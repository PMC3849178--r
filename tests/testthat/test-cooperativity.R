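test_that("pair correlations match the closed-form Pearson formula", {
  vals <- rbind(g1 = c(1, 2, 3, 4), g2 = c(4, 3, 2, 1), g3 = c(1, 2, 3, 100),
                g4 = c(1, 2, 3, 4))
  samples <- data.frame(sample = paste0("s", 1:4), condition = "c",
                        time_h = c(0, 2, 4, 8), replicate = 1)
  colnames(vals) <- samples$sample
  ex <- new_expr(vals, samples)
  pc <- pair_correlations(ex, rownames(vals))
  key <- paste(pc$gene_a, pc$gene_b)
  expect_equal(pc$r[key == "g1 g4"], 1)
  expect_equal(pc$r[key == "g1 g2"], -1)
  expect_equal(pc$r[key == "g1 g3"],
               pearson_direct(c(1, 2, 3, 4), c(1, 2, 3, 100)))
})

test_that("constant genes are excluded and tiny inputs error", {
  vals <- rbind(g1 = c(1, 2, 3, 4), g2 = c(5, 5, 5, 5), g3 = c(2, 1, 4, 3))
  samples <- data.frame(sample = paste0("s", 1:4), condition = "c",
                        time_h = 0:3, replicate = 1)
  colnames(vals) <- samples$sample
  ex <- new_expr(vals, samples)
  expect_warning(pc <- pair_correlations(ex, rownames(vals)), "constant")
  expect_false(any(pc$gene_a == "g2" | pc$gene_b == "g2"))
  expect_error(suppressWarnings(pair_correlations(ex, c("g1", "g2"))),
               "fewer than 2")
})

test_that("coop p-value equals the analytic hypergeometric marginal", {
  # N = 10, m = 3, k = 2, x = 2 -> C(3,2)/C(10,2) = 3/45
  expect_equal(coop_pvalue(2, 3, 7, 2), 3 / 45, tolerance = 1e-12)
  expect_equal(coop_pvalue(0, 3, 7, 2), 1)
})

test_that("coop p-value matches exhaustive enumeration for all small cases", {
  for (m in 1:5) {
    for (n_single in 1:(12 - m)) {
      N <- m + n_single
      for (k in 1:min(6, N)) {
        for (x in 0:min(k, m)) {
          expect_equal(coop_pvalue(x, m, n_single, k),
                       hyper_tail_enum(x, m, n_single, k),
                       tolerance = 1e-12,
                       label = sprintf("m=%d ns=%d k=%d x=%d", m, n_single,
                                       k, x))
        }
      }
    }
  }
})

test_that("coop p-value is monotone non-increasing in x", {
  p <- vapply(0:5, coop_pvalue, 0, n_pairs_both = 5, n_pairs_single = 15,
              top_k = 5)
  expect_true(all(diff(p) <= 0))
})

test_that("degenerate binding classes give p = 1 with a flag", {
  set.seed(1)
  cx <- classed_expr(1, 5, 5, 0.5, 0.1)
  res <- coop_test_sets(cx$both, cx$a_only, cx$b_only, cx$expr)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
})

test_that("planted cooperative structure is detected and the test is symmetric", {
  set.seed(42)
  cx <- classed_expr(20, 25, 25, r_both = 0.7, r_single = 0.1)
  res <- coop_test_sets(cx$both, cx$a_only, cx$b_only, cx$expr,
                        tf_a = "A", tf_b = "B")
  expect_lt(res$p_value, 1e-3)
  res_swapped <- coop_test_sets(cx$both, cx$b_only, cx$a_only, cx$expr,
                                tf_a = "B", tf_b = "A")
  expect_equal(res$p_value, res_swapped$p_value)
  expect_equal(res$x_observed, res_swapped$x_observed)
})

test_that("coop_test works from a binding matrix", {
  set.seed(2)
  cx <- classed_expr(10, 10, 10, 0.7, 0.1)
  genes <- c(cx$both, cx$a_only, cx$b_only)
  binding <- cbind(A = as.integer(genes %in% c(cx$both, cx$a_only)),
                   B = as.integer(genes %in% c(cx$both, cx$b_only)))
  rownames(binding) <- genes
  res <- coop_test(binding, cx$expr, "A", "B")
  expect_s3_class(res, "coop_test")
  expect_equal(res$n_both, 10L)
  expect_lt(res$p_value, 0.05)
})

test_that("partner screen reports absent motifs as 'no binding sites'", {
  set.seed(3)
  tss <- data.frame(gene_id = sprintf("g%02d", 1:6), chrom = "chr1",
                    strand = "+", tss = seq(1000L, 51000L, by = 10000L),
                    stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = "chr1", start = tss$tss[1:4] - 100L,
                      end = tss$tss[1:4] + 100L,
                      name = paste0("p", 1:4), posterior = 1,
                      stringsAsFactors = FALSE)
  part <- consensus_pwm("PART", "CCAATGGC")
  absent <- consensus_pwm("ABS", "GGGACTTG")
  seqs <- vapply(seq_len(4), function(i) {
    s <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
    s[101:108] <- strsplit(pwm_consensus(part), "")[[1]]
    paste(s, collapse = "")
  }, "")
  names(seqs) <- peaks$name
  samples <- data.frame(sample = paste0("s", 1:8), condition = "c",
                        time_h = rep(c(0, 2, 4, 8), 2),
                        replicate = rep(1:2, each = 4))
  vals <- matrix(rnorm(6 * 8), nrow = 6,
                 dimnames = list(tss$gene_id, samples$sample))
  ex <- new_expr(vals, samples)
  scr <- known_partner_screen(primary_targets = tss$gene_id[1:4],
                              partner_pwms = list(PART = part, ABS = absent),
                              peaks = peaks, seqs = seqs, tss = tss,
                              expr = ex, frac = 0.9)
  expect_equal(scr$status[scr$partner == "ABS"], "no binding sites")
  expect_true(is.na(scr$p_value[scr$partner == "ABS"]))
  expect_true(scr$status[scr$partner == "PART"] %in% c("ok", "degenerate"))
})
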