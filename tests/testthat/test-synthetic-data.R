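test_that("scenario configuration validates its invariants", {
  expect_error(scenario_config(n_genes = 10, n_targets = 20), "exceed")
  expect_error(scenario_config(planted_partners = list(
    list(pwm = consensus_pwm("P", "ACGTACGT"), gap = 5,
         quadrant = "same-strand-right", fraction = 1.5))), "fraction")
  cfg <- scenario_config()
  expect_s3_class(cfg, "scenario_config")
  expect_equal(cfg$time_points, c(0, 2, 4, 8))
  expect_equal(cfg$replicates, 4)
})

test_that("peak sequences carry the primary motif and honour fractions", {
  part <- consensus_pwm("P1", "CCAATGGC")
  cfg <- scenario_config(seed = 9, n_peaks = 500, n_genes = 10, n_targets = 2,
                         planted_partners = list(
                           list(pwm = part, gap = 10,
                                quadrant = "same-strand-right",
                                fraction = 0.6)))
  out <- make_peak_sequences(cfg)
  expect_length(out$seqs, 500)
  # the best primary hit usually sits at the recorded planted offset; a
  # random site can outscore a weakly sampled instance of the short
  # degenerate TRE, so agreement is high but not total
  at_truth <- vapply(seq_len(500), function(i) {
    best_hit(out$seqs[[i]], cfg$primary_pwm)$offset ==
      out$truth$primary_offset[i]
  }, TRUE)
  expect_gte(mean(at_truth), 0.7)
  # planted fraction within the Binomial(500, 0.6) 99% interval
  n_planted <- sum(out$truth$planted_P1)
  expect_gte(n_planted, qbinom(0.005, 500, 0.6))
  expect_lte(n_planted, qbinom(0.995, 500, 0.6))
})

test_that("fraction 1 plants the partner in every sequence at the stated gap", {
  part <- consensus_pwm("P1", "CCAATGGC")
  # non-palindromic primary so sequence orientation is unambiguous
  cfg <- scenario_config(seed = 10, n_peaks = 20, n_genes = 5, n_targets = 1,
                         primary_motif = consensus_pwm("PRIM", "GTAACGCT"),
                         planted_partners = list(
                           list(pwm = part, gap = 12,
                                quadrant = "same-strand-right",
                                fraction = 1)))
  out <- make_peak_sequences(cfg)
  expect_true(all(out$truth$planted_P1))
  res <- spacing_enrichment(out$seqs, cfg$primary_pwm, list(P1 = part))
  top <- as.data.frame(res)[1, ]
  expect_equal(top$gap, 12L)
  expect_gte(top$count / attr(res, "n_seqs"), 0.8)
})

test_that("generators are deterministic given the seed", {
  cfg <- scenario_config(seed = 33, n_peaks = 30, n_genes = 20, n_targets = 5)
  expect_identical(make_peak_sequences(cfg)$seqs,
                   make_peak_sequences(cfg)$seqs)
  expect_identical(simulate_expression(cfg)$expr$values,
                   simulate_expression(cfg)$expr$values)
  expect_identical(make_tss_and_binding(cfg)$peaks,
                   make_tss_and_binding(cfg)$peaks)
  expect_error(make_peak_sequences(
    scenario_config(seed = 1, peak_len = 60, n_genes = 5, n_targets = 1)),
    "too short")
})

test_that("gaps incompatible with the margin are rejected", {
  part <- consensus_pwm("P1", "CCAATGGC")
  cfg <- scenario_config(seed = 1, n_genes = 5, n_targets = 1,
                         planted_partners = list(
                           list(pwm = part, gap = 45,
                                quadrant = "same-strand-right",
                                fraction = 0.5)))
  expect_error(make_peak_sequences(cfg, margin = 50), "incompatible")
})

test_that("simulated targets follow the ODE and non-targets stay basal", {
  cfg <- scenario_config(seed = 5, n_genes = 40, n_targets = 10,
                         noise_sd = 1e-4)
  out <- simulate_expression(cfg)
  ex <- out$expr
  wky <- ex$samples$condition == "WKY"
  tr <- out$truth[out$truth$gene_id == "gene_020", ]   # non-target
  expect_false(tr$is_target)
  expect_equal(unname(ex$values["gene_020", wky]),
               rep(tr$B / tr$D, 16), tolerance = 1e-2)
  # S = 0 equivalent check: quasi-constant trajectory at B/D
  tg <- out$truth[out$truth$gene_id == "gene_001", ]
  expect_true(tg$is_target)
  resp <- ex$values["gene_001", wky]
  expect_gt(max(resp) - min(resp), 0.5)   # induction visible
  # attenuated condition: 20x weaker TF pulse
  tf_wky <- ex$values["TF", wky]
  tf_con <- ex$values["TF", !wky]
  expect_gt(max(tf_wky) - min(tf_wky), 10 * (max(tf_con) - min(tf_con)))
})

test_that("quasi-steady-state limit tracks S f/D + B/D", {
  cfg <- scenario_config(seed = 8, n_genes = 2, n_targets = 1,
                         noise_sd = 1e-6,
                         ode_ranges = list(B = c(1, 1), S = c(2, 2),
                                           D = c(30, 30)))
  out <- simulate_expression(cfg)
  wky <- out$expr$samples$condition == "WKY"
  x <- out$expr$values["gene_001", wky]
  t <- out$expr$samples$time_h[wky]
  pulse <- 3 * (t / 2) * exp(1 - t / 2)
  expect_equal(unname(x), 1 / 30 + 2 * pulse / 30, tolerance = 0.05)
})

test_that("cooperative blocks share correlation structure", {
  cfg <- scenario_config(seed = 12, n_genes = 60, n_targets = 0,
                         coop_blocks = list(list(n_genes = 20, r = 0.7)))
  out <- simulate_expression(cfg)
  blk <- out$truth$gene_id[!is.na(out$truth$coop_block)]
  rest <- setdiff(out$truth$gene_id, blk)
  pc_blk <- pair_correlations(out$expr, blk, condition = "WKY")
  pc_bg <- pair_correlations(out$expr, rest[1:20], condition = "WKY")
  expect_gt(mean(pc_blk$r), 0.5)
  expect_lt(abs(mean(pc_bg$r)), 0.15)
})

test_that("synthetic chromosome layout exercises promoter and boundary cases", {
  cfg <- scenario_config(seed = 14, n_peaks = 120, n_genes = 50,
                         n_targets = 20)
  out <- make_tss_and_binding(cfg)
  expect_equal(sum(out$truth_binding), 20 + cfg$n_bound_nontargets)
  kept <- filter_peaks(out$peaks)
  asn <- assign_peaks(kept, out$tss)
  expect_true(all(asn$distance <= 20000))
  # bound genes recovered through promoter_binding on the truth peaks
  bm <- promoter_binding(list(primary = out$peaks[seq_len(30), ]), out$tss)
  expect_equal(sum(bm), 30)
  # beyond-window peaks exist and are unassigned
  expect_lt(length(unique(asn$peak)), nrow(kept))
})
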