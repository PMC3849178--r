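# Independent oracles used across tests.  These deliberately avoid the
# code paths they check: brute-force quadrature, direct summation, and
# loop-based running sums.

# covariance of two ODE outputs by adaptive double quadrature
quad_sim_cov <- function(t1, t2, Dj, Dk, Sj, Sk, l) {
  if (t1 == 0 || t2 == 0) return(0)
  inner <- function(v) {
    vapply(v, function(vv) {
      stats::integrate(function(u) exp(-Dj * (t1 - u) - (u - vv)^2 / l^2),
                       0, t1, rel.tol = 1e-11)$value
    }, 0)
  }
  Sj * Sk * stats::integrate(function(v) exp(-Dk * (t2 - v)) * inner(v),
                             0, t2, rel.tol = 1e-10)$value
}

# exact upper-tail binomial probability by direct summation
binom_tail_sum <- function(count, n, p) {
  if (count <= 0) return(1)
  sum(vapply(count:n, function(i) stats::dbinom(i, n, p), 0))
}

# hypergeometric upper tail by exhaustive enumeration of top-set draws
hyper_tail_enum <- function(x, m, n_single, k) {
  N <- m + n_single
  if (k > N) stop("k > N")
  labs <- c(rep(TRUE, m), rep(FALSE, n_single))
  draws <- utils::combn(N, k)
  hits <- colSums(matrix(labs[draws], nrow = k))
  mean(hits >= x)
}

# loop-based weighted running-sum enrichment score
es_oracle <- function(scores, gene_set, weight_p = 1) {
  ord <- order(-scores, names(scores))
  ranked <- scores[ord]
  hit <- names(ranked) %in% gene_set
  vals <- unname(abs(ranked))
  nr <- sum(vals[hit]^weight_p)
  run <- 0
  best <- 0
  for (i in seq_along(ranked)) {
    if (hit[i]) {
      run <- run + if (nr > 0) vals[i]^weight_p / nr else 1 / sum(hit)
    } else {
      run <- run - 1 / (length(ranked) - sum(hit))
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# closed-form Pearson correlation
pearson_direct <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Mann-Whitney AUROC of score against a logical truth label
auroc <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# iid-normal expression fixture with the study design
null_expr <- function(n_genes, conditions = "WKY", times = c(0, 2, 4, 8),
                      reps = 4, gene_prefix = "g") {
  samples <- expand.grid(replicate = seq_len(reps), time_h = times,
                         condition = conditions, stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_t%g_r%d", samples$condition, samples$time_h,
                            samples$replicate)
  samples <- samples[c("sample", "condition", "time_h", "replicate")]
  vals <- matrix(rnorm(n_genes * nrow(samples)), nrow = n_genes,
                 dimnames = list(sprintf("%s%03d", gene_prefix,
                                         seq_len(n_genes)),
                                 samples$sample))
  new_expr(vals, samples)
}

# expression fixture with three binding classes and controlled pairwise
# correlations (shared latent per class)
classed_expr <- function(n_both, n_a, n_b, r_both, r_single, n_samples = 16) {
  mk_block <- function(n, r, prefix) {
    z <- rnorm(n_samples)
    t(vapply(seq_len(n), function(i) {
      sqrt(r) * z + sqrt(1 - r) * rnorm(n_samples)
    }, numeric(n_samples)))
  }
  vals <- rbind(mk_block(n_both, r_both), mk_block(n_a, r_single),
                mk_block(n_b, r_single))
  genes <- c(sprintf("both%03d", seq_len(n_both)),
             sprintf("aa%03d", seq_len(n_a)),
             sprintf("bb%03d", seq_len(n_b)))
  rownames(vals) <- genes
  samples <- data.frame(sample = sprintf("s%02d", seq_len(n_samples)),
                        condition = "WKY",
                        time_h = rep(c(0, 2, 4, 8),
                                     length.out = n_samples),
                        replicate = rep(seq_len(4), each = 4)[seq_len(n_samples)],
                        stringsAsFactors = FALSE)
  colnames(vals) <- samples$sample
  list(expr = new_expr(vals, samples),
       both = genes[seq_len(n_both)],
       a_only = genes[n_both + seq_len(n_a)],
       b_only = genes[n_both + n_a + seq_len(n_b)])
}
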