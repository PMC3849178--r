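# SAM-style permutation differential expression: regularized t-like d
# statistic with a fudge factor s0 chosen by the Tusher coefficient-of-
# variation criterion, and permutation-based FDR (median false-call count).

#' SAM d statistic for two replicate groups
#'
#' `d = (mean2 - mean1) / (s + s0)` where `s` is the pooled standard error
#' `sqrt((1/n1 + 1/n2) * pooled variance)` and `s0` a small regularizer
#' protecting against near-zero variances.
#'
#' @param group1,group2 Numeric replicate vectors (>= 2 values each).
#' @param s0 Fudge factor added to the standard error.
#' @export
sam_d <- function(group1, group2, s0 = 0) {
  if (length(group1) < 2L || length(group2) < 2L) {
    stop("each group needs >= 2 replicates")
  }
  s <- sam_se(matrix(group1, nrow = 1L), matrix(group2, nrow = 1L))
  (mean(group2) - mean(group1)) / (s + s0)
}

# row-wise pooled standard error for matrices of replicate values
sam_se <- function(m1, m2) {
  n1 <- ncol(m1); n2 <- ncol(m2)
  ss1 <- rowSums((m1 - rowMeans(m1))^2)
  ss2 <- rowSums((m2 - rowMeans(m2))^2)
  sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
}

sam_d_rows <- function(m1, m2, s0) {
  r <- rowMeans(m2) - rowMeans(m1)
  d <- r / (sam_se(m1, m2) + s0)
  d[r == 0] <- 0                 # 0/0 (constant identical groups) scores 0
  d
}

# Tusher s0: the percentile of the s distribution (grid 0,5,...,100)
# minimizing the coefficient of variation of median |d| across s-quantile
# windows
choose_s0 <- function(m1, m2) {
  s <- sam_se(m1, m2)
  r <- rowMeans(m2) - rowMeans(m1)
  qs <- stats::quantile(s, probs = seq(0, 1, by = 0.05), names = FALSE)
  breaks <- unique(stats::quantile(s, probs = seq(0, 1, 0.1)))
  if (length(breaks) < 2L) return(breaks[1L])   # degenerate: constant s
  win <- cut(s, breaks = breaks, include.lowest = TRUE)
  cvs <- vapply(qs, function(s0) {
    d <- r / (s + s0)
    med <- tapply(abs(d), win, stats::median)
    stats::sd(med) / mean(med)
  }, 0)
  qs[which.min(cvs)]
}

#' SAM permutation differential expression between two time points
#'
#' Compares the replicates of `time_b` against the basal `time_a` within
#' one condition.  The fudge factor `s0` is chosen by the Tusher
#' coefficient-of-variation criterion; the null distribution of `d` comes
#' from group-label permutations (exhaustive when fewer distinct
#' assignments than `n_perm` exist, e.g. C(8,4) = 70 for a 4 + 4 design).
#' For a threshold at each gene's `|d|`, the estimated FDR is the median
#' false-call count across permutations divided by the observed call
#' count; q values are made monotone in `|d|`.
#'
#' @param expr A [new_expr()] object.
#' @param condition Condition label.
#' @param time_a Basal time point (default 0).
#' @param time_b Post-stimulation time point to compare.
#' @param n_perm Number of label permutations (default 200).
#' @param fdr_cut FDR threshold for the up/down calls (default 0.05).
#' @param seed Seed for permutation sampling.
#' @return Object of class `sam_result`: `data.frame` with `gene_id`, `d`,
#'   `fold_change` (difference of log2 group means), `q`, `direction`
#'   (`up`/`down`/`ns`), plus attributes `s0`, `n_perm`, `exhaustive`.
#' @export
sam_test <- function(expr, condition, time_a = 0, time_b, n_perm = 200,
                     fdr_cut = 0.05, seed = 1) {
  if (n_perm < 20L) warning("n_perm < 20 gives unstable FDR estimates")
  sa <- expr$samples$condition == condition & expr$samples$time_h == time_a
  sb <- expr$samples$condition == condition & expr$samples$time_h == time_b
  if (sum(sa) < 2L || sum(sb) < 2L) {
    stop("need >= 2 replicates at both time points")
  }
  m1 <- expr$values[, expr$samples$sample[sa], drop = FALSE]
  m2 <- expr$values[, expr$samples$sample[sb], drop = FALSE]
  n1 <- ncol(m1); n2 <- ncol(m2)
  s0 <- choose_s0(m1, m2)
  d_obs <- sam_d_rows(m1, m2, s0)
  fc <- rowMeans(m2) - rowMeans(m1)

  # permutation null: reassign group labels across the pooled columns
  pooled <- cbind(m1, m2)
  all_assign <- utils::combn(n1 + n2, n1)
  exhaustive <- ncol(all_assign) <= n_perm
  if (exhaustive) {
    assigns <- all_assign
  } else {
    set.seed(seed)
    assigns <- all_assign[, sample.int(ncol(all_assign), n_perm), drop = FALSE]
  }
  n_used <- ncol(assigns)
  d_perm <- matrix(0, nrow = nrow(pooled), ncol = n_used)
  for (j in seq_len(n_used)) {
    g1 <- assigns[, j]
    d_perm[, j] <- sam_d_rows(pooled[, g1, drop = FALSE],
                              pooled[, -g1, drop = FALSE], s0)
  }

  # FDR at threshold |d_i|: median (over permutations) false-call count
  # divided by the observed call count at that threshold
  abs_obs <- abs(d_obs)
  ord <- order(abs_obs, decreasing = TRUE)
  sorted_thr <- abs_obs[ord]
  n_called <- seq_along(sorted_thr)           # calls at threshold |d_(i)|
  false_counts <- vapply(seq_len(n_used), function(j) {
    col <- sort(abs(d_perm[, j]))
    length(col) - findInterval(sorted_thr - 1e-12, col)
  }, numeric(length(sorted_thr)))
  med_false <- apply(false_counts, 1L, stats::median)
  q_sorted <- pmin(1, med_false / n_called)
  q_sorted <- rev(cummin(rev(q_sorted)))      # monotone in |d|
  q <- numeric(length(d_obs)); q[ord] <- q_sorted

  direction <- rep("ns", length(d_obs))
  direction[q <= fdr_cut & fc > 0] <- "up"
  direction[q <= fdr_cut & fc < 0] <- "down"
  res <- data.frame(gene_id = rownames(expr$values), d = d_obs,
                    fold_change = fc, q = q, direction = direction,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, s0 = s0, n_perm = n_used, exhaustive = exhaustive,
            condition = condition, time_a = time_a, time_b = time_b,
            fdr_cut = fdr_cut,
            class = c("sam_result", "data.frame"))
}

#' @export
print.sam_result <- function(x, ...) {
  cat("<sam_result> ", attr(x, "condition"), ": ", attr(x, "time_b"),
      " h vs ", attr(x, "time_a"), " h; s0 = ",
      format(attr(x, "s0"), digits = 3), "; ", attr(x, "n_perm"),
      " permutations", if (attr(x, "exhaustive")) " (exhaustive)", "\n",
      "  calls at FDR ", attr(x, "fdr_cut"), ": ",
      sum(x$direction == "up"), " up, ", sum(x$direction == "down"),
      " down of ", nrow(x), " genes\n", sep = "")
  invisible(x)
}

#' Differentially expressed gene ids from a SAM result
#' @param sam A [sam_test()] result.
#' @param direction `"up"`, `"down"` or `"any"`.
#' @export
de_genes <- function(sam, direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  keep <- if (direction == "any") sam$direction != "ns" else sam$direction == direction
  sam$gene_id[keep]
}
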