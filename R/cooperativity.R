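# Cooperative TF-pair inference: are the expression correlations of genes
# bound by BOTH TFs over-represented among the most-correlated gene pairs,
# relative to pairs of genes bound by either TF alone?  The null for the
# three pair classes (both / A-only / B-only) is multivariate
# hypergeometric; the reported p-value is the (hypergeometric) marginal of
# the both-bound class.

#' Pairwise expression correlations
#'
#' Pearson (or Spearman) correlation of gene expression profiles across the
#' samples of one condition.  Constant-expression genes are excluded with a
#' warning (their correlation is undefined).
#'
#' @param expr A [new_expr()] object.
#' @param genes Gene ids to correlate.
#' @param condition Optional condition label; default uses all samples.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return `data.frame` with `gene_a`, `gene_b` (`gene_a` < `gene_b`), `r`.
#' @export
pair_correlations <- function(expr, genes, condition = NULL,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!is.null(condition)) expr <- subset_expr(expr, condition)
  missing_g <- setdiff(genes, rownames(expr$values))
  if (length(missing_g)) {
    warning("gene(s) absent from expression matrix dropped: ",
            paste(utils::head(missing_g, 5L), collapse = ", "))
    genes <- setdiff(genes, missing_g)
  }
  m <- expr$values[genes, , drop = FALSE]
  if (ncol(m) < 3L) stop("need >= 3 samples to correlate")
  const <- apply(m, 1L, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("constant-expression gene(s) excluded: ",
            paste(utils::head(genes[const], 5L), collapse = ", "))
    m <- m[!const, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("fewer than 2 usable genes")
  r <- stats::cor(t(m), method = method)
  idx <- which(upper.tri(r), arr.ind = TRUE)
  data.frame(gene_a = rownames(r)[idx[, 1L]], gene_b = rownames(r)[idx[, 2L]],
             r = r[idx], stringsAsFactors = FALSE)
}

#' Hypergeometric upper-tail p-value of the cooperativity test
#'
#' `P(X >= x)` for `X ~ Hypergeom(N, m, k)` with `N = n_pairs_both +
#' n_pairs_single` pairs, `m = n_pairs_both` both-bound pairs and `k`
#' pairs drawn into the top-correlation set.  The three-class pair null
#' (A-only / B-only / both) is multivariate hypergeometric; this is its
#' marginal for the both-bound class.
#'
#' @param x Observed both-bound pairs in the top set.
#' @param n_pairs_both,n_pairs_single Pair-class sizes.
#' @param top_k Size of the top-correlation set.
#' @export
coop_pvalue <- function(x, n_pairs_both, n_pairs_single, top_k) {
  stats::phyper(x - 1L, n_pairs_both, n_pairs_single, top_k,
                lower.tail = FALSE)
}

within_pairs <- function(genes) {
  if (length(genes) < 2L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  }
  g <- sort(genes)
  idx <- utils::combn(length(g), 2L)
  data.frame(gene_a = g[idx[1L, ]], gene_b = g[idx[2L, ]],
             stringsAsFactors = FALSE)
}

#' Cooperativity test for a TF pair
#'
#' Gene pairs are formed within the both-bound gene set (`P_both`) and
#' within each single-TF set (`P_single` = pairs within A-only plus pairs
#' within B-only; cross-class pairs are excluded).  All
#' `N = |P_both| + |P_single|` pairs are ranked by expression correlation
#' (descending, ties by lexicographic pair id) and the top
#' `k = ceiling(top_fraction * N)` pairs taken; the number `x` of both-bound
#' pairs among them is tested against the hypergeometric upper tail
#' `P(X >= x)` with `X ~ Hypergeom(N, |P_both|, k)`.
#'
#' @param binding Binary genes x TFs indicator matrix
#'   ([promoter_binding()]) containing columns `tf_a` and `tf_b`.
#' @param expr A [new_expr()] object.
#' @param tf_a,tf_b Column names in `binding`.
#' @param top_fraction Fraction of pairs regarded as "most correlated"
#'   (default 0.05).
#' @param condition,method Passed to [pair_correlations()].
#' @return Object of class `coop_test`: list with `tf_a`, `tf_b`, `n_both`,
#'   `n_a_only`, `n_b_only`, `n_pairs_both`, `n_pairs_single`, `top_k`,
#'   `x_observed`, `p_value`, `degenerate`.
#' @export
coop_test <- function(binding, expr, tf_a, tf_b, top_fraction = 0.05,
                      condition = NULL, method = "pearson") {
  stopifnot(top_fraction > 0, top_fraction < 1)
  if (!all(c(tf_a, tf_b) %in% colnames(binding))) {
    stop("binding matrix lacks column(s) for ", tf_a, " / ", tf_b)
  }
  a <- binding[, tf_a] > 0
  b <- binding[, tf_b] > 0
  genes <- rownames(binding)
  coop_test_sets(both = genes[a & b], a_only = genes[a & !b],
                 b_only = genes[!a & b], expr = expr,
                 tf_a = tf_a, tf_b = tf_b, top_fraction = top_fraction,
                 condition = condition, method = method)
}

#' @rdname coop_test
#' @param r_both,r_single Pre-computed correlation scores for the
#'   both-bound and single-bound pair classes (lowest-level entry point;
#'   ranking ties are broken by the vector names when present, else by
#'   position).
#' @export
coop_test_cor <- function(r_both, r_single, top_fraction = 0.05,
                          tf_a = "A", tf_b = "B") {
  m <- length(r_both); n_single <- length(r_single)
  res <- list(tf_a = tf_a, tf_b = tf_b, n_both = NA_integer_,
              n_a_only = NA_integer_, n_b_only = NA_integer_,
              top_fraction = top_fraction,
              n_pairs_both = m, n_pairs_single = n_single)
  if (m == 0L || n_single == 0L) {
    res <- c(res, list(top_k = 0L, x_observed = 0L, p_value = 1,
                       degenerate = TRUE))
    return(structure(res, class = "coop_test"))
  }
  r <- c(r_both, r_single)
  ids <- names(r) %||% as.character(seq_along(r))
  ord <- order(-r, ids)
  k <- as.integer(ceiling(top_fraction * (m + n_single)))
  x <- sum(ord[seq_len(k)] <= m)
  res <- c(res, list(top_k = k, x_observed = x,
                     p_value = coop_pvalue(x, m, n_single, k),
                     degenerate = FALSE))
  structure(res, class = "coop_test")
}

#' @rdname coop_test
#' @param both,a_only,b_only Explicit gene sets for the three binding
#'   classes (alternative entry point when binding classes are known
#'   directly).
#' @export
coop_test_sets <- function(both, a_only, b_only, expr, tf_a = "A", tf_b = "B",
                           top_fraction = 0.05, condition = NULL,
                           method = "pearson") {
  drop_missing <- function(g) {
    miss <- setdiff(g, rownames(expr$values))
    if (length(miss)) {
      warning("bound gene(s) without expression dropped: ",
              paste(utils::head(miss, 5L), collapse = ", "))
    }
    intersect(g, rownames(expr$values))
  }
  both <- drop_missing(unique(both))
  a_only <- drop_missing(unique(a_only))
  b_only <- drop_missing(unique(b_only))
  res <- list(tf_a = tf_a, tf_b = tf_b, n_both = length(both),
              n_a_only = length(a_only), n_b_only = length(b_only),
              top_fraction = top_fraction)
  p_both <- within_pairs(both)
  p_single <- rbind(within_pairs(a_only), within_pairs(b_only))
  res$n_pairs_both <- nrow(p_both)
  res$n_pairs_single <- nrow(p_single)
  if (length(both) < 2L || nrow(p_both) == 0L || nrow(p_single) == 0L) {
    res <- c(res, list(top_k = 0L, x_observed = 0L, p_value = 1,
                       degenerate = TRUE))
    return(structure(res, class = "coop_test"))
  }
  all_genes <- unique(c(both, a_only, b_only))
  cors <- pair_correlations(expr, all_genes, condition = condition,
                            method = method)
  key <- function(df) paste(df$gene_a, df$gene_b, sep = "\r")
  rmap <- stats::setNames(cors$r, key(cors))
  pairs <- rbind(cbind(p_both, class = "both"),
                 cbind(p_single, class = "single"))
  pairs$r <- rmap[key(pairs)]
  if (anyNA(pairs$r)) {          # genes excluded as constant: drop their pairs
    pairs <- pairs[!is.na(pairs$r), , drop = FALSE]
  }
  N <- nrow(pairs)
  m <- sum(pairs$class == "both")
  if (m == 0L || m == N) {
    res <- c(res, list(top_k = 0L, x_observed = 0L, p_value = 1,
                       degenerate = TRUE))
    return(structure(res, class = "coop_test"))
  }
  is_both <- pairs$class == "both"
  inner <- coop_test_cor(stats::setNames(pairs$r[is_both], key(pairs)[is_both]),
                         stats::setNames(pairs$r[!is_both], key(pairs)[!is_both]),
                         top_fraction = top_fraction, tf_a = tf_a, tf_b = tf_b)
  res$n_pairs_both <- m
  res$n_pairs_single <- N - m
  res <- c(res, list(top_k = inner$top_k, x_observed = inner$x_observed,
                     p_value = inner$p_value, degenerate = FALSE))
  structure(res, class = "coop_test")
}

#' @export
print.coop_test <- function(x, ...) {
  cat("<coop_test> ", x$tf_a, " x ", x$tf_b,
      if (isTRUE(x$degenerate)) " (degenerate)" else "", "\n",
      "  genes: both=", x$n_both, " a_only=", x$n_a_only,
      " b_only=", x$n_b_only, "\n",
      "  pairs: both=", x$n_pairs_both, " single=", x$n_pairs_single,
      "; top k=", x$top_k, ", x=", x$x_observed, "\n",
      "  hypergeometric upper-tail p = ", format(x$p_value, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Screen candidate partner motifs for cooperativity with a primary TF
#'
#' The end-to-end partner workflow: for each candidate partner motif, find
#' the peaks whose sequence contains the motif, intersect their promoter
#' binding (+/- `half_width` bp of the TSS) with the primary TF's target
#' genes, and run [coop_test()] on the both / primary-only / partner-only
#' gene classes.  Partners whose motif occurs under no peak are reported
#' with status `"no binding sites"` rather than a p-value.
#'
#' @param primary_targets Gene ids bound by the primary TF.
#' @param partner_pwms Named list of candidate partner PWMs.
#' @param peaks Peak data frame (posterior-filtered).
#' @param seqs Named character vector of peak sequences (names matching
#'   `peaks$name`).
#' @param tss TSS annotation.
#' @param expr Expression matrix.
#' @param half_width Promoter half-width (default 500).
#' @param frac Motif-presence threshold for [has_motif()].
#' @param top_fraction,condition,method Passed to [coop_test()].
#' @return `data.frame` with one row per partner: `partner`, `status`
#'   (`"ok"`, `"no binding sites"` or `"degenerate"`), class sizes,
#'   `x_observed`, `top_k`, `p_value`.
#' @export
known_partner_screen <- function(primary_targets, partner_pwms, peaks, seqs,
                                 tss, expr, half_width = 500, frac = 0.6,
                                 top_fraction = 0.05, condition = NULL,
                                 method = "pearson") {
  rows <- lapply(names(partner_pwms), function(tf) {
    pwm <- partner_pwms[[tf]]
    present <- vapply(peaks$name, function(nm) {
      s <- seqs[[nm]]
      !is.null(s) && has_motif(s, pwm, frac = frac)
    }, TRUE)
    if (!any(present)) {
      return(data.frame(partner = tf, status = "no binding sites",
                        n_both = 0L, n_a_only = length(unique(primary_targets)),
                        n_b_only = 0L, x_observed = NA_integer_,
                        top_k = NA_integer_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    bm <- promoter_binding(stats::setNames(list(peaks[present, , drop = FALSE]), tf),
                           tss, half_width = half_width)
    partner_genes <- rownames(bm)[bm[, tf] > 0]
    ct <- coop_test_sets(both = intersect(primary_targets, partner_genes),
                         a_only = setdiff(primary_targets, partner_genes),
                         b_only = setdiff(partner_genes, primary_targets),
                         expr = expr, tf_a = "primary", tf_b = tf,
                         top_fraction = top_fraction, condition = condition,
                         method = method)
    data.frame(partner = tf,
               status = if (ct$degenerate) "degenerate" else "ok",
               n_both = ct$n_both, n_a_only = ct$n_a_only,
               n_b_only = ct$n_b_only, x_observed = ct$x_observed,
               top_k = ct$top_k, p_value = ct$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
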