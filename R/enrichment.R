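# Preranked gene set enrichment (weighted Kolmogorov-Smirnov running sum,
# gene-label permutation null, max-statistic FWER) and direction-separated
# Fisher over-representation of target sets in differentially expressed
# genes.

#' Weighted running-sum enrichment score
#'
#' Genes are ranked by the metric (descending, ties by gene id); walking
#' down the list, set members increment the running sum by
#' `|metric|^weight_p / sum_set |metric|^weight_p` and non-members
#' decrement it by `1 / (N - N_H)`.  The enrichment score is the extreme
#' (signed) deviation of the running sum from zero.
#'
#' @param scores Named numeric vector: ranking metric per gene.
#' @param gene_set Character vector of member gene ids (at least one must
#'   be in `scores`; the set must not cover the whole universe).
#' @param weight_p Weighting exponent (0 gives the classic unweighted KS
#'   statistic; default 1).
#' @return List with `es` and `running` (the running-sum profile over the
#'   ranked list, named by gene).
#' @export
es_score <- function(scores, gene_set, weight_p = 1) {
  if (is.null(names(scores))) stop("scores must be named by gene id")
  ord <- order(-scores, names(scores))
  ranked <- scores[ord]
  hit <- names(ranked) %in% gene_set
  n <- length(ranked)
  n_h <- sum(hit)
  if (n_h == 0L) stop("gene set has no member in the ranked universe")
  if (n_h == n) stop("gene set covers the whole ranked universe")
  w <- abs(ranked)^weight_p
  denom <- sum(w[hit])
  inc <- if (denom > 0) w * hit / denom else hit / n_h
  dec <- (!hit) / (n - n_h)
  running <- cumsum(inc - dec)
  names(running) <- names(ranked)
  es <- running[[which.max(abs(running))]]
  list(es = es, running = running)
}

# ES from a ranked universe given hit positions only; O(N_H) per set once
# the weights are precomputed.  Equals es_score() on the same input.
es_fast <- function(idx, w, n) {
  n_h <- length(idx)
  idx <- sort(idx)
  denom <- sum(w[idx])
  cum_hit <- if (denom > 0) cumsum(w[idx]) / denom else seq_len(n_h) / n_h
  miss_unit <- 1 / (n - n_h)
  at_hit <- cum_hit - (idx - seq_len(n_h)) * miss_unit       # peak after hit
  before_hit <- c(0, cum_hit[-n_h]) - (idx - 1 - (seq_len(n_h) - 1)) * miss_unit
  cands <- unname(c(at_hit, before_hit))
  cands[which.max(abs(cands))]
}

#' Preranked GSEA with permutation FWER
#'
#' Tests each gene set for enrichment at the top or bottom of the ranked
#' metric.  The null is built from random gene-label sets of matched size
#' (`n_perm` draws).  Normalized scores are sign-stratified
#' (`nes = es / mean(same-sign null es)`); the family-wise error rate is
#' the fraction of permutations whose maximum `|nes|` over the whole
#' collection exceeds the observed `|nes|`.
#'
#' @param scores Named numeric ranking metric (e.g. the `score` column of
#'   [rank_genes()] named by gene).
#' @param gene_sets Named list of character vectors, or a [read_gmt()]
#'   list.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the permutation draws.
#' @param weight_p Running-sum weight exponent.
#' @param min_size,max_size Set-size filter applied after restriction to
#'   the universe.
#' @return Object of class `gsea_result`: `data.frame` with `set_id`,
#'   `size`, `es`, `nes`, `p_nominal`, `fwer`, sorted by `fwer` then
#'   `p_nominal`.
#' @export
gsea_preranked <- function(scores, gene_sets, n_perm = 1000, seed = 1,
                           weight_p = 1, min_size = 5, max_size = 500) {
  if (n_perm < 100L) warning("n_perm < 100 gives coarse FWER estimates")
  if (length(gene_sets) && is.list(gene_sets[[1L]])) {
    gene_sets <- gmt_genes(gene_sets)
  }
  universe <- names(scores)
  n <- length(universe)
  sets <- lapply(gene_sets, function(g) intersect(g, universe))
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size & sizes < n
  if (!any(keep)) stop("no gene set passes the size filter")
  sets <- sets[keep]
  sizes <- sizes[keep]

  ord <- order(-scores, universe)
  ranked_names <- universe[ord]
  w <- abs(scores[ord])^weight_p
  pos <- seq_len(n)
  names(pos) <- ranked_names

  es_obs <- vapply(names(sets), function(id) es_fast(pos[sets[[id]]], w, n), 0)

  # shared null draws per distinct set size
  set.seed(seed)
  usizes <- sort(unique(sizes))
  null_es <- matrix(0, nrow = length(sets), ncol = n_perm,
                    dimnames = list(names(sets), NULL))
  for (sz in usizes) {
    rows <- which(sizes == sz)
    for (j in seq_len(n_perm)) {
      e <- es_fast(sample.int(n, sz), w, n)
      null_es[rows, j] <- e
    }
  }

  norm_const <- function(es_vec, x) {
    # mean |null es| of the same sign as x
    same <- if (x >= 0) es_vec[es_vec >= 0] else -es_vec[es_vec < 0]
    if (!length(same)) return(NA_real_)
    mean(same)
  }
  nes <- numeric(length(sets))
  p_nom <- numeric(length(sets))
  null_nes <- null_es
  for (i in seq_along(sets)) {
    ne <- null_es[i, ]
    c_pos <- mean(ne[ne >= 0]); c_neg <- mean(-ne[ne < 0])
    nes[i] <- if (es_obs[i] >= 0) es_obs[i] / c_pos else es_obs[i] / c_neg
    same <- if (es_obs[i] >= 0) ne[ne >= 0] else ne[ne < 0]
    p_nom[i] <- if (length(same)) mean(abs(same) >= abs(es_obs[i])) else NA_real_
    null_nes[i, ] <- ifelse(ne >= 0, ne / c_pos, ne / c_neg)
  }
  max_null <- apply(abs(null_nes), 2L, max)
  fwer <- vapply(abs(nes), function(v) mean(max_null >= v), 0)

  res <- data.frame(set_id = names(sets), size = sizes, es = es_obs,
                    nes = nes, p_nominal = p_nom, fwer = fwer,
                    stringsAsFactors = FALSE)
  res <- res[order(res$fwer, res$p_nominal, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, n_perm = n_perm, weight_p = weight_p,
            class = c("gsea_result", "data.frame"))
}

#' @export
print.gsea_result <- function(x, ...) {
  cat("<gsea_result> ", nrow(x), " gene set(s), ", attr(x, "n_perm"),
      " permutations; ", sum(x$fwer < 0.05), " at FWER < 0.05\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Fisher over-representation of a gene set in DE genes
#'
#' Hypergeometric upper-tail probability of the observed overlap between a
#' target gene set and a (direction-restricted) differentially expressed
#' gene list, within a fixed gene universe.  The odds ratio comes from the
#' 2 x 2 table with a Haldane correction of 0.5 when any cell is zero.
#'
#' @param gene_set,de_genes Character vectors (subsets of `universe`).
#' @param universe All assayed genes.
#' @param direction Label carried into the result (`"up"` or `"down"`).
#' @return One-row `data.frame`: `direction`, `k_overlap`, `n_set`,
#'   `n_de`, `n_universe`, `odds_ratio`, `p`.
#' @export
fisher_overrep <- function(gene_set, de_genes, universe,
                           direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  gene_set <- intersect(unique(gene_set), universe)
  de_genes <- intersect(unique(de_genes), universe)
  k <- length(intersect(gene_set, de_genes))
  n_set <- length(gene_set); n_de <- length(de_genes); n_u <- length(universe)
  p <- stats::phyper(k - 1L, n_de, n_u - n_de, n_set, lower.tail = FALSE)
  a <- k; b <- n_set - k; cc <- n_de - k; d <- n_u - n_set - n_de + k
  if (min(a, b, cc, d) == 0L) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  data.frame(direction = direction, k_overlap = k, n_set = n_set,
             n_de = n_de, n_universe = n_u, odds_ratio = (a * d) / (b * cc),
             p = p, stringsAsFactors = FALSE)
}

#' Direction-separated over-representation for a collection of sets
#'
#' Runs [fisher_overrep()] for every set against the up- and down-regulated
#' genes of a [sam_test()] result.
#'
#' @param gene_sets Named list of character vectors or [read_gmt()] list.
#' @param sam A `sam_result`.
#' @param universe Gene universe (default: all genes in the SAM result).
#' @export
overrep_by_direction <- function(gene_sets, sam, universe = sam$gene_id) {
  if (length(gene_sets) && is.list(gene_sets[[1L]])) {
    gene_sets <- gmt_genes(gene_sets)
  }
  rows <- list()
  for (dir in c("up", "down")) {
    de <- de_genes(sam, dir)
    for (id in names(gene_sets)) {
      r <- fisher_overrep(gene_sets[[id]], de, universe, dir)
      rows[[length(rows) + 1L]] <- cbind(set_id = id, r,
                                         stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
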