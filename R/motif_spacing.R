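# Spaced-motif co-occurrence enrichment: infer TF partners from enrichment
# of fixed spacings between a primary motif (e.g. TRE/CRE) and secondary
# motifs inside ChIP-seq peak sequences.

QUADRANTS <- c("same-strand-left", "same-strand-right",
               "opposite-left", "opposite-right")

#' Spaced-motif enrichment of secondary motifs around a primary motif
#'
#' Each sequence is centred and oriented on the best hit of the primary
#' motif; sequences without a primary hit, or whose flanking margins
#' truncate at the sequence edge, are dropped (the count is reported).  For
#' each secondary motif the single best hit inside the two `margin`-bp
#' regions flanking the primary site is binned by gap (bp between the
#' primary edge and the nearer secondary edge, 1-bp bins) and quadrant
#' (left/right x same/opposite strand).  With `n_bins = 4 * (margin - L2 +
#' 1)` equiprobable bins under the null, the bin count is tested with an
#' upper-tail binomial probability `P[Binom(n_seqs, 1/n_bins) >= count]`,
#' Bonferroni-adjusted for the number of bins times the number of secondary
#' motifs tested.
#'
#' @param seqs Named character vector of peak sequences.
#' @param primary_pwm The primary motif ([new_pwm()]).
#' @param secondary_pwms Named list of candidate partner motifs.
#' @param margin Flank width in bp on either side of the primary site
#'   (default 50).
#' @param alpha Significance level on the adjusted p-value (default 0.01).
#' @param min_secondary_score Optional log-odds threshold for the secondary
#'   hit; by default every surviving sequence contributes its best hit
#'   regardless of score.
#' @param background Background base composition.
#' @return An object of class `spacing_result`: a `data.frame` of occupied
#'   bins (`primary_id`, `secondary_id`, `gap`, `quadrant`, `count`,
#'   `n_seqs`, `p_raw`, `p_adj`, `significant`), sorted by `p_adj`, with
#'   attributes `n_dropped`, `n_seqs`, `n_bins` (per secondary motif),
#'   `alpha`.
#' @export
spacing_enrichment <- function(seqs, primary_pwm, secondary_pwms,
                               margin = 50, alpha = 0.01,
                               min_secondary_score = -Inf,
                               background = c(0.25, 0.25, 0.25, 0.25)) {
  if (margin < 1) stop("margin must be >= 1")
  L1 <- nrow(primary_pwm$probs)
  oriented <- list()
  n_dropped <- 0L
  for (sid in names(seqs)) {
    s <- toupper(seqs[[sid]])
    bh <- best_hit(s, primary_pwm, background)
    if (is.null(bh)) { n_dropped <- n_dropped + 1L; next }
    if (bh$strand == "-") {
      s <- revcomp(s)
      bh$offset <- nchar(s) - L1 - bh$offset
    }
    p_start <- bh$offset
    p_end <- bh$offset + L1
    if (p_start < margin || p_end + margin > nchar(s)) {
      n_dropped <- n_dropped + 1L
      next
    }
    oriented[[sid]] <- list(left = substr(s, p_start - margin + 1L, p_start),
                            right = substr(s, p_end + 1L, p_end + margin))
  }
  n_seqs <- length(oriented)
  if (n_seqs == 0L) stop("no sequences survive primary-motif centring")

  keep <- vapply(secondary_pwms, function(p) nrow(p$probs) <= margin, TRUE)
  if (any(!keep)) {
    warning("secondary motif(s) longer than the margin skipped: ",
            paste(names(secondary_pwms)[!keep], collapse = ", "))
    secondary_pwms <- secondary_pwms[keep]
  }
  if (!length(secondary_pwms)) stop("no usable secondary motifs")
  n_motifs <- length(secondary_pwms)

  rows <- list()
  for (mid in names(secondary_pwms)) {
    pwm <- secondary_pwms[[mid]]
    L2 <- nrow(pwm$probs)
    n_gaps <- margin - L2 + 1L
    n_bins <- 4L * n_gaps
    counts <- matrix(0L, nrow = n_gaps, ncol = 4L,
                     dimnames = list(NULL, QUADRANTS))
    for (o in oriented) {
      best <- best_spaced_hit(o, pwm, margin, L2, min_secondary_score,
                              background)
      if (is.null(best)) next
      counts[best$gap + 1L, best$quadrant] <- counts[best$gap + 1L, best$quadrant] + 1L
    }
    occ <- which(counts > 0L, arr.ind = TRUE)
    if (nrow(occ) == 0L) next
    p_raw <- stats::pbinom(counts[occ] - 1L, n_seqs, 1 / n_bins,
                           lower.tail = FALSE)
    rows[[mid]] <- data.frame(primary_id = primary_pwm$motif_id,
                              secondary_id = mid,
                              gap = occ[, 1L] - 1L,
                              quadrant = QUADRANTS[occ[, 2L]],
                              count = counts[occ],
                              n_seqs = n_seqs,
                              p_raw = p_raw,
                              p_adj = pmin(1, p_raw * n_bins * n_motifs),
                              stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(primary_id = character(), secondary_id = character(),
               gap = integer(), quadrant = character(), count = integer(),
               n_seqs = integer(), p_raw = double(), p_adj = double(),
               stringsAsFactors = FALSE)
  }
  res$significant <- res$p_adj < alpha
  res <- res[order(res$p_adj, res$secondary_id, res$gap), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, n_dropped = n_dropped, n_seqs = n_seqs, alpha = alpha,
            class = c("spacing_result", "data.frame"))
}

# best secondary hit over both margins / strands of one oriented sequence;
# ties: smallest gap, then quadrant order as in QUADRANTS
best_spaced_hit <- function(o, pwm, margin, L2, min_score, background) {
  cand <- list()
  for (side in c("left", "right")) {
    sc <- scan_both(o[[side]], pwm, background)
    if (length(sc$plus) == 0L) next
    offs <- seq_along(sc$plus) - 1L
    gap <- if (side == "left") margin - (offs + L2) else offs
    quad_same <- if (side == "left") "same-strand-left" else "same-strand-right"
    quad_opp <- if (side == "left") "opposite-left" else "opposite-right"
    cand[[length(cand) + 1L]] <- data.frame(score = sc$plus, gap = gap,
                                            quadrant = quad_same,
                                            stringsAsFactors = FALSE)
    cand[[length(cand) + 1L]] <- data.frame(score = sc$minus, gap = gap,
                                            quadrant = quad_opp,
                                            stringsAsFactors = FALSE)
  }
  if (!length(cand)) return(NULL)
  cand <- do.call(rbind, cand)
  cand <- cand[cand$score >= min_score, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  best <- max(cand$score)
  cand <- cand[cand$score >= best - 1e-9, , drop = FALSE]
  cand <- cand[order(cand$gap, match(cand$quadrant, QUADRANTS)), , drop = FALSE]
  cand[1L, ]
}

#' @export
print.spacing_result <- function(x, ...) {
  cat("<spacing_result> primary ", x$primary_id[1L] %||% "?", ": ",
      attr(x, "n_seqs"), " sequences analysed (", attr(x, "n_dropped"),
      " dropped), ", sum(x$significant), " bin(s) significant at alpha = ",
      attr(x, "alpha"), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Significant partner motifs from a spacing analysis
#'
#' Collapses a [spacing_enrichment()] table to one row per secondary motif
#' (its best bin), keeping motifs whose adjusted p-value beats `alpha`.
#'
#' @param spacing A `spacing_result`.
#' @param alpha Threshold on `p_adj`; defaults to the analysis alpha.
#' @export
significant_partners <- function(spacing, alpha = attr(spacing, "alpha")) {
  df <- as.data.frame(spacing)
  df <- df[df$p_adj < alpha, , drop = FALSE]
  df[!duplicated(df$secondary_id), , drop = FALSE]
}
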