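# PWM scanning: log-odds scoring of sequences on both strands.
# Sequences are plain upper-case character strings over {A,C,G,T,N}; N
# contributes 0 bits (it is scored as the background).

BASES <- c("A", "C", "G", "T")

seq_to_int <- function(sequence) {
  v <- match(strsplit(toupper(sequence), "", fixed = TRUE)[[1L]],
             c(BASES, "N"))
  if (anyNA(v)) stop("sequence contains characters outside {A,C,G,T,N}")
  v
}

#' Reverse complement of a DNA string
#' @param sequence Character string over A/C/G/T/N.
#' @export
revcomp <- function(sequence) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(sequence), "",
                                              fixed = TRUE)[[1L]]),
                                 collapse = ""))
}

#' Log-odds score matrix of a PWM
#'
#' `score[i, b] = log2(probs[i, b] / background[b])`, in bits.
#'
#' @param pwm A [new_pwm()] object.
#' @param background Base composition (A, C, G, T); must sum to 1.
#' @return L x 4 numeric matrix.
#' @export
log_odds <- function(pwm, background = c(0.25, 0.25, 0.25, 0.25)) {
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8) {
    stop("background must be 4 positive probabilities summing to 1")
  }
  sc <- log2(sweep(pwm$probs, 2L, background, "/"))
  dimnames(sc) <- dimnames(pwm$probs)
  sc
}

# score every offset of one strand; lod5 has a 5th zero column for N
scan_strand <- function(seq_int, lod5) {
  L <- nrow(lod5)
  n <- length(seq_int)
  if (n < L) return(numeric(0))
  n_off <- n - L + 1L
  scores <- numeric(n_off)
  idx <- seq_len(n_off)
  for (i in seq_len(L)) {
    scores <- scores + lod5[i, seq_int[idx + (i - 1L)]]
  }
  scores
}

with_n_col <- function(lod) cbind(lod, 0)

# log-odds of the reverse complement motif: reverse rows, swap A<->T, C<->G
revcomp_lod <- function(lod) lod[rev(seq_len(nrow(lod))), c(4L, 3L, 2L, 1L), drop = FALSE]

scan_both <- function(sequence, pwm, background) {
  lod <- log_odds(pwm, background)
  si <- seq_to_int(sequence)
  list(plus = scan_strand(si, with_n_col(lod)),
       minus = scan_strand(si, with_n_col(revcomp_lod(lod))),
       L = nrow(lod))
}

#' Best motif hit in a sequence
#'
#' Scores every offset on both strands and returns the maximal hit.  Ties
#' are broken by smaller offset, then by the + strand, so the result is
#' deterministic (a palindromic best site reports the + strand).
#'
#' @param sequence DNA string.
#' @param pwm A [new_pwm()] object.
#' @param background Background base composition for [log_odds()].
#' @return A one-row `data.frame` (`offset` 0-based, `strand`, `score` in
#'   bits), or `NULL` if the sequence is shorter than the motif.
#' @export
best_hit <- function(sequence, pwm, background = c(0.25, 0.25, 0.25, 0.25)) {
  sc <- scan_both(sequence, pwm, background)
  if (length(sc$plus) == 0L) return(NULL)
  best <- max(sc$plus, sc$minus)
  tol <- 1e-9
  cand_plus <- which(sc$plus >= best - tol)
  cand_minus <- which(sc$minus >= best - tol)
  off_p <- if (length(cand_plus)) cand_plus[1L] else Inf
  off_m <- if (length(cand_minus)) cand_minus[1L] else Inf
  if (off_p <= off_m) {
    data.frame(offset = off_p - 1L, strand = "+", score = sc$plus[off_p],
               stringsAsFactors = FALSE)
  } else {
    data.frame(offset = off_m - 1L, strand = "-", score = sc$minus[off_m],
               stringsAsFactors = FALSE)
  }
}

#' All motif hits at or above a score threshold
#'
#' @inheritParams best_hit
#' @param min_score Minimal log-odds score (bits) to report.
#' @return `data.frame` with `offset` (0-based), `strand`, `score`, sorted
#'   by offset (+ before - at equal offset).
#' @export
hits_above <- function(sequence, pwm, min_score,
                       background = c(0.25, 0.25, 0.25, 0.25)) {
  sc <- scan_both(sequence, pwm, background)
  hp <- which(sc$plus >= min_score)
  hm <- which(sc$minus >= min_score)
  out <- data.frame(offset = c(hp, hm) - 1L,
                    strand = rep(c("+", "-"), c(length(hp), length(hm))),
                    score = c(sc$plus[hp], sc$minus[hm]),
                    stringsAsFactors = FALSE)
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Maximum achievable log-odds score of a PWM
#' @inheritParams log_odds
#' @export
max_score <- function(pwm, background = c(0.25, 0.25, 0.25, 0.25)) {
  sum(apply(log_odds(pwm, background), 1L, max))
}

#' Does a sequence contain a motif?
#'
#' Presence is scored as best hit >= `frac` of the maximum achievable
#' log-odds, a dialect-independent threshold.  The default 0.6 tolerates
#' roughly one mismatch to the consensus of a typical 8-mer matrix;
#' stricter cuts miss a large share of genuine sites drawn from the PWM
#' itself.
#'
#' @inheritParams best_hit
#' @param frac Fraction of [max_score()] required.
#' @export
has_motif <- function(sequence, pwm, frac = 0.6,
                      background = c(0.25, 0.25, 0.25, 0.25)) {
  bh <- best_hit(sequence, pwm, background)
  !is.null(bh) && bh$score >= frac * max_score(pwm, background)
}

#' Build a PWM from an IUPAC consensus string
#'
#' Each position puts probability about `conc` on the consensus base(s)
#' (split equally among degenerate alternatives) and the rest on the other
#' bases.  As in real motif matrices, columns are not identical: the
#' concentration varies deterministically by position and the
#' off-consensus mass is split unevenly, so different windows essentially
#' never tie on the log-odds score.
#'
#' @param motif_id,name Identifiers for [new_pwm()].
#' @param consensus IUPAC string (supports A,C,G,T,R,Y,S,W,K,M,N).
#' @param conc Approximate probability on consensus bases.  Default 0.94.
#' @param pseudocount Passed to [new_pwm()].
#' @export
consensus_pwm <- function(motif_id, consensus, name = motif_id, conc = 0.94,
                          pseudocount = 0.01) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                N = c("A", "C", "G", "T"))
  chars <- strsplit(toupper(consensus), "", fixed = TRUE)[[1L]]
  off_split <- c(0.5, 0.3, 0.2)
  probs <- t(vapply(seq_along(chars), function(i) {
    hit <- iupac[[chars[i]]]
    if (is.null(hit)) stop("unsupported IUPAC code '", chars[i], "'")
    if (length(hit) == 4L) return(rep(0.25, 4L))
    ci <- conc - 0.05 * ((i - 1L) %% 4L) / 3
    p <- numeric(4L)
    p[match(hit, BASES)] <- ci / length(hit)
    off <- setdiff(seq_len(4L), match(hit, BASES))
    p[off] <- (1 - ci) * off_split[seq_along(off)] / sum(off_split[seq_along(off)])
    p
  }, numeric(4L)))
  new_pwm(motif_id, name, probs, pseudocount)
}

#' The canonical AP-1 response elements
#'
#' TRE (TPA-responsive element, `TGA[C/G]TCA`, preferred by Jun/Jun and
#' Jun/Fos dimers) and CRE (cAMP-responsive element, `TGACGTCA`, preferred
#' by Jun/ATF dimers) as PWM objects.
#'
#' @return Named list with elements `TRE` and `CRE`.
#' @export
ap1_pwms <- function() {
  list(TRE = consensus_pwm("TRE", "TGASTCA", name = "AP1_TRE"),
       CRE = consensus_pwm("CRE", "TGACGTCA", name = "AP1_CRE"))
}

#' Scan many sequences for motif hits
#'
#' @param seqs Named character vector of sequences.
#' @param pwms Named list of [new_pwm()] objects.
#' @param frac Presence threshold as in [has_motif()].
#' @param background Background composition.
#' @return `data.frame` with columns `seq_id`, `motif_id`, `offset`,
#'   `strand`, `score`: the best hit per (sequence, motif) pair that
#'   reaches the threshold.
#' @export
scan_sequences <- function(seqs, pwms, frac = 0.6,
                           background = c(0.25, 0.25, 0.25, 0.25)) {
  rows <- list()
  for (mid in names(pwms)) {
    pwm <- pwms[[mid]]
    thr <- frac * max_score(pwm, background)
    for (sid in names(seqs)) {
      bh <- best_hit(seqs[[sid]], pwm, background)
      if (!is.null(bh) && bh$score >= thr) {
        rows[[length(rows) + 1L]] <- data.frame(seq_id = sid, motif_id = mid,
                                                bh, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(seq_id = character(), motif_id = character(),
                      offset = integer(), strand = character(),
                      score = double(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
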