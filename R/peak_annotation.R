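# Peak-to-gene annotation: posterior filtering, nearest-TSS assignment
# within a window, promoter-window binding indicators, and QC clustering of
# ChIP-seq libraries by read-count correlation.

#' Filter peaks on posterior probability
#'
#' Keeps peaks whose peak-caller posterior probability exceeds
#' `min_posterior` (strict inequality; the conventional significance cut is
#' posterior > 0.9).
#'
#' @param peaks Peak data frame ([read_bed()]).
#' @param min_posterior Threshold; peaks with `posterior > min_posterior`
#'   are kept.  Default 0.9.
#' @export
filter_peaks <- function(peaks, min_posterior = 0.9) {
  peaks[peaks$posterior > min_posterior, , drop = FALSE]
}

#' Assign peaks to the nearest TSS within a window
#'
#' Each peak is mapped to the gene whose TSS is nearest to the peak
#' midpoint (`floor((start + end) / 2)`), provided the distance does not
#' exceed `window_bp`; peaks with no TSS in range are left unassigned.
#' Distance is unstranded.  Equidistant TSS ties go to the
#' lexicographically smallest gene id so output is deterministic.
#'
#' @param peaks Peak data frame.
#' @param tss TSS annotation ([read_tss()]).
#' @param window_bp Maximum midpoint-to-TSS distance in bp (default 20000,
#'   i.e. a +/-20 kb window).
#' @return `data.frame` with one row per assigned peak: `peak`, `chrom`,
#'   `gene_id`, `distance`.  The number of distinct genes in the output is
#'   the transcript tally associated with the peak set.
#' @export
assign_peaks <- function(peaks, tss, window_bp = 20000) {
  if (nrow(tss) == 0L) stop("empty TSS annotation")
  if (window_bp <= 0) stop("window_bp must be positive")
  validate_tss(tss)
  out <- vector("list", nrow(peaks))
  mid <- (peaks$start + peaks$end) %/% 2L
  tss_by_chrom <- split(tss, tss$chrom)
  for (i in seq_len(nrow(peaks))) {
    cand <- tss_by_chrom[[peaks$chrom[i]]]
    if (is.null(cand)) next
    d <- abs(cand$tss - mid[i])
    ok <- which(d <= window_bp)
    if (!length(ok)) next
    best <- ok[order(d[ok], cand$gene_id[ok])][1L]
    out[[i]] <- data.frame(peak = peaks$name[i], chrom = peaks$chrom[i],
                           gene_id = cand$gene_id[best], distance = d[best],
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(peak = character(), chrom = character(),
                      gene_id = character(), distance = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Promoter-window binding indicator matrix
#'
#' For each TF (whose peak list should already be restricted to peaks
#' containing that TF's motif) marks the genes with at least one peak
#' overlapping the promoter window `[tss - half_width, tss + half_width]`
#' (an overlap of a single base suffices).
#'
#' @param tf_to_peaks Named list mapping TF id to a peak data frame.
#' @param tss TSS annotation.
#' @param half_width Promoter half-width in bp (default 500).
#' @return Binary genes x TFs matrix (dimnames set).  Empty peak lists give
#'   all-zero columns.
#' @export
promoter_binding <- function(tf_to_peaks, tss, half_width = 500) {
  validate_tss(tss)
  genes <- tss$gene_id
  ind <- matrix(0L, nrow = length(genes), ncol = length(tf_to_peaks),
                dimnames = list(genes, names(tf_to_peaks)))
  win_start <- tss$tss - half_width          # window is [win_start, win_end)
  win_end <- tss$tss + half_width + 1L
  for (tf in names(tf_to_peaks)) {
    pk <- tf_to_peaks[[tf]]
    if (is.null(pk) || nrow(pk) == 0L) next
    for (j in seq_len(nrow(pk))) {
      hit <- tss$chrom == pk$chrom[j] & pk$start[j] < win_end & pk$end[j] > win_start
      ind[hit, tf] <- 1L
    }
  }
  ind
}

#' Correlation clustering of ChIP-seq read-count profiles
#'
#' QC step: Pearson correlation between libraries on log2(count + 1)
#' transformed per-peak read counts, with average-linkage hierarchical
#' clustering of `1 - r`.  Libraries from the same biological group are
#' expected to cluster together with high within-cluster correlation.
#'
#' @param read_counts Non-negative peaks x libraries matrix.
#' @return List with `correlation` (symmetric, unit diagonal), `hclust`
#'   (average linkage on `1 - r`) and `order` (dendrogram leaf order).
#' @export
correlation_clusters <- function(read_counts) {
  read_counts <- as.matrix(read_counts)
  if (ncol(read_counts) < 2L) stop("need at least 2 libraries")
  if (any(read_counts < 0)) stop("read counts must be non-negative")
  lg <- log2(read_counts + 1)
  sds <- apply(lg, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance library: ",
         colnames(lg)[which(sds == 0)[1L]] %||% which(sds == 0)[1L])
  }
  r <- stats::cor(lg, method = "pearson")
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  list(correlation = r, hclust = hc, order = hc$order)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
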