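#' coopnet: cooperative TF partner and target inference
#'
#' Integrates ChIP-seq peak evidence with short time-course expression data
#' to infer a transcription factor's cooperative partners (spaced-motif
#' enrichment, correlation-based cooperativity test), its functionally
#' active targets (Gaussian-process latent-force ranking plus preranked
#' GSEA), the transcriptional response (SAM-style permutation differential
#' expression, direction-separated over-representation), and to assemble
#' the resulting TF-centred regulatory network.
#'
#' All genomic coordinates inside the package are 0-based half-open
#' (BED-native); dialects that differ are converted at the I/O boundary.
#'
#' @name coopnet-package
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Peaks (BED)
# ---------------------------------------------------------------------------

#' Read ChIP-seq peaks from a BED file
#'
#' Reads a 3-5 column BED file into a peak data frame.  Column 4 is taken as
#' the peak name and column 5 as a posterior probability in \[0, 1\] (the
#' peak-caller's confidence score).  Peaks without a score column are given
#' posterior 1 so that pre-filtered inputs pass through untouched.
#'
#' Coordinates are kept exactly as written: BED is 0-based half-open, which
#' is also the package-internal convention.
#'
#' @param path Path to a tab-separated BED file.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `posterior`, in file order.
#' @seealso [filter_peaks()], [assign_peaks()]
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), posterior = double(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3L)) {
    stop("malformed BED line ", which(n_fields < 3L)[1L],
         ": fewer than 3 tab-separated columns")
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("malformed BED line ", bad[1L], ": non-integer coordinate")
  name <- ifelse(n_fields >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""),
                 paste0("peak_", seq_along(fields)))
  name[n_fields < 4L] <- paste0("peak_", which(n_fields < 4L))
  posterior <- rep(1.0, length(fields))
  has_score <- n_fields >= 5L
  if (any(has_score)) {
    sc <- suppressWarnings(as.numeric(vapply(fields[has_score], `[[`, "", 5L)))
    if (anyNA(sc)) {
      stop("malformed BED line ", which(has_score)[which(is.na(sc))[1L]],
           ": non-numeric score column")
    }
    posterior[has_score] <- sc
  }
  peaks <- data.frame(chrom = vapply(fields, `[[`, "", 1L),
                      start = start, end = end, name = name,
                      posterior = posterior, stringsAsFactors = FALSE)
  validate_peaks(peaks)
  peaks
}

validate_peaks <- function(peaks) {
  bad <- which(peaks$start >= peaks$end)
  if (length(bad)) {
    stop("invalid peak interval at line ", bad[1L], ": start (", peaks$start[bad[1L]],
         ") >= end (", peaks$end[bad[1L]], ")")
  }
  if (any(peaks$start < 0L)) stop("negative peak start coordinate")
  bad <- which(peaks$posterior < 0 | peaks$posterior > 1)
  if (length(bad)) {
    stop("posterior probability outside [0, 1] at line ", bad[1L],
         " (", peaks$posterior[bad[1L]], ")")
  }
  invisible(peaks)
}

#' Write peaks as BED
#'
#' @param peaks Peak data frame as returned by [read_bed()].
#' @param path Output path.
#' @export
write_bed <- function(peaks, path) {
  validate_peaks(peaks)
  out <- sprintf("%s\t%d\t%d\t%s\t%s", peaks$chrom, peaks$start, peaks$end,
                 peaks$name, format(peaks$posterior, trim = TRUE, digits = 15))
  writeLines(out, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# TSS annotation
# ---------------------------------------------------------------------------

#' Read a TSS annotation table
#'
#' Expects a tab-separated file with header columns `gene_id`, `chrom`,
#' `strand`, `tss` (0-based transcription start position).  Gene identifiers
#' must be unique and strands must be `+` or `-`.
#'
#' @param path Path to the annotation TSV.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `strand`, `tss`.
#' @export
read_tss <- function(path) {
  tss <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  need <- c("gene_id", "chrom", "strand", "tss")
  missing_cols <- setdiff(need, names(tss))
  if (length(missing_cols)) {
    stop("TSS annotation missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  tss <- tss[need]
  validate_tss(tss)
  tss
}

validate_tss <- function(tss) {
  if (anyDuplicated(tss$gene_id)) {
    stop("duplicate gene_id in TSS annotation: ",
         tss$gene_id[which(duplicated(tss$gene_id))[1L]])
  }
  if (any(tss$tss < 0)) stop("negative TSS coordinate")
  if (!all(tss$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  invisible(tss)
}

#' @rdname read_tss
#' @param tss TSS data frame.
#' @export
write_tss <- function(tss, path) {
  validate_tss(tss)
  utils::write.table(tss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Position weight matrices
# ---------------------------------------------------------------------------

#' Construct a position weight matrix object
#'
#' Rows are motif positions, columns the bases A, C, G, T.  Probabilities
#' receive a small pseudocount and are renormalized so that no base has
#' probability exactly zero (which would give -Inf log-odds).
#'
#' @param motif_id Identifier (e.g. a TRANSFAC accession).
#' @param name TF name.
#' @param probs Numeric L x 4 matrix of base probabilities (or counts; any
#'   non-negative rows with positive sums are accepted and normalized).
#' @param pseudocount Probability mass added to each entry before
#'   renormalization.  Default 0.01.
#' @return An object of class `pwm`: a list with `motif_id`, `name`,
#'   `probs`, `pseudocount`.
#' @export
new_pwm <- function(motif_id, name, probs, pseudocount = 0.01) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stop("PWM must have 4 columns (A, C, G, T)")
  if (nrow(probs) < 4L) stop("PWM '", motif_id, "' shorter than 4 positions")
  if (any(probs < 0)) stop("negative entry in PWM '", motif_id, "'")
  rs <- rowSums(probs)
  if (any(rs <= 0)) {
    stop("PWM '", motif_id, "' has an all-zero row (position ",
         which(rs <= 0)[1L], ")")
  }
  probs <- probs / rs
  probs <- (probs + pseudocount) / (1 + 4 * pseudocount)
  dimnames(probs) <- list(NULL, c("A", "C", "G", "T"))
  structure(list(motif_id = motif_id, name = name, probs = probs,
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$motif_id, " (", x$name, "), length ", nrow(x$probs),
      ", consensus ", pwm_consensus(x), "\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a PWM (most probable base per position)
#' @param pwm A [new_pwm()] object.
#' @export
pwm_consensus <- function(pwm) {
  paste(c("A", "C", "G", "T")[max.col(pwm$probs, ties.method = "first")],
        collapse = "")
}

#' Read position weight matrices
#'
#' Supports two dialects: TRANSFAC count matrices (`AC`/`ID`/`NA` header
#' lines, a `P0`/`PO` column header, numbered count rows, `//` terminators)
#' and MEME minimal motif format (`MOTIF` lines followed by a
#' letter-probability matrix).  TRANSFAC counts are converted to
#' probabilities by row-sum normalization; both dialects then receive the
#' [new_pwm()] pseudocount.
#'
#' @param path Path to the motif file.
#' @param dialect `"transfac"` or `"meme"`.
#' @param pseudocount Passed to [new_pwm()].
#' @return A named list of `pwm` objects (names are motif ids).
#' @export
read_pwm <- function(path, dialect = c("transfac", "meme"), pseudocount = 0.01) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (dialect == "transfac") {
    parse_transfac(lines, pseudocount)
  } else {
    parse_meme(lines, pseudocount)
  }
}

parse_transfac <- function(lines, pseudocount) {
  pwms <- list()
  acc <- NULL; nm <- NULL; rows <- list()
  flush <- function() {
    if (is.null(acc) && length(rows) == 0L) return()
    if (length(rows) == 0L) stop("TRANSFAC record '", acc, "' has no matrix rows")
    probs <- do.call(rbind, rows)
    id <- if (!is.null(acc)) acc else "unnamed"
    pwms[[id]] <<- new_pwm(id, if (is.null(nm)) id else nm, probs, pseudocount)
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (startsWith(ln, "//")) { flush(); acc <- NULL; nm <- NULL; rows <- list(); next }
    tag <- substr(ln, 1L, 2L)
    rest <- trimws(substr(ln, 3L, nchar(ln)))
    if (tag %in% c("AC", "ID")) {
      # prefer ID as the motif id when both are present (TRANSFAC convention)
      if (tag == "ID" || is.null(acc)) acc <- rest
    } else if (tag == "NA") {
      nm <- rest
    } else if (tag %in% c("P0", "PO")) {
      next
    } else if (grepl("^[0-9]+$", tag)) {
      vals <- strsplit(rest, "\\s+")[[1L]]
      counts <- suppressWarnings(as.numeric(vals[seq_len(min(4L, length(vals)))]))
      if (length(counts) < 4L || anyNA(counts)) {
        stop("malformed TRANSFAC matrix row: '", ln, "'")
      }
      rows[[length(rows) + 1L]] <- counts
    }
  }
  flush()
  pwms
}

parse_meme <- function(lines, pseudocount) {
  pwms <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "MOTIF")) {
      toks <- strsplit(ln, "\\s+")[[1L]]
      id <- if (length(toks) >= 2L) toks[2L] else stop("MEME MOTIF line without id")
      nm <- if (length(toks) >= 3L) toks[3L] else id
      # advance to the letter-probability matrix header
      j <- i + 1L
      while (j <= length(lines) &&
             !grepl("^letter-probability matrix", trimws(lines[j]))) {
        if (startsWith(trimws(lines[j]), "MOTIF")) {
          stop("MEME motif '", id, "' has no letter-probability matrix")
        }
        j <- j + 1L
      }
      if (j > length(lines)) stop("MEME motif '", id, "' has no letter-probability matrix")
      w <- NA_integer_
      m <- regmatches(lines[j], regexec("w=\\s*([0-9]+)", lines[j]))[[1L]]
      if (length(m) == 2L) w <- as.integer(m[2L])
      rows <- list()
      j <- j + 1L
      while (j <= length(lines)) {
        rln <- trimws(lines[j])
        if (!nzchar(rln) || startsWith(rln, "MOTIF") || grepl("^URL", rln)) break
        vals <- suppressWarnings(as.numeric(strsplit(rln, "\\s+")[[1L]]))
        if (length(vals) != 4L || anyNA(vals)) break
        rows[[length(rows) + 1L]] <- vals
        j <- j + 1L
      }
      if (!is.na(w) && length(rows) != w) {
        stop("MEME motif '", id, "': expected ", w, " rows, found ", length(rows))
      }
      pwms[[id]] <- new_pwm(id, nm, do.call(rbind, rows), pseudocount)
      i <- j
    } else {
      i <- i + 1L
    }
  }
  pwms
}

# ---------------------------------------------------------------------------
# Expression matrix + samplesheet
# ---------------------------------------------------------------------------

#' Construct an annotated expression matrix
#'
#' The substrate for all expression analyses: a genes x samples matrix of
#' (assumed log2-scale) values together with per-sample metadata.  Samples
#' are ordered by (condition, time, replicate).
#'
#' @param values Numeric matrix, rownames = gene ids, colnames = sample labels.
#' @param samples `data.frame` with columns `sample`, `condition`, `time_h`,
#'   `replicate`; one row per column of `values`.
#' @return An object of class `coop_expr`: list with `values` and `samples`.
#' @export
new_expr <- function(values, samples) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("expression matrix needs gene rownames")
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene id in expression matrix: ",
         rownames(values)[which(duplicated(rownames(values)))[1L]])
  }
  need <- c("sample", "condition", "time_h", "replicate")
  if (!all(need %in% names(samples))) {
    stop("samplesheet must have columns: ", paste(need, collapse = ", "))
  }
  if (ncol(values) != nrow(samples)) stop("samplesheet rows != matrix columns")
  missing_lab <- setdiff(colnames(values), samples$sample)
  if (length(missing_lab)) {
    stop("sample label(s) absent from samplesheet: ",
         paste(missing_lab, collapse = ", "))
  }
  samples <- samples[match(colnames(values), samples$sample), need, drop = FALSE]
  ord <- order(samples$condition, samples$time_h, samples$replicate)
  samples <- samples[ord, , drop = FALSE]
  rownames(samples) <- NULL
  values <- values[, samples$sample, drop = FALSE]
  if (!all(is.finite(values))) stop("expression matrix contains non-finite values")
  structure(list(values = values, samples = samples), class = "coop_expr")
}

#' @export
print.coop_expr <- function(x, ...) {
  cat("<coop_expr> ", nrow(x$values), " genes x ", ncol(x$values), " samples; ",
      "conditions: ", paste(unique(x$samples$condition), collapse = ", "),
      "; times (h): ", paste(sort(unique(x$samples$time_h)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Read an expression matrix with its samplesheet
#'
#' @param matrix_path TSV with gene ids in the first column and one column
#'   per sample.
#' @param samplesheet_path TSV with columns `sample`, `condition`, `time_h`,
#'   `replicate`.
#' @return A [new_expr()] object; samples ordered by (condition, time,
#'   replicate).
#' @export
read_expression <- function(matrix_path, samplesheet_path) {
  raw <- utils::read.table(matrix_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) stop("expression matrix needs a gene column plus samples")
  genes <- raw[[1L]]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = dimnames(vals)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric expression value for gene '", genes[idx[1L]],
         "', sample '", colnames(vals)[idx[2L]], "'")
  }
  rownames(num) <- genes
  sheet <- utils::read.table(samplesheet_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "")
  new_expr(num, sheet)
}

#' Write an expression matrix and samplesheet back to disk
#' @param expr A [new_expr()] object.
#' @inheritParams read_expression
#' @export
write_expression <- function(expr, matrix_path, samplesheet_path) {
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$samples, samplesheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}

#' Subset an expression matrix to one condition (optionally one time point)
#' @param expr A [new_expr()] object.
#' @param condition Condition label to keep.
#' @param time_h Optional time point (hours) to keep.
#' @export
subset_expr <- function(expr, condition, time_h = NULL) {
  keep <- expr$samples$condition == condition
  if (!is.null(time_h)) keep <- keep & expr$samples$time_h %in% time_h
  if (!any(keep)) stop("no samples match condition '", condition, "'")
  new_expr(expr$values[, expr$samples$sample[keep], drop = FALSE],
           expr$samples[keep, , drop = FALSE])
}

# ---------------------------------------------------------------------------
# Gene sets (GMT)
# ---------------------------------------------------------------------------

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated as set id, description,
#' then member genes.  Duplicate members within a line are dropped with a
#' warning.
#'
#' @param path Path to a GMT file.
#' @return A named list; each element is a list with `set_id`,
#'   `description`, `genes` (unique character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("GMT parse error at line ", i, ": fewer than 3 fields")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("GMT set '", f[1L], "': duplicate members deduplicated")
      genes <- unique(genes)
    }
    if (length(genes) == 0L) stop("GMT set '", f[1L], "' is empty")
    sets[[f[1L]]] <- list(set_id = f[1L], description = f[2L], genes = genes)
  }
  sets
}

#' @rdname read_gmt
#' @param sets A list as returned by [read_gmt()], or a named list of
#'   character vectors (descriptions default to the set id).
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    s <- sets[[id]]
    if (is.character(s)) s <- list(set_id = id, description = id, genes = s)
    paste(c(s$set_id, s$description, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Extract the plain gene vectors from a GMT list
#' @param sets A [read_gmt()] list.
#' @return Named list of character vectors.
#' @export
gmt_genes <- function(sets) lapply(sets, `[[`, "genes")

# ---------------------------------------------------------------------------
# FASTA (via Biostrings)
# ---------------------------------------------------------------------------

#' Read sequences from a FASTA file
#' @param path Path to a (plain-text) FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Network edge list
# ---------------------------------------------------------------------------

#' Write a regulatory-network edge list
#'
#' Tab-separated with columns `source`, `target`, `edge_type`
#' (`"dimer-partner"` or `"complex-target"`) and the evidence fields
#' `fwer`, `fisher_p`, `direction`.  Duplicate (source, target, edge_type)
#' triples are written once.
#'
#' @param edges `data.frame` with at least `source`, `target`, `edge_type`.
#' @param path Output path.
#' @export
write_network <- function(edges, path) {
  cols <- c("source", "target", "edge_type", "fwer", "fisher_p", "direction")
  for (cl in setdiff(cols, names(edges))) edges[[cl]] <- rep(NA, nrow(edges))
  edges <- edges[cols]
  if (nrow(edges)) {
    key <- paste(edges$source, edges$target, edges$edge_type, sep = "\r")
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
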