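# Synthetic-data generator: fixtures with the statistical structure the
# analysis assumes (planted spaced motifs in peak sequences, promoter /
# window peak placement, an ODE-driven two-condition time course with an
# attenuated-TF condition, cooperative gene blocks with elevated pairwise
# correlation), each with a truth table.

#' Scenario configuration for the synthetic-data generator
#'
#' Defaults emulate the macrophage activation study design: a 0/2/4/8 h
#' LPS-style time course with 4 biological replicates in two conditions,
#' the second condition carrying a 20-fold attenuated TF induction; peak
#' sequences carry one primary-motif instance (TRE by default) and planted
#' partners at fixed spacings.
#'
#' @param seed Master seed; every generator draw derives from it.
#' @param n_peaks,peak_len Number and length (bp) of peak sequences.
#' @param primary_motif `"TRE"` (`TGA[C/G]TCA`) or `"CRE"` (`TGACGTCA`),
#'   or any [new_pwm()] object.
#' @param planted_partners List of partner specs: each a list with `pwm`,
#'   `gap` (bp), `quadrant` (see [spacing_enrichment()]), `fraction` of
#'   sequences carrying the partner, and optionally `force_first` (plant
#'   unconditionally in the first so-many sequences).  Fractions must sum
#'   to at most 1: each sequence carries at most one partner.
#' @param n_genes,n_targets Total genes and TF-driven target genes.
#' @param time_points Observation times in hours.
#' @param replicates Biological replicates per time point.
#' @param noise_sd Gaussian observation noise on the log2 scale.
#' @param conditions Two condition labels; the second gets the attenuated
#'   TF pulse.
#' @param tf_attenuation Fold-attenuation of the TF pulse in the second
#'   condition (default 20).
#' @param ode_ranges Ranges for per-target ODE parameters: list with `B`,
#'   `S`, `D` two-element ranges.
#' @param coop_blocks List of cooperative blocks: each a list with
#'   `n_genes` and `r` (target pairwise correlation); block genes share a
#'   per-sample latent component.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1, n_peaks = 500, peak_len = 200,
                            primary_motif = "TRE",
                            planted_partners = list(),
                            n_genes = 200, n_targets = 40,
                            time_points = c(0, 2, 4, 8), replicates = 4,
                            noise_sd = 0.25,
                            conditions = c("WKY", "congenic"),
                            tf_attenuation = 20,
                            ode_ranges = list(B = c(0.5, 2), S = c(1, 3),
                                              D = c(0.4, 1.2)),
                            coop_blocks = list(),
                            n_bound_nontargets = 10) {
  if (n_targets > n_genes) stop("n_targets cannot exceed n_genes")
  for (p in planted_partners) {
    if (p$fraction < 0 || p$fraction > 1) stop("partner fraction outside [0, 1]")
  }
  if (length(conditions) != 2L) stop("exactly two condition labels expected")
  pwm <- if (inherits(primary_motif, "pwm")) primary_motif
         else ap1_pwms()[[match.arg(primary_motif, c("TRE", "CRE"))]]
  structure(list(seed = seed, n_peaks = n_peaks, peak_len = peak_len,
                 primary_pwm = pwm, planted_partners = planted_partners,
                 n_genes = n_genes, n_targets = n_targets,
                 time_points = time_points, replicates = replicates,
                 noise_sd = noise_sd, conditions = conditions,
                 tf_attenuation = tf_attenuation, ode_ranges = ode_ranges,
                 coop_blocks = coop_blocks,
                 n_bound_nontargets = n_bound_nontargets),
            class = "scenario_config")
}

sample_from_pwm <- function(pwm, rng_n) {
  paste(apply(pwm$probs, 1L, function(p) sample(BASES, 1L, prob = p)),
        collapse = "")
}

random_seq <- function(len) {
  paste(sample(BASES, len, replace = TRUE), collapse = "")
}

#' Generate peak sequences with planted motifs
#'
#' Each sequence carries one primary-motif instance (sampled from the PWM)
#' at a random offset leaving both flanking margins inside the sequence;
#' the whole sequence is then reverse-complemented with probability 1/2 so
#' both orientations occur.  For each planted partner a random `fraction`
#' of sequences receives a secondary instance at the configured gap and
#' quadrant relative to the primary site.
#'
#' @param config A [scenario_config()].
#' @param margin Flank (bp) kept free inside the sequence on both sides of
#'   the primary site (matches the spacing-analysis margin; default 50).
#' @return List with `seqs` (named character vector) and `truth`
#'   (`data.frame`: `seq_id`, `primary_offset`, `primary_strand`, one
#'   logical `planted_<partner>` column per partner).
#' @export
make_peak_sequences <- function(config, margin = 50) {
  set.seed(config$seed)
  L1 <- nrow(config$primary_pwm$probs)
  if (config$peak_len < L1 + 2 * margin) {
    stop("peak_len too short for the primary motif plus margins")
  }
  for (p in config$planted_partners) {
    L2 <- nrow(p$pwm$probs)
    if (p$gap + L2 > margin) stop("planted gap incompatible with the margin")
    if (!p$quadrant %in% QUADRANTS) stop("unknown quadrant '", p$quadrant, "'")
  }
  n <- config$n_peaks
  seqs <- character(n)
  truth <- data.frame(seq_id = sprintf("peak_%03d", seq_len(n)),
                      primary_offset = NA_integer_,
                      primary_strand = NA_character_,
                      stringsAsFactors = FALSE)
  # at most one partner per sequence: overlapping plantings would corrupt
  # each other's instances and create artificial cross-motif spacings
  planted <- matrix(FALSE, nrow = n, ncol = length(config$planted_partners))
  if (length(config$planted_partners)) {
    fracs <- vapply(config$planted_partners, `[[`, 0, "fraction")
    if (sum(fracs) > 1 + 1e-9) {
      stop("planted partner fractions sum to more than 1; ",
           "each sequence carries at most one partner")
    }
    force_first <- vapply(config$planted_partners,
                          function(p) p$force_first %||% 0L, 0)
    free <- rep(TRUE, n)
    for (j in seq_along(config$planted_partners)) {
      if (force_first[j] > 0L) {
        idx <- seq_len(min(force_first[j], n))
        planted[idx, j] <- TRUE
        free[idx] <- FALSE
      }
    }
    which_partner <- sample.int(length(fracs) + 1L, n, replace = TRUE,
                                prob = c(fracs, max(0, 1 - sum(fracs))))
    for (j in seq_along(config$planted_partners)) {
      planted[free & which_partner == j, j] <- TRUE
    }
  }
  for (i in seq_len(n)) {
    s <- strsplit(random_seq(config$peak_len), "", fixed = TRUE)[[1L]]
    off <- sample(margin:(config$peak_len - L1 - margin), 1L)  # 0-based
    s[(off + 1):(off + L1)] <-
      strsplit(sample_from_pwm(config$primary_pwm), "", fixed = TRUE)[[1L]]
    for (j in seq_along(config$planted_partners)) {
      if (!planted[i, j]) next
      p <- config$planted_partners[[j]]
      L2 <- nrow(p$pwm$probs)
      inst <- sample_from_pwm(p$pwm)
      if (grepl("opposite", p$quadrant)) inst <- revcomp(inst)
      sec_off <- if (grepl("right", p$quadrant)) off + L1 + p$gap
                 else off - p$gap - L2
      s[(sec_off + 1):(sec_off + L2)] <- strsplit(inst, "", fixed = TRUE)[[1L]]
    }
    sq <- paste(s, collapse = "")
    if (stats::runif(1) < 0.5) {
      sq <- revcomp(sq)
      truth$primary_offset[i] <- config$peak_len - L1 - off
      truth$primary_strand[i] <- "-"
    } else {
      truth$primary_offset[i] <- off
      truth$primary_strand[i] <- "+"
    }
    seqs[i] <- sq
  }
  names(seqs) <- truth$seq_id
  for (j in seq_along(config$planted_partners)) {
    truth[[paste0("planted_", config$planted_partners[[j]]$pwm$motif_id)]] <-
      planted[, j]
  }
  list(seqs = seqs, truth = truth)
}

# smooth TF induction pulse: rises to its peak by 2 h, decayed by 8 h
tf_pulse <- function(t, amplitude = 3, t_peak = 2) {
  amplitude * (t / t_peak) * exp(1 - t / t_peak)
}

ode_response <- function(t, B, S, D, x0, force, n_grid = 401) {
  vapply(t, function(tt) {
    base <- B / D + (x0 - B / D) * exp(-D * tt)
    if (tt == 0) return(base)
    u <- seq(0, tt, length.out = n_grid)
    g <- exp(-D * (tt - u)) * force(u)
    base + S * sum(diff(u) * (utils::head(g, -1) + utils::tail(g, -1)) / 2)
  }, 0)
}

#' Simulate the two-condition time-course expression matrix
#'
#' The TF gene follows a smooth induction pulse on top of a basal level;
#' in the second condition the pulse is attenuated `tf_attenuation`-fold.
#' Target genes respond through the linear ODE
#' `dx/dt = B + S f(t) - D x` (trapezoidal integration of the convolution
#' on a fine grid); non-targets sit at their basal level `B/D`.  Genes of
#' a cooperative block additionally share a per-sample latent component
#' scaled so the expected pairwise correlation within the block is `r`.
#' Gaussian noise of sd `noise_sd` (log2 scale) is added everywhere.
#'
#' @param config A [scenario_config()].
#' @param tf_gene_id Name given to the TF gene row (default `"TF"`).
#' @param tf_basal Basal TF expression (log2 units, default 7).
#' @param tf_amplitude Pulse amplitude (default 3).
#' @return List with `expr` (a [new_expr()] with `n_genes + 1` rows) and
#'   `truth` (`data.frame`: `gene_id`, `is_target`, `B`, `S`, `D`,
#'   `coop_block`).
#' @export
simulate_expression <- function(config, tf_gene_id = "TF", tf_basal = 7,
                                tf_amplitude = 3) {
  for (rg in config$ode_ranges) stopifnot(length(rg) == 2L)
  if (any(config$ode_ranges$D <= 0)) stop("decay range must be positive")
  set.seed(config$seed + 1L)
  genes <- sprintf("gene_%03d", seq_len(config$n_genes))
  targets <- genes[seq_len(config$n_targets)]
  tps <- config$time_points
  reps <- config$replicates
  samples <- expand.grid(replicate = seq_len(reps), time_h = tps,
                         condition = config$conditions,
                         stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_t%g_r%d", samples$condition, samples$time_h,
                            samples$replicate)
  samples <- samples[c("sample", "condition", "time_h", "replicate")]

  rg <- config$ode_ranges
  truth <- data.frame(gene_id = genes,
                      is_target = genes %in% targets,
                      B = stats::runif(config$n_genes, rg$B[1], rg$B[2]),
                      S = stats::runif(config$n_genes, rg$S[1], rg$S[2]),
                      D = stats::runif(config$n_genes, rg$D[1], rg$D[2]),
                      coop_block = NA_integer_,
                      stringsAsFactors = FALSE)
  gi <- 0L
  for (b in seq_along(config$coop_blocks)) {
    nb <- config$coop_blocks[[b]]$n_genes
    truth$coop_block[gi + seq_len(nb)] <- b
    gi <- gi + nb
  }

  vals <- matrix(NA_real_, nrow = config$n_genes + 1L, ncol = nrow(samples),
                 dimnames = list(c(tf_gene_id, genes), samples$sample))
  for (cond_i in 1:2) {
    amp <- if (cond_i == 1L) tf_amplitude else tf_amplitude / config$tf_attenuation
    force <- function(u) tf_pulse(u, amplitude = amp)
    cols <- samples$condition == config$conditions[cond_i]
    tcol <- samples$time_h[cols]
    tf_mean <- tf_basal + force(tcol)
    vals[tf_gene_id, cols] <- tf_mean + stats::rnorm(sum(cols), 0, config$noise_sd)
    resp <- lapply(seq_len(config$n_genes), function(g) {
      B <- truth$B[g]; S <- truth$S[g]; D <- truth$D[g]
      if (truth$is_target[g]) {
        ode_response(tps, B, S, D, x0 = B / D, force = force)
      } else {
        rep(B / D, length(tps))
      }
    })
    for (g in seq_len(config$n_genes)) {
      mu <- resp[[g]][match(tcol, tps)]
      vals[genes[g], cols] <- mu + stats::rnorm(sum(cols), 0, config$noise_sd)
    }
    # cooperative blocks: shared per-sample latent component
    for (b in seq_along(config$coop_blocks)) {
      blk <- config$coop_blocks[[b]]
      r <- blk$r
      sd_z <- config$noise_sd * sqrt(r / (1 - r))
      z <- stats::rnorm(sum(cols), 0, sd_z)
      members <- truth$gene_id[!is.na(truth$coop_block) & truth$coop_block == b]
      for (g in members) vals[g, cols] <- vals[g, cols] + z
    }
  }
  list(expr = new_expr(vals, samples), truth = truth)
}

#' Lay out genes and peaks on a synthetic chromosome
#'
#' Genes are spaced 50 kb apart on one synthetic chromosome.  The first
#' `n_targets` peaks are placed inside their gene's promoter (so the truth
#' binding indicator is 1); remaining peaks alternate between
#' gene-proximal placements inside the assignment window, boundary cases
#' just outside it, and low-posterior peaks that the posterior filter
#' should drop.
#'
#' @param config A [scenario_config()].
#' @param window_bp Assignment window the boundary cases are built around.
#' @param half_width Promoter half-width for the truth binding matrix.
#' @return List with `peaks` (BED-style data frame), `tss`, and
#'   `truth_binding` (genes x 1 indicator matrix for the primary TF).
#' @export
make_tss_and_binding <- function(config, window_bp = 20000, half_width = 500) {
  set.seed(config$seed + 2L)
  genes <- sprintf("gene_%03d", seq_len(config$n_genes))
  tss <- data.frame(gene_id = genes, chrom = "chrS",
                    strand = rep(c("+", "-"), length.out = config$n_genes),
                    tss = 50000L * seq_len(config$n_genes),
                    stringsAsFactors = FALSE)
  n <- config$n_peaks
  len <- config$peak_len
  peaks <- data.frame(chrom = "chrS", start = 0L, end = 0L,
                      name = sprintf("peak_%03d", seq_len(n)),
                      posterior = round(stats::runif(n, 0.92, 1), 4),
                      stringsAsFactors = FALSE)
  bound <- rep(FALSE, config$n_genes)
  n_prom <- config$n_targets + min(config$n_bound_nontargets,
                                   config$n_genes - config$n_targets)
  if (n_prom > n) stop("n_peaks too small for the promoter-bound genes")
  for (i in seq_len(n)) {
    if (i <= n_prom) {
      g <- i             # promoter peak: targets first, then bound non-targets
      center <- tss$tss[g] + sample(-(half_width - 1):(half_width - 1), 1L)
      bound[g] <- TRUE
    } else if (i %% 7L == 0L) {
      g <- sample(config$n_genes, 1L)          # just outside the window
      center <- tss$tss[g] + (window_bp + 1L + len %/% 2L)
    } else {
      g <- sample(config$n_genes, 1L)          # distal but assignable
      center <- tss$tss[g] + sample(c(-1, 1), 1L) * sample(2000:15000, 1L)
    }
    peaks$start[i] <- center - len %/% 2L
    peaks$end[i] <- peaks$start[i] + len
  }
  # a few sub-threshold distal peaks for the posterior filter to drop
  low <- seq_len(n) %% 11L == 0L & seq_len(n) > n_prom
  peaks$posterior[low] <- round(stats::runif(sum(low), 0.2, 0.9), 4)
  truth_binding <- matrix(as.integer(bound), ncol = 1L,
                          dimnames = list(genes, "primary"))
  list(peaks = peaks, tss = tss, truth_binding = truth_binding)
}
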