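# Assembly of the TF-centred regulatory network: spacing-significant
# partners whose target sets pass the GSEA family-wise error cut become
# partner nodes; the union of the retained sets' members are the target
# nodes, flagged with their differential-expression evidence.

#' Assemble the dimer-partner-target regulatory network
#'
#' One analysis is the result bundle for one dimer anchor (e.g. the
#' Jun-family TRE anchor or the ATF-family CRE anchor): the spacing table,
#' the GSEA table over the partner target sets, the direction-separated
#' over-representation table, and the target sets themselves, all keyed by
#' the partner motif id.  A partner is retained when its best spacing bin
#' has `p_adj < spacing_alpha` and its target set has
#' `fwer < fwer_cut`; a TF retained under several anchors becomes a single
#' node with one dimer edge per anchor.
#'
#' @param analyses Named list (names are dimer labels, e.g. `"TF/Jun"`);
#'   each element a list with `spacing` ([spacing_enrichment()]), `gsea`
#'   ([gsea_preranked()]), `overrep` ([overrep_by_direction()]; optional)
#'   and `target_sets` (named list of gene vectors).
#' @param fwer_cut GSEA FWER threshold (default 0.05).
#' @param fisher_cut Over-representation p threshold used to attach a DE
#'   direction to target edges (default 0.05).
#' @param spacing_alpha Threshold on the spacing adjusted p-value;
#'   defaults to each spacing table's own alpha.
#' @return Object of class `regulatory_network`: list with `nodes`
#'   (`data.frame`: `id`, `type` in dimer/partner/target), `edges`
#'   (`source`, `target`, `edge_type`, `fwer`, `fisher_p`, `direction`),
#'   `partners`, `targets`, and `counts` (named vector with `n_partners`,
#'   `n_targets`).
#' @export
assemble_network <- function(analyses, fwer_cut = 0.05, fisher_cut = 0.05,
                             spacing_alpha = NULL) {
  edges <- list()
  partners <- character()
  targets <- character()
  dimers <- names(analyses)
  if (is.null(dimers)) stop("analyses must be a named list of dimer anchors")
  for (dimer in dimers) {
    an <- analyses[[dimer]]
    alpha <- spacing_alpha %||% attr(an$spacing, "alpha") %||% 0.05
    sp <- significant_partners(an$spacing, alpha)
    gs <- as.data.frame(an$gsea)
    orphans <- setdiff(gs$set_id, names(an$target_sets))
    if (length(orphans)) {
      stop("set id(s) in GSEA results without a target set: ",
           paste(orphans, collapse = ", "))
    }
    keep <- gs$set_id[gs$fwer < fwer_cut & gs$set_id %in% sp$secondary_id]
    for (id in keep) {
      ov <- NULL
      if (!is.null(an$overrep)) {
        ov <- an$overrep[an$overrep$set_id == id & an$overrep$p < fisher_cut, ,
                         drop = FALSE]
        ov <- if (nrow(ov)) ov[which.min(ov$p), ] else NULL
      }
      edges[[length(edges) + 1L]] <- data.frame(
        source = dimer, target = id, edge_type = "dimer-partner",
        fwer = gs$fwer[gs$set_id == id][1L],
        fisher_p = if (is.null(ov)) NA_real_ else ov$p,
        direction = if (is.null(ov)) NA_character_ else ov$direction,
        stringsAsFactors = FALSE)
      members <- an$target_sets[[id]]
      edges[[length(edges) + 1L]] <- data.frame(
        source = id, target = members, edge_type = "complex-target",
        fwer = gs$fwer[gs$set_id == id][1L],
        fisher_p = if (is.null(ov)) NA_real_ else ov$p,
        direction = if (is.null(ov)) NA_character_ else ov$direction,
        stringsAsFactors = FALSE)
      partners <- c(partners, id)
      targets <- c(targets, members)
    }
  }
  partners <- unique(partners)
  targets <- unique(targets)
  edges <- if (length(edges)) do.call(rbind, edges) else {
    data.frame(source = character(), target = character(),
               edge_type = character(), fwer = double(), fisher_p = double(),
               direction = character(), stringsAsFactors = FALSE)
  }
  key <- paste(edges$source, edges$target, edges$edge_type, sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- data.frame(id = c(dimers, partners, targets),
                      type = rep(c("dimer", "partner", "target"),
                                 c(length(dimers), length(partners),
                                   length(targets))),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, partners = partners,
                 targets = targets,
                 counts = c(n_partners = length(partners),
                            n_targets = length(targets))),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("<regulatory_network> ", sum(x$nodes$type == "dimer"), " dimer(s), ",
      x$counts["n_partners"], " partner TF(s), ", x$counts["n_targets"],
      " distinct target gene(s), ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}
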