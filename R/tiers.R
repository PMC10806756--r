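.NDD_DISEASES <- c("AD", "ALS", "FTLD", "LBD", "PD", "PSP")

#' The six neurodegenerative diseases covered by the triage scheme
#' @return Character vector of disease codes.
#' @export
ndd_diseases <- function() .NDD_DISEASES

#' Multi-disease overlap summary
#'
#' Aggregates filtered gene-disease associations into, per gene, the set of
#' diseases it is significant in and its total association count. Ordering is
#' deterministic: descending disease count, then gene symbol.
#'
#' @param assocs Data frame with columns `gene` and `disease` (one row per
#'   association; other columns ignored).
#' @return Data frame with `gene`, `diseases` (comma-joined sorted labels),
#'   `n_diseases`, `n_assoc`.
#' @export
disease_overlap <- function(assocs) {
  if (nrow(assocs) == 0L) {
    return(data.frame(gene = character(), diseases = character(),
                      n_diseases = integer(), n_assoc = integer()))
  }
  sp <- split(assocs$disease, assocs$gene)
  out <- data.frame(
    gene = names(sp),
    diseases = vapply(sp, function(d) paste(sort(unique(d)), collapse = ","), ""),
    n_diseases = vapply(sp, function(d) length(unique(d)), 1L),
    n_assoc = lengths(sp),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$n_diseases, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Direction-of-effect consensus per gene
#'
#' Fraction of a gene's significant associations with positive SMR beta; a
#' gene is labeled "positive" above 0.5 (increased omic level associated with
#' increased risk), "negative" below, "split" at exactly 0.5.
#'
#' @param assocs Data frame with columns `gene` and `b_SMR` (all nonzero).
#' @return Data frame with `gene`, `frac_positive`, `consensus`.
#' @export
direction_consensus <- function(assocs) {
  if (any(assocs$b_SMR == 0)) stop("zero SMR beta violates the result contract")
  sp <- split(assocs$b_SMR > 0, assocs$gene)
  frac <- vapply(sp, mean, 0)
  data.frame(
    gene = names(sp),
    frac_positive = unname(frac),
    consensus = ifelse(frac > 0.5, "positive",
                       ifelse(frac < 0.5, "negative", "split")),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Multi-ancestry replication and direction concordance
#'
#' Checks which previously nominated genes also pass the significance
#' thresholds in multi-ancestry QTL results, and compares effect signs
#' between the discovery (European-panel) and multi-ancestry associations.
#'
#' @param candidates Data frame of discovery candidates with `gene` and
#'   `b_SMR` columns (one or more rows per gene).
#' @param ma_results Multi-ancestry SMR result rows (columns `gene`,
#'   `b_SMR`, `p_SMR_multi`, `p_HEIDI`).
#' @param cfg [significance_config()].
#' @return List with `replicated` (gene vector), `n_assoc_replicated`
#'   (passing multi-ancestry association count) and `concordance` (per
#'   candidate gene: "concordant", "discordant", "mixed" or "untested",
#'   comparing majority signs).
#' @export
replicate_multi_ancestry <- function(candidates, ma_results,
                                     cfg = significance_config()) {
  thr <- bonferroni_threshold(cfg$alpha, cfg$n_genes_tested)
  pass <- ma_results[ma_results$p_SMR_multi < thr &
                       !is.na(ma_results$p_HEIDI) &
                       ma_results$p_HEIDI > cfg$p_heidi_min, , drop = FALSE]
  cand_genes <- sort(unique(candidates$gene))
  pass <- pass[pass$gene %in% cand_genes, , drop = FALSE]
  replicated <- sort(unique(pass$gene))
  sign_of <- function(b) {
    f <- mean(b > 0)
    if (f > 0.5) 1L else if (f < 0.5) -1L else 0L
  }
  eur_sign <- vapply(split(candidates$b_SMR, candidates$gene), sign_of, 1L)
  conc <- vapply(cand_genes, function(g) {
    if (!g %in% replicated) return("untested")
    ms <- sign_of(pass$b_SMR[pass$gene == g])
    es <- eur_sign[[g]]
    if (ms == 0L || es == 0L) "mixed"
    else if (ms == es) "concordant" else "discordant"
  }, "")
  list(replicated = replicated,
       n_assoc_replicated = nrow(pass),
       concordance = data.frame(gene = cand_genes,
                                concordance = unname(conc),
                                stringsAsFactors = FALSE))
}

.resolve_aliases <- function(genes, aliases = NULL) {
  if (is.null(aliases) || nrow(aliases) == 0L) return(genes)
  i <- match(genes, aliases$alias)
  ifelse(is.na(i), genes, aliases$symbol[i])
}

#' Classify nominated genes into druggability tiers
#'
#' Three-tier scheme: "known" — druggable and targeted by a drug approved for
#' a neurodegenerative disease; "novel" — druggable but with no NDD-approved
#' drug (prime repurposing candidates); "difficult" — not annotated as
#' druggable. Trial-stage evidence does not promote a gene to known; only an
#' approved NDD indication does. Tiers partition the input gene set.
#'
#' @param genes Character vector of nominated genes.
#' @param druggable Character vector: the druggable-genome snapshot.
#' @param indications Data frame with columns `drug`, `gene`, `disease`,
#'   `approval_status` ("approved" or otherwise).
#' @param diseases Disease codes counting as NDD (default [ndd_diseases()]).
#' @param aliases Optional alias table (`alias`, `symbol`) applied to all
#'   gene inputs before matching.
#' @return Data frame: `gene`, `tier`, `druggable`, `ndd_approved_drugs`
#'   (comma-joined, possibly empty), `unannotated` (TRUE when the gene was
#'   absent from the druggability snapshot, hence treated as not druggable).
#' @export
classify_tiers <- function(genes, druggable, indications,
                           diseases = ndd_diseases(), aliases = NULL) {
  genes <- unique(.resolve_aliases(genes, aliases))
  druggable <- unique(.resolve_aliases(druggable, aliases))
  ind <- indications
  ind$gene <- .resolve_aliases(ind$gene, aliases)
  appr <- ind[ind$approval_status == "approved" & ind$disease %in% diseases, ,
              drop = FALSE]
  is_drug <- genes %in% druggable
  drugs <- vapply(genes, function(g) {
    paste(sort(unique(appr$drug[appr$gene == g])), collapse = ",")
  }, "")
  tier <- ifelse(!is_drug, "difficult",
                 ifelse(drugs != "", "known", "novel"))
  out <- data.frame(gene = genes, tier = tier, druggable = is_drug,
                    ndd_approved_drugs = unname(drugs),
                    unannotated = !is_drug & !genes %in% ind$gene,
                    stringsAsFactors = FALSE)
  out[order(match(out$tier, c("novel", "known", "difficult")), out$gene), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
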