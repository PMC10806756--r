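#' Assemble the final target-nomination report
#'
#' Joins the outputs of the pipeline stages into one row per nominated gene:
#' diseases, association count, direction consensus, druggability tier,
#' companion-gene and proxy-drug summary, liver-toxicity flags, EPR support
#' in disease-relevant cell types, and multi-ancestry replication status.
#' Per-disease and per-tier tallies are attached as attributes.
#'
#' @param candidates Filtered association table ([apply_filters()] output;
#'   columns `gene`, `disease`, `b_SMR`).
#' @param tiers [classify_tiers()] output.
#' @param companions Annotated companion report
#'   ([annotate_proxy_drugs()] output), or NULL.
#' @param liver_flags [liver_toxicity_flags()] output, or NULL.
#' @param epr_summary [expression_summary()] output, or NULL.
#' @param ma_replication [replicate_multi_ancestry()] output, or NULL.
#' @return Data frame, one row per gene in `tiers`, with attributes
#'   `tier_tally` (named integer vector novel/known/difficult),
#'   `disease_tally` and `n_associations`.
#' @export
build_report <- function(candidates, tiers, companions = NULL,
                         liver_flags = NULL, epr_summary = NULL,
                         ma_replication = NULL) {
  need <- c("gene", "tier")
  if (!all(need %in% names(tiers))) stop("schema mismatch in stage: tiers")
  if (nrow(candidates) > 0 &&
      !all(c("gene", "disease", "b_SMR") %in% names(candidates))) {
    stop("schema mismatch in stage: candidates")
  }
  ov <- disease_overlap(candidates)
  dc <- if (nrow(candidates) > 0) direction_consensus(candidates) else
    data.frame(gene = character(), frac_positive = double(),
               consensus = character())
  out <- data.frame(gene = tiers$gene, tier = tiers$tier,
                    stringsAsFactors = FALSE)
  out$diseases <- ov$diseases[match(out$gene, ov$gene)]
  out$n_assoc <- ov$n_assoc[match(out$gene, ov$gene)]
  out$n_assoc[is.na(out$n_assoc)] <- 0L
  out$diseases[is.na(out$diseases)] <- ""
  out$direction_consensus <- dc$consensus[match(out$gene, dc$gene)]
  if (!is.null(companions)) {
    if (!all(c("seed_gene", "companion") %in% names(companions))) {
      stop("schema mismatch in stage: companions")
    }
    sp <- split(companions, companions$seed_gene)
    out$n_companions <- vapply(out$gene, function(g) {
      if (g %in% names(sp)) length(unique(sp[[g]]$companion)) else 0L
    }, 1L)
    out$n_druggable_companions <- vapply(out$gene, function(g) {
      if (g %in% names(sp)) sum(tapply(sp[[g]]$druggable,
                                       sp[[g]]$companion, any)) else 0L
    }, 1L)
  }
  if (!is.null(liver_flags)) {
    out$liver_flag <- out$gene %in% liver_flags$gene[liver_flags$liver_flag]
  }
  if (!is.null(epr_summary)) {
    pg <- epr_summary$per_gene
    i <- match(out$gene, pg$gene)
    out$epr_relevant_support <- !is.na(i) & !pg$relevant_all_off[i]
  }
  if (!is.null(ma_replication)) {
    out$ma_replicated <- out$gene %in% ma_replication$replicated
    out$ma_concordance <- ma_replication$concordance$concordance[
      match(out$gene, ma_replication$concordance$gene)]
  }
  out <- out[order(match(out$tier, c("novel", "known", "difficult")),
                   out$gene), , drop = FALSE]
  rownames(out) <- NULL
  tier_tally <- vapply(c("novel", "known", "difficult"),
                       function(t) sum(out$tier == t), 1L)
  disease_tally <- if (nrow(candidates) > 0) {
    tab <- table(candidates$disease)
    setNames(as.integer(tab), names(tab))
  } else setNames(integer(0), character(0))
  attr(out, "tier_tally") <- tier_tally
  attr(out, "disease_tally") <- disease_tally
  attr(out, "n_associations") <- nrow(candidates)
  out
}

#' Write a report (or any stage table) as TSV with a JSON tally sidecar
#'
#' @param report [build_report()] output.
#' @param path Output TSV path; the sidecar is written at `<path>.tally.json`
#'   when the jsonlite package is available.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    tallies <- list(tiers = as.list(attr(report, "tier_tally")),
                    diseases = as.list(attr(report, "disease_tally")),
                    n_associations = attr(report, "n_associations"))
    jsonlite::write_json(tallies, paste0(path, ".tally.json"),
                         auto_unbox = TRUE)
  }
  invisible(path)
}
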