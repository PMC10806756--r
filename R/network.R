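#' Expand a seed gene into its curated companion network
#'
#' Companions are the one-hop neighborhood of the seed in a directed,
#' manually curated interaction table: direct regulators (upstream) and
#' direct targets (downstream). No transitive closure is taken; a gene that
#' is both regulator and target of the seed yields one row per direction.
#'
#' @param seed Seed gene symbol.
#' @param edges Data frame with columns `regulator`, `target`, `relation`,
#'   `source`.
#' @return Data frame with `seed_gene`, `companion`, `direction`
#'   ("upstream"/"downstream"), `relation`, `source`, ordered by direction
#'   then companion. A seed absent from the table returns zero rows with
#'   `attr(, "note") = "no network"`.
#' @export
expand_companions <- function(seed, edges) {
  up <- edges[edges$target == seed & edges$regulator != seed, , drop = FALSE]
  down <- edges[edges$regulator == seed & edges$target != seed, , drop = FALSE]
  out <- rbind(
    if (nrow(up) > 0L) data.frame(seed_gene = seed, companion = up$regulator,
                                  direction = "upstream",
                                  relation = up$relation, source = up$source,
                                  stringsAsFactors = FALSE),
    if (nrow(down) > 0L) data.frame(seed_gene = seed, companion = down$target,
                                    direction = "downstream",
                                    relation = down$relation,
                                    source = down$source,
                                    stringsAsFactors = FALSE)
  )
  if (is.null(out)) {
    out <- data.frame(seed_gene = character(), companion = character(),
                      direction = character(), relation = character(),
                      source = character(), stringsAsFactors = FALSE)
    if (!seed %in% c(edges$regulator, edges$target)) {
      attr(out, "note") <- "no network"
    }
    return(out)
  }
  out <- unique(out)
  out <- out[order(out$direction, out$companion), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate companion genes with proxy-drug evidence
#'
#' Fills druggability and drug columns on a companion report using the same
#' rules as [classify_tiers()]: a companion is druggable if it is in the
#' druggable-genome snapshot; its known drugs are all drugs listed against it
#' in the indication table; `ndd_approved` is TRUE when any of those drugs
#' has an approved indication for one of the study diseases.
#'
#' @param reports Output of [expand_companions()] (possibly row-bound over
#'   seeds).
#' @param druggable Character vector of druggable genes.
#' @param indications Data frame (`drug`, `gene`, `disease`,
#'   `approval_status`).
#' @param diseases NDD disease codes.
#' @return `reports` with added columns `druggable`, `known_drugs`,
#'   `ndd_approved`; the companion set is never altered.
#' @export
annotate_proxy_drugs <- function(reports, druggable, indications,
                                 diseases = ndd_diseases()) {
  if (nrow(reports) == 0L) {
    reports$druggable <- logical(0)
    reports$known_drugs <- character(0)
    reports$ndd_approved <- logical(0)
    return(reports)
  }
  reports$druggable <- reports$companion %in% druggable
  reports$known_drugs <- vapply(reports$companion, function(g) {
    paste(sort(unique(indications$drug[indications$gene == g])), collapse = ",")
  }, "")
  appr <- indications[indications$approval_status == "approved" &
                        indications$disease %in% diseases, , drop = FALSE]
  reports$ndd_approved <- reports$companion %in% appr$gene
  reports
}

#' Flag liver-eQTL toxicity signals in a target network
#'
#' Liver expression is used as a drug-toxicity proxy: a seed or companion
#' gene with a filtered, significant liver-tissue SMR association in any
#' disease is flagged, with the disease context reported. Flags are monotone
#' in the liver evidence — adding associations can only switch flags on.
#'
#' @param reports Companion report (columns `seed_gene`, `companion`).
#' @param seeds Character vector of seed genes (flagged at seed level too).
#' @param liver_results Filtered association rows restricted to liver tissue
#'   (columns `gene`, `disease`).
#' @return Data frame with `gene`, `role` ("seed"/"companion"),
#'   `liver_flag`, `liver_diseases` (comma-joined, empty when unflagged).
#' @export
liver_toxicity_flags <- function(reports, seeds, liver_results) {
  genes <- unique(c(seeds, reports$companion))
  role <- ifelse(genes %in% seeds, "seed", "companion")
  dis <- vapply(genes, function(g) {
    paste(sort(unique(liver_results$disease[liver_results$gene == g])),
          collapse = ",")
  }, "")
  data.frame(gene = genes, role = role, liver_flag = dis != "",
             liver_diseases = unname(dis),
             stringsAsFactors = FALSE, row.names = NULL)
}
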