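#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param n Number of tests (here, protein-coding genes tested).
#' @return `alpha / n`.
#' @export
bonferroni_threshold <- function(alpha, n) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be a count >= 1")
  alpha / n
}

#' Significance configuration for candidate filtering
#'
#' The study-wide defaults: family alpha 0.05 over 16,875 protein-coding
#' genes (the multi-SNP SMR threshold), HEIDI p > 0.01 required for inclusion
#' (small HEIDI p indicates linkage rather than a shared causal variant), and
#' a relaxed exploratory threshold of 0.05 for pleiotropy lookups in diseases
#' with no genome-wide-significant hit.
#'
#' @param alpha Family-wise error rate.
#' @param n_genes_tested Number of genes tested.
#' @param p_heidi_min HEIDI p-value that must be exceeded.
#' @param relaxed_p Relaxed multi-SNP SMR threshold for pleiotropy lookups.
#' @return Named list.
#' @export
significance_config <- function(alpha = 0.05, n_genes_tested = 16875,
                                p_heidi_min = 0.01, relaxed_p = 0.05) {
  stopifnot(alpha > 0, alpha < 1, n_genes_tested >= 1,
            p_heidi_min > 0, p_heidi_min < 1, relaxed_p > 0, relaxed_p < 1)
  list(alpha = alpha, n_genes_tested = n_genes_tested,
       p_heidi_min = p_heidi_min, relaxed_p = relaxed_p)
}

#' Default extended-MHC interval (hg19)
#'
#' chr6:28,477,797-33,448,354; genes overlapping it are excluded because the
#' region's extreme LD defeats fine-scale colocalization-style inference.
#'
#' @return List with `chrom`, `start`, `end`.
#' @export
mhc_interval <- function() list(chrom = "6", start = 28477797L, end = 33448354L)

#' Build a gene annotation table
#'
#' @param gene_symbol,chrom,start,end,protein_coding Parallel vectors; spans
#'   are 1-based inclusive (hg19).
#' @param mhc MHC interval as from [mhc_interval()]; `in_mhc` is derived by
#'   span overlap.
#' @return Data frame with an `in_mhc` column.
#' @export
gene_annotation <- function(gene_symbol, chrom, start, end, protein_coding,
                            mhc = mhc_interval()) {
  stopifnot(all(start <= end))
  data.frame(
    gene_symbol = gene_symbol, chrom = as.character(chrom),
    start = start, end = end, protein_coding = protein_coding,
    in_mhc = as.character(chrom) == mhc$chrom &
      start <= mhc$end & end >= mhc$start,
    stringsAsFactors = FALSE
  )
}

#' Filter SMR results to candidate associations
#'
#' Applies, in fixed order, the exclusion rules: no annotation, not
#' protein-coding, in the MHC, multi-SNP SMR p at or above the Bonferroni
#' threshold, HEIDI p at or below the floor (with a missing HEIDI p tallied
#' separately but also excluded). The first matching rule claims each
#' excluded row, so the counts partition the input.
#'
#' @param results Data frame as from [run_smr()] (needs columns `gene`,
#'   `p_SMR_multi`, `p_HEIDI`).
#' @param annot Annotation table from [gene_annotation()].
#' @param cfg [significance_config()].
#' @return The retained rows; `attr(, "exclusions")` is a named integer
#'   vector of per-rule counts and `attr(, "p_threshold")` the threshold used.
#' @export
apply_filters <- function(results, annot, cfg = significance_config()) {
  thr <- bonferroni_threshold(cfg$alpha, cfg$n_genes_tested)
  n <- nrow(results)
  rule <- rep(NA_character_, n)
  ai <- match(results$gene, annot$gene_symbol)
  claim <- function(cond, label) {
    hit <- which(cond & is.na(rule))
    rule[hit] <<- label
  }
  claim(is.na(ai), "no_annotation")
  claim(!is.na(ai) & !annot$protein_coding[ai], "not_protein_coding")
  claim(!is.na(ai) & annot$in_mhc[ai], "in_mhc")
  claim(results$p_SMR_multi >= thr, "p_smr_multi")
  claim(is.na(results$p_HEIDI), "p_heidi_missing")
  claim(results$p_HEIDI <= cfg$p_heidi_min, "p_heidi")
  kept <- results[is.na(rule), , drop = FALSE]
  rownames(kept) <- NULL
  counts <- table(factor(rule, levels = c("no_annotation",
                                          "not_protein_coding", "in_mhc",
                                          "p_smr_multi", "p_heidi_missing",
                                          "p_heidi")))
  attr(kept, "exclusions") <- setNames(as.integer(counts), names(counts))
  attr(kept, "p_threshold") <- thr
  kept
}

#' Relaxed-threshold pleiotropy lookup
#'
#' For a disease with no association passing the stringent threshold,
#' restricts its full SMR results to genes already nominated in other
#' diseases and reports rows below a relaxed multi-SNP SMR threshold —
#' evidence of a shared (pleiotropic) signal too weak to clear the
#' genome-wide correction on its own.
#'
#' @param candidate_genes Character vector of nominated genes.
#' @param results SMR result data frame for the target disease.
#' @param relaxed_p Relaxed threshold (default 0.05).
#' @return List with `hits` (qualifying rows) and `n_genes` (unique genes).
#' @export
relaxed_pleiotropy_lookup <- function(candidate_genes, results,
                                      relaxed_p = 0.05) {
  if (length(candidate_genes) == 0L) stop("candidate gene set is empty")
  hits <- results[results$gene %in% candidate_genes &
                    results$p_SMR_multi < relaxed_p, , drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits, n_genes = length(unique(hits$gene)))
}
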