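#' Convert feature counts to TPM
#'
#' Per cell, counts are divided by the gene's maximum nonredundant
#' intron-removed exon length and scaled by `1e6 / T` (T the sum of
#' length-normalized counts) so each cell's TPM vector sums to one million.
#'
#' @param counts Gene x cell matrix (base or `Matrix` sparse) of nonnegative
#'   counts; rownames are genes.
#' @param exon_length Named numeric vector of exon lengths (bp) covering
#'   every gene.
#' @return Dense gene x cell TPM matrix; every column sums to 1e6.
#' @export
counts_to_tpm <- function(counts, exon_length) {
  genes <- rownames(counts)
  if (is.null(genes)) stop("counts must carry gene rownames")
  len <- exon_length[genes]
  if (anyNA(len)) {
    stop("missing exon length for: ",
         paste(genes[is.na(len)], collapse = ", "))
  }
  if (any(len <= 0)) stop("exon lengths must be positive")
  m <- as.matrix(counts)
  rate <- m / len
  tot <- colSums(rate)
  if (any(tot == 0)) {
    stop("all-zero cell(s): ",
         paste(colnames(m)[tot == 0], collapse = ", "))
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' Expression percentile ranks within each cell
#'
#' A gene's EPR in a cell is 100 times the empirical cumulative distribution
#' function of that cell's gene-wise TPM values evaluated at the gene's TPM;
#' ties share the maximal rank of their tie group, so values lie in (0, 100].
#'
#' @param tpm Gene x cell TPM matrix.
#' @return Gene x cell matrix of percentile ranks.
#' @export
epr_ranks <- function(tpm) {
  n <- nrow(tpm)
  apply(tpm, 2, function(x) 100 * rank(x, ties.method = "max") / n)
}

#' EPR bin boundaries
#'
#' Mean EPR below 10 is "off", above 90 is "high", otherwise "low"; the
#' boundary values 10 and 90 fall in "low" (closed interval convention).
#'
#' @param mean_epr Numeric vector of mean EPR values.
#' @return Character vector of bins.
#' @export
epr_bin <- function(mean_epr) {
  ifelse(mean_epr < 10, "off", ifelse(mean_epr > 90, "high", "low"))
}

#' Aggregate EPR per gene and cell type
#'
#' Mean and median EPR over cells of each type, with the off/low/high bin
#' assigned from the mean. Cell types with no cells are omitted (they cannot
#' occur given labels come from the cells themselves).
#'
#' @param epr Gene x cell EPR matrix.
#' @param cell_type Character vector of cell-type labels, one per column.
#' @return Data frame: `gene`, `cell_type`, `mean_epr`, `median_epr`, `bin`.
#' @export
aggregate_epr <- function(epr, cell_type) {
  stopifnot(length(cell_type) == ncol(epr))
  types <- sort(unique(cell_type))
  out <- do.call(rbind, lapply(types, function(ct) {
    sub <- epr[, cell_type == ct, drop = FALSE]
    data.frame(gene = rownames(epr), cell_type = ct,
               mean_epr = rowMeans(sub),
               median_epr = apply(sub, 1, median),
               stringsAsFactors = FALSE)
  }))
  out$bin <- epr_bin(out$mean_epr)
  rownames(out) <- NULL
  out
}

#' Summarize EPR support across the cell-type universe
#'
#' Per-gene categories over all observed cell types: `all_off` (off
#' everywhere), `all_low` (low everywhere), `any_high` (high in at least one
#' type); plus the same recount restricted to a disease-relevant subset and
#' per-cell-type tallies of off/low/high gene counts.
#'
#' @param records Output of [aggregate_epr()].
#' @param relevant_types Cell types to recount over (default
#'   [relevant_cell_types()]); silently intersected with the observed
#'   universe.
#' @return List: `per_gene` (gene, all_off, all_low, any_high, plus the
#'   `relevant_` variants), `counts` (n_all_off, n_all_low, n_any_high),
#'   `per_cell_type` (cell_type, n_off, n_low, n_high), and
#'   `incomplete_genes` (genes missing some cell types, counted against the
#'   types they have).
#' @export
expression_summary <- function(records, relevant_types = relevant_cell_types()) {
  universe <- sort(unique(records$cell_type))
  relevant <- intersect(relevant_types, universe)
  sp <- split(records, records$gene)
  per_gene <- do.call(rbind, lapply(sp, function(r) {
    rel <- r[r$cell_type %in% relevant, , drop = FALSE]
    data.frame(
      gene = r$gene[1],
      all_off = all(r$bin == "off"),
      all_low = all(r$bin == "low"),
      any_high = any(r$bin == "high"),
      relevant_all_off = nrow(rel) > 0 && all(rel$bin == "off"),
      relevant_all_low = nrow(rel) > 0 && all(rel$bin == "low"),
      relevant_any_high = nrow(rel) > 0 && any(rel$bin == "high"),
      n_types = nrow(r),
      stringsAsFactors = FALSE
    )
  }))
  rownames(per_gene) <- NULL
  per_cell_type <- do.call(rbind, lapply(universe, function(ct) {
    b <- records$bin[records$cell_type == ct]
    data.frame(cell_type = ct, n_off = sum(b == "off"),
               n_low = sum(b == "low"), n_high = sum(b == "high"),
               stringsAsFactors = FALSE)
  }))
  list(
    per_gene = per_gene,
    counts = c(n_all_off = sum(per_gene$all_off),
               n_all_low = sum(per_gene$all_low),
               n_any_high = sum(per_gene$any_high)),
    per_cell_type = per_cell_type,
    incomplete_genes = per_gene$gene[per_gene$n_types < length(universe)]
  )
}

#' Disease-relevant cell types
#'
#' The adult human brain cell types found enriched for AD/PD-relevant gene
#' expression, used as the default subset for the restricted EPR recount.
#'
#' @return Character vector of 17 cell-type labels.
#' @export
relevant_cell_types <- function() {
  c("Bergmann glia", "CGE interneuron", "committed oligodendrocyte precursor",
    "deep-layer intratelencephalic", "eccentric medium spiny neuron",
    "hippocampal CA1-3", "hippocampal dentate gyrus", "LAMP5",
    "LHX6 and chandelier", "MGE interneuron", "mammillary body", "microglia",
    "midbrain derived inhibitory", "oligodendrocyte precursor",
    "thalamic excitatory", "upper layer intratelencephalic",
    "upper rhombic lip")
}

#' Union exon length per gene from a GTF file
#'
#' Reads exon features from an uncompressed GTF and returns, per gene, the
#' total length of the union of its exon intervals (maximum nonredundant
#' intron-removed length), ignoring strand.
#'
#' @param path GTF path.
#' @param gene_attr Attribute key holding the gene identifier.
#' @return Named numeric vector of lengths (bp).
#' @export
exon_lengths_from_gtf <- function(path, gene_attr = "gene_id") {
  g <- read.delim(path, header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE,
                  col.names = c("seqname", "source", "feature", "start",
                                "end", "score", "strand", "frame",
                                "attribute"))
  g <- g[g$feature == "exon", , drop = FALSE]
  pat <- paste0(gene_attr, "[ =]+\"?([^\";]+)\"?")
  m <- regmatches(g$attribute, regexec(pat, g$attribute))
  gene <- vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
  if (anyNA(gene)) stop("exon rows without a ", gene_attr, " attribute")
  key <- paste(gene, g$seqname)
  sp <- split(data.frame(start = g$start, end = g$end), key)
  union_len <- vapply(sp, function(iv) {
    iv <- iv[order(iv$start), , drop = FALSE]
    tot <- 0; cur_s <- iv$start[1]; cur_e <- iv$end[1]
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv$start[i] <= cur_e + 1) cur_e <- max(cur_e, iv$end[i])
      else { tot <- tot + (cur_e - cur_s + 1); cur_s <- iv$start[i]; cur_e <- iv$end[i] }
    }
    tot + (cur_e - cur_s + 1)
  }, 0)
  gene_of_key <- vapply(strsplit(names(union_len), " "), `[[`, "", 1L)
  tapply(union_len, gene_of_key, sum)
}

#' Read a counts matrix with gene and cell sidecars
#'
#' Loads an MTX counts file together with `genes.tsv` (gene, exon_length)
#' and `cells.tsv` (cell, cell_type).
#'
#' @param mtx,genes_tsv,cells_tsv File paths.
#' @return List with `counts` (sparse gene x cell matrix), `exon_length`
#'   (named vector) and `cell_type` (named vector).
#' @export
read_counts_mtx <- function(mtx, genes_tsv, cells_tsv) {
  counts <- Matrix::readMM(mtx)
  genes <- read.delim(genes_tsv, stringsAsFactors = FALSE)
  cells <- read.delim(cells_tsv, stringsAsFactors = FALSE)
  stopifnot(nrow(genes) == nrow(counts), nrow(cells) == ncol(counts))
  rownames(counts) <- genes$gene
  colnames(counts) <- cells$cell
  list(counts = counts,
       exon_length = setNames(genes$exon_length, genes$gene),
       cell_type = setNames(cells$cell_type, cells$cell))
}
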