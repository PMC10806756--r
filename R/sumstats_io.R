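#' @importFrom stats cor integrate median pchisq pnorm qchisq qnorm quantile
#'   rnbinom rnorm runif sd setNames var
#' @importFrom utils read.delim write.table head
"_PACKAGE"

.MA_COLS <- c("SNP", "A1", "A2", "freq", "b", "se", "p", "n")

#' Read GWAS summary statistics in "ma" format
#'
#' Parses a whitespace- or tab-separated file with header
#' `SNP A1 A2 freq b se p n` (the layout consumed by summary-data MR tools).
#' Alleles are uppercased. Rows failing basic validity checks (non-numeric or
#' non-positive `se`, `p` outside (0, 1], `freq` outside \[0, 1\], missing
#' effect size) are dropped and reported.
#'
#' @param path Path to the file.
#' @return A `data.frame` with columns `snp, a1, a2, freq, b, se, p, n` and an
#'   attribute `"rejected"`: a data.frame of row numbers and reasons for any
#'   rejected rows.
#' @export
read_gwas_ma <- function(path) {
  raw <- read.delim(path, sep = "", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = "character")
  missing_cols <- setdiff(.MA_COLS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("malformed summary-statistics file: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    snp  = raw$SNP,
    a1   = toupper(raw$A1),
    a2   = toupper(raw$A2),
    freq = suppressWarnings(as.numeric(raw$freq)),
    b    = suppressWarnings(as.numeric(raw$b)),
    se   = suppressWarnings(as.numeric(raw$se)),
    p    = suppressWarnings(as.numeric(raw$p)),
    n    = suppressWarnings(as.numeric(raw$n)),
    stringsAsFactors = FALSE
  )
  bad_reason <- rep(NA_character_, nrow(out))
  flag <- function(cond, reason) {
    hit <- which(cond & is.na(bad_reason))
    bad_reason[hit] <<- reason
  }
  flag(is.na(out$b) | is.na(out$se) | is.na(out$p), "non-numeric b/se/p")
  flag(!is.na(out$se) & out$se <= 0, "se not positive")
  flag(!is.na(out$p) & (out$p <= 0 | out$p > 1), "p outside (0,1]")
  flag(!is.na(out$freq) & (out$freq < 0 | out$freq > 1), "freq outside [0,1]")
  flag(out$a1 == out$a2, "identical alleles")
  rejected <- data.frame(row = which(!is.na(bad_reason)),
                         snp = out$snp[!is.na(bad_reason)],
                         reason = bad_reason[!is.na(bad_reason)],
                         stringsAsFactors = FALSE)
  out <- out[is.na(bad_reason), , drop = FALSE]
  dup <- unique(out$snp[duplicated(out$snp)])
  if (length(dup) > 0L) {
    stop("duplicate snp_id in summary statistics: ",
         paste(head(dup, 10L), collapse = ", "))
  }
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write GWAS summary statistics in "ma" format
#'
#' Inverse of [read_gwas_ma()]; numbers are written with full precision so a
#' write/read cycle round-trips exactly.
#'
#' @param sumstats Data frame as returned by [read_gwas_ma()].
#' @param path Output path.
#' @export
write_gwas_ma <- function(sumstats, path) {
  out <- data.frame(SNP = sumstats$snp, A1 = sumstats$a1, A2 = sumstats$a2,
                    freq = format(sumstats$freq, digits = 17, trim = TRUE),
                    b = format(sumstats$b, digits = 17, trim = TRUE),
                    se = format(sumstats$se, digits = 17, trim = TRUE),
                    p = format(sumstats$p, digits = 17, trim = TRUE),
                    n = format(sumstats$n, digits = 17, trim = TRUE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Complete effect sizes from Z scores
#'
#' Derives a per-allele effect and standard error from a standardized score,
#' the effect-allele frequency and the study sample size, for panels that
#' report only Z scores:
#' `se = 1 / sqrt(2 f (1 - f) (n + z^2))`, `beta = z * se`, so that
#' `beta / se` reproduces `z` exactly.
#'
#' @param z Standardized association score(s).
#' @param freq_a1 Effect-allele frequency in (0, 1).
#' @param n Study sample size.
#' @return A list with numeric vectors `beta` and `se`.
#' @export
z_to_beta_se <- function(z, freq_a1, n) {
  if (any(freq_a1 <= 0 | freq_a1 >= 1)) {
    stop("monomorphic variant: freq_a1 must lie strictly inside (0,1)")
  }
  if (any(n <= 0)) stop("n must be positive")
  se <- 1 / sqrt(2 * freq_a1 * (1 - freq_a1) * (n + z^2))
  list(beta = z * se, se = se)
}

#' Harmonize two summary-statistic sources to a shared effect allele
#'
#' Aligns QTL records to the GWAS effect allele. For variants whose a1/a2 are
#' swapped between the two sources the QTL beta is negated and its frequency
#' complemented; variants whose allele sets do not match, and variants whose
#' allele frequencies disagree by more than `freq_tol`, are dropped and
#' reported. Output rows are ordered by genomic position when available,
#' otherwise by snp id.
#'
#' @param gwas Data frame of GWAS records (`snp, a1, a2, freq, b, se, p, n`).
#' @param qtl Data frame of QTL records with the same columns (optionally
#'   `chrom`, `pos`).
#' @param freq_tol Maximum tolerated absolute difference in effect-allele
#'   frequency after alignment (default 0.2).
#' @return A list with data.frames `gwas` and `qtl` (row-aligned, one row per
#'   retained shared variant, QTL alleles aligned to the GWAS a1) and
#'   `dropped` (snp ids and reasons). Strand-ambiguous (A/T, C/G) variants are
#'   retained and flagged in a logical column `palindromic`.
#' @export
harmonize <- function(gwas, qtl, freq_tol = 0.2) {
  shared <- intersect(gwas$snp, qtl$snp)
  if (length(shared) == 0L) stop("no shared variants")
  g <- gwas[match(shared, gwas$snp), , drop = FALSE]
  q <- qtl[match(shared, qtl$snp), , drop = FALSE]

  same <- g$a1 == q$a1 & g$a2 == q$a2
  swap <- g$a1 == q$a2 & g$a2 == q$a1
  mismatch <- !(same | swap)

  q$b[swap] <- -q$b[swap]
  q$freq[swap] <- 1 - q$freq[swap]
  tmp <- q$a1[swap]; q$a1[swap] <- q$a2[swap]; q$a2[swap] <- tmp

  freq_bad <- !mismatch & abs(g$freq - q$freq) > freq_tol
  drop <- mismatch | freq_bad
  dropped <- data.frame(
    snp = shared[drop],
    reason = ifelse(mismatch[drop], "allele mismatch", "freq discordant"),
    stringsAsFactors = FALSE
  )
  g <- g[!drop, , drop = FALSE]
  q <- q[!drop, , drop = FALSE]

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  palindromic <- q$a2 == unname(comp[q$a1])
  ord <- if (!is.null(q$pos)) order(q$pos, q$snp) else order(q$snp)
  g <- g[ord, , drop = FALSE]; q <- q[ord, , drop = FALSE]
  g$palindromic <- q$palindromic <- palindromic[ord]
  rownames(g) <- rownames(q) <- NULL
  list(gwas = g, qtl = q, dropped = dropped)
}

#' Construct a QTL probe
#'
#' A probe is one molecular trait (gene expression level, CpG methylation,
#' protein abundance or chromatin peak) together with the summary statistics
#' of its cis variants.
#'
#' @param probe_id Probe identifier, unique within a dataset.
#' @param gene_symbol Gene symbol, or `NA`.
#' @param chrom Chromosome label.
#' @param probe_pos 1-based probe coordinate.
#' @param omic One of `"eQTL"`, `"mQTL"`, `"pQTL"`, `"caQTL"`.
#' @param tissue Tissue label.
#' @param ancestry Ancestry label (e.g. `"EUR"`, `"multi"`).
#' @param records Data frame of cis-variant records
#'   (`snp, chrom, pos, a1, a2, freq, b, se, p, n`).
#' @return An object of class `qtl_probe`.
#' @export
qtl_probe <- function(probe_id, gene_symbol, chrom, probe_pos, omic, tissue,
                      ancestry = "EUR", records) {
  omic <- match.arg(omic, c("eQTL", "mQTL", "pQTL", "caQTL"))
  if (nrow(records) > 0L && any(records$chrom != chrom)) {
    stop("probe ", probe_id, ": cis records must lie on the probe chromosome")
  }
  structure(list(probe_id = probe_id, gene_symbol = gene_symbol,
                 chrom = chrom, probe_pos = probe_pos, omic = omic,
                 tissue = tissue, ancestry = ancestry, records = records),
            class = "qtl_probe")
}

#' @export
print.qtl_probe <- function(x, ...) {
  cat(sprintf("<qtl_probe> %s (%s) %s:%d [%s, %s, %s] - %d cis variants\n",
              x$probe_id, x$gene_symbol, x$chrom, x$probe_pos, x$omic,
              x$tissue, x$ancestry, nrow(x$records)))
  invisible(x)
}

# Missing effect sizes in the on-disk store are written as this sentinel,
# never as zero (zero is a legitimate estimate).
.MISSING_SENTINEL <- "NA"

#' Serialize a QTL dataset to a three-file store
#'
#' Writes the plain-text analogue of the three-file QTL summary-data layout:
#' `<prefix>.vars.tsv` (variant index: snp, chrom, pos, a1, a2, freq),
#' `<prefix>.probes.tsv` (probe index: probe, chrom, pos, gene, omic, tissue,
#' ancestry) and `<prefix>.effects.tsv` (probe, snp, b, se, p, n). Missing
#' effects are stored as the literal `NA` sentinel. [load_qtl()] reconstructs
#' the dataset exactly.
#'
#' @param probes List of [qtl_probe()] objects.
#' @param out_prefix Output path prefix.
#' @return `out_prefix`, invisibly.
#' @export
serialize_qtl <- function(probes, out_prefix) {
  ids <- vapply(probes, `[[`, "", "probe_id")
  if (anyDuplicated(ids)) stop("duplicate probe_id in dataset")
  recs <- lapply(probes, `[[`, "records")
  allv <- do.call(rbind, c(list(data.frame(snp = character(), chrom = character(),
                                           pos = integer(), a1 = character(),
                                           a2 = character(), freq = double())),
                           lapply(recs, function(r)
                             r[, c("snp", "chrom", "pos", "a1", "a2", "freq")])))
  vars <- allv[!duplicated(allv$snp), , drop = FALSE]
  # a variant must carry consistent metadata everywhere it appears
  chk <- merge(allv, vars, by = "snp", suffixes = c("", ".idx"))
  bad <- chk$chrom != chk$chrom.idx | chk$pos != chk$pos.idx |
    chk$a1 != chk$a1.idx | chk$a2 != chk$a2.idx |
    abs(chk$freq - chk$freq.idx) > 1e-12
  if (any(bad)) {
    stop("inconsistent variant metadata across probes: ",
         paste(unique(chk$snp[bad]), collapse = ", "))
  }
  probe_idx <- data.frame(
    probe = ids,
    chrom = vapply(probes, `[[`, "", "chrom"),
    pos = vapply(probes, function(p) as.integer(p$probe_pos), 1L),
    gene = vapply(probes, function(p) as.character(p$gene_symbol), ""),
    omic = vapply(probes, `[[`, "", "omic"),
    tissue = vapply(probes, `[[`, "", "tissue"),
    ancestry = vapply(probes, `[[`, "", "ancestry"),
    stringsAsFactors = FALSE
  )
  eff <- do.call(rbind, c(
    list(data.frame(probe = character(), snp = character(), b = double(),
                    se = double(), p = double(), n = double())),
    Map(function(id, r) {
      if (nrow(r) == 0L) return(NULL)
      data.frame(probe = id, snp = r$snp, b = r$b, se = r$se, p = r$p, n = r$n)
    }, ids, recs)))
  num <- function(x) ifelse(is.na(x), .MISSING_SENTINEL,
                            format(x, digits = 17, trim = TRUE))
  eff_out <- data.frame(probe = eff$probe, snp = eff$snp, b = num(eff$b),
                        se = num(eff$se), p = num(eff$p), n = num(eff$n))
  vars_out <- vars
  vars_out$freq <- num(vars$freq)
  write.table(vars_out, paste0(out_prefix, ".vars.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(probe_idx, paste0(out_prefix, ".probes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(eff_out, paste0(out_prefix, ".effects.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(out_prefix)
}

#' Load a QTL dataset from a three-file store
#'
#' @param prefix Prefix previously passed to [serialize_qtl()].
#' @return List of [qtl_probe()] objects in probe-index order.
#' @export
load_qtl <- function(prefix) {
  vars <- read.delim(paste0(prefix, ".vars.tsv"), stringsAsFactors = FALSE,
                     colClasses = c(pos = "integer"))
  probe_idx <- read.delim(paste0(prefix, ".probes.tsv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  eff <- read.delim(paste0(prefix, ".effects.tsv"), stringsAsFactors = FALSE)
  if (nrow(eff) > 0L && !all(eff$snp %in% vars$snp)) {
    stop("effects store references variants absent from the index")
  }
  vars$chrom <- as.character(vars$chrom)
  lapply(seq_len(nrow(probe_idx)), function(i) {
    pi <- probe_idx[i, ]
    pe <- eff[eff$probe == pi$probe, , drop = FALSE]
    recs <- merge(pe[, c("snp", "b", "se", "p", "n")], vars, by = "snp",
                  sort = FALSE)
    recs <- recs[, c("snp", "chrom", "pos", "a1", "a2", "freq",
                     "b", "se", "p", "n")]
    recs[c("freq", "b", "se", "p", "n")] <-
      lapply(recs[c("freq", "b", "se", "p", "n")], as.numeric)
    rownames(recs) <- NULL
    qtl_probe(pi$probe, if (is.na(pi$gene)) NA_character_ else pi$gene,
              pi$chrom, pi$pos, pi$omic, pi$tissue, pi$ancestry, recs)
  })
}
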