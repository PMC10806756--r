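#' Construct an LD reference panel
#'
#' Wraps a hard-call allele-dosage matrix (samples x SNPs, values 0/1/2) with
#' its variant metadata. Pairwise LD correlations are computed on demand from
#' the dosages, after aligning each SNP to a requested effect allele.
#'
#' @param genotypes Numeric matrix, samples in rows, SNPs in columns; column
#'   names are snp ids. Dosages count copies of the panel effect allele.
#' @param snp_info Data frame with columns `snp, chrom, pos, a1, a2, freq`
#'   (`a1` is the allele counted by the dosages; `freq` its panel frequency).
#' @return An object of class `ld_panel`.
#' @export
ld_panel <- function(genotypes, snp_info) {
  if (is.null(colnames(genotypes))) colnames(genotypes) <- snp_info$snp
  if (!identical(colnames(genotypes), snp_info$snp)) {
    stop("genotype columns and snp_info must list the same SNPs in order")
  }
  structure(list(genotypes = genotypes, snp_info = snp_info),
            class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("<ld_panel> %d samples x %d SNPs\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  invisible(x)
}

#' LD correlation submatrix from a panel
#'
#' @param panel An [ld_panel()].
#' @param snps SNP ids to extract (must all be present in the panel).
#' @param effect_allele Optional character vector (parallel to `snps`) naming
#'   the effect allele each requested SNP's statistics refer to. Where it is
#'   the panel's other allele, that SNP's dosage is reflected, which negates
#'   its correlations; an allele matching neither panel allele is an error.
#' @return Correlation matrix with `snps` as dimnames.
#' @export
ld_cor <- function(panel, snps, effect_allele = NULL) {
  idx <- match(snps, panel$snp_info$snp)
  if (anyNA(idx)) {
    stop("SNP(s) absent from LD panel: ",
         paste(snps[is.na(idx)], collapse = ", "))
  }
  g <- panel$genotypes[, idx, drop = FALSE]
  if (!is.null(effect_allele)) {
    pa1 <- panel$snp_info$a1[idx]
    pa2 <- panel$snp_info$a2[idx]
    flip <- effect_allele == pa2
    bad <- !flip & effect_allele != pa1
    if (any(bad)) {
      stop("effect allele matches neither panel allele for: ",
           paste(snps[bad], collapse = ", "))
    }
    g[, flip] <- 2 - g[, flip, drop = FALSE]
  }
  r <- suppressWarnings(cor(g))
  r[is.na(r)] <- 0 # monomorphic columns carry no LD information
  diag(r) <- 1
  dimnames(r) <- list(snps, snps)
  r
}
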