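#' Default SMR engine configuration
#'
#' Mirrors the documented defaults of the reference summary-data MR tooling:
#' a 2,000 kb cis window and genome-wide instrument threshold for instrument
#' discovery, HEIDI on at most the top 20 SNPs within 500 kb of the probe with
#' LD-to-top r-squared restricted to \[0.05, 0.9\] and at least 3 SNPs
#' required for a reported p, and multi-SNP pruning at r-squared 0.9.
#'
#' @param cis_window_kb Instrument-discovery window around the probe (kb).
#' @param p_instrument QTL p-value threshold for an instrument.
#' @param heidi_window_kb HEIDI window around the probe (kb).
#' @param heidi_max_snps Maximum SNPs consumed by HEIDI (top instrument plus
#'   best-p others).
#' @param heidi_r2_min,heidi_r2_max Bounds on r-squared with the top SNP for a
#'   SNP to enter HEIDI.
#' @param heidi_min_snps Minimum non-top SNPs for a reported HEIDI p.
#' @param prune_r2_max Pairwise r-squared above which multi-SNP instruments
#'   are pruned (best QTL p kept).
#' @param freq_tol Allele-frequency concordance tolerance for harmonization.
#' @return Named list of settings.
#' @export
smr_config <- function(cis_window_kb = 2000, p_instrument = 5e-8,
                       heidi_window_kb = 500, heidi_max_snps = 20,
                       heidi_r2_min = 0.05, heidi_r2_max = 0.9,
                       heidi_min_snps = 3, prune_r2_max = 0.9,
                       freq_tol = 0.2) {
  list(cis_window_kb = cis_window_kb, p_instrument = p_instrument,
       heidi_window_kb = heidi_window_kb, heidi_max_snps = heidi_max_snps,
       heidi_r2_min = heidi_r2_min, heidi_r2_max = heidi_r2_max,
       heidi_min_snps = heidi_min_snps, prune_r2_max = prune_r2_max,
       freq_tol = freq_tol)
}

#' Select cis instruments for a probe
#'
#' Returns the probe's cis records restricted to the discovery window and the
#' instrument significance threshold, ordered by ascending QTL p-value so the
#' first row is the top instrument.
#'
#' @param probe A [qtl_probe()].
#' @param window_kb Window half-width around the probe position, in kb.
#' @param p_instrument Instrument p-value threshold.
#' @return Data frame of qualifying records (possibly zero rows), best p first.
#' @export
select_instruments <- function(probe, window_kb = 2000, p_instrument = 5e-8) {
  r <- probe$records
  keep <- abs(r$pos - probe$probe_pos) <= window_kb * 1000 & r$p < p_instrument
  out <- r[keep, , drop = FALSE]
  out <- out[order(out$p, out$snp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Single-SNP SMR statistic
#'
#' The ratio (Wald) estimate of the exposure effect on the outcome at one
#' instrument: `beta_smr = b_gwas / b_qtl`, with the 1-df chi-square statistic
#' `t_smr = z_g^2 z_x^2 / (z_g^2 + z_x^2)` where `z = b/se` in each source,
#' and a delta-method standard error. `b_gwas = 0` yields `beta_smr = 0`,
#' `t_smr = 0`, `p_smr = 1` by continuity.
#'
#' Vectorized over its arguments.
#'
#' @param b_g,se_g Outcome (GWAS) effect and standard error.
#' @param b_x,se_x Exposure (QTL) effect and standard error.
#' @return List with `beta_smr`, `se_smr`, `t_smr`, `p_smr`.
#' @export
smr_single <- function(b_g, se_g, b_x, se_x) {
  if (any(se_g <= 0) || any(se_x <= 0)) stop("standard errors must be positive")
  if (any(b_x == 0)) stop("undefined ratio: exposure effect b_x is zero")
  z_g <- b_g / se_g
  z_x <- b_x / se_x
  denom <- z_g^2 + z_x^2
  t_smr <- ifelse(denom == 0, 0, (z_g^2 * z_x^2) / denom)
  beta_smr <- b_g / b_x
  se_smr <- ifelse(
    b_g == 0,
    se_g / abs(b_x),
    sqrt(beta_smr^2 * (se_g^2 / b_g^2 + se_x^2 / b_x^2))
  )
  list(beta_smr = beta_smr, se_smr = se_smr, t_smr = t_smr,
       p_smr = pchisq(t_smr, df = 1, lower.tail = FALSE))
}

# Delta-method covariance of the per-SNP ratio estimates b_xy, given LD r.
# GWAS and QTL samples are independent, so cross-source terms vanish.
.bxy_cov <- function(b_g, se_g, b_x, se_x, r) {
  m <- length(b_g)
  sg <- outer(se_g, se_g) * r
  sx <- outer(se_x, se_x) * r
  inv_bx <- 1 / b_x
  gt <- outer(b_g * inv_bx^2, b_g * inv_bx^2)
  outer(inv_bx, inv_bx) * sg + gt * sx
}

#' HEIDI heterogeneity test
#'
#' Tests whether the ratio estimates `b_xy(i)` at cis SNPs surrounding the
#' top instrument are homogeneous, as expected when a single shared causal
#' variant (pleiotropy) drives both sources, against the heterogeneity
#' produced by distinct causal variants in LD (linkage). Differences
#' `d_i = b_xy(i) - b_xy(top)` are standardized with a delta-method
#' covariance incorporating panel LD; the statistic `sum z_d_i^2` is referred
#' to a weighted sum of 1-df chi-squares with weights the eigenvalues of the
#' correlation matrix of the `z_d` vector.
#'
#' SNPs are screened by LD with the top instrument (`heidi_r2_min` to
#' `heidi_r2_max`) and mutually pruned at `heidi_r2_max`; at most
#' `heidi_max_snps` (including the top) enter. If the standardized-difference
#' correlation matrix is numerically singular the SNP in highest LD with the
#' rest is dropped and the test retried. Fewer than `heidi_min_snps` non-top
#' SNPs yields a missing p.
#'
#' @param gwas,qtl Row-aligned harmonized record data frames (same SNPs, same
#'   order, columns `snp, b, se, p`), covering the top instrument and the
#'   candidate cis SNPs.
#' @param top_snp Id of the top instrument.
#' @param panel [ld_panel()] covering all candidate SNPs.
#' @param config [smr_config()] list.
#' @return List with `p_heidi` (NA when untestable) and `n_snps` (SNPs
#'   entering the statistic, counting the top).
#' @export
heidi <- function(gwas, qtl, top_snp, panel, config = smr_config()) {
  stopifnot(identical(gwas$snp, qtl$snp))
  if (!top_snp %in% gwas$snp) stop("top_snp absent from harmonized records")
  snps <- gwas$snp
  r_all <- ld_cor(panel, snps, effect_allele = gwas$a1)
  r_top <- r_all[, top_snp]
  r2_top <- r_top^2
  cand <- snps[snps != top_snp &
                 r2_top[snps] >= config$heidi_r2_min &
                 r2_top[snps] <= config$heidi_r2_max]
  # mutual pruning at the upper bound, best QTL p first, top always kept
  ord <- cand[order(qtl$p[match(cand, snps)])]
  kept <- top_snp
  for (s in ord) {
    if (all(r_all[s, kept]^2 <= config$heidi_r2_max)) kept <- c(kept, s)
    if (length(kept) >= config$heidi_max_snps) break
  }
  repeat {
    if (length(kept) - 1L < config$heidi_min_snps) {
      return(list(p_heidi = NA_real_, n_snps = 0L))
    }
    idx <- match(kept, snps)
    res <- .heidi_stat(gwas$b[idx], gwas$se[idx], qtl$b[idx], qtl$se[idx],
                       r_all[kept, kept, drop = FALSE], which(kept == top_snp))
    if (!is.null(res)) return(res)
    # singular: drop the non-top SNP in highest aggregate LD with the rest
    non_top <- setdiff(kept, top_snp)
    agg <- vapply(non_top, function(s)
      max(abs(r_all[s, setdiff(kept, s)])), 0)
    kept <- setdiff(kept, non_top[which.max(agg)])
  }
}

.heidi_stat <- function(b_g, se_g, b_x, se_x, r, top_i) {
  m <- length(b_g)
  V <- .bxy_cov(b_g, se_g, b_x, se_x, r)
  bxy <- b_g / b_x
  others <- setdiff(seq_len(m), top_i)
  d <- bxy[others] - bxy[top_i]
  Vd <- V[others, others, drop = FALSE] -
    outer(V[others, top_i], rep(1, length(others))) -
    outer(rep(1, length(others)), V[others, top_i]) +
    V[top_i, top_i]
  vd <- diag(as.matrix(Vd))
  if (any(vd <= 0)) return(NULL)
  z <- d / sqrt(vd)
  C <- Vd / outer(sqrt(vd), sqrt(vd))
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6 || max(ev) < 1e-12) return(NULL)
  ev <- pmax(ev, 0)
  t_heidi <- sum(z^2)
  list(p_heidi = quadform_pvalue(t_heidi, ev),
       n_snps = length(others) + 1L)
}

#' Multi-SNP SMR test
#'
#' Combines the single-SNP SMR chi-square statistics of a near-independent
#' set of cis instruments. Instruments are greedily pruned at pairwise
#' r-squared `prune_r2_max`, keeping the best QTL p in each clash; the
#' combined statistic `sum t_smr_i` is referred to a weighted sum of 1-df
#' chi-squares whose weights are the eigenvalues of the retained SNPs' LD
#' correlation matrix. With one retained instrument the result equals the
#' single-SNP p exactly.
#'
#' @inheritParams heidi
#' @param instruments Character vector of instrument snp ids (subset of the
#'   harmonized records), best QTL p first.
#' @return List with `p_smr_multi` and `snps_used`.
#' @export
smr_multi <- function(gwas, qtl, instruments, panel, config = smr_config()) {
  stopifnot(identical(gwas$snp, qtl$snp), length(instruments) >= 1L)
  r <- ld_cor(panel, instruments, effect_allele =
                gwas$a1[match(instruments, gwas$snp)])
  kept <- character(0)
  for (s in instruments) {
    if (length(kept) == 0L || all(r[s, kept]^2 < config$prune_r2_max)) {
      kept <- c(kept, s)
    }
  }
  idx <- match(kept, gwas$snp)
  st <- smr_single(gwas$b[idx], gwas$se[idx], qtl$b[idx], qtl$se[idx])
  t_multi <- sum(st$t_smr)
  ev <- eigen(r[kept, kept, drop = FALSE], symmetric = TRUE,
              only.values = TRUE)$values
  list(p_smr_multi = quadform_pvalue(t_multi, pmax(ev, 0)),
       snps_used = kept)
}

#' Run SMR, HEIDI and multi-SNP SMR over a QTL dataset
#'
#' For each probe: harmonizes the GWAS records with the probe's cis records,
#' selects instruments, computes the single-SNP SMR statistic at the top
#' instrument, the HEIDI heterogeneity p over the top-20-within-500kb set,
#' and the multi-SNP SMR p over the pruned instrument set. Probes with no
#' instrument (or no panel-covered instrument) are skipped with a logged
#' reason.
#'
#' @param gwas GWAS summary statistics data frame (see [read_gwas_ma()]).
#' @param probes List of [qtl_probe()] objects.
#' @param panel [ld_panel()].
#' @param disease Disease label attached to every result row.
#' @param config [smr_config()] list.
#' @return Data frame with one row per analyzable probe, ordered by
#'   (disease, omic_tissue, chrom, probe position): probe, gene, chrom,
#'   probe_pos, topSNP, A1, A2, freq, b_GWAS, se_GWAS, p_GWAS, b_eQTL,
#'   se_eQTL, p_eQTL, b_SMR, se_SMR, p_SMR, p_SMR_multi, p_HEIDI, nsnp_HEIDI,
#'   plus disease, omic_tissue, ancestry and direction columns. Skips are in
#'   `attr(, "skipped")`.
#' @export
run_smr <- function(gwas, probes, panel, disease = "trait",
                    config = smr_config()) {
  rows <- list()
  skipped <- list()
  for (probe in probes) {
    tag <- probe$probe_id
    h <- tryCatch(harmonize(gwas, probe$records, freq_tol = config$freq_tol),
                  error = function(e) NULL)
    if (is.null(h) || nrow(h$qtl) == 0L) {
      skipped[[tag]] <- "no shared variants"
      next
    }
    in_panel <- h$qtl$snp %in% panel$snp_info$snp
    hq <- h$qtl[in_panel, , drop = FALSE]
    hg <- h$gwas[in_panel, , drop = FALSE]
    probe_cis <- qtl_probe(probe$probe_id, probe$gene_symbol, probe$chrom,
                           probe$probe_pos, probe$omic, probe$tissue,
                           probe$ancestry, hq)
    inst <- select_instruments(probe_cis, config$cis_window_kb,
                               config$p_instrument)
    if (nrow(inst) == 0L) {
      skipped[[tag]] <- "no instrument"
      next
    }
    top <- inst$snp[1L]
    ti <- match(top, hq$snp)
    st <- smr_single(hg$b[ti], hg$se[ti], hq$b[ti], hq$se[ti])

    heidi_set <- hq$snp[abs(hq$pos - probe$probe_pos) <=
                          config$heidi_window_kb * 1000]
    hi <- hq$snp %in% heidi_set
    hres <- heidi(hg[hi, , drop = FALSE], hq[hi, , drop = FALSE], top,
                  panel, config)
    mres <- smr_multi(hg, hq, inst$snp, panel, config)

    rows[[tag]] <- data.frame(
      probe = probe$probe_id, gene = probe$gene_symbol, chrom = probe$chrom,
      probe_pos = probe$probe_pos, topSNP = top,
      A1 = hg$a1[ti], A2 = hg$a2[ti], freq = hg$freq[ti],
      b_GWAS = hg$b[ti], se_GWAS = hg$se[ti], p_GWAS = hg$p[ti],
      b_eQTL = hq$b[ti], se_eQTL = hq$se[ti], p_eQTL = hq$p[ti],
      b_SMR = st$beta_smr, se_SMR = st$se_smr, p_SMR = st$p_smr,
      p_SMR_multi = mres$p_smr_multi, p_HEIDI = hres$p_heidi,
      nsnp_HEIDI = hres$n_snps,
      disease = disease,
      omic_tissue = paste(probe$omic, probe$tissue, sep = ":"),
      ancestry = probe$ancestry,
      direction = ifelse(st$beta_smr >= 0, 1L, -1L),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else data.frame()
  if (nrow(out) > 0L) {
    out <- out[order(out$disease, out$omic_tissue, out$chrom, out$probe_pos), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- unlist(skipped)
  out
}
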