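# Run code with a private RNG state derived from `seed`, restoring the
# caller's stream afterwards, so generators are reproducible bit-for-bit
# without clobbering the session RNG.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulate an LD reference panel
#'
#' Haplotypes are drawn from a multivariate threshold model: a latent
#' standard-normal AR(1) process with lag-one correlation `ld_rho` is
#' dichotomized at each SNP's allele-frequency quantile, and two haplotypes
#' are summed into a diploid dosage. Realized adjacent-SNP dosage correlation
#' converges to a deterministic function of `ld_rho` as the panel grows.
#'
#' @param m_snps Number of SNPs (>= 1).
#' @param n_hap Number of haplotypes (>= 50; two per sample).
#' @param ld_rho Latent AR(1) correlation in (-1, 1).
#' @param maf_range Interval the per-SNP allele frequencies are drawn from.
#' @param seed Integer seed.
#' @param chrom Chromosome label for the variant metadata.
#' @param start_pos,spacing_bp Position of the first SNP and inter-SNP
#'   spacing (bp).
#' @return An [ld_panel()] whose `model` attribute carries the generative
#'   parameters, allowing cohort genotypes to be drawn from the same LD
#'   structure.
#' @export
simulate_ld_panel <- function(m_snps, n_hap, ld_rho, maf_range = c(0.1, 0.5),
                              seed = 1, chrom = "1", start_pos = 1e6,
                              spacing_bp = 10000) {
  stopifnot(m_snps >= 1, n_hap >= 50, abs(ld_rho) < 1)
  if (maf_range[1] >= maf_range[2] || maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("degenerate maf_range")
  }
  .with_seed(seed, {
    maf <- runif(m_snps, maf_range[1], maf_range[2])
    model <- list(m_snps = m_snps, ld_rho = ld_rho, maf = maf)
    geno <- .draw_genotypes(model, n_hap %/% 2L)
    info <- data.frame(
      snp = paste0("rs", seq_len(m_snps)),
      chrom = chrom,
      pos = as.integer(start_pos + (seq_len(m_snps) - 1L) * spacing_bp),
      a1 = "A", a2 = "G",
      freq = colMeans(geno) / 2,
      stringsAsFactors = FALSE
    )
    colnames(geno) <- info$snp
    panel <- ld_panel(geno, info)
    panel$model <- model
    panel
  })
}

# Diploid dosages under the latent AR(1) threshold model. Caller seeds.
.draw_genotypes <- function(model, n) {
  m <- model$m_snps
  rho <- model$ld_rho
  thr <- qnorm(model$maf)
  hap <- function() {
    z <- matrix(rnorm(2L * n * m), nrow = 2L * n)
    if (m > 1L && rho != 0) {
      for (j in 2:m) z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * z[, j]
    }
    sweep(z, 2, thr, `<`) + 0
  }
  h <- hap()
  h[seq_len(n), , drop = FALSE] + h[n + seq_len(n), , drop = FALSE]
}

#' Specify a simulation scenario
#'
#' Three generative regimes for one cis region: `pleiotropy` — one causal
#' SNP affects the exposure (`b_zx`) and, through it, the outcome (marginal
#' outcome effect `b_zx * b_xy`); `linkage` — SNP A affects the exposure
#' only, and a distinct SNP B in LD about `r_link` with A carries the same
#' outcome effect; `null` — the exposure effect is present but the outcome
#' is pure noise.
#'
#' @param kind `"pleiotropy"`, `"linkage"` or `"null"`.
#' @param m_snps Number of cis SNPs.
#' @param ld_rho Latent AR(1) LD parameter.
#' @param b_zx SNP-to-exposure effect at the causal SNP.
#' @param b_xy Exposure-to-outcome effect.
#' @param r_link Target LD between the two causal SNPs (linkage only).
#' @param n_gwas,n_qtl Cohort sizes.
#' @param seed Integer seed.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(kind = c("pleiotropy", "linkage", "null"),
                          m_snps = 30, ld_rho = 0.7, b_zx = 0.3, b_xy = 0.2,
                          r_link = 0.7, n_gwas = 5e4, n_qtl = 5e3, seed = 1) {
  kind <- match.arg(kind)
  structure(list(kind = kind, m_snps = m_snps, ld_rho = ld_rho, b_zx = b_zx,
                 b_xy = b_xy, r_link = r_link, n_gwas = n_gwas, n_qtl = n_qtl,
                 seed = seed),
            class = "scenario_spec")
}

# Causal SNP indices: exposure causal at the middle SNP; for linkage the
# outcome SNP is the distinct SNP whose realized panel LD with it is closest
# to the requested r_link.
.causal_indices <- function(spec, panel) {
  a <- (spec$m_snps + 1L) %/% 2L
  if (spec$kind != "linkage") return(list(a = a, b = a))
  r <- drop(cor(panel$genotypes[, a], panel$genotypes))
  r[a] <- NA
  b <- which.min(abs(r - spec$r_link))
  list(a = a, b = b, r_realized = r[b])
}

# Marginal per-SNP regressions of each phenotype column on each dosage.
# G: n x m dosages, Y: n x R phenotype replicates.
# Returns list of m x R matrices b, se (normal-approximation p implied).
.marginal_stats <- function(G, Y) {
  pre <- .center_genotypes(G)
  .marginal_stats_pre(pre, Y)
}

.center_genotypes <- function(G) {
  Gc <- sweep(G, 2, colMeans(G))
  ssx <- colSums(Gc^2)
  ssx[ssx == 0] <- NA_real_ # monomorphic in cohort
  list(Gc = Gc, ssx = ssx, n = nrow(G))
}

.marginal_stats_pre <- function(pre, Y) {
  Yc <- sweep(Y, 2, colMeans(Y))
  b <- crossprod(pre$Gc, Yc) / pre$ssx   # m x R
  ssy <- colSums(Yc^2)                   # R
  rss <- rep(ssy, each = nrow(b)) - b^2 * pre$ssx
  rss[rss < 0] <- 0
  se <- sqrt(rss / ((pre$n - 2) * pre$ssx))
  list(b = b, se = se)
}

#' Simulate summary statistics for one scenario replicate
#'
#' Individual-level cohorts are drawn from the panel's generative LD model,
#' phenotypes are built per the scenario, and each cohort is reduced to
#' per-SNP marginal summary statistics (beta, se, p, freq, n) — preserving
#' the LD-induced correlation structure the heterogeneity and multi-SNP
#' tests depend on.
#'
#' @param spec A [scenario_spec()].
#' @param panel An [ld_panel()] from [simulate_ld_panel()] (its `model` must
#'   cover `spec$m_snps` SNPs).
#' @return List with `gwas` (summary-record data frame) and `probe` (a
#'   [qtl_probe()] whose position is the exposure causal SNP).
#' @export
simulate_scenario <- function(spec, panel) {
  batch <- simulate_scenario_batch(spec, panel, n_rep = 1L)
  .batch_to_records(batch, panel, rep = 1L)
}

#' Simulate many phenotype replicates of one scenario
#'
#' Draws the GWAS and QTL cohort genotypes once and generates `n_rep`
#' independent phenotype replicates on them, returning per-SNP summary
#' statistics as m x n_rep matrices. Conditional on genotypes the replicates
#' are independent, which is what the calibration suites need, at a fraction
#' of the cost of re-drawing cohorts.
#'
#' @inheritParams simulate_scenario
#' @param n_rep Number of phenotype replicates.
#' @param block Replicates simulated per block (caps the size of the
#'   individual-level phenotype matrices held in memory at once).
#' @return List with matrices `gwas_b`, `gwas_se`, `qtl_b`, `qtl_se`
#'   (m x n_rep), vectors `gwas_freq`, `qtl_freq`, the causal indices and the
#'   spec.
#' @export
simulate_scenario_batch <- function(spec, panel, n_rep, block = 200L) {
  model <- panel$model
  if (is.null(model)) stop("panel carries no generative model")
  stopifnot(model$m_snps == spec$m_snps)
  ci <- .causal_indices(spec, panel)
  .with_seed(spec$seed, {
    G_q <- .draw_genotypes(model, spec$n_qtl)
    G_g <- .draw_genotypes(model, spec$n_gwas)
    pre_q <- .center_genotypes(G_q)
    pre_g <- .center_genotypes(G_g)
    g_exp_q <- G_q[, ci$a]
    sd_x <- sqrt(max(1 - spec$b_zx^2 * var(g_exp_q), 0.1))
    b_out <- spec$b_zx * spec$b_xy
    g_out <- switch(spec$kind,
                    pleiotropy = G_g[, ci$a],
                    linkage = G_g[, ci$b],
                    null = NULL)
    m <- model$m_snps
    out <- list(gwas_b = matrix(NA_real_, m, n_rep),
                gwas_se = matrix(NA_real_, m, n_rep),
                qtl_b = matrix(NA_real_, m, n_rep),
                qtl_se = matrix(NA_real_, m, n_rep))
    done <- 0L
    while (done < n_rep) {
      nb <- min(block, n_rep - done)
      X <- spec$b_zx * g_exp_q +
        matrix(rnorm(spec$n_qtl * nb, sd = sd_x), spec$n_qtl)
      Y <- matrix(rnorm(spec$n_gwas * nb), spec$n_gwas)
      if (!is.null(g_out) && b_out != 0) Y <- Y + b_out * g_out
      qs <- .marginal_stats_pre(pre_q, X)
      gs <- .marginal_stats_pre(pre_g, Y)
      cols <- done + seq_len(nb)
      out$qtl_b[, cols] <- qs$b; out$qtl_se[, cols] <- qs$se
      out$gwas_b[, cols] <- gs$b; out$gwas_se[, cols] <- gs$se
      done <- done + nb
    }
    c(out, list(gwas_freq = colMeans(G_g) / 2, qtl_freq = colMeans(G_q) / 2,
                causal = ci, spec = spec))
  })
}

# Materialize one replicate of a batch as harmonizable record frames.
.batch_to_records <- function(batch, panel, rep = 1L) {
  info <- panel$snp_info
  spec <- batch$spec
  two_sided <- function(b, se) pchisq((b / se)^2, df = 1, lower.tail = FALSE)
  gwas <- data.frame(
    snp = info$snp, a1 = info$a1, a2 = info$a2, freq = batch$gwas_freq,
    b = batch$gwas_b[, rep], se = batch$gwas_se[, rep],
    p = two_sided(batch$gwas_b[, rep], batch$gwas_se[, rep]),
    n = spec$n_gwas, stringsAsFactors = FALSE
  )
  recs <- data.frame(
    snp = info$snp, chrom = info$chrom, pos = info$pos,
    a1 = info$a1, a2 = info$a2, freq = batch$qtl_freq,
    b = batch$qtl_b[, rep], se = batch$qtl_se[, rep],
    p = two_sided(batch$qtl_b[, rep], batch$qtl_se[, rep]),
    n = spec$n_qtl, stringsAsFactors = FALSE
  )
  probe <- qtl_probe(
    probe_id = paste0("probe_", spec$kind), gene_symbol = "GENE1",
    chrom = info$chrom[1], probe_pos = info$pos[batch$causal$a],
    omic = "eQTL", tissue = "sim", ancestry = "EUR", records = recs
  )
  list(gwas = gwas, probe = probe)
}

#' Empirical SMR size/power and effect recovery over scenario replicates
#'
#' For each phenotype replicate, selects the top instrument by QTL p-value
#' (subject to the instrument threshold) and computes the single-SNP SMR
#' statistic at it.
#'
#' @inheritParams simulate_scenario_batch
#' @param p_instrument Instrument threshold; replicates whose best QTL p
#'   misses it are dropped (counted in `n_skipped`).
#' @return List with vectors `p_smr` and `beta_smr` over usable replicates
#'   and `n_skipped`.
#' @export
smr_scenario_stats <- function(spec, panel, n_rep,
                               p_instrument = 5e-8) {
  batch <- simulate_scenario_batch(spec, panel, n_rep)
  z2 <- (batch$qtl_b / batch$qtl_se)^2
  z2_thr <- qchisq(p_instrument, df = 1, lower.tail = FALSE)
  p_smr <- beta_smr <- rep(NA_real_, n_rep)
  for (r in seq_len(n_rep)) {
    top <- which.max(z2[, r])
    if (!is.finite(z2[top, r]) || z2[top, r] < z2_thr) next
    st <- smr_single(batch$gwas_b[top, r], batch$gwas_se[top, r],
                     batch$qtl_b[top, r], batch$qtl_se[top, r])
    p_smr[r] <- st$p_smr
    beta_smr[r] <- st$beta_smr
  }
  ok <- !is.na(p_smr)
  list(p_smr = p_smr[ok], beta_smr = beta_smr[ok], n_skipped = sum(!ok))
}

#' HEIDI rejection rate over scenario replicates
#'
#' Runs the full HEIDI test on each phenotype replicate of a scenario and
#' returns the fraction of (testable) replicates rejected at `alpha`.
#'
#' @inheritParams simulate_scenario_batch
#' @param alpha Rejection threshold on the HEIDI p.
#' @param config [smr_config()].
#' @return List with `reject_rate`, `n_tested`, `p_heidi` vector.
#' @export
heidi_scenario_rate <- function(spec, panel, n_rep, alpha = 0.01,
                                config = smr_config()) {
  batch <- simulate_scenario_batch(spec, panel, n_rep)
  info <- panel$snp_info
  p_out <- rep(NA_real_, n_rep)
  for (r in seq_len(n_rep)) {
    rec <- .batch_to_records(batch, panel, rep = r)
    h <- harmonize(rec$gwas, rec$probe$records, freq_tol = config$freq_tol)
    inst <- select_instruments(
      qtl_probe(rec$probe$probe_id, rec$probe$gene_symbol, rec$probe$chrom,
                rec$probe$probe_pos, rec$probe$omic, rec$probe$tissue,
                rec$probe$ancestry, h$qtl),
      config$cis_window_kb, config$p_instrument)
    if (nrow(inst) == 0L) next
    res <- heidi(h$gwas, h$qtl, inst$snp[1L], panel, config)
    p_out[r] <- res$p_heidi
  }
  tested <- !is.na(p_out)
  list(reject_rate = mean(p_out[tested] < alpha), n_tested = sum(tested),
       p_heidi = p_out)
}

#' Simulate a single-nucleus counts matrix
#'
#' Negative-binomial counts with gene-by-cell-type mean structure. Expected
#' counts scale with the gene's exon length so that the designed expression
#' level is recovered on the TPM scale, where percentile ranks are taken.
#'
#' @param structure Numeric matrix, genes x cell types, of relative
#'   expression levels (rownames genes, colnames types).
#' @param cells_per_type Named integer vector of cells per type (names must
#'   match `colnames(structure)`).
#' @param exon_length Optional named vector of exon lengths; drawn uniformly
#'   from 500-5,000 bp when omitted.
#' @param dispersion Negative-binomial size parameter (default 10).
#' @param seed Integer seed.
#' @return List with `counts` (gene x cell integer matrix), `exon_length`,
#'   `cell_type` (label per cell).
#' @export
simulate_counts <- function(structure, cells_per_type, exon_length = NULL,
                            dispersion = 10, seed = 1) {
  stopifnot(all(names(cells_per_type) %in% colnames(structure)),
            all(cells_per_type > 0), all(structure >= 0))
  .with_seed(seed, {
    genes <- rownames(structure)
    if (is.null(exon_length)) {
      exon_length <- setNames(round(runif(length(genes), 500, 5000)), genes)
    }
    cols <- list(); labels <- character(0)
    for (ct in names(cells_per_type)) {
      mu <- structure[, ct] * exon_length[genes] / 1000
      for (i in seq_len(cells_per_type[[ct]])) {
        cols[[length(cols) + 1L]] <-
          rnbinom(length(genes), mu = mu, size = dispersion)
        labels <- c(labels, ct)
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- genes
    colnames(counts) <- paste0("cell", seq_along(labels))
    list(counts = counts, exon_length = exon_length,
         cell_type = setNames(labels, colnames(counts)))
  })
}
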