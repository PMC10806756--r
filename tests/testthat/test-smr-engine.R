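test_that("single-SNP SMR handles the null numerator by continuity", {
  st <- smr_single(0, 0.1, 0.5, 0.05)
  expect_equal(st$t_smr, 0)
  expect_equal(st$p_smr, 1)
  expect_equal(st$beta_smr, 0)
  expect_equal(st$se_smr, 0.1 / 0.5)
})

test_that("single-SNP SMR statistic matches its chi-square form", {
  # z_g = 2, z_x = 4 -> t = 64/20
  st <- smr_single(b_g = 0.2, se_g = 0.1, b_x = 0.4, se_x = 0.1)
  expect_equal(st$t_smr, 64 / 20)
  expect_equal(st$p_smr, pchisq(3.2, 1, lower.tail = FALSE))
  expect_equal(st$beta_smr, 0.5)
  # equal z in both sources -> t = z^2 / 2
  for (z in c(0.5, 2, 7)) {
    st <- smr_single(z * 0.1, 0.1, z * 0.2, 0.2)
    expect_equal(st$t_smr, z^2 / 2)
  }
  expect_error(smr_single(0.1, 0.1, 0, 0.1), "undefined ratio")
})

test_that("SMR p-value is invariant to rescaling the outcome statistics", {
  set.seed(5)
  for (i in 1:20) {
    b_g <- rnorm(1); se_g <- runif(1, 0.01, 1)
    b_x <- rnorm(1); se_x <- runif(1, 0.01, 1)
    if (b_x == 0) next
    c <- runif(1, 0.1, 10)
    a <- smr_single(b_g, se_g, b_x, se_x)
    b <- smr_single(c * b_g, c * se_g, b_x, se_x)
    expect_equal(a$t_smr, b$t_smr)
    expect_equal(a$p_smr, b$p_smr)
  }
})

test_that("instrument selection filters by window and threshold, best p first", {
  recs <- toy_records(5, p = c(0.5, 1e-9, 1e-12, 0.2, 1e-6))
  probe <- toy_probe(recs, pos = recs$pos[1])
  out <- select_instruments(probe, window_kb = 2000, p_instrument = 5e-8)
  expect_equal(out$snp, c("rs3", "rs2"))
  # a SNP 600 kb away is excluded by a 500 kb window
  recs2 <- toy_records(2, spacing = 6e5, p = c(1e-9, 1e-9))
  probe2 <- toy_probe(recs2, pos = recs2$pos[1])
  expect_equal(select_instruments(probe2, window_kb = 500)$snp, "rs1")
  # nothing qualifies
  expect_equal(nrow(select_instruments(toy_probe(toy_records(3, p = rep(0.5, 3))))), 0L)
})

test_that("HEIDI is null when all ratio estimates coincide", {
  panel <- test_panel()
  info <- panel$snp_info
  m <- nrow(info)
  b_x <- seq(0.3, 0.5, length.out = m)
  qtl <- toy_records(m, b = b_x, se = rep(0.02, m), p = rep(1e-20, m))
  qtl$freq <- info$freq
  gwas <- qtl
  gwas$b <- 0.4 * b_x # identical b_xy everywhere
  gwas$se <- rep(0.02, m)
  res <- heidi(gwas, qtl, top_snp = "rs15", panel = panel)
  expect_equal(res$p_heidi, 1)
  expect_gte(res$n_snps, 4L)
})

test_that("HEIDI p is missing when only the top instrument is usable", {
  panel <- test_panel()
  recs <- toy_records(1)
  res <- heidi(recs, recs, top_snp = "rs1", panel = panel)
  expect_true(is.na(res$p_heidi))
  expect_equal(res$n_snps, 0L)
})

test_that("HEIDI consumes at most its configured top-SNP budget", {
  panel <- test_panel()
  spec <- scenario_spec("pleiotropy", b_zx = 0.5, seed = 31)
  sc <- simulate_scenario(spec, panel)
  h <- harmonize(sc$gwas, sc$probe$records)
  inst <- select_instruments(toy_probe(h$qtl, pos = sc$probe$probe_pos))
  res <- heidi(h$gwas, h$qtl, inst$snp[1], panel)
  expect_lte(res$n_snps, smr_config()$heidi_max_snps)
  expect_gte(res$n_snps, smr_config()$heidi_min_snps + 1L)
})

test_that("HEIDI keeps its size under the pleiotropy null", {
  panel <- test_panel()
  rate <- heidi_scenario_rate(scenario_spec("pleiotropy", seed = 13),
                              panel, n_rep = 100, alpha = 0.05)
  expect_gte(rate$n_tested, 90)
  # 99% binomial envelope around 0.05 at n ~ 100, upper side
  expect_lte(rate$reject_rate, 0.05 + 2.576 * sqrt(0.05 * 0.95 / rate$n_tested))
})

test_that("multi-SNP SMR reduces to the single-SNP test", {
  panel <- test_panel()
  m <- nrow(panel$snp_info)
  qtl <- toy_records(m, b = rep(0.4, m), se = rep(0.02, m))
  gwas <- toy_records(m, b = rep(0.05, m), se = rep(0.01, m))
  one <- smr_multi(gwas, qtl, instruments = "rs15", panel = panel)
  st <- smr_single(0.05, 0.01, 0.4, 0.02)
  expect_equal(one$p_smr_multi, st$p_smr)
  expect_equal(one$snps_used, "rs15")
  # two perfectly correlated instruments prune to one
  g2 <- cbind(panel$genotypes, rs_dup = panel$genotypes[, "rs15"])
  info2 <- rbind(panel$snp_info,
                 data.frame(snp = "rs_dup", chrom = "1",
                            pos = max(panel$snp_info$pos) + 1e4, a1 = "A",
                            a2 = "G", freq = panel$snp_info$freq[15]))
  panel2 <- ld_panel(g2, info2)
  qtl2 <- rbind(qtl, within(qtl[15, ], snp <- "rs_dup"))
  gwas2 <- rbind(gwas, within(gwas[15, ], snp <- "rs_dup"))
  two <- smr_multi(gwas2, qtl2, instruments = c("rs15", "rs_dup"),
                   panel = panel2)
  expect_equal(two$snps_used, "rs15")
  expect_equal(two$p_smr_multi, st$p_smr)
})

test_that("independent instruments combine to a 2-df chi-square tail", {
  panel <- simulate_ld_panel(2, n_hap = 60000, ld_rho = 0, seed = 3)
  qtl <- toy_records(2, b = c(0.4, 0.35), se = c(0.02, 0.02))
  gwas <- toy_records(2, b = c(0.03, 0.05), se = c(0.01, 0.01))
  res <- smr_multi(gwas, qtl, instruments = c("rs1", "rs2"), panel = panel)
  t1 <- smr_single(0.03, 0.01, 0.4, 0.02)$t_smr
  t2 <- smr_single(0.05, 0.01, 0.35, 0.02)$t_smr
  expect_equal(res$p_smr_multi,
               pchisq(t1 + t2, df = 2, lower.tail = FALSE),
               tolerance = 0.02)
})

test_that("run_smr keeps bookkeeping of skipped probes and is deterministic", {
  panel <- test_panel()
  specs <- lapply(1:7, function(i)
    scenario_spec("pleiotropy", seed = 100 + i))
  probes <- list(); gwas <- NULL
  for (i in seq_along(specs)) {
    sc <- simulate_scenario(specs[[i]], panel)
    p <- sc$probe; p$probe_id <- paste0("probe", i)
    probes[[i]] <- p
    if (is.null(gwas)) gwas <- sc$gwas
  }
  # three probes that cannot yield an instrument
  dead <- toy_records(3, p = rep(0.9, 3))
  for (j in 1:3) {
    probes[[7 + j]] <- qtl_probe(paste0("dead", j), "GENEX", "1", 1e6,
                                 "eQTL", "brain", records = dead)
  }
  res1 <- run_smr(gwas, probes, panel, disease = "AD")
  res2 <- run_smr(gwas, probes, panel, disease = "AD")
  expect_equal(nrow(res1), 7L)
  expect_length(attr(res1, "skipped"), 3L)
  expect_identical(res1, res2)
  expect_true(all(res1$direction %in% c(-1L, 1L)))
  expect_true(all(res1$p_SMR_multi > 0 & res1$p_SMR_multi <= 1))
})

test_that("SMR recovers the generating exposure effect under pleiotropy", {
  panel <- test_panel()
  rec <- smr_scenario_stats(scenario_spec("pleiotropy", b_xy = 0.2,
                                          seed = 17),
                            panel, n_rep = 100)
  expect_gt(length(rec$beta_smr), 90)
  se_med <- 1.2533 * sd(rec$beta_smr) / sqrt(length(rec$beta_smr))
  expect_lt(abs(median(rec$beta_smr) - 0.2), 4 * se_med)
  expect_gt(mean(sign(rec$beta_smr) == 1), 0.95)
})
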