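test_that("well-formed ma files parse with uppercased alleles", {
  f <- withr::local_tempfile(fileext = ".ma")
  writeLines(c("SNP\tA1\tA2\tfreq\tb\tse\tp\tn",
               "rs1\ta\tg\t0.3\t0.1\t0.02\t1e-6\t1000",
               "rs2\tC\tt\t0.5\t-0.2\t0.05\t0.004\t1000",
               "rs3\tG\tA\t0.1\t0\t0.1\t1\t1000"), f)
  x <- read_gwas_ma(f)
  expect_equal(nrow(x), 3L)
  expect_equal(x$a1, c("A", "C", "G"))
  expect_equal(x$a2, c("G", "T", "A"))
  expect_equal(x$b, c(0.1, -0.2, 0))
  expect_equal(nrow(attr(x, "rejected")), 0L)
})

test_that("invalid rows are rejected with a row-numbered report", {
  f <- withr::local_tempfile(fileext = ".ma")
  writeLines(c("SNP\tA1\tA2\tfreq\tb\tse\tp\tn",
               "rs1\tA\tG\t0.3\t0.1\t0\t1e-6\t1000",
               "rs2\tC\tT\t0.5\t-0.2\t0.05\t0.004\t1000",
               "rs3\tG\tA\t0.1\txx\t0.1\t0.5\t1000"), f)
  x <- read_gwas_ma(f)
  expect_equal(nrow(x), 1L)
  rej <- attr(x, "rejected")
  expect_setequal(rej$snp, c("rs1", "rs3"))
  expect_true("se not positive" %in% rej$reason)
})

test_that("missing columns and duplicate ids are hard errors", {
  f <- withr::local_tempfile(fileext = ".ma")
  writeLines(c("SNP\tA1\tA2\tfreq\tb\tse\tn", "rs1\tA\tG\t0.3\t0.1\t0.02\t1000"), f)
  expect_error(read_gwas_ma(f), "missing column.*p")
  writeLines(c("SNP\tA1\tA2\tfreq\tb\tse\tp\tn",
               "rs1\tA\tG\t0.3\t0.1\t0.02\t1e-6\t1000",
               "rs1\tA\tG\t0.3\t0.1\t0.02\t1e-6\t1000"), f)
  expect_error(read_gwas_ma(f), "duplicate.*rs1")
})

test_that("a written 1000-row file round-trips identically", {
  set.seed(11)
  n <- 1000
  x <- data.frame(
    snp = paste0("rs", seq_len(n)),
    a1 = sample(c("A", "C", "G", "T"), n, TRUE),
    a2 = "X", freq = runif(n), b = rnorm(n), se = runif(n, 0.01, 1),
    p = runif(n), n = sample(500:5000, n, TRUE),
    stringsAsFactors = FALSE
  )
  x$a2 <- ifelse(x$a1 == "A", "G", "A")
  f <- withr::local_tempfile(fileext = ".ma")
  write_gwas_ma(x, f)
  y <- read_gwas_ma(f)
  attr(y, "rejected") <- NULL
  x$n <- as.numeric(x$n)
  expect_identical(y, x)
})

test_that("z_to_beta_se satisfies its closed form and identities", {
  # zero score
  r <- z_to_beta_se(0, 0.3, 2119)
  expect_equal(r$beta, 0)
  expect_equal(r$se, 1 / sqrt(2 * 0.3 * 0.7 * 2119))
  # beta/se returns z to machine precision
  r <- z_to_beta_se(5, 0.5, 2119)
  expect_equal(r$beta / r$se, 5)
  # direct arithmetic oracle
  z <- 2.4; f <- 0.1; n <- 2119
  expected_se <- 1 / sqrt(2 * f * (1 - f) * (n + z^2))
  r <- z_to_beta_se(z, f, n)
  expect_equal(r$se, expected_se)
  expect_equal(r$beta, z * expected_se)
  expect_error(z_to_beta_se(1, 0, 100), "monomorphic")
})

test_that("z_to_beta_se standard error is monotone in n and heterozygosity", {
  z <- 1.7
  se_n <- vapply(c(100, 1000, 10000), function(n)
    z_to_beta_se(z, 0.2, n)$se, 0)
  expect_true(all(diff(se_n) < 0))
  se_f <- vapply(c(0.05, 0.2, 0.5), function(f)
    z_to_beta_se(z, f, 1000)$se, 0)
  expect_true(all(diff(se_f) < 0))
})

test_that("harmonization passes aligned alleles through and flips swaps", {
  g <- toy_records(3, b = c(0.1, 0.2, 0.3), freq = c(0.3, 0.4, 0.2))
  q <- g
  out <- harmonize(g, q)
  expect_equal(out$qtl$b, g$b)
  expect_equal(out$qtl$freq, g$freq)
  # swap alleles at SNP 2 (its freq is stated for the swapped effect allele)
  q2 <- q
  q2$a1[2] <- "G"; q2$a2[2] <- "A"
  q2$b[2] <- 0.3; q2$freq[2] <- 0.6
  out <- harmonize(g, q2)
  expect_equal(out$qtl$b[2], -0.3)
  expect_equal(out$qtl$freq[2], 0.4)
  expect_equal(out$qtl$a1[2], "A")
})

test_that("frequency-discordant and allele-mismatched variants are dropped", {
  g <- toy_records(3, freq = c(0.3, 0.3, 0.3))
  q <- g
  q$freq[1] <- 0.65 # |diff| = 0.35 > 0.2
  q$a2[2] <- "T"    # allele set differs, not a swap
  out <- harmonize(g, q, freq_tol = 0.2)
  expect_equal(out$qtl$snp, "rs3")
  expect_setequal(out$dropped$snp, c("rs1", "rs2"))
  expect_setequal(out$dropped$reason, c("freq discordant", "allele mismatch"))
  expect_error(harmonize(g[1, ], q[3, ]), "no shared variants")
})

test_that("harmonization is involutive under allele swap", {
  set.seed(21)
  g <- toy_records(10, b = rnorm(10), freq = runif(10, 0.1, 0.9))
  q <- toy_records(10, b = rnorm(10), freq = g$freq + rnorm(10, sd = 0.02))
  swapped <- q
  swapped$a1 <- q$a2; swapped$a2 <- q$a1
  swapped$b <- -q$b; swapped$freq <- 1 - q$freq
  out <- harmonize(g, swapped)
  expect_equal(out$qtl$b, q$b)
  expect_equal(out$qtl$freq, q$freq)
})

test_that("three-file QTL store round-trips, including missing effects", {
  recs1 <- toy_records(5, b = c(0.1, NA, 0.3, 0.4, 0.5))
  recs2 <- toy_records(3)
  p1 <- toy_probe(recs1)
  p2 <- qtl_probe("probe2", "GENE2", "1", 1.5e6, "mQTL", "blood",
                  records = recs2)
  prefix <- withr::local_tempfile()
  serialize_qtl(list(p1, p2), prefix)
  back <- load_qtl(prefix)
  expect_length(back, 2L)
  expect_equal(back[[1]]$records$b, recs1$b)
  expect_true(is.na(back[[1]]$records$b[2]))
  expect_equal(back[[2]]$omic, "mQTL")
  expect_equal(back[[2]]$records, recs2)
})

test_that("empty QTL datasets serialize to three valid empty stores", {
  prefix <- withr::local_tempfile()
  serialize_qtl(list(), prefix)
  for (suffix in c(".vars.tsv", ".probes.tsv", ".effects.tsv")) {
    expect_true(file.exists(paste0(prefix, suffix)))
  }
  expect_length(load_qtl(prefix), 0L)
})

test_that("serialization round-trip is lossless on random datasets", {
  for (seed in 1:5) {
    set.seed(seed)
    probes <- lapply(seq_len(3), function(i) {
      n <- sample(1:8, 1)
      recs <- toy_records(n, b = rnorm(n), se = runif(n, 0.01, 0.2),
                          p = runif(n), freq = runif(n, 0.05, 0.95))
      recs$snp <- paste0("pr", i, "_", recs$snp)
      qtl_probe(paste0("pr", i), paste0("G", i), "1", 1e6 + i * 1000,
                sample(c("eQTL", "mQTL", "pQTL", "caQTL"), 1), "tissue",
                records = recs)
    })
    prefix <- withr::local_tempfile()
    serialize_qtl(probes, prefix)
    back <- load_qtl(prefix)
    for (i in seq_along(probes)) {
      expect_equal(back[[i]]$records, probes[[i]]$records)
      expect_equal(back[[i]]$omic, probes[[i]]$omic)
    }
  }
})
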