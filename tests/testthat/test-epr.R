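test_that("TPM normalization conserves the per-cell total", {
  # single expressed gene takes the whole million
  counts <- matrix(c(5, 0), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
  tpm <- counts_to_tpm(counts, c(g1 = 1000, g2 = 1000))
  expect_equal(tpm["g1", 1], 1e6)
  # equal counts, 1 kb vs 2 kb lengths -> 2:1 TPM ratio
  counts <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "c1"))
  tpm <- counts_to_tpm(counts, c(a = 1000, b = 2000))
  expect_equal(tpm["a", 1] / tpm["b", 1], 2)
  # random matrix: every column sums to 1e6
  set.seed(3)
  m <- matrix(rpois(50 * 20, 5), 50, 20,
              dimnames = list(paste0("g", 1:50), paste0("c", 1:20)))
  m[1, ] <- m[1, ] + 1 # no all-zero cell
  lens <- setNames(runif(50, 500, 5000), rownames(m))
  tpm <- counts_to_tpm(m, lens)
  expect_equal(unname(colSums(tpm)), rep(1e6, 20), tolerance = 1e-9)
  # all-zero cells are named in the error
  m0 <- m; m0[, 3] <- 0
  expect_error(counts_to_tpm(m0, lens), "c3")
})

test_that("percentile ranks follow the maximal-tie ECDF convention", {
  col <- matrix(c(1, 2, 3, 4), 4, 1,
                dimnames = list(paste0("g", 1:4), "c1"))
  expect_equal(unname(epr_ranks(col)[, 1]), c(25, 50, 75, 100))
  ties <- matrix(rep(7, 5), 5, 1, dimnames = list(paste0("g", 1:5), "c1"))
  expect_equal(unname(epr_ranks(ties)[, 1]), rep(100, 5))
})

test_that("percentile ranks match a brute-force counting oracle", {
  set.seed(8)
  tpm <- matrix(sample(c(runif(80), rep(0.5, 20))), 25, 4,
                dimnames = list(paste0("g", 1:25), paste0("c", 1:4)))
  epr <- epr_ranks(tpm)
  for (j in 1:4) {
    for (i in 1:25) {
      expect_equal(epr[i, j], 100 * sum(tpm[, j] <= tpm[i, j]) / 25)
    }
  }
  expect_true(all(epr > 0 & epr <= 100))
})

test_that("EPR is invariant to per-cell monotone rescaling", {
  set.seed(12)
  tpm <- matrix(runif(60), 20, 3, dimnames = list(paste0("g", 1:20), NULL))
  expect_equal(epr_ranks(tpm), epr_ranks(tpm^3))
  expect_equal(epr_ranks(tpm), epr_ranks(sweep(tpm, 2, c(2, 5, 9), "*")))
})

test_that("binning is exhaustive, exclusive, and closed at the boundaries", {
  x <- c(0, 5, 9.999, 10, 50, 90, 90.001, 95, 100)
  b <- epr_bin(x)
  expect_equal(b, c("off", "off", "off", "low", "low", "low",
                    "high", "high", "high"))
  set.seed(4)
  r <- runif(500, 0, 100)
  expect_true(all(epr_bin(r) %in% c("off", "low", "high")))
})

test_that("per-type aggregation averages cells and bins from the mean", {
  epr <- matrix(c(20, 95, 80, 5, 20, 95), 1, 6,
                dimnames = list("g1", paste0("c", 1:6)))
  types <- c("t1", "t1", "t2", "t2", "t3", "t3")
  agg <- aggregate_epr(epr, types)
  expect_equal(agg$mean_epr, c(57.5, 42.5, 57.5))
  # one cell per type: mean = median = the cell's value
  agg1 <- aggregate_epr(matrix(c(95, 5), 1, 2, dimnames = list("g", NULL)),
                        c("a", "b"))
  expect_equal(agg1$bin, c("high", "off"))
  expect_equal(agg1$mean_epr, agg1$median_epr)
})

test_that("expression summary reproduces an engineered cohort design", {
  # 7 genes off everywhere, 2 genes high somewhere, 3 in between
  genes <- paste0("g", 1:12)
  types <- paste0("t", 1:4)
  rec <- expand.grid(gene = genes, cell_type = types,
                     stringsAsFactors = FALSE)
  rec$mean_epr <- 50
  rec$mean_epr[rec$gene %in% paste0("g", 1:7)] <- 5
  rec$mean_epr[rec$gene %in% c("g8", "g9") & rec$cell_type == "t2"] <- 95
  rec$median_epr <- rec$mean_epr
  rec$bin <- epr_bin(rec$mean_epr)
  sm <- expression_summary(rec, relevant_types = c("t1", "t2"))
  expect_equal(unname(sm$counts["n_all_off"]), 7L)
  expect_equal(unname(sm$counts["n_any_high"]), 2L)
  expect_equal(unname(sm$counts["n_all_low"]), 3L)
  # categories partition: all-off + any-high + all-low + mixed = genes
  pg <- sm$per_gene
  mixed <- !pg$all_off & !pg$all_low & !pg$any_high
  expect_equal(sum(pg$all_off) + sum(pg$all_low) + sum(pg$any_high) +
                 sum(mixed), length(genes))
  # per-cell-type tallies cover every gene
  expect_true(all(rowSums(sm$per_cell_type[, c("n_off", "n_low", "n_high")])
                  == length(genes)))
  expect_equal(sm$per_cell_type$n_high[sm$per_cell_type$cell_type == "t2"], 2L)
})

test_that("designed high-expression genes land in the high bin", {
  structure <- matrix(5, 40, 2, dimnames = list(paste0("g", 1:40),
                                                c("neuron", "glia")))
  structure["g1", "neuron"] <- 250 # 50x the background
  hits <- 0L
  for (seed in 1:20) {
    sim <- simulate_counts(structure, c(neuron = 15L, glia = 15L),
                           seed = seed)
    tpm <- counts_to_tpm(sim$counts, sim$exon_length)
    agg <- aggregate_epr(epr_ranks(tpm), unname(sim$cell_type))
    bin <- agg$bin[agg$gene == "g1" & agg$cell_type == "neuron"]
    if (bin == "high") hits <- hits + 1L
  }
  expect_gt(hits / 20, 0.9)
})

test_that("count simulation is deterministic and unbiased across types", {
  structure <- matrix(5, 10, 2, dimnames = list(paste0("g", 1:10),
                                                c("a", "b")))
  s1 <- simulate_counts(structure, c(a = 5L, b = 5L), seed = 7)
  s2 <- simulate_counts(structure, c(a = 5L, b = 5L), seed = 7)
  expect_identical(s1, s2)
  # all-equal means: no gene systematically tops the EPR ranking
  set.seed(1)
  wins <- integer(10)
  for (seed in 1:15) {
    s <- simulate_counts(structure, c(a = 8L, b = 8L), seed = seed)
    tpm <- counts_to_tpm(s$counts, s$exon_length)
    agg <- aggregate_epr(epr_ranks(tpm), unname(s$cell_type))
    wins[which.max(agg$mean_epr[agg$cell_type == "a"])] <-
      wins[which.max(agg$mean_epr[agg$cell_type == "a"])] + 1L
  }
  expect_lt(max(wins), 15L)
})

test_that("GTF exon lengths are unioned per gene", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    "chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id \"gA\";",
    "chr1\tsrc\texon\t150\t250\t.\t+\t.\tgene_id \"gA\";",
    "chr1\tsrc\texon\t400\t500\t.\t-\t.\tgene_id \"gA\";",
    "chr2\tsrc\texon\t10\t19\t.\t+\t.\tgene_id \"gB\";",
    "chr1\tsrc\tCDS\t100\t200\t.\t+\t.\tgene_id \"gA\";"
  ), gtf)
  lens <- exon_lengths_from_gtf(gtf)
  # gA: union [100,250] (151) + [400,500] (101) = 252; gB: 10
  expect_equal(unname(lens[["gA"]]), 252)
  expect_equal(unname(lens[["gB"]]), 10)
})

test_that("counts matrices round-trip through the MTX sidecar layout", {
  dir <- withr::local_tempdir()
  structure <- matrix(5, 6, 2, dimnames = list(paste0("g", 1:6), c("a", "b")))
  sim <- simulate_counts(structure, c(a = 3L, b = 2L), seed = 2)
  Matrix::writeMM(Matrix::Matrix(sim$counts, sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  write.table(data.frame(gene = rownames(sim$counts),
                         exon_length = sim$exon_length[rownames(sim$counts)]),
              file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(cell = colnames(sim$counts),
                         cell_type = unname(sim$cell_type)),
              file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- read_counts_mtx(file.path(dir, "counts.mtx"),
                          file.path(dir, "genes.tsv"),
                          file.path(dir, "cells.tsv"))
  expect_equal(as.matrix(back$counts),
               matrix(as.numeric(sim$counts), nrow(sim$counts),
                      dimnames = dimnames(sim$counts)))
  expect_equal(unname(back$cell_type), unname(sim$cell_type))
})
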