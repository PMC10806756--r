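# Shared toy builders. Everything is generated in code; no stored fixtures.

toy_records <- function(n, chrom = "1", start = 1e6, spacing = 1e4,
                        b = NULL, se = NULL, p = NULL, freq = NULL,
                        nsamp = 1000) {
  data.frame(
    snp = paste0("rs", seq_len(n)),
    chrom = chrom,
    pos = as.integer(start + (seq_len(n) - 1) * spacing),
    a1 = "A", a2 = "G",
    freq = if (is.null(freq)) rep(0.3, n) else freq,
    b = if (is.null(b)) rep(0.2, n) else b,
    se = if (is.null(se)) rep(0.05, n) else se,
    p = if (is.null(p)) rep(1e-10, n) else p,
    n = nsamp,
    stringsAsFactors = FALSE
  )
}

toy_probe <- function(records, pos = records$pos[1], gene = "GENE1",
                      omic = "eQTL", tissue = "brain") {
  qtl_probe("probe1", gene, records$chrom[1], pos, omic, tissue,
            records = records)
}

# a deterministic panel shared by engine tests
test_panel <- function(m = 30, rho = 0.7, seed = 42) {
  simulate_ld_panel(m, n_hap = 2000, ld_rho = rho, seed = seed)
}

random_smr_table <- function(n, seed) {
  set.seed(seed)
  data.frame(
    probe = paste0("p", seq_len(n)),
    gene = sample(c(paste0("G", 1:20), "UNKNOWN_GENE"), n, replace = TRUE),
    disease = sample(ndd_diseases(), n, replace = TRUE),
    omic_tissue = "eQTL:brain",
    b_SMR = rnorm(n),
    p_SMR_multi = 10^runif(n, -9, -0.1),
    p_HEIDI = ifelse(runif(n) < 0.1, NA, runif(n)),
    ancestry = "EUR",
    stringsAsFactors = FALSE
  )
}

random_annotation <- function(genes, seed) {
  set.seed(seed)
  gene_annotation(
    gene_symbol = genes,
    chrom = sample(c("1", "2", "6"), length(genes), replace = TRUE),
    start = s <- sample(1e6:2e8, length(genes)),
    end = s + 1e4,
    protein_coding = runif(length(genes)) < 0.8
  )
}
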