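.TABLE2 <- list(
  ARL17B   = list(diseases = c("AD", "PD")),
  KAT8     = list(diseases = c("AD", "PD")),
  LRRC37A2 = list(diseases = c("AD", "PD")),
  KANSL1   = list(diseases = c("AD", "PD", "PSP")),
  ARL17A   = list(diseases = c("AD", "PD", "PSP")),
  PRSS36   = list(diseases = c("AD", "PD")),
  MAPT     = list(diseases = c("AD", "PD", "PSP")),
  IDUA     = list(diseases = c("LBD", "PD")),
  TMEM175  = list(diseases = c("LBD", "PD")),
  ARHGAP27 = list(diseases = c("AD", "PD", "PSP")),
  CRHR1    = list(diseases = c("AD", "PD", "PSP")),
  FMNL1    = list(diseases = c("AD", "PSP")),
  PLEKHM1  = list(diseases = c("PD", "PSP")),
  WNT3     = list(diseases = c("AD", "PD")),
  SPPL2C   = list(diseases = c("AD", "PD"))
)

.TIER_NOVEL <- c(
  "ADAM10", "SNCA", "EGFR", "POU5F1", "STK39", "INPP5D", "CRHR1", "APH1B",
  "MINK1", "CLU", "CR1", "ACE", "CD38", "RABEP1", "ERCC2", "KAT8", "ITGAX",
  "GAK", "STX4", "EPHB4", "EPHA1", "GPNMB", "STAG3", "CHRNE", "NDUFS2",
  "FCER1G", "VKORC1", "DNTT", "CKM", "HSD3B7", "BST1", "STX1B", "PSMC3",
  "CDSN", "MICB", "MS4A2", "PSORS1C1", "EPHX2", "SLC44A4", "MAT1A", "FBXL19"
)

.TIER_KNOWN <- c("MAPT", "KCNN4", "ADORA2B")

.TIER_DIFFICULT <- c(
  "TRIM27", "PPP4C", "SPI1", "EFNA3", "KIF1C", "WNT3", "CD2AP", "CCNE2",
  "KCTD13", "C9orf72", "SRCAP", "CELF1", "HIP1R", "GRN", "APOC2", "ARHGAP27",
  "MEPCE", "LRRFIP2", "COPS6", "GIGYF1", "BCKDK", "POLR2E", "EFNA4", "DYDC1",
  "ATF6B", "LLGL1", "MTMR2", "GPC2", "LRRC37A", "ARL17B", "INO80E", "SNX31",
  "CEACAM19", "DGKQ", "NUP42", "LRRC37A2", "KANSL1", "ARL17A", "ANXA11",
  "TSPAN14", "CASTOR3", "ZNF232", "ZNF45", "TSBP1", "TREM2", "PRSS36",
  "IDUA", "CCDC158", "CCDC189", "ZSWIM7", "PLEKHM1", "STH", "PVRIG", "YPEL3",
  "MMRN1", "SPPL2C", "SCIMP", "PILRB", "PILRA", "LACTB", "FMNL1", "APOC4",
  "ZNF646", "CPSF3", "ZSCAN9", "ZKSCAN3", "TREML2", "EPDR1", "UFSP1",
  "FAM131B", "TAS2R60", "USP6NL", "MS4A4A", "CASS4", "G2E3", "SCFD1",
  "PCGF3", "SETD1A", "DCAKD", "ZNF668", "AGFG2", "TMEM175", "TOMM40",
  "TRIM40", "WDR81", "TMEM106B", "FNBP4", "SHROOM3", "CYP21A2", "REXO1",
  "TNXB", "MS4A3", "AIF1", "RAB8B", "ZFP57", "FAM200B", "BTNL2", "IGSF9B",
  "HS3ST1", "ZNF311", "NDUFAF6", "TMEM163", "APOC1", "C17orf107", "EXOC3L2",
  "DYDC2", "DOC2A", "ACMSD", "TRIM31", "PRDM7", "TRIM10", "ZAN", "MS4A6A",
  "CPLX1", "SFTA2"
)

#' Packaged worked-example fixtures
#'
#' Returns the bundle of small reference tables the worked examples and
#' self-consistency tests run on:
#'
#' * `table2`: the 15 genes significant in two or more diseases, one row per
#'   gene-disease pair.
#' * `tiers`: the published three-tier gene lists (41 novel / 3 known /
#'   115 difficult; 159 genes in total).
#' * `druggable`: druggability snapshot — the novel and known genes plus the
#'   druggable companion genes. The snapshot (and the indication and edge
#'   tables) is a synthetic reconstruction: it is built to be consistent with
#'   the published tier lists and named gene-drug-network relations, not a
#'   copy of any curation database.
#' * `indications`: drug-gene-disease rows with approval status; the known
#'   tier's NDD-approved drugs (apomorphine, carbidopa, istradefylline,
#'   riluzole) and companion-gene drugs including neflamapimod.
#' * `edges`: directed curated-style interaction rows covering the named
#'   companion relations (e.g. TRIM27-MAPK14, CD38-OXT, the gamma-secretase
#'   partners of APH1B).
#' * `ma_results`: multi-ancestry replication fixture — 11 passing
#'   associations over 9 genes, with the GPNMB effect sign opposite to its
#'   European-panel sign.
#'
#' Each call returns a fresh copy.
#'
#' @return Named list as described.
#' @export
make_fixture_bundle <- function() {
  table2 <- do.call(rbind, lapply(names(.TABLE2), function(g) {
    data.frame(gene = g, disease = .TABLE2[[g]]$diseases,
               stringsAsFactors = FALSE)
  }))
  rownames(table2) <- NULL

  companions_druggable <- c("MAPK14", "NCSTN", "PSEN1", "PSEN2", "PSENEN")
  druggable <- c(.TIER_NOVEL, .TIER_KNOWN, companions_druggable)

  indications <- rbind(
    data.frame(drug = "apomorphine", gene = "MAPT", disease = "PD",
               approval_status = "approved"),
    data.frame(drug = "carbidopa", gene = "MAPT", disease = "PD",
               approval_status = "approved"),
    data.frame(drug = "riluzole", gene = "KCNN4", disease = "ALS",
               approval_status = "approved"),
    data.frame(drug = "istradefylline", gene = "ADORA2B", disease = "PD",
               approval_status = "approved"),
    # novel-tier drugs: indications outside the NDD set only
    data.frame(drug = "glembatumumab vedotin", gene = "GPNMB",
               disease = "cancer", approval_status = "trial"),
    data.frame(drug = "erlotinib", gene = "EGFR", disease = "cancer",
               approval_status = "approved"),
    data.frame(drug = "lisinopril", gene = "ACE", disease = "hypertension",
               approval_status = "approved"),
    # trial-stage NDD evidence must not promote a gene to the known tier
    data.frame(drug = "riluzole", gene = "ADAM10", disease = "AD",
               approval_status = "trial"),
    # companion-gene therapeutics
    data.frame(drug = "neflamapimod", gene = "MAPK14", disease = "AD",
               approval_status = "approved"),
    data.frame(drug = "neflamapimod", gene = "MAPK14", disease = "LBD",
               approval_status = "approved"),
    data.frame(drug = "tarenflurbil", gene = "PSEN1", disease = "AD",
               approval_status = "approved"),
    data.frame(drug = "semagacestat", gene = "PSEN2", disease = "AD",
               approval_status = "approved"),
    data.frame(drug = "avagacestat", gene = "NCSTN", disease = "AD",
               approval_status = "approved"),
    data.frame(drug = "semagacestat", gene = "PSENEN", disease = "AD",
               approval_status = "approved")
  )

  edges <- rbind(
    data.frame(regulator = "TRIM27", target = "MAPK14",
               relation = "down-regulates", source = "curated"),
    data.frame(regulator = "OXT", target = "CD38",
               relation = "up-regulates", source = "curated"),
    data.frame(regulator = "MINK1", target = "MAPK14",
               relation = "up-regulates", source = "curated"),
    data.frame(regulator = "PSEN1", target = "APH1B",
               relation = "binds", source = "curated"),
    data.frame(regulator = "PSEN2", target = "APH1B",
               relation = "binds", source = "curated"),
    data.frame(regulator = "NCSTN", target = "APH1B",
               relation = "binds", source = "curated"),
    data.frame(regulator = "PSENEN", target = "APH1B",
               relation = "binds", source = "curated"),
    data.frame(regulator = "TOMM40", target = "APOC1",
               relation = "unknown", source = "curated")
  )

  ma_genes <- c("ARHGAP27", "ARL17A", "GPNMB", "KANSL1", "KANSL1",
                "LRRC37A2", "LRRC37A2", "PILRA", "PILRB", "PRSS36", "ZNF232")
  ma_results <- data.frame(
    gene = ma_genes,
    disease = "PD",
    omic_tissue = "eQTL:multi-ancestry whole-brain",
    b_SMR = ifelse(ma_genes == "GPNMB", -0.108, 0.15),
    p_SMR_multi = 1e-8,
    p_HEIDI = 0.5,
    ancestry = "multi",
    stringsAsFactors = FALSE
  )

  list(
    table2 = table2,
    tiers = list(novel = .TIER_NOVEL, known = .TIER_KNOWN,
                 difficult = .TIER_DIFFICULT),
    druggable = druggable,
    indications = indications,
    edges = edges,
    ma_results = ma_results
  )
}
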