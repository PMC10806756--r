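---
title: "Methods: summary-data MR for drug-target triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-data MR for drug-target triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrtriage)
```

## The problem

Drugs whose targets carry human genetic support succeed in trials at roughly
twice the background rate. For neurodegenerative diseases (AD, ALS, FTLD,
LBD, PD, PSP) the question is which genes, when their expression, methylation
or protein level is perturbed, change disease risk. `smrtriage` answers this
with summary-data-based Mendelian randomization (SMR): disease GWAS summary
statistics supply the outcome, molecular QTL summary statistics (cis-eQTL,
mQTL, pQTL, caQTL) supply the exposure, and genetic variants act as
instruments. Downstream stages turn the significant associations into a
triage of therapeutic targets: druggability tiers, companion-gene networks
with proxy drugs and a liver-eQTL toxicity screen, and single-nucleus
expression support.

## The statistics

### Single-SNP SMR

At an instrument SNP with GWAS effect $b_G \pm s_G$ and QTL effect
$b_X \pm s_X$, the ratio (Wald) estimate of the exposure effect on the
outcome is $\hat\beta_{SMR} = b_G / b_X$. Writing $z_G = b_G/s_G$ and
$z_X = b_X/s_X$, the test statistic is

$$ T_{SMR} \;=\; \frac{z_G^2\, z_X^2}{z_G^2 + z_X^2}, $$

referred to a 1-df chi-square. $T_{SMR}$ is invariant to rescaling either
source's effect-size units, and with a strong instrument
($z_X^2 \gg z_G^2$) approaches $z_G^2$, so under the null the p-value is
very slightly conservative at finite instrument strength. The standard error
comes from the delta method,
$s_{SMR}^2 = \hat\beta_{SMR}^2 (s_G^2/b_G^2 + s_X^2/b_X^2)$, with the exact
$b_G = 0$ case handled by continuity ($\hat\beta_{SMR}=0$, $p=1$,
$s_{SMR}=s_G/|b_X|$) rather than as an error.

### HEIDI: pleiotropy versus linkage

A significant SMR association can arise from a single variant affecting both
the molecular trait and disease (pleiotropy/causality — the interesting
case) or from two distinct causal variants in LD (linkage). Under a single
shared causal variant, the ratio $b_{xy}(i) = b_G(i)/b_X(i)$ is the same at
every cis SNP $i$ in LD with it; under linkage it varies. HEIDI tests this
homogeneity. For each non-top SNP, $d_i = b_{xy}(i) - b_{xy}(\text{top})$ is
standardized using a delta-method covariance that carries the LD correlation
$r(i,j)$ estimated from a reference genotype panel (GWAS and QTL cohorts are
independent, so cross-source covariances vanish):

$$ \mathrm{cov}(b_{xy,i}, b_{xy,j}) \approx
   \frac{r_{ij}\, s_{G,i}\, s_{G,j}}{b_{X,i}\, b_{X,j}}
 + \frac{b_{G,i}\, b_{G,j}\, r_{ij}\, s_{X,i}\, s_{X,j}}
        {b_{X,i}^2\, b_{X,j}^2}. $$

The statistic $T_{HEIDI} = \sum_i z_{d_i}^2$ follows, under homogeneity, a
weighted sum of 1-df chi-squares with weights the eigenvalues of the
correlation matrix of the $z_d$ vector. SNP screening mirrors the reference
implementation's defaults: at most the top 20 SNPs within 500 kb of the
probe, LD with the top instrument restricted to $r^2 \in [0.05, 0.9]$
(SNPs nearly collinear with the top carry no independent information; SNPs
nearly independent of it carry no information about the shared variant),
mutual pruning at $r^2 = 0.9$, and at least 3 non-top SNPs required for a
reported p. A small HEIDI p indicates linkage, so candidate filtering
*keeps* associations with $p_{HEIDI}$ above the floor (default 0.01).

### Multi-SNP SMR

To gain power from allelic heterogeneity, near-independent instruments
(greedy pruning at pairwise $r^2 < 0.9$, best QTL p kept) are combined as
$T_{multi} = \sum_i T_{SMR,i}$, referred to a weighted chi-square sum whose
weights are the eigenvalues of the retained SNPs' LD correlation matrix
(under the null the per-SNP z statistics are approximately jointly normal
with that correlation). With one retained instrument this reduces exactly to
the single-SNP test.

### Weighted chi-square tails

No installed package provides the tail of $\sum_k \lambda_k \chi^2_1$, so
`quadform_pvalue()` implements Imhof's inversion integral directly. The
integrand oscillates with asymptotic frequency $q/2$; generic adaptive
quadrature on $(0,\infty)$ fails to converge there, so the integral is
evaluated by composite Simpson with at least 40 points per period of the
fastest oscillation (phase derivative bound $(q + \sum\lambda_k)/2$) and
truncated where one further oscillation contributes less than $10^{-9}$
(consecutive half-periods nearly cancel, so the local envelope bounds the
remainder). A Satterthwaite-Welch moment-matched scaled chi-square is the
fallback for degenerate inputs. The dedicated oracle tests pin the analytic
tail against $10^5$-draw Monte-Carlo nulls to within 3 Monte-Carlo standard
errors; during development agreement with $2\times10^6$-draw nulls was
$\sim 10^{-4}$ absolute across 2-19 weights.

## Harmonization and I/O

GWAS files use the whitespace-separated `SNP A1 A2 freq b se p n` layout.
Harmonization aligns QTL records to the GWAS effect allele: clean swaps
negate the beta and complement the frequency; non-swap allele mismatches and
frequency discrepancies beyond 0.2 are dropped with reasons. Strand-ambiguous
(A/T, C/G) SNPs are retained but flagged — the LD panel, not strand
heuristics, disambiguates within this package. Z-score-only panels are
completed by $s = 1/\sqrt{2f(1-f)(n+z^2)}$, $b = z\,s$, which preserves
$b/s = z$ exactly. QTL datasets serialize to a documented three-file
plain-text store (variant index, probe index, effects) with `NA` as the
missing-effect sentinel — never zero, which is a legitimate estimate. The
binary dialect of the reference tool is out of scope.

## Filtering and multiple testing

Candidates must be annotated, protein-coding, outside the extended MHC
(default chr6:28,477,797-33,448,354, hg19; the region's extreme LD defeats
this style of inference), pass $p_{SMR,multi}$ below the Bonferroni
threshold, and pass the HEIDI floor. The threshold is computed as the exact
quotient $\alpha / n_{genes}$ (default $0.05/16{,}875 \approx 2.96\times
10^{-6}$). Exclusion rules run in a fixed order
(annotation, coding, MHC, SMR-multi, HEIDI) with first-match-counts
semantics, so the exclusion tally always partitions the input; a missing
HEIDI p (too few SNPs) fails the filter but is tallied separately. For a
disease with no genome-wide hit, `relaxed_pleiotropy_lookup()` re-screens
its results at a relaxed threshold (default 0.05) restricted to genes
already nominated elsewhere.

## Tiers, networks, expression support

`classify_tiers()` partitions nominated genes: **known** = druggable with a
drug approved for one of the six diseases; **novel** = druggable without one
(repurposing candidates); **difficult** = not annotated druggable. Only an
approved NDD indication promotes to known; trial-stage evidence does not.
Gene identity is by symbol after an optional alias table. The packaged
`make_fixture_bundle()` carries the published tier lists and overlap table
verbatim; its druggability, indication and interaction snapshots are a
synthetic reconstruction built to be exactly consistent with those lists and
the named relations, and are labeled as such — they are not a database
export.

Companion analysis takes the directed one-hop neighborhood of a seed gene in
a curated interaction snapshot (no transitive closure; depth beyond 1 adds
partners the curation does not vouch for as direct), annotates companions
with the same druggability rules, and flags any seed or companion with a
significant liver-eQTL association as a toxicity consideration — the liver
being the organ of drug metabolism, a liver expression effect on a target
is an early warning, not a verdict.

Expression support uses single-nucleus counts: per-cell TPM (counts over
union exon length, scaled to sum to $10^6$), per-cell expression percentile
rank EPR $= 100\cdot$ECDF with maximal-tie ranks (values in $(0,100]$),
mean/median per gene and cell type, and bins off ($<10$), low, high
($>90$). Boundary values land in "low": the published notation leaves both
endpoints open, and assigning them to the middle bin is the conservative
choice for both the "all off" and the "any high" summaries. The
disease-relevant recount defaults to the 17 enriched cell types shipped in
`relevant_cell_types()`.

## The synthetic-data generator

Real GWAS/QTL downloads are out of scope, so calibration runs on simulated
data whose defaults are the package's study conditions: 30 cis SNPs at 10 kb
spacing, latent AR(1) LD $\rho = 0.7$, MAF uniform on $[0.1, 0.5]$,
SNP-exposure effect $b_{zx} = 0.3$, exposure-outcome effect $b_{xy} = 0.2$,
$n_{GWAS} = 5\times10^4$, $n_{QTL} = 5\times10^3$, panel of 1,000 diploid
samples. Haplotypes come from a dichotomized latent AR(1) Gaussian;
dichotomization attenuates dosage LD relative to the latent $\rho$
(adjacent-SNP $r \approx 0.45$ at $\rho = 0.7$), so the linkage scenario
selects the outcome variant by realized panel LD closest to the requested
`r_link`. Phenotypes are simulated at the individual level and reduced to
marginal per-SNP regressions — sampling betas directly would destroy the
LD-induced correlation structure that HEIDI and multi-SNP SMR depend on.
For replicate suites the cohort genotypes are drawn once and phenotypes
re-drawn per replicate; conditional on genotypes the replicates are
independent, which is exactly what size/power estimation needs. All
generators restore the caller's RNG state and are bit-reproducible under a
seed.

What the generator does *not* emulate: realistic recombination maps and
coalescent haplotype structure, imputation noise, sample overlap between
GWAS and QTL cohorts, case-control ascertainment, and population
stratification. Passing calibration here shows the statistics are computed
correctly under their stated model, not that real-data associations are
immune to those artifacts.

## Problem sizes and numerical choices

The shipped suites use: 2,000 phenotype replicates for null calibration
(99% binomial envelope at $\alpha \in \{0.05, 0.01\}$), 500 replicates for
effect recovery (median $\hat\beta_{SMR}$ within Monte-Carlo error of 0.2),
80 replicates per arm for the linkage/pleiotropy HEIDI comparison, and
$10^5$ draws for quadratic-form oracle checks. Near-singular HEIDI
correlation matrices are handled by dropping the non-top SNP in highest
aggregate LD and retrying; eigenvalues below $10^{-8}$ of the maximum are
dropped before tail evaluation. Monomorphic cohort columns yield missing
marginal statistics and are never selected as instruments.

## Known limitations

Trans-QTLs, conditional/COJO analysis, sample-overlap correction and
colocalization posteriors are out of scope. The multi-SNP test treats the
per-SNP z correlation as the SNP LD matrix, which is exact in the
strong-instrument limit. Tier assignments inherit whatever staleness the
druggability/indication snapshots carry; the packaged bundle is a worked
example, not a current curation.
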