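---
title: "Methods: rare-variant collapsing and biallelic case meta-analysis for cardiomyopathy genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant collapsing and biallelic case meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmspectrum)
```

# Scientific setting

Cardiomyopathy genes discovered through recessive (biallelic) inheritance
increasingly show monoallelic effects as well: heterozygous carriers of
protein-truncating variants (PTVs) in genes like *ALPK3* or *LMOD2* can
develop adult-onset disease, while biallelic genotypes cause severe
pediatric phenotypes. `cmspectrum` implements the two computational arms
needed to study this dominance–recessiveness spectrum:

1. an **association arm** — mask-based rare-variant collapsing tests of
   heterozygous (dominant-model) carrier burdens against disease
   endpoints and quantitative cardiac traits in a biobank-scale cohort,
   with saddlepoint-approximated score tests, Firth-penalized effect
   re-estimation, Cauchy omnibus aggregation across masks, and FDR
   control; and
2. a **case arm** — survival and onset meta-analysis of curated
   biallelic patient series: Kaplan–Meier freedom-from-event curves, Cox
   proportional-hazards contrasts between causal genes, onset z- and
   Wilcoxon tests, outcome tallies, compound-heterozygote zygosity
   logic, ClinGen-style estimated LOD scores, and per-population
   heterozygous-LOF carrier prevalence.

The real inputs of such studies (UK Biobank exomes, gnomAD frequency
tables, curated supplementary case tables) are access-restricted, so the
package ships a first-class synthetic-data module that generates every
input with known ground truth. All empirical statements below are the
ones the test suite and `scripts/acceptance.R` themselves compute.

# Variant classification

Variants enter as an annotation table (one row per variant on the
canonical transcript; duplicates are an error).

* **Consequence class.** Truncating classes (nonsense/stop-gained,
  frameshift, essential splice acceptor/donor) with a high-confidence
  loss-of-function call and no predicted escape from nonsense-mediated
  decay are `PTV`. LOF calls flagged as dubious are demoted to `other`
  and never qualify for any mask; non-canonical splice-region variants
  are `other` as well. `missense` passes through.
* **Missense deleteriousness score.** The fraction of in-silico tools
  calling the variant damaging: `n_damaging / n_predicting` in [0, 1],
  e.g. 14 of 28 tools gives 0.5. Variants with fewer than 7 predictions
  (configurable) get a missing score and are excluded from missense
  masks. The tool roster is not hard-coded: any named set of binary
  predictions is accepted (31 by default, recorded in the output
  metadata), so the score is reproducible without pinning an external
  tool list.
* **POPMAX.** The maximum allele frequency across the five continental
  reference populations (AFR, AMR, EAS, NFE, SAS); missing populations
  count as 0. Bottleneck populations (ASJ, FIN) are reported separately
  but excluded from the maximum, following the usual popmax convention.
  Whether frequencies come from an exomes-only or a combined reference
  is up to the supplied table; the default expectation is a single
  exomes-style table.

# The mask grid

A *mask* is a rule deciding which rare variants of a gene are collapsed
into one carrier burden. The default grid crosses

* two strict POPMAX frequency filters — MAF < 0.1% and MAF < 0.001% —
  with
* eleven consequence filters: PTV-only, plus PTV together with missense
  variants at deleteriousness score ≥ s for s = 1.0, 0.9, …, 0.1,

giving 22 masks. The exact composition of the eleven consequence filters
in the source analyses is not fully published; this ladder is an
explicit, documented reconstruction preserving the 2 × 11 structure, and
both axes are overridable in `build_mask_grid()` (including
missense-only filters, should a user want them; the default includes
PTVs in every filter). Frequency filtering uses the annotation-table
POPMAX, not the in-cohort frequency, and the inequalities are strict.

Collapsing is dominant-model: a sample is a carrier when it holds at
least one qualifying alternate allele; the cumulative minor allele count
(CMAC) is the total of qualifying alternate alleles. Missing dosages are
treated as reference for carrier status — conservative with respect to
burden inflation — and tallied per mask. Masks are nested by
construction: relaxing a threshold can only grow the qualifying and
carrier sets, which the property tests exercise.

# The association model

## Null model and covariates

For each trait a covariate-only null model is fitted: age, age², sex,
sequencing tranche, ancestry PCs 1–4 always, and each of PCs 5–20 when
its marginal single-covariate association with the trait has P < 0.05.
Missing covariate handling is complete-case per trait, with counts
recorded. Binary traits use logistic regression; quantitative traits use
ordinary least squares. If the null fit separates, a ridge-stabilized
IRLS fallback (λ = 10⁻⁴) is used with a warning.

An optional sparse kinship matrix adds a single variance component:
penalized quasi-likelihood for binary traits, REML for quantitative
ones, with dense solves sized for cohorts up to a few thousand samples —
appropriate for the synthetic test regime; the no-kinship path is the
default and scales to biobank n. A kinship input with no off-diagonal
entries carries no relatedness information separable from the residual,
so the component is fixed at zero and the fit reduces exactly to the
plain regression (verified to 10⁻⁸ on p-values in tests).

## Score test and saddlepoint approximation

The carrier vector g is residualized on the fixed-effect design under
the null working weights, giving g̃; the efficient score is
S = Σᵢ g̃ᵢ (yᵢ − μᵢ) with model-based variance Var(S) = g̃'Wg̃ (or the
mixed-model projection when a kinship component is present). The normal
p-value is the two-sided tail of S/√Var(S). All-carrier or no-carrier
vectors are degenerate and return p = 1 with a flag.

Under extreme case–control imbalance the normal tail is
anti-conservative. The saddlepoint approximation replaces it with the
Barndorff-Nielsen tail of the exact conditional null distribution of
S = Σ g̃ᵢ Bᵢ, Bᵢ ~ Bernoulli(μᵢ): the cumulant generating function is
solved for the saddlepoint by safeguarded bracketing/uniroot (tolerance
10⁻⁸), and both tails are summed for a two-sided p. When |S/√Var(S)| is
below a switch threshold (default 2) — where the normal tail is
accurate — or the root-finder fails, the normal p is returned and
flagged. Within the saddlepoint branch the p-value is a continuous
function of the score.

The acceptance suite verifies the motivating property at study scale:
with 1:300 case:control imbalance, n = 50,000 and CMAC ≈ 20 null
carriers over 2,000 replicates, the saddlepoint p-values are calibrated
at α = 10⁻⁴ (inside the binomial 95% CI) while the normal p-values
reject two orders of magnitude too often.

## CMAC filter, effects, Firth re-estimation

Masks with CMAC < 20 are flagged and excluded downstream (they are
dropped from, not imputed into, the omnibus). Effects are one-step
score estimates (S/Var(S)); for linear models this equals the exact
covariate-adjusted coefficient. Because score-model effect sizes are
unreliable for rare outcomes and rare carriers, any unfiltered binary
association with nominal p < 0.05 and OR > 1 is re-estimated by Firth's
bias-reduced logistic regression on the full covariate design: Newton
iterations on the Jeffreys-penalized likelihood with step-halving (the
penalized likelihood increases monotonically by construction), Wald 95%
CIs from the penalized information. Firth estimates are finite even
under complete separation; the tests check the 2×2-table estimate
against a grid-search maximizer of the penalized likelihood and
unbiasedness at zero effect.

# Omnibus aggregation and FDR

Per gene–trait pair, the unfiltered masks' nominal p-values (saddlepoint
for binary traits) are combined with the Cauchy (ACAT) test:
T = (1/k) Σ tan{(0.5 − pᵢ)π}, p = P(Cauchy > T), with the substitution
tan{(0.5 − p)π} ≈ 1/(pπ) below 10⁻¹⁵ and clipping of p ≥ 1 to 1 − 10⁻¹⁵.
Masks are equally weighted (a weight vector is exposed). Each pair is
summarized by its best mask — lowest nominal p, ties broken by larger
CMAC then lexicographic mask id — and Benjamini–Hochberg q-values are
computed within separate trait families (disease endpoints vs
quantitative traits).

A point worth stating precisely: the Cauchy combination of *dependent*
tests is valid in the rejection tail — its type-I error at conventional
and small α is controlled, which the tests verify empirically at
α = 0.05 and 0.01 over 22 correlated nested masks — but its null
distribution is **not** uniform in the bulk. An independent
equicorrelated-normal oracle shows the same bulk shift at any
intermediate correlation, so a full-distribution uniformity test (e.g.
Kolmogorov–Smirnov over a thousand null replicates) rejects for any
faithful implementation once masks are nested. The corresponding
full-uniformity assertion in the acceptance suite documents this: it
fails by design of the method, while the tail-calibration assertions in
the same block pass.

# The case arm

**Survival.** Time zero is birth; the endpoint is freedom from death,
heart transplant, or LVAD implantation; cases alive at last report are
censored at that age. Cases with unknown outcome or missing outcome age
are excluded and counted (alive cases without a stated age are dropped
rather than censored at onset). Fetal termination appears in the outcome
vocabulary but not in the endpoint list, so it is excluded by default
with a flag to count it as an event at age 0. The Kaplan–Meier estimate
is the product-limit estimator (via `survival::survfit`, cross-checked
in tests against a brute-force risk-set oracle); gene contrasts use a
Cox model with the causal gene as the only covariate, Efron ties,
baseline *NRAP*, restricted to genes with at least nine (i.e. more than
eight) outcome-complete cases. A gene with no events produces a flagged
infinite-HR sentinel rather than an error.

**Onset.** Comparisons against registry summaries use a two-sample
z-test on published mean ± SD and n (two-tailed normal tail); with the
published one-decimal summaries for the DCM-gene vs HCM-gene contrast
this reproduces the published P ≈ 5 × 10⁻¹¹ within the rounding those
inputs allow. Sample-level comparisons use the Wilcoxon rank-sum test
with midranks; exact enumeration of all rank assignments when
n₁ + n₂ ≤ 12 (the exact branch handles ties, unlike the stock exact
path), otherwise the continuity-corrected normal approximation.

**Zygosity.** One variant at dosage 2 is homozygous. Two variants are
compound-heterozygous only with explicit trans evidence — each parent
heterozygous for exactly one, or direct phase showing trans; otherwise
double-heterozygous. Contradictory parental genotypes (one parent
carrying both variants) can never produce a compound-het call.

**Estimated LOD.** For pedigrees reported without a LOD score, an
estimate in the spirit of gene-curation practice is computed when the
eligibility gates hold (≥ 3 affected biallelic cases, genotypes known,
recessive inheritance demonstrated through a heterozygous parent);
otherwise a refusal with reason is returned, never a zero. The default
arithmetic — log₁₀(4) per affected individual beyond the proband(s),
log₁₀(4/3) per informative unaffected relative — is a documented,
overridable default: the exact arithmetic behind published estimated
LODs cannot be reverse-engineered without the source pedigrees, and no
claim is made that this reproduces it.

# Population-frequency arm

Per population, the probability that an individual carries at least one
qualifying LOF allele (high-confidence PTVs excluding NMD-escape, plus
configured recurrent missense LOF-equivalents) under Hardy–Weinberg
equilibrium and independence across variants is
1 − Πᵢ (1 − qᵢ)², reported as a percentage; a count-based mode
(Σ het + hom individuals / N) is provided for datasets that publish
genotype counts, and the mode used is recorded. Frequencies above 0.5
trigger a minor-allele warning. For small Σq the closed form linearizes
to 2Σqᵢ (checked within 1% relative below Σq = 0.005).

The biallelic-PTV screen classifies samples per gene: dosage-2
high-confidence PTV → homozygous; two heterozygous PTVs predicted in
trans → compound-het (trans); without phase, or explicitly unphased →
compound-het (unphased); pairs phased in cis are monoallelic and yield
no call.

# Synthetic data: what it emulates and what it does not

`simulate_cohort()` draws two haplotypes per sample (so cis/trans phase
truth exists for the biallelic screen), giving Binomial(2, q) dosages
under HWE; covariates emulate a middle-aged volunteer biobank (age
uniform on 40–69 years, balanced sex, standard-normal PCs); binary
phenotypes follow a logistic model with a planted carrier log-odds and a
baseline prevalence, quantitative traits a linear model with unit
residual SD. Optional sibling blocks share parental haplotypes and emit
kinship triples (coefficient 0.25). `simulate_case_series()` draws
log-normal onset ages and exponential event ages per gene with uniform
censoring; `simulate_trios()` produces Mendelian segregation from
heterozygous parents in homozygous and compound-het designs. All
generators are pure functions of (spec, seed).

Deliberately not emulated: linkage disequilibrium, sequencing error,
population structure beyond sibships, informative censoring, and
between-study heterogeneity of curated case reports. Passing tests
therefore demonstrate the statistical machinery is correct under the
stated generative model, not that real-data artifacts are handled.

# Numerical choices and problem sizes

* Saddlepoint switch |z| > 2; root-finding tolerance 10⁻⁸; fallbacks
  flagged. Cauchy small-p substitution below 10⁻¹⁵.
* Firth: Newton with step-halving, score tolerance 10⁻⁸, maximum 100
  iterations (error with diagnostics beyond that).
* Ties in the best-mask summary: larger CMAC, then lexicographic id.
* The calibration suites run at n = 50,000 (2,000 null replicates,
  imbalance 1:300) for the saddlepoint check, 1,000 simulated gene–trait
  pairs at n = 2,000 for the omnibus tail check, and 100 replicates at
  n = 200,000 for end-to-end recovery of a planted OR of 14.3 at carrier
  frequency 2 × 10⁻⁴ and prevalence 0.003 — sizes chosen to make the
  Monte-Carlo error small relative to each assertion while keeping a
  routine run of the full suite inside tens of minutes on one core.

# Known limitations

* The mixed-model (kinship) path uses dense linear algebra and is meant
  for method validation at modest n, not biobank-scale related cohorts.
* Effect sizes for unrefit masks are one-step score estimates; only
  triggered associations get the Firth treatment, mirroring the
  two-stage design it implements.
* The estimated-LOD arithmetic is a documented default, not a
  reproduction of any particular published pedigree computation.
* The minimal VCF reader is GT-only and biallelic by design; multi-
  allelic records must be pre-split.
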