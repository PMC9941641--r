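---
title: "Proteome-wide MR and colocalization: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteome-wide MR and colocalization: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protmr)
```

# The model

`protmr` screens circulating proteins for causal effects on a binary
disease outcome using two-sample MR on GWAS summary statistics. For each
protein, genetic instruments (pQTLs) are SNPs associated with the
protein's plasma level; under the instrumental-variable assumptions
(relevance, no confounding, no horizontal pleiotropy) the ratio of a
SNP's outcome effect to its protein effect estimates the causal log-OR
per SD of protein. Because each assumption fails in predictable ways at
proteome scale, the workflow layers instrument hygiene, estimator
cross-checks, independent replication, and a colocalization screen for
LD confounding on top of the basic estimator.

## Instrument selection and the four groups

Instruments must be genome-wide significant (p < 5×10⁻⁸) and strong
(F = (β/se)² ≥ 10, the conventional weak-instrument bound). SNPs in the
MHC (chr6:27,477,797–34,448,354, GRCh37) are removed for its extreme LD
and pervasive immune pleiotropy; SNPs associated with more than five
proteins are removed as pleiotropy hubs; predicted
protein-coding-altering variants (missense, stop/start changes,
frameshifts, in-frame indels) are removed because they can perturb the
affinity-reagent measurement of the protein rather than its abundance;
palindromic (A/T, C/G) SNPs are always dropped at harmonization rather
than frequency-aligned, because the source GWAS frequencies are not
always available or reliable.

Cis status is assigned within ±1 Mb of the encoding gene's transcription
start site — the field-standard window, consistent with the 2 Mb
colocalization window used later. Four instrument groups trade bias
against power:

* **A** — the sentinel (lowest-p) cis-pQTL per ±1 Mb region. No clumping
  is applied: a sentinel is by construction the top SNP of its region.
* **B** — sentinels plus conditionally independent cis-pQTLs found by
  stepwise summary-statistic conditional analysis, then clumped at
  r² < 0.1.
* **C** — trans-pQTLs only, clumped.
* **D** — all pQTLs, clumped.

The conditional analysis works on the standardized scale (b = z/√n,
se = 1/√n): for a candidate set S the joint effects are R_S⁻¹ b_S with
sampling covariance R_S⁻¹/n, and a SNP joins S when its conditional p is
the smallest and below 5×10⁻⁸. Candidates with r² > 0.9 against S are
skipped as collinear; these two thresholds follow the established
summary-statistic conditional-analysis defaults.

Two greedy conventions are worth stating. Clumping prunes at r² ≥
threshold (the retained set is therefore strictly below threshold), and
ties in p are broken by larger F then lexicographic SNP id, so results
are order-independent. Group D is clumped with the already-selected A, B
and C members given priority in the greedy order; this keeps the groups
nested (A ⊆ B ⊆ D, C ⊆ D) — with an unseeded greedy pass, a
marginally-lower-p but conditionally redundant SNP could evict a group-B
member from D, which would make the "total pQTL" analysis inconsistent
with the cis analysis it is meant to extend.

## Estimators

With harmonized per-SNP pairs (βx, se_x, βy, se_y):

* Wald ratio (single instrument): βy/βx, se = se_y/|βx| (first-order
  delta method).
* IVW: β̂ = Σβxβy/se_y² / Σβx²/se_y². The fixed-effect se is
  (Σβx²/se_y²)^(−1/2); under heterogeneity (Cochran's Q p < 0.05 in
  `auto` mode) the multiplicative random-effects se inflates it by
  max(1, √(Q/(L−1))). The multiplicative se can never fall below the
  fixed one.
* MR-Egger: weighted least squares of βy on βx with intercept, weights
  1/se_y², exposure effects oriented positive first. The intercept is the
  directional-pleiotropy diagnostic. Standard errors follow the usual
  Egger convention of flooring the residual sd at 1 (no underdispersion
  credit), with t(L−2) p-values.
* Weighted median: per-SNP ratios ordered, inverse-variance weights
  normalized, estimate interpolated at cumulative weight 0.5; the se
  comes from a parametric bootstrap (default 1000 draws, seeded, recorded
  in the call).
* MR-PRESSO: the observed statistic is the weighted residual sum of
  squares Σ(βy_i − β̂₍₋ᵢ₎βx_i)²/se_y,i² with leave-one-out IVW
  predictions; its null distribution is rebuilt by redrawing both βx and
  βy from their sampling normals and recomputing the statistic, giving
  global p = (1 + #{RSS* ≥ RSS})/(n_sim + 1). Per-SNP outlier p-values
  are Bonferroni-corrected, so flagging requires n_sim comfortably above
  20·L; flagged SNPs are removed before the final MR fit. The distortion
  test is omitted: the test's role here is identify-and-remove.
* Steiger directionality: per-trait variance explained approximated as
  z²/(z²+n), summed over instruments; the direction is supported when
  r²_exposure > r²_outcome, with a Fisher-z comparison p-value.

Statistical power for a binary outcome uses the non-centrality
approximation: the causal OR is converted to an approximate risk-scale
effect b = K(OR/(1+K(OR−1)) − 1) with K the case fraction, v =
(K(1−K) − b²)/N, NCP = b²·r²/v, and power = P(χ²₁(NCP) > χ²₁,1−α). This
reproduces the printed power values of reference instrument
configurations exactly (e.g. 0.99 at r² = 0.096, OR = 0.814,
N = 24,510), where the simpler Φ(|ln OR|√(N r² K(1−K)) − z) form rounds
one of them to 1.00. At OR = 1 the two-sided form returns α, not α/2.

## Discovery, FDR and replication

BH-FDR is computed within each instrument group, over the proteins
actually testable in that group — groups differ in protein coverage, and
pooling across groups would let the well-powered cis groups pay the
multiplicity bill of the trans group. A protein is reported when its
discovery FDR < 0.05 **and** it achieves nominal p < 0.05 with a
direction-concordant estimate in the independent replication cohort.
Replication uses nominal α rather than a second FDR because the
replication hypothesis set is small (the discovery survivors) and
pre-specified by the discovery stage. Proteins absent from the
replication data are recorded as untestable, never promoted. When a
protein passes in several groups the sentinel-cis result is reported
first (preference A > B > D > C): group A has the least pleiotropy
exposure and the most direct interpretation, and D is preferred over C
because it at least contains the cis evidence.

## Colocalization

A significant, replicated MR hit can still be an LD artifact: the
protein's causal variant and a distinct disease variant in LD produce a
nonzero Wald ratio with no causal link. The screen is single-causal-
variant colocalization over the sentinel region (±1 Mb): per-SNP
Wakefield log-ABFs ½[log(1−r) + rz²] (r = W/(V+W), prior effect sd 0.15
for quantitative traits and 0.2 on the log-OR scale for case-control
traits), hypothesis evidence accumulated by log-sum-exp, priors
p1 = p2 = 10⁻⁴, p12 = 10⁻⁵ (the established single-variant defaults; all
configurable). The H3 cross-sum Σ_{i≠j}exp(L1ᵢ+L2ⱼ) is computed in
shifted space with the diagonal excluded term by term: the tempting
shortcut exp(LSE₁+LSE₂) − exp(LSE₁₂) cancels catastrophically exactly in
the interesting case where one SNP dominates both traits.

Decisions follow the 0.8 posterior rule: PP.H4 > 0.8 — shared variant,
the MR finding is reinforced; PP.H3 > 0.8 — distinct variants, the
finding is excluded as LD-confounded; otherwise the verdict stays
`replicated` unmodified (colocalization can only ever *exclude* via H3 or
*upgrade* via H4 — an underpowered coloc is not evidence against a
replicated MR result). A conditional-analysis check reports regions with
more than one independent signal per trait, where the single-variant
assumption (and hence any PP) is unreliable; the flag annotates but does
not gate, since multi-signal regions invalidate the coloc verdict, not
the MR estimate. With a single SNP in the region H3 has no i ≠ j term;
its posterior is fixed at 0 and flagged. The region window is "within
2 Mb of the sentinel" read as a 2 Mb total window (±1 Mb); the ±2 Mb
reading is available through `half_width`.

# The synthetic-data generator

`simulate_region`, `simulate_mr_instruments` and `simulate_proteome`
draw marginal summary statistics from the standard model
z ~ MVN(√n_eff·R·b, R) on the genotype-standardized scale, with AR1
(R_ij = ρ^|i−j|, default ρ = 0.9) or block-exchangeable LD. Case-control
traits are emitted on the log-OR scale with the large-sample
se ≈ [2·maf(1−maf)·N·K(1−K)]^(−1/2), which avoids individual-level
genotype simulation while matching the power formula's assumptions.
Correlated noise (covariance R/n_eff, per-SNP sd exactly 1/√n) rather
than independent noise is essential: clumping, conditional analysis and
colocalization all read LD consistency out of the z field.

Defaults describe the study design the generator emulates: a pooled
protein GWAS of 51,799; a discovery outcome cohort of 8021 cases /
16,489 controls and a replication cohort of 346 cases / 207,748 controls
(two cohorts of very different case counts — replication is the
bottleneck, exactly as in real proteome screens); sentinel cis-pQTLs
explaining 10–30% of protein variance (plasma pQTLs are routinely this
strong); causal effect −0.3 log-OR per SD; trans signals weaker (2–8%).
The proteome generator plants three architectures: causal (outcome
effect mediated through the protein's variants, hence shared), null, and
LD-confounded (an outcome-only variant at r² ≈ 0.3–0.6 with the sentinel
— the architecture MR cannot distinguish and colocalization must catch).
It also places one gene inside the MHC and routes six proteins through a
shared trans hub so the MHC and pleiotropy filters are exercised on
every run. Ground truth is emitted alongside and is sufficient to score
every pipeline decision; the analysis code never reads it.

What the generator does **not** emulate: realistic human LD maps (AR1
decay is far more regular), allele-frequency–dependent effect-size
architecture, sample overlap between exposure and outcome GWASs,
population stratification, or platform heterogeneity between protein
assays. Passing tests therefore demonstrate the statistical machinery is
correct and calibrated under its stated model, not that real-data
results are unbiased against these additional failure modes.

# Numerical and design choices

* z/p consistency on input is enforced at 10% relative tolerance —
  loose enough for rounded published p-values, tight enough to catch
  column mix-ups.
* Meta-analysis across protein GWASs is fixed-effect inverse-variance
  (β* = Σβᵢ/seᵢ² / Σ1/seᵢ²), the general-purpose scheme when per-study
  effects are on a common scale; single-study SNPs pass through flagged.
* Seeds: every stochastic routine (weighted-median bootstrap, MR-PRESSO,
  all simulators) takes an explicit seed, saves and restores the
  caller's RNG state, and records the seed in its output.
* Degenerate inputs: IVW with one pair delegates to the Wald ratio;
  Egger refuses L < 3; PRESSO skips L < 4 with a message; empty region
  intersections yield an `underpowered` coloc verdict rather than an
  error; a missing gene location demotes a protein to trans-only with a
  warning.
* Problem sizes in the test suite (50-instrument sets, 60–200-SNP
  regions, 100-protein proteomes, 500–1000 replicate calibrations, 20
  pipeline seeds) were chosen as the smallest designs at which the
  Monte-Carlo bands (95% ± 2% coverage, KS p > 0.01 uniformity, ≥ 90%
  scenario discrimination, pooled FDR ≤ 0.1) are stable.

# Known limitations

Single-causal-variant colocalization underestimates sharing in
multi-signal regions (flagged, not resolved — no SuSiE-style
decomposition). The conditional analysis assumes the supplied LD matrix
matches the GWAS sample; mismatched reference panels are a known failure
mode and no regularization is applied beyond the collinearity guard.
Binary-trait Steiger r² uses the z²/(z²+n) approximation on the
observed scale. No multivariable MR, no sample-overlap correction, no
genome-build liftover.
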