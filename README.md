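# protmr

Proteome-wide two-sample Mendelian randomization (MR) with Bayes-factor
colocalization, for screening plasma proteins as causal candidates for a
binary disease outcome from GWAS summary statistics.

## The problem

Protein quantitative trait loci (pQTLs) let us ask, protein by protein,
whether genetically higher circulating levels change disease risk. Doing
this credibly at proteome scale needs more than a Wald ratio: instruments
must be strong, non-pleiotropic and outside pathological LD regions;
estimates must survive an independent replication cohort and
multiple-testing control; and every hit must be checked for the classic
failure mode where the protein's causal variant merely sits in LD with a
distinct disease variant — a configuration that produces a significant MR
estimate with no causal effect at all. `protmr` implements that whole
workflow, plus a synthetic summary-statistics generator with exported
ground truth so the pipeline's operating characteristics (sensitivity,
realized FDR, confounding exclusion) are measurable.

## What it computes

**Instrument selection.** Genome-wide-significant pQTLs (p < 5×10⁻⁸) with
F = (β/se)² ≥ 10, outside the MHC (chr6:27,477,797–34,448,354, GRCh37),
associated with ≤ 5 proteins, not protein-coding-altering, and not
palindromic after harmonization. Instruments are organized into four
groups: **A** sentinel cis-pQTLs (lowest p per ±1 Mb region), **B**
sentinel plus conditionally independent cis signals (stepwise
summary-statistic conditional analysis, joint effects R⁻¹b), **C**
trans-pQTLs, **D** all pQTLs; B–D are LD-clumped at r² < 0.1.

**MR estimators.** For harmonized instrument–outcome pairs (βx, βy):

- Wald ratio βy/βx with se = se_y/|βx|;
- IVW β̂ = Σβxβy/se_y² ∕ Σβx²/se_y², fixed-effect se or multiplicative
  random-effects inflation max(1, √(Q/(L−1))) when Cochran's Q p < 0.05;
- MR-Egger weighted regression with intercept (directional-pleiotropy
  test); weighted median with parametric-bootstrap se;
- MR-PRESSO simulation-based global and per-SNP outlier tests;
- Steiger directionality (r² = z²/(z²+n) per trait), leave-one-out;
- binary-outcome power via the non-centrality approximation
  b = K(OR/(1+K(OR−1)) − 1), v = (K(1−K)−b²)/N, NCP = b²r²/v.

Discovery associations are BH-FDR-controlled within each instrument group
(FDR < 0.05); a protein is reported only if it also replicates
(p < 0.05, concordant direction) in an independent cohort.

**Colocalization.** Wakefield log approximate Bayes factors
½[log(1−r) + rz²] per SNP feed posterior probabilities for the five
single-causal-variant hypotheses (H0 none, H1/H2 one trait, H3 distinct
variants, H4 shared variant). PP.H4 > 0.8 marks a shared causal variant;
PP.H3 > 0.8 marks an LD-confounded MR hit, which the pipeline excludes.

## Worked example

Fifty independent instruments with a true causal effect of −0.3 log-OR
per SD of protein, at a discovery cohort of 8021 cases / 16,489 controls:

```r
library(protmr)
cfg <- sim_config(seed = 20230207, true_theta = -0.3)
d <- simulate_mr_instruments(cfg)$discovery
mr_ivw(d, "auto")
#>   method n_snps   beta_mr      se_mr         pval      or_   or_lci   or_uci
#>   ivw_fe     50 -0.267161 0.03131693 1.452482e-17 0.76555 0.719974 0.814012
mr_power_binary(r2 = 0.278, or_alt = 0.890, n = 24510,
                case_fraction = 8021/24510)
#> [1] 0.9931723
```

The IVW estimate recovers the planted effect (−0.267 ± 0.031 against a
truth of −0.3, OR 0.77 [0.72, 0.81]); the power call says an instrument
set explaining 27.8% of protein variance has 99% power to detect an OR of
0.89 in that cohort.

The numbered scripts under `analysis/` run the full study: `01_simulate.R`
(synthetic proteome: 100 proteins, 5 causal, 1 LD-confounded),
`02_instruments.R` (filters and groups), `03_mr.R` (estimator suite and
MR-PRESSO), `04_coloc.R` (scenario discrimination), `05_pipeline.R`
(end-to-end verdicts scored against truth). Each writes its tables under
`results/`. On the default seed the pipeline reports 3 proteins (all
colocalized, FDR 0 against truth) and, pooled over 10 further seeds,
attains sensitivity 0.66 at realized FDR 0 while excluding 5 planted
LD-confounded architectures via PP.H3.

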