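---
title: "Carrier burden, heterogeneity and cumulative risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carrier burden, heterogeneity and cumulative risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvburden)
```

# The analysis in one paragraph

`pvburden` implements the analysis chain used by large registry-based
case-control studies of rare pathogenic variants in cancer predisposition
genes (the motivating setting is *BRCA1*/*BRCA2* across 14 common cancer
types): per-gene dominant-model **carrier collapsing** from classified
variant calls, age-adjusted logistic **burden tests** per gene and cancer
type with carrier-count gating, **between-gene heterogeneity** of the odds
ratios (Cochran Q, I², DerSimonian–Laird random effects), **lifetime
cumulative risk** to age 85 from the estimated OR, the control carrier
frequency and age-band population incidence, and **enrichment analyses**
(regional founder structure, family-history trend and cross-tabulation).
Because individual-level data of such studies are not public, the package
ships a synthetic cohort generator with known ground truth; every stage is
validated against it.

# Generative model

`simulate_cohort()` draws, per individual: sex (`p_female`, default 0.44),
region (weighted categories emulating the 7 hospital-service regions of a
Japanese nationwide registry), and a registration age from a truncated
normal (default mean 62, SD 14.5 on [20, 95], matching the control-group
age structure such registries report). Carrier status per gene combines a
uniform **background** pathogenic-variant frequency with **founder
variants** confined to single regions — founder structure is what produces
the several-fold regional differences in carrier frequency that the
regional χ² analysis targets. Within each region the carrier probability is
`1 - (1 - bg) * prod(1 - f_founder)`.

Cancer onsets use discrete per-band hazards (5-year bands on [0, 85)):
baseline hazards per cancer, sex and band, multiplied for carriers by the
configured relative risk of each carried gene (multipliers multiply across
genes; both-gene carriers are rare enough that this choice is essentially
unobservable). Within a band, the onset year is geometric with the per-year
event probability `1 - exp(-hazard)`. Onsets after the registration age are
censored — the individual is cancer-free at recruitment. This band-level
model is deliberately simpler than a continuous survival model: the
penetrance stage works on the same bands, so band-level hazards are
sufficient, and the sampling is exact for the model as stated.

Family history per cancer type is marginal Bernoulli, with the rate
multiplied by `fh_carrier_multiplier` (default 2) for carriers; pedigrees
are out of scope. The registry-style status split follows: **patients**
(any observed cancer), **controls** (cancer-free and family-history-free),
and **excluded** (cancer-free but reporting family history) — mirroring a
control definition of "no history or family history of cancer". Because
carriers report family history more often, this control definition depletes
carriers from the control pool; the same depletion acts on
family-history-free cases, so the burden OR of the matching design is
unaffected, but the control carrier frequency visibly undershoots the
population frequency. That is a property of the emulated study design, not
a bug.

**Multiple primaries.** The target fraction of patients with 2+ cancer
types (default 6.3%) is enforced from both sides after hazard-driven
generation: a deficit is topped up by injecting one extra sex-compatible
primary into randomly chosen single-cancer patients, an excess is thinned
by reducing randomly chosen multi-primary patients to their earliest
diagnosis. The default 14-type configuration naturally overshoots (about
11% under independent hazards at these lifetime risks), so the thinning
path is the one usually taken. Both adjustments touch patients only and
leave carrier status untouched.

**Decoy calls.** A configurable fraction of individuals (default 3%)
receives a VUS / likely-benign / benign call; classification is a property
of the variant id, so the minimal-VCF writer (one record per variant,
`CLASS=` in INFO) is always consistent. Decoys must never flip carrier
status — a collapsing-rule test, not an afterthought.

## Default parameter choices

The `demo_config()` defaults encode the study conditions the package
emulates: two genes with background carrier frequencies 0.15% and 0.28%
plus founder variants at 0.3–1.1% in single regions (overall carrier
frequencies in the 0.1–1.5% range, with 5–12-fold regional spreads);
genotype relative risks set to the published burden ORs of the
gene-cancer pairs (e.g. 75.6 for gene-1/ovarian, 10.9 for gene-2/female
breast); and lifetime baseline risks of plausible East-Asian registry
magnitude (0.9% ovarian to 9% prostate; exponential age-ramps with slope
0.8 per decade of log-hazard). These baselines are the one component not
dictated by the emulated study (which used national incidence tables we do
not redistribute); they were chosen once for realism and are not
calibrated against any test.

# Burden association

`fit_logistic()` fits the dominant-model logistic regression by binomial
IRLS (`stats::glm.fit`, relative deviance tolerance 1e-12, at most 100
iterations), with age entered linearly in years — **age at diagnosis for
cases, age at registration for controls**, reproducing the emulated
study's covariate. Complete separation (an empty carrier-by-outcome cell)
and non-convergence are flagged on the result rather than raised. Wald
tests and intervals (z = 1.959964) are used throughout because published
tables in this literature print symmetric-on-log-scale CIs.

Two designs mirror the two published analyses: `all_patients` reports the
p-value only (unrestricted case recruitment biases the estimate, so
estimates are withheld), and `no_family_history` restricts cases to those
reporting no family history — of *any* cancer by default, the stricter of
the two readings; `fh_scope = "same"` gives the laxer alternative.
Controls need no filtering (family-history-free by construction).
`region_adjusted` adds region as a categorical covariate and
`single_cancer_only` drops multi-primary patients, the two published
sensitivity analyses. Any analysis with fewer than 3 carriers among cases
or among controls is **gated**: no estimates, reason recorded. We read
"category" in the gating rule as cases and controls separately.

A note on the estimand: because the age covariate means different things
in the two outcome groups, the fitted carrier log-OR carries a small
negative bias relative to the generative log relative risk when the
carrier cumulative risk is non-negligible (we measured roughly −0.1 to
−0.2 at carrier cumulative risks of 15–20%; the bias disappears when the
covariate is dropped). This is a property of the emulated design itself
and is visible in the coverage experiment below, which still stays within
its nominal band.

# Heterogeneity

`se_from_ci()` inverts a printed OR (95% CI) to `theta = ln OR`,
`SE = (ln hi − ln lo) / (2 × 1.959964)`; `heterogeneity()` computes
fixed-effect weights `w = 1/SE²`, Cochran Q on k−1 degrees of freedom, the
χ² upper-tail heterogeneity p, `I² = max(0, (Q − df)/Q) × 100` (floored at
zero, reported to one decimal), the DerSimonian–Laird `tau²` and the
random-effects pooled OR. No small-k corrections are applied — the
analysis is k = 2 throughout. The shipped fixture
(`published_or_pairs()`) carries the published OR pairs for the eight
cancer types with both gene estimates; recomputation reproduces the
published I² exactly for five of the eight (ovarian 90.9, gastric 0,
female breast 0.0, pancreatic 0, and the heterogeneity p 9.0e-4 for
ovarian) and within about 2 points for lymphoma and lung. The prostate
(73.4 recomputed vs 77.4 published) and colorectal (24.7 vs 28.9) rows
cannot be reproduced from the printed, rounded ORs under any τ² estimator
we tried (the published prostate heterogeneity p of .04 implies a Q
unreachable from the rounded pair 1.1/4.0) — those published values were
evidently computed from unrounded estimates, so the recomputed values are
reported as computed.

# Penetrance

With carrier frequency `p` and relative risk `rr` constant over age, the
population incidence in each band is the mixture
`lambda_pop = p·rr·lambda_n + (1−p)·lambda_n`, so
`partition_hazard()` recovers `lambda_n = lambda_pop / (1 + p(rr−1))` and
`lambda_c = rr·lambda_n` — the standard constrained-partition approach of
the penetrance literature, with the OR standing in for `rr` under the
rare-disease assumption (carrier frequencies at or below 1.5% support it).
`cumulative_risk()` gives `F(a) = 1 − prod exp(−lambda·width)`. Note the
conservation identity is exact on the hazard scale and hence as the
*geometric* survival mixture `S_pop = S_c^p · S_n^(1−p)`; the arithmetic
survival mixture holds only to first order in the rates.

The 95% CI for the terminal risk propagates log-OR uncertainty by Monte
Carlo: draws from Normal(beta, SE²) are pushed through the partition, and
the reported interval is the **normal approximation on the risk scale**
(point ± 1.959964 × SD of draws). That construction — rather than a
percentile or logit interval — is the one consistent with published
penetrance tables in this setting, which print negative lower bounds for
small risks (a percentile interval cannot go negative; both are emitted).
Carrier frequency is taken from the (family-history-free) controls, per
the emulated design, and competing mortality is ignored: the curve is a
cumulative incidence to 85, not a life-table risk. Reproducing the
absolute published risk figures is explicitly out of scope — they require
national age-specific incidence tables that are external data — so the
penetrance stage is validated by its conservation, monotonicity,
round-trip and recovery properties instead.

# Enrichment analyses

The regional analysis is a Pearson χ² (no continuity correction) on the
regions × carrier/noncarrier table among patients; with
`exclude_founders = TRUE`, individuals whose carrier status rests solely
on founder-flagged variants are recounted as noncarriers — the
qualitative published result this emulates is a strongly significant
regional difference that disappears after founder exclusion. The
family-history trend is a signed Cochran–Armitage statistic with scores
fixed at 0/1/2 for none / 1 / 2+ associated cancer types reported in
relatives (the published categorization; alternative scores are not
exposed), cross-checked in the tests against `stats::prop.trend.test`.
Cross-tabulation cells use Fisher exact tests with Bonferroni correction
across the whole grid. `summarize_cohort()` reproduces the
participants-table aggregation (counts by sex, mean (SD) diagnosis age,
same-type family-history percentage — first/second-degree relatives pooled,
as the cohort format does not distinguish degree — and the multi-primary
fraction).

# Validation experiments and problem sizes

The test suite runs four simulation experiments, with sizes chosen to keep
the default run a few minutes while leaving the checks statistically
sharp; all seeds are fixed:

- **Type-I error**: complete null (RR 1, family-history multiplier 1),
  carrier frequency 1.5% (the upper end of the emulated range, so carrier
  counts clear the gating rule), a common-cancer baseline (10% lifetime
  risk), n = 20 000, 500 seeds; the rejection rate at p < 0.05 must lie in
  5% ± 2%.
- **CI coverage**: RR 10, carrier frequency 0.4%, rare-cancer baseline
  (2%), n = 20 000, 500 seeds; nominal 95% Wald coverage must lie in
  93–97%.
- **End-to-end penetrance recovery**: RR 11, carrier frequency 0.7%,
  ovarian-like baseline (1.1%), n = 100 000, 100 seeds; the estimated OR
  pushed through the hazard partition must recover the generative carrier
  risk to a median relative error below 15%. The 0.7% frequency is the
  smallest at which the log-OR sampling error alone does not exceed that
  band — a design (power) consideration, decided before the experiment was
  frozen.
- **Logistic oracle**: 100 random small datasets against the closed-form
  2×2 cross-product (tolerance 1e-9) and 100 against a direct numeric
  likelihood maximization (log-likelihood within 1e-6).

What passing these shows — and does not show: the generator emulates the
*structure* of registry data (sex/region/age mixtures, founder geography,
band-level onset, marginal family history, the control definition), not
linkage disequilibrium, pedigrees, sequencing error or somatic variation;
agreement on synthetic cohorts therefore validates the statistical
machinery, not the biology of any particular dataset.

# Degenerate inputs and numerical conventions

Empty groups, unknown genes/cancers/designs and malformed configurations
raise errors naming the offending field; separation and non-convergence
are flags; gated analyses carry `NA` estimates and a reason; constant-age
groups yield a zero shift with an undefined Welch p; `I²` is floored at 0;
`tau²` at 0; machine-readable outputs are never rounded (rounding only in
printed summaries). z is 1.959964 everywhere, stated for determinism; the
difference from 1.96 is below printed precision.

# Known limitations

The OR-as-RR substitution overstates risks for common cancers at high ORs;
competing mortality is ignored; the age covariate's mixed meaning biases
the carrier coefficient slightly toward the null at high penetrance (see
above); the multi-primary adjustment is marginal, not etiologic; and the
family-history generator has no pedigree structure, so kin-cohort style
analyses are out of scope.
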