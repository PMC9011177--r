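# pvburden

Case-control analysis of rare pathogenic-variant carrier status across
multiple cancer types, for statistical geneticists and cancer
epidemiologists working with biobank-style registries. The motivating
setting is germline *BRCA1*/*BRCA2* testing across 14 common cancer types:
carriers are rare (0.1–1.5%), founder variants concentrate them
regionally, and the clinically relevant outputs are per-cancer burden odds
ratios, their between-gene heterogeneity, and lifetime cumulative risk
(penetrance) for carriers.

## What it computes

- **Carrier collapsing** (`collapse_carriers`): an individual is a carrier
  of a gene if they have ≥1 variant classified P or LP in it (dominant
  model); VUS/LB/B calls never qualify. Carrier proportions come with
  exact (Clopper–Pearson) intervals.
- **Burden test** (`run_association`): logistic regression of case status
  on carrier status, age-adjusted (diagnosis age for cases, registration
  age for controls), per gene × cancer × design. The `all_patients` design
  reports p only; the `no_family_history` design reports OR with 95% Wald
  CI; region-adjusted and single-cancer-only sensitivity designs included.
  Cells with <3 carriers among cases or controls are gated (no estimates).
  Burden significance is declared at p < 1e-4.
- **Heterogeneity** (`heterogeneity`, `se_from_ci`): from two gene-specific
  ORs with CIs, θ = ln OR and SE = (ln hi − ln lo)/(2·1.959964), then
  Cochran Q with inverse-variance weights, p from the χ² upper tail,
  I² = max(0, (Q−df)/Q)·100, DerSimonian–Laird τ² and the random-effects
  pooled OR.
- **Penetrance** (`partition_hazard`, `cumulative_risk`, `risk_ci`): with
  carrier frequency p and the OR as relative risk rr, each age band's
  population incidence splits as λ_n = λ_pop/(1 + p(rr−1)), λ_c = rr·λ_n;
  cumulative risk F(85) = 1 − Π exp(−λ·width), with a Monte-Carlo normal
  CI on the risk scale (negative lower bounds possible, by design).
- **Enrichment** (`regional_chisq`, `fh_trend`, `fh_cross_tab`,
  `summarize_cohort`): regional carrier heterogeneity with founder
  stratification, signed Cochran–Armitage trend of carrier status over
  family-history burden (scores 0/1/2), Fisher-exact cross-tabulations
  with grid Bonferroni, and participants-table summaries.
- **Synthetic cohorts** (`simulate_cohort`, `demo_config`): a generator
  with known ground truth (regions, founder variants, band-level hazards,
  genotype relative risks, family-history reporting, multiple primaries)
  so the whole chain is testable without restricted data.

## Worked example

The `analysis/` scripts run the whole chain on a synthetic 50 000-person
cohort and write their tables under `results/run/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_collapse.R
Rscript analysis/03_associations.R
Rscript analysis/04_heterogeneity.R
Rscript analysis/05_penetrance.R
Rscript analysis/06_enrichment.R
```

Stage 3 prints the burden-significant pairs of this run:

```
burden-significant (p < 1e-4) gene-cancer pairs: 4
  gene  cancer  sex carriers_case carriers_control    or   lo    hi        p
 BRCA1    lung both             5               20 17.66 6.59  47.3 1.16e-08
 BRCA2 ovarian    F             3               39 29.21 8.48 100.7 9.01e-08
 BRCA2 gastric both             7               69  6.48 2.96  14.2 3.03e-06
 BRCA2  breast    F             5               39  7.76 3.02  20.0 2.12e-05
```

(the odds ratios are noisy at this demonstration scale — 21 of 30 cells
are gated — which is exactly why the acceptance experiments run hundreds
of seeds). Stage 5 converts them to lifetime risks:

```
  gene  cancer  sex        or                   risk noncarrier
 BRCA1    lung both 17.657933 57.8% (25.7% to 89.9%)       4.8%
 BRCA2  breast    F  7.759711 37.6% (11.0% to 64.2%)       5.9%
```

i.e. the estimated carrier cumulative risk to age 85 with its
normal-approximation CI, next to the noncarrier risk. Stage 6 shows the
founder-variant signature — a strong regional difference that vanishes
when founder variants are excluded:

```
BRCA1: 11.2-fold regional spread; chi2=35.3 p=3.8e-06; founders excluded: chi2=3.5 p=0.74
BRCA2: 12.0-fold regional spread; chi2=51.2 p=2.7e-09; founders excluded: chi2=3.4 p=0.76
```

Desk-scale, the heterogeneity module works straight off published OR
pairs:

```r
library(pvburden)
heterogeneity_pairs(published_or_pairs())[, c("cancer", "Q", "p_het", "I2")]
#>          cancer       Q    p_het   I2
#> ...
#>         ovarian 11.0261 0.000898 90.9
#>        prostate  3.7622 0.052423 73.4
```

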