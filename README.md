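# mirgi — miRNA expression scoring of tumour genome instability

`mirgi` links miRNA expression to genome instability in high-grade serous
ovarian cancer, for bioinformaticians and translational researchers who
want a deliberately simple, rank-based biomarker of homologous
recombination (HR) deficiency. HR-deficient tumours accumulate somatic
mutations and respond better to platinum chemotherapy; the package turns
that causal chain into a reusable analysis pipeline:

1. **Screen.** For each miRNA, tumours are split at the median of its
   expression and the per-sample somatic mutation counts of the two halves
   are compared with a Mann–Whitney U test (both one-sided p-values; the
   smaller, with its direction, is reported; significance at raw
   p < 0.01).
2. **Score.** Given a signed signature of k miRNAs (the default is the
   10-miRNA set split 6 positive / 4 negative), each sample's integer
   score is

   `score(s) = Σ_{m ∈ positive} 1[x_ms > median_m] + Σ_{m ∈ negative} 1[x_ms < median_m]`

   with medians taken across the scored cohort — no fitted weights, so no
   over-fitting to outcome data. Scores ≥ 6 define the high-score group.
3. **Validate.** Score levels are associated with median mutation burden
   (Spearman over level medians), HR-defect frequencies are compared
   between score groups (Fisher exact), platinum-response rates are
   trended across levels, and survival is analysed by Kaplan–Meier,
   log-rank and Cox (Efron ties).
4. **Disentangle.** A rank-adjacency matching algorithm selects
   equal-sized score groups with near-identical mutation-burden
   distributions (and vice versa), so the score's prognostic value can be
   separated from raw burden.

A synthetic cohort generator (`simulate_cohort()`) emulates the assumed
data-generating process — a latent DDR-deficiency variable driving miRNA
shifts, over-dispersed mutation counts, defect flags, survival and
platinum response — with known ground truth, so the whole pipeline is
testable offline.

## Worked example

```r
library(mirgi)
cohort <- simulate_cohort(simulation_config(seed = 2026))
report <- run_pipeline(cohort$bundle)
print(report)
```

```
Analysis report
  screen               OK
  network_enrichment   OK
  score                OK
  association          OK
  response_trends      OK
  defect_enrichment    OK
  survival             OK
  matching             OK
  score-level Spearman rho = 0.920 (p = 5.95e-05)
  log-rank p = 0.00027; univariate HR(high score) = 0.620
```

The screen flags instability-associated miRNAs, the derived signature is
scored, and the high-score group shows higher mutation burden, more HR
defects and better survival — the pattern the score is designed to
detect. Digging into the report:

```r
de <- report$defect_enrichment$hr_defect
sprintf("HR-defect frequency: %.0f%% (high) vs %.0f%% (low), Fisher p = %.2g",
        100 * de$rate_high, 100 * de$rate_low, de$p_value)
#> "HR-defect frequency: 67% (high) vs 33% (low), Fisher p = 3.3e-11"

km <- report$survival$km
sprintf("5-year survival: %.1f%% (high score) vs %.1f%% (low score)",
        100 * survival_rate_at(km$high, 5), 100 * survival_rate_at(km$low, 5))
#> "5-year survival: 58.6% (high score) vs 44.5% (low score)"

report$matching$score_matched_on_mutations$balance_p
#> 0.99   # kept score groups are balanced on mutation burden
```

Real data enter through `read_expression_matrix()`, `read_maf_lite()`,
`read_clinical()`, `read_network_edges()` and `assemble_cohort()`; a small
curated-network fixture and the default signature ship in
`inst/extdata/`.

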