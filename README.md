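# sirhist

Histology-specific standardized incidence ratios for same-site second
primary cancer, with multiple-primary rule engines and a fully synthetic
validation pipeline.

## The problem

Cancer registries disagree on when a second tumor in the same organ is a new
primary. Registries following the IARC/IACR multiple-primary (MP) rules
allow only one primary per organ per lifetime unless the tumors belong to
different histology groups; SEER-style registries additionally count a new
primary after three disease-free years, when the ICD-O-3 histology differs
at the third digit, or when laterality differs. As a consequence, the
conventional standardized incidence ratio

```
SIR = O / E,   E = sum over strata of PY_s × IR_s
```

systematically under-estimates the risk of a second primary lung cancer
(SPLC) in lung-cancer survivors under IARC/IACR rules: same-histology
second tumors are missing from the observed count `O`, while the general
reference rates `IR_s` used for `E` still include them. If second-tumor
histology follows the index distribution `p` over histology groups, only the
fraction `x_j = 1 − p_j` of second primaries after an index tumor of group
`j` is registrable, so the registry reports

```
SIR_sim = SIR_real × Σ_j w_j · x_j
```

— roughly a 30% shortfall for lung cancer, whose histology mix has
`Σ p_j² ≈ 0.3`.

`sirhist` implements both the conventional SIR (`sir1_raw`) and a
histology-specific SIR (`sir2_sub`) that removes this bias: estimation is
stratified by the histology group of the index tumor, same-group second
primaries are not counted as observed, and the reference rates for index
group `j` exclude group `j` from their numerator. Two further variants
(`sir3_iarc`, `sir4_subiarc`) restrict observed events and rate numerators
to IARC/IACR-countable (INTPRIM-flagged) records for validation on
SEER-style data. Confidence intervals are exact Poisson (Breslow–Day)
intervals from chi-square quantiles.

Because person-level registry data of this kind is access-restricted, the
package ships a synthetic registry generator with known ground truth
(`generate_cohort()`, `generate_population_denominators()`), so every stage
— cohort selection, MP-rule adjudication, person-time splitting, rate
construction, SIR estimation and the bias simulation — is testable end to
end.

## Worked example

Generate a 50,000-person survivor cohort whose true SPLC hazard is twice
the reference rate, with IARC/IACR suppression switched on, and estimate
both SIR variants against the exact reference rates:

```r
library(sirhist)

cfg <- synth_config(n_persons = 50000, seed = 42, sir_real = 2,
                    apply_iarc_suppression = TRUE)
records <- generate_cohort(cfg)
rates   <- rate_tables_from_config(cfg)
res <- estimate_splc_sir(records, cfg$cohort, rates = rates,
                         variants = c("sir1_raw", "sir2_sub"))
subset(as.data.frame(res), stratum_label == "total")
```

```
  variant    sex stratum_label   O     E  sir ci_low ci_high level
 sir1_raw female         total  74  53.7 1.38   1.08    1.73  0.95
 sir1_raw   male         total 170 114.4 1.49   1.27    1.73  0.95
 sir1_raw    all         total 244 168.1 1.45   1.27    1.65  0.95
 sir2_sub female         total  74  37.7 1.96   1.54    2.47  0.95
 sir2_sub   male         total 170  80.1 2.12   1.82    2.47  0.95
 sir2_sub    all         total 244 117.8 2.07   1.82    2.35  0.95
```

The conventional estimate (1.45 overall) sits far below the true ratio of
2; the histology-specific estimate (2.07, 95% CI 1.82–2.35) recovers it.
`O` is the observed count of registered second primary lung cancers, `E`
the expected count from stratified reference rates applied to the cohort's
person-years at risk.

The closed-form bias simulation gives the same picture without any
event-level data — a uniform four-group histology distribution shrinks a
true SIR of 2 to 1.5:

```r
u <- tibble::tibble(group = c("squamous", "adenocarcinoma",
                              "small_cell", "other_carcinoma"), p = 0.25)
simulate_sir_iarc(u, sir_real = 2, expected_total = 100)
```

```
 sir_real sir_sim o_sim expected_total ci_low ci_high
        2     1.5   150            100   1.27    1.76
```

A command-line front end (`inst/cli/sirhist`) exposes the same machinery as
`synth`, `mp-annotate`, `rates`, `sir` and `bias-sim` subcommands over
delimited-text files.

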