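# countdisp

Count-data regression for disease incidence disparities across
administrative units, built around the Consul–Jain **generalized Poisson
(GP)** distribution.

Routine health-information-system data — disease counts per district
council, per year — are almost always *over-dispersed*: the variance far
exceeds the mean because incidence clusters within councils that share
social and environmental conditions. A standard Poisson regression then
understates standard errors and overstates significance. `countdisp`
fits and compares the three count models a practitioner reaches for in
this situation:

* **Poisson**, variance `Var(Y) = μ` (equi-dispersion),
* **negative binomial (NB2)**, `Var(Y) = μ + μ²/α`,
* **generalized Poisson (GP)**, `Var(Y) = ϑ²μ`, where the dispersion
  factor `ϑ = 1/(1−δ)` handles over- (`ϑ > 1`), equi- (`ϑ = 1`, exactly
  Poisson) and under-dispersion (`ϑ < 1`, with a truncated support).

All three use a log link, `log μ_i = x_i'β`, and are fitted by maximum
likelihood with analytic gradients; the GP pmf is

```
P(Y = y) = μ [μ + (ϑ−1)y]^(y−1) ϑ^(−y) / y! · exp{−[μ + (ϑ−1)y]/ϑ}
```

Model adequacy is compared with −2logL, AIC, AICc, BIC and the Pearson
chi-square dispersion ratio χ²/df (≈ 1 when dispersion is modelled
adequately, ≫ 1 for an over-dispersed Poisson fit). A descriptive stage
bands counts into `<50 / 51-200 / >200`, cross-tabulates them against
residence (rural/urban) and zone (7 levels), and runs Pearson chi-square
independence tests.

Because council-level health data are typically access-restricted, the
package ships a seeded synthetic generator (`synth_config()`,
`generate_councils()`) that emulates the structure of a 184-council
national dataset — zone and residence frequencies, right-skewed
covariates, GP counts with log-link means — so every pipeline stage is
testable end to end, including parameter recovery against the known
generator truth.

## Worked example

```r
library(countdisp)

cfg     <- synth_config(seed = 1)            # 184 councils, GP counts
records <- generate_councils(cfg)$records
report  <- run_analysis(records)
report
```

```
Council count-analysis report (countdisp-report/1)
  n = 177 of 184 councils; response: total
  residence association: chi2 = 78.915, df = 2, p = 7.308e-18
  zone association: chi2 = 37.221, df = 12, p = 0.0002057
  model comparison:
   model    loglik minus2loglik      aic     aicc      bic pearson_chi2  df pearson_ratio   n  k
      gp  -893.731     1787.462 1815.462 1818.054 1859.928      170.130 163         1.044 177 14
      nb  -900.745     1801.491 1829.491 1832.083 1873.957      180.569 163         1.108 177 14
 poisson -2101.995     4203.990 4229.990 4232.223 4271.280     3206.136 164        19.550 177 13
```

Seven of the 184 synthetic councils have missing counts, so the fits use
n = 177 complete cases. The GP model attains the smallest AIC/AICc/BIC
and a Pearson ratio near 1 (1.044: dispersion well controlled), while
the Poisson ratio of 19.6 flags severe over-dispersion. Coefficients
with Wald inference:

```r
head(wald_inference(report$fits$gp), 8)
```

```
            term estimate std_error      z  p_value
1    (Intercept)   4.5229   0.80619  5.610 2.02e-08
2     pplhiv_pct   0.0354   0.01720  2.059 3.95e-02
3     population   0.1468   0.04750  3.091 2.00e-03
4            gdp  -0.1565   0.04215 -3.714 2.04e-04
5   n_facilities   0.0108   0.00183  5.892 3.81e-09
6       pct_male   0.0021   0.00250  0.842 4.00e-01
7 residenceUrban   1.1158   0.06043 18.464 4.03e-76
```

On the log-link scale these are multiplicative effects: e.g. urban
councils are predicted `exp(1.116) ≈ 3.1` times more cases than rural
councils with the same covariates. Reports serialize to JSON or a CSV
bundle with `write_report()`; `cli_main()` (and the launcher at
`inst/cli/countdisp.R`) exposes `simulate` / `analyze` / `compare`
subcommands.

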