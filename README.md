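# childineq

Wealth-related inequality in binary child-health indicators from
complex-survey microdata.

Public-health surveys such as the Demographic and Health Surveys (DHS)
record, for each child, a design weight, a cluster (primary sampling
unit) id, a household wealth score, vaccination-card entries, food-group
consumption flags and anthropometry. `childineq` turns these into the
standard health-economics inequality analysis:

* **Outcomes** — full immunization (a configurable schedule of
  card-dated doses; 7 vaccines / 15 doses by default), food insecurity
  (dietary diversity below a threshold over 13 food groups) and
  malnutrition (weight-for-age z-score < −2 SD).
* **Concentration index** — with weighted midpoint fractional ranks
  `R`, `CI = 2 cov_w(h, R) / μ`; for bounded (binary) outcomes the
  Erreygers-normalized index `ENCI = 4μ/(b−a) · CI`, which spans
  [−1, 1] and obeys the mirror property `ENCI(1−h) = −ENCI(h)`.
  Positive = concentrated among the rich. Standard errors come from the
  convenient regression with a cluster-robust (PSU) sandwich variance.
* **Concentration curves** — ordinates `L(p)` at 19 quantile points with
  influence-function standard errors, and the multiple-comparison ("mca")
  dominance test against the 45-degree line of equality.
* **Decomposition** — via a weighted linear probability model,
  `ENCI = Σ_k 4 β_k x̄_k CI_k + residual`; the adding-up identity is
  algebraic and holds to machine precision.
* **Synthetic data** — a clustered DHS-like generator with known
  population truth (`generate_dataset()`, `population_truth()`), so the
  whole pipeline is testable without restricted survey files.

## Worked example

```r
library(childineq)

gen <- generate_dataset(generator_config(n_children = 5000, n_psu = 200),
                        seed = 2)
d <- derive_outcomes(gen$data)   # reproduces the generator's labels exactly
report_indices(d)
#>         outcome       enci         se       p_value stars    n clusters
#> 1     immunized  0.2551849 0.01593519  1.021548e-57   *** 5000      200
#> 2 food_insecure -0.2302510 0.01509814  1.638986e-52   *** 5000      200
#> 3  malnourished -0.2880531 0.01310080 3.798554e-107   *** 5000      200
```

Immunization is concentrated among richer children (positive ENCI,
pro-rich), food insecurity and malnutrition among poorer children —
the gradients the generator's coefficients encode, each about 16–22
cluster-robust standard errors from zero.

```r
dec <- report_decomposition(d, "immunized",
  c("wealth_quintile", "rural", "mother_edu", "mother_age", "anc4",
    "facility_delivery", "media_exposure", "birth_order"))
dec
#> Decomposition of ENCI = 0.2552 (SE 0.0159)
#>          Covariate Elasticity Concentration Index Contribution Contribution (%)
#>    wealth_quintile     0.1504              0.2666       0.1604            62.84
#>              rural    -0.0146             -0.1884       0.0110             4.32
#>         mother_edu     0.0334              0.3023       0.0403            15.81
#>         ...
#> Residuals: 0.60%
decomposition_gap(dec)
#> [1] 0
```

Each row multiplies the covariate's elasticity (`β_k x̄_k`) by its own
concentration index and the Erreygers factor 4: household wealth alone
accounts for ~63% of the immunization inequality in this synthetic
population, and the residual row closes the identity exactly.

The cell identity also audits published decomposition tables directly:

```r
enci_contribution(0.0439, 0.2870)   # elasticity, covariate CI
#> [1] 0.0503964                     # printed contribution: 0.0504
```

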