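# mcatsim

Simulation engine for **multidimensional computerized adaptive testing
(MCAT)** over polytomous item banks, with a focus on **item usage
analysis**: which items an adaptive algorithm actually administers, how
that depends on the respondent's latent-trait level, and how much of an
item bank is effectively inactive.

The package targets the setting of health-related quality-of-life (HRQL)
measurement: a 194-item bank spanning four correlated domains (fatigue,
physical function, participation in social roles, and a COPD-specific
set), calibrated with the between-item multidimensional graded response
model. Because the calibrated parameters are not redistributable, a
synthetic-bank generator reproduces the bank's described structure so the
whole pipeline runs and is tested end to end.

## The model and the algorithm

Item $i$ loads on a single dimension $d(i)$ with discrimination
$\alpha_i$ and ordered thresholds $\beta_{ij}$; category probabilities
are differences of logistic curves in $\alpha_i\theta_{d(i)} - \beta_{ij}$
(graded response model). Dimensions correlate through $\Phi$, which is
also the prior covariance of the MAP estimator
$\hat\theta = \arg\max\ \ell(\theta) + \log\mathrm{MVN}(\theta; 0, \Phi)$.

Items are selected by Segall's D-optimal rule: maximize
$\det\!\big(J + s_k \alpha_k^2 e_{d_k} e_{d_k}^\top\big)$, where
$J = \Phi^{-1} + \sum_{\text{admin}} s_i \alpha_i^2 e_{d_i} e_{d_i}^\top$
is the posterior information matrix — computed via the rank-1
determinant identity, so selection is $O(\text{bank})$ per step. A CAT
starts with one random item per domain and terminates a dimension when
its posterior SE falls below 0.316 (reliability 0.9); the test ends when
all four dimensions have terminated.

Usage statistics per grid value $g$: usage rate (fraction of CATs
administering the item), expected rate (mean test length / bank size),
*overused* (rate strictly above expected), *active* (rate $> 0$), and
*overlap* ($100\cdot\#\text{overused}/\#\text{active}$).

## Worked example

```r
library(mcatsim)
bank   <- generate_item_bank(bank_recipe(seed = 1))   # 194 items, 4 domains
design <- study_design(-2, 2, 1, replicates_per_point = 100, seed = 2)
study  <- run_study(bank, design, cat_config())
usage  <- classify_and_summarize(
  compute_usage_rates(study, bank, include_initial = FALSE), bank)
subset(usage$summary, group == "Total")
```

```
 grid_value group group_size n_active n_overused active_pct overused_pct overlap_pct
         -2 Total        194       34         22      17.53        11.34        64.7
         -1 Total        194       27         21      13.92        10.82        77.8
          0 Total        194       20         19      10.31         9.79        95.0
          1 Total        194       16         15       8.25         7.73        93.8
          2 Total        194       48         23      24.74        11.86        47.9
```

Reading: at central trait values the adaptive algorithm lives off ~20 of
194 items (10% active bank), almost all of them used more than chance
would predict (overlap 95%); at extreme trait values tests lengthen, the
active bank widens (18–25%) and overused items become a minority of it —
the characteristic usage signature of an unconstrained MCAT.

A single respondent:

```r
run_cat(bank, rep(0, 4), cat_config(seed = 42))
#> <cat_result sim> 9 items, converged
#>   theta_final: 0.473 0.337 0.394 0.126
#>   se_final   : 0.301 0.288 0.305 0.285
```

## Command line

```sh
MCAT=$(Rscript -e 'cat(system.file("cli", "mcat", package = "mcatsim"))')
Rscript "$MCAT" generate-bank --seed 1 --out bank.csv
Rscript "$MCAT" run-cat   --bank bank.csv --theta 0,0,0,0 --seed 2
Rscript "$MCAT" run-study --bank bank.csv --replicates 100 --seed 3 --out out/
```

`run-study` writes a per-respondent CAT log, per-item usage rates, the
active-size / overused / overlap summary tables (one row per grid
value), an accuracy table and a JSON run manifest.

See the methods vignette (`vignettes/mcat-usage-simulation.Rmd`) for the
model, the analysis definitions, the synthetic-bank design and its
limitations.
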