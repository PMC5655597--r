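---
title: "Simulating item usage in a multidimensional adaptive HRQL test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating item usage in a multidimensional adaptive HRQL test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Computerized adaptive tests (CATs) pick each next item to be maximally
informative about the respondent's current latent-trait estimate. In health
measurement this buys short questionnaires, but it concentrates
administrations on a few highly discriminating items: much of a carefully
built item bank may never be shown to anyone. `mcatsim` simulates a
four-domain multidimensional CAT over a polytomous health-related
quality-of-life (HRQL) bank and measures exactly that: which items the
algorithm uses, how that depends on the respondent's true trait level, and
how much of the bank is effectively dead weight.

## Measurement model

Items follow the graded response model with *between-item*
multidimensionality: item $i$ measures exactly one of $D$ latent
dimensions ($D = 4$ here: fatigue, physical function, participation in
social roles, and a disease-specific COPD domain), with discrimination
$\alpha_i > 0$ and ordered thresholds
$\beta_{i1} < \dots < \beta_{im}$ on the $\alpha\theta - \beta$ metric.
With $\Psi$ the logistic function and $z = \alpha_i \theta_{d(i)}$,

$$P(X_i = j \mid \theta) =
  \Psi(z - \beta_{ij}) - \Psi(z - \beta_{i(j+1)}),
  \qquad \Psi(z - \beta_{i0}) \equiv 1,\; \Psi(z - \beta_{i(m+1)}) \equiv 0 .$$

Only the $\alpha\theta - \beta$ parametrization is meaningful in the
multidimensional case; IRTPRO-style "easiness" parameters $c = -\beta$
are converted at the file boundary (`read_item_bank(parametrization =
"easiness")`), never inside the model. Multidimensionality enters purely
through the latent correlation matrix $\Phi$ (unit variances), which also
serves as the prior covariance below. Internally an item stores
`(domain, alpha)` rather than a length-$D$ loading vector — the vector is
reconstructed only where the information matrix needs it.

The scalar Fisher information of an item's linear predictor is the
standard graded-response form
$s(\theta) = \sum_j (w_j - w_{j+1})^2 / P_j$ with
$w_j = \Psi_j(1 - \Psi_j)$; it is not taken on faith but checked in the
test suite against a finite-difference expected negative Hessian
(tolerance $10^{-4}$). The $D \times D$ item information is the rank-1
matrix $s\,\alpha^2 e_d e_d^\top$.

## Estimation and item selection

The latent trait is estimated by MAP: the mode of likelihood times
$\mathrm{MVN}(0, \Phi)$. The optimizer is Newton–Raphson with the
analytic gradient and the *expected-information* Hessian, step-halving on
any non-increase of the log-posterior, warm-started from the previous
estimate inside a CAT. Convergence is $\lVert\Delta\theta\rVert_\infty <
10^{-6}$ with a 100-iteration cap; failure is an error that reports the
last iterate. Expected (rather than observed) information is used
throughout — for the Hessian, for the posterior information matrix and
for the standard errors — so the selection criterion and the termination
rule are internally consistent.

Item selection is Segall's D-optimal rule ("Bayesian volume decrease"):
among eligible items, maximize $\det(J + s_k a_k a_k^\top)$ where
$J = \Phi^{-1} + \sum_{\text{administered}} s_i a_i a_i^\top$ is the
posterior information at the current estimate. The matrix determinant
lemma collapses this to maximizing $s_k \alpha_k^2 (J^{-1})_{d_k d_k}$,
one $D \times D$ inverse per step and $O(1)$ per candidate — which is
what makes 21,000 CATs over ~190 candidates tractable. The test suite
checks this shortcut against dense determinants on random states.
Exact criterion ties are broken uniformly at random.

A CAT starts with one uniformly random item per domain (to give the MAP
step data in every dimension), then loops select → simulate response →
re-estimate. A dimension *terminates* when its posterior SE drops below
0.316 (the reliability-0.9 convention); its items leave the eligible set,
but the determinant objective stays the full $D \times D$ matrix.
Because the prior is strongly correlated, a dimension can terminate
before any adaptive item of its own domain was asked. The CAT stops when
all dimensions have terminated, the eligible set is empty, or a safety
cap (default: bank size) is hit; non-converged runs are recorded, not
discarded.

## Study design and seeding

`study_design()` reproduces the simulation grid: every increment of 0.2
on $[-2, 2]$, 1000 simulees per point, each simulee's true $\theta$
having all four coordinates equal to the grid value (the grid is read as
uniform coverage of the multidimensional scale along its diagonal; a
correlated-population alternative is available through
`generate_population()`). One master seed pre-draws a substream seed per
simulee, so single CATs can be re-run in isolation and serial and
forked (`threads > 1`) execution produce identical output.

## Usage statistics

For grid value $g$: an item's *usage rate* is the fraction of CATs at
$g$ that administered it; the *expected usage rate* is the mean test
length at $g$ divided by the total bank size (194 — the total-bank
denominator is kept even for per-domain classification); an item is
*overused* when its rate strictly exceeds the expected rate and *active*
when its rate is positive. Active/overused percentages divide by domain
size within domains and by bank size overall; *overlap* is
$100 \cdot \#\text{overused} / \#\text{active}$, the definition uniquely
consistent with the published central-trait tables (7 overused of 9
active → 78%). Full precision is kept internally; rendered tables round
half-up to integers.

One analysis choice deserves emphasis. The engine's random warm-up items
are real administrations — they count toward test length — but the
study-level usage statistics exclude them
(`compute_usage_rates(..., include_initial = FALSE)`). Counting them
would mark essentially the whole bank active at any realistic number of
replicates (four uniform draws per simulee across 1000 simulees touch
nearly every item) and would make reported active-bank sizes around 10%
arithmetically impossible; the published tables are therefore only
reproducible over the adaptive selections. The default of
`compute_usage_rates()` still counts everything, so the exclusion is an
explicit, visible choice at the analysis layer. When initial items are
excluded, the table's mean test length refers to the counted (adaptive)
part, keeping the identity
$\sum_i \text{rate}(i \mid g) = \overline{\text{length}}(g)$ exact.

## The synthetic bank: a stated world

The calibrated item parameters live in a supplementary PDF and are not
bundled; `generate_item_bank()` emulates their described structure so the
pipeline is testable end to end:

* 194 items in domains of 50/63/35/46; the published $\Phi$
  (`copd_hrql_correlation()`).
* Category profile 139/51/4 items with 5/4/3 categories — the residue of
  merging sparsely endorsed categories in 55 of 194 items.
* Discriminations log-uniform on $[0.82, 5.40]$: log-uniformity puts
  more mass at moderate values, as calibrated clinical banks do.
* Threshold *locations* drawn on the latent scale — item centers
  $N(0, 1.2)$, within-item spread $N(0, 0.7)$ — then multiplied by
  $\alpha$ onto the $\alpha\theta - \beta$ metric, sorted, clipped to
  $[-7.57, 7.67]$ and pushed to a minimum gap of 0.2. The
  multiplication is what reconciles a modest trait range with the wide
  printed $\beta$ range ($\pm 7.6$): in this parametrization $\beta$
  scales with $\alpha$. (Drawing $\beta$ directly from a central normal
  leaves the bank uninformative at $\theta = \pm 2$ and whole domains
  exhaust without terminating — a regime the study bank demonstrably was
  not in.)

What the generator does **not** emulate: the real banks' deliberate
content coverage (locations are exchangeable within domain), calibration
error in the parameters, domain-specific category wording, and any
clustering of discrimination by domain. A green scaled-down acceptance
run therefore establishes that the *mechanism* reproduces the qualitative
usage pattern — longer tests and a wider active bank at extreme traits,
overuse dominating the active bank centrally, MAP shrinkage biases at the
grid edges — not the published percentages themselves, which require
transcribing the supplementary parameters into the bank CSV format.

`collapse_sparse_categories()` implements the data-preparation rule
(categories with fewer than 10 responses merge with a neighbor). The
source states only the threshold and adjacency, so the loop order is a
design choice: repeatedly take the sparsest under-threshold category,
merge extremes inward and interior categories into the smaller-count
neighbor (ties toward the lower index), stop at two categories. The
procedure is idempotent.

## Numerical choices

* Probabilities are floored at $10^{-10}$ before logs and divisions;
  with thresholds out to $\pm 7.7$, extreme $\theta$ genuinely
  underflows category probabilities.
* Newton tolerance $10^{-6}$ (max-norm of the step), cap 100; the
  posterior is smooth and close to quadratic, so 3–6 iterations are
  typical with warm starts.
* Selection ties: criterion values within a $10^{-12}$ relative band are
  treated as tied and resolved by one draw from the CAT's RNG stream.
* Degenerate inputs: an empty administered set is legal everywhere
  (prior-only posterior: $\hat\theta = 0$, SE $= 1$); an exhausted
  eligible set raises a typed `bank_exhausted` condition from
  `select_next_item()` and a recorded non-converged result from
  `run_cat()`.

## Worked example

```{r example}
library(mcatsim)
bank   <- generate_item_bank(bank_recipe(seed = 1))
design <- study_design(-2, 2, 1, replicates_per_point = 100, seed = 2)
study  <- run_study(bank, design, cat_config())
usage  <- classify_and_summarize(
  compute_usage_rates(study, bank, include_initial = FALSE), bank)
subset(usage$summary, group == "Total")
accuracy_metrics(study)
```

The same computation, exported as CSV tables shaped like the published
ones, is available from the command line:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
Rscript "$(Rscript -e 'cat(system.file("cli", "mcat", package = "mcatsim"))')" \
  run-study --seed 1 --replicates 100 --out out/
```

## Limitations

* Without the transcribed calibrated parameters, all full-bank numbers
  are for the synthetic stand-in; only the qualitative pattern is a
  tested claim.
* No content constraints or formal exposure control are modeled — their
  absence is the point of the usage analysis.
* Calibration itself (marginal maximum likelihood), linking designs and
  short-form construction are out of scope.
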