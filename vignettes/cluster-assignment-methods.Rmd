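---
title: "Assigning disease clusters to people: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning disease clusters to people: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(mltcassign)
library(dplyr)
```

## The problem

Multimorbidity — multiple long-term conditions (MLTC), i.e. two or more
chronic diseases in one person — is increasingly described through *disease
clusters*: groups of conditions that tend to co-occur. A clustering of
diseases, however, does not by itself say anything about a *person*: people
typically carry diseases spanning several clusters, so any analysis relating
clusters to patient outcomes needs a rule for mapping a person's disease set
onto the clusters. This package implements and evaluates seven such rules,
operating on a fixed many-to-one partition of `D` diseases into `K` clusters
(the motivating setting has `D = 212` and `K = 15`; both are free
parameters, so a 25-cluster sensitivity analysis is just `n_clusters = 25`).

For a patient with disease set $S$ and per-cluster counts
$n_c = |\{d \in S : \mathrm{cluster}(d) = c\}|$, $N = \sum_c n_c = |S|$:

| strategy | representation of cluster $c$ |
|---|---|
| `ge1`, `ge2`, `ge3` (generally `ge<m>`) | $\mathbf{1}[n_c \ge m]$ |
| `modal` | one-hot at $\arg\max_c n_c$, ties broken uniformly at random |
| `majority` | $\mathbf{1}[n_c / N > 0.5]$ (strict; exactly half assigns nothing) |
| `count` | $n_c$ |
| `proportion` | $n_c / N$ |

Useful consequences that the tests assert as invariants: the assigned sets
are nested across thresholds ($m{+}1$ implies $m$); `ge1`, `count` and
`proportion` share the same nonzero pattern; whenever `majority` assigns a
cluster, `modal` assigns the same cluster without a tie; proportions sum to
one.

The *strict* reading of "over 50%" for the majority rule is deliberate: a
patient split 2–2 between two clusters gets no majority cluster. The modal
tie-break consumes one random draw per patient in patient-id order from a
seeded stream, so a given (cohort, seed) pair is exactly reproducible while
the tie rate remains an honest, reportable quantity.

## Evaluating strategies against outcomes

Each representation enters a multivariable logistic regression for each of
three one-year binary outcomes — death from any cause, any emergency
department (ED) attendance, any emergency hospital admission — alongside the
covariates age (linear, continuous), gender, ethnicity (dummies, reference =
most frequent level) and IMD deprivation decile (dummies, reference = lowest
observed decile; a continuous encoding is available via
`build_design(imd = "continuous")`). A reference model replaces the cluster
block with one binary indicator per disease. Models are compared by
$\mathrm{AIC} = 2k - 2\ln L$ with $k$ counting every estimated coefficient
including the intercept; zero-variance or aliased columns are dropped and do
not count. Because all cluster strategies have the same number of exposure
columns, a lower AIC among them means more explained variation.

Patients who de-register from a contributing practice during follow-up are
excluded first (`apply_followup_exclusion()`), so every model sees the same
patients with equal follow-up; `compare_strategies()` additionally
guarantees a single retained-patient set and ordering across all
representation × outcome cells.

Fitting is plain maximum likelihood via iteratively reweighted least squares
(`stats::glm.fit`) with the convergence tolerance tightened
(`epsilon = 1e-12`, up to 100 iterations) so log-likelihoods are stable far
below the differences AIC comparisons care about. Standard errors come from
the inverse observed information. Separation is flagged (|coefficient| >
15), never corrected — with hundreds of rare binary predictors, occasional
extreme coefficients are expected and the flag tells you which odds ratios
not to over-read. Wald tests at the 0.05 level, unadjusted for multiplicity,
drive the `significant` labels downstream; absolute AIC values depend on
encodings and are only meaningful as orderings within one run.

## Within- versus between-cluster dispersion

If clusters were outcome-homogeneous, the member diseases of a cluster would
share similar adjusted odds ratios (aORs). `odds_ratio_table()` pairs the
count-strategy model (cluster-level aORs, interpreted per additional disease
in the cluster) with the disease-level model, and `dispersion_summary()`
computes, per cluster, the range (max − min) of member-disease log-aORs, and
compares the median of these within-cluster ranges against the range of the
cluster-level log-aORs. Ranges are taken on the log-odds scale so protective
and harmful effects are treated symmetrically; by construction the log-scale
range equals the log of the max/min aOR ratio, so nothing is lost relative
to an odds-ratio-scale reading. Both an all-diseases and a
significant-only variant are computed, since either convention is defensible
and they can disagree; clusters with fewer than two usable disease estimates
are excluded from the median with a warning.

Two precision safeguards matter here. Separation-flagged coefficients are
excluded from all ranges: their magnitudes are artefacts of quasi-complete
separation and a single one would dominate any range it enters. And the
all-diseases within-range always carries a sampling-noise floor set by the
least-informative member diseases — rare conditions with a handful of
outcome events have standard errors approaching 1 even in large cohorts, so
even perfectly homogeneous clusters show a positive estimated range. The
significant-only variant largely removes that floor (a noise-dominated
estimate rarely clears its own standard error), which is why the
homogeneous-cluster limit is cleanest in that variant.

## The synthetic cohort generator

Real primary-care EHR data of this kind is access-restricted, so the
package ships a generator (`sim_config()`, `make_catalog()`,
`simulate_cohort()`) that reproduces the statistical structure the analysis
depends on, with known ground truth:

* **Demographics.** Age ~ Normal(53, 18) truncated at 18; 53.1% female;
  ethnicity 86.2% in the reference category; IMD deciles with 52.3% in the
  five least-deprived — the published profile of the motivating cohort.
* **LTC count.** $L = 2 + \mathrm{NB}(\text{size}=3, \mu=6.5)$, giving
  quartiles exactly 5 / 8 / 11: a right-skewed count with median 8,
  guaranteed MLTC ($L \ge 2$). Counts above $D$ are capped with a warning.
* **Cluster-correlated co-occurrence.** Each patient draws a cluster
  propensity $\pi \sim \mathrm{Dirichlet}(\alpha \mathbf{1}_K)$ and then $L$
  distinct diseases without replacement with weight
  $\text{base\_prevalence}(d) \cdot \pi_{\mathrm{cluster}(d)}$. The single
  concentration $\alpha$ is the co-occurrence knob: small $\alpha$
  concentrates a patient's diseases in few clusters (more modal/majority
  structure), large $\alpha$ spreads them. The default $\alpha = 0.5$
  produces patients typically spanning several clusters with a substantial
  modal-tie rate, matching the qualitative assignment patterns reported for
  real data. Per-disease relative prevalences are log-uniform over two
  orders of magnitude — a modelling choice (real per-condition prevalences
  are not published at this granularity) that yields the realistic mix of
  common and rare conditions.
* **Onset ages.** Per-disease onset medians are uniform on 25–80 years and
  spreads on 8–15 years; each event's age at diagnosis is drawn from the
  corresponding normal truncated to (0, age at index]. Truncation uses
  exact inverse-CDF sampling (a uniform draw between the CDF bounds mapped
  through the normal quantile function): it is distribution-exact and has
  bounded cost even when the window is far in a tail, where
  accept-reject schemes stall; values are clamped only when the window has
  numerically zero probability mass. Onset is sampled independently of the
  outcomes given the disease set, since the onset analysis is descriptive.
* **Outcomes.** Each disease $d$ carries a log-odds contribution
  $\gamma_d = \mu_{c(d)} + \mathrm{Normal}(0, \tau)$ per outcome, with
  cluster means $\mu_c \sim \mathrm{Normal}(0, \sigma_b)$. Outcomes are
  Bernoulli on the logistic scale from a baseline logit (defaults: 3%
  death, 25% ED attendance, 15% emergency admission at reference
  covariates), linear covariate effects, and $\sum_{d \in S}\gamma_d$. The
  within-cluster heterogeneity SD $\tau$ (default 0.5) against the
  between-cluster SD $\sigma_b = 0.3$ is what makes within-cluster
  effect dispersion exceed between-cluster dispersion, as observed in real
  data; $\tau = 0$ produces perfectly outcome-homogeneous clusters and
  reverses the comparison. The true $\gamma_d$ are retained
  (`write_catalog_truth()`) for recovery checks.
* **Censoring.** De-registration is Bernoulli(0.049), independent of
  everything else — the published exclusion rate.

What the generator does **not** emulate: calendar time and coding-practice
artefacts (incentive-driven recording, free-text omissions), correlations
between demographics and *which* diseases a person has, order-of-onset
dependence between diseases, and informative censoring. Passing tests on
synthetic cohorts therefore demonstrate that the pipeline's statistical
machinery behaves as specified under the assumed generative structure — not
that any particular clinical finding transfers to a specific real dataset.

## Numerical and design choices

* **Medians** use the standard midpoint convention for even sample sizes.
  Cluster onset medians pool all member-disease events (event-weighted)
  rather than averaging per-disease medians: "median age at diagnosis of
  any disease in the cluster" is read as pooling, and the package keeps a
  per-disease table so the other convention is one `group_by` away.
* **Unassigned-LTC counts** are the patient's diseases lying in clusters
  not assigned to them; for the one-cluster strategies (modal, majority)
  this counts everything outside the single assigned cluster.
* **Duplicate diagnosis rows** collapse to the earliest age (the first
  recorded observation defines diagnosis); diagnoses after the index date
  are errors, not silently clipped.
* **Ages, not dates.** All analyses need only ages at index and diagnosis,
  so the tables store fractional years and synthetic data needs no
  calendar.
* **Problem sizes.** The replicated synthetic study used by the end-to-end
  checks runs 10 cohorts of 20,000 patients (212 diseases, 15 clusters,
  $\tau = 0.5$) for the AIC-ordering and dispersion findings, and one
  cohort of 80,000 for disease-effect recovery (correlation between fitted
  disease coefficients and generating $\gamma_d$, which exceeds 0.9 at that
  size). These sizes give stable orderings across seeds while keeping a
  full run in the minutes range on one core.

## A small worked run

```{r example, message = FALSE, warning = FALSE}
cfg <- sim_config(n_patients = 2000)
catalog <- make_catalog(cfg, seed = 1)
ch <- simulate_cohort(catalog, seed = 2)

counts <- cluster_counts(ch, catalog$map)
summarize_assignments(counts, seed = 3)

cmp <- compare_strategies(ch, catalog$map, seed = 3)
glance(cmp)

or_tab <- odds_ratio_table(
  comparison_fits(cmp, "death", "count"),
  comparison_fits(cmp, "death", "diseases"),
  catalog$map
)
glance(dispersion_summary(or_tab))
```

At this small size the orderings are noisier than in the replicated study,
but the moving parts are all visible: the assignment-pattern table, the AIC
comparison with its per-outcome verdicts, and the dispersion summary.

## Known limitations

* The disease-level reference model with hundreds of rare indicators can
  show separation for very rare disease–outcome pairs; flagged coefficients
  should not be interpreted, though AIC comparisons remain valid.
* Cluster-level aORs from the count model are per-additional-disease
  effects; comparing them with binary disease indicators mixes effect
  scales, which is inherent to the design being evaluated, not an artefact.
* The generator's single Dirichlet concentration cannot represent
  cluster-pair-specific co-occurrence (e.g. two clusters that co-occur more
  with each other than with the rest).
* Embedding-based person-level assignment (nearest cluster centroid in a
  disease-vector space) is out of scope.
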