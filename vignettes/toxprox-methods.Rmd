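---
title: "Methods: matched case-control analysis of industrial point-source emissions"
author: "toxprox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched case-control analysis of industrial point-source emissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Industrial facilities in the United States report chemical releases
annually to the EPA's Toxics Release Inventory (TRI); the Risk-Screening
Environmental Indicators (RSEI) model weights those releases by chemical-
and route-specific toxicity into a unitless *modeled hazard*. `toxprox`
implements a reusable pipeline for matched case-control studies that ask
whether residential proximity to such point sources is associated with
incident cancer (breast and lung in the motivating design): geospatial
exposure proxies from the facility records, three independent matching
strategies, conditional logistic regression (CLR), and a deliberately
conservative multiple-comparisons consensus rule. Because clinical tables
of this kind cannot be shared, the package ships a synthetic-data
generator with known ground truth, so every stage is testable end to end
and the pipeline's operating characteristics (bias, family-wise error,
power) can be measured rather than assumed.

## Exposure model

For participant $i$ with residence $r_i$ and visit year $v_i$, an
*exposure definition* is a cell of the grid
(agent $a$, metric, buffer $b$, lag $L$) with
$b \in \{2, 5, 10, 20\}$ km and $L \in \{1,\dots,5\}$ years — 3 metrics
$\times$ 4 buffers $\times$ 5 lags $= 60$ definitions per agent. Let
$S_i$ be the facility-year records of agent $a$ with reporting year in
$[v_i - L,\; v_i - 1]$ (whole calendar years strictly before the visit;
TRI reporting is annual) and great-circle distance
$d(r_i, f) \le b$. The three metrics are

* **presence**: $\mathbf{1}\{S_i \neq \emptyset\}$,
* **count**: number of distinct facilities in $S_i$ (a facility reporting
  in several window years counts once),
* **idw_hazard**: $\sum_{f \in S_i} h_f / \max(d(r_i, f), 0.1)^{\gamma}$,
  the inverse-distance-weighted modeled hazard $h_f$.

Distances are geodesic (haversine on a sphere of radius 6371.0088 km),
not planar projections, so the contract is scale-free. The 0.1 km floor
bounds the weight of co-located points: geocoding precision makes
sub-100 m distances unreliable. The weight exponent $\gamma$ defaults to
1 (plain inverse distance) and is exposed as a parameter, since nothing
deeper than convention selects it.

Analyses use only binary exposure contrasts. Presence is already binary;
a count column is coded $\mathbf{1}\{\text{count} \ge 2\}$ when at least
one participant has two or more in-buffer facilities and is otherwise
flagged redundant with presence (testing an identical column twice would
only inflate the correction factor); an IDW column is cut at the median
of its *positive* values over the pooled case + control dataset, computed
before matching, with strictly-greater coded as exposed. Definitions are
then passed through the prevalence filter: at least 10 exposed cases
**and** 10 exposed controls, evaluated on the binary coding (the stricter
of the two possible readings; for presence the two coincide). The 2 km
buffer stays in the grid even though it rarely survives the filter at
realistic facility densities.

The engine computes the whole grid in one compiled pass per agent and is
tested to be bit-identical to the plain per-participant reference
implementation (`computeExposure`), including the accumulation order of
the IDW sums; a coarse spatial shortcut that changed results in the last
bits would silently break that contract.

## Matching

Three matched control sets are built per cancer type, all without
replacement and with a default ratio of $k = 4$ controls per case (the
source design does not state its ratio; 1:4 is the conventional
efficiency point for case-control designs, and the ratio is a
parameter):

* **Nearest-neighbor** (greedy): cases processed in a fixed order
  (descending age, then id), each taking its $k$ nearest unused controls;
  ties broken by control id. Matching variables: age, sex, race, visit
  year.
* **Exact**: strata on the joint key of sex, race, visit year and age
  coarsened to 5-year bins (continuous age cannot match exactly; the bin
  width is a parameter). Controls in a stratum are dealt to that
  stratum's cases by a seeded draw, so every emitted set has exactly one
  case — this keeps the CLR likelihood in the same one-case-per-set form
  for all three methods. Cases in strata without controls are dropped
  with a warning.
* **Optimal**: minimum-total-distance assignment of $k$ distinct
  controls per case, solved exactly as a rectangular min-cost bipartite
  assignment (each case replicated $k$ times; shortest augmenting paths
  with dual potentials, implemented in C++ and tested against an
  exhaustive-permutation oracle). Matching variables add alcohol,
  tobacco and the standardized deprivation index.

The distance for the nearest-neighbor and optimal methods is Euclidean
over the continuous variables standardized by the pooled pre-match SDs,
plus a fixed penalty of 1000 per mismatched categorical variable. The
design names matching variables rather than a propensity model, so a
transparent composite distance is used instead of a fitted score; the
penalty effectively enforces categorical agreement whenever any
same-category control remains. Missing categorical values form their own
category; visit year is treated as continuous in the distance (and as an
exact key in exact matching). Balance is reported as standardized mean
differences (pooled pre-match SD) and per-level proportion differences,
with $|SMD| \le 0.1$ flagged — reported, never enforced.

## Conditional logistic regression

For matched sets $s$ with one case each, the conditional likelihood is

$$\ell(\beta) = \sum_s \left[ x_{\text{case}(s)}^\top \beta -
\log \sum_{j \in s} \exp(x_j^\top \beta) \right],$$

maximized by Newton-Raphson with step-halving; convergence when the
maximum absolute score falls below $10^{-8}$ or the relative
log-likelihood change falls below $10^{-12}$, capped at 100 iterations.
Sets without within-set exposure variation contribute a constant factor
and are retained (they do not bias the fit); their number is reported as
`n_informative`. Monotone separation is flagged at $|\hat\beta| > 15$ and
propagated as a non-evaluable result rather than numbers, as are
non-converged fits; a singular information matrix falls back to a
$10^{-8}$ ridge with a warning. Wald statistics are used throughout
($z = \hat\beta/\widehat{se}$, two-sided normal $p$, 95% intervals
$\exp(\hat\beta \pm 1.959964\,\widehat{se})$), matching the
per-coefficient framing of the volcano displays.

Nearest-neighbor and exact models adjust for alcohol, tobacco and the
deprivation index; optimal-matching models contain the exposure only,
because those covariates were matched on. Alcohol and tobacco are
dummy-coded with reference *never*; *unknown* is kept as an explicit
level because unknown strata are large in EHR data and dropping them
would discard most of it. The handling of unknown levels and reference
choices is not dictated by the source design; this is the package's
coding. Set-constant adjustment columns are inestimable under the
conditional likelihood and are dropped with a warning.

The fitter is validated three ways: the 1:1 exposure-only model equals
the discordant-pair closed form $n_{10}/n_{01}$ exactly; small designs
match an independent one-dimensional maximizer; and estimates, standard
errors and log-likelihoods agree with `survival::clogit` to $10^{-6}$,
which serves purely as a cross-check, never as the implementation.

## Inference

P-values are Bonferroni-adjusted within the family (agent, matching
method, cancer type), with the family size $m$ equal to the number of
*evaluable* definitions — those surviving the prevalence filter with an
"ok" fit. Counting only tested definitions is the stricter reading of a
per-tested-agent correction; the alternative (all 60 grid cells) is a
one-line change. A definition is **overall significant** only when its
adjusted p-value is below 0.01 under *all three* matching methods *and*
the direction of association agrees across them; the explicit direction
condition prevents declaring sign-discordant "consensus". Agent
summaries report, per agent and method, the percentage of evaluable
definitions that are significant with an odds ratio above 1, rounded
half-up to integers to match the usual printed format; agents with no
significant definition anywhere are omitted from the table. Volcano
exports use the natural log odds ratio on x and $-\log_{10}$ of the
adjusted p-value on y (the bases are recorded in the export metadata;
the threshold line sits at $-\log_{10}(0.01) = 2$).

## The synthetic generator

`simConfig()` encodes the study conditions the generator emulates, at
reduced scale:

* a ~260 km x 220 km mid-Atlantic bounding box; facilities uniform over
  it (an optional Gaussian-blob cluster mode mimics industrial
  corridors, since the true geography is not reproducible), reporting
  each calendar year from five years before the first visit year with
  probability 0.8, with lognormal(8, 2) annual modeled hazard — RSEI
  scores span orders of magnitude;
* visit years 2010-2023; 11 agents (antimony, arsenic, benzene,
  beryllium, cadmium, chromium, cobalt, ethylene oxide, formaldehyde,
  hydrazine, nickel); 25 facilities per agent by default, which puts
  presence prevalence at a few percent at 5 km — comparable to the
  motivating population — so that small buffers sit near the prevalence
  filter's boundary, as they do in real data;
* covariate category frequencies close to the control population of a
  large hospital EHR (sex 54/46, race 46/41/3/10, tobacco
  18/14/43/25 across current/past/never/unknown, and so on); a raw
  deprivation index standardized to mean 100, SD 20;
* case status drawn from
  $\text{logit}^{-1}(\beta_0 + \sum_e \beta_e z_{e}
  + \sum_c \gamma_c c)$, where $z_e$ is the any-in-buffer-facility
  indicator of each planted definition — for presence definitions this
  *is* the analysis coding, which makes parameter recovery well defined —
  and the default confounders are lifestyle indicators plus a per-point
  deprivation effect, centered at 100. Accrual continues until the exact
  case and control targets are met (1:4 by default) and fails loudly at
  a configured attempt cap.

Two modeling choices deserve explanation. First, age appears in the
configuration as separate case and control means (reflecting the large
age gap between cancer cases and primary-care controls) and is drawn
*conditional on realized status*: age cannot simultaneously drive the
logistic model and be set by it, and for a generator whose purpose is to
stress the matching stage, reproducing the marginal age gap is what
matters. Second, the emitted deprivation index is standardized against
the configured population parameters rather than the realized sample, so
accrual-time case probabilities are well defined and stages re-run
identically; `standardizeADI()` (sample mean, $n-1$ SD) remains the
operation for raw external inputs. All randomness flows from one master
seed through labeled sub-streams (facilities, participants, each
matching method), so stages can be re-run in isolation with identical
results. Ground truth stores the full-grid exposures computed by the
same engine the analysis uses, and the tests require recomputation from
the emitted tables to reproduce them bit for bit.

What the generator does **not** emulate: real city-level geography and
commuting, residential mobility over the lag window, spatial correlation
between deprivation and facility siting (the deprivation index is drawn
independently of location, so there is no built-in spatial confounding),
multiple visits per control, and exposure misclassification. Passing
tests therefore demonstrate that the pipeline's statistics behave as
designed under a known model — not that the epidemiological conclusions
of any particular dataset are correct.

## Calibration studies and problem sizes

The acceptance suite measures the pipeline's operating characteristics
at sizes chosen once as reduced-scale analogues of the motivating design
(control pools roughly 9x the cases, as in the source population):

* **Recovery**: 200 datasets of 500 sets (1 case + 4 controls), exposure
  prevalence 0.3, true OR 2.0, generated directly from the conditional
  model (`simulateMatchedSets`); the mean $\hat\beta$ must sit within 3
  Monte-Carlo SEs of $\log 2$ and 95% Wald coverage within
  $[0.91, 0.98]$.
* **Family-wise error**: 200 fully null end-to-end simulations (two
  agents, 100 cases, 900 controls, 25 facilities/agent); the share of
  seeds with any overall-significant definition for a given agent must
  not exceed 5% — the consensus rule is far more conservative than plain
  Bonferroni, and observed rates are near zero.
* **Power**: 100 end-to-end simulations with ethylene oxide planted at
  OR 2.5 on presence within 20 km (lag 3), 400 cases and 3600 controls
  with 60 facilities per agent so that 300+ cases are exposed; the
  planted agent must be overall-significant in at least 80% of seeds and
  dominate a null agent's summary percentages. The binding margin is the
  exact-matched analysis, whose strata thin out when control ages are far
  from case ages — exactly the regime the 9:1 pool is there to cover.

`scripts/acceptance.R` re-runs smaller versions of these studies (50
recovery replicates, 40 null seeds, 25 power seeds) from a command-line
seed and writes the measured quantities as JSON.

## Known limitations

Facility coordinates are taken per facility (sites are fixed; the
validator flags inconsistent coordinates across records). The optimal
method's caliper support is advisory only. Exact matching with
continuous covariates depends on the bin width, and its seeded
control-partition makes within-stratum allocation (not membership)
seed-dependent. The consensus rule is intentionally conservative; it
trades power for robustness to the choice of matching method, and the
power study above quantifies that trade at one design point only.
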