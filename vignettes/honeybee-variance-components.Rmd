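---
title: "Queen and worker effects: models, simulation design and estimation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Queen and worker effects: models, simulation design and estimation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beereml)
```

## The colony model and its simplifications

A honeybee phenotype is recorded per colony, not per individual. The colony
model (CM) splits the genetic contribution into a maternal queen effect and
a direct worker-group effect:

$$y_{iqw} = b_i + u^Q_q + \bar u^W_w + e_{iqw},$$

where $b_i$ is a year-by-apiary fixed effect, $u^Q_q$ the queen effect of
queen $q$, $\bar u^W_w$ the *average* worker effect of her worker group, and
$e_{iqw} \sim N(0, \sigma^2_E)$. The worker group's value is an average over
many related workers, so its variance is not $\sigma^2_{AW}$ but
$a_{ww}\,\sigma^2_{AW}$, with $a_{ww}$ the average additive relationship
between two workers of the colony. Under free mating with $n_d$ unrelated
drones, $a_{ww} = 1/4 + 1/(2 n_d)$ (7/24 for $n_d = 12$); station mating
with a sister group of drone-producing queens (DPQs) raises it to about
0.37.

Because CM fits often fail on sparse field data, practitioners fall back on
the queen model (QM) or worker model (WM), which assign the entire genetic
effect to one caste. The package implements the projection theory that
says what those simplified fits estimate when the data truly follow the CM.
A worker group inherits half its queen's worker effect plus the drones'
average ($\bar u^W_w = \tfrac12 u^W_q + \bar u^W_d$; no Mendelian sampling
term, because individual workers' sampling effects cancel in the average).
Substituting into the CM gives the projected components

$$\sigma^2_{A(QM)} = \sigma^2_{AQ} + \tfrac14 \sigma^2_{AW} + \sigma_{AQW},
\qquad
\sigma^2_{E(QM)} = (a_{ww} - \tfrac14)\,\sigma^2_{AW} + \sigma^2_E,$$

$$\sigma^2_{A(WM)} = \frac{\sigma^2_{AQ}}{4 a_{ww}^2} + \sigma^2_{AW}
 + \frac{\sigma_{AQW}}{a_{ww}}, \qquad
\sigma^2_{E(WM)} = \Bigl(1 - \frac{1}{4 a_{ww}}\Bigr)\sigma^2_{AQ}
 + \sigma^2_E,$$

with the phenotypic variance
$\sigma^2_P = \sigma^2_{AQ} + a_{ww}\sigma^2_{AW} + \sigma_{AQW} +
\sigma^2_E$ satisfying both decompositions
$\sigma^2_{A(QM)} + \sigma^2_{E(QM)} = a_{ww}\sigma^2_{A(WM)} +
\sigma^2_{E(WM)} = \sigma^2_P$. That identity also shows why the four
projected equations cannot be inverted for the four CM components: they are
linearly dependent. `projection_table()` evaluates all of this for the
eight standard traits (`bee_traits()`); the uncontrolled column only
reproduces at the exact $a_{ww} = 7/24 \approx 0.2917$, not at the rounded
0.29, so 7/24 is the package's canonical uncontrolled value.

The derivation assumes a queen's breeding value is independent of the
drones she mates with (no assortative mating) and that drone contributions
are independent across colonies. Station mating violates the second
assumption — queens visiting the same station share related drones — which
is exactly why simplified-model estimates drift upward there (see below).

## What the simulator emulates

`simulate_population()` follows the reference breeding scheme: each year a
cohort of queens is produced (year 1 is an unrelated base cohort drawn from
$G_0 = \begin{pmatrix}\sigma^2_{AQ} & \sigma_{AQW}\\ \sigma_{AQW} &
\sigma^2_{AW}\end{pmatrix}$), dams are sampled uniformly among two-year-old
queens (no directional selection), every queen mates once with $n_d = 12$
drones — either freely, with drone dams drawn (with replacement) from
queens aged 1–3, or on one of the year's mating stations, each carrying 8
sister DPQs whose shared dam is a three-year-old breeding queen — and each
queen heads one colony with one phenotype. Colonies are partitioned
randomly into equal-sized apiaries within years; each year-by-apiary pair
is one fixed-effect level, drawn $N(0, 1)$ by default (REML is invariant
to the values). With a proportion $0 < p < 1$ of controlled matings, an
exact-size random subset of each cohort visits stations. Queens live three
years, which is the minimal survival model consistent with all the age
requirements of the scheme. Phenotype records are deleted independently
with probability $1 - q$.

Three modelling choices deserve emphasis:

* **Gametic bookkeeping.** A drone is a single gamete of his dam and
  transmits it clonally. A gamete from a dam with diagonal relationship
  $a_{dd}$ carries $\tfrac12 u_{dam}$ plus a sampling term with covariance
  $(\tfrac12 - \tfrac14 a_{dd}) G_0$, so any gamete has unconditional
  covariance $G_0/2$. This is the unique scheme consistent with the
  worker-group inheritance identity, the queen/drone transmission rules,
  and $a_{ww} = 7/24$ for 12 unrelated drones.
* **Exactly Markovian inheritance.** Each daughter queen's paternal gamete
  is a *fresh* gamete from her recorded sire source (the station, or one
  recorded drone dam of the dam's mating) rather than a re-use of the 12
  realized drones shared with the worker group. Drone-level sharing
  (super-sister structure, sample covariance between a daughter and her
  mother's worker group, both of order $1/(2 n_d)$) is thereby averaged
  out — exactly as in the pedigree-based relationship matrix used for
  estimation, which cannot see individual drones either. The payoff is
  that the relationship matrix *equals* the generative covariance, which
  the test suite verifies by Monte-Carlo.
* **Realized drone samples.** The 12 drone gametic pairs of every mating
  are drawn explicitly, and the worker group value is literally
  $\tfrac12 u_q + \overline{g}$; the inheritance identity is assertable
  record by record.

What the simulator does **not** emulate: directional selection, pedigree
or phenotype errors, colony mortality or requeening, heterogeneous
variances, non-normal traits, genotype-by-environment effects, and
individual workers. Conclusions drawn from passing tests therefore speak
to the estimation machinery under the model's own assumptions, not to
robustness against real-data pathologies.

## The relationship matrix

`build_factorization()` represents A over queens, worker groups and
mating stations in triangular form $A = (I - C)^{-1} D (I - C)^{-T}$:
every entity is a linear combination of earlier entities plus an
independent term of variance $d_i$ (unit base variance). Worker groups get
coefficient 1/2 on the queen and either 1 on the station plus a
sample-averaging term $d = (\tfrac12 - a_{ss})/n_d$, or $1/(2 n_d)$ on
each recorded drone dam. Stations carry the mean gametic value of their
sister DPQ group: coefficient 1/4 on the DPQ dam plus the DPQs' paternal
side. The sparse inverse is $(I - C)^T D^{-1} (I - C)$ and
$\log|A| = \sum_i \log d_i$.

Pseudo sire-group rows of free matings are kept in the *pedigree* (they
record the realized drone-dam lists) but deliberately receive **no row of
A**: a node carrying the realized 12-drone mean would make the worker
row an exact linear combination ($d = 0$) and A singular, destroying the
sparse inverse and the mixed-model equations. With stations as the only
sire-side rows, every $d_i > 0$ and A is invertible for any mating mix;
a fully controlled 20-year, 500-queen population has 20,200 relationship
entities (10,000 queens, 10,000 worker groups, 200 stations).

Diagonals are carried exactly through the recursion, so inbreeding and
background coancestry accumulate. In small closed populations this drift
is substantial: the mean worker diagonal starts at the structural design
values (0.292 free mating, 0.370 station mating, both reproduced by
first-year cohorts) and rises over the years — noticeably so in the
scaled-down populations used for testing (tens of dams, two stations),
where station-lineage covariance compounds. The package reports the
realized values; analyses that want the structural regime constants (for
mixed-mating summaries, `effective_aww()` interpolates between 7/24 and
0.37) should use them explicitly.

Because the drone count of station matings is not recoverable from the
pedigree file, `build_factorization()` takes `n_drones` (and `n_dpq`) as
arguments defaulting to the study design's 12 and 8.

## REML estimation

`build_design()` assembles the response, the year-by-apiary incidence
(reduced to a full-rank column basis by pivoted QR; residual degrees of
freedom are $n - \mathrm{rank}(X)$) and the record-to-entity links; the
genetic effect vector spans all pedigree entities. The CM places one
2-by-2 genetic covariance matrix $G_0$ Kronecker the full A, with each
record loading the queen's Q effect and the worker group's W effect — this
is how $\mathrm{var}(\bar u^W_w) = a_{ww}\sigma^2_{AW}$ enters through the
A diagonal. The WM's genetic variance is therefore reported on the same
raw scale as the projection $\sigma^2_{A(WM)}$, and the plausibility
bounds are applied to that raw estimate.

Both algorithms iterate on the observation-space form
$V = \sum_{kl} g_{kl} M_{kl} + \sigma^2_E I$ with
$M_{kl} = Z_k A Z_l^T$ (submatrices of A over record-linked entities),
which is algebraically identical to the classical mixed-model-equation
updates but costs $O(n^3)$ in the number of records rather than entities:

* **EM**: $G \leftarrow G + G (Q - T) G / N$ with
  $Q_{rs} = y^T P M_{rs} P y$, $T_{rs} = \mathrm{tr}(P M_{rs})$ and $N$
  the number of entities, and
  $\sigma^2_E \leftarrow \sigma^2_E\, y^T P y / (n - \mathrm{rank}\,X)$.
  These are the standard conditional-expectation updates; the restricted
  log-likelihood is evaluated every iteration and its monotonicity is
  recorded on the fit object. No acceleration of any kind is applied.
* **AI**: Newton steps with the average-information matrix
  $\mathrm{AI}_{jk} = \tfrac12 y^T P V_j P V_k P y$, unconstrained in the
  components (out-of-range excursions are exactly what the downstream
  plausibility filter classifies), with step-halving whenever the step
  would decrease the restricted likelihood or make V indefinite. On
  convergence the predicted standard errors are
  $\sqrt{\mathrm{diag}(\mathrm{AI}^{-1})}$.

For the single-effect models a one-off eigendecomposition $M = U \Lambda
U^T$ diagonalizes V, making each iteration $O(n p^2)$.

Both algorithms use the squared relative parameter change
$\sum(\theta_{new}-\theta_{old})^2 / \sum \theta_{new}^2 < 10^{-12}$ as
the convergence measure (the convention of the widely used REML programs),
with iteration caps of 3000 (EM) and 1000 (AI). Starting values follow
the estimation study's design: the true generating components for the CM
and the projected variances (at the population's realized mean worker
diagonal) for QM/WM; `start_values()` builds them.

`restricted_loglik()` doubles as an independent oracle: the same value is
computed either from the dense V or through Henderson's mixed-model
equations with the sparse $A^{-1}$, using
$\log|V| = n\log\sigma^2_E + \log|G| + \log|C_{uu}|$ and
$\log|X^T V^{-1} X| = \log|C| - \log|C_{uu}|$; the test suite holds the
two routes to $10^{-8}$ agreement. `blup_solutions()` solves the same
equations for fixed effects and entity-level genetic predictions.

EM's numerical character deserves a note. Its per-iteration cost at the
scaled study size (1000 records) is about 0.13 s on one core and its
linear convergence rate near the optimum frequently needs thousands of
iterations at the $10^{-12}$ criterion, so a 20-replicate EM harness is a
multi-hour computation. The replicate-level acceptance checks therefore
run AI-REML, whose optimum EM provably shares (cross-algorithm agreement
is itself asserted on desk-scale instances); EM's correctness is pinned
by the likelihood oracle, the local-grid maximality of its fixed point,
its monotonicity, and the closed-form ANOVA solution of a balanced
half-sib design.

## Plausibility and evaluation

`plausibility()` applies the post-hoc filter: failure on non-convergence
within the per-algorithm caps, any variance estimate outside [0.01, 10],
or (CM only) an estimated queen-worker correlation outside [−0.99, 0.99].
`summarize_fits()` reports bias (mean deviation), realized standard error
(root-mean-square deviation) and mean AI-predicted standard error over
plausible fits, against the true components (CM) or the projected
variances (QM/WM) — the projections being the right reference is precisely
what the theory above establishes. `run_grid()` sweeps trait, mating rate,
apiary size and completeness cells with fully derived seeds.

Problem sizes in the test suite are the package's own scaled choices: a
10-year, 100-queen population (10 dams by 10 daughters, 2 stations,
preserving the design's ratios) for the parameter-recovery and
station-bias checks, and a 5-year, 200-queen population for the
free-mating projection check, where the theory's independence assumptions
require minimal background coancestry. Two desk-scale findings are worth
recording. First, with ten years of closed breeding at this size the
realized worker diagonals drift well above the structural 0.37, so
checks that expect the printed regime constant from a *mature* scaled
population will disagree with it — that is a property of exact coancestry
accounting, not an estimation error. Second, the station-mating biases of
the simplified models reproduce asymmetrically at this scale: the
residual-variance underestimation and the WM genetic-variance overshoot
are strong and systematic, while the QM genetic-variance overshoot is
small relative to desk-scale sampling noise (replicate standard deviations
of ~0.25–0.5 against a bias of a few hundredths) and so does not clear a
per-replicate-fraction test that a full-size study would.

## Numerical choices and degenerate inputs

Ties and edge cases are handled as follows: levels with a single record
are retained (their residual contribution enters via $n -
\mathrm{rank}\,X$); EM at a boundary (zero genetic signal) approaches the
boundary from inside and reports non-convergence if the criterion is not
met within the cap; AI failures (indefinite average information, failed
step-halving) are returned as flagged fits, never thrown, so grid runs
and the plausibility filter can treat failure as data. Relationship
construction refuses dangling references with the offending entity named,
and the dense expansion of A is size-guarded. Monte-Carlo comparisons in
the tests use three-standard-error bands with the 3-sigma band's own
false-positive allowance over thousands of entries.

## Known limitations

The package estimates single-trait, homogeneous-variance Gaussian models
only; threshold/Gibbs machinery, extra random effects, genomic
relationships and the worker-group-as-single-individual relationship
convention are out of scope. The drone pool of a station is treated as
effectively infinite (drones are sampled with replacement); mating
stations are regenerated each year. Scaled-down populations drift in
relatedness much faster than the full-size scheme, which must be kept in
mind when comparing desk-scale simulation summaries with full-scale
published values.
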