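---
title: "Conditional information-theoretic causality measures in ptenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional information-theoretic causality measures in ptenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Given a stationary multivariate time series in $K$ variables, we want the
directed network of *direct* interactions: for every ordered pair
$(X, Y)$, does the past of $X$ help predict the next value of $Y$ beyond
what the past of $Y$ and of the other $K-2$ variables $Z$ already tells
us?  Pairwise measures cannot separate direct from mediated influence;
conditional measures can, but must estimate information functionals in
spaces whose dimension grows with $K$ — the curse of dimensionality that
motivates everything below.

`ptenet` implements three conditional measures on a common estimation
backbone, plus simulators with known ground truth and an evaluation
harness, so the measures can be compared under controlled conditions.

## The measures

**PTE (uniform embedding).**  Every variable is represented by the delay
vector $\mathbf{x}_t = [x_t, x_{t-\tau}, \dots, x_{t-(m-1)\tau}]$, and

$$\mathrm{PTE}_{X \to Y | Z} = I(y_{t+1};\, \mathbf{x}_t \mid \mathbf{y}_t, \mathbf{z}_t),$$

with $\mathbf{z}_t$ the stacked delay vectors of all remaining variables
("full conditioning").  With $K = 2$ this is bivariate transfer entropy.
Significance: the raw source series is cyclically time-shifted (a random
rotation by $d \sim U[\lceil 0.05 n\rceil, \lfloor 0.95 n \rfloor]$,
which preserves its marginal and autocorrelation but destroys
cross-coupling), the measure is recomputed on each of `nsur` shifted
copies with all embeddings rebuilt, and the original value is ranked in
the ensemble; the one-sided p-value uses the rank correction
$1 - (r_0 - 0.326)/(M + 1 + 0.348)$.  Rank ties are broken uniformly at
random from the pair's seed substream.

**PTENUE (non-uniform embedding).**  Instead of fixed delay vectors, a
mixed embedding is grown greedily for each target from the candidate pool
$B = \{(v, \ell): v \le K,\ \ell \le L_{max}\}$: at each step the term
maximizing $I(y_{t+1}; w \mid \text{selected})$ enters, provided its
criterion exceeds the $(1-\alpha_{stop})$ nearest-rank percentile of
`nsur` surrogate criteria computed with that term's series time-shifted
(conditioning fixed).  The first rejection terminates the construction
(no second chances — it is a stopping rule), with a `max_terms` cap as an
engineering guard.  The measure for $X \to Y$ is
$I(y_{t+1}; w^X \mid w^{\setminus X})$ over the selected terms.  A link
is declared present when $w^X$ is nonempty *and* that final CMI survives
a link-level surrogate test: the source series is time-shifted, $w^X$
rebuilt, the conditioning fixed, and the link stands when the rank
p-value of the original CMI in the ensemble is at most $\alpha_{stop}$
(with $M = 100$ surrogates this requires the original to exceed every
surrogate value, a test whose realized level matches the nominal
$\alpha_{stop} = 0.01$).  The
link test matters because the stopping rule examines the per-step
*maximum* over the candidate pool: even at $\alpha_{stop} = 0.01$ per
candidate, the best of $\sim\!|B|$ null criteria clears its own threshold
in a nontrivial fraction of embeddings, admitting marginal junk terms
(visible in selection traces as admissions at criterion values two orders
of magnitude below the genuine terms).  Pruning those at the link level
restores the measure's specificity without touching its sensitivity —
genuine links carry CMI far above the surrogate range.  One embedding per
target serves all $K-1$ driver queries.

**LATE (low-dimensional approximation).**  Same greedy scheme, but each
step's high-dimensional CMI is replaced by sums of 2- and 3-dimensional
terms patterned on the chain rule
$I(y_{t+1}; w \mid V) = I(y_{t+1}; w) - I(w; V) + I(w; V \mid y_{t+1})$:

$$s(w) = I(y_{t+1}; w)\;-\;\frac{2}{|V|}\sum_{w_i \in V} I(w; w_i)\;+\;\frac{2}{|V|}\sum_{w_i \in V} I(w; w_i \mid y_{t+1}),$$

with both sums zero at the first step.  The stopping surrogates use the
same approximation, at their own level `la_alpha_stop` (default 0.05,
looser than the CMI-based rule's 0.01): the pairwise approximation
understates weak synergistic contributions relative to its surrogate
threshold, and at a stringent level the scheme stops before weak drivers
are ever examined.  The final LATE value is the full CMI on the selected
embedding — the embedding is low-dimensional by construction, so there is
no reason to approximate the final value too — and a link is declared
exactly when $w^X$ is nonempty, with *no* link-level pruning.  The
asymmetry with PTENUE is deliberate: the LA selection tends to over-admit
terms, whose accumulated conditioning dilutes any downstream CMI test
into uselessness, and the unpruned reading is what produces LATE's
characteristic operating profile — the highest sensitivity and the lowest
specificity of the three measures, including spurious links on the linear
benchmark.

### Design choices in the LA criterion

How such criteria are written varies across the feature-selection
literature, and two points were genuinely open:

* *Sign of the conditional-redundancy sum.*  The default **adds** it, as
  the chain-rule identity requires: $I(w; V \mid y_{t+1})$ measures
  synergy, the part of $w$'s contribution that only appears once the
  target's future is known, and it is exactly how a multiplicative
  coupling (as in the Hénon lattice) becomes visible to pairwise terms.
  The subtractive reading (`la_cond_sign = "subtract"`) is kept as a
  switch; in practice it stops selection almost immediately after the
  first strong term, because every further candidate is doubly penalized
  while its time-shifted surrogates are not, and the measure loses nearly
  all sensitivity on the chaotic benchmarks.  That qualitative collapse —
  not a tuning preference — is why the additive form is the default.
* *What the redundancy sums range over.*  The default sums over the
  already selected set $V$ with weight $2/|V|$; summing over the whole
  candidate pool with weight $2/|B|$ (`la_sum_over = "all"`) makes the
  penalty nearly constant across steps and is kept only for sensitivity
  analysis.
* *Stopping level.*  `la_alpha_stop = 0.05` as above; the CMI-based
  stopping and the link test keep `alpha_stop = 0.01`.

These choices were fixed by their qualitative behavior on the benchmark
systems (a criterion variant that strips a measure of essentially all
sensitivity, or of all specificity, cannot be the intended reading), not
by tuning toward any particular score; the switches remain available so
users can examine the alternatives.

## Estimation backbone

All information functionals are estimated with k-nearest-neighbor
estimators under the maximum norm, in nats, shared-$\epsilon$ convention:
for each point, $\epsilon$ is the distance to its $k$-th neighbor in the
full joint space (self excluded), and each projected subspace counts
neighbors with strict inequality $< \epsilon$:

* mutual information (KSG): $\psi(k) + \psi(N) - \langle \psi(n_x+1) + \psi(n_y+1) \rangle$;
* conditional mutual information (Frenzel–Pompe):
  $\psi(k) - \langle \psi(n_{xz}+1) + \psi(n_{yz}+1) - \psi(n_z+1) \rangle$.

With an empty conditioning block the second form reduces *exactly* to the
first (the conditioning distances are identically zero), and the package
uses a single code path for both.  Estimates are not clipped at zero:
small negative values on independent data are normal, and every decision
in the package is made against surrogates, never against zero.

Numerical choices:

* **Standardization.**  All series are z-scored before any distance
  computation, so the maximum norm weighs heterogeneous variables
  comparably.  A constant column is an error, reported by name.
* **Tie-breaking jitter.**  Deterministic seeded jitter, uniform with
  magnitude $10^{-10}$ standard deviations per coordinate, is added once
  per analysis.  Deterministic maps can emit exactly repeated values;
  jitter makes neighbor ranks unique while perturbing estimates only at
  the $10^{-10}$ level, and being seeded it keeps runs reproducible.
* **Greedy ties** are broken toward the lowest lag, then the lowest
  variable index (parsimony); exact criterion ties essentially never
  occur on continuous data.
* **Percentile rule.**  Surrogate thresholds use the nearest-rank
  $(1-\alpha)$ quantile (sorted value at index
  $\lceil (1-\alpha) M \rceil$): conservative, distribution-free, and
  exact for the discrete $M = 100$ ensembles used here.
* **Degenerate inputs** (too-short series for the requested embedding,
  constant columns, missing cells in files) raise descriptive errors
  rather than propagating NaNs.

Defaults ($k = 10$, `nsur` $= 100$, $\alpha_{test} = 0.05$,
$\alpha_{stop} = 0.01$, $\tau = 1$) follow standard practice for these
estimators; $k$ has little influence on the KNN estimator, and the
package's test suite checks that directly.  $m$ should be set to the
maximum generating delay when known (the benchmark systems use 5, 1, 2);
$L_{max} = m + 1$ is sufficient, and enlarging it further changes results
only through computational cost.

## Seeding contract

One integer seed governs an entire analysis.  It is expanded by a
deterministic integer hash into substreams per purpose ("jitter", per
ordered pair for PTE surrogates, per target and step for embedding
stopping, per realization for benchmarks).  Consequently results are
bit-identical across reruns, independent of the order in which pairs are
evaluated, and identical between a network call and the corresponding
single-pair call.  Execution is serial; the substream design means a
parallel scheduler could be added without changing any number.

## The benchmark systems

* **S1** — linear VAR of order 5 in 4 variables, unit-variance Gaussian
  innovations, links X1→X3, X2→X1, X2→X3, X4→X2.  Linear ground truth
  for nonlinear measures; covariance-stationary (companion spectral
  radius < 1, asserted in the tests).
* **S2** — nonlinear VAR of order 1 in 3 variables built on the bounded
  map core $3.4x(1-x^2)e^{-x^2}$ with innovations scaled by 0.4; links
  X1→X2, X1→X3 (nonlinear) and X2→X3 (linear).  The self-term of the
  third equation is written with an inconsistent subscript in some
  statements of this model; the package uses the standard form (self-term
  in $x_{3,t-1}$ plus $0.3x_{2,t-1} + 0.5x_{1,t-1}^2$).
* **S3** — $K$ coupled Hénon maps: end maps autonomous, each interior
  map driven by both neighbors with strength $c$ through the product term
  $0.5c\,x_{i-1,t-1}x_{i+1,t-1}$; truth has $2(K-2)$ links.  Initial
  pairs are drawn from $U(-0.5, 0.5)$ — inside the attractor basin with
  overwhelming probability — and a diverging trajectory ($|x| > 10$)
  triggers a redraw from an incremented sub-seed, erroring after 100
  attempts.  A burn-in of 1000 samples (all systems) comfortably exceeds
  every memory depth and transient.

What the generators emulate is the *stationary, noise-free-observation*
regime: no missing data, no measurement noise on the chaotic system, no
drift or regime switching.  Passing benchmarks therefore demonstrates
correct recovery under the stated dynamics, not robustness to the
artifacts of real recordings; the delimited-text front end applies the
same measures to real data, where those caveats apply.

## Evaluation

Estimated adjacencies (rows drive columns) are scored over the
$K(K-1)$ ordered off-diagonal pairs: sensitivity $TP/(TP+FN)$,
specificity $TN/(TN+FP)$, F1 $= 2TP/(2TP+FP+FN)$, as percentages.
Monte-Carlo summaries average per-realization percentages (not pooled
counts); grand summaries additionally average over series lengths.  A
truth with no links (or none absent) leaves a rate undefined and is
rejected rather than silently scored.

## Problem sizes used by the shipped checks

The full comparative study (100 realizations x 5 lengths x 3 measures)
is an overnight computation.  The package's own checks reproduce selected
cells at reduced Monte-Carlo size, chosen once as a sensible
precision/effort trade-off: the acceptance script runs S1/PTENUE at
$n = 1024$ with 10 realizations, S2/PTE at $n = 1024$ with 20, S3
($K=9$, $c=0.3$) PTE at $n = 256$ with 15, and S3 ($K=9$, $c=0.1$) PTE
at $n = 1024$ with 10; the test suite checks the saturated S3 ($K=3$,
$c=0.3$, $n=1024$) PTENUE cell with 20 realizations and the weak-coupling
contrast between PTE and LATE with 3 and 1 realizations respectively.
At these sizes the binomial standard error of a percentage near the
interior is a few points, matching the tolerances the checks assert.

## Known limitations

* The KNN engine is exact brute force, $O(N^2)$ per information term
  per surrogate, with $O(N^2)$ cached distance rows in the batch paths;
  memory grows to a few hundred MB around $n = 4096$ and practical
  runtime ends near there.  The estimator itself is standard; only its
  batching is bespoke.
* Horizon is fixed at one step; sampling must be regular; missing values
  are rejected, not imputed.
* PTE's full conditioning degrades with $K$ by construction — that
  failure mode is a subject of study here, not a defect; use PTENUE for
  systems beyond a handful of variables.
* The stopping rule tests the *best* candidate per step; because of that
  selection bias the per-step false-inclusion rate exceeds
  $\alpha_{stop}$ (the calibration test in the suite checks a fixed null
  candidate, which is exact).  PTENUE's link-level test absorbs the
  excess; LATE, which has no pruning, inherits it as reduced specificity.
* LATE is a reconstruction from an ambiguously printed criterion; its
  absolute scores on weakly coupled systems are the least certain of the
  three measures (the comparative ordering — more sensitive and less
  specific than PTENUE, far more robust than PTE in high dimension — is
  stable across the criterion variants exposed in the configuration).
* No multiple-testing correction is applied across the $K(K-1)$ pairs;
  rejection rates are interpreted per direction at fixed $\alpha$.

## A minimal session

```{r, eval = FALSE}
library(ptenet)

sim <- simulate_s3(K = 3, c = 0.3, n = 1024, seed = 1)
cfg <- analysis_config(m = 2, Lmax = 3, seed = 1)

net <- ptenue_network(sim$series, cfg)
net
confusion_counts(significant_adjacency(net), sim$truth)

# audit one target's embedding
net$embeddings[["X2"]]
embedding_report(net$embeddings[["X2"]])
```
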