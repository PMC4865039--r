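---
title: "Regulation-pattern-guided network inference: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regulation-pattern-guided network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpni)
```

## The problem and the model

Given steady-state expression measurements for $n$ genes across $m$ samples,
the package estimates the undirected skeleton of the gene regulatory network:
which pairs of genes are directly coupled, as opposed to merely correlated
through shared regulators or regulatory cascades.

All dependence measures assume the expression vector is multivariate
Gaussian, so every quantity reduces to determinants and blocks of the sample
covariance matrix (unbiased, divisor $m-1$).  In nats:

* entropy: $H(X) = \tfrac{d}{2}\log(2\pi e) + \tfrac12 \log|C|$;
* mutual information:
  $\mathrm{MI}(X,Y) = \tfrac12 \log\frac{|C(X)|\,|C(Y)|}{|C(X,Y)|}
  = -\tfrac12\log(1-\rho^2)$ for a bivariate pair with correlation $\rho$;
* conditional MI:
  $\mathrm{CMI}(X,Y\mid Z) = \tfrac12 \log
  \frac{|C(X,Z)|\,|C(Y,Z)|}{|C(Z)|\,|C(X,Y,Z)|}$, kept as a comparison mode
  (`measure = "cmi"`).

### CMI2: averaged interventional divergences

CMI underestimates regulatory strength in some configurations, so the
primary dependence measure is CMI2 (conditional mutual *inclusive*
information).  Its definition, for an edge $(X, Y)$ given conditioning genes
$Z$, is the average of two Kullback–Leibler divergences between the joint
density $p(x,y,z)$ and two *interventional factorizations*:

$$
q_1(x,y,z) = p(x,z)\int p(y\mid x',z)\,p(x')\,dx', \qquad
q_2(x,y,z) = p(y,z)\int p(x\mid y',z)\,p(y')\,dy',
$$
$$
\mathrm{CMI2}(X,Y\mid Z) = \tfrac12\left[ D_{KL}(p\,\|\,q_1) +
D_{KL}(p\,\|\,q_2) \right].
$$

In $q_1$ the dependence of $Y$ on its putative input $X$ is severed by
averaging the conditional over the input's marginal (a do-operation), while
the dependence on $Z$ is retained.  CMI2 is symmetric in $X$ and $Y$,
nonnegative, zero exactly when $X \perp Y \mid Z$, and coincides with MI
when $Z$ is empty.

Under the Gaussian model both $q_1$ and $q_2$ are again Gaussian and the
divergences have closed forms, which we derive by regression algebra: write
the conditional $Y \mid X,Z$ as $Y = aX + b^\top Z + \varepsilon$ with
residual variance $s$.  Averaging over $X\sim p(x)$ yields, under $q_1$,
$Y = b^\top Z + \varepsilon'$ with
$\operatorname{Var}\varepsilon' = s + a^2\operatorname{Var}X$, independent of
$X$ given $Z$; assembling the implied covariance matrix $\Sigma_{q_1}$ and
applying the Gaussian KL formula
$D_{KL} = \tfrac12(\operatorname{tr}(\Sigma_q^{-1}\Sigma_p) - d +
\log|\Sigma_q| - \log|\Sigma_p|)$ gives the estimator implemented in
`cmi2()`.  The derivation is validated in the test suite against a
Monte-Carlo oracle that draws $10^6$ samples from the fitted joint and
evaluates the interventional densities pointwise by quadrature — a route
that shares none of the closed-form algebra.

### Candidate patterns and direction hints

The path-consistency (PC) loop must choose which genes to condition on for
each edge.  Conditioning sets are restricted to the edge's *common
neighbors* that instantiate one of three biological patterns:

* **co-regulation** — a gene $A$ upstream of both endpoints (single-input
  module): conditioning on $A$ removes the spurious dependence between its
  co-targets;
* **indirect regulation** — a cascade $i \to A \to j$ (regulator chain):
  conditioning on the intermediate removes the indirect dependence;
* **mix** — a neighbor playing both roles.

Orientation evidence comes from knockout (null-mutant) compendia.  For each
knockout strain (gene $k$ deleted) and readout gene $g$, the z-score
$z = (x_{g,\Delta k} - \mathrm{wt}_g)/\hat\sigma$ is compared to a two-sided
normal threshold at level $\alpha$ (default 0.05, no multiple-testing
correction); significant shifts yield the ordered hint $k \to g$ — deleting
$k$ moved $g$, so $k$ acts upstream.  Note the causal reading: the
differential readouts of a knockout are its *downstream* targets.

Two design points deserve emphasis:

1. **The z-test scale.**  With one profile per strain, a per-gene spread
   across strains is not a noise estimate: a gene downstream of several
   regulators is genuinely shifted in most strains, so both the plain
   standard deviation and the per-gene MAD absorb the regulatory signal and
   mask true regulations (we measured recovery of true adjacent-pair
   regulations collapsing from ~0.96 to 0.27 with a plain per-gene sd).
   The package instead estimates a single noise scale robustly across the
   whole compendium, $\hat\sigma = 1.4826 \cdot
   \operatorname{median}|x - \mathrm{wt}|$ over all gene-strain cells,
   under the sparsity assumption that most cells are unperturbed.  The cost
   is the homoscedasticity assumption: for strongly heteroscedastic real
   data the test is approximate, and hints should be treated as a candidate
   filter, not as significance statements.
2. **Per-neighbor fallback.**  A common neighbor with *no* orientation
   evidence at all is admitted as a candidate under
   `fallback = "neighbors"` (with no knockout data this reduces to
   classical neighborhood conditioning, the PC-over-CMI scheme); a neighbor
   with partial evidence that completes no pattern is excluded — that
   exclusion is precisely how pattern guidance prunes the search space.

### The edge-thinning loop

`rpni()` starts from the complete graph.  At order 0 every pair's MI is
computed and edges with $\mathrm{MI} < \theta$ are deleted.  At order
$L \ge 1$, for each surviving edge with $T \ge L$ candidates, all
$\binom{T}{L}$ size-$L$ candidate subsets are scored and the edge is deleted
iff the *maximum* score is below $\theta$; edges with $T < L$ are skipped.
The loop stops after the first pass that deletes nothing (including the case
that no edge has enough candidates).  Deletions act on a live graph within a
pass; edges and subsets are enumerated in lexicographic gene-id order, so
inference is deterministic.  The worst-case number of dependence
evaluations is bounded by $n^2 (n-1)^{k-1}/(k-1)!$ for maximal degree $k$
(`cmi2_call_bound()`), which the recorded trace never exceeds.

Reported edge strengths are the minimum over orders of the evidence that
retained the edge (its MI at order 0, its maximal CMI2 at each later order)
— the binding, weakest link.  The output is undirected; the method does not
orient edges.

**Resolved ambiguities** (decided here, documented as package choices):
order 0 uses MI, which coincides with CMI2 under empty conditioning in the
Gaussian model; the "stop when $T < L$" rule is read per-edge, with global
termination only when no surviving edge can be tested — a literal global
stop on the first starved edge would make results depend on edge order; a
deleted edge immediately stops contributing common neighbors (live graph),
mirroring reference PC implementations; in the bivariate MI formula the
product in the numerator is $|C(X)|\cdot|C(Y)|$ — the only reading
consistent with the entropy identity $\mathrm{MI} = H(X)+H(Y)-H(X,Y)$ and
the $-\tfrac12\log(1-\rho^2)$ closed form.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `theta` | 0.03 ($n \le 20$), 0.05 otherwise | nats | deletion threshold; the defaults are the benchmark operating points for ~10- and ~50-gene data |
| `alpha` | 0.05 | level | two-sided z-test level for direction hints |
| `fallback` | `"neighbors"` | — | candidate policy without orientation evidence |
| `max_order` | unbounded | — | safety cap on the conditioning order |
| `measure` | `"cmi2"` | — | dependence measure at orders $\ge 1$ |

Because MI/CMI2 are plug-in functionals of the sample covariance (divisor
$m-1$), $\theta$ is comparable across sample sizes, but small-$m$ estimates
are noisy: at $m \approx 11$ (a 10-gene null-mutant compendium) the
plug-in MI of an independent pair has expectation $\approx 1/(2m) \cdot
\mathrm{dof}$, which is close to $\theta = 0.03$ — the threshold choice
absorbs that bias.

## The synthetic-data generator

`simulate_network()` draws a DAG whose gene indices are the topological
order, plants the requested single-input modules and regulator chains, and
fills to the target density (default 0.2) with random forward edges.
Effects are $\pm\mathrm{U}(0.5, 1.5)$, structural noise is
$\mathrm{N}(0, 1)$ per gene, and each gene has a basal level
$\mathrm{U}(1,3)$, raised in topological order where necessary so every
steady-state mean is at least 0.5 — expression levels are concentrations,
and a regulator silenced by signed-effect cancellation would make its own
knockout undetectable for reasons that have nothing to do with the
detector.  Basal levels shift only means, never the covariance the
inference consumes.

`simulate_steady_state()` samples the linear-Gaussian structural equations;
`simulate_knockouts()` produces the null-mutant layout (wild type = exact
structural means; each mutant = interventional means with the deleted gene
clamped to 0, plus observation noise).  `corrupt_expression()` implements
the three robustness noise models: per-gene Gaussian noise with variance
equal to the gene's own sample variance (doubling it in expectation),
outlier replacement of a fraction (default 1/10) of cells by draws from the
global mean/variance, and position permutation of a fraction of cells
(value-conserving; a swap variant is available behind `mode = "swap"`).

What the generator emulates: steady-state, interventional, approximately
Gaussian expression with motif structure.  What it does not: kinetic/ODE
dynamics, feedback loops (the DAG constraint), mRNA-count noise models,
heteroscedastic measurement error, or the actual generative process behind
the public DREAM benchmarks.  Passing the recovery tests therefore
demonstrates correctness of the estimators under their own assumptions, not
performance on real compendia.

## Evaluation protocol

Evaluation is over unordered pairs: gold standards (directed, DREAM-style
3-column edge lists) are collapsed to undirected presence by OR across
directions, because the method's output is undirected — the four confusion
counts then always partition the $\binom{n}{2}$ pair universe.
`grn_metrics()` reports TPR, FPR, PPV, ACC and MCC, with zero-denominator
metrics returned as `NA` (undefined) and MCC set to 0 by convention when a
factor of its denominator vanishes.

The ROC (`roc_sweep()`) traces the algorithm's *binary decisions* as
$\theta$ sweeps from near 0 to infinity — each operating point is a full
inference run — with anchors $(0,0)$ and $(1,1)$ and trapezoid AUC over
unique FPR (maximal TPR per FPR).  This matches the method's own
benchmarking protocol; a conventional strength-ranking AUC is available
separately as `ranking_auc()` and labeled as such.  Exact AUC values are
grid-dependent, so cross-study comparisons should fix the grid.

`robustness_experiment()` repeats the sweep (default 10 times) under each
noise model and aggregates per threshold: mean FPR, median TPR, and the
TPR spread for box-and-whisker overlays.

## Problem sizes and numerical choices

The shipped tests and the reproduction script run at desk scale, chosen as
the smallest sizes at which the statistical claims are stable: 10-gene
networks at density 0.2 with $m = 500$ samples and 20 seeds for recovery;
10 repeats at $m = 200$ for robustness; $10^6$ Monte-Carlo draws per
covariance for the CMI2 oracle; 50 random SPD covariances for the entropy
identity.  Determinants go through LU factorization with a hard floor
(determinant $\le 10^{-300}$ raises a singular-covariance error rather than
returning infinities); dependence values are clamped at 0 and a negative
value beyond $-10^{-9}$ is treated as an error; candidate subsets whose
covariance blocks are singular are skipped with a warning and do not
contribute to the max.  Ties in the argmax subset go to the first subset in
lexicographic enumeration (this affects only trace reporting, not
deletions).

## Known limitations

* **The max rule caps recall of conditional independences.**  An edge is
  deleted only if *every* size-$L$ candidate subset scores below $\theta$.
  Conditioning sets containing colliders or partial separators can keep the
  maximum above threshold even when a separating set exists.  On our
  simulated benchmark (10 genes, density 0.2, $m = 500$, $\theta = 0.03$)
  the median MCC across 20 seeds is ~0.75, while an oracle that deletes on
  the *minimum* over subsets reaches ~0.86 on identical data; threshold
  sweeps nonetheless give median AUC > 0.95.  This is a property of the
  decision rule itself, faithfully implemented.
* With a single profile per knockout strain, direction hints depend on the
  homoscedastic-noise assumption described above.
* The Gaussian closed forms capture only linear dependence on real
  (non-Gaussian) data, and the output carries no edge directions.
* Global threshold monotonicity across orders is not guaranteed: raising
  $\theta$ changes the surviving graph and with it the candidate sets of
  later orders (order-0 edge sets are nested in $\theta$, and this is
  tested).

## Reproducing the published-scale benchmarks

The public DREAM3 null-mutant benchmarks (10- and 50-gene Yeast
subnetworks) are not redistributed with the package.  With the challenge
files in hand the workflow is: read the strains-by-genes table with
`read_expression(file, dialect = "dream3_null_mutants")`, the gold standard
with `read_gold_standard()`, run `rpni()` at $\theta = 0.03$ (size 10) or
$0.05$ (size 50), and score with `confusion()`/`grn_metrics()` and
`roc_sweep()`.  The shipped `scripts/acceptance.R` reproduces everything
that does not require those external files.
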