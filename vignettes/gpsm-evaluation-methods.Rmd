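---
title: "Evaluating generative protein sequence models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating generative protein sequence models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gpsmeval)
```

# The problem

A generative protein sequence model (GPSM) learns a probability
distribution $P(S)$ over aligned sequences of a protein family and emits
new synthetic sequences. Judging whether a GPSM has captured the
*biophysical* constraints of the family — rather than artifacts of how the
training alignment was assembled — requires two ingredients this package
provides:

1. **Phylogenetic corrections.** Real alignments contain clusters of
   recently diverged sequences. Such clusters inflate the apparent
   covariation between columns: if an ancestor carried residues (R, Q) at
   two positions, its many near-copies all carry (R, Q), and the excess
   joint count looks like an interaction even on a flat fitness
   landscape. Identity filtering (iteratively dropping one member of any
   pair above an identity threshold) removes this redundancy, and a
   phylogeny-aware split keeps residual relatives on one side of the
   training/reference divide.

2. **Higher-order marginal statistics.** Pairwise frequencies are easy to
   match; chains and networks of interactions show up only in the joint
   frequencies of *words* — the states of a sequence at $n$ chosen
   columns. The r20 statistic measures how well a model reproduces these.

# Models

## Potts model

The Potts model assigns
$P(S) \propto \exp(-E(S))$, $E(S) = \sum_{i<j} J^{ij}_{s_i s_j}
(+ \sum_i h^i_{s_i})$,
with a $q \times q$ coupling block per column pair ($q = 21$: 20 amino
acids plus gap, or a reduced alphabet for fast experiments). Couplings are
defined up to gauge transformations; `zero_sum_gauge()` converts to the
conventional normal form (zero row/column means per block, single-site
parts absorbed into explicit fields) without changing probabilities, so
coupling matrices from different fits are comparable.

`fit_potts()` implements the marginal-matching (Boltzmann-machine)
maximum-likelihood condition: at the optimum the model's bivariate
marginals equal the pseudocounted training marginals, and the gradient of
the log-likelihood in $J^{ij}_{\alpha\beta}$ is
$f^{model} - f^{data}$. Two gradient back-ends:

* **enumeration** — for $q^L \le 10^5$ the partition function and exact
  model marginals are computed by enumerating all sequences; gradient
  ascent with backtracking drives the mean absolute marginal deviation
  below $10^{-6}$. This back-end doubles as the oracle against which the
  stochastic machinery is validated.
* **mcmc** — persistent-chain estimation: a population of Metropolis
  chains is advanced a few sweeps per iteration and its empirical
  marginals provide the stochastic gradient. A search phase stops at 3×
  the chain population's finite-sampling noise floor; a refinement phase
  then quadruples the population, decays the step size
  (Robbins–Monro), and returns tail-averaged couplings.

**Pseudocount.** Scale $s$ adds $sN$ uniform pseudo-observations:
$f \leftarrow (1-w) f_{emp} + w\,u$, $w = sN/(N+sN)$, with $u = 1/q$ or
$1/q^2$ blended consistently at both orders so bivariate tables always
marginalize to the single-site frequencies. The conventional default for
fitting is $s = 1/N$ (one pseudo-observation, $w = 1/(N{+}1)$), which also
guarantees the strictly positive bivariate marginals that coupling
inference needs.

**Regularization.** `fit_potts(l2 = ...)` exposes an optional ridge
penalty on the couplings; the default is off. We probed the default by
parameter-recovery quality on synthetic landscapes with known couplings
(correlation between fitted and true zero-sum couplings at
$N = 10^4$–$5\times10^4$): recovery was insensitive to mild ridge values
and degraded for strong ones, because the penalty's stationary condition
$f^{model} = f^{data} + \lambda J$ distorts exactly the strongly coupled
marginals. With no evidence of benefit the penalty stays off by default; the
option remains available for ill-conditioned data.

**Fields.** Fits are fields-free by default (with couplings on every pair
the fields are gauge-absorbable); the zero-sum gauge applied to the
returned model reconstructs explicit fields. Synthetic landscapes from
`random_potts()` can carry explicit Gaussian fields (`field_scale`),
because landscapes distilled from natural alignments are strongly
field-rich: natural residue usage per column is far from uniform, and
this dominates low-order word statistics.

## Site-independent model

`fit_independent()` stores the (optionally pseudocounted) single-site
frequencies; sampling draws columns independently. All of its connected
correlations vanish by construction, which makes it the baseline that any
covariation-sensitive metric must separate from a coupled model.

# Metrics

## r20

For each order $n$ (default 2–8), `n_sets` random column sets are drawn
(default 3000). Per set, the `top_k` (default 20) most frequent words in
the *reference* MSA are located — ties at the boundary broken by
lexicographic word order so results are reproducible — and the Pearson
correlation between the reference and evaluation frequencies of those
words is computed. The per-order mean over retained sets is r20. Sets
where either frequency vector is constant are skipped and counted
(`n_skipped`), never averaged as `NaN`. Words may contain the gap state;
`exclude_allgap` optionally removes the all-gap word.

Position sets can be drawn once (`position_sets()`) and shared across all
model arms of an experiment, so model comparisons are paired rather than
independently noisy; `run_experiment()` always does this.

## Null model

`null_r20(training, reference)` scores the training MSA itself in the
evaluation role. A well-specified model whose only error is finite
sampling cannot beat this curve; it falls with order (word frequencies
shrink, relative sampling error grows) and rises with MSA depth. Note a
subtlety of the matched-size design (training, reference, and evaluation
MSAs all of size $N$): even an *exactly* converged refit carries the
training MSA's sampling noise in its marginals, and its finite evaluation
sample adds an independent noise of the same size, so the refit's
expected r20 sits slightly below the null —
$r_{refit} \approx r_{null}\,\sqrt{(S+\sigma^2)/(S+2\sigma^2)}$ for
signal variance $S$ and per-word sampling variance $\sigma^2$. The
deficit vanishes as $N$ grows or as the model generalizes (regularization
pulls fitted marginals off the training noise toward the underlying
distribution), which is a second, independent reason for the ridge
default above.

## Connected-correlation r20 (cc-r20)

The connected correlation (Ursell function) of a word is the part of its
frequency not explained by any factorization over subsets of its
positions: writing $X_i$ for the indicator that column $i$ carries the
word's residue, the word frequency over a subset $B$ is the moment
$m(B) = E[\prod_{i \in B} X_i]$ and the connected correlation is the
joint cumulant, computed by the first-element recursion
$g(A) = m(A) - \sum_{C \ni a_1,\, C \subsetneq A} g(C)\, m(A \setminus C)$,
equivalent to the explicit sum over set partitions but exponentially
cheaper. At $n = 2$ it is the familiar covariation
$C^{ij}_{\alpha\beta} = f^{ij}_{\alpha\beta} - f^i_\alpha f^j_\beta$; under
any product distribution it vanishes for $n \ge 2$. `cc_r20()` applies
the r20 scaffolding to these values — same reference-selected top-20
words (the word-selection rule is our interpretation; selecting by
connected-correlation magnitude instead would change the emphasis), same
shared position sets. Empirical connected correlations use plug-in
frequencies without pseudocount; pseudocounts enter model fitting only.

This metric is far harsher than r20: an independent model scores near 1
on low-order r20 of a field-rich family (single-site structure carries
most of the frequency signal) but near 0 on cc-r20 at every order.

# Synthetic data

`random_potts()` draws sparse random landscapes: a fraction `density` of
column pairs receives a Gaussian coupling block (`scale`), projected onto
the zero-sum gauge; `field_scale` adds Gaussian site fields.
`generate_iid_msa()` runs one independent Metropolis chain per sequence.
`generate_phylo_msa()` emulates phylogenetic clusters on a star tree: per
cluster a founder is equilibrated under $P(S)$, and leaves are produced
by a *short* run of fitness-weighted MCMC from the founder — evolution
respects the landscape rather than mutating uniformly. Divergence is
parameterized in sweeps and may be fractional (internally random-scan
single-site updates, `round(divergence_sweeps * L)` of them), because on
a weak-coupling landscape a single full sweep already nearly randomizes a
sequence; tight clusters of, say, 90% identity correspond to divergence
of roughly 0.1 sweeps. A single cluster with long divergence reduces to
the i.i.d. generator.

What the generator does *not* emulate: realistic tree shapes beyond the
star topology, indels and length variation, codon-level mutation biases,
and alignment errors. Tests passing on these synthetics therefore
demonstrate the statistical machinery (bias detection and removal, null
calibration, metric orderings) — not performance on any natural family.

# MCMC and numerical choices

* Metropolis with uniform state proposals, sequential site sweeps;
  independent chains per sequence (no thinning ambiguity). All RNG flows
  through R's stream, so every function is exactly reproducible under its
  `seed` argument.
* Equilibration: when `nsweeps` is `NULL`, sweeps proceed in batches of
  64 until the mean energy of consecutive batches agrees within twice its
  combined standard error, then one extra batch is run (cap 4096 sweeps,
  with a warning). Strongly coupled landscapes mix slowly; the
  glassiness threshold in our experiments sits near coupling scale ≈ 1.0
  at density 0.2 ($L=50$, $q=8$), and the default experiment conditions
  (density 0.15, scale 0.8) were verified to mix — 1024- and 4096-sweep
  samples agree to finite-sampling accuracy.
* Degenerate inputs: identity filtering of an all-identical MSA keeps
  exactly one sequence; `r20` on a constant reference skips every set
  and reports `NA` with a full skip count; marginal estimation rejects
  negative pseudocounts; `fit_potts` refuses training marginals with
  zeros (pointing at the pseudocount) and raises an error carrying the
  final deviation when the gradient loop does not converge.

# Experiment pipeline

`experiment_config()` + `run_experiment()` wire the full design together:
optional identity filter → phylogeny-aware split → model fits on the
training half → evaluation MSAs sized to the reference → r20 and cc-r20
per arm over shared position sets → null curves → position-set bootstrap
CIs (200 replicates by default). Every stochastic stage has its own seed
derived from one base seed; re-running a config reproduces the report
numbers exactly. `evaluate_external()` scores any third-party evaluation
MSA against the stored reference and position sets, so external
generators can be compared on identical footing.

# Problem sizes used in the shipped tests

The package's validation suite runs at desk scale, chosen so each
property is measured with adequate power:

* exact-oracle comparisons at $q^L \le 10^5$ (e.g. $L=5, q=8$;
  $L=10, q=3$);
* parameter recovery at $L=10$, $q=4$, $N = 5\times10^4$ against a
  doubled-$N$ refit, using the attenuation prediction
  $r(N) = (1 + 2(r(2N)^{-2} - 1))^{-1/2}$ as the self-consistency bound;
* null-matching and model-ordering experiments at $L=50$, $q=8$,
  $N = 10^4$, orders 2–5, 500–1000 position sets;
* phylogenetic-bias experiments on flat landscapes with 30–60 clusters
  and fractional divergence.

# Known limitations

* The identity filter is $O(N^2)$ in both time and memory (full identity
  matrix); practical to a few times $10^4$ sequences, as in the intended
  filtered-MSA regime.
* cc-r20 at order 8 over the full default 3000 sets is expensive in R
  (the per-set cost grows as $3^n$); the pipeline defaults to orders 2–5.
* The MCMC fit is tuned for the desk-scale regimes above; very large
  $L$ or glassy landscapes would need longer schedules.
* Fractional-sweep divergence uses random-scan updates, so two leaves of
  the same founder differ at a Poisson-distributed number of sites.
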