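---
title: "Dynamical networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynet)
```

This vignette documents the science implemented by `dynet` and the
decisions made where the method leaves room: what is computed, under which
assumptions, which knobs matter, and what a passing test does and does not
establish.

## From spike trains to a network

A *dynamical network* represents the momentary functional organisation of a
recorded population: nodes are neurons, links are pairwise activity
interactions. It is emphatically not the anatomical (synaptic) wiring — a
strong link can arise from common input to two unconnected cells, and no
pairwise measure can tell those apart.

**Smoothing.** Each neuron's spike train is converted to an instantaneous
rate estimate by summing a unit-area Gaussian density (width $\sigma$,
seconds) over its spikes, evaluated at the midpoints of a regular grid with
interval `dt`. Choices made here:

* *Kernel normalisation* — unit area, so the series estimates rate in
  spikes/s. The correlation measure is scale-invariant, so this choice only
  affects reported series, not networks.
* *`dt` default* — $\sigma/10$, floored at 1 ms. This resolves the kernel
  (10 samples per standard deviation); a `dt` larger than $\sigma$
  undersamples it and triggers a warning rather than an error, since the
  result is still defined.
* *Truncation and boundaries* — the kernel is truncated at $\pm 5\sigma$
  (mass beyond that is below $6\times10^{-7}$), and mass falling outside
  the recording window is discarded: no reflection, no renormalisation.
  Rates within $\sim 2\sigma$ of the window edges are therefore biased
  low. This is the simplest defensible convention; it is symmetric across
  neurons and so largely cancels in pairwise correlations.

**Interaction measure.** The default link weight is the rectified Pearson
correlation between two smoothed series: $w_{ij} = \max(0, R_{ij})$.
Rectification discards anticorrelations by design — link weights must be
nonnegative for the weighted graph measures downstream; an option to retain
signed weights is deliberately out of scope. Cosine similarity is provided
as the one alternative (nonnegative automatically for rate series). The
measure argument is the extension point for nonlinear measures (mutual
information, transfer entropy, model-based couplings), which are not
implemented.

A neuron whose smoothed series is constant (e.g. it never fired) gets
weight 0 with every partner — never `NaN` — and stays in the network as an
isolated node, so weight matrices from different trials of one session
always align neuron-for-neuron.

**Whole-trial correlation.** Correlations are computed over the entire
trial window, which assumes the interaction structure is stationary within
a trial. Trial-to-trial change is handled explicitly by the tracking layer
instead.

## Weighted network measures

* **Degree / strength** count and sum strictly positive links. There is no
  epsilon threshold: a rectified-Pearson zero is a structural absence.
* **Weighted clustering** uses the triangles-to-triples ratio on weights
  scaled to $[0,1]$ by the network maximum:
  $C_i = \sum_{j \neq k} u_{ij} u_{jk} u_{ki} \big/
  \left( (\sum_j u_{ij})^2 - \sum_j u_{ij}^2 \right)$,
  with both sums over ordered pairs and $C_i = 0$ when the denominator
  vanishes (degree < 2). On a binary network this is exactly the classic
  triangles/triples clustering coefficient, which the test suite asserts
  against brute-force triangle counting. The geometric-mean (Onnela)
  variant used by some toolboxes is available via `variant = "onnela"` but
  is not the default.
* **Global efficiency** maps each link to a length $1/w$, solves all-pairs
  weighted shortest paths, and averages $1/d_{ij}$ over ordered pairs with
  $1/\infty = 0$ for disconnected pairs. The $1/w$ mapping is the standard
  weighted extension; nothing in the interaction model singles it out, so
  treat absolute efficiency values as comparable only across networks
  built the same way.
* **Efficiency fingerprint** $\Delta\mathrm{Eff}_i$ re-averages the
  reduced graph over its own $(n-1)(n-2)$ ordered pairs. The alternative
  (keeping the original $n(n-1)$ denominator) shifts small deltas and can
  flip their sign; with our convention a deletion that *raises* mean
  efficiency yields a negative delta, which is meaningful (the deleted
  node was a drag on the average), so we keep it.

## Null models

The reference null "conserves node strength but randomly reassigns the set
of weights". Exact strength conservation under a weight permutation is
generally impossible (strengths are sums of shared weights), so two
bracketing approximations are provided:

* `weight_shuffle` — permute the multiset of existing weights uniformly
  over the existing link positions. Conserves topology, degree sequence,
  total weight and the weight multiset exactly; strengths in expectation.
* `strength_rank` — same positions and multiset, but link slots are
  visited in random order and each receives the remaining weight whose
  rank matches the slot's rank by source strength product. This
  concentrates large weights on high-strength pairs and tracks the source
  strength sequence more closely than the uniform shuffle (asserted in the
  tests), at the cost of a residual bias toward the source configuration.

Binary controls (`erdos_renyi_binary`, degree-preserving
`degree_rewire_binary` with $10\times$links double-edge swaps) cover
hypotheses about link existence rather than weight placement. Default
sample count is 20 per network. Every sample is drawn from its own
substream derived by hashing (master seed, model, sample index), so sample
$k$ is reproducible regardless of how many samples are requested or in
which order they are evaluated.

Excess structure is reported as $100 \times M_\text{data}/M_\text{null}$;
100 means "fully explained by the null".

## Tracking across trials

Stability between consecutive trials is the Pearson correlation of the
vectorised *strict upper triangles* of the two weight matrices. Including
the zero diagonal or the duplicated lower triangle would inflate the
correlation, so both are excluded. Two deliberate edge rules: identical
matrices return exactly 1 (short-circuiting the floating-point dance), and
a constant matrix yields `NA` because the correlation is undefined — not 0,
which would masquerade as "maximally unstable".

`track()` draws each trial's null sample from a substream keyed by the
trial's weight-matrix content rather than its index. Identical trials are
thus compared against identical null ensembles (their excess ratios agree
exactly), while distinct trials draw independent nulls; determinism under
the master seed is unaffected.

## Ensembles as network modules

An ensemble is operationalised as a module of the dynamical network: a
group of neurons more strongly coactive with each other than with the rest
of the population. Partitions are scored with weighted Newman–Girvan
modularity
$Q = \frac{1}{2m} \sum_{ij} \left( w_{ij} - \frac{s_i s_j}{2m} \right)
\delta(c_i, c_j)$.

**Base optimizer.** Greedy agglomerative (Louvain-style) moves on the
weighted graph, followed by a node-swap refinement pass that relocates
single nodes to the neighbouring module with the largest positive
$\Delta Q$ until no move helps. Each run draws its initial conditions from
its own seed substream, so runs differ.

**Consensus.** With `n_runs` partitions (default 100) in hand, the
co-assignment matrix $P$ (fraction of runs placing each pair together) is
computed. If all runs agree ($P$ entries all 0 or 1), that partition is
returned. Otherwise $P$ is thresholded at the co-assignment expected if
each run's labels were permuted across neurons (preserving module sizes),
and the thresholded matrix is itself clustered by the same base algorithm,
iterating until agreement. The threshold and the 50-iteration cap are
engineering choices — the method's description fixes neither — and
exceeding the cap raises an error that carries the last consensus matrix
for inspection.

Three guard rails:

* Zero-strength neurons are set aside as singleton modules before
  consensus and reattached after, so silent cells can never distort the
  co-assignment statistics.
* If thresholding empties the consensus matrix (no pair co-assigned above
  chance), the highest-$Q$ single run is returned: there is no consensus
  structure to iterate on.
* The converged consensus partition receives a final node-swap pass
  against the *data* matrix, and is returned only if its data-$Q$ is at
  least that of the best single base run; otherwise the best run wins.
  Rationale: consensus reclustering optimizes agreement, and on weakly
  structured networks the agreement average can sit measurably below the
  attainable modularity; a modularity maximizer should be monotone in its
  own objective. On clearly structured networks the consensus partition
  ties or wins and is always the one returned.

Module labels are consecutive integers from 1 (R convention), ordered by
first appearance in the roster. Recovery against planted truth is scored
with the adjusted Rand index, which is invariant to label permutation.

## Timescales

$\sigma$ is a scientific parameter, not a nuisance: small values ask about
spike-time precision, large values about firing-rate covariation. The
default grid is 10 log-spaced points from one quarter of the pooled median
interspike interval to ten times it — the median ISI being the natural
first guess at the timescale on which a population's coactivity could be
organised. `timescale_scan()` rebuilds the network and re-detects modules
at each $\sigma$, records $Q(\sigma)$, and summarises cross-timescale
agreement in a confusion matrix whose $(i,j)$ entry is the fraction of
timescales assigning $i$ and $j$ to one module (entries are exact
multiples of 1/grid size; unit diagonal; symmetric). `peak_timescale()`
returns the $\sigma$ maximizing $Q$, breaking ties toward the smaller
$\sigma$ (the more parsimonious, more precise timescale). A flat
$Q(\sigma)$ curve is a legitimate outcome — some populations show no
preferred timescale — so the full curve is always returned alongside the
peak.

## The synthetic world

The generator instantiates the operational ensemble definition directly:
neurons are partitioned into equal-size ensembles; each ensemble emits
shared events as a homogeneous Poisson process (`event_rate_hz`); each
member spikes per event with probability `participation_p` at the event
time plus Gaussian jitter (`jitter_s`), clipped — not wrapped — at the
window edges; an independent background Poisson train
(`background_rate_hz`) is superimposed; and between trials each neuron
switches to a uniformly random ensemble with probability `drift`,
emulating reorganisation of interactions across learning.

Defaults describe a plausible cortical session: 52 neurons, 70 s trials,
1 Hz background, 1 Hz events, participation 0.8, 50 ms jitter, no drift.
The jitter is the planted coactivity timescale, which is what the
timescale scan should recover.

What the generator does **not** emulate: refractoriness, bursting,
rate nonstationarity within trials, overlapping ensemble membership,
common slow drives, and realistic interspike-interval statistics beyond
Poisson. A green recovery test therefore establishes that the pipeline
recovers *event-locked, disjoint* ensembles against Poisson background at
the stated rates — not that it is robust to every failure mode of real
recordings.

## Numerical conventions

* Weight matrices are validated symmetric/nonnegative/zero-diagonal at
  construction (tolerance $10^{-8}$) and snapped exactly; all downstream
  code may assume exact symmetry.
* Text round trips are lossless: weights are written in shortest
  round-trip decimal form and parsed with the correctly rounded base-R
  parser (fast approximate parsers can be off by one ulp).
* Seeds everywhere are integers below $2^{31}$; substreams are derived by
  a multiplicative string hash of (master seed, purpose), so stages,
  samples and runs are independently reproducible.
* Degenerate inputs resolve to defined values rather than errors wherever
  a value is defensible: empty networks summarise to zeros, constant
  series to zero weights, `NA` stability for constant matrices. Errors are
  reserved for contradictions (negative times, roster mismatches, empty
  windows, modularity of a weightless network).

## Limitations

Pairwise linear interactions cannot separate direct coupling from common
input; rectification discards inhibition-like anticorrelation; whole-trial
correlation assumes within-trial stationarity; consensus modularity
inherits the resolution limit of modularity maximization and cannot assign
one neuron to two ensembles. Trial windows are taken from the data range
unless supplied explicitly — when event-aligned windows matter, supply
them.
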