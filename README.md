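# dynet: dynamical networks from multineuron spike recordings

`dynet` turns simultaneously recorded spike trains into **dynamical
networks** — weighted graphs whose nodes are neurons and whose links are
pairwise activity interactions — and provides the network-science toolkit to
describe them, test them against null models, track them across trials, and
decompose them into **neural ensembles**. It is written for systems
neuroscientists analysing population recordings (tens to hundreds of
neurons) who want compact, quantitative, hypothesis-testable descriptions of
population coactivity, and it follows tidyverse conventions: tibbles in and
out, `tidy()`/`glance()` on every result, `autoplot()` for figures.

## The model

1. **Interaction weights.** Each spike train is convolved with a unit-area
   Gaussian of width σ (the analysis timescale), and every pair of smoothed
   rate series is scored with the rectified Pearson correlation

   *w<sub>ij</sub>* = max(0, *R*(*x<sub>i</sub>*, *x<sub>j</sub>*)) ∈ [0, 1]

   (cosine similarity is also available). The result is a symmetric,
   nonnegative, zero-diagonal weight matrix *W* per trial.

2. **Weighted structure.** Node degree and strength, the weighted clustering
   coefficient *C<sub>i</sub>* (ratio of weighted triangles to weighted
   triples at neuron *i*), global efficiency
   *Eff* = mean over pairs of 1/*d<sub>ij</sub>* with link length 1/*w*, and
   per-neuron fingerprints (ΔEff after deleting each neuron — large drops
   flag hub neurons).

3. **Null models.** `weight_shuffle` permutes the set of link weights over
   the existing links (conserving topology, degrees and the weight multiset
   exactly, strength in expectation); `strength_rank` rank-matches large
   weights to high-strength node pairs; binary Erdős–Rényi and
   degree-preserving rewiring cover the binarized network. Excess structure
   is reported as 100 × *C*<sub>data</sub>/*C*<sub>null</sub>.

4. **Tracking.** Across trials: the correlation of consecutive weight
   matrices (network stability), total weight and link counts, and per-trial
   data-vs-null clustering.

5. **Ensembles.** Modules of the dynamical network found by maximizing the
   weighted modularity

   *Q* = (1/2m) Σ<sub>ij</sub> (*w<sub>ij</sub>* − *s<sub>i</sub>s<sub>j</sub>*/2m) δ(*c<sub>i</sub>*, *c<sub>j</sub>*)

   with a consensus procedure: many randomized runs of a greedy
   (Louvain-style, node-swap refined) optimizer, co-assignment matrix
   thresholded against a label-permutation null, reclustered to agreement.
   Scanning σ re-asks the question at every timescale — small σ captures
   spike-time precision, large σ rate covariation — with *Q*(σ) locating the
   most structured timescale and a cross-timescale confusion matrix showing
   which neuron pairs stay together.

A synthetic-data generator plants ground-truth ensembles (background Poisson
firing plus jittered event-locked spiking, with optional between-trial
membership drift) so every step of the pipeline can be validated against a
known answer.

## Worked example

```r
library(dynet)

sim <- generate_synthetic_session(synthetic_config(
  n_neurons = 52, n_ensembles = 3, duration_s = 70, n_trials = 5,
  participation_p = 0.8, jitter_s = 0.05, seed = 42
))

nets <- build_networks(sim$session, sigma = 0.25)
glance(summarise_network(nets[[1]]))
#> # A tibble: 1 × 5
#>   n_neurons n_links total_weight global_efficiency mean_clustering
#>       <int>   <int>        <dbl>             <dbl>           <dbl>
#> 1        52     963         206.             0.214           0.444

report <- track(nets, null_model = "weight_shuffle", n_samples = 20, seed = 1)
dplyr::select(tibble::as_tibble(report), trial, clustering_data,
  clustering_null_mean, excess_clustering_pct, stability)
#> # A tibble: 5 × 5
#>   trial clustering_data clustering_null_mean excess_clustering_pct stability
#>   <chr>           <dbl>                <dbl>                 <dbl>     <dbl>
#> 1 1               0.444                0.268                  166.    NA
#> 2 2               0.487                0.278                  175.     0.847
#> 3 3               0.439                0.255                  172.     0.836
#> 4 4               0.387                0.247                  156.     0.792
#> 5 5               0.484                0.283                  171.     0.804

ensembles <- detect_modules(nets[[1]], n_runs = 100, seed = 1)
glance(ensembles)
#> # A tibble: 1 × 4
#>       q n_modules n_neurons iterations
#>   <dbl>     <int>     <int>      <int>
#> 1 0.455         3        52          1

truth1 <- dplyr::filter(sim$truth, trial == "1")
adjusted_rand_index(ensembles$module, truth1$ensemble)
#> [1] 1
```

Reading the numbers: the trial-1 network links 963 of the 1326 possible
pairs; its mean weighted clustering (0.444) is about 1.7× the
weight-shuffle null (excess ≈ 166%), so triads of neurons are far more
densely interlinked than their overall interaction levels predict. Network
stability sits near 0.8–0.85 (the planted memberships never change;
residual variation is estimation noise on 70 s trials). Consensus module
detection agrees across all 100 runs in one iteration and recovers the 3
planted ensembles exactly (ARI = 1).

Spike data are read from plain text (`trial_id`, `neuron_id`,
`spike_time_s`) with `read_spike_file()`; networks and partitions round-trip
through TSV/CSV/GraphML. `autoplot()` works on networks, metric summaries,
tracking reports and timescale scans. A command-line wrapper lives at
`inst/cli/dynet.R` (subcommands `synth`, `build`, `metrics`, `null`,
`track`, `ensembles`, `pipeline`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch on a freshly synthesized
multi-trial session at the package defaults (52 neurons, 3 planted
ensembles, 70 s trials, rectified Pearson at σ = 250 ms, 20 null networks
per trial, 100-run consensus detection, automatic median-ISI timescale
grid), logs the headline quantities (efficiency, clustering, modularity,
ensemble-recovery ARI, stability, excess clustering, peak timescale) and
writes the collected target values as JSON to `--out`.
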