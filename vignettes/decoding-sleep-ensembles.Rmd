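---
title: "Decoding sleep-associated ensemble spike activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding sleep-associated ensemble spike activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(sleepreplay)
```

# The problem

Hippocampal place cells fire selectively at particular locations, so the
position of an animal can be decoded from the joint spike counts of a few
dozen cells. During quiet wakefulness and slow-wave sleep the same
ensembles re-express compressed spike sequences ("replay") inside
sharp-wave-ripple events. Decoding that activity is much harder than
decoding behaviour: the data arrive in short epochs (tens of 250-ms bins,
or ~10 bins at the 20-ms ripple timescale), only a fraction of the
population is active in any epoch, sequences may run time-reversed, and
there is no concurrent behaviour to supervise against.

This package implements two complementary decoding strategies for that
regime, a shuffle-based statistical framework for calling replay
significant, and a synthetic-data module that emulates the relevant
properties of real recordings, so every stage can be exercised and
validated without any proprietary data.

# Models

## Poisson population likelihood

Both decoders share the observation model. Given per-cell rate functions
$\lambda_c(S)$ over a discrete support $S$ (spatial bins, or latent
states) and a count vector $y$ in a bin of width $\Delta$:

$$\ell(S) \;=\; \sum_{c=1}^{C}\Big[\,y_c \log(\lambda_c(S)\Delta)
\;-\; \lambda_c(S)\Delta \;-\; \log (y_c!)\,\Big].$$

Counts are conditionally independent across cells and bins. All
computation is in the log domain with per-bin max subtraction; rates are
floored at 0.01 Hz before the log so finite-sample empty field bins never
produce $-\infty$ (`poisson_loglik`). A useful structural property tested
in the suite: a flat-tuned cell only shifts $\ell$ by a constant, so
non-place cells cannot change the posterior.

## Supervised decoder (with receptive fields)

`estimate_place_fields` computes the classical occupancy-normalised
fields from a behaviour session: spikes at $S$ divided by time spent at
$S$, on 10-cm bins (1-D) or 15×15-cm bins (2-D, 5×5 available via
`spatial_bin_cm`), after removing immobility with a 15-cm/s speed filter.
Both the spike map and the occupancy-time map are smoothed with the same
small Gaussian operator (5 taps in 1-D, 3×3 in 2-D, SD = 0.5 bins,
column-normalised) and the ratio taken, which makes the smoothing
mass-conserving: $\sum_S \lambda_c(S)\,t(S)$ equals the cell's spike
count exactly. Unvisited bins are masked, not zeroed, and excluded from
the decoding support.

`decode_posterior` then yields $p(S_t \mid y_t)$ under a uniform temporal
prior (each bin independent) or $p(S_t \mid y_{1:t})$ by forward
filtering under a Markov prior. Because the uniform-prior posterior is a
row-wise computation, the decoder is *exactly* invariant to how the data
are cut into epochs, reversed, or reordered — the property the acceptance
suite asserts bit-identically across epoch lengths 10, 50, 100 and the
whole session.

Cells are scored by their spatial information rate
$I_c = \sum_S p(S)\lambda_c(S)\log_2(\lambda_c(S)/\bar\lambda_c)$
(bits/s) and its normalised form $I_c/\bar\lambda_c$ (bits/spike)
(`spatial_information_rate`); `partition_by_information` median-splits a
population into information-rich and information-poor halves.

## Unsupervised decoder (without receptive fields)

`fit_hdp_hmm` treats the ensemble activity as a hidden Markov model with
Poisson emissions whose state count is not fixed in advance: a
hierarchical-Dirichlet-process HMM, sampled with a weak-limit Gibbs
sampler at truncation $L$ (default 100). Each epoch is an independent
chain sharing the transition matrix $P$ and the state rate matrix
$\Lambda$; epoch-initial states follow the stationary distribution of
$P$. One sweep:

1. sufficient statistics (transition counts, occupancies, per-state spike
   and exposure totals) from the current paths;
2. conjugate gamma–Poisson update of $\Lambda$ (prior shape 1, prior rate
   matched so the prior mean equals the grand mean rate);
3. HDP auxiliary table counts and the shared stick weights $\beta$;
4. transition rows $P_j \sim \mathrm{Dir}(\alpha\beta + \kappa e_j + n_{j\cdot})$
   (sticky mass $\kappa$, default 0);
5. forward-filter/backward-sample of the state paths (C++).

The paths are initialised by k-means on square-root counts; starting from
a data-driven segmentation (rather than random labels) keeps distinct
firing patterns in distinct states from the first sweep and avoids a
state-collapse failure mode. The returned model is the single
post-burn-in sample with the highest complete-data log joint, keeping $P$
and $\Lambda$ coherent, reduced to the states occupying at least 0.5 % of
the bins; that reduced state count is the reported $m$. Convergence is
scored by a Geweke-style z on the log-joint trace (a warning is raised
above $|z| = 3$).

Two sampler behaviours are worth knowing about, both documented by tests:
on *unstructured* data, short chains can end in a mode where two
near-identical states split the bins (~300 sweeps reliably merge them);
and on long structured sequences the sampler occasionally splits one true
state into two near-duplicates. The transition-recovery property test
therefore also evaluates a many-to-one matching (inferred states assigned
to the nearest true state by rate vector, transition mass aggregated by
occupancy), under which the recovery error decreases monotonically with
the sequence length.

States carry no spatial meaning during fitting. For evaluation only,
`build_state_space_map` assigns each state the centroid (circular mean on
circular tracks) of the true positions of its Viterbi-assigned bins, and
`decode_position_from_states` scores the mapped Viterbi path against the
true trajectory with the same metric as the supervised decoder.
`topology_layout` renders the learned transition structure as an
undirected graph with strengths $w_{ij} = P_{ij} + P_{ji}$ under a
force-directed (Fruchterman–Reingold) layout normalised to the unit
bounding box.

## Replay significance

An event decoded to a posterior matrix is scored by the *weighted
correlation* between time-bin index and support position, with the
posterior mass as weights:

$$R = \frac{\mathrm{cov}_w(t, x)}{\sqrt{\mathrm{var}_w(t)\,\mathrm{var}_w(x)}},$$

which is +1 for a perfect forward sweep, −1 for a perfect reverse sweep,
and reduces to the ordinary Pearson correlation when the posterior is
one-hot. The null is built by re-decoding `n_shuffle` (default 1000)
surrogates obtained by permuting whole time-bin columns (temporal
shuffle) and row identities (cell shuffle); both preserve the multiset of
matrix entries exactly. The Z-score is computed on $|R|$ so forward and
reverse events are treated symmetrically; when Shapiro–Wilk rejects
normality of the null, the add-one Monte-Carlo p-value
$(1 + \#\{|R_s| \ge |R|\})/(n+1)$ replaces the normal tail.

An event is significant iff (1) $|R| > 0.5$; (2) it spans at least 5
temporal bins (100 ms at $\Delta = 20$ ms) *and* its average MAP
probability score exceeds the chance level $5/\#\text{support bins}$; and
(3) $Z > 1.65$, or $p < 0.05$ on the Monte-Carlo branch. On shuffled
events the full pipeline fires at well under the nominal 5 % (the extra
criteria only remove false positives); on clean synthetic forward events
at 5× gain it detects over 90 % — both rates are recomputed by
`scripts/acceptance.R`.

Candidate events are screened from a multi-unit activity trace:
Gaussian-smoothed MUA above mean + 3 SD (optionally gated by a
ripple-band power trace), expanded to the nearest sub-mean crossings, and
kept only if at least $\max(6, \lceil 0.1\,C\rceil)$ cells fire inside
(`detect_candidate_events`).

# The synthetic generator

No public recordings accompany the methods this package implements, so
the generator is designed to emulate the relevant regime rather than any
particular dataset:

- **Tuning curves**: Gaussian bumps with uniformly placed centres, width
  12 cm, peak rates 5–15 Hz over a 0.1-Hz baseline — a few dozen cells
  with session-mean rates around 1–1.5 Hz, the typical scale of a dorsal
  CA1 ensemble. Non-place cells get flat tuning.
- **Behaviour**: back-and-forth laps (linear track), unidirectional laps
  (circular track), or an Ornstein–Uhlenbeck random walk with reflecting
  boundaries (open field), sampled at 60 Hz like standard video tracking.
- **Spikes**: Poisson counts with mean $\lambda_c(\text{pos})\Delta$ per
  bin — the exact generative twin of the decoding likelihood, verified by
  a chi-square goodness-of-fit test on $10^5$ bins.
- **Sleep-like structure**: `split_into_epochs` (contiguous blocks of
  `T0` bins, each independently reversed with probability 0.5, order
  shuffled; trailing remainder dropped), `subsample_cells` (active set
  `max(round(rho * C), 10)`, fixed or per-epoch), `thin_spikes` (clip to
  one spike per bin; Bernoulli subsampling behind a flag),
  `remove_time_bins`, and `make_nonplace_cells` (total counts preserved
  exactly, spikes redistributed in proportion to occupancy).
- **Replay events**: a path traversed at one position per 20-ms bin with
  rates scaled by a gain factor (default 5), embedded in a baseline MUA
  trace at a known onset for detector tests.

# Experiment harnesses

`run_representation_experiment` sweeps epoch length, active-cell ratio,
bin width, thinning and per-epoch resampling over a grid; each Monte
Carlo run simulates a fresh session (run $i$ is seeded `base_seed + i`),
so conditions within a run share the same substrate and can be compared
pairwise. Decoding error is summarised as mean ± SEM of the per-run
median error, via `summarise_results`. `run_detection_experiment` does
the same for replay detection power under cell removal and bin removal.
Desk-scale defaults (300-s sessions, 20–50 runs, truncation 30, 60
sweeps) keep a full sweep in minutes; they are the package's own choices
and can be raised freely.

```{r experiment, eval = FALSE}
fields <- make_ground_truth_fields(spatial_env("linear_track", 200, 10),
                                   n_cells = 40, seed = 1)
res <- run_representation_experiment(
  fields, grid = data.frame(rho = c(0.3, 0.5, 0.8, 1.0)),
  duration = 300, n_runs = 20, base_seed = 100)
summarise_results(res)
```

# Numerical choices

- Log-domain decoding with per-row max subtraction throughout; posterior
  rows sum to 1 within 1e-9.
- Rate floor 0.01 Hz in the supervised likelihood; 1e-3 Hz inside the
  HMM emission likelihood.
- MAP ties break to the lowest support index (deterministic).
- Every seeded operation restores the caller's RNG state, so seeded calls
  are bit-reproducible and side-effect free.
- Weighted-correlation antisymmetry under time reversal is exact in exact
  arithmetic; floating-point summation order limits it to ~1e-15 in
  practice.

# Limitations

- The generator does not model theta-phase precession, LFP waveforms
  beyond an MUA trace, or interneurons; the trajectory model is a
  convenience, not a behavioural model.
- The weak-limit sampler is a single-chain MCMC: the inferred $m$ has
  run-to-run variability, and heavier problems deserve longer chains (or
  several seeds, keeping the best log-joint fit) — the fixtures in the
  test suite show working settings at several scales.
- Monte-Carlo p-values are bounded below by $1/(n_\text{shuffle}+1)$.
- The 1-D weighted correlation measures linear time–position trend; it is
  the standard first-pass replay statistic, not a trajectory fit.
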