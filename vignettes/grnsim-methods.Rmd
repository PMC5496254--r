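---
title: "Methods: delayed stochastic simulation of gene networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delayed stochastic simulation of gene networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`grnsim` turns a directed, signed gene regulatory network into a delayed
chemical-reaction system and samples it exactly as a continuous-time Markov
jump process. Each gene X contributes an RNA species `RX`, a protein `PX`,
and promoter species: one free/bound pair `ProX.NoY`/`ProX.Y` per incoming
regulator Y, or a single constitutive `ProX` for unregulated genes. Three
reaction sections are compiled per network:

* **translation/decay**: `RX → RX + PX` (catalytic in `RX`), `RX → ∅`,
  `PX → ∅`;
* **binding/unbinding**: `PY + ProX.NoY ⇌ ProX.Y`, the regulator protein
  occupying its site;
* **transcription**: one reaction per non-empty subset of X's bound
  activator forms (2^k − 1 for k activators), each producing `RX`; every
  free repressor site enters catalytically, so occupancy of any repressor
  site sets the propensity to zero.

Propensities are stochastic mass action, a = c · Π choose(n_s, ν_s), with
catalysts included in the product but never consumed. Designated products
carry a delay: instead of appearing at the firing time t they are pushed
onto a wait list and released at t + τ, with τ drawn per firing from the
product's delay law. This models multi-step processes — elongation,
folding, maturation — as single time-delayed events while keeping the
firing statistics exact.

### Repression semantics

The blocking mechanism of a bound repressor is not fully determined by the
qualitative description the model follows: a bound repressor form "does not
allow" transcription and releases after some time. We implement the
simplest mechanism consistent with that behaviour: every transcription
reaction of gene X requires (catalytically) each *free* repressor site
`ProX.NoZ`, so transcription stalls exactly while any repressor is bound,
and resumes on unbinding. The choice is isolated in the compiler; no other
component depends on it. A gene with repressors but no activators keeps its
basal reaction, gated the same way — without this, repression of
activator-less genes would be inert.

### Other compiler decisions

* **Unregulated genes** transcribe constitutively at the global
  transcription rate; otherwise source nodes would stay silent forever and
  all downstream dynamics would degenerate to extinction.
* **Per-subset transcription rates** are all equal to the gene's
  transcription rate — no synergy scaling with subset size; an override
  hook (`rate_params(overrides = ...)`) exists for users who want one.
* **Bound promoter complexes do not decay**; only free proteins do. The
  model lists degradation for RNA and protein species only.
* **Promoter delay** applies to the re-release of the promoter forms used
  by a transcription reaction (occupancy during elongation). With a nonzero
  promoter delay those forms are consumed at firing and re-released after
  the sampled delay; with the delay off they are pure catalysts.
* **One promoter copy per site** — single-gene-copy, single-cell
  semantics.

## The engine

The core is the Gillespie direct method plus a time-ordered wait list,
in C++:

* waiting time τ ~ Exponential(Σa); if the earliest wait-list release
  precedes the candidate firing time, the release is applied and the firing
  redrawn (valid by memorylessness). At exactly equal times the release
  wins: it is an already-committed event.
* the wait list is a binary heap keyed by (release time, insertion
  sequence), so releases are applied in non-decreasing time order and ties
  resolve deterministically;
* after each event only reactions whose reactants changed are recomputed
  (per-species dependency lists), and the propensity total is maintained
  incrementally with periodic full refreshes (every 2^14 events) to bound
  floating-point drift. Together these give the expected
  O(T·R·(D log R + log W)) complexity for simulated time T, R reactions,
  dependency degree D and wait-list size W.
* readout times are computed by index (t0 + iΔ), never by accumulation;
  the snapshot at grid time g reflects every event with time ≤ g.
* when Σa = 0 with an empty wait list the run is deadlocked and
  fast-forwards to `stop_time` (a notice is emitted).

Randomness comes from R's RNG (the engine draws through the R API), so
`set.seed()` makes whole trajectories bit-identical across runs and
platforms with the same RNG kind. Replicate r of an ensemble uses child
seed r of a seed vector drawn once from the master seed; `run_timeseries()`
uses child 1 of the same spawn, so an n = 1 ensemble column equals the last
time-series column. Statistical correctness is checked two ways: against
closed-form laws (birth–death stationary Poisson mean and Fano factor,
exponential inter-event gaps), and against an independent plain-R
direct-method reference implementation (`ssa_direct_reference`, no shared
code with the C++ path) on a zero-delay three-species cascade, by
rank-sum tests at α = 0.01.

### Delay laws

`none`, `constant(value)`, `gaussian(mean, sd)`, `gamma(shape, scale)`,
`exponential(rate)`, all in simulated time units. Gaussian draws are
truncated at zero by resampling (at most 100 attempts) then clamping —
this preserves the shape for mostly-positive parameterisations and can
never stall. For realistic transcription/translation timing the gamma law
is the recommended choice; a gamma(2, 1) delay on a birth process provably
leaves the linear birth–death stationary mean k/γ unchanged, which the
tests exploit.

## Default kinetic parameters

The model description does not pin numeric defaults, so the package fixes
one realistic prokaryotic-scale world (all rates s⁻¹; binding
s⁻¹·molecule⁻¹) and the tests and experiments do not move them:

| parameter | default | rationale |
|---|---|---|
| transcription | 0.1 | ~1 initiation / 10 s from an active promoter |
| translation | 0.05 | a few proteins per transcript lifetime |
| RNA degradation | 0.01 | mean RNA lifetime 100 s, level ≈ 10 |
| protein degradation | 0.005 | protein level ≈ 100 per expressed gene |
| binding | 0.001 | with ~100 regulator proteins, on-propensity ≈ 0.1 |
| unbinding | 0.1 | promoter occupancy ≈ ½ at that abundance, so sites fluctuate and carry signal |
| initial RNA/protein | 0 | expression builds up from the promoters |

Scale-free generation uses preferential attachment with power 1 and m = 1,
edges oriented from the earlier-attached node to the later one
(deterministic and reproducible); edge signs are i.i.d. Bernoulli(0.5)
activating. These generator settings are this package's own: the reference
description reports only summary edge counts for its benchmark networks,
not generator parameters.

## What the synthetic data does and does not emulate

Ensembles are n replicates from identical initial conditions, each
contributing its endpoint counts at `stop_time` — "steady state" is
operational (endpoint-at-T), with no stationarity detection beyond a notice
when the last two snapshots differ by more than 20% in total count.
Choosing T is the user's burden; the default experiment uses T = 1500 s,
several protein lifetimes. The data are intrinsic-noise molecule counts
from single-copy genes: no extrinsic noise, no measurement noise layer
(microarray/RNA-seq error models are out of scope), no cooperative binding
or protein complexes, no cell growth or division. A green edge-separation
test therefore establishes that regulatory structure is recoverable from
the simulator's intrinsic fluctuations — not that any particular inference
method will recover it from noisy measured data.

## The edge-separation diagnostic

To verify the simulator encodes topology, the validation module computes
plug-in mutual information (log base 2) between all gene pairs of an
ensemble after equal-width binning into ⌈√n⌉ bins per gene (constant genes
get weight 0), and compares edge pairs against non-edge pairs: medians and
the rank-sum effect size P(edge > non-edge). On 20-node scale-free
networks with 200-replicate ensembles, the edge median exceeds the
non-edge median in 18 of 20 seeded repetitions. A full inference method
(e.g. an ensemble MI method) is deliberately *not* reimplemented here: the
claim under test concerns the simulator's output, and absolute weight
values depend on the inference method's internals, so only the ordinal
separation is meaningful.

## Numerical and interface choices

* Counts are non-negative integers at all times; zero propensity below
  stoichiometric thresholds enforces this without clamping.
* The reaction-text grammar normalises typographic dashes before
  tokenising, so typeset arrows like `–[0.2]– >` parse as written; parsing
  is locale-independent (decimal point).
* An unstarred reactant that reappears as a product (e.g. `ProA` in
  `ProA + *Ind → A + ProA`) is treated literally as consume-and-reproduce —
  dynamically equivalent to a catalyst at zero delay.
* Loaders never default missing edge signs; an explicit
  `activation_prob` policy is required.
* The CLI's config file is JSON (versioned schema) rather than YAML: no
  YAML parser is available in the supported dependency set, and jsonlite is
  already required for the provenance sidecars. Flags override file values.

## Known limitations

Tau-leaping or other approximate accelerations are not provided; systems
with ≫10⁴ events/second of simulated time are slow by design (exactness
first). SBML import/export is out of scope. Bit-compatibility with other
delayed-SSA implementations is not a goal — statistical equivalence is,
and that is what the test suite asserts.
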