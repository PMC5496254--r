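# grnsim

Stochastic simulation of gene expression from an underlying regulatory
network, with transcription, translation and promoter dynamics modelled as
time-delayed chemical reactions.

## The problem

Network-inference methods (mutual-information, regression, Bayesian) need
benchmark expression data whose *true* generating network is known. `grnsim`
produces such data: it takes a directed, signed gene regulatory network —
supplied as an edge list, adjacency matrix or GraphML file, or generated
internally (scale-free, Erdős–Rényi) — compiles it into a delayed
chemical-reaction system, and simulates that system exactly with a
time-delayed stochastic simulation algorithm (SSA). The output is either a
time-series matrix (genes × readout times) or a steady-state ensemble
(genes × replicates) of integer molecule counts.

## The model

Each gene X is represented by a promoter, an RNA species `RX` and a protein
species `PX`. For every regulator Y of X there is a free promoter site
`ProX.NoY` and a bound form `ProX.Y`. Compilation emits three reaction
sections (rates `c` in parentheses):

1. **Translation and decay** — `RX → RX + PX` (translation; `PX` may carry a
   protein delay), `RX → ∅`, `PX → ∅`.
2. **Binding/unbinding** — `PY + ProX.NoY → ProX.Y` (binding),
   `ProX.Y → ProX.NoY + PY` (unbinding).
3. **Transcription** — one reaction per non-empty subset S of X's
   *activators*: the bound forms `{ProX.Y : Y ∈ S}` act catalytically and
   produce `RX` (optionally delayed). A gene with k activators therefore
   owns 2^k − 1 transcription reactions. Every free *repressor* site
   `ProX.NoZ` is a catalytic reactant too, so a bound repressor silences the
   gene. Unregulated genes transcribe constitutively from `ProX`.

The engine is an exact Gillespie direct method extended with a time-ordered
wait list: a delayed product is not released at firing time t but scheduled
at t + τ, with τ drawn from a constant, Gaussian (truncated at 0), gamma or
exponential delay law. Propensities are mass-action,
a = c · Π choose(n_s, ν_s). The wait list is a binary heap and propensity
updates touch only the dependency neighbourhood of the fired reaction,
giving the O(T·R·(D log R + log W)) behaviour expected of delayed-SSA
engines.

Hand-written systems are supported through a plain-text grammar, e.g. the
bistable toggle switch:

```
ProA + *Ind --[0.002]--> A + ProA
A + ProB + *ProA --[0.2]--> ProB.A
ProB.A --[0.01]--> ProB + A
...
```

`*` marks a catalyst; `(5)`, `(gamma:2,1)`, `(gauss:10,1)`, `(exp:0.5)`
annotate delayed products.

## Worked example

```r
library(grnsim)

# B and C activate A; D represses A
net <- gene_network(c("A", "B", "C", "D"),
                    data.frame(source = c("B", "C", "D"), target = "A",
                               sign   = c("+", "+", "-")))
sys <- compile_network(net)
length(sys$reactions)   # 24 reactions; gene A owns 3 transcription reactions
#> [1] 24

cfg <- sim_config(stop_time = 1500, readout_interval = 150,
                  seed = 1, sample = 200)
expr <- run_ensemble(sys, cfg)   # genes x 200 steady-state replicates
expr
#> expression_matrix (ensemble): 4 genes x 200 replicates

w <- mutual_information_matrix(expr)
edge_separation(w, net)[c("edge_median", "nonedge_median", "effect_size")]
```

On a 20-node scale-free network with the default kinetics
(`separation_experiment(seed = 1)`) the median binned-MI weight of true
edge pairs (0.507 bits) exceeds the non-edge median (0.437 bits) with
rank-sum effect size 0.60 — the simulated expression encodes the topology,
which is the property a benchmark generator must have. Across seeds 1–20
this separation holds in 18 of 20 repetitions (see
`tests/testthat/test-acceptance.R`).

## Command line

```sh
Rscript inst/cli/grnsim.R simulate --network net.tsv --config cfg.json \
        --seed 1 --out expr.tsv
```

Modes: `compile`, `simulate`, `ensemble`, `parse-simulate`, `validate`.
Every run writes a JSON sidecar echoing its configuration; identical seeds
give byte-identical outputs.

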