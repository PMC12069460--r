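---
title: "Building maximum-parsimony ancestral recombination graphs by reinforcement learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building maximum-parsimony ancestral recombination graphs by reinforcement learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(argrl)
```

## The problem

An ancestral recombination graph (ARG) describes how a sample of present-day
haplotypes is related to its most recent common ancestor (MRCA) through three
kinds of events, read backwards in time:

* **coalescence** — two lineages merge into a common ancestor; legal whenever
  their ancestral material agrees wherever both carry it;
* **mutation** — under the infinite-sites model each marker mutates at most
  once in the whole genealogy, so a derived allele (`1`) carried by exactly
  one sequence copy may be reverted to the ancestral allele (`0`);
* **recombination** — one lineage splits into two parental lineages at a
  breakpoint, each carrying the ancestral material on its side; positions a
  lineage did not transmit are written `*` (non-ancestral material).

A sample is a multiset of polarized 0/1 sequences of `L` SNPs.  The process
ends at a single fully ancestral all-zero sequence.  We call the number of
events the *length* of the ARG; because the mutation and coalescence tallies
of a complete genealogy are fixed by the sample (one mutation per derived
column, `n - 1 + R` coalescences for `R` recombinations), minimizing length
is the same as minimizing the number of recombinations — the classical
maximum-parsimony objective.

Genealogy construction is here cast as a shortest-path Markov decision
process: states are multisets of sequences, actions are the legal events,
every action costs one step (reward −1), and the terminal state is the MRCA.
This package implements that decision process exactly at toy scale, trains a
reinforcement-learning (RL) agent with a function approximator at 10-SNP
scale, combines independently trained agents into ensembles, and
re-implements the ARG4WG heuristic as a baseline.

## The decision process

`legal_actions()` enumerates, in a fixed canonical order (coalescences, then
mutations, then recombinations, each sorted lexicographically — needed for
reproducible tie-breaking under seeds):

* coalescence for every unordered pair of compatible sequence *types* (a
  type present twice may coalesce with itself);
* mutation `(type, marker)` when exactly one copy carries the derived allele
  there;
* recombination `(type, gap)` for every type except the fully ancestral
  all-zero sequence (the MRCA itself — splitting it is never useful), at
  every gap with ancestral material strictly on both sides.

Three conventions deserve comment because the event rules alone do not pin
them down:

* **Disjoint coalescence.**  Two sequences whose ancestral material does not
  overlap satisfy the compatibility rule vacuously; we allow the merge by
  default.  We verified during development that both conventions reproduce
  the reference counts below (the minimal genealogies of the worked samples
  never use such merges), so the permissive literal reading is the default
  and `allow_disjoint = FALSE` is available.
* **Which sequences recombine.**  Only the fully ancestral all-zero sequence
  is excluded; a partially ancestral sequence such as `*00*` remains
  splittable (`recomb_exclude = "ancestral-zero"` gives the stricter rule).
* **Breakpoint validity.**  A gap is a breakpoint only if ancestral material
  lies strictly on both sides.  This forbids fragments of pure `*`, and for
  fully ancestral 4-SNP sequences yields exactly 3 gaps per sequence — hence
  the worked inventory of 12 recombinations for a 4-sequence state.

Two conservation laws make useful invariants: every marker column keeps at
least one ancestral copy under every event, and a complete ARG from a sample
with `S` segregating sites and `n` sequences has length `S + n − 1 + 2R`, so
all complete genealogies of one sample have the same length parity.

## Exact layer

Because the process is deterministic with unit costs, the optimal value
function is minus the distance-to-MRCA, and everything of interest can be
computed exactly for toy samples:

```{r exact}
ex <- example_states()
min_arg_length(ex$sample_a)
count_min_args(ex$sample_a)
count_min_args(ex$sample_b)
```

All searches share one pruning rule that is exact rather than heuristic:
from a state with `m` derived columns and `n` sequences, every completion
has length `m + n − 1 + 2R`, so a budget below `m + n − 1` or of the wrong
parity contributes zero genealogies.  With it, counting the 758 minimal
genealogies of the first worked sample touches only a few hundred memoized
states instead of the ~780,000 states reachable within nine events.

`value_iteration()` runs the classical sweep (values initialized to −1 on
non-terminal states, 0 on terminal ones, updates
`V(s) ← max_a (−1 + V(s'))`, stop when the largest change drops below
`theta`, default `1e-6` — the dynamics are integral, so any `theta < 1` is
exact).  The stored state space is restricted to states reachable at depth
`d` with `d + m + n − 1` within the depth cap, i.e. states from which a
complete ARG within the cap is still arithmetically possible.  The test
suite cross-checks every converged table against an independent reverse
breadth-first search (`terminal_distances()`).

`optimal_policy()` keeps, per state, all actions whose successor improves
the value by exactly one; under the optimal policy these are equally
likely, which induces a probability on every minimal genealogy
(`arg_probability()`; the probabilities of all minimal genealogies sum
to 1).  *Distinct* genealogies are distinct ordered event lists, not graph
isomorphism classes — this is the convention under which the enumeration
reproduces the 758/414 reference counts.

## Featurization and the value network

Tabular methods die quickly: the state space grows as `O(n^(3L−1))`.  The
approximation layer represents a state by block counts
(`make_scheme()`, `featurize()`): for blocks of `B` markers shifted by `o`
positions there are `P = (L − B + o)/o` positions and `3^B` block types
over `{0, 1, *}`, giving a feature dimension `c = 3^B · P` independent of
the number of sequences.  The block idea mirrors the three-gamete test
(`recombination_required()`): with polarized data, a column pair showing
gametes `01`, `10` and `11` forces a recombination, and two-marker blocks
carry exactly that signal.  The default for 10-SNP data is `B = 3`, `o = 1`
(`c = 216`); the worked 4-SNP examples use `B = 2`, `o = 1` (`c = 27`).

The value network (`init_network()`) is `c → ⌊c/2⌋ → 1` with ReLU hidden
activation and −ReLU output, so estimates are never positive — correct,
since true values are −(events remaining).  Its parameter count is
`d = (c + 1)·⌊c/2⌋ + ⌊c/2⌋ + 1`, e.g. 23,545 at `c = 216`.  The hidden
width uses the floor because `c/2` is fractional whenever `P` is odd.
Weights are initialized uniform per layer fan-in,
`U(−1/√fan_in, 1/√fan_in)`, fully determined by `(scheme, seed)` — except
the output bias, which starts at +1.  This is not cosmetic: with a −ReLU
output, any initialization whose output pre-activation is negative in the
visited region has zero gradient everywhere, so the network freezes at
birth and every rollout stays a random walk; roughly half of unconstrained
random initializations are affected.  Starting the output bias at +1 puts
the output unit on the active side of its kink and makes the initial
estimate close to −1 for every state, mirroring the tabular sweep's
`V = −1` start.

Three numerical choices are deliberate:

* **Terminal states are valued exactly 0 and excluded from updates.**  The
  sweep fixes `V = 0` on terminals, but a raw network output merely hovers
  near zero; without the hard convention a greedy agent may never prefer
  finishing.  `state_value(..., terminal_zero = FALSE)` exposes the raw
  output for diagnostics.
* **ReLU derivative at the kink is 0.**  The analytic gradient
  (`net_gradient()`) is checked against central finite differences to
  better than `1e-5` relative error in the test suite.

## Training

`train_same_sample()` implements gradient Monte Carlo: generate an episode
with an ε-greedy policy, then for each visited state apply
`w ← w + α (G_t − v̂(S_t, w)) ∇v̂(S_t, w)` with `G_t = −(T − t)`, each step
using the weights already updated by the earlier steps of the same episode.
Defaults: `α = 1e-4`, `ε = 0.1`, 10,000 episodes, and deduplication of the
initial sample to unique types (the learned policy still applies to the
full sample).  Training episodes are capped at 10,000 steps; a capped
episode has no observed return, so it is recorded as truncated and skipped
by the update rather than bootstrapped — the Monte Carlo target stays
unbiased at the cost of discarding a little early experience.

`train_generalize()` targets samples unseen during training: each episode
starts from the next `n_tr` sequences of a seeded without-replacement
stream over a training pool (duplicates kept — with small `n_tr` they teach
the agent when to coalesce), the pool is reshuffled when fewer than `n_tr`
remain (the remainder is discarded; a top-up variant would mix epochs, so
the simpler stream was chosen), and checkpoints are kept at every pool
exhaustion, on a fixed cadence (default every 2,000 episodes from episode
40,000), and at the end.

Evaluation rollouts (`build_arg()`) are greedy with seeded tie-breaks and a
step cap `Stepmax` (default 300); a rollout hitting the cap is classified
an *infinite-length genealogy* — the characteristic failure mode is a loop
in which a recombination is immediately undone by the coalescence of its
two fragments.  `soften_policy()` turns the greedy policy into a
distribution over the `g` best actions; the functional form of those
probabilities is not dictated by anything upstream, so the package uses a
softmax over successor values with a temperature (temperature → 0 recovers
greedy, `g = 1` is degenerate).

All randomness flows from one master seed through derived sub-streams
(initialization, exploration and tie-breaks, pool rotation), so identical
configurations reproduce identical networks, checkpoints and histories.

## Model selection and ensembles

Checkpoints are compared on a validation set cut into samples
(`evaluate_policy()`): the best model is the one with the smallest
proportion of infinite-length genealogies, then the smallest mean finite
length, then the earliest checkpoint (`select_best_checkpoint()`).
Generalization is judged more important than raw length, hence the
lexicographic order.

`arg_ensemble()` combines `M` independently initialized agents three ways:
**mean** (average the value estimates, act greedily on the average),
**majority** (each member votes its greedy action at every state of one
joint rollout; plurality wins, ties broken by seeded draws), and
**minimum** (build one ARG per member, keep the shortest finite one).  The
majority method votes per state rather than comparing whole trajectories —
with per-state voting the ensemble walks a single coherent genealogy and
degenerates gracefully to the single-member policy at `M = 1`.  The
minimum method gives two invariants the tests assert: its length never
exceeds any member's, and its infinite proportion never exceeds any
member's.

## The ARG4WG baseline

The heuristic builds genealogies by strict priority: any legal coalescence;
else any legal mutation; else find the pair of sequences with the longest
*shared end* — the maximal run of ancestral-and-equal symbols from either
the left or the right end — recombine one sequence of the pair at the inner
boundary of the shared segment, and immediately coalesce the
shared-segment fragment with the partner.  The description leaves the pair,
the end direction and which sequence to split open; all three are
tie-break dimensions, resolved by a seed in `arg4wg_build()` and explored
exhaustively in `arg4wg_enumerate()`.  Under these conventions the
enumeration yields exactly 8 distinct genealogies of length 9 on each of
the two worked samples, against 758 and 414 for the exact optimal policy —
the heuristic is as short but far less diverse.  On three-gamete-compatible
samples the priority order implies it never recombines, and it can never
beat the exact minimum (both asserted in the tests).

## Synthetic data

`sim_hudson()` is a compact single-population coalescent-with-recombination
simulator in the Hudson style: lineages carry ancestral intervals annotated
with descendant sets over a discrete sequence of candidate sites;
coalescence merges interval maps (intervals whose descendants reach the
full sample are dropped — their genealogy is complete), recombination
splits at a uniform breakpoint inside a lineage's ancestral span at rate
proportional to that span, and infinite-sites mutations ride competing
exponential clocks on the total ancestral material, with second hits on a
site discarded.  `simulate_sample()` keeps the first `L_keep` segregating
columns in genomic order (the same sites for every individual),
re-simulating with fresh sub-seeds when a replicate yields too few.

What it emulates: neutral constant-size coalescent genealogies, Watterson
scaling of segregating sites (checked against
`E[S] = 4·Ne·mu·region·H_{n−1}` at `rho = 0` in the test suite), seeded
reproducibility, and tree-compatible samples at `rho = 0` (so the
three-gamete test, the perfect-phylogeny identity
`min length = S + n − 1` and the zero-recombination behaviour of ARG4WG
can all be exercised).  What it does not emulate: demography, selection,
gene conversion, recurrent mutation, or the exact internal conventions of
any external simulator — `read_haplotypes()` imports externally simulated
matrices for anyone who needs parity with a specific tool.

## Problem sizes used by the tests

The test suite runs the exact layer on the two worked 4×4 samples (their
full minimal enumerations: 758 and 414 genealogies), value-iteration/BFS
cross-checks on a handful of toy states, 20-case finite-difference gradient
checks on 4-SNP networks, same-sample training at the default
hyperparameters (`α = 1e-4`, `ε = 0.1`, 10,000 episodes) over three seeds
on the first worked sample, and a reduced generalization pipeline (a
simulated 30-sequence 4-SNP pool, two agents, 60 episodes each, all three
ensembles).  These sizes were chosen so the whole suite documents every
layer of the method while remaining a routine desk-scale run; the
full-scale generalization protocol (13 agents × 100,000 episodes on a
15,500-sequence 10-SNP pool) is documented in
`scripts/replicate_full.R`, which runs the identical code path at any
`--scale`.

Passing tests show that the implementation is faithful to the decision
process and reproduces the exact reference quantities; they do not show
that the RL agent is competitive on real data — 10 SNPs is far below
genomic scale, the simulator is deliberately minimal, and same-sample
training must be repeated per sample.

## Known limitations

* The exact layer is feasible only around 4 sequences × 4 SNPs; the state
  space explodes as `O(n^(3L−1))`.
* The approximation layer is engineered for `L = 10`; longer sequences
  inflate both `c` and the parameter vector quadratically.
* ARGs carry no branch lengths or times — genealogies are event sequences.
* Greedy rollouts can loop (the infinite-length pathology); `Stepmax`
  classifies rather than cures, and ensembles mitigate rather than
  eliminate it.
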