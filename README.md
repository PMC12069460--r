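# argrl

Maximum-parsimony ancestral recombination graphs (ARGs) by reinforcement
learning.

An ARG relates a sample of polarized SNP haplotypes (0 = ancestral allele,
1 = derived allele) to its most recent common ancestor (MRCA) through
coalescence, mutation and recombination events, read backwards in time.
Under the usual parsimony assumption the most plausible genealogies are the
shortest ones — those with the fewest recombinations.  `argrl` treats
genealogy construction as a shortest-path Markov decision process: states
are multisets of sequences over `{0, 1, *}` (`*` marks non-ancestral
material), actions are the legal events, every action costs one step
(reward −1), and the terminal state is the single all-zero MRCA sequence.
The optimal value function is `v*(s) = −(minimal number of events from s to
the MRCA)`.

The package provides:

* **an exact tabular layer** for toy samples — minimal ARG length, value
  iteration with a breadth-first-search cross-check, exhaustive enumeration
  and counting of all minimal genealogies, and the probability each one
  receives under the optimal policy (all optimal actions equally likely);
* **a reinforcement-learning agent** for 10-SNP samples — a block-of-markers
  feature vector of dimension `c = 3^B · P` with `P = (L − B + o)/o`, a
  `c → ⌊c/2⌋ → 1` value network (ReLU hidden layer, −ReLU output so
  estimates stay non-positive, `d = (c+1)·⌊c/2⌋ + ⌊c/2⌋ + 1` parameters),
  trained by gradient Monte Carlo
  `w ← w + α (G_t − v̂(S_t, w)) ∇v̂(S_t, w)` under an ε-greedy behavior
  policy, in both a same-sample regime and a pool-rotation regime that
  generalizes to unseen samples;
* **ensemble policies** over independently trained agents — mean value,
  per-state majority vote, and shortest-of-M construction — plus
  validation-based checkpoint selection by smallest proportion of
  infinite-length genealogies, then smallest mean length;
* **the ARG4WG heuristic** as a baseline (coalesce if possible, else
  mutate, else recombine at the longest shared end and coalesce the shared
  fragment), with exhaustive tie-break enumeration;
* **a seeded coalescent-with-recombination simulator** in the Hudson style
  for generating test haplotype pools without external tools.

## Worked example

The classic 4-sequence, 4-SNP sample `{0011, 1011, 1000, 1100}`:

```r
library(argrl)
s <- example_states()$sample_a

min_arg_length(s)
#> [1] 9
count_min_args(s)
#> [1] 758
```

The shortest genealogy needs 9 events, and 758 distinct event sequences
achieve that length — an exhaustive answer obtained by memoized search.
Value iteration agrees and induces a distribution over them:

```r
vt  <- value_iteration(s, depth_cap = 9)
state_value(vt, s)
#> [1] -9
pol  <- optimal_policy(vt)
args <- enumerate_min_args(s)
sum(vapply(args, arg_probability, numeric(1), pol = pol))
#> [1] 1
```

The ARG4WG heuristic also reaches length 9 on this sample, but exhausting
every tie-break yields only 8 distinct genealogies — the learned optimal
policy is two orders of magnitude more diverse:

```r
arg4wg_build(s, seed = 1)$length
#> [1] 9
length(arg4wg_enumerate(s))
#> [1] 8
```

Training an agent on the same sample recovers the exact minimum without
any pre-programmed rules:

```r
run <- train_same_sample(s, train_config(alpha = 1e-4, epsilon = 0.1,
                                         episodes = 10000, seed = 1))
a <- build_arg(s, run$net, stepmax = 300, seed = 1)
a$length
#> [1] 9
```

A command-line front end (`inst/cli/argrl`) wraps the same functions:
`simulate`, `exact`, `arg4wg`, `train`, `select`, `ensemble`, `evaluate`.

```sh
inst/cli/argrl exact solve --haplotypes inst/extdata/sample_a.txt --count
# minimal ARG length: 9
# minimal genealogies: 758
```

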