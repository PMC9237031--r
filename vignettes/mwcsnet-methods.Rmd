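---
title: "Detecting active modules with mwcsnet: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting active modules with mwcsnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwcsnet)
```

## The problem

A differential-expression experiment yields one p-value per gene. Genes do
not act alone: the biologically meaningful readout is often a *module* — a
connected neighborhood of a protein–protein interaction (PPI) network whose
members are jointly, if individually weakly, perturbed. `mwcsnet` turns
per-gene p-values into additive node scores, finds the most-weighted
connected subgraph (MWCS) of the reference network, and attaches empirical
significance to each module gene. A companion analysis asks a related
question for curated disease gene sets: are they more connected to the
differentially expressed genes than expression-matched random sets would
be?

## The beta-uniform mixture

The p-value distribution from a genome-wide test is modelled as a mixture
of noise and signal:

$$f(x) = \lambda + (1 - \lambda)\,\alpha\,x^{\alpha - 1},
  \qquad \lambda, \alpha \in (0, 1),$$

a Uniform(0,1) noise component with weight $\lambda$ and a
Beta($\alpha$, 1) signal component concentrating near zero. `fit_bum()`
estimates $(\lambda, \alpha)$ by maximum likelihood. Because the likelihood
is flat-to-multimodal when signal is weak, the optimizer works on the logit
scale (keeping both parameters strictly inside $(10^{-4}, 1-10^{-4})$ so
the density and the scores stay finite) and restarts from a fixed
four-point grid plus seeded random starts, keeping the best run. The
diagnostic `pi0_upper` $= \lambda + (1-\lambda)\alpha = f(1)$ is the usual
upper bound on the true-null fraction.

Inputs need at least 100 p-values; below that the fit is refused unless
forced, because two-parameter MLE on a handful of order statistics is not
stable. p-values of exactly zero are clamped to $10^{-300}$ on load (the
log-likelihood needs $\log p$ finite) with a warning.

## Node scores

Given a threshold $\tau$, genes are scored with the log signal-to-noise
ratio of the beta component relative to the threshold:

$$s(x) = (\alpha - 1)\,(\ln x - \ln \tau).$$

$s(\tau) = 0$; genes with $p < \tau$ score positive, others negative, and
$s$ is strictly decreasing in $x$, with the antisymmetry
$s(\tau r) = -s(\tau / r)$. The default $\tau$ is the Bonferroni-adjusted
level over the scored genes, $0.05 / \#\text{genes expressed}$, and the
significance level is exposed as `alpha_level`. Natural logarithms are
used: the base only rescales all scores by a positive constant, so it
cannot change which connected subgraph is heaviest, but it does change the
printed magnitudes, and that choice is therefore documented.

By default the mixture is fitted to *all* genes in the supplied table, not
only those present on the network: the p-value distribution being modelled
is the experiment's, and restricting it to network-mapped genes would tie
the noise model to the coverage of the interaction database. A caller who
prefers the restricted fit can subset the table first.

## The MWCS search

`solve_exact()` enumerates every connected induced subgraph (recursive
extension with per-branch bans so each subset is visited once, plus an
admissible bound — current score plus all still-allowed positive scores —
for pruning) and is intended for graphs of a few dozen nodes at most; it
doubles as the reference the heuristic is validated against. Ties are
broken by fewer nodes, then lexicographically on the sorted member list,
so outputs are byte-stable.

`solve_heuristic()` scales to real interactomes with a prize-collecting
pipeline:

1. connected components of positive-score nodes are contracted into
   super-nodes weighted by their score sums;
2. a Steiner-like tree over super-nodes is grown greedily from the
   heaviest one, connecting the next super-node through its cheapest
   node-weighted path (cost = minus the sum of non-positive interior
   scores; nodes already in the tree cost nothing), accepted only when the
   super-node weight exceeds the path cost;
3. the tree is expanded to original nodes, absorbing any positive
   component a path runs through;
4. leaves with non-positive scores are pruned to a fixpoint.

The result is always connected, never retains a prunable non-positive
leaf, contains every positive component either wholly or not at all, and
never scores below the best single node. Disconnected inputs are searched
per component and the best module returned. When no gene scores positive
the single best node is returned with a warning — a module is always
reported, weak signal or not, with the warning carrying the caveat. On
random benchmark graphs the heuristic attains at least 95% of the exact
optimum in about 99% of instances and can never exceed it (it returns a
feasible subgraph).

## Permutation significance

A gene can sit in the MWCS because of its own p-value or because the
topology funnels paths through it. The null model therefore randomizes
both at once, every iteration: p-values are permuted across genes
(preserving their multiset) *and* the network is rewired by double-edge
swaps that preserve every node's degree and reject any swap creating a
self-loop or duplicate edge. Scores are recomputed from the permuted
p-values with the *observed* fit's $(\alpha, \tau)$ — so the score multiset
is exactly preserved and the null isolates assignment and topology;
refitting per permutation is available behind `refit = TRUE`. Each
iteration draws its own substream seed from the master seed, so results
are reproducible and independent of iteration order.

Per observed-module gene the null appearance count $k$ out of $B$
(default 1000) yields the raw frequency $k/B$ (the scale on which a
"fewer than 5/1000" reporting cut operates) and the pseudocounted
empirical p-value $(k+1)/(B+1)$, which can never be zero and has floor
$1/(B+1)$. Bonferroni adjustment multiplies by the observed module size —
the number of gene-level hypotheses actually tested. Both estimators are
reported side by side.

One calibration caveat is worth stating plainly. When the data are pure
noise, a Bonferroni $\tau$ leaves essentially no positive scores and both
the observed and the null modules collapse to single-node fallbacks; the
null frequency of any particular gene is then about $1/n$ for a network of
$n$ genes, so *unadjusted* empirical p-values of the (selection-biased)
observed gene are small by construction. This is module-selection bias,
not evidence; it is the reason the package reports and thresholds the
*adjusted* p-values, and the test suite checks the mechanics (estimator
identities, determinism, degree conservation) plus the concentration of
null frequencies around the null module coverage rather than asserting
uniformity of selection-biased unadjusted p-values.

## Connectivity enrichment

For a disease gene set $A$ and a DE gene set $B$ on a network, the
statistic is the proportion of connections involving either set that link
the two:

$$T(A, B) = \frac{\#\{\text{edges with one end in } A,
  \text{ the other in } B\}}
  {\#\{\text{edges with at least one end in } A \cup B\}}.$$

The denominator phrase "all connections observed for all genes in both
sets" admits two readings; edges *incident* to the union is the default
(degree-robust, and the more literal reading), with `denominator =
"within"` for the union-internal alternative. Genes in both sets are
assigned to the disease set only, so a gene can never link the sets to
itself. $T$ is symmetric in its arguments.

Co-expressed genes are better connected than random pairs, so the null
sets must match the disease set's expression profile. Two matchers are
provided: `decile` bins all genes into ten near-equal rank bins of mean
expression (ties broken by gene id) and resamples the disease set's exact
bin histogram; `pct10` replaces each disease gene with a random gene whose
mean expression lies within ±10%. Empirical p-values use the one-sided
$(1 + \#\{T_\text{null} \ge T_\text{obs}\})/(B+1)$ estimator and are
Bonferroni-adjusted over the number of disease sets tested. Simple
overlap questions use `overlap_test()`: hypergeometric and binomial upper
tails with an odds ratio (Haldane 0.5 correction on empty cells); the
binomial success probability defaults to $|R|/|U|$ and is exposed as a
parameter.

## The synthetic benchmark

`simulate_instance()` generates the complete study: a network
(preferential attachment by default — degree-heterogeneous, like real
interactomes; Erdős–Rényi and configuration models available), a planted
connected module grown by random walk, p-values — Beta($\alpha_s$, 1) for
planted genes, Uniform(0,1) for the rest, a *sharp-null* mixture so the
recovery truth is unambiguous — log-normal mean expression
(`meanlog = 5`, `sdlog = 1.5`: median ≈ 150 with a long right tail, a
plausible normalized-count profile), and optionally a disease set with a
planted excess of cross-edges to the top DE genes. Expression is
independent of p-values by default. Defaults are `n_nodes = 500`,
`module_size = 20`, `alpha_signal = 0.1`, chosen as a desk-scale analogue
of a transcriptome-by-interactome study: large enough for degree
heterogeneity and matched-sampling structure, small enough that a
1000-permutation run completes in about a minute.

What the generator does *not* emulate: count-level noise and dispersion
(DE testing is upstream and out of scope), correlated p-values among
neighbors, annotation bias of PPI databases (hub genes are better
studied), or expression–connectivity correlation (a knob exists for
stressing the decile matcher). Passing benchmarks here demonstrates the
statistical machinery is correct, not that any particular biological
dataset will yield a clean module.

Two scale effects of the benchmark are worth knowing. First, with
$\tau = 0.05/500 = 10^{-4}$ and a Beta(0.1, 1) signal (median p-value
$0.5^{10} \approx 9.8\times10^{-4}$, above $\tau$), only a minority
(about $\tau^{0.1} \approx 40\%$) of planted genes score positive; since
a score-maximal subgraph takes negative nodes only as connectors, module
sensitivity to the full planted set plateaus around one half at these
settings even for an exact solver — the recovered module is essentially
the positive planted genes plus their cheapest bridges, which is the
correct optimum, with a false-member fraction near zero. Second, a
particular gene's null appearance frequency is bounded below by roughly
(module size)/$n$, so the very small per-gene frequencies reported for
genome-scale networks are only reachable as $n$ grows.

## Numerical and degenerate-input choices

* Optimizer: BFGS on logit-transformed parameters, 8 starts, relative
  tolerance $10^{-12}$; all-identical p-values are refused as degenerate.
* Score/total-score comparisons use a $10^{-12}$ slack; candidate modules
  tie-break by (score, size, lexicographic members).
* Rewiring proposals default to $10\times$ the edge count; graphs with no
  valid swap are returned unchanged with a warning.
* Decile bins: rank-based (`ceiling(rank * 10 / n)`), ties broken by gene
  id, so bins are deterministic and near-equal; monotone transformations
  of expression leave the binning unchanged.
* Empty intersections (no scored network gene, both enrichment sets
  empty, empty universe) are errors, not silent zeros; a zero connectivity
  denominator returns 0 with a warning.
* All stochastic entry points take a seed and draw per-iteration
  substreams from it, so every result is reproducible bit-for-bit.

## Problem sizes used by the shipped checks

The test-suite and acceptance-script benchmarks run at: 20 replicates of
$n = 10{,}000$ for mixture recovery; 200 random graphs ($n \in [6, 14]$)
for the solver cross-check; 10 seeds of the $n = 500$ planted-module
instance; $B = 200$–$1000$ permutation runs; 100 calibration replicates at
$B = 200$ for connectivity enrichment. These sizes were chosen so the
whole battery reruns in a few minutes on a laptop while keeping
Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* The heuristic has no approximation guarantee; its quality is validated
  empirically against the exact solver on small graphs.
* Identifier matching is exact and case-sensitive; mapping between
  identifier systems is out of scope.
* Edge confidence weights are parsed but ignored: scoring is node-based.
* The permutation null preserves the degree sequence but not higher-order
  structure (clustering, communities); empirical p-values inherit that
  choice of null.
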