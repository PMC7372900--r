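---
title: "Logic-based GRN inference with a beta likelihood: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logic-based GRN inference with a beta likelihood: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(logicgrn)
```

## The model

`logicgrn` treats a normalized expression level in $[0,1]$ as the
probability that a gene is active. A set of $k$ regulators partitions the
space of joint activity states into $2^k$ disjoint activatory/inhibitory
combinations — the Venn partitions, or minterms: for $k=2$ these are
$G_1G_2$, $G_1\bar G_2$, $\bar G_1 G_2$, $\bar G_1\bar G_2$. A logic
function is a union of some subset of partitions, encoded by a bit per
partition; the bits, read as a binary number, give the function index $i$,
and there are $2^{2^k}$ functions of $k$ inputs. Index 8 of two inputs is
AND (only $G_1G_2$ active), 14 is OR, 6 is XOR, 0 and $2^{2^k}-1$ the
constants.

Two evaluation semantics are provided:

* **Probabilistic-continuous (PC)** — a partition is the probability of
  the corresponding joint event under independence,
  $\prod_j x_j^{[j\,\in\,p]}(1-x_j)^{[j\,\notin\,p]}$, and the union is the
  plain sum (the partitions are disjoint and exhaustive, so the result is
  always in $[0,1]$ and complementary masks sum to 1 exactly).
* **Fuzzy** — literals combine by $\min$ within a partition and by the
  bounded sum $\min(1, \Sigma)$ across partitions. Kept as the comparison
  semantics; on Boolean inputs both agree with the mask's truth table.

The target's level in sample $s$ is modelled as
$T_s \sim \mathrm{Beta}(c f^{(s)} + \varepsilon,\; c(1-f^{(s)}) + \varepsilon)$
where $f^{(s)}$ is the logic output on that sample's regulator values.
With $\varepsilon = 0$ the beta mean equals $f^{(s)}$ exactly, so the
logic is an unbiased estimator of the target level and $c=\alpha+\beta$
controls how tightly the data must hug it. Because the parameters are set
per sample, multi-modal target distributions pose no difficulty.

Model search is exhaustive: every regulator subset of size $1..k_{\max}$
times every logic of that arity, scored by
$\mathrm{BIC} = -2\,\ell + 2^k \ln n$ (one on/off parameter per
partition), with ties broken toward fewer regulators, then the earlier
subset, then the smaller index. The per-target candidate count is
$\sum_{j=1}^{k_{\max}} 2^{2^j}\binom{N-1}{j}$
(`count_candidate_models(10, 3)` = 22116), and all logics of one subset
are evaluated in a single mask-matrix product over the shared partition
probabilities — the search is exact, not heuristic. The minimum-BIC model
is accepted only if its Bayes factor against a null logic exceeds 100
(strict), and its essential inputs — the inputs its truth table actually
depends on — become signed directed edges.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `c` | 1000 | beta concentration $\alpha+\beta$ (unitless); larger = tighter coupling of target to logic output. Benchmarks are insensitive over 500–1250. |
| `eps` | 1e-4 | added to both shapes so $f \in \{0,1\}$ never yields a zero parameter; applied always, for continuity. |
| `delta` | 1e-4 | targets clamped into $[\delta, 1-\delta]$ before logs; min-max scaling guarantees exact 0s and 1s that would otherwise be $-\infty$. |
| `k_max` | 3 | deepest regulator subset; 4 is supported but the $2^{2^k}$ factor makes it expensive. |
| `bf_threshold` | 100 | decisive-evidence cutoff, strict. |
| `null_mode` | `constant_half` | the null logic $f \equiv 0.5$: deterministic, data-independent, and equal to the expected output of a uniformly random logic at random inputs. `random_sample` instead averages the log-likelihood of logics drawn (without replacement) from the enumeration. |

Neither `eps` nor `delta` has a canonical published value; both are
configuration knobs and results are insensitive to them at these
magnitudes.

## What the simulator emulates — and what it does not

`make_random_signed_network` draws a uniform simple digraph (no
self-loops, in-degree capped at 3 by default so the default search depth
can represent every target exactly); edge signs are inhibitory with
probability 0.3 — a round value in the range typical of curated bacterial
subnetworks, chosen once. `assign_random_logics` gives each multi-regulator
target a uniform draw from AND/OR/XOR over its sign-adjusted literals
(single regulators get the plain literal; XOR with one input is
meaningless and never drawn; XOR over $m \ge 3$ literals is parity).
`simulate_expression` draws root genes $\mathrm{Uniform}(0,1)$, evaluates
regulated genes in topological order, and takes one beta draw per gene and
sample at the model's own noise law. Cycles are handled by five rounds of
synchronous deterministic relaxation from uniform starts, with the beta
draw taken once at the end. Roots' distribution, the relaxation scheme and
the sweep count are not canonical — they are this package's choices, made
once and fixed; with them the benchmark reproduces the qualitative
behavior (and approximate magnitudes) of published three-level results,
not their exact values, which also depend on a specific curated topology.

Simulated matrices are *not* min-max rescaled before inference in the
benchmark. The draws already live on $[0,1]$, and per-row stretching
breaks the exact functional relation between a target and its regulators
that the tight beta likelihood tests: on a seeded replicate, rescaling
drops the directed-logical F from about 0.39 to 0.09 while leaving
directed-edge recovery similar. Scaling remains the default path for real
data (`minmax_scale`, CLI `infer --scale`), whose units are arbitrary.
Consequently, passing benchmarks here says nothing about the adequacy of
min-max scaling, measurement noise models, unmeasured confounders, or
post-transcriptional regulation in real data — only that the
search-and-score machinery recovers structure and logic when the model
family matches the generator.

## Numerical choices and degenerate inputs

* Likelihoods go through the beta log-density (`stats::dbeta(log=TRUE)`);
  tests cross-check against an independent `lgamma`-form implementation
  and, for the symmetric case, the Legendre-duplication closed form.
* Boundary targets are clamped, never dropped; the likelihood is finite
  for every valid input.
* Overflowing Bayes factors return `Inf`, which passes the strict
  threshold — the intended reading of "decisive".
* Constant expression rows are rejected by name at scaling time (they
  carry no signal and would divide by zero).
* Candidates whose logic has non-essential inputs are enumerated (no
  pruning rule is assumed), but an equal-likelihood reduced model always
  has strictly smaller BIC, so accepted models never carry a non-essential
  regulator; this is asserted exhaustively in tests at $k \le 3$.
* Partition indexing is uniformly binary in $k$ (input 1 = most
  significant bit). Published two-input tables match this convention
  exactly; a published three-input listing orders partitions by negation
  count instead, so three-input *indices* from that source are not
  directly comparable — the function set is identical, only labels differ.

## The Bayes-factor filter in practice

Against the `constant_half` null, targets that genuinely track a logic of
their regulators pass with enormous margins, and targets whose
distribution the null already explains (levels concentrated near 0.5) are
rejected. But for a target of unstructured uniform noise the null itself
fits very poorly, and the best of tens of thousands of candidates
practically always clears the threshold — the filter is not a false-positive
control for such targets, under either null mode. This matches the
behavior of the published procedure (every gene receives a model, and the
directed-logical level accounts for the resulting false partitions); treat
the BF as a measure of support relative to an uninformative reference, not
as an error-rate guarantee.

## Problem sizes used in tests and the acceptance script

The bundled benchmark runs 20 replicates of 10-gene/15-edge networks at 10
samples with $k_{\max}=3$ (one replicate scores $10 \times 22116$
candidates and takes on the order of a second), plus a 20-replicate
fixed-structure AND-recovery study at $n = 10$ and $50$. These sizes give
stable aggregate metrics while keeping a full run in tens of seconds;
counts at the three evaluation levels are accumulated over replicates and
converted to metrics once, the way benchmark totals are usually tabulated.

## Known limitations

* Exhaustive search is exponential in $2^k$: $k_{\max} = 4$ over tens of
  genes is the practical ceiling, and hundreds of genes require
  restricting candidate regulators.
* Steady-state, observational data only: a cyclic truth can only be
  approximated, and causal direction rests on the asymmetry of the
  likelihood, not interventions.
* The beta noise model with a global $c$ is both the generator and the
  scorer in simulations; real data will violate it to an unknown degree.
* Logic detection is per target; no attempt is made to reconcile global
  consistency (e.g. a gene called activator for one target and inhibitor
  for another is left as is).
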