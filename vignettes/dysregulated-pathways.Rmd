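---
title: "Detecting dysregulated pathways from mutual exclusivity and mutation-expression connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting dysregulated pathways from mutual exclusivity and mutation-expression connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyspathr)
```

## The model

Cancer driver mutations cluster into pathways: because one hit per
pathway is usually sufficient, the genes of a pathway are mutated in
largely non-overlapping patient sets. `dyspathr` detects such pathways
from a binary sample-by-gene mutation matrix $A$ paired with an
expression matrix $E$ over the same samples, in four stages.

**Pairwise exclusivity.** With $\Gamma(g)$ the coverage of gene $g$ (the
samples mutated in it), a pair is scored by the exclusive degree
$$\mathrm{ED}(g_i,g_j)=\frac{|\Gamma(g_i)\cup\Gamma(g_j)|}{|\Gamma(g_i)|+|\Gamma(g_j)|}\in[0.5,1]$$
and the weight degree
$$\mathrm{WD}(g_i,g_j)=1-\frac{|\Gamma(g_i)\cap\Gamma(g_j)|}{\min(|\Gamma(g_i)|,|\Gamma(g_j)|)}\in[0,1].$$
ED reaches 1 exactly for disjoint coverages; WD reaches 0 exactly when
one coverage nests inside the other. The weight degree matters because
ED alone is blind to coverage balance: over 100 samples, coverage pairs
of sizes 50/50, 75/25, 85/15 and 95/5, each with overlap 5, all have
ED = 0.95, yet their weight degrees are 0.9, 0.8, 2/3 and 0. Only the
balanced configurations deserve to be called exclusive; the nested 95/5
pair is an artefact of one very high-coverage gene. The coverage degree
$\mathrm{CD}=|\Gamma(g_i)\cup\Gamma(g_j)|/m$ is computed and reported by
`pair_scores()` but deliberately enters no decision: it has no role in
the edge criterion.

**Connectivity.** The matrix $C = A^\top E$ sums each expression gene's
values over the samples mutated in each mutation gene. The pair
$(g_h, g_k)$ is *connected* when
$$C_{hk}/|\Gamma(g_h)| \;\ge\; \tfrac1m\textstyle\sum_i e_{ik},$$
i.e. $g_k$'s mean expression in the mutated samples reaches its
cohort-wide mean, with ties passing. The mirrored form via $E^\top A$ is
algebraically the transpose of the same quantity, so the criterion is
evaluated once and the direction kept only as annotation.

**Network.** After a mutation-rate filter (default: keep genes mutated
in at least 3% of samples), an undirected edge joins two genes when
$\mathrm{ED}\ge\lambda$ **and** $\mathrm{WD}\ge\gamma$, or when the
connectivity criterion holds for the pair in either direction. Genes
with no edges do not appear. Exclusivity is evaluated over all
rate-filtered mutation genes; expression genes enter the network only
through connectivity edges.

**Cliques and merging.** All maximal cliques of size $\ge$ 3 are
enumerated (Bron–Kerbosch with pivoting, via igraph); a k-clique
percolation mode (`clique_mode = "cpm"`), in which communities are
unions of $k$-cliques chained by $(k{-}1)$-node overlaps, is available
as an alternative clustering of the same network. The clique sets are
then merged greedily: the pair with the highest overlap score
$$\mathrm{OS}(A,B)=\frac{|A\cap B|^2}{|A|\,|B|}$$
is replaced by its union while that highest score is strictly above
0.25. For equal-size sets, 0.25 means the intersection is half of each
set; a pair sitting exactly at 0.25 is not merged. Each merge reduces
the set count by one, so the loop terminates after at most
$n_\text{sets}-1$ merges, and on exit no surviving pair exceeds the
threshold.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `lambda_excl` ($\lambda$) | 0.95 | ED units | near-perfect exclusivity while tolerating noise that disrupts ideal exclusivity in real mutation data |
| `gamma_weight` ($\gamma$) | 0.8 | WD units | admits the balanced 50/50 and 75/25 configurations above and rejects 85/15 and nested pairs |
| `min_mutation_rate` | 0.03 | fraction of samples | genes below ~3% are treated as passengers; boundary is `>=` with a `>` option |
| `overlap_threshold` | 0.25 | OS units | strict: equal-size sets sharing exactly half their members stay separate |
| `min_clique_size` | 3 | genes | an isolated edge is a weak module; configurable down to 2 |
| `connectivity_mode` | `"signed"` | — | literal one-sided criterion; `"absolute"` applies it to $|e|$ for centered data dysregulated in either direction |

Expression values are used exactly as supplied; `scale_expression()`
(per-gene z-scores) is available and off by default, because the
appropriate normalisation depends on the platform and is not the
package's decision to make silently.

## Numerical choices

* All metrics are ratios of small integer counts computed in double
  precision; tests compare them at absolute tolerance $10^{-12}$, and
  the 85/15 weight degree is treated as the exact rational 2/3.
* Boundary comparisons are `>=` throughout the edge criteria and the
  rate filter, matching the method's definitions; the merge threshold
  alone is strict (`>`).
* Merge tie-breaking: among pairs with equal highest OS, the pair whose
  sorted member lists are lexicographically smallest is merged, making
  runs reproducible; the underlying greedy rule does not prescribe an
  order. Duplicate cliques are collapsed before merging.
* After alignment, samples are put in lexicographic order so results do
  not depend on input row order; clique output is ordered by size
  descending, then lexicographically.
* Degenerate inputs: empty coverage sets make ED/WD undefined and raise
  errors (they cannot arise after the rate filter); mutation genes with
  zero mutated samples are skipped, with a message, by
  `connectivity_pairs()`; an edgeless network yields an empty pathway
  list with a warning, not an error.

## The synthetic-data generator

`simulation_config()` / `generate_cohort()` emulate the data model the
method assumes: per sample and per planted pathway, with probability
$c$ (the pathway's coverage) exactly one member gene, chosen uniformly,
is mutated — so within-pathway exclusivity is structural and the ground
truth exact. Passenger mutations are added i.i.d. per matrix entry at
rate $\varepsilon$, the simplest corruption that can violate
exclusivity. Expression is a mean-zero Gaussian baseline
($\sigma$ = `noise_sd`) plus an additive effect $\delta$ for each
planted mutation→expression link in the samples where the linked
mutation gene is mutated. All randomness flows from one integer seed;
identical seeds give bit-identical cohorts.

The defaults — 300 samples, a 40-gene universe, two disjoint planted
pathways of four genes at $c=0.95$, $\varepsilon=0.005$, one link per
pathway with $\delta = 5\sigma$ — were fixed from a design analysis of
the thresholds, not tuned afterwards:

* Per planted gene the mutation rate is about $c/4 \approx 0.24$, far
  above the 3% filter. For two genes in *different* pathways the
  expected chance coverage overlap is $m p^2 \approx 17$ samples, while
  ED $\ge 0.95$ would require overlap $\le 0.05 \cdot 2mp \approx 7$ —
  roughly three standard deviations below the mean — so spurious
  cross-pathway exclusivity edges are rare. Smaller pathways with high
  coverage sharpen this separation, which is why the defaults use four
  genes at $c=0.95$ rather than larger, shallower pathways.
* The expression matrix measures only the link partner genes, and each
  partner is itself a member of the linked pathway. This reflects a
  targeted-partner view of mutation–expression coupling and keeps the
  detected pathways close to the planted truth, because the one-sided
  mean criterion is extremely permissive under mean-zero noise: an
  *unlinked* (mutation, expression) pair passes with probability ~0.5
  (the difference of two means of the same Gaussian sample is symmetric
  around zero). Any expression gene therefore attaches to an existing
  clique with substantial probability, and every foreign expression
  gene in the universe would inflate the detected pathways. With the
  default geometry, at most one foreign partner can join each pathway,
  bounding the recovery Jaccard below by 4/5.

What the generator does **not** emulate: mutational signatures and
copy-number structure, subtype mixtures, correlated passenger
mutations, expression platform artefacts, and any realistic marginal
distribution of expression. Recovery results on these cohorts therefore
certify the pipeline's logic — that the stages compose correctly and
the planted structure is recovered under the stated noise — not its
performance on real tumour cohorts.

## Problem sizes in the test suite

The suite checks each stage against independent brute-force oracles:
exhaustive subset enumeration for maximal cliques (100 random 12-node
graphs, ≤ 4096 subsets each), direct set arithmetic and per-sample
summation for the metrics and the connectivity criterion (100 random
cohorts of 6–15 samples), and 50 seeded 300-sample cohorts for
end-to-end planted-pathway recovery (pass when both planted pathways
reach Jaccard ≥ 0.8 in at least 90% of seeds). These sizes make every
oracle exact or near-exact while the whole suite runs in a few minutes.

## Known limitations

* The connectivity criterion is a deterministic threshold, not a
  statistical test; it carries no control of false positives and, as
  noted above, passes about half the time for unrelated pairs under
  centered noise. On cohorts with many expression genes it will
  dominate the network. The `"absolute"` mode changes what it detects,
  not its permissiveness. Treating connectivity as an eQTL-style test
  with significance control is out of scope by design.
* Hard thresholds on ED/WD carry no multiple-testing or permutation
  null either; λ and γ are screening knobs, not error rates.
* Maximal-clique enumeration is exponential in the worst case; the
  intended regime is the sparse networks that survive λ = 0.95.
* The number of final pathways is data-driven: nothing guarantees any
  particular count, and an edgeless network legitimately returns none.
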