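# dyspathr

Network-based detection of dysregulated pathways in cancer cohorts from
paired somatic-mutation and gene-expression data.

Driver mutations hitting one biological pathway tend to be **mutually
exclusive** across patients: a tumour usually needs only one hit per
pathway, so the patient sets covered by two same-pathway genes barely
overlap. A second, complementary signal is **mutation–expression
connectivity**: mutation of one gene shifts the expression of its pathway
partners. `dyspathr` combines the two signals into a gene network, finds
the densely connected gene sets in it, and merges overlapping sets into
candidate dysregulated pathways.

## The method

Inputs are a binary mutation matrix *A* (samples × genes, `a_ij = 1` when
gene *j* is mutated in sample *i*) and an expression matrix *E* over the
same samples. Writing `Γ(g)` for the coverage of gene *g* (the set of
samples in which it is mutated), each unordered gene pair gets:

* **exclusive degree** `ED(gi, gj) = |Γ(gi) ∪ Γ(gj)| / (|Γ(gi)| + |Γ(gj)|)`
  — 1 for perfectly exclusive pairs, 0.5 for identical coverages;
* **weight degree** `WD(gi, gj) = 1 − |Γ(gi) ∩ Γ(gj)| / min(|Γ(gi)|, |Γ(gj)|)`
  — 0 when one coverage nests inside the other, filtering spurious
  "exclusive" pairs with very unbalanced coverages;
* **coverage degree** `CD(gi, gj) = |Γ(gi) ∪ Γ(gj)| / m` (reported only).

The connectivity matrix `C = AᵀE` sums each expression gene's values over
the samples mutated in each mutation gene; the pair (h, k) is *connected*
when `C[h,k] / |Γ(g_h)| ≥ mean(e_k)`, i.e. gene *k*'s mean expression in
the mutated samples reaches its cohort-wide mean.

An undirected edge joins two genes when `ED ≥ λ` **and** `WD ≥ γ`
(defaults λ = 0.95, γ = 0.8, after a 3% mutation-rate filter), **or** when
the connectivity criterion holds. All maximal cliques (size ≥ 3) of the
network are enumerated, and the pair of gene sets with the highest
**overlap score** `OS(A, B) = |A ∩ B|² / (|A| · |B|)` is merged repeatedly
while that score exceeds 0.25. The surviving sets are the reported
dysregulated pathways.

## Worked example

The built-in simulator plants mutually exclusive pathways and
mutation-driven expression shifts, with exact ground truth:

```r
library(dyspathr)

cohort <- generate_cohort(simulation_config(seed = 7))
result <- run_pipeline(cohort$mutation, cohort$expression)
print(result)
#> <dyspath_result> 300 samples, 8/40 genes past rate filter
#> <gene_network> 8 genes, 17 edges (10 exclusivity / 5 connectivity / 2 both); lambda=0.95 gamma=0.8
#>   4 clique(s) of size >= 3
#> <pathway_result> 2 pathway(s) from 4 clique(s), 2 merge(s), OS threshold 0.25
#>   P1 (5 genes, merged): PWA_1, PWA_2, PWA_3, PWA_4, PWB_2
#>   P2 (5 genes, merged): PWA_2, PWB_1, PWB_2, PWB_3, PWB_4

recovery_report(cohort$truth, result$pathways)
#> <recovery_report>
#> # A tibble: 2 × 4
#>   pathway    size best_match best_jaccard
#>   <chr>     <int> <chr>             <dbl>
#> 1 planted_1     4 P1                  0.8
#> 2 planted_2     4 P2                  0.8
#> gene precision 1.000, recall 1.000
```

The two planted four-gene pathways (`PWA_*`, `PWB_*`) are found as the two
reported pathways; each also picks up the other pathway's expression
partner through a chance connectivity edge — the one-sided mean criterion
passes about half the time for an unlinked pair under mean-zero noise —
giving a Jaccard index of 4/5 against the planted truth. `tidy(result)`
returns the gene-to-pathway table, `glance(result)` the one-row run
summary, and `autoplot(result$network)` / `autoplot(result$pathways)`
draw the network and the membership tiles. A thin command-line front end
with `run` / `simulate` / `metrics` / `network` subcommands is installed
at `inst/cli/dyspathr.R`.

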