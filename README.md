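# sqamp — functional-gene amplicon analysis for the sulfoquinovosidase marker *yihQ*

Sulfoquinovose (SQ), the head group of the plant sulfolipid SQDG, is a
major organosulfur substrate for microbial communities; the
sulfoquinovosidase gene *yihQ* (glycoside hydrolase family 31) marks
most known SQ-degrading organisms and can be surveyed directly with
degenerate-primer amplicon sequencing. `sqamp` is an R toolkit for the
computational side of such a functional-gene assay, aimed at microbial
ecologists who run (or design) marker-gene amplicon surveys:

- **primers** — represent degenerate IUPAC primers, search binding
  sites, run in-silico PCR, report database coverage and melting
  temperatures, and propose candidate primers from conserved alignment
  windows;
- **verify** — six-frame translation of amplicon sequence variants
  (ASVs) and a protein homology filter against the curated YihQ
  reference family (targets plus paralogous GH31 decoys);
- **place** — maximum-likelihood evolutionary placement of candidate
  peptides on the fixed reference tree, with jplace export; an ASV is
  *verified* when its best placement edge lies inside the monophyletic
  target clade (stem included);
- **otu / diversity** — greedy abundance-sorted OTU clustering at 90%
  identity and rarefied alpha diversity (observed richness, Shannon,
  Gini–Simpson) at 100 / 1 000 / 10 000 reads;
- **taxonomy** — best-hit classification against a genome-protein
  database with a conservative 90% identity floor, plus per-clade
  composition tables;
- **enrich** — a transparent, unshrunken negative-binomial Wald test
  (median-of-ratios size factors, method-of-moments dispersion,
  Student-t reference) for two-condition differential abundance;
- **synth** — a synthetic-data generator that emulates the whole input
  bundle (reference family + decoys, primer sites, a 340 bp amplicon
  window, error-bearing reads, spiked multi-sample count tables) so
  every stage is testable offline.

The placement model: for a query peptide $q$ and each reference-tree
edge $e$, the engine maximizes over the pendant branch length $p$ the
likelihood $L(q \mid T, e, p)$ of the tree with $q$ attached at the
midpoint of $e$ under the LG substitution model, computed by Felsenstein
pruning with per-site scaling. Edges are compared by like-weight ratios
$\mathrm{lwr}_e = e^{\ell_e - \ell_{\max}} / \sum_{e'} e^{\ell_{e'} -
\ell_{\max}}$. The differential-abundance statistic is
$z = \log_2\frac{\bar\mu_T + 0.5}{\bar\mu_C + 0.5} \Big/ \mathrm{SE}$
with $\mathrm{Var}(\hat\mu_g) = (\mu_g + \alpha\mu_g^2)/n_g$ and a
$t_{n_1+n_2-2}$ reference.

## Worked example

Simulate a reference bundle and amplicon dataset, evaluate the
generator's degenerate primer pair, verify and place ASVs:

```r
library(sqamp)

cfg <- synth_config(seed = 42)
ref <- simulate_reference(cfg)
ref$resource
#> <reference_resource> 18 entries (12 target), 18 tree leaves, 33 edges, alignment 18 x 250
ref$primers$fwd
#> <degenerate_primer> SYNF (forward) AYTTYCCRAAYTGYTCRATYG  [21 nt, degeneracy 128]

tdb <- setNames(ref$resource$entries$nt_seq[ref$resource$entries$label == "target"],
                ref$resource$entries$id[ref$resource$entries$label == "target"])
primer_pair_coverage(ref$primers$fwd, ref$primers$rev, tdb)
#> <coverage_report> 9/12 templates perfect (75.0%)

amp <- simulate_amplicons(ref, cfg)
v <- verify_asvs(amp$asvs[1:5, ], ref$resource)
v[, c("id", "strand", "frame", "status", "reason", "identity")]
#>        id strand frame    status reason  identity
#> 1 ASV_001      -     2 candidate     ok 0.9910714
#> 2 ASV_002      +     2 candidate     ok 0.9639640
#> 3 ASV_003      +     2 candidate     ok 0.9821429
#> 4 ASV_004      -     2 candidate     ok 0.9910714
#> 5 ASV_005      +     2 candidate     ok 0.9821429

pl <- place_asvs(v, ref$resource, amp$counts)
pl$table[, c("id", "status", "best_edge", "lwr_best", "clade_id")]
#>        id   status best_edge lwr_best clade_id
#> 1 ASV_001 verified        21        1        1
#> 2 ASV_002 verified        15        1        1
#> 3 ASV_003 verified         8        1        1
#> 4 ASV_004 verified         9        1        1
#> 5 ASV_005 verified         3        1        1

am <- alpha_metrics(rowSums(amp$counts))
sprintf("observed %d, Shannon %.3f, Gini-Simpson %.3f",
        am$observed, am$shannon, am$simpson)
#> [1] "observed 70, Shannon 2.362, Gini-Simpson 0.793"
```

Nine of twelve target references carry exact sites for both primers
(the generator plants controlled third-base wobble inside the primer
sites, so coverage is high but imperfect, as for real degenerate
assays); all five ASVs shown translate in the recovered frame at high
identity to a reference and place inside the target clade
(`clade_id 1`, like-weight ratio 1).

The whole pipeline — verification, placement with jplace export, OTUs,
rarefied diversity, taxonomy, enrichment, summary tables and a run
manifest — runs from one config:

```r
run_pipeline(list(seed = 42L, out_dir = "run1", synth = list()))
```

or from a shell via the thin CLI wrapper: `Rscript inst/cli/sqamp.R run
--config pipeline.yaml` (see `?pipeline_config` for the YAML schema).

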