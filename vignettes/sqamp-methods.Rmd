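---
title: "Methods: functional-gene amplicon analysis with sqamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional-gene amplicon analysis with sqamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`sqamp` implements the computational side of a functional-gene amplicon
assay for the sulfoquinovosidase gene *yihQ*, a glycoside hydrolase family
31 (GH31) marker of sulfoquinovose degradation. The workflow it supports
is the one used for environmental *yihQ* amplicon surveys: degenerate
primers are evaluated against a curated reference database in silico;
sequenced amplicon sequence variants (ASVs) are translated, screened for
protein homology to the reference family, and placed on a fixed
maximum-likelihood reference tree; ASVs whose best placement falls inside
the monophyletic target clade are "verified", the rest (placements among
paralogous GH31 decoys, non-homologous amplification products,
pseudogene-like reads) are excluded. Verified ASVs are clustered into
OTUs, summarized by subsampled alpha diversity, classified against a
genome-protein database with a conservative identity floor, and tested
for differential abundance between two conditions.

Every stage is exercisable without external data through a synthetic-data
generator that emulates the structure of the reference bundle and its
amplicon data.

# The reference bundle

A `reference_resource` holds the reference proteins (targets plus decoy
homologs), their gapped alignment, an unrooted reference tree with branch
lengths in expected substitutions per site, optional coding sequences,
and per-entry metadata (target/non-target label, GTDB-style
semicolon-separated taxonomy). Loading validates all cross-references:
every tree leaf and alignment row must correspond to a database entry,
alignment rows must ungap to their protein, coding sequences must
translate to their protein under the bacterial genetic code (table 11,
initiator-codon rules disabled), and branch lengths must be non-negative.

**Edge numbering.** Placement output must be reproducible, so edges are
numbered canonically: the tree is traversed depth-first from the first
leaf in protein-file order, visiting incident edges in ascending order of
the smallest file-order index reachable through them; edges receive
0-based ids in discovery order. The convention is invariant to Newick
rotations, so writing and reloading a bundle reproduces the numbering
exactly — a property the jplace export relies on.

**Target clade.** The target edge set is the minimal spanning subtree
connecting the target leaves plus, when the targets are a proper subset
of the leaves, the stem edge of that subtree — defined in the canonical
rooted view as the parent edge of the targets' most recent common
ancestor. A query placed on the stem is adjacent to the clade by
construction and is counted as verified; this errs on the inclusive side
for deep-branching relatives of the marker family. When the traversal
root is itself a target, the subtree touches the root and there is no
stem.

# Primer evaluation

Degenerate primers are IUPAC strings with an orientation and an optional
5'-head (the generic two-step-barcoding adapter), which never
participates in matching. The binding model is deliberately simple and
exact: a site's mismatch count is the number of positions where the
template base is not in the primer position's allowed set; indels are not
modelled, since primer-template bulges rarely support amplification at
the stringencies used for functional markers. Template ambiguity codes
count as matches only when the primer code subsumes them (conservative
coverage). Reverse primers are scanned as their reverse complement along
the plus strand.

In-silico PCR reports every properly oriented, non-overlapping site pair
whose product length — primers included, as amplicon sizes are read off a
gel — falls within a size window. A template counts toward the pair's
"perfect coverage" fraction only when some product has zero mismatches
under both primers, which is the statistic used to compare candidate
assays. Melting temperatures use the Wallace rule, 2(A+T) + 4(G+C),
enumerated over all concrete expansions (minimum, mean, maximum);
nearest-neighbour thermodynamics would be a straightforward extension but
adds parameters the comparison does not need.

`propose_primers` slides a window (>= 15 nt) over gap-free alignment
columns and emits the minimal IUPAC consensus per window, discarding
candidates above a degeneracy cap. With `min_base_freq > 0`, bases rarer
than the cutoff are dropped from the consensus before encoding, trading
coverage for degeneracy the way a practitioner designing broad-coverage
degenerate primers does.

# ASV verification

Verification is deterministic and proceeds in two stages.

**Frame choice.** All six reading frames are translated (table 11, stops
as `*`, `N`-containing codons as `X`, trailing partial codons dropped,
no initiator-codon special-casing since amplicons are gene-internal).
Each translation is aligned locally (affine gaps, open 11 / extend 1,
BLOSUM62) against every reference protein; the frame with the maximal
best-hit score wins, with ties broken by fewer internal stops, then plus
strand, then lower frame offset.

**Homology filter.** An ASV remains a candidate iff its best local
alignment to *any* reference entry — target or decoy alike; the
placement stage, not the filter, decides the class — reaches both an
identity threshold (default 40% over the aligned span) and a normalized
score threshold, *and* the aligned span contains no stop codon. The
normalized score is the alignment score divided by the query length, not
by the aligned-span length: a short spurious 10-residue alignment can
easily exceed any per-column score cutoff, whereas dividing by the query
length (default cutoff 0.8 per residue) requires homology across most of
the read. These two thresholds replace BLASTp's E-value machinery; on
random peptides drawn from the amino-acid background distribution the
false-candidate rate is below 1% (property-tested). Any internal stop in
the span excludes the read as a pseudogene/frameshift proxy. Exclusion
reasons are reported in the fixed order `too_short` (ASV shorter than
100 nt, about a third of the expected amplicon), `internal_stop`,
`no_homology`, and read counts are conserved across the
candidate/excluded split.

A consequence worth knowing: random sequencing errors occasionally create
stop codons (roughly 4% of random coding substitutions), so at a 1%
per-base error rate on a 340 nt amplicon a noticeable fraction of genuine
marker reads — on the order of 5-10% — is excluded by the stop rule.
This is the intended, conservative behaviour of the filter; with
denoised ASVs (error rates well below 0.1%) the effect is negligible.

# Phylogenetic placement

Candidate peptides are placed on the fixed reference tree by the
evolutionary-placement approach: the reference topology and branch
lengths never change; the query is attached to each edge in turn and the
attachment likelihood is maximized over the pendant branch length.

**Query alignment.** The peptide is aligned to the reference alignment's
position-specific profile (column score = column-frequency-weighted
BLOSUM62 average) by glocal affine-gap dynamic programming: reference
columns skipped before and after the aligned region are free, query
residues are either matched to columns or inserted at affine cost, and
insertions are discarded so the query row lives in reference column
space. Queries whose alignment covers less than half of their residues
are flagged unplaceable and excluded downstream.

**Model.** The default substitution model is LG (exchangeabilities and
equilibrium frequencies as distributed with phangorn) with no rate
heterogeneity; a Poisson (equal-rates) model is provided both for
closed-form testing and as a deliberately misspecified simulation mode.
Adding discrete-gamma categories is an extension point, not a default,
because verification-grade placement is driven by the clade-level signal.
Gaps, `X` and stops in the query contribute a vector of ones (missing
data), never a 21st state.

**Likelihood engine.** Conditional likelihoods of the reference tree are
query-independent; they are computed once per bundle by directed-message
pruning (Felsenstein's algorithm on directed edges) with per-site
scaling, so underflow cannot produce `-Inf` for finite input. Attaching
a query at the midpoint of an edge then costs only one 20x20 transition
matrix product per likelihood evaluation. Attachment is at the midpoint
only — the distal position is not optimized — which sacrifices a little
likelihood relative to full two-parameter EPA optimization but none of
the verification accuracy the tool needs; the jplace `distal_length` is
accordingly always half the edge length. The pendant length is optimized
on [1e-8, 5] substitutions/site by Brent's method (golden-section with
parabolic refinement, tolerance 1e-5). For a query identical to a
reference leaf the optimized pendant collapses to the lower bound.

Per query, the engine reports the best edge, its log-likelihood and
pendant length, like-weight ratios `lwr_e = exp(ll_e - max) / sum` over
all edges (they sum to 1 by construction), the verified flag (best edge
in the target edge set), and a clade id. Clades for composition
reporting are contiguous runs of edges sharing target/non-target status,
numbered in edge-traversal order. Ties in the best-edge choice resolve
to the lowest edge id. Placements are exported as jplace v3 with the
canonical edge numbering embedded in the tree string and read counts as
multiplicities.

The engine is cross-checked in the test suite against (i) a closed-form
single-site Poisson likelihood, (ii) phangorn's independent pruning
implementation on the reference tree, and (iii) a naive oracle that
physically rebuilds the attached tree and recomputes the likelihood by
plain post-order recursion over an edge-by-pendant grid.

# OTU clustering

Verified ASVs are clustered at a configurable nucleotide identity
threshold (default 0.9, the species-level proxy for this marker) by
greedy abundance-sorted centroid clustering: ASVs are processed in
decreasing total-count order (ties lexicographic), each joining the
*first* centroid at or above the threshold — vsearch's behaviour — or
founding a new cluster; a best-match rule is available as an option.
Identity is matches divided by alignment columns of a global affine-gap
alignment, excluding columns inside terminal gap runs, so a read that is
a clean prefix of another counts as identical. Among the several
identity definitions in circulation this is the one that treats length
differences between denoised amplicons leniently; it is stated here
because results at a fixed threshold depend on it.

# Alpha diversity

Subsampling is rarefaction proper: a multivariate hypergeometric draw
without replacement at fixed depth, reproducible bit-for-bit for a fixed
seed. Samples shallower than a requested depth are skipped with a
warning, never silently padded. Metrics are observed richness, Shannon
entropy in natural log, and the Gini-Simpson index 1 - sum(p^2); the
default depths (100, 1000, 10000 reads) with 10 replicates match the
library sizes at which functional-amplicon surveys typically compare
communities. The contrast that motivates depth profiling: for a 15-ASV
even community, 100 reads already recover >98% of richness, while for a
1000-ASV log-series community they recover well under half.

# Taxonomy

Classification is best-hit: local alignment of the verified peptide
against a genome-protein database, assignment of the top-scoring entry's
taxonomy only when span identity reaches the floor (default 0.9 —
the conservative convention for this marker), otherwise "unclassified".
Score ties resolve by higher identity, then lexicographic id. Genomes
carrying two marker copies appear as two database entries sharing a
taxonomy string. Per-clade composition tables cross-tabulate placement
clades against one taxonomy rank, with "unclassified" as its own
category and percentages summing to 100 within each clade.

# Differential abundance

The two-condition test is an intentionally transparent, unshrunken
negative-binomial Wald test. Counts are normalized by median-of-ratios
size factors (median over all-positive features of the count over the
feature's geometric mean; total-count scaling as a warned fallback).
Per feature, a single NB dispersion is estimated by method of moments
pooled across the two groups (floored at 1e-8), the effect is
`log2((mean_T + 0.5) / (mean_C + 0.5))` with a 0.5 pseudocount for
zeros, and the standard error follows from the NB variance
`mu + a mu^2` by the delta method. The p-value uses a Student t
reference with `n1 + n2 - 2` degrees of freedom rather than a normal:
with triplicates the plug-in dispersion is estimated from four residual
degrees of freedom, and the normal reference is several-fold
anticonservative at `alpha = 0.01`, while the t reference restores the
nominal level (verified by simulation in the test suite). The
significance flag follows the raw-p rule `p < alpha` with `alpha = 0.01`
by default; Benjamini-Hochberg q-values are reported alongside for users
who prefer FDR control. Because dispersions are neither shrunken nor
trended, power at triplicate scale is below what moderated tests
achieve; this is the price of having no tuning parameters, and the test
is not intended to replace a full DESeq2 analysis on real studies.

# The synthetic-data generator

`simulate_reference` emulates the *structure* of the real reference
bundle: a monophyletic target family and a paralogous decoy family, each
grown as a random topology with exponential branch lengths (mean 0.15
substitutions/site), joined by a 1.5-substitutions/site ancestral branch
so that inter-group protein identity sits well below intra-target
identity. Proteins (250 residues by default) evolve along the tree under
the same LG model the placement engine uses, making the model
well-specified for recovery tests; a misspecified mode evolves under
Poisson instead. Coding sequences are produced by per-column canonical
codons with 30% synonymous noise outside the primer sites — enough
nucleotide diversity for OTU clustering to be non-trivial.

The amplicon window is 340 nt (the marker assay's product size),
deliberately not codon-aligned (frame offset 2) so frame recovery is
exercised. The amino acids under the two 21-nt primer sites are frozen
across the target family; the degenerate primer pair carries two-fold
IUPAC codes at third-codon positions, and target coding sequences
receive third-base wobble noise inside the primer sites (5% transitions,
covered by the degeneracy; 1% transversions, true mismatches). Those
rates were fixed once to put the pair's perfect-match coverage in the
80-95% range typical of well-designed degenerate assays; they are
generator constants, not fitted quantities.

`simulate_amplicons` cuts reads from the window of randomly chosen
source leaves (50 target-derived and 20 decoy-derived ASVs by default),
applies uniform per-base substitution errors (default 1%), reverse-
complements each ASV with probability 1/2, and draws per-sample counts
(three samples per condition, mean library 20000) from the community
model — log-series with x = 0.999 for rumen-like dominance, or uniform
for gut-like low-richness communities — with NB replicate noise
(dispersion 0.05) and 8-fold spikes of three target features in the
treated condition. A complete truth table (source leaf, strand, frame,
true fold) accompanies every dataset.

What the generator does **not** emulate: PCR chimeras, indel errors,
quality scores, denoising artifacts, compositional biases of extraction
and amplification, and length variation among amplicons. Passing
recovery tests on synthetic data therefore demonstrates the internal
correctness of the pipeline under its own model assumptions, not
robustness to every failure mode of real amplicon data.

# Numerical choices and degenerate inputs

- Pruning uses per-site max rescaling at every internal node; site
  likelihoods are floored at 1e-300 before the log so zero-length edges
  with conflicting states cannot produce `-Inf`.
- The pendant optimizer never evaluates exactly at the interval
  boundary; the lower bound is checked explicitly so self-placements
  report pendant 1e-8 rather than the optimizer's interior estimate.
- Profile-alignment traceback resolves equal-score predecessors in the
  fixed order match, deletion, insertion; all its scores are kept in
  double precision with a 1e-9 comparison tolerance.
- Greedy clustering ties (equal total counts) resolve lexicographically;
  degenerate all-zero count features get `p = 1`, `log2fc = 0` in the
  differential test; all-zero count vectors are an error for alpha
  diversity.
- Test and example problem sizes (8-leaf oracle bundles, 25-residue
  proteins, 70-ASV pipelines, 2000-feature calibration simulations) were
  chosen as the smallest sizes at which the checked statistics are
  stable; they are package choices, not statements about the method's
  limits.

# Known limitations

- Placement optimizes the pendant length only; the distal attachment
  position is fixed at the edge midpoint.
- No rate heterogeneity across sites by default; deep intra-family
  divergences may be compressed.
- The homology filter's thresholds were calibrated on the synthetic
  generator's error model; highly diverged true homologs (below ~40%
  span identity) will be excluded by design.
- The differential-abundance test handles exactly two conditions and no
  covariates, and does not moderate dispersions.
- The in-silico PCR model ignores primer-dimer, hairpin and annealing
  thermodynamics; it measures sequence compatibility, not amplification
  efficiency.
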