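---
title: "Phylogenetically-informed annotation: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetically-informed annotation: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pia)
```

This vignette is the package's own account of its science: the models it
assumes, the algorithms it runs, the tunable parameters and why their
defaults are what they are, what the simulator does and does not emulate,
and the choices made where the design was genuinely open.

## The annotation problem

Best-hit annotation of assembled transcriptomes conflates orthologs with
paralogs and other characterized relatives. `pia` treats annotation as a
*placement* problem: a candidate sequence is attached to a fixed,
curated gene-family tree at the edge that maximizes the likelihood of
the extended alignment, and then interpreted by its position relative to
landmark genes of known function. Keeping the reference tree fixed is
both the speed trick — nothing is re-estimated per query — and the
scientific framing: the curated tree is the stable coordinate system
that successive transcriptomes are mapped onto.

## Pipeline stages and their parameters

### ORF extraction

`six_frame_orfs()` reports every maximal stop-free stretch in all six
reading frames translating to at least `min_aa` residues (default 30
amino acids — the threshold is a strict boundary: a 29-residue stretch
is dropped, a 30-residue one kept). Two decisions here were open:

* **No start-codon requirement.** Open readings are stop-to-stop, the
  default of the classic ORF finders for transcriptome input; requiring
  ATG would discard 5'-truncated assemblies.
* **Edge-truncated readings are kept.** Assembled contigs routinely cut
  coding regions; a stretch running into the sequence edge counts as an
  ORF if long enough.

Coordinates are 0-based half-open on the forward strand, stops excluded
from the length; codons containing N translate to X. ORFs are indexed in
descending length (ties by strand then start) so labels like
`fam_hit_UN0029_ORF1` are deterministic.

### Homolog search

Candidates are found by optimal Smith–Waterman local alignment of each
ORF against each bait (the alignment engine is
`Biostrings::pairwiseAlignment`; a brute-force recursion oracle in the
test suite checks it on short sequences). Defaults are the classic
gapped protein-search settings — BLOSUM62, gap open −11, extend −1, and
Karlin–Altschul constants λ = 0.267 nats, K = 0.041 — all exposed in
`scoring_scheme()`. Significance uses `E = K·m·n·exp(−λS)` with `n` the
family's total bait letters: each family is its own search space, since
families are searched independently.

Retention follows two thresholds: a family E-value gate (default
`1e-20`) and a top-`k` cut (default 3) applied over ORFs after
collapsing each ORF to its best bait. Whether "top three" should count
alignments, ORFs or transcripts was open; the ORF-level reading was
chosen because ORFs are the placement unit downstream, and per-bait
scores remain available in the hit table.

### Profile alignment

Queries are added to the fixed family alignment one at a time
(`add_to_alignment()`), matching how placement consumes them. The match
score of query residue *q* against column *i* is the frequency-weighted
mean substitution score `w_i · Σ_a f_i(a) S(a, q)`, where `f_i` are the
column's residue frequencies over non-gap rows and `w_i` its non-gap
fraction — the simplest profile-sequence scheme consistent with
"align to an existing alignment". Gap costs reuse the search scheme.
Terminal query gaps are free (semi-global): transcript ORFs are often
fragments and should not pay for the profile they do not span.

Reference columns are immutable by construction: query-only residues
open all-gap *insert* columns, recorded in an attribute and lower-cased
in a2m-style output. `mask_query_to_ref()` drops them, giving the query
on reference coordinates for placement. The reference-immutability
invariant (strip query row + drop all-gap columns = input, exactly) is
tested over randomized profiles.

### Substitution model and likelihood

The default model is WAG with its published stationary frequencies,
uniform rates across sites. The rate matrix is built as
`Q_ij = s_ij π_j`, diagonal set to zero row sums, rescaled to unit mean
rate so branch lengths are expected substitutions per site. Transition
probabilities come from one symmetric eigendecomposition
(`B = D^{1/2} Q D^{-1/2}`), making `P(t)` cheap inside optimization
loops. Two optional toggles exist and default off, because the cited
tree-building convention states only "WAG": empirical frequencies from
the reference alignment (+F), and discrete-gamma rate variation
(`n_gamma_cats`, `alpha`; mean-per-category discretization of
Gamma(α, α)).

`pruning_loglik()` is Felsenstein pruning with per-site scaling; gaps
and X are missing data (all-ones partials), while stops and unknown
letters are errors — silently treating corrupt data as missing would
mask upstream bugs. Likelihood is invariant to the rooting of the
stored tree (checked to 1e-9 on every edge), and equals explicit
ancestral-state enumeration on small trees to 1e-8.

### Placement

For each query, `epa_place()` evaluates every edge. The key data
structure is a bidirectional partials cache: for every edge, the
conditional likelihood of the data below the edge (at its child) and of
everything else (at its parent), computed once per reference and reused
for all edges and queries. Attaching a query at distance `x` from the
parent with pendant `q` then costs three 20×20 matrix exponentials and
three matrix products per evaluation — the reference tree is never
recomputed. Per edge, `x` and `q` are optimized coordinate-wise
(derivative-free 1-D optimization, at most 32 rounds, convergence at
1e-6 log-likelihood improvement; pendant bounds `[1e-8, 10]`
substitutions/site, initial value 0.1). The split edge's two sub-lengths
are constrained to sum to the original length and all reference branch
lengths stay fixed — deliberately matching fast placement behavior
rather than re-estimating the tree.

All edges are reported, ranked by log-likelihood with near-ties (within
1e-9) broken by smaller edge id, each with its likelihood weight ratio;
the best is flagged. Reporting everything (not only the winner) lets
users see when weight is spread across a region of the tree. Output is
jplace v3 on edge-numbered Newick (`{N}` tags); a test verifies the
cached computation equals full pruning on a freshly grafted tree.

### Annotation

The interpretive step is intentionally explicit where practice is
usually by eye. From the best placement's attachment point,
`classify_query()` computes patristic distances to the nearest LANDMARK1
and LANDMARK2 tips and flags:

* `candidate_ortholog_context` — nearest landmark is tier 1 **and** the
  pendant is short (`pendant_length ≤ pendant_max`, default 2× the
  reference tree's median terminal branch length);
* `distant_relative_context` — nearest landmark is tier 2;
* `ambiguous` — everything else, including tier distances tied within
  1e-9 and trees without landmarks.

The thresholds are explicit stand-ins for a judgement the literature
leaves unquantified ("short branches", "sensible positions"); the flag
is therefore labelled advisory, both distances are always reported, and
tagged Newick trees are emitted for inspection. Contamination marks in
the presence matrix are user-supplied annotations, never computed — no
defensible automatic rule exists at this level.

### Reference package construction

`dereplicate()` removes exact duplicates and exact substrings at the
default threshold 1.0 (keeping the longest, ties by id) and clusters
greedily longest-first by alignment identity over the shorter sequence
at lower thresholds; every removal is logged with its representative.
`prune_long_branches()` iteratively removes the tip whose terminal
branch exceeds `factor` × the current median terminal length (default
10), longest first, recomputing the median each round, never below
3 tips. Both rules are declared replacements for unspecified curation
tools, which is why their behavior is fully logged and property-tested.
Topology search and bootstrap support are out of scope by design:
packages ship a topology from any external tree builder, and
`reoptimize_branch_lengths()` refreshes lengths under the package model
by monotone per-edge sweeps (convergence when a sweep gains < 1e-4
log-likelihood).

Packages serialize to a plain-text directory (`manifest.json` with md5
checksums and model settings, `baits.faa`, `ref.aln.faa`, `ref.nwk` with
`{N}` tags, `landmarks.tsv`) and validate on read: missing files,
checksum mismatches and tip/alignment mismatches are named errors.

## The simulator: what it emulates, what it does not

`simulate_refpkg()` draws a uniform random unrooted topology with
exponential branch lengths (mean 0.1 substitutions/site — a typical
scale for within-family protein divergence), evolves a gap-free
alignment under the package model from stationary root draws, and
assigns two LANDMARK1 tips and one LANDMARK2 tip. `make_query()`
fabricates a query descending from a known edge: the state at the edge
midpoint is drawn conditionally on *both* endpoint states
(`P(mid = s | ends) ∝ P_{a,s}(l/2) P_{s,b}(l/2)` — the true lineage
passes through the midpoint), then evolves along the pendant branch. This requires the
ancestral node states, which `evolve()` stores as an alignment
attribute — real alignments cannot drive `make_query()`, by design.
`simulate_transcriptome()` back-translates queries with random
synonymous codons and pads with random decoy transcripts. A single
integer seed fixes every draw, and the caller's RNG state is restored.

What this does **not** emulate: insertions/deletions (queries are
gap-free; insert handling is tested with hand-built fragments),
alignment error in the reference, compositional heterogeneity,
model misspecification (data are generated under the same WAG model
used for placement), sequencing error and chimeric assembly. Passing
recovery tests therefore demonstrate correctness of the machinery under
the model, not robustness of annotation on real, messy data — which is
exactly why the classification output is advisory.

## Numerical choices

* Branch-length bounds `[1e-8, 10]`; 1-D optimization tolerance 1e-6 on
  lengths, with endpoint checks so reported likelihoods never fall below
  the starting value.
* Per-site scaling in pruning (column maxima, log-accumulated) guards
  against underflow on larger trees.
* Transition-probability entries are clamped at 0 against rounding; rows
  sum to 1 within 1e-10.
* Ties: placement near-ties (< 1e-9 log-likelihood) break to the smaller
  edge id; search ties break by higher raw score then lexicographic
  query id; dereplication ties by lexicographic id — every pipeline
  output is deterministic for fixed inputs.
* Degenerate inputs: empty bait sets, empty alignments, < 3-tip trees,
  unknown edges and mismatched query widths are errors, not warnings;
  a transcriptome with zero passing hits is a *successful* run with
  empty outputs.

## Verification experiment sizes

The test-suite experiments were sized to be decisive yet quick on one
CPU: likelihoods against brute-force enumeration on 20 random trees of
up to 4 tips and 5 sites (tolerance 1e-8); rooting invariance on every
edge of 6-tip trees; fast placement against exhaustive re-optimized
insertion for 20 queries on 8-tip, 120-site packages; placement recovery
for 50 queries (pendant 0.1) on a 16-tip, 200-site package, scored as
true-or-adjacent edge; branch-length recovery on a 6-tip, 2000-site
simulation. For the branch-recovery experiment simulated branch lengths
are floored at 0.02 substitutions/site, since relative error on
near-zero exponential draws is ill-posed. For planted-*ortholog*
demonstrations the pendant is 0.02 — an ortholog should sit on a short
branch next to its landmark — whereas recovery experiments use the more
demanding 0.1.

## Known limitations

* Search is full dynamic programming without heuristic seeding: suitable
  for desk-scale family databases, not genome-scale screens.
* Placement optimizes one query at a time; co-placement interactions
  between queries are not modelled.
* The classification heuristic encodes one defensible reading of
  landmark context; it is a triage aid, and the package deliberately
  surfaces the evidence (distances, weights, trees) rather than a
  verdict.
* Model choice is fixed per package (WAG by default); model selection is
  out of scope.
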