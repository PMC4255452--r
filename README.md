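# pia — phylogenetically-informed annotation of transcriptomes

Similarity search alone annotates a transcript by its best database hit,
which routinely confuses orthologs with paralogs and other relatives.
`pia` instead annotates candidate gene-family members *phylogenetically*:
each candidate is placed by maximum likelihood onto a pre-calculated
reference tree for its family, and interpreted by where it lands relative
to functionally characterized **landmark** genes. Because the reference
tree is fixed, annotating a new transcriptome never re-estimates a tree —
only the query's attachment is optimized.

The package is aimed at researchers annotating assembled transcriptomes
of non-model organisms (e.g. light-interaction genes in cephalopod or
cnidarian eye tissue) against curated families with well-characterized
exemplars.

## The method

For a transcriptome and one reference package per family (baits, fixed
reference alignment, edge-numbered reference tree, landmark table, model):

1. **ORF extraction.** Six-frame, stop-to-stop open readings of at least
   30 amino acids (`six_frame_orfs`); no start codon is required and
   edge-truncated readings are kept.
2. **Homolog search.** Every ORF is Smith–Waterman-aligned against every
   bait (BLOSUM62, gap open −11 / extend −1). An ORF's family E-value is
   its best bait E-value under the Karlin–Altschul formula
   `E = K·m·n·exp(−λS)` (λ = 0.267, K = 0.041); ORFs with `E > 1e-20` are
   discarded and the best three per family are retained
   (`search_family`). All three thresholds are configuration.
3. **Profile alignment.** Each retained ORF is threaded onto the fixed
   family alignment by profile-to-sequence affine-gap DP; reference
   columns are immutable, query-only residues become all-gap insert
   columns (`add_to_alignment`, `mask_query_to_ref`).
4. **Evolutionary placement.** For every edge of the reference tree the
   query is attached by a pendant branch; attachment position and
   pendant length are optimized under WAG with Felsenstein pruning, with
   the reference partial likelihoods on both sides of every edge computed
   once and reused (`epa_place`). Candidates are ranked by log-likelihood
   and reported with likelihood weight ratios
   `lwr_i = exp(ℓ_i − ℓ_max) / Σ_j exp(ℓ_j − ℓ_max)` in jplace v3 format.
5. **Annotation.** The best placement is read against the landmark map:
   tier LANDMARK1 marks genes with the sought function, LANDMARK2 marks
   characterized but functionally distinct relatives. A query attaching
   nearest (patristically) to a LANDMARK1 tip on a short pendant is
   flagged `candidate_ortholog_context`; nearest-LANDMARK2 placements are
   `distant_relative_context`; everything else is `ambiguous`. The flag
   is advisory — both nearest-landmark distances are always reported, and
   tagged Newick trees (`…_LANDMARK1`, `…_QUERY`) are written for
   inspection. A family × sample presence matrix summarizes candidate
   orthologs across transcriptomes.

Reference packages are built with `reference_package()` /
`write_refpkg()` from user-supplied trees, with dereplication
(`dereplicate`), long-branch pruning (`prune_long_branches`) and
branch-length re-optimization on the fixed topology
(`reoptimize_branch_lengths`). A full simulator (`simulate_refpkg`,
`evolve`, `make_query`, `simulate_transcriptome`) generates packages and
transcriptomes with known truth, so everything is testable offline.

## Worked example

Simulate a reference package for a family ("Gprk1", 8 reference genes,
two LANDMARK1 tips and one LANDMARK2 tip), plant one true family member
in a small transcriptome, and annotate:

```r
library(pia)

pkg <- simulate_refpkg("Gprk1", n_tips = 8, n_sites = 150, seed = 42)
te  <- tree_edges(pkg$tree)
l1  <- pkg$landmarks$tip_id[pkg$landmarks$tier == "LANDMARK1"][1]
sim <- simulate_transcriptome(pkg, n_queries = 1, n_decoys = 3,
                              pendant = 0.02, seed = 43,
                              edge_ids = te$edge_id[!is.na(te$tip_label) &
                                                    te$tip_label == l1])
write_refpkg(pkg, "demo/Gprk1")
write_fasta(sim$transcripts, "demo/eye_transcriptome.fna")
run_pia(pia_config(c(squid_eye = "demo/eye_transcriptome.fna"),
                   "demo/Gprk1", "demo/out"))
```

The run log prints the per-stage counts:

```
[squid_eye] transcripts=4 orfs=19 (min_aa=30)
[squid_eye/Gprk1] hits=1 placed=1
```

19 ORFs pass the 30-residue minimum, exactly one survives the `1e-20`
E-value gate, and it is placed. `demo/out/annotation.tsv` then reads
(columns abridged):

```
query_id               best_edge_id  best_lwr  pendant_length  nearest_L1  nearest_L1_dist  flag
Gprk1_hit_UN0001_ORF1  7             0.990284  0.0215567       t1          0.0226457        candidate_ortholog_context
```

The query (labelled family + transcript + ORF ordinal) attached on edge 7
with likelihood weight 0.99, a short pendant branch (0.022
substitutions/site, the simulation's true value was 0.02) and landmark
`t1` (LANDMARK1) only 0.023 away on the tree — the configuration
expected of an ortholog, so the presence matrix
(`demo/out/presence_matrix.tsv`) books one filled cell:

```
family  squid_eye
Gprk1   1
```

Per-family jplace files (`squid_eye.Gprk1.jplace`) and tagged Newick
trees with the query grafted at its best placement are written alongside.

A thin command-line wrapper with the same functionality ships in
`inst/scripts/pia` (subcommands `run`, `build-refpkg`, `simulate`,
`validate`).

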