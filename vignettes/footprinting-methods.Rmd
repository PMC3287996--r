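---
title: "Phylogenetic footprinting with footprintr: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic footprinting with footprintr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footprintr)
```

## The problem

Regulatory DNA — promoters and enhancers — evolves more slowly than the
neutral sequence around it. Phylogenetic footprinting exploits this:
stretches of non-coding DNA upstream of a gene that remain highly similar
across distantly related mammals are candidate regulatory elements, and
the transcription-factor binding motifs that recur at orthologous
positions within them are candidate functional sites. `footprintr`
implements this workflow end to end for ATG-anchored upstream sequence:
pairwise local alignment, conserved-region calling, per-region multiple
alignment, motif over-representation, cross-species motif filtering, and
a wild-type/mutant site check — together with a sequence-evolution
simulator that provides ground truth for validating every stage.

## Coordinates

All genomic positions are expressed relative to the translation start:
`+1` is the `A` of the ATG, `-1` the base immediately 5' of it, and
there is no position 0. This is the only convention consistent with the
field's habit of writing both fully upstream intervals ("−57 to −284")
and intervals spanning the start ("+97 to −259"); intervals are printed
downstream-endpoint-first in that same style. Internally every interval
is stored canonically (`low <= high` in 5'→3' order) and mapped to a
gapless integer axis before any arithmetic, so the missing zero can
never produce an off-by-one. BED output is converted to the 0-based
half-open BED standard at the boundary and nowhere else.

## Pairwise conservation

`find_local_alignments()` is a classic seed-and-extend gapped local
aligner: exact-word seeding (default word size 11, the traditional
nucleotide-search default), X-drop ungapped extension (default X-drop
20), then banded affine-gap extension (default half-band 40) anchored at
the best-scoring position of the ungapped segment — that position is
always a match pair, which keeps the gapped extension centred on the
high-scoring core rather than on whichever seed fired first. Scoring
defaults are match +1, mismatch −2, gap existence 5, gap extension 2 (a
gap of length L costs `5 + 2L`). These search heuristics are validated
in the test suite against an exhaustive affine-gap Smith–Waterman
implementation from Biostrings, which the aligner must match exactly on
hundreds of randomized instances when the band and X-drop are opened
wide.

Significance uses Karlin–Altschul statistics, `E = K·m·n·exp(−λS)`.
`λ` is the unique positive root of `Σ p_i p_j exp(λ s_ij) = 1`, found by
bracketing plus Newton polishing to a residual below 1e−12. `K` is
computed numerically from the score random walk by renewal theory: the
density of strict descending ladder points times the first-passage
probability of an excursion reaching height `y` before falling below its
origin (a small linear system), with `K = θ·h(y)·exp(λy)` taken in the
large-`y` limit. For the default scheme on uniform composition this
reproduces the tabulated ungapped constant (K ≈ 0.621) to three decimal
places. Two documented simplifications follow standard practice for
this kind of screen: raw sequence lengths are used without edge
correction, and the ungapped `K` is reused for gapped scores. Retained
alignments must have `E ≤ 0.001`; the search-time reporting threshold is
10.

`call_conserved_regions()` applies the footprinting rule: reference
positions covered by an alignment of ≥80% identity (identities over all
alignment columns, gaps in the denominator, `N` never matching) are
marked per species; per-position support is the reference plus the
number of marked species; maximal runs with support ≥4 are extracted,
runs separated by ≤25 bp (`merge_gap`, configurable) are stitched, and
runs under 100 bp are dropped. Two genuinely open points are resolved as
follows and exposed as configuration:

* **The reference counts toward the species minimum.** "Present in four
  or more species" is read as the human region plus three aligning
  species. This is the weaker reading; requiring four non-reference
  species is one `min_species` step away.
* **Identity is assessed per alignment (HSP), not re-measured per merged
  region** — matching how a screen over reported pairwise alignments
  would have been done. `mean_identity` of a region is the
  coverage-weighted mean over its supporting alignments.

Only same-strand alignments are searched: upstream regulatory regions of
orthologous genes are syntenic here, and a reverse-strand hit would not
be interpretable in the ATG-anchored frame. Low-complexity masking is
not implemented; with the stringent identity/length/support rule, simple
repeats would have to be independently conserved in four species to
produce a false call.

## Multiple alignment

Orthologous conserved regions are aligned progressively: global
affine-gap pairwise distances (1 − identity), a UPGMA guide tree, and
profile–profile merges in post-order. UPGMA rather than
neighbour-joining because the inputs are short, closely related region
sequences where ultrametricity is harmless, and because its ties can be
broken deterministically (lexicographically smallest cluster labels);
the tree and its newick serialization are pure functions of the distance
matrix. An externally supplied tree can be passed instead. Profile
columns are scored by the mean pairwise substitution score between their
residues (`N` never matches; gap characters contribute nothing), with
affine penalties charged once per gapped column — a standard profile
simplification. The dynamic programs break ties in fixed order
(match > delete > insert), so the alignment is reproducible to the byte.
A single progressive pass is used, with no iterative refinement: this
mirrors a default run of the classical progressive aligners, and for
>80%-identical regions the guide-tree order, not refinement, determines
the result. Progressive alignment is a heuristic — it does not in
general attain the optimal sum-of-pairs score — so the tests assert the
reconstruction invariants (degapping any row returns its input), order
invariance, and superiority over randomized legal alignments rather than
global optimality.

## Motif over-representation

Motifs are position weight matrices: per-column counts regularized with
a pseudocount (default 0.25 per cell), `f_j(b) = (n_jb + 0.25)/(N_j +
1)`. A window `w` scores the likelihood ratio `LR = Π_j
f_j(w_j)/q(w_j)` against the background composition `q` (default
uniform). `N` bases score at the pseudocount floor, i.e. like a base
never observed in the motif. A scan hit requires the log2-odds to reach
a fraction (default 0.80) of the maximum achievable log2-odds, on either
strand; if a degenerate matrix has non-positive maximum log-odds, only
windows attaining that maximum exactly are hits.

The set-level over-representation statistic is

&nbsp;&nbsp;&nbsp;&nbsp;`R = Σ_i ln A_i`, with `A_i` the mean `LR` over
every window of sequence `i` on both strands.

This is the package's own operationalization of cis-element
over-representation against a background — chosen because it is
strand-symmetric, order-invariant, and analytically checkable
(`E[LR] = 1` under the background, so background-like motifs give
`R ≈ 0`, and tiny cases enumerate by hand: a width-1 all-A motif on
`"AA"` gives exactly `R = ln 2`). It is not a re-implementation of any
published enrichment recursion, and scores are not comparable to any
particular program's output.

Significance comes from randomization: per-sequence nucleotide shuffles,
PWM column permutations, and/or length-matched fragments resampled from
a background sequence set, with the add-one estimator
`p = (1 + #{R_null ≥ R})/(1 + n_rand)` so p-values are never zero and
are uniform under the null up to the `1/(n_rand+1)` granularity.
Everything is seed-reproducible. Mononucleotide shuffles preserve base
composition but not dinucleotide structure; a dinucleotide-preserving
shuffle would be a natural extension and is deliberately out of scope.

### The wild-type/mutant check

`motif_lost_on_mutation()` scans a published wild-type site and its
engineered mutant with the same matrix at the same threshold. Sites
shorter than the motif are padded on both sides with identical
fixed-seed uniform flanks so the two alleles are compared in the same
context; sites at least as long as the motif are scanned as-is (padding
a full-length site can manufacture spurious junction motifs). The
bundled matrices for Sp1, HNF-1, NF-Y and CREB are *representative
reconstructions* from each factor's published consensus site families
(GC-box core for Sp1, the palindromic `GTTAATNATTAAC` for HNF-1, the
CCAAT box for NF-Y, the CRE `TGACGTCA` for CREB), shipped in JASPAR text
format with "synthetic" in the filename; they are not copies of any
curated database, and motif inventories obtained with them will differ
from database-specific results. Against these matrices the Sp1, HNF-1
and NF-Y wild-type sites are detected and all their mutants are lost.
The CREB pair is reported but never asserted: the engineered change
creates a canonical CRE core, so whether a matrix "loses" the site
depends entirely on how palindromic the matrix is — the bundled strict
CRE matrix scores the native half-site below threshold as well.

## Cross-species motif conservation

Hits are mapped from each species' ungapped region sequence onto
alignment columns (gaps inside a hit's span widen its column interval),
then clustered per matrix: clusters are seeded in column order and a
species joins when one of its hits overlaps the seed interval by at
least half the shorter interval, contributing at most its best
overlapping hit (ties: higher likelihood ratio, then leftmost). Clusters
carried by ≥4 species are emitted with the union column interval. The
50%-of-shorter overlap rule is the package's own quantitative reading of
"spatially conserved at aligned positions"; it is configurable, and
emission is monotone in the species threshold by construction.

## The synthetic-data generator

`simulate_evolution()` is the package's stand-in for multi-species
genomic downloads, and its defaults define the validation conditions
used throughout the tests:

* **Tree:** a 7-leaf mammal-like phylogeny (human, chimp, dog, horse,
  cow, mouse, rat) with branch lengths in substitutions/site chosen so
  neutral pairwise identities span ~96% (human–chimp) to ~53%
  (human–mouse) under JC69 — the regime in which only the close pair
  aligns wall-to-wall and deep-branch support has to come from genuinely
  constrained sequence.
* **Root:** 5 kb drawn from the background composition (uniform by
  default), anchored at its 3' end so every position has a negative
  ATG-relative coordinate.
* **Elements:** a 250 bp promoter-like element ending 50 bp from the
  anchor and a 400 bp enhancer-like element ~3 kb upstream, both
  evolving at 5% of the neutral rate — one proximal and one distal
  block, sized like the regulatory regions this kind of screen targets.
* **Substitution model:** JC69 per branch
  (`P(change) = 3/4·(1 − e^(−4dr/3))` at distance `d` and per-site rate
  multiplier `r`), chosen for its closed-form identity
  `1/4 + 3/4·e^(−4d/3)` that the tests check directly; K80 with a
  transition/transversion ratio is available.
* **Indels:** Poisson events at 0.02 per site per unit branch length
  outside elements, geometric lengths (mean 2), insertions drawn from
  the background. Indels are disallowed inside elements by default so
  that element and planted-motif truth coordinates stay exact under
  full per-species coordinate bookkeeping; enabling them inside elements
  would only blur the truth intervals, not the pipeline.
* **Plantings:** motif instances are sampled column-wise from the PWM's
  (pseudocounted) probabilities and written into elements at the root;
  a planting can be restricted to a carrier subset, in which case the
  site is re-randomized from the background in non-carriers. Sampled
  instances of a soft matrix can legitimately score below a strict scan
  threshold — exact recovery tests therefore plant from zero-pseudocount
  single-site matrices, whose samples are always the consensus.
* **Determinism:** the same spec and seed give byte-identical FASTA.

What the simulator does *not* emulate: context-dependent substitution
(CpG hypermutability), rate variation outside the element/neutral
dichotomy, rearrangements and duplications, lineage-specific element
gain, assembly gaps, and base-composition heterogeneity. Passing
recovery tests therefore show that the pipeline's logic is correct under
its own stated model of conservation — not that real 15 kb mammalian
loci will yield exactly the same regions, where alignment artifacts,
repeats and annotation offsets also intervene. Comparisons against real
multi-genome data are treated as an external validation exercise (see
`validate_against_expected()`), not part of the automated suite.

## Problem sizes and numerical choices

The automated checks run at desk scale by design: 5 kb × 7 taxa for
recovery (20 replicate seeds), 10 kb two-taxon simulations for the
closed-form identity checks, ≥200 randomized ≤25 bp instances for the
aligner-vs-oracle equality, 200 replicate motifs × 100 randomizations
for null-calibration, and 100+ randomized instances for the
region-caller-vs-brute-force equality. Tolerances are 3 standard errors
for Monte-Carlo quantities, 1e−9 for the λ residual, and exact equality
for everything discrete. Floating-point ties in the scan threshold are
absorbed with a 1e−9 slack on the log2-odds cutoff; DP ties are broken
match > delete > insert; cluster seeding, region ordering and BED output
ordering are all fixed, so identical inputs give identical bytes.

## Known limitations

Reverse-strand local alignment, low-complexity masking, edge-corrected
E-values, dinucleotide-preserving shuffles, iterative MSA refinement and
genome-scale inputs (the banded extension allocates per-row traceback;
very long, highly similar pairs should keep the default band) are all
out of scope. The bundled transcription-factor matrices are
reconstructions — any analysis that depends on a specific curated motif
inventory should load that inventory in JASPAR format instead.
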