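---
title: "Comparative mitogenome screening for CMS candidate ORFs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenome screening for CMS candidate ORFs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cytoplasmic male sterility (CMS) in plants is typically caused by a novel
chimeric open reading frame in the mitochondrial genome: a fusion of a
fragment of a conserved mitochondrial gene with sequence of unknown
origin, often encoding a transmembrane protein, created by the
repeat-mediated recombination that constantly reshuffles plant
mitogenomes. The standard comparative strategy for nominating such a
gene is to sequence the mitogenome of a sterile line and a closely
related fertile (normal) line, decompose the two circles into syntenic
blocks and unique regions, screen the open reading frames of the sterile
genome for ones that are absent from the normal genome, chimeric with
known genes, transmembrane-encoding, or adjacent to known genes, and
then use repeats and long reads to explain how the rearranged genome
arises as one of several coexisting isomeric "master circles".

`mitoscreen` implements this entire desk-side pipeline as composable R
functions returning tibbles, plus a seeded synthetic mitogenome-pair
generator with a ground-truth manifest so every stage can be validated
end to end without any external data.

## Coordinate model

All coordinates are 1-based inclusive. On a circular molecule an
interval with `end < start` wraps through the origin and spans
`length - start + 1 + end` bases; a published repeat table entry such as
"2–9732" therefore spans 9731 bp, and that convention is what
`interval_span()` implements. Genomes are held in a light `circular_seq`
container; all downstream operations are required to be
rotation-invariant because the deposited origin of a circular mitogenome
is arbitrary. BED output is converted to 0-based half-open coordinates
at the boundary, with wrapping intervals split at the origin.

## ORF discovery and naming

`find_orfs()` scans all six reading frames; on circular sequences frames
continue across the origin (internally the sequence is scanned in a
tripled copy and one representative per circular position is kept). One
ORF is called per stop-to-stop segment, from the *first* `ATG` after the
preceding in-frame stop; this avoids counting nested ORFs at every
internal `ATG`, which would inflate genome-wide totals. The stop codon
is excluded from `aa_count`, so a chimera of 128 + 1261 coding bases
encodes exactly 1389/3 = 463 amino acids. `aa_count` counts every sense
codon including the initial methionine, and the published "longer than
70 amino acids" screen is read as `aa_count >= 70`. Only `ATG` starts
are considered (plant mitochondria use the standard genetic code;
alternative starts such as `ACG` are deliberately out of scope). A codon
containing `N` is treated as non-coding: it breaks the reading but can
neither start nor terminate an ORF. Names follow the field's
`orf<aa><letter>` convention with letters assigned in ascending start
position among ORFs of equal length, continuing `aa`, `ab`, ... after
`z`.

The tests validate the scanner against an independent position-wise
oracle (walk forward from each `ATG` to the next in-frame stop, walk
backward to the previous breaker) on ~160 random circles of 90–5000 bp,
and check strand symmetry and rotation invariance as properties.

## Uniqueness, chimera, transmembrane and adjacency screens

An ORF is *unique* when its full nucleotide sequence has no exact match
in the comparison genome on either strand, wrap-aware. This mirrors the
logic of a presence/absence screen between two near-identical genomes;
note that a single SNP inside a conserved gene makes that gene's ORF
"unique" by this definition, which is also true of the published screens
(unique ORFs are reported both inside and outside unique regions).

Chimera detection aligns the ORF coding sequence locally
(Smith–Waterman via `Biostrings::pairwiseAlignment`; match +1, mismatch
−1, gap −2) against every known-gene CDS and its reverse complement,
greedily accepting the best non-overlapping matches with identity ≥ 0.9
over ≥ 60 bp; leftover stretches ≥ 100 bp are reported as novel. An ORF
is chimeric when it has at least one match and one novel segment — the
classic CMS signature. The thresholds are exposed because no published
criterion exists for them; the defaults were chosen once so that a
128-bp known fragment is comfortably above the match floor and the
novel remainder above the novel floor.

Transmembrane segments use a Kyte–Doolittle sliding window (19 residues,
threshold 1.6), the standard published hydropathy heuristic. This is a
stand-in for HMM-based topology predictors, not a re-implementation of
one: agreement with TMHMM is not claimed anywhere, and the tests only
assert recovery of planted hydrophobic stretches and the closed-form
window arithmetic.

Adjacency flags the nearest annotated gene within 1000 bp of circular
gap distance, with the side reported relative to the ORF's strand.
Candidates are the unique ORFs with a transmembrane segment or an
adjacent known gene; chimeric candidates are additionally marked.

## Syntenic blocks and unique regions

Anchors are maximal exact matches ≥ 100 bp whose sequence occurs exactly
once in each genome counting both strands (MUM-style), computed from
unique k-mer runs on the doubled circular sequences and merged across
the origin. Anchors are chained greedily in genome-A order when
co-oriented, within 2 kb gaps, and on a consistent diagonal (±30 bp,
absorbing small indels); same-diagonal anchors may overlap by up to the
seed length, which happens around short duplicated stretches such as the
known-gene fragment inside a chimeric ORF. Chains shorter than 500 bp
are dropped. Unique regions are the ≥ 200 bp components of the circle
not covered by any block. None of these four thresholds has a published standard value (genome
comparisons of this kind are usually run through external aligners
with their own defaults); they are package defaults chosen so that block structure at mitogenome scale is
recoverable, and all are exposed in `default_config()`.

Rearrangement classes are assigned after circularly rotating the block
order to align the largest block: blocks on the longest
order-preserving backbone (longest increasing subsequence of the
partner-genome ranks) are collinear, or inversions if inverted in place;
blocks off the backbone are translocations, or translocation+inversion.

Variant calling inspects the gaps between chained anchors inside each
block: equal-length gaps are compared base by base, unequal gaps are
globally aligned. Substitution alleles are reported on each genome's
plus strand (inverted blocks flip the strand of homology, which the
effect classifier undoes when mapping into an annotated CDS).
Single-codon effects are classified with the standard genetic code as
synonymous or `X-Y` amino-acid changes; indels are frameshift or
in-frame by length, and indels flanked by a homopolymer 5-mer are marked
as such, reflecting their usual sequencing-bias origin.

## Repeats and recombination

`find_repeats()` reports maximal exact repeats ≥ 80 bp with ≥ 2 copies
(direct or inverted), grouped into families by identical unit sequence;
80 bp sits just below the shortest repeat units reported in published
radish mitogenome repeat tables (81 bp). Families over 1 kb are reported as large repeats,
shorter ones named `R1`, `R2`, ... by descending unit length.
Overlapping tandem-like copies collapse into a single family — how to
delimit such copies is a genuine free choice, and this is the simplest
rule consistent with maximal exact matching. A repeat copy is associated
with a syntenic-block junction when it comes within 200 bp (circular
distance) of a block boundary.

Genome isomers are modelled as circles of signed segments. Circles are
identified up to rotation *and* reflection, because a flipped
double-stranded circle is the same molecule; the canonical form is the
lexicographically minimal rotation. One homologous crossover between two
repeat copies gives: fission into two circles (direct copies on one
circle), inversion of the intervening segment (inverted copies on one
circle), or fusion (copies on two circles). Fusion of a single copy pair
has one product — homologous pairing fixes the relative orientation of
the two molecules — and the published "merging in two possible
orientations" emerges when the circles share repeats in two orientations
or share two families, giving two distinct recombination routes.
`enumerate_isomers()` is the breadth-first closure of these events over
all multi-copy families, deduplicating configurations canonically, with
an explicit state cap.

`toy_master_circle()` encodes a five-block arrangement with two repeat
families (three copies each, including inverted tandem copies) whose
closure contains exactly three master-circle isomers and four
subgenomic circles in five states — the configuration reported for
CMS-type radish mitogenomes. The design space here is constrained:
under single-crossover recombination, a five-block circle with two
families of two separated copies each can reach either two masters with
four subcircles (both pairs direct, interleaved) or three masters with
two subcircles (one pair inverted), but not both counts at once;
reproducing the published three-and-four pattern requires a third copy
of each family, which matches the multi-copy families seen in real
repeat tables. The shipped toy is small enough that its five-state
closure can be checked by hand.

Long-read junction support requires a read to contain the junction
point plus 50 bp of exact (or bounded-mismatch) context on each side,
mirroring the breakpoint-spanning logic of PCR and long-read assays;
reads matching two mutually exclusive junctions are counted as
ambiguous and excluded.

## Quantitative utilities

Relative expression uses the 2^−ΔΔCt method: per-sample ΔCt is the mean
target Ct minus the mean reference Ct across replicates, ΔΔCt subtracts
the calibrator group's mean ΔCt, and the standard error is propagated
from replicate variances (difference of means, then the delta method
through the exponentiation). The estimator is invariant to adding a
constant to every Ct, which the tests assert.

The neighbor-joining implementation follows the Saitou–Nei
agglomeration with the standard Q-criterion. It is implemented
in-package rather than delegated because two numerical details are
pinned: ties in Q are broken deterministically by taxon label order,
and negative branch lengths are clamped to zero with the deficit moved
to the sister edge. The reference implementation in `ape` serves as an
independent cross-check in the tests, which also verify exact recovery
of random additive trees up to 12 taxa. Distances are offered as K2P
(`d = -1/2 log((1-2P-Q) sqrt(1-2Q))`) and implicitly p-distance through
the aligned inputs; the composite-likelihood distance used by some GUI
phylogenetics tools is out of scope, so no published branch-length sum
is asserted.

## The synthetic generator

`generate_pair()` builds a "normal" circular genome of ~120 kb (about
half the scale of real radish mitogenomes, keeping tests fast) as 18
syntenic blocks carrying 33 random `ATG`…stop gene models plus tRNA/rRNA
features, then derives the "CMS" genome by permuting and inverting the
blocks (rejecting permutations that keep any original adjacency, so
every planted junction is a real breakpoint), inserting 11 unique
regions and short sub-threshold spacers at the junctions, and injecting
14 SNPs into 7 conserved genes. The unique regions host the planted
repeat families (the nine published short-repeat unit lengths, five of
them with a copy within 200 bp of a junction), a two-copy large repeat
(2 kb by default — the >1 kb size class at this reduced genome scale),
and one chimeric ORF: the first 128 bp of a donor gene fused to a
1261-bp novel segment containing a 25-codon hydrophobic stretch and no
internal stop, preceded by an in-frame stop so the ORF call starts at
the planted `ATG`.

Two generator details exist purely to make planted coordinates exactly
recoverable, and are worth knowing when interpreting test results.
First, the bases flanking every junction are chosen to differ from the
bases that would continue the match in the normal genome, so maximal
exact matches terminate exactly at block boundaries instead of
overshooting by chance (an exact match extends past a random breakpoint
with probability 1/4 per base). Second, the chimera's novel segment is
built so that the running alignment score against the donor gene's
continuation stays strictly negative, and the construction is verified
with the same local aligner the screen uses; without this, a local
alignment would extend a few bases past the planted 128-bp boundary on
a fraction of seeds. Real data offers no such guarantees, so on real
genomes block boundaries and chimera breakpoints should be read with a
few bases of slack.

What the generator does *not* emulate: sequence divergence inside
blocks beyond planted SNPs, diverged (non-identical) repeat copies, RNA
editing, intron-containing genes, read-level indel errors, and
multi-chromosome organelle structures. Passing the parameter-recovery
suite therefore demonstrates correctness of the algorithms under exact
repeats and near-identical genomes — the regime reported for real CMS/normal
mitogenome pairs — not robustness to highly diverged inputs.

## Problem sizes and determinism

All randomness flows through explicit seeds; the same seed gives
byte-identical genomes, reads, Ct tables and report bundles. The test
suite exercises: ~160 random circles (90 bp–5 kb) against the ORF
oracle, ~20 repeat-oracle toys of 400–1000 bp, a 30 kb six-block mini
pair for synteny invariants, the full 120 kb/18-block default pair for
end-to-end parameter recovery, ten random additive trees up to 12 taxa,
and 2000 simulated long reads for the mixture check. The acceptance
script regenerates the default pair from the supplied seed and
recomputes every headline quantity from scratch.

## Known limitations

* Anchors are seeded by unique k-mers at exactly the minimum length, so
  a true maximal match shorter than `anchor_min_len` is invisible, and
  two distinct repeat families that abut within one k-mer can merge.
* Exact-repeat detection only; diverged repeat copies are not grouped.
* The isomer closure grows quickly with repeat copy number; the state
  cap makes this an explicit error rather than an open-ended search.
* The variant caller is designed for near-identical genomes; it
  inspects anchor gaps gap-free or with a single global alignment and
  does not attempt probabilistic realignment.
* Reproducing published block/unique-region counts on real deposited
  accessions depends on unstated analysis thresholds; the package treats those counts as calibration context, not as
  assertions.
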