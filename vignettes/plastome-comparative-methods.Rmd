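---
title: "Methods: comparative plastome analysis with plastcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative plastome analysis with plastcomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastcomp)
```

# Scope and model

`plastcomp` re-implements, as a tested pipeline, the comparative analyses
typically run on small sets of closely related plastid genomes from the
inverted-repeat-lacking clade (IRLC) of legumes: composition accounting,
microsatellite and dispersed/tandem repeat detection, divergence-hotspot
screening of non-coding regions, gene presence/absence with monophyly of
losses, a distance phylogeny with bootstrap, and a pairwise Ka/Ks selection
screen. The genomes are treated as circular, single-copy molecules (no
inverted repeat), annotated with CDS/tRNA/rRNA features; annotation itself
is out of scope — records are consumed, never produced.

Coordinates are 0-based half-open internally and 1-based inclusive in every
report, matching the GenBank convention. Sequences are uppercased on ingest;
`N` is tolerated but excluded from GC and distance denominators.

# Region classes

Three homologous region classes are compared across species:

* **exon** — one spliced, strand-corrected sequence per protein-coding gene;
* **intron** — the gaps between consecutive exons in genome orientation,
  named `gene.intronN`;
* **IGS** — intergenic spacers between adjacent gene extents in genome
  order, named `upstream-downstream` (e.g. `rps12-clpP`), including the
  wrap-around spacer on circular records. Spacers of length < 1 (overlapping
  genes) are dropped.

Spacers are deliberately unoriented (+ strand) and named by genome order
rather than transcription direction: that is how spacer labels are used in
the comparative literature, and it makes names comparable across species.
Homologous regions are matched across species purely by normalized name
equality; regions present in fewer than two species are skipped.

# Composition

GC content is (G+C)/(A+C+G+T). Codon statistics use the bacterial/plastid
genetic code (translation table 11). Two conventions matter for reproducing
published tables:

* amino-acid percentages divide by the **total codon count including stop
  codons** — this is what makes 2336 leucine codons of 22,081 equal 10.58%;
* partition percentages divide by the **total genome length** (66,243
  coding bases of 133,122 equal 49.76%).

All reported percentages are rounded half-up to two decimals; every
percentage in an output table recomputes exactly from its numerator and
denominator.

# Repeat detection

**SSRs.** Perfect microsatellites only, with the MISA-style minimum unit
counts 8, 4, 4, 3, 3, 3 for motif lengths 1–6. A tract is reported under its
primitive period only (`ATATATAT` is four units of `AT`, never two units of
`ATAT`), with the leading unit as the motif, no canonicalization across
rotations or strands, and any trailing partial unit recorded separately. On
circular sequences the origin-spanning tract is found by scanning a doubled
sequence and discarding non-maximal fragments at the seam. Compound or
interrupted SSRs are never merged; detection is therefore deterministic and
checkable against a brute-force per-position oracle, at the cost of small
count differences against tools that merge nearby tracts.

**Dispersed repeats.** Gapless pairs (forward, or palindromic where the
second copy is the reverse complement), minimum length 30, Hamming distance
at most 3 — mismatches only, no indels — hence identity at least 90%. The
detector enumerates, per diagonal and per mismatch count k = 0..3, every
window with exactly k mismatches that cannot be extended without gaining
one ("maximal k-mismatch repeats"). Nested pairs are removed only when the
inner pair has **at most the identity** of its container: an exact core
inside a wider degraded window is kept, which is what makes exact planted
copies recoverable at ±0 coordinates. The production scanner seeds on exact
7-mers — sufficient by pigeonhole for any qualifying window — and the test
suite proves equality with an exhaustive all-diagonals oracle on hundreds of
random sequences.

**Tandem repeats.** A deterministic offset-scoring scan: for each period p
up to 500 the sequence is compared with itself offset by p and maximal
positive segments are scored at +2 per matching position and −7 per
mismatch; tracts scoring ≥ 50 are reported, overlaps resolved to the
highest score (ties to the smaller period). The published parameter set
for the standard tandem finder lists match/mismatch/indel weights 2 and 7
with minimum score 50 and maximum period 500; because the scan is gapless
the indel weight is accepted but never applied. Scores are exactly
reproducible by hand (e.g. 10 copies of `ACGT` score 2 × 36 = 72; a run of
26 A's scores exactly 50 and 25 A's does not qualify).

# Divergence hotspots

Homologous regions are aligned pairwise with a deterministic global
(Needleman–Wunsch) affine-gap aligner: match +1, mismatch −1, gap opening
10 and gap extension 2, so a gap of length L costs 10 + 2L. The gap
penalties mirror the alignment settings used in comparative plastome work;
pairwise alignment replaces progressive multiple alignment because only
pairwise distances are consumed. This substitution is the main expected
source of discrepancy against published distance values computed from
multiple alignments.

For each aligned pair, over columns where both symbols are unambiguous
bases (pairwise deletion of gap/N columns), the Kimura 2-parameter distance
is

$$ d = -\tfrac12 \ln\left((1 - 2P - Q)\sqrt{1 - 2Q}\right), $$

with P and Q the transition and transversion proportions. The distance is
flagged undefined when 1 − 2P − Q ≤ 0 or 1 − 2Q ≤ 0 (saturation) or when no
comparable columns remain.

The hotspot threshold is **mean + 2 standard deviations** over all defined
IGS distances across all species pairs. Two choices were open and are fixed
here: the pool is IGS-only (introns are screened separately), and the SD is
the sample SD (n − 1). A region is a hotspot when its maximum pairwise
distance reaches the threshold; hotspots are reported in decreasing order
of that maximum.

# Gene loss and monophyly

A gene is present in a species iff a non-pseudo feature with that
normalized name exists; pseudogenes count as losses, as they do in
published loss tables where non-functional copies (premature stops) are
scored absent. Loss counts are column sums of the presence/absence matrix.
A 34-species IRLC presence/absence matrix for the nine classically lost
genes ships as a plain-text fixture.

A gene's losses are monophyletic iff the absent species are exactly one
side of one edge of the unrooted tree — a definition invariant to
re-rooting. Genes absent in no or in all species are trivially monophyletic
and flagged as such. When a loss set is not monophyletic the reported
exception set is the smallest symmetric difference between the absent set
and any edge side.

# Phylogeny

The phylogeny stage is an explicitly distance-based stand-in for
maximum-likelihood inference: p-distances (pairwise deletion) on the
concatenation of per-locus alignments, neighbor-joining, and a column
bootstrap (resampling concatenated columns with replacement, NJ per
replicate, bipartition frequencies mapped onto internal edges of the
reference tree). The acceptance surface is clade recovery and support, not
likelihoods or branch lengths. Negative NJ branch lengths are clamped to
zero with the deficit moved to the sibling edge — a common reporting
convention — and all tie-breaking is deterministic, so a fixed seed
reproduces supports exactly.

# Selection screen

The Ka/Ks screen uses Nei–Gojobori (1986) counting with Jukes–Cantor
correction on gapless codon-aligned CDS pairs. Per codon, the synonymous
site count is the expected synonymous fraction of the three possible
single-nucleotide changes at each position; **changes creating a stop codon
count as nonsynonymous**, which preserves the identity N + S = 3 per codon.
Codon pairs differing at multiple positions are averaged over all minimal
mutational pathways, excluding pathways that pass through a stop codon
(falling back to all pathways if every ordering is blocked). Codons
containing an ambiguous base, or that are stops in either sequence, are
excluded pairwise. Proportions are corrected by k = −¾ ln(1 − 4p/3) and the
ratio is undefined when Ks is zero or either proportion saturates. A single
codon can saturate its own synonymous correction (e.g. one Leu→Leu change
against ⅔ of a synonymous site), which is expected behavior, not an error.
Branch-site likelihood models are deliberately out of scope; the screen is
a deterministic ranking proxy.

# The synthetic generator

The generator emulates a desk-scale version of a four-species comparative
study design: a circular root genome assembled gene-by-gene (default 30
genes — 24 CDS, 4 tRNA, 2 rRNA — with three intron-carrying genes, the
first carrying two introns), random intergenic spacers (mean 300 bp), CDS
built from random sense codons between a start and a stop, and random
strands. Into the spacers it plants, at recorded coordinates: ten SSRs
covering motif lengths 1–6, three dispersed repeats (two forward, one
palindromic), and designates two spacers as divergence hotspots with a 10×
substitution-rate multiplier. Planted-element flanks are adjusted so each
planted tract or copy is maximal exactly at its recorded coordinates.

Evolution along a user-supplied tree (branch lengths in expected
substitutions per site; defaults give leaf-pair divergences up to a few
percent, with hotspot spacers reaching K2p ≈ 0.3–0.6, the range reported
for fast IRLC spacers) is by independent per-site substitution in two
classes with transition/transversion rate ratio κ = 2 and **no indels**, so
the leaf genomes remain positionally aligned and realized
transition/transversion counts per region are exact K2p inputs. Planted
elements are exempt from substitution so that every planted truth survives
in every taxon. Gene losses remove the feature and its sequence, shifting
downstream coordinates and fusing the flanking spacers, as real losses do.
Genes given a target dN/dS evolve codon-aware (synonymous proposals
accepted with probability 1/max(1, ω), nonsynonymous with ω/max(1, ω),
stops never created).

What the generator does **not** emulate — and what passing tests therefore
do not certify about real data: indels and alignment uncertainty (an
optional property the aligner is tested on separately), rearrangements and
inverted-repeat dynamics, base-compositional heterogeneity (real plastomes
are AT-rich; the generator is uniform), compound/interrupted SSRs, and
annotation error.

# Problem sizes and tolerances

The test suite and the acceptance script run the four-taxon default
(roughly 37 kb per genome), 100-seed oracle-equivalence sweeps on random
sequences of a few hundred bp, K2p estimator recovery at 10,000 sites × 200
replicates per true distance (asserted within 3 Monte-Carlo standard
errors), NJ recovery on random additive matrices up to 8 taxa, and a
six-taxon planted-clade bootstrap at 200 replicates (support ≥ 95
asserted). These sizes were chosen so every stochastic assertion has
comfortable Monte-Carlo margins while the whole suite stays interactive.

# Known limitations

* Pairwise (not progressive multiple) alignment; distances on gappy,
  highly diverged spacers will differ from multiple-alignment pipelines.
* SSR counts are convention-sensitive against tools that merge compound
  tracts; comparisons should use the same perfect-repeat convention.
* The dispersed-repeat "maximal k-mismatch" reporting enumerates one pair
  per budget split; consumers wanting one call per locus should apply the
  provided containment dedupe and filter on identity.
* The phylogeny is a distance method; it is a stand-in for ML inference,
  adequate for clade-recovery questions at plastome-scale divergences.
* NG86 is a counting method; it underestimates rates at high divergence
  and carries no site-class model.
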