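# plastcomp

Comparative analysis of plastid genomes (plastomes) for small sets of
closely related species, in the style of the comparative studies run on the
inverted-repeat-lacking clade (IRLC) of legumes. Starting from annotated
GenBank records, the package answers the questions such studies ask:

* What are the composition characteristics of each genome (GC overall, by
  partition, by codon position; codon usage; gene counts and partition
  sizes)?
* Where are the microsatellites (SSRs), dispersed repeats and tandem
  repeats, and in which genomic context?
* Which non-coding regions are divergence hotspots suitable for molecular
  markers?
* Which genes have been lost in which species, and are the losses
  monophyletic on the phylogeny?
* Do the focal species form a monophyletic clade, and with what bootstrap
  support?
* Which protein-coding genes show elevated dN/dS?

It is aimed at researchers doing plastome comparative genomics who want a
deterministic, fully tested re-implementation of this workflow, plus a
synthetic-plastome generator with complete ground truth to validate every
stage end to end.

## The statistics at the core

**Kimura 2-parameter distance.** For an aligned region pair with transition
proportion *P* and transversion proportion *Q* over comparable columns
(gaps and N excluded pairwise),

    d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q)),

undefined (saturated) when `1 - 2P - Q <= 0` or `1 - 2Q <= 0`. A spacer is
a **divergence hotspot** when its maximum pairwise *d* reaches
`mean + 2 * SD` over all defined IGS values (sample SD).

**Repeat thresholds.** SSRs: perfect tracts with minimum unit counts
8/4/4/3/3/3 for motif lengths 1–6, reported under their primitive period.
Dispersed repeats: forward and palindromic pairs, length ≥ 30, Hamming
distance ≤ 3 (identity ≥ 90%), maximal per mismatch count. Tandem repeats:
offset-scoring with match +2, mismatch −7, minimum score 50, period ≤ 500.

**Selection.** Nei–Gojobori (1986) pathway counting with Jukes–Cantor
correction, `k = -3/4 * ln(1 - 4p/3)`, ratio Ka/Ks ranked per gene and
species pair.

## Worked example

The `analysis/` directory is a numbered, runnable version of the full
workflow over a simulated four-taxon study set:

```sh
Rscript analysis/01_simulate.R     # generate the four-taxon set + truth
Rscript analysis/02_composition.R
Rscript analysis/03_repeats.R
Rscript analysis/04_divergence.R
Rscript analysis/05_gene_loss.R
Rscript analysis/06_phylogeny.R
Rscript analysis/07_selection.R
```

Output (abridged) from a run of stages 1, 3, 4 and 5:

```
simulated 4 taxa from a 36950 bp root genome (30 genes)
planted: 10 SSRs, 3 dispersed repeats, 2 gene losses, 2 hotspot spacers

SSR counts per taxon: T1=17, T2=17, T3=18, T4=17
planted SSR recovery in T1: 10/10

IGS K2p range: 0.0000 .. 0.3733 over 168 region-pair values
hotspot threshold (mean + 2 SD over IGS): 0.1919
flagged hotspot spacers: trnA-UGC-trnE-UUC, g08-g09

synthetic losses: g05 (1), g12 (1)
losses monophyletic on the generating tree: g05=TRUE, g12=TRUE
IRLC matrix losses per gene: rps16=34, rpl22=34, ycf15=32, ycf4=22,
  psaI=5, ycf1=4, rpl23=3, rps18=3, ndhB=2
```

Reading the numbers: the two spacers flagged by the mean + 2 SD screen are
exactly the two the generator evolved 10× faster — the screen recovered the
planted hotspots with no false positives. All ten planted SSRs were found
at their exact coordinates. The packaged 34-species IRLC presence/absence
matrix reproduces the classical per-gene loss counts (rps16 and rpl22
absent everywhere, ycf15 retained only twice, and so on).

The same objects are available programmatically:

```r
library(plastcomp)
cfg  <- sim_config(seed = 2026)
sim  <- evolve_on_tree(generate_root(cfg), cfg)
tab  <- region_distance_table(lapply(sim$records, extract_igs), categories = "IGS")
identify_hotspots(tab, hotspot_threshold(tab$d))
```

Real data enters through `read_genbank()` — point the same calls at any
annotated single-record GenBank flat files.

## Package layout

* `R/` — the implementation (record model and GenBank/FASTA I/O, region
  extraction, composition, SSR/repeat/tandem scanners, K2p + hotspot
  screen, gene-loss matrix + monophyly, NJ + bootstrap, NG86 screen,
  synthetic generator).
* `analysis/` — the numbered workflow drivers shown above.
* `inst/extdata/gene_loss_irlc.tsv` — the packaged 34-species IRLC
  presence/absence matrix.
* `tests/testthat/` — unit, property and acceptance tests, including
  brute-force oracle equivalence for every detector.
* `vignettes/plastome-comparative-methods.Rmd` — the methods vignette:
  models, conventions, parameter choices, limitations.
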