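---
title: "Models and methods behind codtcr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind codtcr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codtcr)
```

`codtcr` implements two computational layers around the T-cell receptor
(TR) loci of Atlantic cod: germline annotation of TR gene segments in
genomic sequence, and diversity statistics over expressed clonotype
repertoires. A V(D)J recombination simulator ties the layers together by
generating cod-like loci and repertoires with complete ground truth. This
vignette describes the models, the tunable parameters and the numerical
choices, and states what the synthetic data can and cannot tell you about
real sequencing data.

## Germline annotation

### Homology scan

Candidate coding regions are found by aligning reference V/J/C proteins
locally against all six reading-frame translations of the contig
(`find_coding_candidates()`), with BLOSUM62 scores and affine gaps (open
11, extend 1). All local maxima above a per-type raw-score threshold are
enumerated by masking each best hit and re-aligning; no E-value statistics
are computed, so thresholds are in raw score units (defaults V/C = 100,
J = 55 — J genes are ~16 codons, so their attainable scores are lower).
The chain label (alpha, beta, gamma, delta, or the joint alpha/delta
locus) of a segment is taken from its best-scoring reference, mirroring
homology-based chain typing.

### RSS model

A recombination signal sequence is modelled as heptamer + spacer +
nonamer with canonical motifs CACAGTG and ACAAAAACC. `scan_rss()` reports
every position on both strands where both motifs occur within configured
mismatch budgets (default heptamer ≤ 1 with the cleavage-critical CAC
exact, nonamer ≤ 2) separated by an allowed spacer (12, 22 or 23 bp).
The nonamer budget deliberately admits variant nonamers such as
ACATAAACC, which in cod marks the delta-preferential V subgroup together
with a 23-bp spacer. Spacer expectations per segment type follow the
12/23 rule with the teleost 22-bp V variant: V pairs with 22/23, J with
12, and a D gene is flanked by a 12- and a 23-spacer RSS in opposite
orientation. The heptamer always abuts the recombining coding end, so a
V RSS reads heptamer-to-nonamer away from the gene on the gene's own
strand while a J RSS reads away on the opposite strand;
`attach_rss()` encodes exactly this geometry. How close an RSS must sit
to its coding end is rarely stated in the literature (annotations are
usually curated by eye), so the adjacency tolerance is an explicit knob,
`rss_config(max_gap = 10)` nt by default.

D genes carry no useful protein homology at 14-odd nt, so they are
detected purely from RSS geometry (`detect_d_segments()`): two hits
facing each other across a 1..40 nt core, one flank with the 12-spacer
and one with the 23-spacer. The flank carrying the 12-spacer fixes the D
orientation.

### Functionality

A V gene is called functional when (i) its coding region translates
without internal stops, (ii) its length is a codon multiple, (iii) an RSS
is attached, and (iv) its 3' end encodes the conserved 2nd-CYS (Cys104)
with an open reading into the CDR3. The Cys check searches the last five
codons; a missing Cys raises both `missing_cys104` and `incomplete_cdr3`
(the CDR3 opening cannot be anchored without it), which reproduces the
defect pattern of the one pseudogene in the cod alpha/delta locus. J
genes additionally require the F/W-G-X-G anchor motif. That criterion is
a package convention — functional J criteria are rarely stated explicitly
— so it can be disabled (`check_j_motif = FALSE`). C genes are checked
for stops and frame only; D genes for their two RSSs.

### Subgroups, translocons, mini-clusters, names

V subgroups are single-linkage clusters of translated V exons at > 80%
pairwise amino-acid identity (matches over aligned positions, ambiguous
columns deleted pairwise). Single linkage matches the transitive way
subgroup membership is used in IMGT practice; the threshold is the
conventional 80% figure and is tunable. Union-find with a strict `>`
comparison makes the partition exact at the threshold boundary, and
labels are ordered by each subgroup's 5'-most member so numbering is
reproducible. Lowering the threshold can only merge subgroups
(single-linkage monotonicity), which the test suite asserts.

Translocons are delineated as runs from the first V gene to the last
gene before the next V-block: a new translocon opens at the first V
encountered after the current one has acquired a C gene. The slight
generalisation ("last gene" rather than "last C") keeps reverse-strand
J/D cassettes that trail the final C — as in the cod alpha/delta locus —
attached to their translocon instead of orphaned. Gamma-style loci are
instead chunked into V-J-C mini-clusters in transcription order within
each same-strand run; units missing a member are flagged partial.

Names follow the IMGT-style grammar used for cod: beta V genes carry the
translocon digit (`TRB1V5-2` = translocon 1, subgroup 5, second gene),
while beta J/D/C genes are numbered straight through the locus (the last
J genes of three translocons with 8/7/8 J genes are TRBJ8, TRBJ15,
TRBJ23). Alpha/delta V genes are `TRAV{subgroup}-{n}` with the
delta-preferential subgroup marked `/D`; gamma V/J/C genes share their
mini-cluster number, missing members skip their number, and duplicated
genes get letter suffixes.

### Phylogeny

`tr_nj_tree()` implements classic neighbour joining (iterative Q-matrix
reduction) rather than delegating to a library, because two policies are
pinned for determinism: ties in the Q matrix are broken by the
lexicographically smallest pair of current node labels, and a negative
branch arising at a join is clamped to zero with the deficit transferred
to its sister branch so path lengths are preserved. The test suite
cross-checks topologies against `ape::nj()` on random distance matrices
and asserts exactness on additive matrices. Distances are p-distance
(amino acid or nucleotide, pairwise deletion of ambiguous sites) or
Kimura 2-parameter with optional gamma rate correction (shape 5 is the
conventional value for V-gene trees); both are offered because published
analyses use either depending on the figure. Saturated K2P pairs raise an
error naming the pair. Bootstrap support is column resampling with
replacement, reported as the percentage of replicates containing each
internal bipartition, deterministic given a seed.

## The synthetic locus generator

`build_fixture_locus()` emits a genome, its truth annotation, a germline
segment set and the matching reference proteins. The three presets encode
the architecture of the cod loci:

* `cod_AD`: one translocon with 52 forward V genes in five subgroups of
  14/11/10/10/7 members, subgroup 5 carrying the 23-bp spacer and the
  ACATAAACC nonamer variant, the ninth subgroup-1 gene planted as a
  missing-Cys104 pseudogene; then a reverse alpha C gene, 21 reverse J
  genes, and a reverse delta C-J-D cassette.
* `cod_B`: three forward translocons with 10/10/14 V genes (nine
  subgroups), one D, 8/7/8 J genes and one C each; the last J of each
  translocon is long and excluded from recombination.
* `cod_G`: six complete forward V-J-C mini-clusters plus a partial
  reverse V-J cluster without a C gene.

Plants are codon-exact. Gene ends are held fixed within a preset so that
local alignment recovers planted intervals to the base; subgroup
structure is sculpted by mutating interior codons (~35% between subgroup
prototypes, ~5% within), which puts within-subgroup identity near 0.9
and between-subgroup identity near 0.5 — far from the 0.8 decision
boundary on both sides. The substitution alphabet excludes stop and Cys
codons so no spurious pseudogenes or anchor duplications arise.

Germline junctions are deliberately out of frame: each J carries a 2-nt
5' overhang between its RSS and first codon, and D cores are 14 nt, so a
zero-trim zero-insertion joint is out of frame for both the V-J and
V-D-J chains and junctional editing is required for a productive chain —
the hallmark of the cod germline configuration. With the alpha offset at
2 mod 3, every single-nucleotide insertion restores the frame, which the
tests verify by brute-force enumeration.

## The repertoire simulator

`recombine_once()` draws V, (D,) J uniformly among usable functional
segments, trims each coding end geometrically (`p_trim = 0.4`, mean 1.5
nt) and inserts Poisson-many uniform nucleotides per junction
(`lambda_ins = 2`). No junctional-process estimates exist for cod, so
these are package defaults chosen to give CDR3 lengths around 12–13
amino acids, the range observed for cod alpha/beta chains; they are
plainly labelled as defaults and tunable. The CDR3 is delimited by the V
2nd-CYS codon and the J F/W anchor codon, both inclusive — downstream
length statistics depend on this convention, so it is fixed and stated.
A rearrangement is productive when the anchors share a frame and the
reading is stop-free. Trims are bounded so anchors always survive;
draws that would exceed a segment are redrawn a bounded number of times.

`simulate_repertoire()` draws the requested number of distinct CDR3s
(redrawing duplicates, with `selection_mode = "productive_only"` as the
default for alpha/beta-like samples), then assigns read counts by a
rank-abundance Zipf law: clone *i* receives a share proportional to
*i*^−α, apportioned by largest remainder so counts are integers ≥ 1
summing exactly to the read budget. Defaults are 1,000 clones, 50,000
reads, α = 1.1 and a per-nucleotide read error rate of 0.001. The error
model mutates single bases within the CDR3 of individual reads before
collapse, so low-count artifact clonotypes appear and the standard
≥ 5-read filter has realistic work to do.

Under these defaults the filtered D50 lands near 1% of unique
clonotypes — dominated, like the observed cod repertoires, though below
the 2.7–5.4% band printed for spleen samples. That is a structural
property of the model class: a rank-Zipf with α > 1 at 1,000 clones
cannot push D50 above ~2.4% (the α → 1 limit), so the generator
reproduces "a few percent of top clones cover half the reads" only in
order of magnitude. Matching the band exactly would need a flatter or
mixed abundance model, which we deliberately do not fit: the simulator's
job is ground truth for the statistics, not a generative model of cod
spleen.

What the synthetic data do not emulate: PCR amplification bias, indel
sequencing errors, read-level coverage structure (clonotypes are
simulated directly, not assembled from reads), allelic variation,
thymic selection, and paired-chain single-cell structure. Passing tests
therefore demonstrate correctness of the statistics and of the
annotation logic on loci with planted truth, not performance on real
Illumina data.

## Repertoire statistics

All statistics take AIRR-style clonotype tibbles (comma-separated calls
mark ambiguity). Choices that the source material leaves open are fixed
as follows:

* `filter_clonotypes()` keeps clonotypes with ≥ 5 reads (a 5-read clone
  is kept; the cut is "fewer than 5") and productive rows; it is
  idempotent.
* `d50()` works on read counts with ties broken by amino-acid CDR3
  lexicographic order, and reports both the count and the
  proportion-of-unique framing, since both are in circulation.
* `shannon()` uses log base 2 by default; the base is a parameter
  because published values rarely state it.
* `v_usage()` drops ambiguous V calls (reporting the dropped fraction)
  and can weight by clonotypes or reads; `usage_correlation()` defaults
  to Pearson with Spearman behind a flag, as "correlation coefficient"
  in the repertoire literature usually means Pearson. Zero-variance
  usage vectors leave their pairs undefined rather than silently
  contributing.
* `overlap()` compares amino-acid CDR3 sets and computes Kendall's τ-b
  on the paired counts of shared clonotypes: exact permutation p-values
  for ≤ 8 shared CDR3s (ties make the textbook exact distribution
  unavailable, so the permutation null is enumerated directly), normal
  approximation otherwise.
* `publicness()` shares at the amino-acid level by default (nucleotide
  behind a flag) and requires exactly one sample per fish — replicate
  selection (keep the deeper replicate) is an upstream decision.
* `repertoire_bounds()` takes the observed unique count as the lower
  bound and `floor(observed / sampling_fraction)` as the upper bound
  under the minimal-overlap assumption; with the cod spleen fraction of
  0.15 this reproduces 4,422 → 29,480 and 852 → 5,680. Floor is used
  because the printed values that are internally consistent are exactly
  these two; the remaining published values were evidently computed from
  unrounded medians.
* `intertranslocon_events()` counts V–J cross-translocon pairings among
  clonotypes where both calls are unambiguous, reporting the event count
  against both the full clonotype denominator and the unambiguous
  subset.
* `rarefaction()` subsamples reads without replacement from the
  read-expanded multiset; at full depth it returns the exact unique
  count, and on small cases its means are validated against the
  closed-form hypergeometric expectation.

## Problem sizes and determinism

Every stochastic entry point takes a seed and restores the caller's RNG
state. The test suite and the reproduction script run entirely on
generated data at deliberately modest sizes — fixture loci of 9–30 kb,
repertoires of 100–1,000 clones and up to 50,000 reads, 5 simulation
seeds — which keeps a full run in the low minutes while leaving every
statistic's oracle check exact or within stated Monte-Carlo error.

## Known limitations

Annotation assumes single-exon gene models (intron/exon structure is
accepted as metadata, never inferred — splice inference would need
RNA-seq); allele-level naming (`*01`) is out of scope; the homology scan
is not an optimised aligner and is sized for locus-scale contigs, not
whole genomes; and the simulator's abundance model is a single Zipf
family, adequate for dominance statistics but not for fitting observed
rank-abundance curves.
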