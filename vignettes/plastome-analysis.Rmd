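---
title: "Comparative plastome analysis with plastomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome analysis with plastomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(plastomics)
```

`plastomics` implements the analysis stages of a comparative chloroplast
genome study: quadripartite structure detection and junction accounting,
codon-usage-bias statistics, microsatellite and dispersed-repeat detection,
per-locus nucleotide diversity, and pairwise Ka/Ks — together with a
synthetic plastome simulator that plants every one of those signals at known
coordinates so the whole pipeline is testable without any external data.
This vignette records the models the package computes, the defaults it
chooses, and the design decisions behind them.

## The plastome container

A `plastome_record` is a circular DNA molecule over `A,C,G,T,N` with an
ordered table of typed gene features (CDS, tRNA, rRNA). All coordinates in
the package are **1-based inclusive**, the GenBank and IRanges convention;
multi-part features (introns, origin-spanning genes) store one interval per
part in join order, and minus-strand features are reverse-complemented on
splicing. Pseudogene status is taken from the annotation (`/pseudo`), never
re-derived from ORF disruption: annotation pipelines make that call with
information (alignments to functional homologs) that a single record does
not contain. Ambiguity characters other than `N` are rejected at parse;
`N` is tolerated but excluded from GC and codon statistics.

The GenBank reader/writer covers the subset of the flat-file grammar that
annotated plastomes actually use (single entry, `join`/`complement`
locations, `<`/`>` partial markers, `/gene` and `/pseudo` qualifiers) and
round-trips sequence and feature set losslessly; FASTA I/O is delegated to
Biostrings.

## Quadripartite structure

Plastomes are organized as LSC–IRb–SSC–IRa: two near-identical inverted
repeats (IRs) separating a large and a small single-copy region.
`detect_inverted_repeats()` finds this from sequence alone so it works on
bare FASTA: exact k-mer seeds (k ≤ 15) between the sequence and its reverse
complement are extended maximally along their diagonal; the
highest-scoring non-overlapping arm pair (longest, then fewest mismatches,
then smallest start) defines the IRs, and the longer gap between the arms is
the LSC. Circularity is handled by searching the doubled sequence and
normalizing coordinates modulo the genome length; ties between equal-length
single-copy regions are broken by the lexicographically smaller region
sequence so the orientation is deterministic.

Defaults: `min_ir_length = 1000` bp — genuine plastome IRs are tens of
kilobases, and a 1 kb floor rejects incidental palindromic noise while
leaving room for highly reduced IRs; `max_mismatch_fraction = 0` — plastome
IR arms are copy-corrected and near-identical, and exact extension gives
reproducible boundaries (a small budget, split optimally between the two
extension directions, is available for divergent arms). Tests on small
fixtures lower `min_ir_length` explicitly.

Junctions are named JLB (LSC|IRb), JSB (IRb|SSC), JSA (SSC|IRa) and JLA
(IRa|LSC). `junction_report()` measures, for each junction, the nearest
feature on either flank (distance 0 when abutting) and any feature crossing
the boundary with its split lengths; pseudogenes are excluded from the
flank search by default because boundary comparisons across species are
made with functional genes, with `include_pseudo = TRUE` to override.

## Codon usage bias

All codon statistics use translation table 11 (the bacterial/plastid code),
on the functional CDS set with IR duplicates collapsed to one copy, terminal
stop codons excluded, and codons containing `N` skipped — the mode is
recorded in report output, and an all-copies mode exists because published
tables do not always state which convention they used.

* **RSCU** — count of a codon divided by the mean count of its synonymous
  family; 1 means no bias. Family sums equal family sizes by construction,
  which the tests assert on every table. Zero-count families report RSCU 0
  with an `absent` flag rather than NaN, for stable tabular output.
* **Positional GC** — GC1, GC2, GC3 and GC12 = (GC1+GC2)/2 per gene.
* **ENC** — Wright's effective number of codons from family homozygosities
  F = (n·Σp² − 1)/(n − 1), averaged within degeneracy classes, with the
  sixfold families (Leu, Ser, Arg) as their own class:
  ENC = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆. Families with n ≤ 1 or F = 0 are
  excluded from their class average; a missing threefold class (Ile alone)
  is imputed as (F̄₂+F̄₄)/2, matching EMBOSS chips behaviour; a missing
  two-, four- or sixfold class leaves ENC undefined. Values are clipped to
  [20, 61]: 20 is one codon per amino acid, 61 is uniform usage.
  `enc_expected()` provides the mutation-only null curve
  2 + s + 29/(s² + (1−s)²) for ENC-plots.
* **PR2** — third-position balance x = G3/(G3+C3), y = A3/(A3+T3) restricted
  to fourfold-degenerate families. The default family set is the five
  strictly fourfold amino acids plus the fourfold boxes of Leu (CTN),
  Ser (TCN) and Arg (CGN), the usual reading of the "|4" restriction;
  `fourfold = "strict"` keeps only the five.
* **Neutrality regression** — OLS of GC12 on GC3 across genes
  (`stats::lm`). A slope near 1 says the three positions drift together
  under mutation pressure; near 0 says selection decouples the first two
  positions.

## Repeats

`find_ssrs()` reports maximal perfect tandem runs of 1–6 bp units at the
standard plastome MISA thresholds (minimum copies 10, 5, 4, 3, 3, 3 for
mono- through hexanucleotides). A run is reported at its smallest primitive
unit only, which simultaneously prevents poly-A from resurfacing as "AA"
and suppresses duplicate reports of one run at several unit lengths.
Compound/interrupted SSRs are not merged: each perfect run stands alone.
Motif classes canonicalize phase and strand: the lexicographically smallest
rotation of the motif and of its reverse complement, joined in sorted order
(`"TTA"` → `"AAT/ATT"`). Repeat search runs on linear coordinates as
deposited by default — matching how repeat scanners are run on flat files —
with `circular = TRUE` available (doubled-sequence scan, reports
deduplicated modulo length) when origin-spanning runs matter.

`find_dispersed_repeats()` covers the four REPuter classes — forward,
reverse, palindromic (reverse complement) and complementary — with defaults
minimum length 30 bp, Hamming distance ≤ 3, at most 5000 reported pairs.
Exact seeds of length ⌊(min_length − mismatches)/(mismatches + 1)⌋
(pigeonhole: every qualifying pair contains one) are extended along their
diagonal with the mismatch budget split between the two directions to
maximize total length, and extensions always end on a matching base. Pairs
contained within a longer pair of the same kind are suppressed; ties sort
by smaller start. Because IRa is by definition a genome-scale palindromic
match of IRb, supplying `mask_partition` removes pairs coextensive with the
IR arms so the output lists *dispersed* repeats rather than the
quadripartite structure itself.

SSR locations are classified by midpoint: region membership in the
partition, and context `exon` (inside a feature part), `intron` (inside a
feature's extent but between parts) or `IGS`.

## Nucleotide diversity and hypervariable regions

π is the mean over sequence pairs of the proportion of differing sites.
The default site filter is complete deletion — a column is unusable if any
row carries a gap or `N` — matching DnaSP's default; pairwise deletion is a
flag. `shared_locus_pi()` intersects gene and intergenic-spacer loci by
name across records, aligns each shared locus through a pluggable hook, and
flags loci with π above a threshold whose default, 0.07, is the
conventional cut for calling plastome hypervariable regions. The built-in
hook is a center-star alignment via `Biostrings::pairwiseAlignment`
(sequences of equal length are treated as positionally homologous); it is
adequate for the closely related sequences the simulator produces, and any
external multiple aligner can be substituted for production data.

## Ka/Ks

The core estimator is Nei–Gojobori (1986). Synonymous site counts per codon
enumerate the three single-base mutations at each position under table 11,
with mutations to stop codons counted as nonsynonymous so the two site
classes always sum to 3. Observed codon differences are resolved over all
orderings of the differing positions, equally weighted, after discarding
orderings that pass through a stop codon (if every ordering is blocked, all
are used). Proportions are Jukes–Cantor corrected,
d = −(3/4)·ln(1 − (4/3)p), undefined at p ≥ 3/4 (saturation). Codon pairs
are produced by protein-guided alignment (BLOSUM62 global alignment of the
translations, back-mapped to codons; gapped or `N` columns dropped).
Following the usual reporting rule, results with an undefined ratio
(Ks = 0 or saturation) or ratio ≥ 45 are flagged excluded — such genes have
essentially no synonymous signal.

A second method, labelled `"YN-approx"`, weights each possible change by a
transition/transversion parameter estimated from the observed differences
before counting sites. It approximates the behaviour of
mutational-opportunity estimators in the YN00 family; results carry their
method label so downstream figures can state it honestly. The exact
variant used by published KaKs_Calculator analyses is not fully specified,
so cell-level agreement with published matrices is not expected or claimed.

## The synthetic-data generator

`generate_plastome()` builds what the analyses assume: a circular genome
LSC–IRb–SSC–IRa with IRa the exact reverse complement of IRb, genes with
start/stop codons and bodies drawn from a configurable within-family codon
distribution (uniform by default, so every expected RSCU is 1), planted
SSRs and dispersed repeats at recorded coordinates, and a JSON-serializable
truth table. Default region lengths (LSC 83,689, IR 35,027, SSC 4,915 bp)
and background GC (0.365) mirror a real orchid plastome; the test suite and
the acceptance script pass smaller specs (LSC 6–12 kb, IR 2.5–4 kb,
SSC 1.2–2 kb) as the package's own choice of exercise size, which keeps the
full suite under a few minutes while leaving every planted element tens of
standard deviations above background noise.

Determinism and exactness are engineered, not hoped for: a single seeded
generator drives all draws; placements are allocated largest-element-first
into free gaps so crowded regions cannot fail by fragmentation; each
planted SSR is wrapped in breaker bases that cannot extend its run; the
first base of each single-copy region is adjusted not to complement its
last base so maximal IR extension stops exactly at the planted arm; and
after assembly the genome is screened for accidental SSRs or near-threshold
exact repeats and the background re-rolled (up to 20 times) until only the
planted elements remain. Planted SSRs and repeats are restricted to the
single-copy regions because anything placed in the IR is duplicated by
construction.

`mutate_orthologs()` derives a diverged partner record: per CDS position it
re-derives which substitutions are synonymous or nonsynonymous on the
current codon and applies them at the requested per-position rates (never
creating stops); intergenic positions mutate at their own rate, optionally
restricted to named spacers. Applied counts go into the truth table.

What the generator does **not** emulate: indel evolution, rate variation
along a tree, IR boundary expansion/contraction events, compositional
heterogeneity between regions, and sequencing artefacts. Green tests
therefore demonstrate correctness of the statistics and detectors on clean
signals, not robustness to misannotation or alignment error in real data.

## Numerical choices and known limitations

* Neutral-recovery calibration: simulating equal per-site rates while
  rejecting stop-creating substitutions suppresses a few percent of
  nonsynonymous events, so the NG86 ratio centres near 0.95 rather than 1
  with a ~6% Monte-Carlo SE per 10,000-codon pair; calibration checks
  therefore average a handful of replicate pairs.
* The naive aligner is a center-star heuristic; π on loci with substantial
  indel divergence should use a production aligner through the hook.
* Dispersed-repeat maximality under mismatches is defined per diagonal
  (no gapped extension), the Hamming analogue of REPuter's model; published
  repeat counts also depend on sub-maximality and masking conventions that
  tools leave implicit, so the masking and maximality toggles are the
  instrument for matching any particular published table.
* `enc()` on very short genes (a handful of codons) frequently has
  unscorable classes and returns an undefined flag rather than a number.
* Paper-scale reproduction of a deposited record requires the user to fetch
  the GenBank flat file themselves; the package never downloads.
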