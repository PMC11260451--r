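---
title: "Detecting ctDNA integration in coculture: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ctDNA integration in coculture: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `ctdnaIntegrate`, the
parameters that matter, the simulator's scope, and the numerical decisions
taken where the design was genuinely open. Commands are shown but not
evaluated here; the package's test suite and `scripts/acceptance.R` compute
every quantitative claim.

## The experimental design being modeled

A recipient cancer cell line is cultured with patient-derived circulating
tumor DNA (ctDNA). If ctDNA fragments integrate into the recipient genome,
three whole-genome sequencing samples — cell alone, ctDNA alone, and the
coculture — carry a characteristic comparative signature:

* variants private to the donor appear in the coculture sample at loci
  homologous to the integrated fragments ("SNVs of interest");
* de novo assembled coculture contigs contain breakpoints where sequence
  identity switches from the cell genome to a ctDNA fragment ("transition
  points");
* duplications of reference sequence ≥ 10 bp arise uniquely under coculture,
  because fragments preferentially integrate near their locus of origin;
* transposable-element (TE) sequences concentrate within 100 nt of
  transition points, with tissue-specific element usage;
* a transgene cassette delivered the same way produces discordant read
  pairs split between the cell genome and the cassette.

The package implements each analysis plus a generator that emulates the
design end to end, so that every detector can be scored against a known
truth table.

## The simulator: what it emulates, and what it does not

`simulate_genomes()` draws a haploid multi-contig cell genome with uniform
base composition and derives the donor genome by planting substitutions
(either a per-base rate or an exact count). Donor-private SNV positions are
the ground truth for every downstream confirmation step.

`simulate_ctdna()` draws fragment cores as substrings of the donor under a
lognormal size model (default median 170 bp, the typical cfDNA mode, with a
configurable tail). With probability `te_end_probability` a TE consensus
copy is embedded within 100 nt of one fragment end; the copy locally
replaces donor sequence inside the core, so a TE-bearing core is no longer
an exact donor substring over the embedded interval — the deliberate
trade-off that keeps fragment coordinates contiguous and the truth table
simple. Private SNVs wiped out by the overwrite are removed from the
fragment's record, and when a minimum SNV count is requested the placement
is redrawn until it holds after planting. The 14-nt PACBIO adaptor
(`GCGCTCTGTGTGCT`) is ligated to both fragment ends.

`simulate_coculture()` plants fragment cores into the cell genome. Adaptors
are stripped at this point: ligation marks fragment termini for library
identification, and the integrated molecule modeled here is the biological
fragment. Because contigs windowed out of this genome therefore carry no
adaptor, the pipeline's TE selection step defaults to
`require_adaptor = FALSE`; the flag exists (default `TRUE` in
`filter_transition_proximal()`) for ingested contigs assembled from
adaptor-bearing reads, where adaptor evidence next to the junction is the
intended artifact filter. A fraction `proximity_bias` (default 0.8) of
insertion positions is drawn uniformly within `proximity_window` (default
10 kb) of the fragment's origin; the remainder land uniformly anywhere, so
the realized proximal fraction slightly exceeds the bias by the chance mass
of the window. Duplications are planted as tandem copies of reference
segments with lengths ≥ 10 bp. Events keep a minimum spacing (default
2 kb) so that truth windows do not overlap.

`simulate_reads()` samples insert positions uniformly, draws insert sizes
from a normal model, emits forward/reverse mates and applies per-base
substitution errors only. Not modeled: indel errors, quality-score
degradation, GC or chromatin-derived coverage bias, nucleosome footprints
of cfDNA, diploidy and copy-number background, and the repair mechanism
itself. Passing tests therefore demonstrate correctness of the analysis
logic under a clean generative model, not robustness to every artifact of
real libraries.

## Variant calling and the three-way set logic

Reads are placed by unique k-mer anchoring (k = 21 at the caller): a read
maps where one of its terminal k-mers occurs exactly once in the reference,
and is kept when its mismatch count is ≤ 10% of the read length. Pileup
records become calls at allele frequency ≥ 0.01 — the threshold is
inclusive — with total depth ≥ 8. A `min_alt_depth` floor (pipeline default
2) suppresses single-read sequencing errors, which at 30× coverage would
otherwise clear a 0.01 AF threshold by themselves; set it to 1 for the pure
threshold rule. Multi-allelic sites decompose into one record per alt
allele with `af = alt/(ref + alt)`.

`snvs_of_interest()` computes `(ctDNA ∩ coculture) \ cell` on
`contig:pos:ref:alt` keys, and `variant_venn()` reports the full 7-region
partition, whose counts sum to the union size. VAF shifts use a two-sided
exact conditional (Fisher) test on the 2×2 allele-depth table; the paper's
source figures present the shift descriptively, so an exact test was chosen
over an unstated approximation. When the cell sample has no call at a site,
its depth is taken from the cell pileup when supplied, otherwise the
coculture depth is used as a proxy with zero alt reads.

`estimate_tumor_fraction()` uses the fragment-level reading of tumor
content: a fragment is informative if it overlaps ≥ 1 tumor-SNV site, and
tumor-derived if it carries the alt allele at any overlapped site. The
locus-level alternative (averaging per-site allele fractions) is not the
default because the quantity of interest is the fraction of *fragments* of
tumor origin.

## Transition points

Contigs are decomposed into maximal ungapped blocks against two references:
the cell genome and the ctDNA fragment cores. Seeding uses 31-mers, with
two ambiguity rules:

* any k-mer occurring in **both** references is discarded for both — this is
  what confines cell-matching blocks to the flanks even though an inserted
  fragment is nearly identical to its homologous origin locus;
* k-mers shared between **fragments** (overlapping draws from the same donor
  region) keep one deterministic representative rather than being dropped:
  they are unambiguous for the cell-versus-ctDNA decision, and either
  attribution names a fragment covering the same donor interval.

Extension is ungapped with a tolerance of 1 mismatch per 100 nt; a mismatch
is crossed only when followed by ≥ 8 consecutive matches, and boundaries are
always trimmed to the last matching base. This makes the reported
breakpoint equal to the exhaustive maximal split point on error-free
contigs while still bridging isolated sequencing errors in long blocks.

Junction evidence requires each block to contribute ≥ 31 nt outside the
union of opposite-type blocks: chance k-mers spanning a junction can extend
into the other reference's territory (for example one flank base plus 30
origin-homologous bases), and such nested blocks are matches inside the
insert, not junctions. A cell block and a ctDNA block abutting within
`max_gap` (default 20 nt, an allowance for untemplated end-joining scars;
the stripped adaptor, when retained on a constructed contig, also falls in
this gap) yield a transition whose breakpoint is the offset of the first
base beyond the maximal cell-consistent segment. Adaptor adjacency is
scored by searching the adaptor motif with ≤ 1 mismatch, on either strand,
within 30 nt of the breakpoint on the ctDNA side or of the ctDNA-side
contig end — the dual window covers both the junction-retained and the
fragment-end adaptor placements.

`confirm_and_call()` merges junction pairs bounding one insert, lifts the
matched fragment interval to donor coordinates through the fragment's
origin, and confirms a call when ctDNA-private SNV keys fall inside it.
Calls at the same locus under different fragment attributions (possible
with overlapping fragments) are deduplicated to the best-supported one;
requiring adaptor evidence on the ctDNA side of at least one junction is
the recorded convention for ingested data. Unconfirmed calls are retained
and labeled.

## Duplications

A tandem duplication shifts the alignment diagonal between adjacent
colinear blocks by exactly the duplicated length, regardless of chance
matching at the junction — so the ≥ 10 bp threshold is exact, which the
boundary tests (12 bp kept, 9 bp rejected) exercise across seeds. Events
require genuinely overlapping reference intervals; events whose contig also
carries a transition are attributed to the insertion channel in the
pipeline, because a proximal insertion whose origin lies inside the contig
window duplicates its source interval as a side effect. Events found in
cell-only contigs mark the corresponding coculture events as not unique.

## Repeat annotation and enrichment

The TE scanner is a transparent local-alignment stand-in for a repeat
annotator: Smith–Waterman with match +2, mismatch −3, gap open −5, gap
extend −2, reporting score ≥ 40 and identity ≥ 80%, both strands, with
overlaps between different elements resolved by score, then alignment
length, then name. Synthetic consensi are generated mutually
non-homologous under this same scoring (pairwise score < 40), so scan
results on simulated data are unambiguous. The 100-nt transition window is
measured from the breakpoint to the nearest hit edge, inclusive, on the
ctDNA side.

Enrichment uses Pearson's χ² with 1 df, no continuity correction by
default (the correction is a flag); with any expected cell < 5 a warning is
emitted and the exact test p-value is reported alongside. The odds ratio
applies the Haldane 0.5 correction when a zero cell exists; a zero margin
is an error. Per-fragment TE± is the default counting unit, matching the
fragment-level enrichment question; per-occurrence multisets feed the
tissue-specificity ranking, where elements with matched count > 0 and
mismatched count = 0 are ranked by count with name tie-breaks.

## Transgene sites

The cassette must share no 25-mer with the cell genome (checked at load;
violation is a hard error, since anchor-based discordance would be
ambiguous). A pair is discordant when one mate anchors uniquely to the
cell genome, the other uniquely to the cassette, and neither mate maps to
the other reference. Sites are single-linkage clusters with gap ≤ insert
mean + 3 sd, kept at `min_support ≥ 3`. Confidence is
`P(Poisson(λ_bg) < support)` with the background rate estimated from
off-cluster discordant density (floored at 10⁻⁸ so an empty background
yields confidence ≈ 1); frequency is support divided by the expected
physical pair coverage `n_pairs × insert_mean / genome_length`. Because
both mates must map cleanly, junction yield is governed by the inner gap
`insert − 2 × read length` (plus the mapper's 10% mismatch allowance);
simulated transgene libraries therefore use a 400 ± 40 insert with 150-nt
reads, a realistic library choice that gives each junction an expected
double-digit pair support at 30×.

## Problem sizes and reproducibility

All generators set the RNG seed internally, so identical `(config, seed)`
reproduce byte-identical genomes, fragments and FASTQ output; the pipeline
derives per-stage seeds from the master seed. The packaged study
conditions are desk-scale by design: two 100–150 kb contigs, donor SNV rate
10⁻³, 20–30 fragments, 30× coverage (the full design sequences at 50×; the
parameter is exposed), 100-insertion runs for proximity recovery, 200
fragments per arm for enrichment power, and 20–100 seed replicates for the
stochastic properties. The test suite runs in minutes on one CPU at these
sizes.

## Known limitations

* The greedy assembler is a de Bruijn unitig walker adequate for error-free
  reads; real assemblies should be ingested via `assemble_or_ingest(...,
  mode = "ingest")`.
* The read mapper is anchor-based and ungapped; indel-containing or
  junction-spanning reads are left unmapped rather than clipped, which is
  conservative for variant calling and lowers discordant-pair yield
  relative to a soft-clipping aligner.
* Split-read evidence for transgene junctions is not implemented; the
  discordant-pair channel alone localizes sites to within the insert
  length.
* Fragment-level TE enrichment in the default pipeline reflects the
  generator's planting process; it shows enrichment only when the
  integrated and non-integrated arms are generated with different TE
  probabilities, as in the two-arm experiment used by the acceptance
  script.
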