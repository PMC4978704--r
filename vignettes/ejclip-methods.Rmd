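---
title: "EJC iCLIP analysis: models, parameters and design choices"
author: "ejclip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EJC iCLIP analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

The exon junction complex (EJC) is deposited on spliced mRNAs in a
splicing-dependent, largely sequence-independent fashion, canonically
20–24 nt upstream of exon–exon junctions. iCLIP of the four RNA-binding
EJC subunits (eIF4A3, BTZ, UPF3B, RNPS1) produces single-nucleotide
crosslink events: each read truncates at the protein–RNA contact, so the
crosslink nucleotide is the position immediately 5' of the read start on
the read's strand. `ejclip` implements the full analysis path from raw
crosslink reads to high-confidence, multi-protein EJC deposition sites,
positional 5mer motif enrichment, seven-category exon landscapes,
candidate-exon discovery and the accompanying enrichment statistics,
together with a ground-truth simulator used to validate every stage.

# Data model

All intervals are held as `GRanges` (1-based closed, the Bioconductor
convention); BED-convention 0-based half-open coordinates appear only at
file I/O boundaries and in single-position reports such as peak summits.
The central containers are

* `GenomeAnnotation` — genes, transcripts, exons and per-transcript CDS
  spans, validated for sortedness, containment and chromosome bounds;
* `CrosslinkTrack` — per-library unique crosslink-event counts at
  single-nucleotide resolution, with raw and unique totals (their ratio
  is the overamplification rate that the random-barcode system controls);
* `PeakSet` — significant crosslink clusters with summit, flank score and
  permutation FDR;
* `KmerProfileSet` — observed/null counts, Z scores and positional
  occurrence vectors for all 1,024 5mers.

# Peak calling

Within each gene span (intergenic events are not peak-called), every
position with at least one unique event is scored with the sum of unique
events within ±15 nt (the *flank*). The null distribution re-places all
of the segment's events independently and uniformly over segment
positions 100 times and rescores; the FDR attached to an observed score
*s* is

> min(1, mean permuted positions with score ≥ s / observed positions
> with score ≥ s),

and positions inherit the FDR of their score. Positions with FDR
strictly below 0.05 are significant; significant positions within ≤ 15
nt merge into a peak whose summit is the member with the highest event
count (ties resolve toward the transcript 5' end). The permutation null
and the FDR estimator are declared choices of this package — the
uniform within-segment re-placement follows the iCount family of
CLIP peak callers — and the exact draw order (`sample.int(L, n, replace = TRUE)` per
permutation, from a seed derived from the run seed and the segment
coordinates) is part of the contract, which lets independent naive
reimplementations reproduce FDR values seed-for-seed — the test suite
does exactly that.

Replicates are pooled (counts summed) before peak calling; RPM values
are always per library and never pooled. Peak midpoints — the motif
anchor — use `floor((start + end - 1) / 2)` in 0-based half-open
coordinates, the left of the two central positions for even widths.

# Motif analysis

All 5mers whose *center* lies within ±40 nt of a peak midpoint are
counted on the transcribed strand; the shuffled null re-draws midpoints
uniformly within their gene segments 100 times. Z = (observed − null
mean)/null SD, with Z reported as 0 and flagged when the SD is
unavailable (a single shuffle). The positional occurrence vector over
±100 nt is normalized by the mean random per-offset score of that 5mer
across the ±100 nt region (pseudo-count 0.5 for empty nulls); the
region mean is used rather than per-offset null rates so that the
normalization does not itself reshape the positional profile. The
shuffle-SD
Z score (rather than a Poisson approximation) is likewise a recorded
choice. 5mers are classed GT/non-GT by containing the dinucleotide GT;
greedy maximal-overlap assembly (minimum 4 nt for 5mers) merges the top
donor-region motifs into the splice donor consensus AGGTAAG when a
unique overlap chain exists and otherwise returns the input flagged.

# High-confidence sites, candidates, and exon filters

Peaks from different proteins overlapping by ≥ 1 nt (abutting intervals
do not count) merge transitively; sites with fewer than two distinct
supporters are dropped. The GFP background filter defaults to removing
any site that overlaps a GFP peak; a count-ratio mode against a GFP
track is available as an alternative since there is no single canonical
background-filter rule. Candidate exons require (1) no overlap
with any annotated exon, (2) BTZ > 2 RPM confirmed by ≥ 1 other
overlapping EJC protein and (3) a donor motif (AGGTAAG or AGGTGAG)
starting at most 25 nt downstream of the peak end — downstream in
transcript orientation, because the EJC sits upstream of the donor.

Exon-level thresholds and their inclusivity: "above a threshold of 10
reads" and "at least 10 reads" are both implemented as ≥ 10; the
low-abundance filter (iCLIP > 1 RPM with RNA-seq < 0.5 RPM) uses strict
inequalities on both sides, and its percentages are taken over all
annotated exons of the category, not only expressed ones. Whether the
original gene-level counting used crosslink positions or whole-read
overlaps is unstated; this package counts crosslink events, with an
HTSeq-union-style ambiguity rule (an event in the exonic union of two
genes counts for neither) and a parallel intronic counter so that
per-gene, ambiguous, intronic and unassigned counts always sum to the
library total.

# Exon classification

Distinct genomic exons of protein-coding genes take exactly one of seven
categories. Terminal status in any isoform wins over internal
categories, and 3' terminal wins over 5' terminal — relevant for
single-exon transcripts and for exons terminal in one isoform but
internal in another, a case with no canonical convention; the
precedence is this package's documented decision. Internal exons are
constitutive when every isoform contains them with identical boundaries
and variant when skipped with invariant boundaries; within a cluster of
overlapping internal exon forms, a varying donor (the exon 3' boundary
in transcript orientation), acceptor, or both assigns alt_donor,
alt_acceptor or alt_both to all members of the cluster.

# Profiles and differential binding

Relative-length exon matrices map each event to bin
`floor(offset * n_bins / length)` (no interpolation), so binned counts
are conserved exactly; rows are ordered by absolute exon length. log2
fold differences between iCLIP and RNA-seq use the per-exon bin maxima
on RPM-scaled matrices with a pseudo-count of 0.5; RPM rather than raw
maxima keeps the ratio comparable across libraries of different depth,
consistent with the RPM scaling used throughout the pipeline. Peak region assignment uses the summit position
only, so regional percentages always sum to 100; the region map labels
every strand-position with precedence ORF > 5'UTR > 3'UTR > ncRNA >
intron > intergenic, and exons of CDS-less transcripts contribute the
ncRNA label.

Gene-level differential binding ships as a deliberate stand-in, not a
negative-binomial GLM: group means of counts-per-million with
pseudo-count 0.5 for the fold change, an exact binomial test of the
pooled group-A count against the pooled total at the library-size-implied
proportion, and Benjamini–Hochberg adjustment. Raw count matrices export
via `writeCountMatrix()` for external NB-based tools. The enrichment
statistic for gene-set membership is the one-sided hypergeometric upper
tail computed in log space.

# The simulator and what it does (not) emulate

`simulationConfig()` fixes the study conditions; `generateGenomeAnnotation()`
builds a single-chromosome genome with genes on alternating strands:
multi-isoform coding genes realizing constitutive, variant, alt-donor,
alt-acceptor and alt-both internal exons (two isoforms, abundance split
2:1), single-isoform coding genes, intronless genes and non-coding
genes. Every exon–intron junction carries the planted donor consensus
(last 2 exon nt + first 5 intron nt = AGGTAAG); the canonical deposition
window (−24..−20 from each junction-bearing exon 3' end) carries a weak
binding-site 5mer (GAAGA by default), emulating the weak non-GT sequence
preference observed at EJC binding sites, so the GT/non-GT motif-class
separation is reproducible. Coding introns carry 30-nt planted
pyrimidine tracts (the PTB-like substrate). Defaults chosen once as
field-realistic values: internal exons 90–240 nt, introns 250–700 nt,
log-normal gene abundance (meanlog log 10, sdlog 0.8), 10% of coding
genes TOP-like with EJC deposition multiplied by 0.1, signal:noise 4:1,
geometric PCR duplication at rate 0.3 with 9-nt UMIs, 20,000 unique
events per library, RNA-seq depth 2 read starts per exonic nt at mean
abundance. Each library draws from an RNG stream derived from (seed,
library label), so adding a library never perturbs the others.

Not emulated: sequencing errors, RT-stop and fragment-length artifacts,
splice-junction-spanning reads, multi-mapping, isoform-level coverage
non-uniformity, and real genomic sequence composition. Passing tests
therefore demonstrate the correctness and calibration of the algorithms
under the declared generative model, not performance on real libraries.

# Problem sizes and determinism

The validation suite runs the full path on 20-gene simulations (about
20,000 unique events per library) and the end-to-end calibration and
recovery experiments on 200-gene simulations with 40,000 events per
library; the false-discovery calibration plants deposition at 50% of
junction-bearing exon ends with 1:1 uniform background, and site
recovery uses all four EJC libraries plus a GFP control at the default
4:1 signal:noise. These sizes give hundreds of called peaks and sites,
enough for stable proportions at the tolerances asserted. All stages are
deterministic given the run seed; per-segment and per-library seeds are
derived from it.

# Known limitations

* The permutation null assumes uniform placement within a gene span;
  structured backgrounds (transcription-bumps, mappability) are not
  modeled.
* Exon classification trusts the annotation's isoform set; incomplete
  annotations shift variant/constitutive labels.
* The differential-binding stand-in underestimates biological dispersion
  relative to an NB model; use the exported counts with a dedicated tool
  for real data.
* BAM input is out of scope; aligned reads enter as BED6 spans (or
  pre-computed crosslink BEDs), and multi-mapper resolution is an
  upstream responsibility.

# Interfaces

The package is function-first: `runPipeline()` chains simulate →
crosslinks → peaks → motifs → sites → candidates → profiles → stats,
writing versioned artifacts plus JSON manifests with parameter sets,
seeds and md5 checksums (identical configuration reproduces identical
checksums). Individual stages are exported functions over the S4
containers; standard formats (GTF, BED6, bedGraph, FASTA, TSV) are read
and written through the usual Bioconductor I/O machinery.
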