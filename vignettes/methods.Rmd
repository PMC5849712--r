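---
title: "Methods: calling and comparing alternative splicing across species on a shared reference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and comparing alternative splicing across species on a shared reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecasplice)
```

# The analytical model

`ecasplice` implements a comparative survey of alternative splicing (AS)
for the setting in which several closely related species' RNA-seq
libraries are all aligned to *one* shared reference genome and annotation.
That setting sidesteps cross-genome orthology inference entirely: because
every species' reads are expressed in the coordinates of the same gene
models, two species share an AS event exactly when they produce the same
event signature — the same gene, the same event type, the same
coordinates. An event observed in two or more species is called an
evolutionarily conserved AS (ECAS) event; events seen in a single species
are non-ECAS.

The pipeline has five analytic stages, each available as an R function
and as a file-based pipeline stage.

## Splice-junction evidence and filtering

A splice junction is evidenced by a gapped alignment: an `N` operation in
the CIGAR. For every junction the package aggregates, over supporting
reads: the support count, the minimum flanking aligned block length on
either side (*overhang*), the number of distinct read start coordinates,
and the number of uniquely aligned supporting reads (mapping quality
> 0; only primary alignments are considered at all).

A junction is retained when

* support ≥ `max(2, ceiling(2 × total_mapped / 10^7))` — two reads per
  ten million mapped reads, never below the absolute minimum of two
  (libraries below ten million reads still require two reads; the ceiling
  keeps the threshold integral and monotone in library size);
* minimum overhang ≥ 8 bases on both sides over all supporting reads;
* at least 2 supporting reads have a non-repetitive match position.

The last rule is inherently ambiguous in the literature; the package
adopts the strictest plausible reading — at least two supporting reads
must be uniquely aligned *and* the supporting reads must start at two or
more distinct genomic coordinates — and makes all three thresholds
configurable through `filter_policy()`. Rejected junctions carry the
first failed criterion (support, overhang, distinct positions, unique
support, in that order), which makes filter decisions auditable.

No canonical-dinucleotide (GT–AG) requirement is imposed: junction
reliability is argued from read support, not motif.

## Event calling

Five event types are called per species against the shared annotation:

* **IR** (intron retention). An annotated intron is retained when it has
  intron-mapped reads at or above the same library-scaled threshold as
  junctions *and* at least 0.5 of its positions are covered by
  contiguously aligned read blocks. The 0.5 criterion is read as coverage
  *breadth* — fraction of intron positions touched — rather than mean
  depth, because breadth is robust to single-position pileups; a
  mean-depth mode is available (`coverage_mode = "depth"`) via the
  `intron_bases` column of the coverage table. One IR event is produced
  per retained intron per species, regardless of read counts.
* **ES** (exon skipping). A junction whose boundaries coincide exactly
  with the end of annotated exon *i* and the start of annotated exon *j*,
  *j* ≥ *i* + 2, skips the exon(s) in between. A multi-exon skip is one
  event (the junction is the observation unit), with length the summed
  length of all skipped exons.
* **AltD / AltA / AltP**. A passed junction that matches no annotated
  intron exactly and is not an exon-skipping junction is assigned to the
  annotated intron of its gene with maximal *reciprocal* overlap (ties
  broken by smaller total boundary shift, then by coordinate — fully
  deterministic). If only the donor (5′ splice site) is shifted the event
  is AltD; only the acceptor — AltA; both — AltP. Shifts are measured in
  bases; the strand decides which physical intron end is the donor. The
  naming follows the standard convention (AltD = the donor varies); a
  `swap_alt_labels` flag transposes the labels for compatibility with
  tools that use the opposite mapping of the same definition.

A junction that exactly matches an annotated intron is constitutive and
produces no event. Event lengths: IR — intron length; ES — summed skipped
exon length; AltD/AltA — absolute shift at the varying end; AltP — sum of
the absolute shifts at both ends.

Every event is labeled with the genic region of its affected interval
(CDS, 5′UTR, 3′UTR, or a spanning label when the interval crosses a CDS
boundary). UTRs are the exonic sequence outside the CDS bounds of the
retained gene model; genes lacking annotated CDS receive no region label
and are excluded from consequence analysis but kept for event calling.
An interval spanning the whole CDS is labeled 5UTR-CDS (the label
vocabulary has no 5′-to-3′ spanning value; this occurs only for events
larger than the entire coding region, which the simulator never plants).

## Gene models and expression

Where a gene carries several mRNA models, the model with the largest
summed exon length is retained, with ties broken by the
lexicographically smallest model identifier so output is deterministic.
Expression is RPKM on the retained model:
`reads × 10^9 / (exonic_length × total_mapped)`, counting uniquely
aligned primary reads only. No multiread rescue is attempted: the rescue
step of aligner-integrated normalizers depends on alignment internals
that a consumer of SAM files cannot reproduce. A gene is "expressed" when
it has at least one uniquely mapped exonic read.

Trends of AS incidence against genic features (expression, intron/exon
number, mean intron/exon length) are computed by quantile binning
(deciles by default — the bin count is a free choice and is exposed),
taking the per-bin proportion of genes with a qualifying event, and
fitting ordinary least squares of proportion on bin midpoint; the
reported p-value is the two-sided t-test on the slope. A flat response
(zero variance across bins) is reported as slope 0, R² 0, p 1 rather
than an undefined fit.

## Conservation matching

Signatures group events across species: IR by retained intron interval,
ES by skipped exon interval(s), AltD/AltA/AltP by reference intron plus
the observed (shifted) junction coordinates. Matching is exact by
default; a ±k bp tolerance for the shifted splice sites of Alt events
exists (`tolerance`) but defaults to 0, since on a shared reference there
is no alignment jitter to absorb. With a positive tolerance, signatures
are merged by a deterministic greedy pass in coordinate order.

Pairwise sharing between species A and B is reported as
`shared / (|A| + |B| − shared)` — the Jaccard index of the two event
sets, in percent. This union normalization is the only denominator
consistent with the published anchor values it reproduces (see
`sharing_proportion()`), and it extends naturally to triples and the
full species set: shared over the union of the subset's events.

## Coding consequences

Genes qualify for consequence analysis when they carry exactly one event
signature, the event lies in the CDS, and the event does not overlap the
start codon. For a qualifying gene the alternative transcript is rebuilt
in genomic space — IR re-inserts the intron, ES removes the skipped
exons, Alt events replace the reference intron by the observed junction
— and the coding sequence between the annotated start and stop bounds is
extracted and read 5′→3′ (minus-strand genes reverse-complemented).

The consequence rules are purely sequence-based: a **frameshift** is a
length change not divisible by 3; a **PTC** is the first in-frame stop
codon ending strictly before the final position of the alternative CDS
(in the frame-preserving case that final codon *is* the constitutive
stop, so a terminal stop is never premature; in the frameshifted case the
constitutive stop is out of frame and any in-frame stop is premature).
No NMD distance rule is applied by default, because the presence of a
stop — not its degradative fate — is what the outcome tables count. The
classic 50-nt rule is available for exploration
(`call_consequence(..., nmd_distance = 50)` with the last-junction
position returned by `build_alt_cds()`).

Outcome tables report counts and percentages per AS type and
conservation class; percentages are cell over type-by-class total, to two
decimals.

## Statistics

* `g_test()` — likelihood-ratio G = 2 Σ O ln(O/E), zero cells
  contributing nothing, chi-square reference with (r−1)(c−1) df. The
  plain (uncorrected) G is the default because it is the canonical
  definition; the Williams correction
  q = 1 + ((N Σ 1/rᵢ − 1)(N Σ 1/cⱼ − 1)) / (6N·df) is available by flag.
* `wilcoxon_rank_sum()` — two-sided rank-sum with midranks. For
  min(n, m) ≤ 8 the null distribution of the rank sum is enumerated
  exactly over all C(n+m, n) assignments (ties handled naturally since
  the pooled midranks are fixed); larger samples use the normal
  approximation with tie-corrected variance and continuity correction.
  The two regimes agree within 0.02 at the boundary.
* Length summaries print means to two decimals and medians as computed
  (half-integers possible); the per-type Wilcoxon p is NA when either
  class has fewer than two observations.
* No multiple-testing correction is applied to these comparisons.

# The synthetic-data generator

The generator (`simulation_config()`, `simulate_reference()`,
`plant_events()`, `emit_reads()`) emulates the study design it is meant
to exercise: one shared reference annotation, four species' read sets
against it, planted AS events per species with a controlled conservation
design, and known coding outcomes.

**What it generates.** Genes laid out on one contig, alternating strands,
4–8 exons of 80–300 bp, introns of 60–200 bp with GT..AG boundaries on
the coding strand, UTRs of 20–60 bp confined to the terminal exons, CDS
built codon-wise from the 61 sense codons (ATG start, single terminal
stop, no internal in-frame stop). Event types are drawn from an
IR-dominated mixture (IR 68%, AltA 11%, AltP 8%, ES 7%, AltD 6% —
matching the IR-dominated type distributions reported for plant root
transcriptomes), one event per gene, always inside the CDS, and each
signature is assigned to a species subset per the conservation design
(default: 70% private, 15% in two, 8% in three, 7% in all four species —
most events private, a minority deeply conserved, as observed in
congeneric comparisons). Alt-event shifts are 3–18 bp, into the exon
(removing coding bases) or into the intron (adding intronic bases), never
touching the start codon. A configurable fraction of IR events is placed
on frame-preserving (length divisible by 3) introns where the gene offers
one.

Reads are emitted directly as alignments (SAM), not FASTQ, because the
pipeline consumes alignments and read mapping is outside the package's
scope: junction reads with ≥ 10-base overhangs and distinct starts,
intron-tiling reads reaching 0.8 breadth for planted IR (comfortably
above the 0.5 threshold), exonic reads for expression, a handful of
MAPQ-0 decoys so unique and total counts differ, and optional noise
junctions built to fail the support filter. The intended PTC/frameshift
label of every planted event is computed by the generator's *own*
transcript-space reconstruction and `Biostrings::translate()` — a code
path fully disjoint from the consequence caller — so the caller is tested
against labels it did not produce.

**What it does not emulate.** Sequencing errors, quality strings,
expression heterogeneity, repetitive sequence, overlapping genes,
multi-isoform genes, alignment artifacts, and genuine cross-genome
divergence (all species' reads are perfect matches to the one reference).
Passing the recovery tests therefore demonstrates that the pipeline's
logic is exact on clean evidence — coordinates, thresholds, signatures
and translations are right — not that the filters' false-positive /
false-negative trade-offs are well tuned for noisy real libraries.

# Numerical and design choices

* Coordinates are GFF3-native (1-based, inclusive) in every public
  structure; half-open arithmetic is internal only.
* The minimum reference gap treated as a junction is 20 bp (configurable)
  — shorter gaps are deletion-like; the simulator's smallest intron (25
  bp observed junction after shifts) stays above it.
* Reference-intron assignment for Alt events maximizes reciprocal
  overlap; with introns ≥ 60 bp and shifts ≤ 18 bp the true intron always
  wins by a wide margin.
* Problem sizes in tests and the acceptance script (40–520 genes,
  500–2,000 statistical replicates) were chosen so every check is
  discriminating — e.g. the type-I band 0.05 ± 0.02 is ±4 Monte-Carlo
  standard errors at 2,000 replicates — while the whole suite stays
  comfortably in interactive time.
* Degenerate inputs are contracts, not crashes: empty junction tables
  flow through to empty event sets; single-exon genes have no introns;
  all-one-bin trend requests and empty Wilcoxon samples are errors.

# Known limitations

* Multi-mapped reads are handled by the primary-alignment convention;
  aligner-specific "best hit" selection cannot be reproduced from SAM.
* Isoform ratios (PSI) are out of scope — events are presence/absence.
* Protein-domain consequences (gain/loss/modification) would require an
  external profile database; the consequence table is the adapter point.
* The per-species alignment identity cutoffs used upstream of this
  package (92–96% depending on species divergence) apply at alignment
  time and cannot be enforced on consumed SAM files; they are documented
  here for provenance.
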