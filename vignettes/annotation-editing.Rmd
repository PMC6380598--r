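---
title: "Curation semantics: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation semantics: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annoforge)
```

`annoforge` is a headless genome-annotation editing engine: it implements
the computations behind interactive gene-model curation — evidence
promotion with automatic ORF calculation, splice-aware boundary editing,
reading-frame isoform grouping, alteration projection, and a revertible,
attributed edit history — as a plain R library with a command-line
wrapper. This vignette records the models it implements, the parameters
that matter, and the design decisions taken where more than one reasonable
semantics existed.

## The data model

A project holds reference **regions** (uppercase A/C/G/T/N strings),
editable **genes** containing **transcripts** containing exon intervals and
an optional genomic CDS span, read-only **evidence** features, a list of
**sequence alterations**, users with roles, an organism configuration, and
a per-gene edit history. All internal coordinates are 0-based half-open;
the 1-based inclusive conventions of GFF3, GenBank and VCF are converted
exactly once, at the format boundary. This eliminates off-by-one ambiguity
from all interval arithmetic; BED, which is natively 0-based half-open,
passes through untranslated.

Two normalization rules keep downstream logic deterministic: lowercase
residues (soft-masking) are uppercased on load with a notice, since case
information is not modelled; and strandless evidence defaults to the
forward strand with a warning, because ORF and splice computations are
meaningless without a strand. Codons containing `N` translate to `X` and
never match start or stop codons.

## Longest-ORF calculation

When evidence is promoted, the transcript's CDS is the longest open
reading frame of its spliced sequence. Precisely: over all pairs (start
codon position *s*, first in-frame stop end *e*) in the three frames of
the transcript's own strand, the pair maximizing *e − s* wins, ties
breaking to the smallest *s* (the 5'-most start, the usual longest-ORF
convention). Only the transcript's strand is scanned — three frames, not
six — because the editing workflow fixes strand before the ORF is
computed. Start and stop codons come from the configured NCBI translation
table (`organism_config(translation_table =)`); alternative initiation
codons in the table are honored rather than hard-coding ATG.

Open-ended reading frames — a start codon with no downstream in-frame
stop — are accepted when they are *longer* than the best complete ORF, and
flagged `partial` with the CDS running to the transcript end. Assembly
fragments commonly truncate genes, so rejecting such transcripts silently
would lose real biology; the flag is carried into GFF3 as a reserved
attribute. The minimum accepted complete ORF is two codons (start +
stop): no length threshold is imposed, nothing is rejected silently. A
spliced sequence with no start codon at all leaves the transcript CDS-less
and flagged `needs_review`.

`longest_orf()` is tested against an independent brute-force enumerator
(every offset scanned for a start, codons walked to the first stop) on
randomized sequences; the fixture generator uses the same kind of naive
enumerator — not the production path — to compute planted truths.

## Splice sites, snapping and flags

Donor and acceptor sites are exact dinucleotides (default GT / AG,
configurable per organism); no strength scoring is attempted. An intron's
first two and last two bases, read in transcript orientation
(reverse-strand introns on the reverse complement), are compared against
the configured sets; each non-conforming intron yields one warning naming
the observed dinucleotides and the failing side(s). Introns shorter than
four bases are degenerate and flagged on both sides.

Boundary snapping moves an exon edge to the nearest junction in the
requested direction: a 3' exon edge so that the following intron *begins*
with a donor, a 5' exon edge so that the preceding intron *ends* with an
acceptor. The search window spans from inside the exon to the neighboring
exon, capped at 10 kb in either direction — no window is inherent to the
operation, and the cap merely prevents pathological scans on gene-desert
scaffolds. The current boundary itself is excluded, so snapping from a
junction finds the *next* one. If no junction exists in the window the
edit is rejected and the project is unchanged.

## ORF recomputation and translation pins

The ORF is recomputed automatically after every structural edit (drag,
snap, merge, split, flip, projection) *unless* the curator has pinned a
translation boundary. A pin fixes the first (start) or last (end) CDS
base at a genomic position: with the start pinned the CDS runs to the
first in-frame stop (partial if none); with the end pinned the 5'-most
in-frame start codon with a clean frame is chosen. Pins encode deliberate
curator intent, so they survive edits that keep the pinned base inside an
exon; otherwise they are dropped with a notice and automatic recomputation
resumes. Strand flips always drop pins — a frame anchored on one strand
is meaningless on the other.

## Isoform grouping

Under the default `cds_overlap_in_frame` strategy, a transcript joins an
existing gene iff, on the same region and strand, some genomic base is
covered by the CDS of both the transcript and a member transcript *at the
same codon phase*, where the phase of a base is its spliced-CDS offset
modulo 3, accumulated 5'→3'. This makes "same reading frame" precise and
per-base testable, and the witnesses (position, phase pairs) are returned
with every membership decision. The alternative `exon_overlap` strategy
accepts any exonic base overlap on the same strand. When several genes
qualify they are merged — the survivor keeps the lexicographically
smallest id and the union of curation metadata — rather than erroring,
which loses nothing and keeps grouping a partition. Grouping is invariant
under the order transcripts are created, which the tests verify by
permuting promotion order. Transcripts without a CDS never join by CDS
overlap and therefore seed their own gene under the default strategy.

## Sequence alterations and projection

Substitutions, insertions and deletions are stored in *pure* form
(insertions have no reference bases, deletions no alternate bases); VCF
anchor bases are stripped on import by removing the common prefix and then
the common suffix of each REF/ALT pair and adjusting the position.
Assembly corrections and natural variants run through identical machinery
and differ only in a category flag, so corrections can later be committed
to the reference without redesign. Alterations are applied to a read-only
view; the reference project is immutable.

Application builds a piecewise-monotone **coordinate map**: maximal
segments of surviving reference positions with a constant offset, plus the
deleted intervals. Overlapping alterations are rejected, not composed —
no composition semantics would be universally right, and rejection is
explicit. Projection maps each exon boundary through the map; a boundary
landing in a deleted span snaps inward toward the exon body (preserving
the maximal surviving exon sequence), a fully deleted exon is dropped, and
a transcript losing all exons is reported as lost. The ORF is then
recomputed on the altered spliced sequence, and the effect report states
whether and how far the CDS start/end moved (oriented deltas, positive =
downstream, measured against the mapped original boundary) and whether the
protein changed. A deletion spanning the start codon thus shows the
canonical "start relocated downstream" behavior. Whether an interactive
curator would re-derive the transcription or the translation start in that
situation is genuinely ambiguous; this engine recomputes the translation
(ORF) and reports both boundary deltas, leaving the interpretation to the
reader of the report.

## History

History granularity is the top-level feature (the gene): each gene carries
a linear record list — version, username, ISO-8601 UTC timestamp,
operation, parameters, and a **full snapshot** of the gene after the edit —
plus a cursor marking the live version; a project-level log indexes all
records for global search. Full snapshots rather than deltas trade memory
for unconditional revert correctness at desk scale, and a replay oracle in
the test suite (re-running operations 1..cursor from the initial state)
keeps the snapshots honest.

Undo/redo move the cursor; an ordinary edit made while the cursor is
behind the newest version discards the forward records first (standard
truncation). `revert` is different: it is itself an edit — the restored
snapshot is appended as a *new* attributed record — and it never truncates,
so every version a revert record references stays replayable. A finite
`undo_depth` prunes the oldest records (storage, not merely traversal),
preserving version numbers; pruned versions cannot be reverted to. When a
merge absorbs a gene, the absorbed gene's history ends with a terminal
`merged_into` record and the survivor's history continues, so no record is
ever lost. An in-process listener hook delivers every committed record
synchronously to registered callbacks, standing in for network push in a
headless setting.

Timestamps default to the wall clock (`timestamp_mode: "real"`). Because
a CLI session is defined to be reproducible from (input files, edit
script, config), the config may instead select `"logical"` timestamps,
derived deterministically from the edit counter — with that setting,
replaying a session yields byte-identical GFF3/GenBank exports, which the
tests assert. Attribution (who/what/order) is identical in both modes.

## Formats

Readers lean on the standard stack — Biostrings for FASTA, rtracklayer for
GFF3 and BED, vcfR for VCF; writers (GFF3, GenBank flatfile, JSON snippet,
BED12 and VCF in the fixture generator) are implemented here so output is
deterministic: fixed attribute ordering, sorted features, 60-column FASTA
and stable JSON key order, making byte-level golden tests possible. Each
export declares a dialect marker. Curation provenance travels in reserved
GFF3 attributes (`owner`, `date_creation`, `date_last_modified`, `status`,
`partial`) — a compatible invention, as no attribute vocabulary is
standardized for these. CDS phase is honored on read and recomputed on
write. GTF/GVF import and BAM/BigWig evidence are declared unsupported
with explicit errors: they are format plumbing without new semantics, and
GFF3 + BED cover the editing workflow. The fixture VCF carries each
record's category in a `CATEGORY` INFO tag, which `read_vcf_alterations`
honors under `category = "auto"`.

## The synthetic-genome generator

`generate_genome()` emulates the structural skeleton of a curated locus:
genes whose spliced transcript is exactly one clean ORF (ATG … stop, no
internal in-frame stop), GT..AG introns except a configurable
non-canonical fraction (planted as GC donors), intergenic spacing of at
least twice the maximum intron length so planted genes can never satisfy
the membership overlap by accident, evidence that mirrors the exon
structure, and variants with analytically derived effects. Defaults:
2 regions, 10 genes, 2–4 exons of 60–150 bp, introns of 40–80 bp, half the
genes on the reverse strand, evidence split into overlapping halves for
~30% of eligible genes, and two substitutions, insertions and deletions —
sizes chosen as a realistic desk-scale curation scenario that keeps every
test fast. Output is a pure function of the spec (the generator saves and
restores the caller's RNG state), and the JSON manifest records every
planted truth.

Two deliberate subtleties: a mis-placed exon boundary is planted only in
genes whose evidence is *not* split (a shifted boundary in one half would
be erased by the merge union), only at canonical junctions, and only after
verifying no decoy donor occurs between the shifted and true positions, so
the snap target is unambiguous. And the first planted deletion removes a
start codon, chosen so the edited transcript still contains a viable
downstream ORF — the fixture for the "start relocated downstream" behavior
class. Variant truths (expected protein, moved flags, expected spliced
CDS offsets) are computed by direct string surgery plus the naive ORF
enumerator, never by the projection machinery under test; effect deltas
are compared in spliced coordinates, which is what the planted truth pins
down exactly.

What the generator does **not** emulate: realistic base composition, GC
content, repeat structure, UTRs (planted transcripts are exactly their
CDS), overlapping or nested genes, alternative isoforms beyond the planted
split-evidence pairs, and sequencing error. Passing the end-to-end tests
therefore demonstrates structural correctness of the editing calculus on
clean inputs, not robustness to messy real annotations.

## Numerical and degenerate-input choices

* Exons separated by a gap of zero bases after an edit are coalesced
  (zero-length introns are not representable in GFF3).
* A boundary edit that would invert an exon or cross a neighbor is
  rejected atomically; every operation either commits fully (with exactly
  one history record per affected gene) or leaves the project untouched.
* Merging a transcript with a copy of itself is idempotent on the exon
  set; merge followed by split at the seam restores non-overlapping
  originals.
* `validate_project()` never throws; it returns one named report per
  violated invariant.
* Problem sizes in the test suite (1000 random mRNAs of 30–3000 bp for the
  ORF oracle, 500 random pairs/alteration sets, 200 random edit scripts of
  up to 20 operations, 100 round-trip projects, one 20-gene end-to-end
  genome) were chosen to exercise each property across its branch
  structure while keeping the default test run fast.

## Known limitations

* Undoing below a gene's first recorded version (e.g. un-promoting) is not
  possible; creation is the floor of the history.
* A gene absorbed by a merge is not resurrected by undoing the survivor;
  its terminal record preserves the state but re-attachment is manual.
* Per-base membership witnesses are exact but quadratic in CDS length in
  the worst case — appropriate at curation scale, not for genome-wide
  sweeps.
* Effect reports classify structural change only; sequence-ontology
  consequence terms (missense, frameshift, …) are out of scope.
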