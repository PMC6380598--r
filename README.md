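# annoforge

A headless, scriptable genome-annotation curation engine for R.

Manual curation of gene models — promoting aligned or predicted evidence
into editable annotations, fixing exon boundaries against splice signals,
grouping isoforms by reading frame, annotating sequence alterations, and
keeping an attributed, revertible record of every change — is usually bound
to an interactive browser. `annoforge` implements the same curation
semantics as a library plus a command-line tool, so whole curation sessions
can be scripted, replayed and tested, with standard formats (FASTA, GFF3,
BED, VCF, GenBank, JSON) at every boundary.

## What it computes

* **Evidence promotion with automatic ORF calculation.** A promoted
  evidence feature becomes a "protein coding transcript" whose CDS is the
  longest open reading frame of its spliced sequence: over all (start
  codon, first in-frame stop) pairs in the three frames of the transcript's
  own strand, the pair maximizing the nucleotide span wins, ties breaking
  5'-most. Open-ended reading frames (no in-frame stop, common on
  assembly fragments) are accepted and flagged `partial`. Start/stop sets
  come from any NCBI translation table.
* **Splice-aware structural editing.** Exon boundaries can be set
  explicitly or snapped to the nearest configured donor/acceptor
  dinucleotide (default GT/AG) upstream or downstream; transcripts can be
  merged (exon-interval union), split, or strand-flipped, with the ORF
  recomputed after every structural change unless a curator has pinned a
  translation boundary. Introns whose boundary dinucleotides fall outside
  the configured sets are flagged as non-canonical splice sites.
* **Reading-frame isoform grouping.** A transcript joins an existing gene
  iff some genomic base is covered by the CDS of both transcripts *at the
  same codon phase* (`cds_overlap_in_frame`; an `exon_overlap` strategy is
  also available). Grouping is a partition and is invariant under the
  order in which transcripts are created.
* **Sequence alterations and feature projection.** Substitutions,
  insertions and deletions — curated either as assembly-error corrections
  or as natural variants — are applied to a read-only view through a
  piecewise-monotone coordinate map; every transcript is re-projected and
  an effect report compares exon coordinates, CDS boundaries and the
  translated protein before vs after (e.g. a deletion spanning a start
  codon relocates the CDS start downstream).
* **Attributed, revertible history.** Every edit records who, when, what,
  and a full state snapshot per gene; undo/redo walk the version cursor,
  `revert` restores any retained version as a new attributed edit, and a
  configurable undo depth prunes storage. Replaying the recorded
  operations reproduces every snapshot bit-for-bit.
* **Synthetic genomes with planted truth.** A deterministic generator
  plants genes with known ORFs, canonical or deliberately non-canonical
  introns, split/misplaced evidence and variants with analytically known
  effects, plus a JSON manifest of every truth — the oracle for the
  end-to-end tests. No external data is ever needed.

## Worked example

```r
library(annoforge)

# a 6-gene synthetic genome with a planted-truth manifest
fx <- generate_genome(fixture_spec(seed = 11, n_genes = 6))
project <- new_project(fx$regions, organism_config(timestamp_mode = "logical"))
project$evidence <- fx$evidence

# promote every evidence feature: exons copied, longest ORF computed,
# gene membership assigned, one history record written
for (ev in names(project$evidence)) {
  project <- promote_evidence(project, ev, "admin")
}
project
#> <annotation_project> 2 region(s), 6 gene(s), 7 evidence, 0 alteration(s)

t <- project$genes[[1]]$transcripts[[1]]
t$cds                       # genomic CDS span, 0-based half-open
#> [1] 178 423
translate_cds(get_spliced_sequence(project$regions[[t$seq_id]], t))
#> [1] "MLVTGDCPHINIPTRSNRTVIKVNSVLTSPSDFIPTLYLWKIIGT..."  # 97 residues

list_history(project, project$last_edit$gene_id)
#>   version username            timestamp        operation is_current
#> 1       1    admin 2000-01-01T00:00:07Z promote_evidence       TRUE
```

The same session from the shell (`inst/cli/annoforge` is a thin wrapper
over `annoforge_cli()`):

```sh
annoforge fixture       --out fx --seed 11 --genes 6
annoforge init          --fasta fx/genome.fa --config config.yaml --out proj
annoforge load-evidence --project proj --bed fx/evidence.bed --track rnaseq
annoforge load-variants --project proj --vcf fx/variants.vcf --category auto
annoforge apply         --project proj --script edits.jsonl --user alice
annoforge export        --project proj --format gff3 --out curated.gff3
```

where `edits.jsonl` holds one JSON command per line, e.g.
`{"op":"promote","evidence":"tmrna_001_ev"}` or
`{"op":"snap_exon_boundary","transcript":"transcript_00001","exon_index":1,"edge":"three_prime","direction":"downstream"}`.
Exit codes: 0 success, 1 usage, 2 validation, 3 permission, 4 format.

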