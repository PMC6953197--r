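# BACends

Restriction-site split-read profiling of BAC-end junction libraries.

## The problem

Sequencing the insert ends of a large-insert (BAC) clone library ties
clones to reference coordinates — the raw material for physical maps,
scaffolding and assembly QC — but Sanger-sequencing every clone end is slow
and expensive. A cheaper route: digest pooled clone DNA completely with a
6-cutter whose recognition site is absent from the cloning vector,
self-ligate the fragments, and shotgun-sequence the ligation junctions with
short reads. Sticky-end self-ligation restores the full recognition site,
so a read spanning a junction is easy to find: it carries the enzyme motif
with genomic flanks on both sides.

Two junction geometries arise from each clone (insert length ~90 kb):

* **clone-end (BAC_END) junctions** — the vector plus the two terminal
  insert pieces circularize; the two flanks map in the *same* orientation,
  separated by an internal gap of roughly the insert size minus two
  restriction-fragment lengths (concentrating at 60–100 kb for a 90 kb
  library and ~4–6 kb fragments);
* **internal-fragment (INSERTION) junctions** — each internal restriction
  fragment self-circularizes; the flanks map in *inverted* order, one
  fragment length (mostly 1–20 kb) apart.

Classifying each site-carrying read by its flank pair — same chromosome
(subtyped by orientation as above), different chromosome / one end only, or
unmapped — and binning the internal gaps yields the library-quality tables
and per-chromosome anchor maps this package produces. A flank pair is
counted *unique* when both flanks map with MAPQ ≥ 30 and no secondary
alignment; same-chromosome gaps are searched in a 1–150 kb window.

For a read with flank inner coordinates `gL` and `gR` (the motif-adjacent
edges of the two alignments, motif bases belonging to neither flank), on
the `+` strand:

    gR − gL ≥ 0  →  BAC_END,   gap = gR − gL
    gR − gL < 0  →  INSERTION, gap = gL − gR

mirrored on `−`. The package also ships a ground-truthed library simulator
(random genome → clones → in-silico digestion → autoligation junctions →
150 bp junction reads with optional substitution errors, chimeras and
background), a toy exact-match aligner so the whole pipeline runs with no
external tools, in-silico digestion profiling for enzyme selection, an
interlength categorizer for long (Sanger-style) clone-end sequences, and a
variant-zygosity summariser.

## Worked example

```r
library(BACends)
enz <- enzyme("ClaI")
enz
#> RestrictionEnzyme ClaI : AT^CGAT (palindromic)

genome <- simulateGenome(nChrom = 2, lengths = 1e6, gc = 0.5, seed = 7)
vec    <- simulateVector(enz, seed = 8)
clones <- simulateClones(genome, nClones = 500, seed = 9)   # ~90 kb inserts
built  <- buildJunctionFragments(clones, genome, enz, vec)
sim    <- simulateReads(built$junctions, genome, enz, seed = 10)

scr <- screenReads(sim$reads, enz)           # select + split site reads
scr
#> ScreenResult: 11314 reads; 11314 carried a site; 8574 split reads emitted
#>   (no site: 0 | flank too short: 2740 | skipped: 0 )

al    <- alignFlanksToy(splitReads(scr), genome)
calls <- classifyJunctions(al)
calls
#> JunctionCallSet: 8574 reads
#> category
#> MATCH_SAME_CHR
#>           8574
#>            uniqueness
#> subtype     UNIQUE
#>   BAC_END      374
#>   INSERTION   8200

h <- binGapHistogram(calls)
h[6:10, c("label", "bacend_unique", "insertion_unique")]
#>     label bacend_unique insertion_unique
#> 6   50-60             3                0
#> 7   60-70            20                0
#> 8   70-80           105                0
#> 9   80-90           198                0
#> 10 90-100            48                0
gapWindowFraction(h$bacend_unique)$pct    # share of 60-100 kb gaps
#> [1] 99.2

ev <- evaluateAgainstTruth(calls, sim$truth)
ev$subtype_accuracy                        # error-free reads: perfect
#> [1] 1
max(abs(ev$gap_errors$error))
#> [1] 0
```

Every read was screened in (each spans a junction by construction; the
2740 rejects had a flank of 18 bp or less), all flank pairs landed on one
chromosome, and with no sequencing errors every junction subtype and every
gap is recovered exactly. The clone-end gaps peak in the 80–90 kb bin —
the 90 kb insert minus two ~4 kb terminal restriction fragments — while
internal-fragment gaps (1–20 kb, not shown) sit below the displayed rows.
`runEndToEnd(runConfig(simulate = TRUE, seed = 7), "outdir")` runs the same
pipeline end to end and writes TSV/BED/JSON reports plus a stage log.

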