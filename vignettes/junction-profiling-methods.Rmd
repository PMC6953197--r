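---
title: "Methods: junction-library profiling of BAC-end clones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction-library profiling of BAC-end clones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the model it implements, the
parameters that matter, the numerical conventions, and what the tests do
and do not demonstrate.

## The library model

A BAC library pools clones carrying large genomic inserts (mean ~90 kb
here) in a vector chosen so that the profiling enzyme — a palindromic
6-cutter such as ClaI (AT^CGAT) or MluI (A^CGCGT) — has no recognition
site in the vector backbone. Complete digestion of a clone therefore cuts
only at the sites lying fully inside the insert, at positions
$c_1 < \dots < c_k$ (a cut coordinate is the count of bases preceding the
cut: site start + cut offset). Self-ligation of the digest produces:

* one **clone-end junction** per cut clone, from the vector-containing
  fragment (right terminal piece + vector + left terminal piece): the
  sequence approaching $c_1$ is joined to the sequence leaving $c_k$. Its
  cut-to-cut gap $c_k - c_1$ equals the insert length minus the two
  terminal fragment lengths, and can never exceed the insert length;
* $k - 1$ **internal-fragment junctions**, one per fragment
  $[c_i, c_{i+1})$, whose self-circularization joins the fragment's right
  end back to its left end — so the two flanks appear in *inverted* order
  on the reference, one fragment length apart.

Compatible sticky ends re-create the full recognition motif across every
junction. A 150 bp read spanning a junction thus carries the motif with
genomic flanks on both sides; the flanks map to distant reference
positions whose distance (the *internal gap*) estimates the insert size
(clone-end) or the fragment length (internal), and whose relative
orientation distinguishes the two.

Reads are classified by their flank pair: both flanks on one chromosome
(`MATCH_SAME_CHR`, subtyped `BAC_END` / `INSERTION` by the orientation
rule, or `DISCORDANT_STRAND` when the strands disagree), different
chromosomes or only one flank placed (`MATCH_DIFF_CHR`), or neither
(`NO_MATCH`). These three categories partition every read.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `minFlank` | 19 | bp | a flank must exceed 18 bp on each side of the motif to be alignable; both flanks must pass |
| `mapqMin` | 30 | MAPQ | flank pairs with both MAPQ ≥ 30 and no secondary alignment count as uniquely placed |
| `gapMin`, `gapMax` | 1000, 150000 | bp | the gapped-alignment search window; gaps outside keep their category but are excluded from gap reports |
| `binWidth` | 10000 | bp | reporting histogram resolution |
| anchor gap window | [60000, 100000) | bp | clone-end gaps consistent with a ~90 kb insert; these calls become physical-map anchors |
| `adjacency` | 100000 | bp | an anchor with a neighbour closer than this is "dense" (usable for scaffold joining) |
| `insertMean`, `insertSd` | 90000, 5000 | bp | the library's insert distribution (truncated normal, [20, 150] kb) |
| `readLength` | 150 | bp | short-read junction sequencing |

## Coordinate and numerical conventions

* Sequence intervals are 1-based closed throughout (`IRanges`, `substr`),
  the native R/Bioconductor convention. Junction and cut coordinates are
  kept as 0-based offsets (bases before the junction point), which makes
  interval arithmetic exact: two abutting flank alignments give gap 0, a
  degenerate `BAC_END`. BED output converts to 0-based half-open at the
  boundary.
* The inner coordinate of a flank is its motif-adjacent edge: the left
  flank's end on `+` (start on `-`), the right flank's start on `+` (end
  on `-`). With inner coordinates $g_L, g_R$, on `+`: $g_R \ge g_L$ is
  `BAC_END` with gap $g_R - g_L$, otherwise `INSERTION` with gap
  $g_L - g_R$; mirrored on `-`. The rule is symmetric under
  reverse-complementing the read (property-tested).
* **The restored site's 6 bp belong to neither flank.** The measured
  flank-to-flank gap therefore exceeds the cut-to-cut gap by the motif
  length for clone-end junctions and falls short of the fragment length by
  the motif length for internal junctions. The simulator records both
  (`expected_gap` cut-to-cut, `expected_inner_gap` flank-to-flank);
  `evaluateAgainstTruth()` compares measured gaps against
  `expected_inner_gap`, which is exactly zero-error on error-free reads.
  Users preferring cut-to-cut distances can add the motif length
  themselves; at 10 kb bin resolution the 6 bp are invisible.
* Gap histogram bins are lower-inclusive: [1, 10), [10, 20), ...,
  [140, 150] kb, the last bin closing the window. The first bin is 9 kb
  wide because the window starts at 1 kb. This binning reproduces the
  published worked-example shares (22.81% / 24.55% of unique clone-end
  gaps at 60–100 kb; 89.50% of internal gaps at 1–20 kb) exactly, which
  is how the edge convention was validated.
* Percentages are rounded half-up (`roundHalfUp`), not half-to-even,
  because that is how the reference tables print; all printed percentages
  recompute to the digit.
* Sites containing `N` are never called (conservative digestion); IUPAC
  codes in a motif are expanded, but ambiguity letters in the subject
  never match. Overlapping motif matches are all reported and all cut.
* Ties and degenerate cases: multi-site reads take the site maximising the
  *smaller* flank (ties: leftmost) — the choice that maximises the weaker
  anchor; a cut at a sequence boundary produces no empty fragment; a
  sequence without sites is its own single fragment; an empty category
  total reports 0% with a degeneracy flag rather than NaN.

## Open design choices, and how they were settled

* **Deduplication keys.** Read-level duplicates are removed by exact read
  sequence (first kept, order preserved, idempotent); an optional
  canonical mode also collapses a read with its reverse complement.
  Position-level duplicates — junction molecules sequenced at different
  offsets — are removed by the full anchor key (category, subtype, both
  chromosomes, inner coordinates, strands). Sequence dedup runs after
  screening and before alignment.
* **Uniqueness of one-end-mapped reads.** Only same-chromosome two-flank
  pairs can be `UNIQUE`; one-end and cross-chromosome calls with a
  sub-threshold flank are tallied `MULTI`. The multi-mapped columns of the
  gap reports count only two-flank same-chromosome non-unique pairs.
* **Anchor position** for adjacency and density is the midpoint of the two
  inner coordinates; "distance between adjacent anchors" is not otherwise
  pinned down, and the midpoint is insensitive to which flank is longer.
  An anchor is dense if *either* neighbour (previous or next on its
  chromosome) is closer than the threshold; a chromosome's single anchor
  is sparse.
* **Same-chromosome opposite-strand pairs** get their own subtype
  (`DISCORDANT_STRAND`) and no gap: they fit neither junction geometry
  but are worth reporting rather than silently dropping.
* **Long-read (Sanger-style) clone ends** use the published irregular bin
  scheme (<1, 1–10, 30–40, ..., 140–150, >150 kb) verbatim, with a
  10–30 kb catch-all bin added so every interlength has a home; a side
  matches when its alignment exceeds 300 bp on a >1000 bp input (strict
  mode: coverage > 0.8 instead).
* **Zygosity** is defined read-level (one observed base type = homozygous,
  two or more = heterozygous). The VCF mode — heterozygous iff the
  genotype carries two distinct alleles — is a documented approximation
  for data where per-site base-type sets are unavailable.

## The simulator: what it emulates, and what it does not

`simulateGenome` draws i.i.d. bases at a stated GC fraction; at GC 0.5 a
6-mer site occurs at rate $4^{-6}$ per offset, giving ~4 kb mean fragments
— the regime where a 90 kb insert carries ~20 internal sites, so clone-end
gaps concentrate at insert − 2 × fragment ≈ 70–90 kb and internal gaps at
1–20 kb, the qualitative structure of the reference tables. Clones are
placed uniformly (chromosome by length); junction reads span their
junction with the restored motif at a uniform admissible offset, half
reverse-complemented; substitution errors are i.i.d. per base. Optional
negative controls: inter-molecule chimeras (cross-locus right side, true
category `MATCH_DIFF_CHR`) and background genomic reads.

Deliberately not modeled: quality scores, indels, GC/coverage bias,
partial digestion, star activity, methylation, blunt ligation, the pooling
and plate structure of a real library, and reads wrapping small circles
more than once (junctions whose fragments cannot host a full-length read
are skipped). Real genomes are also not i.i.d.: repeats create multi-mapped
flanks at far higher rates than a random sequence, and restriction sites
cluster. Passing the simulation oracle therefore demonstrates the
*bookkeeping* — screening, splitting, pairing, orientation, gap
arithmetic, deduplication, conservation — not performance on repetitive
real data, where uniqueness filtering does the heavy lifting and is
exercised here only through planted-duplication fixtures.

The toy aligner is exact-match only (constant-width seed dictionary over
both strands plus full-flank verification — equivalent to exhaustive
substring search), reporting MAPQ 60 for single-hit flanks and MAPQ 0 with
a secondary flag for multi-hit flanks. It exists so the pipeline is
testable without external tools; real data should be aligned externally
and loaded as SAM (`readFlankSam`, `<read_id>|L` / `|R` naming).

## Problem sizes and determinism

The validation suite simulates 2 × 1 Mb genomes with 500 clones (three
seeds) for the end-to-end oracle and distribution-recovery checks, 1 Mb
genomes for closed-form site-count checks, and 1000 random sequences for
digestion-tiling properties; smaller fixtures cover unit behaviour. These
sizes keep the whole suite in the order of a minute while leaving every
statistical check at least 4 standard deviations of headroom. All
randomness flows through explicit seeds; identical seeds give
byte-identical FASTQ, truth tables and reports.

## Known limitations

* Insert-size inference is only as good as the reference: an anchor gap
  over the insert length flags either a structural difference between the
  sequenced genotype and the reference or a reference mis-join, and the
  package cannot tell these apart.
* The read-level screen keeps one site per read (the best-flanked one);
  reads carrying two junctions (small-circle wrap-around) are not
  resolved.
* MAPQ semantics differ between aligners; the uniqueness rule assumes a
  Bowtie2-like scale where ≥ 30 means effectively unique.
* The positional dedup key is strand-sensitive: the same junction molecule
  sequenced in the two opposite orientations yields mirrored keys and is
  counted as two unique anchors, so strand-balanced libraries can report
  up to twice the molecular junction count. A strand-agnostic canonical
  key would halve this but lose the orientation record.
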