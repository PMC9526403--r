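---
title: "Methods: mitogenome characterization and polycistronic transcript inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitogenome characterization and polycistronic transcript inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocistron)
```

## The problem and the model

Fungal mitogenomes of the *Beauveria* type are single circular molecules of
roughly 27–36 kb carrying a fixed complement — 25 tRNAs, 15 protein-coding
genes (one of which, rps3, is an ORF nested inside the conserved intron of
the large rRNA gene rnl), two rRNAs — all on one strand, with a single
non-coding control region. Transcription is polycistronic; maturation
involves polyadenylation, group I intron splicing, and cleavage that
excises the tRNAs punctuating the precursor. Short-read RNA-seq evidence
reaches us as de novo assembled contigs aligned to the genome, each with a
coordinate interval and a gene-content label, plus individual reads whose
split alignments betray splicing, precursor (intron-containing) molecules,
and wrap-around artefacts of circular or permuted transcripts.

This package models that situation directly. The central object is the
**junction evidence graph**: every circularly adjacent gene pair is a
junction, each junction is assigned one evidence status, and polycistronic
units are the maximal runs of genes joined by non-`unsupported` junctions.
The status rules and their precedence are given in the README; the
rationale for the two non-obvious ones is:

* **`trna_bridge` uses evidence reach, not the genomic gene gap.** A
  cleaved punctuation tRNA leaves no reads, so the contigs on either side
  stop at (or near) its span. The informative quantity is the number of
  *unannotated* bases between the nearest evidence on the covered side and
  the uncovered tRNA's span; when that residue is within δ the tRNA itself
  explains the hole and the junction is bridged. This reproduces the
  canonical cases — a contig ending one base before a tRNA whose span
  exactly fills the gap to the next contig, a contig halting 26 bp short
  of an uncovered tRNA, and two consecutive dropped tRNAs separated by a
  2–3 bp gap — none of which are expressible with a pure gene-gap rule
  (the gene-gap formulation fails whenever the flanking contig extends
  past its last gene into the intergenic region).
* **The control region never carries a punctuation or small-gap bridge.**
  The control region is where transcription initiation is expected, so the
  junction through it must be merged only by evidence that literally spans
  it (a contig chain or an external validation). Without this rule a short
  control region could be "bridged" and the method could never conclude
  anything but one circular unit.

Units always partition the genes, and upgrading any junction from
`unsupported` can only reduce the unit count (monotonicity); both facts
are enforced by property tests against an independent connected-components
oracle (igraph) on random instances of up to 64 genes.

## Tunable parameters

| parameter | default | unit | role and rationale |
|---|---|---|---|
| `delta` | 60 | bp | largest bridged unannotated gap. The largest distance bridged in practice between fragmented contigs of one transcript is ~53 bp; 60 leaves headroom while staying far below real intercistronic breaks (hundreds of bp). |
| `epsilon` | 2 | bp | coverage slack: a gene counts as covered only when evidence overlaps it by more than ε. Printed contig tables carry ±1 bp boundary ambiguity (a contig may begin on the final base of the preceding tRNA); ε = 2 absorbs this, and the same slack gates the gene-content consistency check. |
| `tol` (`classify_read`) | 3 | bp | splice-junction concordance tolerance, matching short-read aligner jitter at exon edges. |
| `min_arm` | 20 | bases | minimum arm for a wrap-around call; avoids calling 1–2 bp spurious splits. |
| `min_tail` | 6 | bases | minimum polyA soft-clip run, with at most one non-A and an untemplated-run check against the genome. |
| `min_aa` | 50 | codons | intron ORF scan threshold; homing endonuclease ORFs (LAGLIDADG, GIY-YIG) are hundreds of codons, rps3 is ~400. |
| `tol` (`intron_presence_matrix`) | 10 | bp | exon-space tolerance for calling intron insertion sites homologous across strains. |
| `trna_dropout` | 0.5 | prob. | probability a cleaved punctuation tRNA leaves no evidence. |
| `at_target` | 73 | % | genome AT content of the generator; fungal mitogenomes of this type sit near 72.5–73. |
| `trna_length` | 71 | bp | tRNA span; matches the one printed tRNA coordinate anchor. |
| `control_length` | 300 | bp | control region length (unconstrained by data; configurable). |

All thresholds are exposed as function arguments; none is read from global
state.

## The synthetic generator

`make_genome()` lays the canonical 41-gene order on a circle: 2–3 bp gaps
inside tRNA clusters, 20–45 bp at tRNA/mRNA boundaries, 60–150 bp between
protein-coding or rRNA genes, 200–400 bp at forced unit breaks, and the
two canonical 1 bp overlaps (nad2/nad3, nad4L/nad5). Introns are planted
per a per-gene plan (default: the intron-richest profile, eight introns)
with canonical boundaries — the upstream exon base is forced to T and the
intron to GT..AG. For protein-coding hosts, insertion points are codon
boundaries, so the forced T lands on a codon third position and can never
create an in-frame stop; coding exons are random non-stop codons between
ATG and a stop. The last rnl intron carries a planted ~400-codon ORF 300 bp
inside each boundary, mirroring the nested rps3. The non-coding background
is calibrated in a second pass so whole-genome AT lands on the target
despite the codon constraints.

`simulate_processing()` emits, per planted unit: the primary transcript
(extended into the flanking gaps by at most half the gap, so neighbouring
units never overlap — the extension into the control region is what the
TSS inference later measures); a polyadenylated **pre-mRNA still carrying
its introns** when `polyA_before_splicing = TRUE`, and never otherwise;
the spliced polyadenylated polycistron; and the tRNA-punctuation cleavage
products. `fragment_to_evidence()` then samples the polyadenylated pool
(polyA selection: molecules without tails are not sequenced), fragments
long molecules into ~2 kb contigs overlapping by ~100 bp, truncates all
evidence over each dropped tRNA, and emits reads: splice-junction reads,
boundary-crossing and intron-internal reads (only from the pre-mRNA),
an rnl head/tail wrap-around read, polyA-clipped 3′-terminal reads, and
plain exonic reads.

The processing-order question becomes a clean discriminator: with
polyadenylation before splicing the sequenced pool contains a
polyadenylated molecule with introns, so intron-containing contigs appear;
with splicing first there are none. The acceptance suite checks both
directions.

The `"pseudobassiana_like"` profile replaces the random layout with a
fixed, internally seeded coordinate table whose positions honour the
published anchors (the tRNA-Arg copy at 17,359–17,429, trnG from 25,199,
trnM_3 ending at 5,543, the printed 2/3/26/53 bp gaps) and are containment-
consistent with the packaged contig table, so printed coordinates can be
interpreted against it. It is regenerated identically by
`make_genome(sim_config(profile = "pseudobassiana_like"))` in every
session.

**What the generator does not emulate:** sequencing errors and quality,
coverage-depth variation, strand-specific artefacts, chimeric
misassemblies beyond simple fragmentation, nuclear background
transcription, and secondary structure of the introns. Passing recovery
tests therefore show that the inference rules invert the assumed
processing model under realistic gap/dropout geometry — not that the model
is robust to assembler pathology beyond the fragmentation and truncation
it simulates.

## Numerical and representational choices

* Coordinates are 1-based inclusive everywhere; a feature with
  `start > end` wraps the origin. All interval arithmetic rotates the
  circle so the operands are contiguous; a gap computed across the origin
  chooses the representation nearer than half the genome, which is safe
  because adjacent features are never half a genome apart.
* `N` bases are excluded from all composition denominators; an all-N (or
  empty-denominator) skew is `NA`, never 0. An empty sequence is an error.
* `gene_content_label()` is a pure ≥1 bp intersection (so enlarging an
  interval never removes genes); the *covered* flag and the printed-label
  consistency check use the ε slack instead. Printed tables store spans
  only, so a spliced transcript's contig can only be called
  intron-containing/free from its span unless alignment `segments` are
  supplied — the in-memory evidence from the generator carries them.
* Contig labels are resolved to the circular gene order by maximising
  exact-name, then base-name agreement over all contiguous windows;
  misprinted duplicate subscripts resolve positionally and are flagged
  rather than corrected silently. Coordinate-level rules (overlap chains,
  same-gene bridges, evidence reach) apply only to contigs whose printed
  coordinates are consistent with the supplied annotation — this
  implements gene-level pooling across strains with per-strain coordinate
  use, without requiring a cross-strain liftover.
* Status precedence is fixed (strongest evidence reported) but does not
  affect unit inference: any non-`unsupported` status merges.
* GFF3 cannot represent origin-wrapping features, so the writer refuses
  them and `rotate_origin()` provides an exact coordinate rotation; the
  generator anchors rnl at position 1 so its output never needs rotation.
* Splice-boundary and GT-AG checks are evaluated on the DNA sense strand
  (U ≡ T); all genes are on the positive strand in this genome type, and
  the dinucleotide model is checked on the intron's first/last genomic
  bases.

## Problem sizes in the test suite

The suite regenerates all fixtures in code: the anchored 26,725 bp
reference, one default 8-intron simulation shared across tests, 20 seeded
simulations with 1–3 planted units for the recovery criterion, 1,000
random junction graphs of 3–64 genes for the component-oracle property,
and 200-case loops for the arithmetic properties. These sizes keep the
default run around a minute while giving the stochastic checks enough
repetitions to be meaningful.

## Known limitations

* Cross-strain coordinate information is discarded for contigs whose
  printed coordinates do not match the reference layout; a liftover would
  recover it but is out of scope.
* The same-gene bridge requires contig ends to fall strictly inside the
  shared gene; transcripts chained through an intergenic region are only
  merged via the gap rules.
* The TSS inference reports extension lengths into the control region; it
  does not model promoter motifs or estimate an initiation point beyond
  the candidate interval.
* Intron ORF scanning is forward-strand ATG-to-stop only; it labels ORF
  presence and length, not endonuclease family membership.
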