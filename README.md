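# mitocistron

Fungal mitochondrial genomes are transcribed as long polycistronic RNAs that
are matured by polyadenylation, group I intron splicing and tRNA-punctuation
cleavage. Short-read RNA-seq sees this process only indirectly: de novo
assembled transcript contigs cover stretches of the circular mitogenome,
stop dead at cleaved tRNAs, and split at spliced introns. `mitocistron` is
an R package for turning that indirect evidence into explicit inferences:
it characterizes a circular mitogenome (composition, strand skews,
intergenic/overlap/intron catalogue), validates group I intron boundaries,
classifies reads and contigs against the annotation, and merges contig
evidence across gene junctions into polycistronic transcription units. It
is written for people annotating fungal (e.g. *Beauveria*-type)
mitogenomes who want their annotations and RNA-processing claims backed by
transcript evidence rather than homology alone.

## The model

**Composition statistics.** For base counts A, C, G, T (ambiguous `N`
excluded from every denominator):

    AT% = 100 (A + T) / (A + C + G + T)
    AT-skew = (A − T) / (A + T)        GC-skew = (G − C) / (G + C)

**Circular coordinate arithmetic.** Coordinates are 1-based inclusive;
intervals may wrap the origin. The gap between adjacent features is the
number of bases strictly between them, `start(b) − end(a) − 1` on the
rotation that makes the operands contiguous; negative gaps are overlaps.

**Group I intron boundaries.** On the DNA sense strand, an intron is
flagged canonical when the upstream exon ends in T (U in the RNA) and the
intron ends in G; the splice-site dinucleotide model is GT..AG. Both are
reported as flags, not filters.

**Junction evidence graph.** Every pair of circularly adjacent genes is a
junction. Each junction receives the strongest applicable status:

1. `supported` — one contig's gene content spans both genes;
2. `overlap_merge` — coordinate-overlapping contigs of one strain jointly
   span the junction (fragmented assemblies of one transcript);
3. `same_gene_bridge` — contigs chained through a shared gene (one ends
   inside it, the next begins inside it) jointly span the junction;
4. `validated` — the pair is in a user-supplied externally validated list
   (e.g. cDNA-PCR across the junction);
5. `trna_bridge` — an uncovered punctuation tRNA explains the evidence gap:
   its span lies within δ unannotated bases of the nearest evidence on the
   covered side (tRNA cleavage removes these tRNAs from the sequenced pool);
6. `small_gap_bridge` — the genomic gap is at most δ (default 60 bp);
7. `unsupported` otherwise.

A junction whose gap contains control-region bases is never bridged by
rules 5–6, so the inference of a single transcription unit hinges on
exactly that break. Polycistronic units are the maximal circular runs of
genes whose internal junctions are all non-unsupported; they always
partition the genes, and adding evidence can only reduce the unit count.

**Synthetic data.** `make_genome()` / `simulate_processing()` /
`fragment_to_evidence()` generate an annotated circular mitogenome with the
canonical 41-gene order (25 tRNAs, 15 protein-coding genes counting the
rps3 ORF nested in the rnl intron, 2 rRNAs, one control region), planted
canonical introns, K transcription units, polyadenylation before or after
splicing, tRNA punctuation cleavage with coverage dropout, and overlapping
contig fragments — with full ground truth for recovery tests.

## Worked example

Interpret the packaged transcript-contig table (23 contigs from three
strains, with printed coordinates and gene contents) against the anchored
reference layout, adding the cDNA-PCR validated junction list:

```r
library(mitocistron)
ref     <- make_genome(sim_config(profile = "pseudobassiana_like"))
ann     <- ref$annotation
contigs <- load_contig_fixture()
jev     <- assess_junctions(ann, contigs,
                            validated = load_validated_junction_fixture())
print(ann)
print(region_catalogue(ann))
print(render_report(infer_units(jev), ann, infer_tss(contigs, ann)))
```

```
<genome_annotation> pseudobassiana_like (26,725 bp): 14 PCG, 25 tRNA, 2 rRNA, 1 control; 1 introns, 1 nested
<region_catalogue> 39 intergenic (3,212 bp, 12.02%), 2 overlapping, 1 abutting; introns 1,882 bp (7.04%)
Polycistronic unit report
  1 unit(s); junction statuses: supported=31 overlap_merge=0 same_gene_bridge=0 validated=5 trna_bridge=2 small_gap_bridge=2 unsupported=1
  unit 1: trnM_1-trnL_1-trnA-trnF-trnK-trnL_2-trnQ-trnH-trnM_2-nad2-nad3-atp9-cox2-trnR_1-nad4L-nad5-cob-trnC-cox1-trnR_2-nad1-nad4-atp8-atp6-rns-trnY-trnD-trnS_1-trnN-cox3-trnG-nad6-trnV-trnI-trnS_2-trnW-trnP-rnl(rps3)-trnT-trnE-trnM_3
  TSS candidates: A(+121 bp)
```

Reading the output: 31 junctions are spanned outright by contig contents;
five are carried by the validated cDNA-PCR pairs; two are bridged by
uncovered punctuation tRNAs whose spans exactly fill the evidence gap
(e.g. the 71 bp tRNA-Arg copy between the cox1 and nad1 contigs); two by
small genomic gaps (2–3 bp tRNA spacings). The only unsupported junction
is the one through the control region, so all 41 genes fall into a single
polycistronic unit, and one contig runs 121 bp past the last gene into the
control region — the candidate transcription-initiation region.

## The analysis workflow

Numbered drivers under `analysis/` reproduce the full study on synthetic
data and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generate genome, annotation, processed molecules, contig/read evidence |
| `02_genome_stats.R` | per-strain composition/skew/region tables, intron counts, presence matrix |
| `03_intron_splicing.R` | splice-boundary checks, spliced transcripts, intron ORF scan |
| `04_transcript_evidence.R` | read/contig classification, polyA sites, coverage |
| `05_polycistron_inference.R` | unit inference on the packaged table + recovery experiment |

Run them in order with `Rscript analysis/01_simulate.R` etc.

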