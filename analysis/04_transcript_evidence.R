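#!/usr/bin/env Rscript
# Classify the simulated transcript evidence: read classes (splicing vs
# intron-containing vs wrap-around), contig classes, polyA sites and
# per-gene coverage. The intron-containing *polyadenylated* evidence is the
# observable that discriminates polyadenylation-before-splicing.

suppressPackageStartupMessages(library(mitocistron))
dir.create("results", showWarnings = FALSE)

ann <- read_annotation("results/sim/genome.gff3", "results/sim/genome.fasta")
contigs <- read_contig_table("results/sim/contigs.tsv")
reads <- read_sam_alignments("results/sim/reads.sam")

cls <- vapply(reads, classify_read, character(1), ann = ann)
cat("Read classes:\n"); print(table(cls))
utils::write.table(
  data.frame(read = vapply(reads, `[[`, character(1), "id"), class = cls),
  "results/read_classes.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

ctg_cls <- vapply(seq_len(nrow(contigs)), function(i)
  classify_contig(contigs[i, ], ann), character(1))
cat("Contig classes:\n"); print(table(ctg_cls))
utils::write.table(cbind(contigs[, c("contig_id", "start", "end")],
                         class = ctg_cls),
                   "results/contig_classes.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

sites <- Filter(Negate(is.null), lapply(reads, detect_polyA, ann = ann))
cat("polyA sites detected:", length(sites), "at positions",
    paste(vapply(sites, `[[`, numeric(1), "position"), collapse = ", "), "\n")

cov <- gene_read_coverage(list(contigs = contigs, reads = reads), ann)
utils::write.table(cov$per_gene, "results/gene_coverage.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
uncov <- cov$per_gene$gene[!cov$per_gene$covered]
cat(sprintf("Genome coverage %.2f%%; uncovered genes: %s\n",
            100 * cov$genome_fraction,
            if (length(uncov)) paste(uncov, collapse = ", ") else "none"))
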