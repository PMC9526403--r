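# Canonical Beauveria-type mitogenome constants and packaged fixtures.
#
# The canonical gene complement is 25 tRNAs, 15 protein-coding genes (rps3
# nested inside the conserved rnl intron) and 2 rRNAs, all on the positive
# strand, with a single control region between trnM_3 and trnM_1. Duplicate
# tRNA names (trnM x3, trnR x2, trnL x2, trnS x2) are disambiguated by a
# subscript index assigned in genomic order.

#' Canonical gene order of the Beauveria-type mitogenome
#'
#' The 41 top-level genes in transcription-unit order, beginning at trnM_1
#' (immediately downstream of the control region) and ending at trnM_3. rps3
#' is not listed: it is nested inside the rnl intron.
#'
#' @return Character vector of 41 gene names.
#' @export
canonical_gene_order <- function() {
  c("trnM_1", "trnL_1", "trnA", "trnF", "trnK", "trnL_2", "trnQ", "trnH",
    "trnM_2", "nad2", "nad3", "atp9", "cox2", "trnR_1", "nad4L", "nad5",
    "cob", "trnC", "cox1", "trnR_2", "nad1", "nad4", "atp8", "atp6", "rns",
    "trnY", "trnD", "trnS_1", "trnN", "cox3", "trnG", "nad6", "trnV", "trnI",
    "trnS_2", "trnW", "trnP", "rnl", "trnT", "trnE", "trnM_3")
}

#' Protein-coding gene concatenation order
#'
#' The 15 protein-coding genes in the standard concatenation order used for
#' phylogenetic matrices.
#'
#' @return Character vector of 15 gene names.
#' @export
pcg_concat_order <- function() {
  c("rps3", "nad2", "nad3", "atp9", "cox2", "nad4L", "nad5", "cob", "cox1",
    "nad1", "nad4", "atp8", "atp6", "cox3", "nad6")
}

#' Feature kind of a canonical gene name
#' @param name Gene name(s).
#' @return Character vector: `"tRNA"`, `"rRNA"` or `"PCG"`.
#' @export
gene_kind <- function(name) {
  ifelse(grepl("^trn", name), "tRNA",
         ifelse(name %in% c("rnl", "rns"), "rRNA", "PCG"))
}

## strip the duplicate-disambiguation subscript: trnM_2 -> trnM
base_gene_name <- function(name) sub("_[0-9]+$", "", name)

## normalise a printed gene label to canonical spelling where unambiguous:
## trnM3 -> trnM_3, trnL2 -> trnL_2; "rnl(rps3)" -> rnl; plain "trnS" stays.
normalize_gene_name <- function(name) {
  name <- gsub("\\s", "", name)
  name <- sub("\\(.*\\)$", "", name)
  sub("^(trn[A-Z])([0-9]+)$", "\\1_\\2", name)
}

#' Path to a packaged fixture file
#' @param file File name under the package's `extdata`.
#' @return Absolute path.
#' @export
mito_fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "mitocistron")
  if (p == "") stop("fixture not found: ", file)
  p
}

#' Packaged per-strain intron count table
#'
#' The printed per-gene intron counts for the eight sequenced strains,
#' including the printed `Total` column (which [intron_count_table()] can
#' recompute from the per-gene counts).
#'
#' @return `data.frame` with `strain`, per-gene counts, `Total`.
#' @export
load_intron_count_fixture <- function() {
  utils::read.delim(mito_fixture_path("intron_counts.tsv"),
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Packaged transcript-contig table
#'
#' The printed contig-to-genome alignment table (contigs A, B1-B13, C1-C9)
#' with positions and dash-separated gene contents, parsed through
#' [read_contig_table()].
#'
#' @return `data.frame` of contig alignments.
#' @export
load_contig_fixture <- function() {
  read_contig_table(mito_fixture_path("polycistron_contigs.tsv"))
}

#' Packaged list of junctions validated by cDNA PCR
#'
#' @return Two-column `data.frame` (`upstream`, `downstream`).
#' @export
load_validated_junction_fixture <- function() {
  read_validated_junctions(mito_fixture_path("validated_junctions.tsv"))
}

## Fixed coordinate layout of the synthetic "pseudobassiana-like" reference
## genome (26,725 bp). Coordinates honour the published anchors: trnR_2 at
## 17,359-17,429, trnG starting at 25,199, trnM_3 ending at 5,543, the 2 bp
## trnM_1-trnL_1 / 3 bp trnY-trnD / 2 bp trnV-trnI / 53 bp trnG-nad6 gaps,
## the 1 bp nad2/nad3 and nad4L/nad5 overlaps, a 1,882 bp rnl intron hosting
## rps3, and containment consistency with the packaged contig table.
pseudobassiana_layout <- function() {
  f <- function(name, kind, start, end)
    data.frame(name = name, kind = kind, start = start, end = end)
  features <- rbind(
    f("rnl", "rRNA", 1L, 5100L),
    f("trnT", "tRNA", 5310L, 5380L),
    f("trnE", "tRNA", 5397L, 5467L),
    f("trnM_3", "tRNA", 5473L, 5543L),
    f("control", "control", 5544L, 6052L),
    f("trnM_1", "tRNA", 6055L, 6125L),
    f("trnL_1", "tRNA", 6128L, 6198L),
    f("trnA", "tRNA", 6201L, 6271L),
    f("trnF", "tRNA", 6274L, 6344L),
    f("trnK", "tRNA", 6347L, 6412L),
    f("trnL_2", "tRNA", 6415L, 6485L),
    f("trnQ", "tRNA", 6488L, 6558L),
    f("trnH", "tRNA", 6561L, 6631L),
    f("trnM_2", "tRNA", 6634L, 6704L),
    f("nad2", "PCG", 6707L, 8506L),
    f("nad3", "PCG", 8506L, 8931L),
    f("atp9", "PCG", 8934L, 9161L),
    f("cox2", "PCG", 9164L, 9913L),
    f("trnR_1", "tRNA", 9916L, 9986L),
    f("nad4L", "PCG", 10541L, 10807L),
    f("nad5", "PCG", 10807L, 12726L),
    f("cob", "PCG", 12790L, 13971L),
    f("trnC", "tRNA", 13974L, 14044L),
    f("cox1", "PCG", 14330L, 16711L),
    f("trnR_2", "tRNA", 17359L, 17429L),
    f("nad1", "PCG", 17440L, 19770L),
    f("nad4", "PCG", 19773L, 20789L),
    f("atp8", "PCG", 20794L, 20940L),
    f("atp6", "PCG", 20943L, 21725L),
    f("rns", "rRNA", 22150L, 23600L),
    f("trnY", "tRNA", 23896L, 23966L),
    f("trnD", "tRNA", 23970L, 24040L),
    f("trnS_1", "tRNA", 24052L, 24122L),
    f("trnN", "tRNA", 24125L, 24195L),
    f("cox3", "PCG", 24198L, 25007L),
    f("trnG", "tRNA", 25199L, 25269L),
    f("nad6", "PCG", 25323L, 25964L),
    f("trnV", "tRNA", 26310L, 26380L),
    f("trnI", "tRNA", 26383L, 26453L),
    f("trnS_2", "tRNA", 26456L, 26526L),
    f("trnW", "tRNA", 26529L, 26599L),
    f("trnP", "tRNA", 26630L, 26700L)
  )
  list(features = features,
       introns = data.frame(gene = "rnl", start = 901L, end = 2782L),
       nested = data.frame(name = "rps3", host_gene = "rnl",
                           start = 1201L, end = 2403L),
       length = 26725L)
}
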