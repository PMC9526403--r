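# Readers and writers: FASTA, GFF3, contig tables (printed-table dialect),
# validated-junction lists, summary stat tables, SAM.

#' Write a genome to FASTA
#' @param genome A [circular_genome()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "circular_genome"))
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- genome$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA path.
#' @param id Optional record id to select (default: first record).
#' @return A [circular_genome()].
#' @export
read_genome_fasta <- function(path, id = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("no sequences in ", path)
  i <- if (is.null(id)) 1L else match(id, names(x))
  if (is.na(i)) stop("sequence id not found: ", id)
  circular_genome(sub("\\s.*$", "", names(x)[i]), as.character(x[[i]]))
}

kind_to_type <- c(PCG = "gene", tRNA = "tRNA", rRNA = "rRNA",
                  control = "region")
type_to_kind <- c(gene = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                  region = "control")

#' Write an annotation to GFF3 (and optionally the genome to FASTA)
#'
#' Emits one feature line per top-level feature (`gene`/`tRNA`/`rRNA`;
#' `region` for the control region), `intron` lines parented to their host
#' gene, `exon` lines for the exon complement of intron-bearing genes, and
#' nested genes parented to their host intron. Origin-wrapping features
#' cannot be represented; rotate with [rotate_origin()] first.
#'
#' @param ann A [genome_annotation()].
#' @param gff_path GFF3 output path.
#' @param fasta_path Optional FASTA output path for the genome.
#' @return Invisibly, `gff_path`.
#' @export
write_annotation <- function(ann, gff_path, fasta_path = NULL) {
  stopifnot(inherits(ann, "genome_annotation"))
  if (any(ann$features$wraps))
    stop("origin-wrapping features cannot be written as GFF3; ",
         "use rotate_origin() first")
  L <- ann$genome$length
  sid <- ann$genome$id

  rows <- list()
  add <- function(type, start, end, ID, Parent = NA_character_,
                  Name = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, start = start, end = end, ID = ID, Parent = Parent,
      Name = Name)
  }
  for (i in seq_len(nrow(ann$features))) {
    fr <- ann$features[i, ]
    add(kind_to_type[[fr$kind]], fr$start, fr$end, fr$name, Name = fr$name)
    gi <- ann$introns[ann$introns$gene == fr$name, , drop = FALSE]
    if (nrow(gi)) {
      for (k in seq_len(nrow(gi)))
        add("intron", gi$start[k], gi$end[k],
            sprintf("%s.intron%d", fr$name, gi$index[k]), Parent = fr$name)
      ## exon complement
      bounds <- c(fr$start, rbind(gi$start - 1L, gi$end + 1L), fr$end)
      for (k in seq_len(length(bounds) / 2L))
        add("exon", bounds[2L * k - 1L], bounds[2L * k],
            sprintf("%s.exon%d", fr$name, k), Parent = fr$name)
    }
  }
  if (nrow(ann$nested)) {
    for (k in seq_len(nrow(ann$nested))) {
      nd <- ann$nested[k, ]
      hi <- ann$introns[ann$introns$gene == nd$host_gene, ]
      idx <- hi$index[hi$start <= nd$start & nd$end <= hi$end]
      add("gene", nd$start, nd$end, nd$name,
          Parent = sprintf("%s.intron%d", nd$host_gene, idx), Name = nd$name)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = sid,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = "+")
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Name <- df$Name
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), NA, df$Parent)
  rtracklayer::export(gr, gff_path, format = "gff3")
  if (!is.null(fasta_path)) write_genome_fasta(ann$genome, fasta_path)
  invisible(gff_path)
}

#' Read an annotation from GFF3 plus FASTA
#'
#' Inverse of [write_annotation()]: top-level features from
#' `gene`/`tRNA`/`rRNA`/`region` lines without a `Parent`, introns from
#' `intron` lines parented to their gene, nested genes from `gene` lines
#' parented to an intron. `exon` lines are derivable and ignored. The
#' sequence id of the GFF3 records must match the FASTA record.
#'
#' @param gff_path GFF3 path.
#' @param fasta_path FASTA path for the genome sequence.
#' @param strain Strain label (default: genome id).
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(gff_path, fasta_path, strain = NULL) {
  genome <- read_genome_fasta(fasta_path)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  if (length(gr) == 0L) stop("no features in ", gff_path)
  sid <- unique(as.character(GenomicRanges::seqnames(gr)))
  if (!genome$id %in% sid)
    stop("GFF3 sequence id(s) ", paste(sid, collapse = ","),
         " do not match FASTA id ", genome$id)
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  id <- as.character(mc$ID)
  parent <- vapply(seq_along(gr), function(i) {
    p <- mc$Parent[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p[1L])
  }, character(1))
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)

  top <- which(type %in% names(type_to_kind) & is.na(parent))
  feats <- data.frame(name = id[top], kind = type_to_kind[type[top]],
                      start = st[top], end = en[top])
  feats <- feats[order(feats$start), ]

  iw <- which(type == "intron")
  introns <- if (length(iw))
    data.frame(gene = parent[iw], start = st[iw], end = en[iw])
  else NULL

  nw <- which(type == "gene" & !is.na(parent))
  nested <- NULL
  if (length(nw)) {
    host <- sub("\\.intron[0-9]+$", "", parent[nw])
    nested <- data.frame(name = id[nw], host_gene = host,
                         start = st[nw], end = en[nw])
  }
  genome_annotation(genome, feats, introns = introns, nested = nested,
                    strain = strain %||% genome$id)
}

strip_num <- function(x) {
  suppressWarnings(as.integer(gsub("[,  ]", "", as.character(x))))
}

#' Read a transcript-contig table (printed-table dialect)
#'
#' Tab-separated with a header. Coordinates either as `start`/`end` columns
#' or a single `position` column (`start-end`, hyphen or en-dash, thousands
#' commas allowed). `gene_content` is dash-separated gene names; a
#' parenthesised name after a gene (e.g. `rnl(rps3)`) marks a nested gene
#' and is retained in the raw label but stripped for resolution.
#'
#' @param path TSV path.
#' @return `data.frame` with `contig_id`, `strain`, `start`, `end`,
#'   `gene_content` (raw string).
#' @export
read_contig_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (nrow(df) == 0L)
    return(data.frame(contig_id = character(), strain = character(),
                      start = integer(), end = integer(),
                      gene_content = character()))
  if (!all(c("contig_id", "gene_content") %in% names(df)))
    stop("contig table needs 'contig_id' and 'gene_content' columns")
  if (all(c("start", "end") %in% names(df))) {
    start <- strip_num(df$start); end <- strip_num(df$end)
  } else if ("position" %in% names(df)) {
    parts <- strsplit(gsub("[,  ]", "", df$position), "[–-]")
    bad <- which(lengths(parts) != 2L)
    if (length(bad))
      stop("malformed position in row(s): ",
           paste(df$contig_id[bad], collapse = ", "))
    start <- as.integer(vapply(parts, `[`, character(1), 1L))
    end <- as.integer(vapply(parts, `[`, character(1), 2L))
  } else {
    stop("contig table needs 'start'/'end' or 'position' columns")
  }
  data.frame(contig_id = as.character(df$contig_id),
             strain = if ("strain" %in% names(df))
               as.character(df$strain) else "unknown",
             start = start, end = end,
             gene_content = as.character(df$gene_content))
}

#' Write a contig table
#' @param contigs Contig `data.frame`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_contig_table <- function(contigs, path) {
  keep <- intersect(c("contig_id", "strain", "start", "end", "gene_content"),
                    names(contigs))
  utils::write.table(contigs[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a validated-junction list
#'
#' Two-column TSV (`upstream`, `downstream`) of gene pairs externally shown
#' to be co-transcribed (e.g. by cDNA PCR across the junction).
#'
#' @param path TSV path.
#' @return `data.frame` with `upstream` and `downstream`.
#' @export
read_validated_junctions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("upstream", "downstream") %in% names(df)))
    stop("validated junction list needs 'upstream'/'downstream' columns")
  df[, c("upstream", "downstream")]
}

#' Genome summary statistics row
#'
#' Length, AT%, skews and (when an annotation is given) intron and
#' intergenic totals with their genome fractions -- the standard per-strain
#' summary table row.
#'
#' @param x A [genome_annotation()] or [circular_genome()].
#' @return One-row `data.frame`: `strain`, `length_bp`, `AT_pct`,
#'   `AT_skew`, `GC_skew`, `intron_bp`, `intron_pct`, `intergenic_bp`,
#'   `intergenic_pct`.
#' @export
genome_stats <- function(x) {
  if (inherits(x, "genome_annotation")) {
    cs <- composition_stats(x$genome)
    rc <- region_catalogue(x)
    data.frame(strain = x$strain, length_bp = x$genome$length,
               AT_pct = cs$at_percent, AT_skew = cs$at_skew,
               GC_skew = cs$gc_skew, intron_bp = rc$intron_total_bp,
               intron_pct = rc$intron_fraction,
               intergenic_bp = rc$total_intergenic_bp,
               intergenic_pct = rc$intergenic_fraction)
  } else {
    cs <- composition_stats(x)
    data.frame(strain = x$id, length_bp = x$length, AT_pct = cs$at_percent,
               AT_skew = cs$at_skew, GC_skew = cs$gc_skew,
               intron_bp = NA_integer_, intron_pct = NA_real_,
               intergenic_bp = NA_integer_, intergenic_pct = NA_real_)
  }
}

#' Write read alignments as SAM
#'
#' One line per aligned segment; the first segment of a read is the primary
#' record, later segments are supplementary (flag 2048). Unaligned read
#' portions (including any polyA soft clip) appear as soft-clipped bases;
#' gaps between colinear segments are not encoded as N skips, so split
#' alignments round-trip as segment sets.
#'
#' @param reads List of [read_alignment()].
#' @param genome A [circular_genome()] (reference for SEQ and the header).
#' @param path Output SAM path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(reads, genome, path) {
  stopifnot(inherits(genome, "circular_genome"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", genome$id, genome$length)), con)
  for (r in reads) {
    seg <- r$segments
    if (nrow(seg) == 0L) next
    total_len <- max(seg$rend) + nchar(r$clip3) + nchar(r$clip5)
    seq_full <- paste0(
      r$clip5,
      paste(vapply(seq_len(nrow(seg)), function(i)
        subseq_circular(genome, seg$gstart[i], seg$gend[i]), character(1)),
        collapse = ""),
      r$clip3)
    for (i in seq_len(nrow(seg))) {
      lead <- nchar(r$clip5) + seg$rstart[i] - 1L
      m <- seg$rend[i] - seg$rstart[i] + 1L
      trail <- total_len - lead - m
      cigar <- paste0(if (lead > 0L) paste0(lead, "S") else "", m, "M",
                      if (trail > 0L) paste0(trail, "S") else "")
      flag <- if (i == 1L) 0L else 2048L
      writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                         r$id, flag, genome$id, seg$gstart[i], cigar,
                         seq_full), con)
    }
  }
  invisible(path)
}

#' Read alignments from a SAM/BAM file
#'
#' Converts SAM to BAM if needed (Rsamtools) and reconstructs one
#' [read_alignment()] per read name, merging primary and supplementary
#' records into ordered segments; leading/trailing soft clips of the
#' outermost segments become `clip5`/`clip3` (sequence recovered from the
#' record when present).
#'
#' @param path SAM or BAM path.
#' @return List of [read_alignment()].
#' @export
read_sam_alignments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE) ||
      !requireNamespace("GenomicAlignments", quietly = TRUE))
    stop("reading SAM requires Rsamtools and GenomicAlignments")
  if (grepl("\\.sam$", path)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             indexDestination = FALSE, overwrite = TRUE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "cigar", "seq"))
  b <- Rsamtools::scanBam(path, param = p)[[1L]]
  n <- length(b$qname)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    ops <- GenomicAlignments::explodeCigarOps(b$cigar[i])[[1L]]
    lens <- GenomicAlignments::explodeCigarOpLengths(b$cigar[i])[[1L]]
    gpos <- b$pos[i]; qpos <- 1L
    gstart <- gpos; qstart <- qpos
    lead_clip <- if (length(ops) && ops[1L] == "S") lens[1L] else 0L
    trail_clip <- if (length(ops) && ops[length(ops)] == "S")
      lens[length(lens)] else 0L
    qpos <- qpos + lead_clip
    m_len <- sum(lens[ops %in% c("M", "=", "X", "D")])
    q_len <- sum(lens[ops %in% c("M", "=", "X", "I")])
    seqc <- as.character(b$seq[i])
    recs[[i]] <- list(
      qname = b$qname[i],
      seg = data.frame(gstart = gpos, gend = gpos + m_len - 1L,
                       rstart = lead_clip + 1L,
                       rend = lead_clip + q_len),
      lead_clip = lead_clip, trail_clip = trail_clip,
      lead_seq = if (lead_clip > 0L) substr(seqc, 1L, lead_clip) else "",
      trail_seq = if (trail_clip > 0L)
        substr(seqc, nchar(seqc) - trail_clip + 1L, nchar(seqc)) else "")
  }
  out <- list()
  for (qn in unique(vapply(recs, `[[`, character(1), "qname"))) {
    rr <- Filter(function(r) r$qname == qn, recs)
    segs <- do.call(rbind, lapply(rr, `[[`, "seg"))
    segs <- segs[order(segs$rstart), , drop = FALSE]
    ## soft-clipped bases covered by another segment of the same read are
    ## that segment's content; only the outermost residue is a real clip
    c5 <- min(segs$rstart) - 1L
    first <- rr[[which.min(vapply(rr, function(r) r$seg$rstart, numeric(1)))]]
    last <- rr[[which.max(vapply(rr, function(r) r$seg$rend, numeric(1)))]]
    clip5 <- if (c5 > 0L) first$lead_seq else ""
    clip3 <- if (last$trail_clip > 0L) last$trail_seq else ""
    ## shift read coordinates so aligned bases start at 1 after the clip
    segs$rstart <- segs$rstart - c5
    segs$rend <- segs$rend - c5
    out[[length(out) + 1L]] <- read_alignment(qn, segs, clip5 = clip5,
                                              clip3 = clip3)
  }
  out
}
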