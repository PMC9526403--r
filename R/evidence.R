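# Classification of transcript evidence (split reads and assembled contigs)
# against a mitogenome annotation: splicing vs intron-containing reads,
# wrap-around reads, polyA tail detection, gene-content labelling and
# coverage accounting.

#' Construct a read alignment record
#'
#' A (possibly split) alignment of one read: ordered genomic segments with
#' their read-coordinate extents, plus any unaligned soft-clipped sequence at
#' the read's 5' or 3' end.
#'
#' @param id Read identifier.
#' @param segments `data.frame` with columns `gstart`, `gend` (genomic,
#'   1-based inclusive) and `rstart`, `rend` (read coordinates); rows in read
#'   order, non-overlapping in read coordinates. May have zero rows for an
#'   unaligned read.
#' @param clip5,clip3 Soft-clipped sequence at the read's 5'/3' end
#'   (`""` if none).
#' @return Object of class `read_alignment`.
#' @export
read_alignment <- function(id, segments, clip5 = "", clip3 = "") {
  stopifnot(is.data.frame(segments))
  if (nrow(segments)) {
    stopifnot(all(c("gstart", "gend", "rstart", "rend") %in% names(segments)))
    for (cn in c("gstart", "gend", "rstart", "rend"))
      segments[[cn]] <- as.integer(segments[[cn]])
    ord <- order(segments$rstart)
    segments <- segments[ord, , drop = FALSE]
    rownames(segments) <- NULL
    if (nrow(segments) > 1L &&
        any(segments$rstart[-1L] <= segments$rend[-nrow(segments)]))
      stop("segments overlap in read coordinates")
  }
  structure(list(id = as.character(id), segments = segments,
                 clip5 = toupper(clip5), clip3 = toupper(clip3)),
            class = "read_alignment")
}

## does interval [s, e] overlap interval [s2, e2] (no wrapping)
iv_overlap <- function(s, e, s2, e2) max(0L, min(e, e2) - max(s, s2) + 1L)

## all annotated intron intervals as a data.frame
all_introns <- function(ann) ann$introns

#' Classify a read alignment
#'
#' Assigns exactly one evidence class:
#' * `splicing` -- consecutive segments abut the donor/acceptor of an
#'   annotated intron (both junction edges within `tol` bp), evidencing the
#'   spliced transcript;
#' * `wraparound` -- consecutive segments jump backwards, mapping to the tail
#'   then the head of the same feature or across the genome origin (both
#'   arms at least `min_arm` bases);
#' * `intron_containing` -- an aligned base falls in an annotated intron, or
#'   a segment crosses an exon/intron boundary contiguously;
#' * `plain_exonic` -- everything else aligned;
#' * `unaligned` -- no segments.
#'
#' @param r A [read_alignment()].
#' @param ann A [genome_annotation()].
#' @param tol Junction concordance tolerance in bp (default 3, short-read
#'   aligner jitter).
#' @param min_arm Minimum arm length for a wraparound call (default 20).
#' @return Single character class.
#' @export
classify_read <- function(r, ann, tol = 3L, min_arm = 20L) {
  stopifnot(inherits(r, "read_alignment"), inherits(ann, "genome_annotation"))
  seg <- r$segments
  if (nrow(seg) == 0L) return("unaligned")
  L <- ann$genome$length
  introns <- all_introns(ann)

  ## splicing: a forward genomic gap between consecutive segments matching an
  ## annotated intron within tol on both edges
  if (nrow(seg) > 1L && nrow(introns)) {
    for (i in seq_len(nrow(seg) - 1L)) {
      gap_s <- seg$gend[i] + 1L
      gap_e <- seg$gstart[i + 1L] - 1L
      if (gap_e < gap_s) next
      hit <- abs(introns$start - gap_s) <= tol & abs(introns$end - gap_e) <= tol
      if (any(hit)) return("splicing")
    }
  }

  ## wraparound: consecutive segments jumping backwards on the genome,
  ## tail then head of one feature or across the origin
  if (nrow(seg) > 1L) {
    for (i in seq_len(nrow(seg) - 1L)) {
      a <- seg[i, ]; b <- seg[i + 1L, ]
      arm_a <- a$gend - a$gstart + 1L
      arm_b <- b$gend - b$gstart + 1L
      if (arm_a < min_arm || arm_b < min_arm) next
      if (b$gstart >= a$gstart) next   # forward jump: not a wrap
      across_origin <- (L - a$gend) <= tol && (b$gstart - 1L) <= tol
      same_feature <- FALSE
      for (k in seq_len(nrow(ann$features))) {
        fr <- ann$features[k, ]
        if (fr$kind == "control") next
        ia <- circ_overlap(list(start = a$gstart, end = a$gend),
                           as_interval(fr), L)
        ib <- circ_overlap(list(start = b$gstart, end = b$gend),
                           as_interval(fr), L)
        if (ia >= min_arm && ib >= min_arm) { same_feature <- TRUE; break }
      }
      if (across_origin || same_feature) return("wraparound")
    }
  }

  ## intron_containing: any aligned base in an intron (which also covers
  ## contiguous exon/intron boundary crossings)
  if (nrow(introns)) {
    for (i in seq_len(nrow(seg))) {
      for (k in seq_len(nrow(introns))) {
        if (iv_overlap(seg$gstart[i], seg$gend[i],
                       introns$start[k], introns$end[k]) > 0L)
          return("intron_containing")
      }
    }
  }
  "plain_exonic"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

contig_segments <- function(contig) {
  if ("segments" %in% names(contig)) {
    s <- contig$segments
    if (is.list(s) && !is.data.frame(s)) s <- s[[1L]]
    if (is.data.frame(s)) return(s[, c("gstart", "gend")])
  }
  data.frame(gstart = as.integer(contig$start), gend = as.integer(contig$end))
}

#' Classify a contig as intron-free or intron-containing
#'
#' A contig is `intron_containing` iff its aligned bases cover at least one
#' annotated intron base. Contigs carrying split `segments` (a spliced
#' transcript aligned with gaps at the introns) are judged on the segments;
#' plain interval contigs on their full span.
#'
#' @param contig One contig: a single row of a contig table (with `start`,
#'   `end` and optionally a `segments` data.frame of `gstart`/`gend` rows).
#' @param ann A [genome_annotation()].
#' @return `"intron_free"` or `"intron_containing"`.
#' @export
classify_contig <- function(contig, ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  seg <- contig_segments(contig)
  introns <- all_introns(ann)
  if (nrow(introns) == 0L) return("intron_free")
  L <- ann$genome$length
  for (i in seq_len(nrow(seg))) {
    for (k in seq_len(nrow(introns))) {
      ov <- circ_overlap(list(start = seg$gstart[i], end = seg$gend[i]),
                         list(start = introns$start[k], end = introns$end[k]),
                         L)
      if (ov > 0L) return("intron_containing")
    }
  }
  "intron_free"
}

#' Genes intersected by a genomic interval
#'
#' Returns the top-level genes (control region excluded) whose spans
#' intersect the interval by at least 1 bp, in genomic order starting from
#' the interval's start. Partial overlaps are included, so enlarging an
#' interval never removes genes from the label.
#'
#' @param interval Numeric `c(start, end)`; `start > end` wraps the origin.
#' @param ann A [genome_annotation()].
#' @return Character vector of gene names.
#' @export
gene_content_label <- function(interval, ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  iv <- as_interval(interval)
  L <- ann$genome$length
  gs <- genes(ann)
  hit <- vapply(seq_len(nrow(gs)), function(i)
    circ_overlap(iv, as_interval(gs[i, ]), L) > 0L, logical(1))
  nm <- gs$name[hit]
  if (length(nm) <= 1L) return(nm)
  ## order genes around the circle starting at the interval start; genes
  ## already underway at the interval start come first
  st <- gs$start[hit]; en <- gs$end[hit]
  key <- (st - iv$start) %% L
  contains <- vapply(which(hit), function(i) {
    fr <- gs[i, ]
    if (fr$start <= fr$end) iv$start >= fr$start && iv$start <= fr$end
    else iv$start >= fr$start || iv$start <= fr$end
  }, logical(1))
  key[contains] <- key[contains] - L
  nm[order(key)]
}

#' Detect a polyA tail site from a read's 3' soft clip
#'
#' Calls a polyadenylation site when the 3' soft-clipped sequence is an
#' A-run of at least `min_tail` bases with at most one non-A, and the tail is
#' not genomically templated (the genome does not continue with an equivalent
#' A-run after the last aligned base).
#'
#' @param r A [read_alignment()] with at least one segment.
#' @param ann A [genome_annotation()] (supplies the genome for the
#'   templated-run check).
#' @param min_tail Minimum tail length (default 6).
#' @return `NULL`, or a list with `position` (genomic coordinate of the last
#'   templated base) and `tail_length`.
#' @export
detect_polyA <- function(r, ann, min_tail = 6L) {
  stopifnot(inherits(r, "read_alignment"), inherits(ann, "genome_annotation"))
  tail <- r$clip3
  if (nchar(tail) < min_tail || nrow(r$segments) == 0L) return(NULL)
  bases <- strsplit(tail, "", fixed = TRUE)[[1L]]
  if (sum(bases != "A") > 1L) return(NULL)
  pos <- max(r$segments$gend)
  L <- ann$genome$length
  ## reject tails explained by a templated genomic A-run
  nxt <- subseq_circular(ann$genome, circ_pos(pos + 1L, L),
                         circ_pos(pos + nchar(tail), L))
  nxt_bases <- strsplit(nxt, "", fixed = TRUE)[[1L]]
  if (sum(nxt_bases == "A") >= nchar(tail) - 1L) return(NULL)
  list(position = pos, tail_length = nchar(tail))
}

evidence_intervals <- function(evidence) {
  segs <- list()
  if (is.data.frame(evidence)) {
    for (i in seq_len(nrow(evidence))) {
      s <- if ("segments" %in% names(evidence) &&
               is.data.frame(evidence$segments[[i]]))
        evidence$segments[[i]]
      else data.frame(gstart = evidence$start[i], gend = evidence$end[i])
      segs[[length(segs) + 1L]] <- s[, c("gstart", "gend")]
    }
  } else if (is.list(evidence)) {
    for (r in evidence) {
      if (inherits(r, "read_alignment") && nrow(r$segments))
        segs[[length(segs) + 1L]] <- r$segments[, c("gstart", "gend")]
    }
  }
  if (length(segs) == 0L)
    return(data.frame(gstart = integer(), gend = integer()))
  do.call(rbind, segs)
}

#' Per-gene and genome-wide evidence coverage
#'
#' Marks which bases are covered by any evidence interval (contig table rows
#' and/or read alignments) and reports, per top-level gene, the covered
#' fraction of its exon space (introns excluded) plus a covered flag, and the
#' genome-wide covered fraction over all positions. A gene counts as covered
#' only when more than `epsilon` of its exon bases are touched, absorbing
#' 1-2 bp boundary jitter in printed contig coordinates.
#'
#' @param evidence Contig `data.frame` (columns `start`, `end`, optional
#'   `segments`) or list of [read_alignment()]s, or a list
#'   `list(contigs =, reads =)`.
#' @param ann A [genome_annotation()].
#' @param epsilon Minimum covered exon bases for the covered flag (default 2).
#' @return List with `per_gene` (`data.frame`: `gene`, `kind`,
#'   `covered_bases`, `exon_bases`, `fraction`, `covered`) and
#'   `genome_fraction`.
#' @export
gene_read_coverage <- function(evidence, ann, epsilon = 2L) {
  stopifnot(inherits(ann, "genome_annotation"))
  if (is.list(evidence) && !is.data.frame(evidence) &&
      !is.null(evidence$contigs)) {
    iv <- rbind(evidence_intervals(evidence$contigs),
                evidence_intervals(evidence$reads %||% list()))
  } else {
    iv <- evidence_intervals(evidence)
  }
  L <- ann$genome$length
  cov <- logical(L)
  for (i in seq_len(nrow(iv))) {
    s <- iv$gstart[i]; e <- iv$gend[i]
    if (is.na(s) || is.na(e)) next
    s <- circ_pos(s, L); e <- circ_pos(e, L)
    if (s <= e) cov[s:e] <- TRUE else { cov[s:L] <- TRUE; cov[1:e] <- TRUE }
  }

  gs <- genes(ann)
  introns <- ann$introns
  rows <- lapply(seq_len(nrow(gs)), function(i) {
    fr <- gs[i, ]
    pos <- if (fr$start <= fr$end) fr$start:fr$end
           else c(fr$start:L, 1:fr$end)
    if (nrow(introns)) {
      gi <- introns[introns$gene == fr$name, , drop = FALSE]
      for (k in seq_len(nrow(gi))) {
        ip <- if (gi$start[k] <= gi$end[k]) gi$start[k]:gi$end[k]
              else c(gi$start[k]:L, 1:gi$end[k])
        pos <- setdiff(pos, ip)
      }
    }
    covered_bases <- sum(cov[pos])
    data.frame(gene = fr$name, kind = fr$kind,
               covered_bases = covered_bases, exon_bases = length(pos),
               fraction = covered_bases / length(pos),
               covered = covered_bases > epsilon)
  })
  per_gene <- do.call(rbind, rows)
  rownames(per_gene) <- NULL
  list(per_gene = per_gene, genome_fraction = mean(cov))
}
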