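# Circular mitogenome data model and descriptive statistics.
#
# Coordinates are 1-based inclusive everywhere (matching GFF3 and the printed
# contig tables). A feature may wrap the origin (start > end); all interval
# arithmetic is done on the rotation that makes the operands contiguous.

#' Construct a circular genome
#'
#' A circular mitochondrial genome: an identifier plus a nucleotide sequence
#' over the alphabet `{A, C, G, T, N}`. Position 1 is the (arbitrary) origin;
#' intervals may wrap past position `length` back to 1.
#'
#' @param id Single character identifier.
#' @param sequence Single non-empty character string of A/C/G/T/N (case
#'   insensitive).
#' @return An object of class `circular_genome` with fields `id`, `length`
#'   and `sequence`.
#' @examples
#' g <- circular_genome("toy", "ACGTACGTAA")
#' g$length
#' @export
circular_genome <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (methods::is(sequence, "DNAString"))
    sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L)
    stop("genome sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence))
    stop("genome sequence may only contain A, C, G, T or N")
  structure(
    list(id = id, length = nchar(sequence), sequence = sequence),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %s bp circular\n",
              x$id, format(x$length, big.mark = ",")))
  invisible(x)
}

## normalise a position onto 1..L
circ_pos <- function(pos, L) ((pos - 1L) %% L) + 1L

#' Extract a (possibly origin-wrapping) subsequence
#'
#' @param genome A [circular_genome()].
#' @param start,end 1-based inclusive coordinates. When `start > end` the
#'   extraction wraps through the origin.
#' @return Character string.
#' @export
subseq_circular <- function(genome, start, end) {
  L <- genome$length
  stopifnot(start >= 1, start <= L, end >= 1, end <= L)
  if (start <= end) {
    substr(genome$sequence, start, end)
  } else {
    paste0(substr(genome$sequence, start, L), substr(genome$sequence, 1, end))
  }
}

## span length of an interval under circular semantics
span_length <- function(start, end, L) {
  if (start <= end) end - start + 1L else L - start + 1L + end
}

#' Assemble and validate a genome annotation
#'
#' An ordered feature set over a circular genome: protein-coding genes, tRNAs,
#' rRNAs, exactly one control region, introns attached to their host gene, and
#' optionally genes nested inside an intron (the rps3 arrangement, where the
#' ribosomal protein S3 ORF sits inside the conserved rnl intron). All
#' features are on the positive strand, as in *Beauveria* mitogenomes.
#'
#' @param genome A [circular_genome()].
#' @param features `data.frame` with columns `name`, `kind` (one of `"PCG"`,
#'   `"tRNA"`, `"rRNA"`, `"control"`), `start`, `end`, listed in genomic
#'   order. A feature with `start > end` wraps the origin.
#' @param introns Optional `data.frame` with columns `gene`, `start`, `end`
#'   (1-based inclusive, inside the host gene span, disjoint and ordered).
#' @param nested Optional `data.frame` with columns `name`, `host_gene`,
#'   `start`, `end` for genes encoded within an intron of the host.
#' @param strain Strain label carried through reports.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genome, features, introns = NULL, nested = NULL,
                              strain = genome$id) {
  stopifnot(inherits(genome, "circular_genome"), is.data.frame(features))
  req <- c("name", "kind", "start", "end")
  if (!all(req %in% names(features)))
    stop("'features' needs columns: ", paste(req, collapse = ", "))
  features <- features[, req]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$kind <- as.character(features$kind)
  features$name <- as.character(features$name)
  L <- genome$length

  if (anyDuplicated(features$name))
    stop("duplicate feature names: ",
         paste(unique(features$name[duplicated(features$name)]), collapse = ", "))
  bad <- features$start < 1 | features$start > L | features$end < 1 | features$end > L
  if (any(bad))
    stop("feature coordinates out of range [1, ", L, "]: ",
         paste(features$name[bad], collapse = ", "))
  if (!all(features$kind %in% c("PCG", "tRNA", "rRNA", "control")))
    stop("unknown feature kind")
  if (sum(features$kind == "control") != 1L)
    stop("annotation must contain exactly one control region")
  features$wraps <- features$start > features$end

  ## genomic order: starts strictly increasing after rotating to feature 1
  rel <- (features$start - features$start[1L]) %% L
  if (is.unsorted(rel, strictly = TRUE))
    stop("features are not listed in circular genomic order")

  if (is.null(introns)) {
    introns <- data.frame(gene = character(), start = integer(), end = integer())
  } else {
    stopifnot(all(c("gene", "start", "end") %in% names(introns)))
    introns <- data.frame(gene = as.character(introns$gene),
                          start = as.integer(introns$start),
                          end = as.integer(introns$end))
    for (g in unique(introns$gene)) {
      i <- match(g, features$name)
      if (is.na(i)) stop("intron host gene not annotated: ", g)
      gi <- introns[introns$gene == g, , drop = FALSE]
      gi <- gi[order(gi$start), ]
      fs <- features$start[i]; fe <- features$end[i]
      rel_s <- (gi$start - fs) %% L
      rel_e <- (gi$end - fs) %% L
      span <- span_length(fs, fe, L)
      if (any(rel_s > rel_e) || any(rel_e >= span))
        stop("intron outside host gene span: ", g)
      if (nrow(gi) > 1L && any(rel_s[-1L] <= rel_e[-nrow(gi)]))
        stop("introns of ", g, " overlap or are unordered")
    }
    introns <- introns[order(match(introns$gene, features$name), introns$start), ]
    rownames(introns) <- NULL
  }
  introns$index <- stats::ave(seq_len(nrow(introns)), introns$gene,
                              FUN = seq_along)

  if (is.null(nested)) {
    nested <- data.frame(name = character(), host_gene = character(),
                         start = integer(), end = integer())
  } else {
    stopifnot(all(c("name", "host_gene", "start", "end") %in% names(nested)))
    nested <- data.frame(name = as.character(nested$name),
                         host_gene = as.character(nested$host_gene),
                         start = as.integer(nested$start),
                         end = as.integer(nested$end))
    for (k in seq_len(nrow(nested))) {
      hi <- introns[introns$gene == nested$host_gene[k], , drop = FALSE]
      inside <- any(hi$start <= nested$start[k] & nested$end[k] <= hi$end)
      if (!inside)
        stop("nested gene ", nested$name[k], " not inside an intron of ",
             nested$host_gene[k])
    }
  }

  structure(
    list(genome = genome, features = features, introns = introns,
         nested = nested, strain = strain, strand = "+"),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  kinds <- table(factor(x$features$kind, c("PCG", "tRNA", "rRNA", "control")))
  cat(sprintf(
    "<genome_annotation> %s (%s bp): %d PCG, %d tRNA, %d rRNA, %d control; %d introns, %d nested\n",
    x$strain, format(x$genome$length, big.mark = ","),
    kinds[["PCG"]], kinds[["tRNA"]], kinds[["rRNA"]], kinds[["control"]],
    nrow(x$introns), nrow(x$nested)))
  invisible(x)
}

#' Top-level genes of an annotation
#'
#' Features in genomic order excluding the control region (and excluding
#' nested genes, which are not independent transcription units).
#'
#' @param ann A [genome_annotation()].
#' @return `data.frame` of gene features.
#' @export
genes <- function(ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  out <- ann$features[ann$features$kind != "control", , drop = FALSE]
  rownames(out) <- NULL
  out
}

feature_row <- function(ann, name) {
  i <- match(name, ann$features$name)
  if (is.na(i)) stop("feature not annotated: ", name)
  ann$features[i, , drop = FALSE]
}

#' Nucleotide composition and strand skew statistics
#'
#' Counts A/C/G/T/N and computes AT content, AT skew `(A - T)/(A + T)` and
#' GC skew `(G - C)/(G + C)` (Perna & Kocher style strand-asymmetry
#' statistics). `N` bases are excluded from every denominator; a skew whose
#' denominator is zero is reported as `NA`.
#'
#' @param seq Nucleotide string (or `circular_genome`).
#' @return A list of class `composition_stats` with `counts`, `at_percent`,
#'   `gc_percent`, `at_skew`, `gc_skew`.
#' @examples
#' composition_stats("AATG")$at_skew  # (2-1)/3
#' @export
composition_stats <- function(seq) {
  if (inherits(seq, "circular_genome")) seq <- seq$sequence
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("empty sequence")
  fr <- Biostrings::alphabetFrequency(Biostrings::DNAString(toupper(seq)))
  counts <- c(A = fr[["A"]], C = fr[["C"]], G = fr[["G"]], T = fr[["T"]],
              N = fr[["N"]])
  acgt <- sum(counts[c("A", "C", "G", "T")])
  at <- counts[["A"]] + counts[["T"]]
  gc <- counts[["G"]] + counts[["C"]]
  structure(list(
    counts = counts,
    at_percent = if (acgt > 0L) 100 * at / acgt else NA_real_,
    gc_percent = if (acgt > 0L) 100 * gc / acgt else NA_real_,
    at_skew = if (at > 0) (counts[["A"]] - counts[["T"]]) / at else NA_real_,
    gc_skew = if (gc > 0) (counts[["G"]] - counts[["C"]]) / gc else NA_real_
  ), class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf("AT%% %.2f | AT-skew %s | GC-skew %s\n", x$at_percent,
              formatC(x$at_skew, digits = 4, format = "f"),
              formatC(x$gc_skew, digits = 4, format = "f")))
  invisible(x)
}

as_interval <- function(x, ann = NULL) {
  if (is.numeric(x) && length(x) == 2L)
    return(list(start = as.integer(x[1L]), end = as.integer(x[2L])))
  if (is.data.frame(x) && nrow(x) == 1L && all(c("start", "end") %in% names(x)))
    return(list(start = as.integer(x$start), end = as.integer(x$end)))
  if (is.list(x) && all(c("start", "end") %in% names(x)))
    return(list(start = as.integer(x$start), end = as.integer(x$end)))
  if (is.character(x) && length(x) == 1L && !is.null(ann))
    return(as_interval(feature_row(ann, x)))
  stop("cannot interpret interval: supply c(start, end), a feature row, ",
       "or a feature name together with an annotation")
}

#' Gap between two circularly ordered intervals
#'
#' Number of bases strictly between the end of `a` and the start of `b`
#' (`start(b) - end(a) - 1` on the rotation that makes the operands
#' contiguous). A negative value means the intervals overlap by that many
#' bases; 0 means they abut. `a` must precede `b` in circular order.
#'
#' @param a,b Intervals: numeric `c(start, end)`, a single feature row, or a
#'   feature name (then `genome` must be a [genome_annotation()]).
#' @param genome A [circular_genome()], a [genome_annotation()], or the
#'   genome length.
#' @return Integer gap in bp (negative = overlap).
#' @examples
#' gap_between(c(25000, 25172), c(25199, 25400), 30000)  # 26
#' @export
gap_between <- function(a, b, genome) {
  ann <- NULL
  if (inherits(genome, "genome_annotation")) {
    ann <- genome
    genome <- genome$genome
  }
  L <- if (inherits(genome, "circular_genome")) genome$length
       else as.integer(genome)
  a <- as_interval(a, ann)
  b <- as_interval(b, ann)
  if (identical(a, b)) stop("identical intervals have no defined gap")
  d <- b$start - a$end - 1L
  ## rotate when the nearer representation crosses the origin
  if (d < -(L / 2)) d <- d + L
  as.integer(d)
}

## circular overlap in bp between two intervals given as start/end lists
circ_overlap <- function(a, b, L) {
  pieces <- function(iv) {
    if (iv$start <= iv$end) list(c(iv$start, iv$end))
    else list(c(iv$start, L), c(1L, iv$end))
  }
  tot <- 0L
  for (p in pieces(a)) for (q in pieces(b)) {
    tot <- tot + max(0L, min(p[2L], q[2L]) - max(p[1L], q[1L]) + 1L)
  }
  tot
}

#' Catalogue intergenic, overlapping and intronic regions
#'
#' Classifies every adjacent top-level feature pair (control region included,
#' wrap-around pair through the origin included) as intergenic (gap >= 1 bp),
#' overlapping (overlap >= 1 bp) or abutting (gap 0), and totals the
#' intergenic and intronic base counts. The intron fraction is
#' `100 * intron_total_bp / genome length`.
#'
#' @param ann A [genome_annotation()].
#' @return A list of class `region_catalogue` with `intergenic`, `overlaps`,
#'   `abutting` data.frames plus `total_intergenic_bp`, `intergenic_fraction`,
#'   `intron_total_bp`, `intron_fraction`.
#' @export
region_catalogue <- function(ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  fe <- ann$features
  L <- ann$genome$length
  n <- nrow(fe)

  ## non-adjacent features must not overlap
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    adjacent <- (j - i == 1L) || (i == 1L && j == n)
    if (adjacent) next
    ov <- circ_overlap(as_interval(fe[i, ]), as_interval(fe[j, ]), L)
    if (ov > 0L)
      stop("non-adjacent features overlap: ", fe$name[i], " / ", fe$name[j])
  }

  up <- fe$name
  dn <- fe$name[c(seq_len(n)[-1L], 1L)]
  gaps <- vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    gap_between(fe[i, ], fe[j, ], L)
  }, integer(1))

  pairs <- data.frame(upstream = up, downstream = dn, gap = gaps)
  intergenic <- pairs[pairs$gap >= 1L, ]
  overlaps <- pairs[pairs$gap <= -1L, ]
  overlaps$overlap <- -overlaps$gap
  abutting <- pairs[pairs$gap == 0L, ]
  rownames(intergenic) <- rownames(overlaps) <- rownames(abutting) <- NULL

  intron_bp <- if (nrow(ann$introns)) {
    sum(vapply(seq_len(nrow(ann$introns)), function(k)
      span_length(ann$introns$start[k], ann$introns$end[k], L), integer(1)))
  } else 0L

  structure(list(
    intergenic = intergenic,
    overlaps = overlaps[, c("upstream", "downstream", "overlap")],
    abutting = abutting[, c("upstream", "downstream")],
    total_intergenic_bp = sum(intergenic$gap),
    intergenic_fraction = 100 * sum(intergenic$gap) / L,
    intron_total_bp = intron_bp,
    intron_fraction = 100 * intron_bp / L,
    genome_length = L
  ), class = "region_catalogue")
}

#' @export
print.region_catalogue <- function(x, ...) {
  cat(sprintf(
    "<region_catalogue> %d intergenic (%s bp, %.2f%%), %d overlapping, %d abutting; introns %s bp (%.2f%%)\n",
    nrow(x$intergenic), format(x$total_intergenic_bp, big.mark = ","),
    x$intergenic_fraction, nrow(x$overlaps), nrow(x$abutting),
    format(x$intron_total_bp, big.mark = ","), x$intron_fraction))
  invisible(x)
}

#' Per-gene intron count table across strains
#'
#' One row per strain, one column per intron-bearing gene (the canonical
#' column set `rnl, cox2, nad5, cob, cox1, nad1` always present, extra genes
#' appended when they carry introns), plus a `Total` column equal to the row
#' sum.
#'
#' @param annotations List of [genome_annotation()] objects, or a
#'   `data.frame` of per-gene intron counts (one row per strain, genes as
#'   columns) from which only the `Total` is recomputed.
#' @return `data.frame` with a `strain` column, per-gene counts and `Total`.
#' @export
intron_count_table <- function(annotations) {
  canonical <- c("rnl", "cox2", "nad5", "cob", "cox1", "nad1")
  if (is.data.frame(annotations)) {
    df <- annotations
    genecols <- setdiff(names(df), c("strain", "Total"))
    df$Total <- as.integer(rowSums(df[, genecols, drop = FALSE]))
    return(df)
  }
  stopifnot(is.list(annotations), length(annotations) >= 1L)
  rows <- lapply(annotations, function(ann) {
    stopifnot(inherits(ann, "genome_annotation"))
    tab <- table(ann$introns$gene)
    cnt <- stats::setNames(rep(0L, length(canonical)), canonical)
    extra <- setdiff(names(tab), canonical)
    cnt[names(tab)[names(tab) %in% canonical]] <-
      as.integer(tab[names(tab) %in% canonical])
    c(cnt, stats::setNames(as.integer(tab[extra]), extra))
  })
  allcols <- unique(unlist(lapply(rows, names)))
  out <- as.data.frame(do.call(rbind, lapply(rows, function(r) {
    full <- stats::setNames(rep(0L, length(allcols)), allcols)
    full[names(r)] <- r
    full
  })))
  out <- cbind(strain = vapply(annotations, function(a) a$strain, character(1)),
               out)
  out$Total <- as.integer(rowSums(out[, allcols, drop = FALSE]))
  rownames(out) <- NULL
  out
}

#' Locate a genomic position within the annotation
#'
#' Deterministically labels a 1-based position as exon of a gene, intron k of
#' a gene, control, or intergenic. Positions inside a nested gene (rps3 in
#' the rnl intron) report both the nested gene and the host intron.
#'
#' @param position 1-based coordinate.
#' @param ann A [genome_annotation()].
#' @return List with `label`, `feature`, `intron`, `nested`, `host`.
#' @export
locate_position <- function(position, ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  L <- ann$genome$length
  position <- as.integer(position)
  if (position < 1L || position > L)
    stop("position out of range [1, ", L, "]")

  inside <- function(s, e) {
    if (s <= e) position >= s & position <= e
    else position >= s | position <= e
  }

  ## nested genes take precedence: report both the gene and the host intron
  if (nrow(ann$nested)) {
    for (k in seq_len(nrow(ann$nested))) {
      nd <- ann$nested[k, ]
      if (inside(nd$start, nd$end)) {
        hi <- ann$introns[ann$introns$gene == nd$host_gene, ]
        idx <- hi$index[hi$start <= position & position <= hi$end]
        return(list(label = sprintf("exon of %s (intron %d of %s)",
                                    nd$name, idx, nd$host_gene),
                    feature = nd$name, intron = idx, nested = nd$name,
                    host = nd$host_gene))
      }
    }
  }
  if (nrow(ann$introns)) {
    for (k in seq_len(nrow(ann$introns))) {
      iv <- ann$introns[k, ]
      if (inside(iv$start, iv$end))
        return(list(label = sprintf("intron %d of %s", iv$index, iv$gene),
                    feature = iv$gene, intron = iv$index,
                    nested = NA_character_, host = NA_character_))
    }
  }
  for (i in seq_len(nrow(ann$features))) {
    fr <- ann$features[i, ]
    if (inside(fr$start, fr$end)) {
      if (fr$kind == "control")
        return(list(label = "control", feature = fr$name,
                    intron = NA_integer_, nested = NA_character_,
                    host = NA_character_))
      return(list(label = sprintf("exon of %s", fr$name), feature = fr$name,
                  intron = NA_integer_, nested = NA_character_,
                  host = NA_character_))
    }
  }
  list(label = "intergenic", feature = NA_character_, intron = NA_integer_,
       nested = NA_character_, host = NA_character_)
}

#' Rotate the origin of an annotated circular genome
#'
#' Shifts all coordinates so that old position `shift + 1` becomes position 1.
#' Useful before GFF3 export when a feature wraps the origin.
#'
#' @param ann A [genome_annotation()].
#' @param shift Integer number of bases to rotate (0 <= shift < length).
#' @return A new [genome_annotation()] on the rotated genome.
#' @export
rotate_origin <- function(ann, shift) {
  stopifnot(inherits(ann, "genome_annotation"))
  L <- ann$genome$length
  shift <- as.integer(shift) %% L
  if (shift == 0L) return(ann)
  seq <- paste0(substr(ann$genome$sequence, shift + 1L, L),
                substr(ann$genome$sequence, 1L, shift))
  mv <- function(p) circ_pos(p - shift, L)
  fe <- ann$features
  fe$start <- mv(fe$start); fe$end <- mv(fe$end)
  ## re-establish listing order starting from the feature nearest new origin
  first <- which.min(fe$start)
  ord <- c(first:nrow(fe), seq_len(first - 1L))
  ## keep circular order as before rotation; reorder only the listing
  fe <- fe[ord, , drop = FALSE]
  rownames(fe) <- NULL
  introns <- ann$introns
  if (nrow(introns)) {
    introns$start <- mv(introns$start); introns$end <- mv(introns$end)
  }
  nested <- ann$nested
  if (nrow(nested)) {
    nested$start <- mv(nested$start); nested$end <- mv(nested$end)
  }
  genome_annotation(circular_genome(ann$genome$id, seq),
                    fe[, c("name", "kind", "start", "end")],
                    introns = introns[, c("gene", "start", "end")],
                    nested = nested, strain = ann$strain)
}
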