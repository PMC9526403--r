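# Group I intron boundary checks, in-silico splicing and intron ORF scans.
#
# Boundary rules are evaluated on the DNA sense strand (U == T): a group I
# intron is flagged by a T at the 3' end of the upstream exon and a G at the
# 3' end of the intron; the splice-site dinucleotide model is GT..AG. Both are
# soft checks (flags, not filters) because the source observations are
# tendencies, not absolutes.

gene_introns <- function(ann, gene) {
  ann$introns[ann$introns$gene == gene, , drop = FALSE]
}

#' Check group I / GT-AG splice boundaries of a gene's introns
#'
#' For each intron of `gene`, reports the last base of the upstream exon, the
#' first and last dinucleotides of the intron, and two independent flags:
#' `group1_ok` (upstream exon ends in T and intron ends in G) and `gtag_ok`
#' (intron starts GT and ends AG).
#'
#' @param gene Gene name.
#' @param ann A [genome_annotation()].
#' @return `data.frame` with one row per intron.
#' @export
check_splice_boundaries <- function(gene, ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  iv <- gene_introns(ann, gene)
  if (nrow(iv) == 0L) stop("gene has no annotated introns: ", gene)
  fr <- feature_row(ann, gene)
  L <- ann$genome$length
  g <- ann$genome

  out <- lapply(seq_len(nrow(iv)), function(k) {
    s <- iv$start[k]; e <- iv$end[k]
    rel_s <- (s - fr$start) %% L
    rel_e <- (e - fr$start) %% L
    if (rel_s > rel_e || rel_e >= span_length(fr$start, fr$end, L))
      stop("intron outside gene span: ", gene)
    up <- subseq_circular(g, circ_pos(s - 1L, L), circ_pos(s - 1L, L))
    last <- subseq_circular(g, e, e)
    first2 <- subseq_circular(g, s, circ_pos(s + 1L, L))
    last2 <- subseq_circular(g, circ_pos(e - 1L, L), e)
    data.frame(gene = gene, intron = iv$index[k], start = s, end = e,
               upstream_exon_last = up, intron_last = last,
               first_two = first2, last_two = last2,
               group1_ok = up == "T" && last == "G",
               gtag_ok = first2 == "GT" && last2 == "AG")
  })
  do.call(rbind, out)
}

#' Splice a gene in silico
#'
#' Concatenates the exon segments of a gene in order, removing annotated
#' introns. Identity for intronless genes.
#'
#' @param gene Gene name.
#' @param ann A [genome_annotation()].
#' @return Spliced nucleotide string.
#' @export
splice_gene <- function(gene, ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  fr <- feature_row(ann, gene)
  L <- ann$genome$length
  full <- subseq_circular(ann$genome, fr$start, fr$end)
  iv <- gene_introns(ann, gene)
  if (nrow(iv) == 0L) return(full)
  rel_s <- (iv$start - fr$start) %% L + 1L
  rel_e <- (iv$end - fr$start) %% L + 1L
  keep <- rep(TRUE, nchar(full))
  for (k in seq_along(rel_s)) keep[rel_s[k]:rel_e[k]] <- FALSE
  paste(strsplit(full, "", fixed = TRUE)[[1L]][keep], collapse = "")
}

## forward-frame ORFs (ATG..stop, stops TAA/TAG/TGA) of length >= min_aa
## codons within a sequence; ORFs may run to the end without a stop.
scan_orfs_fwd <- function(seq, min_aa) {
  n <- nchar(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  res <- list()
  for (frame in 0:2) {
    starts <- seq.int(1L + frame, n - 2L, by = 3L)
    if (length(starts) == 0L) next
    codons <- vapply(starts, function(i)
      paste(bases[i:(i + 2L)], collapse = ""), character(1))
    is_start <- codons == "ATG"
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    i <- 1L
    while (i <= length(codons)) {
      if (is_start[i]) {
        j <- i
        while (j <= length(codons) && !is_stop[j]) j <- j + 1L
        has_stop <- j <= length(codons)
        aa_len <- (if (has_stop) j - i else length(codons) - i + 1L)
        if (aa_len >= min_aa) {
          res[[length(res) + 1L]] <- data.frame(
            frame = frame + 1L,
            start = starts[i],
            end = if (has_stop) starts[j] + 2L else starts[length(starts)] + 2L,
            length_aa = aa_len,
            has_stop = has_stop)
        }
        i <- if (has_stop) j + 1L else length(codons) + 1L
      } else i <- i + 1L
    }
  }
  if (length(res) == 0L)
    return(data.frame(frame = integer(), start = integer(), end = integer(),
                      length_aa = integer(), has_stop = logical()))
  do.call(rbind, res)
}

#' Scan introns of a gene for open reading frames
#'
#' Finds forward-strand ORFs (start codon ATG; stops TAA/TAG/TGA; ORFs
#' reaching the intron boundary without a stop are reported with
#' `has_stop = FALSE`) of at least `min_aa` codons within each intron. An
#' empty result for an intron signals ORF loss. Coordinates are genomic.
#'
#' @param gene Gene name.
#' @param ann A [genome_annotation()].
#' @param min_aa Minimum ORF length in codons (default 50; homing
#'   endonuclease ORFs are long). Must be >= 10.
#' @return `data.frame` with columns `gene`, `intron`, `frame`, `start`,
#'   `end`, `length_aa`, `has_stop`; attribute `has_start_codon` per intron.
#' @export
scan_intron_orfs <- function(gene, ann, min_aa = 50L) {
  stopifnot(inherits(ann, "genome_annotation"), min_aa >= 10L)
  iv <- gene_introns(ann, gene)
  L <- ann$genome$length
  out <- list(); has_start <- logical(nrow(iv))
  for (k in seq_len(nrow(iv))) {
    iseq <- subseq_circular(ann$genome, iv$start[k], iv$end[k])
    has_start[k] <- grepl("ATG", iseq, fixed = TRUE)
    orfs <- scan_orfs_fwd(iseq, min_aa)
    if (nrow(orfs)) {
      orfs$start <- circ_pos(iv$start[k] + orfs$start - 1L, L)
      orfs$end <- circ_pos(iv$start[k] + orfs$end - 1L, L)
      orfs <- cbind(gene = gene, intron = iv$index[k], orfs)
      out[[length(out) + 1L]] <- orfs
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene = character(), intron = integer(), frame = integer(),
               start = integer(), end = integer(), length_aa = integer(),
               has_stop = logical())
  attr(res, "has_start_codon") <-
    stats::setNames(has_start, paste0(gene, "_intron", iv$index))
  res
}

## exon-space insertion coordinate of an intron: number of exon bases of the
## host gene upstream of the intron start
exon_space_site <- function(ann, gene, intron_start) {
  fr <- feature_row(ann, gene)
  L <- ann$genome$length
  iv <- gene_introns(ann, gene)
  rel <- (intron_start - fr$start) %% L
  prior <- iv[((iv$start - fr$start) %% L) < rel & iv$start != intron_start, ,
              drop = FALSE]
  prior_len <- if (nrow(prior))
    sum(vapply(seq_len(nrow(prior)), function(k)
      span_length(prior$start[k], prior$end[k], L), integer(1))) else 0L
  as.integer(rel - prior_len)
}

#' Cross-strain intron presence/absence matrix
#'
#' Builds a strain-by-intron-site matrix in which homologous insertion sites
#' share a column. Sites are matched by host gene plus exon-space insertion
#' coordinate (the position in the spliced gene where the intron sits),
#' within `tol` bp, so strains whose upstream introns differ still align.
#'
#' @param annotations List of two or more [genome_annotation()] objects.
#' @param tol Matching tolerance for insertion sites in exon-space bp
#'   (default 10).
#' @return Integer 0/1 matrix, rows = strains, columns = `gene@site`.
#' @export
intron_presence_matrix <- function(annotations, tol = 10L) {
  stopifnot(is.list(annotations), length(annotations) >= 2L)
  sites <- do.call(rbind, lapply(seq_along(annotations), function(ai) {
    ann <- annotations[[ai]]
    iv <- ann$introns
    if (nrow(iv) == 0L)
      return(data.frame(row = integer(), gene = character(),
                        site = integer()))
    data.frame(row = ai, gene = iv$gene,
               site = vapply(seq_len(nrow(iv)), function(k)
                 exon_space_site(ann, iv$gene[k], iv$start[k]), integer(1)))
  }))
  strains <- vapply(annotations, function(a) a$strain, character(1))
  if (nrow(sites) == 0L)
    return(matrix(0L, length(strains), 0L, dimnames = list(strains, NULL)))

  ## cluster sites per gene by single-linkage within tol
  cols <- list()
  for (g in unique(sites$gene)) {
    s <- sort(unique(sites$site[sites$gene == g]))
    grp <- cumsum(c(1L, diff(s) > tol))
    for (gr in unique(grp)) {
      members <- s[grp == gr]
      cols[[length(cols) + 1L]] <- list(gene = g, sites = members,
                                        label = sprintf("%s@%d", g,
                                                        members[1L]))
    }
  }
  m <- matrix(0L, length(strains), length(cols),
              dimnames = list(strains,
                              vapply(cols, function(cc) cc$label,
                                     character(1))))
  for (k in seq_len(nrow(sites))) {
    for (j in seq_along(cols)) {
      if (cols[[j]]$gene == sites$gene[k] &&
          sites$site[k] %in% cols[[j]]$sites) {
        m[sites$row[k], j] <- 1L
        break
      }
    }
  }
  m
}
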