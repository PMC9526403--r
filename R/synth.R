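# Synthetic circular mitogenome generator with ground truth.
#
# Emulates the assumed RNA-processing model: one or more polycistronic
# primary transcripts initiated near the control region, polyadenylation
# (before splicing by default), group I intron splicing with canonical
# boundaries (upstream exon ends T; intron starts GT, ends AG), and tRNA
# punctuation cleavage that releases mono-/di-/tricistronic RNAs and can
# leave punctuation tRNAs without any sequencing evidence (coverage
# dropout). Transcripts are fragmented into partially overlapping contigs
# the way short-read de novo assemblies are.

#' Simulation configuration
#'
#' Defaults describe a Beauveria-type mitogenome: the canonical 41-gene
#' order with the control region between trnM_3 and trnM_1, an AT content
#' around 73%, 71 bp tRNAs, 2-3 bp gaps inside tRNA clusters and larger gaps
#' elsewhere, an intron plan matching the intron-richest sequenced strain
#' (rnl 2, cox2 1, nad5 1, cob 1, cox1 2, nad1 1; rps3 carried by the last
#' rnl intron), a single transcription unit, polyadenylation before
#' splicing, and a 0.5 probability that a cleaved punctuation tRNA leaves no
#' evidence.
#'
#' @param seed Integer seed driving every random choice.
#' @param strain Strain label for emitted evidence.
#' @param gene_order Character vector of gene names in transcription order.
#' @param intron_plan Named integer vector: gene -> number of introns.
#' @param n_units Number of planted transcription units (`K`); `K - 1`
#'   junctions between protein-coding genes are forced unsupported in
#'   addition to the control-region break.
#' @param polyA_before_splicing Logical; when `TRUE` a polyadenylated,
#'   still intron-containing pre-mRNA enters the sequenced pool.
#' @param trna_dropout Probability that a cleaved punctuation tRNA leaves no
#'   evidence.
#' @param contig_mean,contig_overlap,min_contig Fragmentation parameters in
#'   bp: mean contig length, overlap between successive fragments, minimum
#'   kept piece after tRNA-dropout truncation.
#' @param control_length Control region length in bp.
#' @param at_target Target AT percentage of the genome.
#' @param trna_length tRNA span in bp.
#' @param intron_length_range Intron length range in bp.
#' @param profile `"random"` or `"pseudobassiana_like"` (the deterministic
#'   anchored reference layout, see [pseudobassiana_layout()] sources).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, strain = "sim",
                       gene_order = canonical_gene_order(),
                       intron_plan = c(rnl = 2L, cox2 = 1L, nad5 = 1L,
                                       cob = 1L, cox1 = 2L, nad1 = 1L),
                       n_units = 1L, polyA_before_splicing = TRUE,
                       trna_dropout = 0.5, contig_mean = 2000L,
                       contig_overlap = 100L, min_contig = 40L,
                       control_length = 300L, at_target = 73,
                       trna_length = 71L,
                       intron_length_range = c(800L, 1600L),
                       profile = "random") {
  stopifnot(n_units >= 1L, trna_dropout >= 0, trna_dropout <= 1,
            profile %in% c("random", "pseudobassiana_like"))
  if (anyDuplicated(gene_order))
    stop("gene_order must contain each gene once")
  structure(as.list(environment()), class = "sim_config")
}

## default exon (spliced) lengths in bp; PCG lengths are multiples of 3
default_exon_lengths <- function() {
  c(rnl = 3218L, rns = 1451L,
    nad2 = 1800L, nad3 = 426L, atp9 = 228L, cox2 = 750L, nad4L = 267L,
    nad5 = 1920L, cob = 1182L, cox1 = 2382L, nad1 = 2331L, nad4 = 1017L,
    atp8 = 147L, atp6 = 783L, cox3 = 810L, nad6 = 642L)
}

non_stop_codons <- function() {
  b <- c("A", "C", "G", "T")
  cod <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(cod, c("TAA", "TAG", "TGA"))
}

## sample AT-biased bases / codons
sample_bases <- function(n, at) {
  p <- c(A = at / 200, C = (100 - at) / 200, G = (100 - at) / 200,
         T = at / 200)
  sample(names(p), n, replace = TRUE, prob = p)
}

sample_codons <- function(n, at) {
  cod <- non_stop_codons()
  w <- vapply(strsplit(cod, ""), function(x)
    prod(ifelse(x %in% c("A", "T"), at / 200, (100 - at) / 200)), numeric(1))
  sample(cod, n, replace = TRUE, prob = w)
}

## coding sequence: ATG + non-stop codons + TAA, total length len (mult of 3)
coding_seq <- function(len, at) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  paste0("ATG", paste(sample_codons(len / 3L - 2L, at), collapse = ""), "TAA")
}

assign_seq <- function(chars, start, txt) {
  chars[start:(start + nchar(txt) - 1L)] <- strsplit(txt, "", fixed = TRUE)[[1L]]
  chars
}

#' Generate a synthetic annotated mitogenome with ground truth
#'
#' Lays out the configured gene order on a circular genome (control region
#' at the origin for the random profile), plants introns with canonical
#' group I boundaries (the upstream exon's last base forced to T, intron
#' starting GT and ending AG; for protein-coding hosts introns are inserted
#' at codon boundaries so the reading frame stays stop-free), embeds an rps3
#' ORF in the last rnl intron, and records the planted transcription units.
#'
#' The `"pseudobassiana_like"` profile instead uses a fixed coordinate
#' layout honouring the published anchor coordinates (trnR_2 at
#' 17,359-17,429; trnG from 25,199; trnM_3 ending 5,543; the printed
#' inter-tRNA gaps) with a deterministic internal seed, so the packaged
#' contig table can be interpreted against it.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `mito_sim`: list with `genome`
#'   ([circular_genome()]), `annotation` ([genome_annotation()]), `truth`
#'   (planted `units`, `break_junctions`, `introns`, `rps3`) and `cfg`.
#' @export
make_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$profile == "pseudobassiana_like") return(make_genome_fixture(cfg))
  set.seed(cfg$seed)

  order <- cfg$gene_order
  kinds <- gene_kind(order)
  exon_len <- default_exon_lengths()
  plan <- cfg$intron_plan
  plan <- plan[plan > 0L]
  if (!all(names(plan) %in% order))
    stop("intron plan names genes missing from gene_order: ",
         paste(setdiff(names(plan), order), collapse = ", "))

  ## forced break junctions between protein-coding genes
  candidates <- c("nad3|atp9", "atp9|cox2", "nad1|nad4", "nad4|atp8",
                  "atp8|atp6", "atp6|rns")
  pairs <- paste(order[-length(order)], order[-1L], sep = "|")
  candidates <- candidates[candidates %in% pairs]
  if (cfg$n_units - 1L > length(candidates))
    stop("cannot place ", cfg$n_units - 1L, " breaks; only ",
         length(candidates), " eligible junctions")
  breaks <- sort(match(sample(candidates, cfg$n_units - 1L), pairs))

  ## intron lengths per gene; last rnl intron hosts rps3 and must be long
  intron_lens <- lapply(order, function(g) {
    k <- if (g %in% names(plan)) plan[[g]] else 0L
    if (k == 0L) return(integer())
    lens <- sample(cfg$intron_length_range[1L]:cfg$intron_length_range[2L], k,
                   replace = TRUE)
    if (g == "rnl") lens[k] <- max(lens[k], 1900L)
    lens
  })
  names(intron_lens) <- order

  ## layout
  feats <- data.frame(name = "control", kind = "control", start = 1L,
                      end = cfg$control_length)
  introns <- data.frame(gene = character(), start = integer(),
                        end = integer())
  intron_rel <- list()   # per gene: exon-space insertion offsets
  cursor <- cfg$control_length
  overlap_pairs <- c("nad2|nad3", "nad4L|nad5")
  for (i in seq_along(order)) {
    g <- order[i]
    gap <- if (i == 1L) 2L
      else if ((i - 1L) %in% breaks) sample(200:400, 1L)
      else if (pairs[i - 1L] %in% overlap_pairs) -1L
      else if (kinds[i - 1L] == "tRNA" && kinds[i] == "tRNA") sample(2:3, 1L)
      else if (kinds[i - 1L] == "tRNA" || kinds[i] == "tRNA") sample(20:45, 1L)
      else sample(60:150, 1L)
    start <- cursor + gap + 1L
    elen <- if (kinds[i] == "tRNA") cfg$trna_length else exon_len[[g]]
    ilens <- intron_lens[[g]]
    span <- elen + sum(ilens)
    end <- start + span - 1L
    feats <- rbind(feats, data.frame(name = g, kind = kinds[i],
                                     start = start, end = end))
    if (length(ilens)) {
      ## insertion offsets in exon space; codon-aligned for PCGs so the
      ## forced T before the intron lands on a codon third position
      lo <- 150L; hi <- elen - 150L
      off <- sort(sample(seq(lo, hi, by = 3L), length(ilens)))
      while (any(diff(off) < 30L))
        off <- sort(sample(seq(lo, hi, by = 3L), length(ilens)))
      intron_rel[[g]] <- off
      gstart <- start + off + cumsum(c(0L, ilens[-length(ilens)]))
      introns <- rbind(introns, data.frame(gene = g, start = gstart,
                                           end = gstart + ilens - 1L))
    }
    cursor <- end
  }
  L <- cursor + sample(20:40, 1L)

  ## rps3 inside the last rnl intron
  nested <- NULL
  rps3_iv <- NULL
  if ("rnl" %in% introns$gene) {
    ri <- introns[introns$gene == "rnl", ]
    host <- ri[nrow(ri), ]
    rps3_len <- 1203L
    s <- host$start + 300L
    nested <- data.frame(name = "rps3", host_gene = "rnl", start = s,
                         end = s + rps3_len - 1L)
    rps3_iv <- c(s, s + rps3_len - 1L)
    stopifnot(nested$end <= host$end - 300L)
  }

  chars <- fill_sequences(L, feats, introns, nested, cfg$at_target)
  genome <- circular_genome(cfg$strain, paste(chars, collapse = ""))
  ann <- genome_annotation(genome, feats, introns = introns, nested = nested,
                           strain = cfg$strain)

  ## planted units: gene_order split at forced breaks
  units <- split(order, cumsum(seq_along(order) %in% (breaks + 1L)))
  names(units) <- NULL
  structure(list(
    genome = genome, annotation = ann,
    truth = list(units = units,
                 break_junctions = pairs[breaks],
                 introns = ann$introns, rps3 = rps3_iv),
    cfg = cfg), class = "mito_sim")
}

## deterministic anchored layout (seed pinned so the packaged contig table
## is interpretable against identical coordinates in every session)
make_genome_fixture <- function(cfg) {
  set.seed(90518L)
  lay <- pseudobassiana_layout()
  chars <- fill_sequences(lay$length, lay$features, lay$introns, lay$nested,
                          cfg$at_target)
  genome <- circular_genome("pseudobassiana_like",
                            paste(chars, collapse = ""))
  ann <- genome_annotation(genome, lay$features, introns = lay$introns,
                           nested = lay$nested,
                           strain = "pseudobassiana_like")
  structure(list(
    genome = genome, annotation = ann,
    truth = list(units = list(canonical_gene_order()),
                 break_junctions = character(),
                 introns = ann$introns,
                 rps3 = c(lay$nested$start, lay$nested$end)),
    cfg = cfg), class = "mito_sim")
}

## sequence filling shared by both profiles; enforces coding frames, group I
## intron boundary bases and the nested rps3 ORF. The non-coding background
## is calibrated in a second pass so the whole-genome AT content hits the
## target despite the codon-level constraints.
fill_sequences <- function(L, feats, introns, nested, at_target) {
  chars <- rep(NA_character_, L)

  exon_positions <- function(fr) {
    pos <- if (fr$start <= fr$end) fr$start:fr$end else c(fr$start:L, 1:fr$end)
    gi <- introns[introns$gene == fr$name, , drop = FALSE]
    for (k in seq_len(nrow(gi))) {
      ip <- if (gi$start[k] <= gi$end[k]) gi$start[k]:gi$end[k]
            else c(gi$start[k]:L, 1:gi$end[k])
      pos <- setdiff(pos, ip)
    }
    pos
  }

  for (i in seq_len(nrow(feats))) {
    fr <- feats[i, ]
    if (fr$kind != "PCG") next
    pos <- exon_positions(fr)
    cds <- coding_seq(length(pos), at_target)
    chars[pos] <- strsplit(cds, "", fixed = TRUE)[[1L]]
  }

  ## group I boundaries: upstream exon ends T; intron starts GT, ends AG
  for (k in seq_len(nrow(introns))) {
    s <- introns$start[k]; e <- introns$end[k]
    chars[circ_pos(s - 1L, L)] <- "T"
    chars[s] <- "G"; chars[circ_pos(s + 1L, L)] <- "T"
    chars[circ_pos(e - 1L, L)] <- "A"; chars[e] <- "G"
  }

  if (!is.null(nested) && nrow(nested)) {
    for (k in seq_len(nrow(nested))) {
      len <- nested$end[k] - nested$start[k] + 1L
      chars <- assign_seq(chars, nested$start[k],
                          coding_seq(len, at_target))
    }
  }

  ## calibrate the remaining background to the genome-wide AT target
  bg <- which(is.na(chars))
  if (length(bg)) {
    at_fixed <- sum(chars %in% c("A", "T"), na.rm = TRUE)
    p_at <- (at_target / 100 * L - at_fixed) / length(bg)
    p_at <- min(max(p_at, 0.05), 0.95)
    p <- c(A = p_at / 2, C = (1 - p_at) / 2, G = (1 - p_at) / 2,
           T = p_at / 2)
    chars[bg] <- sample(names(p), length(bg), replace = TRUE, prob = p)
  }
  chars
}

## ---- RNA processing -------------------------------------------------------

## convert an unrolled interval [a, b] (b may exceed L) into genomic segments
unroll_to_segments <- function(a, b, L) {
  segs <- list()
  while (a <= b) {
    hi <- min(b, ceiling(a / L) * L)
    segs[[length(segs) + 1L]] <-
      data.frame(gstart = circ_pos(a, L), gend = circ_pos(hi, L))
    a <- hi + 1L
  }
  do.call(rbind, segs)
}

## subtract a set of unrolled intervals from [a, b]
unrolled_minus <- function(a, b, cuts) {
  if (nrow(cuts) == 0L) return(data.frame(us = a, ue = b))
  cuts <- cuts[order(cuts$us), , drop = FALSE]
  out <- list(); cur <- a
  for (k in seq_len(nrow(cuts))) {
    if (cuts$ue[k] < a || cuts$us[k] > b) next
    if (cuts$us[k] > cur)
      out[[length(out) + 1L]] <- data.frame(us = cur, ue = cuts$us[k] - 1L)
    cur <- max(cur, cuts$ue[k] + 1L)
  }
  if (cur <= b) out[[length(out) + 1L]] <- data.frame(us = cur, ue = b)
  if (length(out) == 0L) return(data.frame(us = integer(), ue = integer()))
  do.call(rbind, out)
}

## unroll a genomic interval relative to anchor a0 (result >= a0)
unroll_iv <- function(s, e, a0, L) {
  len <- span_length(s, e, L)
  us <- s + ceiling((a0 - s) / L) * L
  if (us < a0) us <- us + L
  c(us, us + len - 1L)
}

#' Simulate transcription and RNA maturation
#'
#' For each planted unit, emits the molecule set implied by the processing
#' order: a primary polycistronic transcript (initiated upstream of the
#' first gene, inside the control region for the control-adjacent unit), a
#' polyadenylated pre-mRNA that still contains introns (only when
#' `polyA_before_splicing`), the spliced polyadenylated polycistron, and the
#' tRNA-punctuation cleavage products (mono-/oligocistronic mRNAs, each
#' polyadenylated, plus the excised tRNAs).
#'
#' @param sim A [make_genome()] result.
#' @return List of molecules; each has `id`, `stage`, `unit`, `segments`
#'   (genomic `gstart`/`gend` rows in transcript order), `polyA`,
#'   `contains_intron`.
#' @export
simulate_processing <- function(sim) {
  stopifnot(inherits(sim, "mito_sim"))
  cfg <- sim$cfg
  set.seed(cfg$seed + 1000L)
  ann <- sim$annotation
  L <- ann$genome$length
  fe <- ann$features
  mols <- list()
  add <- function(stage, unit, segs_unrolled, polyA, contains_intron) {
    segs <- do.call(rbind, lapply(seq_len(nrow(segs_unrolled)), function(k)
      unroll_to_segments(segs_unrolled$us[k], segs_unrolled$ue[k], L)))
    mols[[length(mols) + 1L]] <<- list(
      id = sprintf("m%02d", length(mols) + 1L),
      stage = stage, unit = unit, segments = segs, polyA = polyA,
      contains_intron = contains_intron)
  }

  for (uk in seq_along(sim$truth$units)) {
    ug <- sim$truth$units[[uk]]
    first <- feature_row(ann, ug[1L]); last <- feature_row(ann, ug[length(ug)])
    ## extensions into the flanking gaps (control region upstream of the
    ## control-adjacent unit)
    prev_i <- match(ug[1L], fe$name) - 1L
    if (prev_i == 0L) prev_i <- nrow(fe)
    gap5 <- gap_between(fe[prev_i, ], first, L)
    next_i <- match(ug[length(ug)], fe$name) %% nrow(fe) + 1L
    gap3 <- gap_between(last, fe[next_i, ], L)
    ## stay within half the flanking gap so neighbouring units never overlap
    ext5 <- min(max((gap5 - 1L) %/% 2L, 0L), sample(30:120, 1L))
    ext3 <- min(max((gap3 - 1L) %/% 2L, 0L), sample(80:150, 1L))

    a0 <- first$start - ext5
    span <- unroll_iv(circ_pos(a0, L), circ_pos(last$end + ext3, L),
                      circ_pos(a0, L), L)
    a <- span[1L]; b <- span[2L]

    ## unrolled intron and tRNA cut lists within the unit span
    unroll_rows <- function(df) {
      if (nrow(df) == 0L)
        return(data.frame(us = integer(), ue = integer()))
      out <- lapply(seq_len(nrow(df)), function(k) {
        uv <- unroll_iv(df$start[k], df$end[k], a, L)
        if (uv[1L] >= a && uv[2L] <= b) data.frame(us = uv[1L], ue = uv[2L])
        else NULL
      })
      out <- do.call(rbind, out)
      if (is.null(out)) data.frame(us = integer(), ue = integer()) else out
    }
    introns_u <- unroll_rows(ann$introns)
    trnas <- fe[fe$kind == "tRNA" & fe$name %in% ug, , drop = FALSE]
    trnas_u <- unroll_rows(trnas)

    has_intron <- nrow(introns_u) > 0L
    add("primary", uk, data.frame(us = a, ue = b), FALSE, has_intron)
    if (cfg$polyA_before_splicing)
      add("pre_mRNA_polyA", uk, data.frame(us = a, ue = b), TRUE, has_intron)
    spliced <- unrolled_minus(a, b, introns_u)
    add("spliced_polyA", uk, spliced, TRUE, FALSE)

    ## tRNA punctuation cleavage of the spliced polycistron
    if (nrow(trnas_u)) {
      keep <- unrolled_minus(a, b, trnas_u)
      for (r in seq_len(nrow(keep))) {
        pieces <- unrolled_minus(keep$us[r], keep$ue[r], introns_u)
        if (nrow(pieces) && sum(pieces$ue - pieces$us + 1L) >= 50L)
          add("cleaved_mRNA", uk, pieces, TRUE, FALSE)
      }
      for (r in seq_len(nrow(trnas_u)))
        add("cleaved_tRNA", uk,
            data.frame(us = trnas_u$us[r], ue = trnas_u$ue[r]), FALSE, FALSE)
    } else {
      add("cleaved_mRNA", uk, spliced, TRUE, FALSE)
    }
  }
  mols
}

#' Fragment simulated transcripts into contig and read evidence
#'
#' Samples the polyadenylated molecule pool (polyA selection: molecules
#' without a tail are not sequenced), fragments long molecules into
#' partially overlapping contigs, injects coverage dropout at cleaved
#' punctuation tRNAs (each punctuation tRNA independently loses all its
#' evidence with probability `trna_dropout`, truncating any contig that
#' crossed it), and emits read records: splice-junction reads, reads
#' crossing exon/intron boundaries (only when polyadenylation precedes
#' splicing), a wrap-around read for the rnl head/tail, 3'-terminal reads
#' carrying polyA soft clips, and plain exonic reads.
#'
#' @param sim A [make_genome()] result.
#' @param molecules A [simulate_processing()] result.
#' @return List: `contigs` (`data.frame` with `contig_id`, `strain`,
#'   `start`, `end`, `gene_content`, `segments` list column, `source`),
#'   `reads` (list of [read_alignment()]), `dropped_trnas`, `polyA_sites`.
#' @export
fragment_to_evidence <- function(sim, molecules) {
  stopifnot(inherits(sim, "mito_sim"))
  cfg <- sim$cfg
  set.seed(cfg$seed + 2000L)
  ann <- sim$annotation
  L <- ann$genome$length
  fe <- ann$features

  punct <- unlist(lapply(sim$truth$units, function(ug)
    ug[gene_kind(ug) == "tRNA"]))
  dropped <- punct[stats::runif(length(punct)) < cfg$trna_dropout]
  dropped_iv <- lapply(dropped, function(g) as_interval(feature_row(ann, g)))

  pool <- Filter(function(m) isTRUE(m$polyA), molecules)

  raw <- list()
  emit <- function(segs, source) {
    raw[[length(raw) + 1L]] <<- list(segments = segs, source = source)
  }

  for (m in pool) {
    seg <- m$segments
    tot <- sum(seg$gend - seg$gstart + 1L)
    if (m$stage == "spliced_polyA" && tot > 1.5 * cfg$contig_mean) {
      ## overlapping fragments along the molecule footprint
      offs <- list(); cur <- 1L
      while (cur <= tot) {
        len <- max(400L, min(2L * cfg$contig_mean,
                             round(stats::rnorm(1, cfg$contig_mean,
                                                cfg$contig_mean / 4))))
        offs[[length(offs) + 1L]] <- c(cur, min(tot, cur + len - 1L))
        if (cur + len - 1L >= tot) break
        cur <- cur + len - cfg$contig_overlap
      }
      ## map footprint offsets back to genomic segments
      cumlen <- cumsum(seg$gend - seg$gstart + 1L)
      cum0 <- c(0L, cumlen[-length(cumlen)])
      for (o in offs) {
        pieces <- list()
        for (si in seq_len(nrow(seg))) {
          lo <- max(o[1L], cum0[si] + 1L); hi <- min(o[2L], cumlen[si])
          if (lo > hi) next
          pieces[[length(pieces) + 1L]] <- data.frame(
            gstart = seg$gstart[si] + (lo - cum0[si] - 1L),
            gend = seg$gstart[si] + (hi - cum0[si] - 1L))
        }
        emit(do.call(rbind, pieces), m$id)
      }
    } else if (m$stage == "pre_mRNA_polyA") {
      ## contigs straddling each intron retained in this molecule
      a <- seg$gstart[1L]; b <- a + tot - 1L
      for (k in seq_len(nrow(ann$introns))) {
        iv <- ann$introns[k, ]
        uv <- unroll_iv(iv$start, iv$end, a, L)
        if (uv[1L] < a || uv[2L] > b) next
        emit(unroll_to_segments(max(a, uv[1L] - 200L),
                                min(b, uv[2L] + 200L), L), m$id)
      }
    } else {
      ## short spliced polycistrons always assemble (deep unit coverage);
      ## cleaved products are recovered most but not all of the time
      if (m$stage != "spliced_polyA" && stats::runif(1) > 0.7) next
      trim5 <- sample(0:30, 1L); trim3 <- sample(0:30, 1L)
      s2 <- seg
      s2$gstart[1L] <- s2$gstart[1L] + trim5
      s2$gend[nrow(s2)] <- s2$gend[nrow(s2)] - trim3
      if (all(s2$gend >= s2$gstart)) emit(s2, m$id)
    }
  }

  ## dropout: truncate evidence at dropped tRNA spans (segments and feature
  ## spans are both plain genomic intervals here)
  truncate_segments <- function(segs) {
    for (iv in dropped_iv) {
      out <- list()
      for (si in seq_len(nrow(segs))) {
        kept <- unrolled_minus(segs$gstart[si], segs$gend[si],
                               data.frame(us = iv$start, ue = iv$end))
        if (nrow(kept))
          out[[length(out) + 1L]] <-
            data.frame(gstart = kept$us, gend = kept$ue)
      }
      segs <- if (length(out)) do.call(rbind, out) else
        data.frame(gstart = integer(), gend = integer())
    }
    segs
  }

  contigs <- list(); seg_list <- list(); cid <- 0L
  for (rc in raw) {
    segs <- truncate_segments(rc$segments)
    if (nrow(segs) == 0L) next
    ## split into runs of segments not separated by a removed tRNA span:
    ## consecutive original segments stay one contig only while contiguous
    ## in transcript space; after truncation keep maximal groups whose
    ## between-gap is not a dropped tRNA
    grp <- 1L; grps <- integer(nrow(segs))
    grps[1L] <- 1L
    if (nrow(segs) > 1L) for (si in 2:nrow(segs)) {
      gapiv <- list(start = circ_pos(segs$gend[si - 1L] + 1L, L),
                    end = circ_pos(segs$gstart[si] - 1L, L))
      gap_is_drop <- FALSE
      if ((segs$gstart[si] - segs$gend[si - 1L]) %% L != 1L) {
        for (iv in dropped_iv)
          if (circ_overlap(gapiv, iv, L) > 0L) gap_is_drop <- TRUE
      }
      if (gap_is_drop) grp <- grp + 1L
      grps[si] <- grp
    }
    for (g in unique(grps)) {
      sub <- segs[grps == g, , drop = FALSE]
      if (sum(sub$gend - sub$gstart + 1L) < cfg$min_contig) next
      cid <- cid + 1L
      span_s <- sub$gstart[1L]; span_e <- sub$gend[nrow(sub)]
      content <- gene_content_label(c(span_s, span_e), ann)
      content <- content[vapply(content, function(gn) {
        any(vapply(seq_len(nrow(sub)), function(si)
          circ_overlap(list(start = sub$gstart[si], end = sub$gend[si]),
                       as_interval(feature_row(ann, gn)), L) > 0L,
          logical(1)))
      }, logical(1))]
      contigs[[cid]] <- data.frame(
        contig_id = sprintf("S%03d", cid), strain = cfg$strain,
        start = span_s, end = span_e,
        gene_content = paste(content, collapse = "-"),
        source = rc$source)
      seg_list[[cid]] <- sub
    }
  }
  contig_df <- if (length(contigs)) do.call(rbind, contigs) else
    data.frame(contig_id = character(), strain = character(),
               start = integer(), end = integer(),
               gene_content = character(), source = character())
  contig_df$segments <- seg_list

  ## reads
  reads <- list(); rid <- 0L
  add_read <- function(segments, clip3 = "", tag = "r") {
    ## drop reads touching a dropped tRNA
    for (iv in dropped_iv) for (si in seq_len(nrow(segments))) {
      if (circ_overlap(list(start = segments$gstart[si],
                            end = segments$gend[si]), iv, L) > 0L)
        return(invisible(NULL))
    }
    rid <<- rid + 1L
    reads[[length(reads) + 1L]] <<- read_alignment(
      sprintf("%s%03d", tag, rid), segments, clip3 = clip3)
    invisible(NULL)
  }

  spliced_present <- any(vapply(pool, function(m)
    m$stage %in% c("spliced_polyA", "cleaved_mRNA"), logical(1)))
  pre_present <- any(vapply(pool, function(m)
    m$stage == "pre_mRNA_polyA", logical(1)))
  for (k in seq_len(nrow(ann$introns))) {
    iv <- ann$introns[k, ]
    if (spliced_present)
      add_read(data.frame(
        gstart = c(circ_pos(iv$start - 40L, L), circ_pos(iv$end + 1L, L)),
        gend = c(circ_pos(iv$start - 1L, L), circ_pos(iv$end + 40L, L)),
        rstart = c(1L, 41L), rend = c(40L, 80L)), tag = "spl")
    if (pre_present) {
      add_read(data.frame(gstart = circ_pos(iv$start - 30L, L),
                          gend = circ_pos(iv$start + 29L, L),
                          rstart = 1L, rend = 60L), tag = "bnd")
      add_read(data.frame(gstart = circ_pos(iv$start + 50L, L),
                          gend = circ_pos(iv$start + 129L, L),
                          rstart = 1L, rend = 80L), tag = "int")
    }
  }
  ## rnl head/tail wrap-around read (circularized rnl evidence)
  if ("rnl" %in% fe$name) {
    rnl <- feature_row(ann, "rnl")
    add_read(data.frame(
      gstart = c(circ_pos(rnl$end - 39L, L), rnl$start),
      gend = c(rnl$end, circ_pos(rnl$start + 39L, L)),
      rstart = c(1L, 41L), rend = c(40L, 80L)), tag = "wrap")
  }
  ## polyA 3'-terminal reads
  pa <- list()
  for (m in pool) {
    e <- m$segments$gend[nrow(m$segments)]
    add_read(data.frame(gstart = circ_pos(e - 59L, L), gend = e,
                        rstart = 1L, rend = 60L),
             clip3 = strrep("A", 10L), tag = "pA")
    pa[[length(pa) + 1L]] <- data.frame(molecule = m$id, position = e)
  }
  ## plain exonic reads from protein-coding interiors
  pcg <- fe[fe$kind == "PCG", ]
  for (k in sample(nrow(pcg), min(5L, nrow(pcg)))) {
    fr <- pcg[k, ]
    s <- fr$start + sample(10:50, 1L)
    add_read(data.frame(gstart = s, gend = s + 79L, rstart = 1L, rend = 80L),
             tag = "ex")
  }

  list(contigs = contig_df, reads = reads,
       dropped_trnas = dropped,
       polyA_sites = if (length(pa)) do.call(rbind, pa) else
         data.frame(molecule = character(), position = integer()))
}
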