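# Junction evidence graph and polycistronic unit inference.
#
# Every pair of circularly adjacent genes defines a junction. Contig evidence
# is resolved to runs over the canonical gene order (pooled across strains at
# gene level; coordinate-level rules only for contigs whose printed
# coordinates are consistent with the supplied annotation). Each junction is
# assigned the strongest applicable evidence status:
#
#   supported > overlap_merge > same_gene_bridge > validated > trna_bridge >
#   small_gap_bridge > unsupported
#
# Any non-unsupported status merges the two genes into one transcription
# unit; maximal merged runs are the inferred polycistronic units. The control
# region never carries a tRNA/small-gap bridge: a junction whose gap contains
# control bases is only merged by a contig chain that literally spans it (or
# an externally validated pair), so the inference of a single unit hinges on
# exactly that break.

junction_statuses <- c("supported", "overlap_merge", "same_gene_bridge",
                       "validated", "trna_bridge", "small_gap_bridge",
                       "unsupported")

#' Build the circular junction list of an annotation
#'
#' One junction per pair of circularly adjacent top-level genes (control
#' region excluded as an endpoint; the trnM_3 to trnM_1 junction passes
#' through it). Gap composition reports the fraction of gap bases annotated
#' as tRNA, as any other feature (control region included), or unannotated.
#'
#' @param ann A [genome_annotation()].
#' @return `data.frame` with one row per junction: `upstream`, `downstream`,
#'   `gap`, `frac_trna`, `frac_other`, `frac_unannotated`,
#'   `contains_control`.
#' @export
build_junctions <- function(ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  gs <- genes(ann)
  n <- nrow(gs)
  L <- ann$genome$length
  cr <- ann$features[ann$features$kind == "control", ]

  rows <- lapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    gap <- gap_between(gs[i, ], gs[j, ], L)
    frac_trna <- frac_other <- frac_un <- NA_real_
    contains_control <- FALSE
    if (gap > 0L) {
      pos <- circ_pos(gs$end[i] + seq_len(gap), L)
      in_iv <- function(s, e) if (s <= e) pos >= s & pos <= e
                              else pos >= s | pos <= e
      trna <- rep(FALSE, gap); other <- rep(FALSE, gap)
      for (k in seq_len(nrow(ann$features))) {
        fr <- ann$features[k, ]
        hit <- in_iv(fr$start, fr$end)
        if (fr$kind == "tRNA") trna <- trna | hit else other <- other | hit
      }
      contains_control <- any(in_iv(cr$start, cr$end))
      frac_trna <- mean(trna)
      frac_other <- mean(other & !trna)
      frac_un <- mean(!trna & !other)
    }
    data.frame(upstream = gs$name[i], downstream = gs$name[j], gap = gap,
               frac_trna = frac_trna, frac_other = frac_other,
               frac_unannotated = frac_un,
               contains_control = contains_control)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Resolve contig gene-content labels to canonical gene positions
#'
#' Maps each contig's printed gene-content list onto a contiguous run of the
#' annotation's circular gene order. Duplicate tRNA labels without a
#' subscript (or with a misprinted one) are resolved positionally: the run
#' maximising exact-name then base-name agreement wins, and entries whose
#' printed name differs from the canonical slot are flagged. Coordinate-level
#' rules downstream only use contigs whose interval fits the genome and whose
#' computed gene content is consistent with the printed label
#' (`coord_ok = TRUE`).
#'
#' @param contigs Contig `data.frame` (columns `contig_id`, `strain`,
#'   `start`, `end`, `gene_content`; `gene_content` dash-separated or a list
#'   column of character vectors).
#' @param ann A [genome_annotation()].
#' @param epsilon Coverage slack in bp used in the consistency check.
#' @return The contig table with added columns `run_start`, `run_len`,
#'   `resolved` (list of canonical names), `coord_ok`, `label_flags`.
#' @export
resolve_contigs <- function(contigs, ann, epsilon = 2L) {
  stopifnot(inherits(ann, "genome_annotation"))
  gs <- genes(ann)
  order_names <- gs$name
  order_base <- base_gene_name(order_names)
  n <- length(order_names)
  L <- ann$genome$length

  content_list <- if (is.list(contigs$gene_content) &&
                      !is.character(contigs$gene_content)) {
    contigs$gene_content
  } else {
    lapply(strsplit(as.character(contigs$gene_content), "-", fixed = TRUE),
           trimws)
  }

  run_start <- integer(nrow(contigs))
  run_len <- integer(nrow(contigs))
  resolved <- vector("list", nrow(contigs))
  coord_ok <- logical(nrow(contigs))
  flags <- character(nrow(contigs))

  for (ci in seq_len(nrow(contigs))) {
    printed <- normalize_gene_name(content_list[[ci]])
    printed_base <- base_gene_name(printed)
    unknown <- setdiff(printed_base, order_base)
    if (length(unknown))
      stop("contig ", contigs$contig_id[ci],
           ": gene content names absent from annotation: ",
           paste(unknown, collapse = ", "))
    m <- length(printed)
    best <- -Inf; best_s <- NA_integer_
    for (s in seq_len(n)) {
      idx <- ((s - 1L + seq_len(m) - 1L) %% n) + 1L
      exact <- printed == order_names[idx]
      base <- printed_base == order_base[idx]
      if (!all(base)) next
      score <- sum(2L * exact + 1L * (!exact & base))
      if (score > best) { best <- score; best_s <- s }
    }
    if (is.na(best_s))
      stop("contig ", contigs$contig_id[ci],
           ": gene content does not match any contiguous run of the ",
           "annotation gene order: ",
           paste(content_list[[ci]], collapse = "-"))
    idx <- ((best_s - 1L + seq_len(m) - 1L) %% n) + 1L
    run_start[ci] <- best_s
    run_len[ci] <- m
    resolved[[ci]] <- order_names[idx]
    mism <- printed != order_names[idx]
    flags[ci] <- if (any(mism))
      paste(sprintf("%s->%s", printed[mism], order_names[idx][mism]),
            collapse = ";")
    else ""

    ## coordinate consistency against this annotation
    st <- suppressWarnings(as.integer(contigs$start[ci]))
    en <- suppressWarnings(as.integer(contigs$end[ci]))
    ok <- !is.na(st) && !is.na(en) && st >= 1L && en >= 1L &&
      st <= L && en <= L
    if (ok) {
      span <- c(st, en)
      lab <- gene_content_label(span, ann)
      demanded <- lab[vapply(lab, function(g)
        circ_overlap(list(start = st, end = en),
                     as_interval(feature_row(ann, g)), L) > epsilon,
        logical(1))]
      ok <- all(base_gene_name(demanded) %in% printed_base) &&
        all(printed_base %in% base_gene_name(lab))
    }
    coord_ok[ci] <- ok
  }

  contigs$run_start <- run_start
  contigs$run_len <- run_len
  contigs$resolved <- resolved
  contigs$coord_ok <- coord_ok
  contigs$label_flags <- flags
  contigs
}

## gene indices (into the circular gene order) covered by a resolved contig
run_indices <- function(run_start, run_len, n) {
  ((run_start - 1L + seq_len(run_len) - 1L) %% n) + 1L
}

## union-find
uf_new <- function(n) seq_len(n)
uf_find <- function(p, i) { while (p[i] != i) i <- p[i]; i }
uf_union <- function(p, i, j) {
  ri <- uf_find(p, i); rj <- uf_find(p, j)
  if (ri != rj) p[rj] <- ri
  p
}

#' Assess every gene junction against contig evidence
#'
#' Assigns each circular junction the strongest applicable evidence status
#' (see the status precedence in the package overview):
#' 1. `supported`: one contig's gene content spans both genes consecutively;
#' 2. `overlap_merge`: coordinate-overlapping contigs of one strain jointly
#'    span the junction (fragmented assemblies of one transcript);
#' 3. `same_gene_bridge`: contigs chained through a shared gene (one ends
#'    inside it, the next begins inside it) jointly span the junction;
#' 4. `validated`: the pair is in the externally validated junction list
#'    (e.g. cDNA-PCR results);
#' 5. `trna_bridge`: a flanking uncovered punctuation tRNA explains the
#'    evidence gap -- the tRNA span lies within `delta` unannotated bases of
#'    the nearest evidence on the covered side (tRNA punctuation cleavage
#'    removes these tRNAs from the sequenced pool);
#' 6. `small_gap_bridge`: the genomic gap between the genes is at most
#'    `delta` bp;
#' 7. `unsupported` otherwise. A junction whose gap contains control-region
#'    bases is never bridged by rules 5-6.
#'
#' @param ann A [genome_annotation()].
#' @param contigs Contig table (see [resolve_contigs()]); `NULL` for none.
#' @param validated Optional two-column `data.frame` (`upstream`,
#'   `downstream`) of externally validated junction pairs.
#' @param delta Maximum bridged unannotated gap in bp (default 60).
#' @param epsilon Coverage/label slack in bp (default 2).
#' @param bridge_trna,bridge_small_gap Logical switches for rules 5 and 6.
#' @return `data.frame`: the junction list plus `status` and `support`
#'   (comma-separated ids of contigs whose content spans the junction).
#' @export
assess_junctions <- function(ann, contigs = NULL, validated = NULL,
                             delta = 60L, epsilon = 2L, bridge_trna = TRUE,
                             bridge_small_gap = TRUE) {
  jx <- build_junctions(ann)
  gs <- genes(ann)
  n <- nrow(gs)
  L <- ann$genome$length

  has_contigs <- !is.null(contigs) && nrow(contigs) > 0L
  if (has_contigs) {
    if (is.null(contigs$run_start))
      contigs <- resolve_contigs(contigs, ann, epsilon)
    runs <- lapply(seq_len(nrow(contigs)), function(ci)
      run_indices(contigs$run_start[ci], contigs$run_len[ci], n))
  } else {
    contigs <- data.frame()
    runs <- list()
  }

  ## gene coverage: resolved runs (any strain) plus coordinate overlap > eps
  covered <- rep(FALSE, n)
  for (r in runs) covered[r] <- TRUE
  if (has_contigs) {
    for (ci in which(contigs$coord_ok)) {
      iv <- list(start = as.integer(contigs$start[ci]),
                 end = as.integer(contigs$end[ci]))
      for (gi in seq_len(n)) {
        if (!covered[gi] &&
            circ_overlap(iv, as_interval(gs[gi, ]), L) > epsilon)
          covered[gi] <- TRUE
      }
    }
  }

  ## contig chains per strain (coordinate rules): overlap edges, then
  ## same-gene edges
  comp_ov <- comp_all <- rep(NA_integer_, if (has_contigs) nrow(contigs) else 0L)
  if (has_contigs) {
    cidx <- which(contigs$coord_ok)
    if (length(cidx)) {
      p_ov <- uf_new(length(cidx)); p_all <- uf_new(length(cidx))
      iv <- lapply(cidx, function(ci)
        list(start = as.integer(contigs$start[ci]),
             end = as.integer(contigs$end[ci])))
      gene_at <- function(pos) {
        for (gi in seq_len(n)) {
          fr <- gs[gi, ]
          inside <- if (fr$start <= fr$end) pos >= fr$start && pos <= fr$end
                    else pos >= fr$start || pos <= fr$end
          if (inside) return(gi)
        }
        NA_integer_
      }
      end_gene <- vapply(iv, function(v) gene_at(v$end), integer(1))
      start_gene <- vapply(iv, function(v) gene_at(v$start), integer(1))
      strains <- contigs$strain[cidx]
      for (a in seq_along(cidx)) for (b in seq_along(cidx)) {
        if (a >= b || strains[a] != strains[b]) next
        if (circ_overlap(iv[[a]], iv[[b]], L) >= 1L) {
          p_ov <- uf_union(p_ov, a, b)
          p_all <- uf_union(p_all, a, b)
        } else if (!is.na(end_gene[a]) && !is.na(start_gene[b]) &&
                   end_gene[a] == start_gene[b]) {
          p_all <- uf_union(p_all, a, b)
        } else if (!is.na(end_gene[b]) && !is.na(start_gene[a]) &&
                   end_gene[b] == start_gene[a]) {
          p_all <- uf_union(p_all, a, b)
        }
      }
      comp_ov[cidx] <- vapply(seq_along(cidx), function(k)
        uf_find(p_ov, k), integer(1))
      comp_all[cidx] <- vapply(seq_along(cidx), function(k)
        uf_find(p_all, k), integer(1))
    }
  }

  chain_covers <- function(comp, i, j) {
    if (!has_contigs) return(FALSE)
    for (cc in unique(stats::na.omit(comp))) {
      members <- which(!is.na(comp) & comp == cc)
      if (length(members) < 2L) next
      gset <- unique(unlist(runs[members]))
      if (i %in% gset && j %in% gset) return(TRUE)
    }
    FALSE
  }

  if (!is.null(validated) && nrow(validated)) {
    vu <- normalize_gene_name(as.character(validated$upstream))
    vd <- normalize_gene_name(as.character(validated$downstream))
  } else vu <- vd <- character()

  status <- character(n)
  support <- character(n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    u <- gs[i, ]; v <- gs[j, ]

    span_ids <- if (has_contigs) {
      hits <- vapply(seq_along(runs), function(ci)
        i %in% runs[[ci]] && j %in% runs[[ci]], logical(1))
      contigs$contig_id[hits]
    } else character()
    support[i] <- paste(span_ids, collapse = ",")

    ## validated match: exact canonical or base-name pair match
    val_hit <- any((vu == u$name | (vu == base_gene_name(u$name) &
                                      !vu %in% gs$name)) &
                   (vd == v$name | (vd == base_gene_name(v$name) &
                                      !vd %in% gs$name)))

    trna_ok <- FALSE
    if (bridge_trna && !jx$contains_control[i]) {
      u_unc <- !covered[i] && u$kind == "tRNA"
      v_unc <- !covered[j] && v$kind == "tRNA"
      if (v_unc && covered[i]) {
        reach <- u$end
        if (has_contigs) {
          for (ci in which(contigs$coord_ok)) {
            ivc <- list(start = as.integer(contigs$start[ci]),
                        end = as.integer(contigs$end[ci]))
            if (circ_overlap(ivc, as_interval(u), L) >= 1L) {
              d <- (ivc$end - u$end) %% L
              if (d <= L / 2 && d > (reach - u$end) %% L) reach <- ivc$end
            }
          }
        }
        g <- v$start - reach - 1L
        if (g < -(L / 2)) g <- g + L
        trna_ok <- g <= delta
      } else if (u_unc && covered[j]) {
        reach <- v$start
        if (has_contigs) {
          for (ci in which(contigs$coord_ok)) {
            ivc <- list(start = as.integer(contigs$start[ci]),
                        end = as.integer(contigs$end[ci]))
            if (circ_overlap(ivc, as_interval(v), L) >= 1L) {
              d <- (v$start - ivc$start) %% L
              if (d <= L / 2 && d > (v$start - reach) %% L) reach <- ivc$start
            }
          }
        }
        g <- reach - u$end - 1L
        if (g < -(L / 2)) g <- g + L
        trna_ok <- g <= delta
      } else if (u_unc && v_unc) {
        trna_ok <- jx$gap[i] <= delta
      }
    }

    status[i] <-
      if (length(span_ids)) "supported"
      else if (chain_covers(comp_ov, i, j)) "overlap_merge"
      else if (chain_covers(comp_all, i, j)) "same_gene_bridge"
      else if (val_hit) "validated"
      else if (trna_ok) "trna_bridge"
      else if (bridge_small_gap && !jx$contains_control[i] &&
               jx$gap[i] <= delta) "small_gap_bridge"
      else "unsupported"
  }

  jx$status <- factor(status, levels = junction_statuses)
  jx$support <- support
  jx
}

#' Infer polycistronic units from junction evidence
#'
#' Units are the maximal circular runs of genes whose internal junctions are
#' all non-unsupported. With zero unsupported junctions the result is a
#' single circular unit; with all junctions unsupported every gene is its own
#' unit. Units partition the genes.
#'
#' @param junctions `data.frame` from [assess_junctions()] (columns
#'   `upstream`, `downstream`, `status`, circularly ordered so junction `i`
#'   joins gene `i` to gene `i + 1`).
#' @return Object of class `polycistron_units`: list with `units` (each a
#'   list of `genes`, `circular`, `statuses`) and the junction table.
#' @export
infer_units <- function(junctions) {
  stopifnot(all(c("upstream", "downstream", "status") %in% names(junctions)))
  gene_names <- as.character(junctions$upstream)
  n <- length(gene_names)
  st <- as.character(junctions$status)
  breaks <- which(st == "unsupported")

  units <- list()
  if (length(breaks) == 0L) {
    units[[1L]] <- list(genes = gene_names, circular = TRUE, statuses = st)
  } else {
    for (k in seq_along(breaks)) {
      b <- breaks[k]
      start <- (b %% n) + 1L            # gene after the break
      nb <- breaks[if (k == length(breaks)) 1L else k + 1L]
      len <- ((nb - start) %% n) + 1L   # genes up to and incl. next break's u
      idx <- ((start - 1L + seq_len(len) - 1L) %% n) + 1L
      units[[k]] <- list(genes = gene_names[idx], circular = FALSE,
                         statuses = st[idx[-length(idx)]])
    }
  }
  structure(list(units = units, junctions = junctions,
                 n_genes = n), class = "polycistron_units")
}

#' @export
print.polycistron_units <- function(x, ...) {
  cat(sprintf("<polycistron_units> %d unit(s) over %d genes\n",
              length(x$units), x$n_genes))
  for (k in seq_along(x$units)) {
    u <- x$units[[k]]
    cat(sprintf("  unit %d (%d genes%s): %s\n", k, length(u$genes),
                if (u$circular) ", circular" else "",
                paste(u$genes, collapse = "-")))
  }
  invisible(x)
}

#' Candidate transcription start sites in the control region
#'
#' Reports contigs whose alignment extends past the terminal gene into the
#' control region; the extension length bounds where transcription
#' initiation can start.
#'
#' @param contigs Contig table with `contig_id`, `start`, `end` (coordinates
#'   interpretable on the annotation's genome).
#' @param ann A [genome_annotation()].
#' @return `data.frame`: `contig_id`, `side` (`"end"`/`"start"`),
#'   `extension_bp`, `control_start`, `control_end`.
#' @export
infer_tss <- function(contigs, ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  cr <- ann$features[ann$features$kind == "control", ]
  L <- ann$genome$length
  fe <- ann$features
  ci <- which(fe$kind == "control")
  prev <- fe[if (ci == 1L) nrow(fe) else ci - 1L, ]
  nxt <- fe[if (ci == nrow(fe)) 1L else ci + 1L, ]

  out <- list()
  for (k in seq_len(nrow(contigs))) {
    st <- suppressWarnings(as.integer(contigs$start[k]))
    en <- suppressWarnings(as.integer(contigs$end[k]))
    if (is.na(st) || is.na(en) || st < 1L || en > L || st > L || en < 1L)
      next
    ## 3' end running from the last gene into the control region
    ext_end <- (en - prev$end) %% L
    lim_end <- (cr$end - prev$end) %% L
    if (ext_end <= lim_end &&
        circ_overlap(list(start = st, end = en), as_interval(prev), L) > 0L) {
      out[[length(out) + 1L]] <- data.frame(
        contig_id = contigs$contig_id[k], side = "end",
        extension_bp = as.integer(ext_end),
        control_start = cr$start, control_end = cr$end)
    }
    ## 5' start reaching back from the first gene into the control region
    ext_st <- (nxt$start - st) %% L
    lim_st <- (nxt$start - cr$start) %% L
    if (ext_st > 0L && ext_st <= lim_st &&
        circ_overlap(list(start = st, end = en), as_interval(nxt), L) > 0L) {
      out[[length(out) + 1L]] <- data.frame(
        contig_id = contigs$contig_id[k], side = "start",
        extension_bp = as.integer(ext_st),
        control_start = cr$start, control_end = cr$end)
    }
  }
  if (length(out) == 0L)
    return(data.frame(contig_id = character(), side = character(),
                      extension_bp = integer(), control_start = integer(),
                      control_end = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Format a gene run as a dash-separated order string
#'
#' Nested genes are shown in parentheses after their host (`rnl(rps3)`).
#'
#' @param gene_names Character vector of gene names in order.
#' @param ann Optional [genome_annotation()] supplying nested genes.
#' @return Single string.
#' @export
format_gene_order <- function(gene_names, ann = NULL) {
  if (!is.null(ann) && nrow(ann$nested)) {
    for (k in seq_len(nrow(ann$nested))) {
      h <- ann$nested$host_gene[k]
      gene_names[gene_names == h] <-
        sprintf("%s(%s)", h, ann$nested$name[k])
    }
  }
  paste(gene_names, collapse = "-")
}

#' Render the polycistron inference report
#'
#' @param units A [infer_units()] result.
#' @param ann Optional [genome_annotation()] (for nested-gene display).
#' @param tss Optional [infer_tss()] result.
#' @return List of class `polycistron_report` with `junctions`, `units`
#'   (data.frame incl. the gene-order string) and `tss`.
#' @export
render_report <- function(units, ann = NULL, tss = NULL) {
  stopifnot(inherits(units, "polycistron_units"))
  udf <- do.call(rbind, lapply(seq_along(units$units), function(k) {
    u <- units$units[[k]]
    data.frame(unit = k, n_genes = length(u$genes), circular = u$circular,
               start_gene = u$genes[1L],
               end_gene = u$genes[length(u$genes)],
               gene_order = format_gene_order(u$genes, ann))
  }))
  structure(list(junctions = units$junctions, units = udf,
                 tss = tss %||% data.frame()),
            class = "polycistron_report")
}

#' @export
print.polycistron_report <- function(x, ...) {
  cat("Polycistronic unit report\n")
  cat(sprintf("  %d unit(s); junction statuses: %s\n", nrow(x$units),
              paste(sprintf("%s=%d", names(table(x$junctions$status)),
                            as.integer(table(x$junctions$status))),
                    collapse = " ")))
  for (k in seq_len(nrow(x$units)))
    cat(sprintf("  unit %d: %s\n", k, x$units$gene_order[k]))
  if (nrow(x$tss))
    cat(sprintf("  TSS candidates: %s\n",
                paste(sprintf("%s(+%d bp)", x$tss$contig_id,
                              x$tss$extension_bp), collapse = ", ")))
  invisible(x)
}

#' Write a polycistron report to disk
#'
#' Writes `junctions.tsv`, `units.tsv`, `tss.tsv` and a combined
#' `report.json` under `dir`.
#'
#' @param report A [render_report()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "polycistron_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("junctions.tsv", "units.tsv", "tss.tsv",
                            "report.json"))
  jx <- report$junctions
  jx$status <- as.character(jx$status)
  utils::write.table(jx, paths[1L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$units, paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$tss, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(junctions = jx, units = report$units, tss = report$tss),
    paths[4L], dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
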