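test_that("junction list covers every adjacent gene pair with printed gaps", {
  ann <- fixture_ann()
  jx <- build_junctions(ann)
  expect_equal(nrow(jx), nrow(genes(ann)))   # one junction per gene, circularly
  gap_of <- function(u, v) jx$gap[jx$upstream == u & jx$downstream == v]
  expect_equal(gap_of("trnM_1", "trnL_1"), 2L)
  expect_equal(gap_of("trnY", "trnD"), 3L)
  expect_equal(gap_of("trnV", "trnI"), 2L)
  expect_equal(gap_of("trnG", "nad6"), 53L)
  expect_equal(gap_of("trnP", "rnl"), 25L)
  expect_equal(gap_of("nad2", "nad3"), -1L)
  ## only the trnM_3 -> trnM_1 junction passes through the control region
  cc <- jx[jx$contains_control, ]
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$upstream, "trnM_3")
  expect_gt(cc$frac_other, 0.9)
})

test_that("contig labels resolve positionally, flagging printed anomalies", {
  ann <- fixture_ann()
  contigs <- load_contig_fixture()
  rc <- resolve_contigs(contigs, ann)
  ## the misprinted trnM3 in the C1 row resolves to the trnM_2 slot
  c1 <- rc[rc$contig_id == "C1", ]
  expect_match(c1$label_flags, "trnM_3->trnM_2")
  expect_equal(c1$resolved[[1]][7], "trnM_2")
  ## unsubscripted trnS resolves by neighbours to the right copy
  expect_equal(rc$resolved[[which(rc$contig_id == "C6")]][2], "trnS_1")
  expect_equal(rc$resolved[[which(rc$contig_id == "C9")]][2], "trnS_2")
  ## other-strain coordinates are excluded from coordinate-level rules
  expect_true(all(rc$coord_ok[startsWith(rc$contig_id, "B")]))
  expect_false(any(rc$coord_ok[startsWith(rc$contig_id, "C")]))
  ## unknown gene names error with the row named
  bad <- data.frame(contig_id = "X", strain = "s", start = 1, end = 10,
                    gene_content = "nad9-cox5")
  expect_error(resolve_contigs(bad, ann), "nad9")
})

test_that("junction statuses follow the evidence rules and their precedence", {
  ann <- fixture_ann()
  contigs <- load_contig_fixture()
  ## without the validated list the tRNA punctuation bridge carries
  ## cox1 -> trnR_2 -> nad1 (the evidence gap is exactly the trnR_2 span)
  jev0 <- assess_junctions(ann, contigs)
  s0 <- function(u) as.character(jev0$status[jev0$upstream == u])
  expect_equal(s0("cox1"), "trna_bridge")
  expect_equal(s0("trnR_2"), "trna_bridge")
  expect_equal(s0("cox3"), "trna_bridge")   # B12 ends 26 bp before trnG
  expect_equal(s0("trnG"), "trna_bridge")   # uncovered trnG, 53 bp to nad6
  ## with the punctuation bridge disabled the 53 bp gap still merges
  jev_sg <- assess_junctions(ann, contigs, bridge_trna = FALSE)
  expect_equal(as.character(jev_sg$status[jev_sg$upstream == "trnG"]),
               "small_gap_bridge")
  expect_equal(s0("trnM_2"), "supported")   # inside contig B2's content
  expect_equal(s0("trnM_3"), "unsupported") # the control-region break
  ## validated pairs take their place under the precedence
  val <- load_validated_junction_fixture()
  jev <- assess_junctions(ann, contigs, validated = val)
  s1 <- function(u) as.character(jev$status[jev$upstream == u])
  expect_equal(s1("cox1"), "validated")
  expect_equal(s1("trnG"), "validated")
  expect_equal(s1("trnM_2"), "supported")   # supported outranks validated
  ## an isolated junction with a large unannotated gap stays unsupported
  toy <- toy_annotation()
  jt <- assess_junctions(toy, contigs = NULL)
  expect_equal(as.character(jt$status[jt$upstream == "geneB"]),
               "unsupported")               # 100 bp gap to control+wrap side
})

test_that("overlap and same-gene chains merge fragmented assemblies", {
  ann <- fixture_ann()
  ## overlap merge: neither contig spans cob -> trnC, but they overlap by
  ## 2 bp and jointly cover both genes
  ct <- data.frame(
    contig_id = c("x1", "x2"),
    strain = "pseudobassiana_like",
    start = c(12790L, 13970L), end = c(13971L, 14044L),
    gene_content = c("cob", "trnC"))
  jev <- assess_junctions(ann, ct, bridge_trna = FALSE,
                          bridge_small_gap = FALSE)
  expect_equal(as.character(jev$status[jev$upstream == "cob"]),
               "overlap_merge")
  ## same-gene bridge: one contig ends inside cob, the next begins inside
  ## cob, with no coordinate overlap between them
  ct2 <- data.frame(
    contig_id = c("z1", "z2"),
    strain = "pseudobassiana_like",
    start = c(12000L, 13970L), end = c(13000L, 14044L),
    gene_content = c("nad5-cob", "trnC"))
  jev2 <- assess_junctions(ann, ct2, bridge_trna = FALSE,
                           bridge_small_gap = FALSE)
  expect_equal(as.character(jev2$status[jev2$upstream == "cob"]),
               "same_gene_bridge")
  ## a single contig spanning both genes outranks the chain statuses
  ct3 <- data.frame(
    contig_id = "w1", strain = "pseudobassiana_like",
    start = 12790L, end = 14044L, gene_content = "cob-trnC")
  jev3 <- assess_junctions(ann, ct3, bridge_trna = FALSE,
                           bridge_small_gap = FALSE)
  expect_equal(as.character(jev3$status[jev3$upstream == "cob"]),
               "supported")
  ## contigs of different strains never chain by coordinates
  ct4 <- ct
  ct4$strain <- c("s1", "s2")
  jev4 <- assess_junctions(ann, ct4, bridge_trna = FALSE,
                           bridge_small_gap = FALSE)
  expect_equal(as.character(jev4$status[jev4$upstream == "cob"]),
               "unsupported")
})

test_that("units partition the genes and match the connected-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(61)
  statuses <- c("supported", "validated", "trna_bridge", "small_gap_bridge",
                "unsupported")
  for (i in 1:200) {
    n <- sample(3:64, 1)
    st <- sample(statuses, n, replace = TRUE,
                 prob = c(.4, .1, .1, .1, .3))
    jev <- make_jev(sprintf("g%02d", seq_len(n)), st)
    u <- infer_units(jev)
    ## partition: every gene in exactly one unit
    all_genes <- unlist(lapply(u$units, `[[`, "genes"))
    expect_equal(sort(all_genes), sort(jev$upstream))
    expect_equal(length(all_genes), n)
    ## oracle equivalence
    expect_equal(length(u$units), oracle_unit_count(st))
    ## each unit is a contiguous circular subsequence of the gene order
    for (un in u$units) {
      idx <- match(un$genes, jev$upstream)
      expect_true(all(diff(idx) %% n == 1 | diff(idx) == 1))
    }
  }
})

test_that("edge cases: all unsupported gives singletons, none gives one circular unit", {
  jev_all <- make_jev(c("a", "b", "c", "d"), rep("unsupported", 4))
  u_all <- infer_units(jev_all)
  expect_equal(length(u_all$units), 4L)
  expect_true(all(lengths(lapply(u_all$units, `[[`, "genes")) == 1L))
  jev_none <- make_jev(c("a", "b", "c", "d"), rep("supported", 4))
  u_none <- infer_units(jev_none)
  expect_equal(length(u_none$units), 1L)
  expect_true(u_none$units[[1]]$circular)
})

test_that("adding evidence never increases the unit count", {
  set.seed(71)
  for (i in 1:100) {
    n <- sample(4:40, 1)
    st <- sample(c("supported", "unsupported"), n, replace = TRUE)
    u1 <- length(infer_units(make_jev(sprintf("g%d", 1:n), st))$units)
    st2 <- st
    flip <- which(st == "unsupported")
    if (length(flip)) {
      k <- sample(flip, sample(length(flip), 1))
      st2[k] <- "supported"
    }
    u2 <- length(infer_units(make_jev(sprintf("g%d", 1:n), st2))$units)
    expect_lte(u2, u1)
  }
})

test_that("TSS inference measures extensions into the control region", {
  ann <- fixture_ann()
  contigs <- load_contig_fixture()
  tss <- infer_tss(contigs, ann)
  expect_equal(nrow(tss), 1L)
  expect_equal(tss$contig_id, "A")
  expect_equal(tss$extension_bp, 121L)   # 5,664 - 5,543
  ## a contig ending exactly at the last gene end extends 0 bp
  ct <- data.frame(contig_id = "t0", start = 4000L, end = 5543L)
  expect_equal(infer_tss(ct, ann)$extension_bp, 0L)
  ## contigs away from the control region yield nothing
  ct2 <- data.frame(contig_id = "t1", start = 10000L, end = 12000L)
  expect_equal(nrow(infer_tss(ct2, ann)), 0L)
})

test_that("the report renders gene-order strings with the nested rps3", {
  ann <- fixture_ann()
  contigs <- load_contig_fixture()
  val <- load_validated_junction_fixture()
  units <- infer_units(assess_junctions(ann, contigs, validated = val))
  rep <- render_report(units, ann, tss = infer_tss(contigs, ann))
  expect_equal(nrow(rep$units), 1L)
  expect_match(rep$units$gene_order, "^trnM_1-trnL_1-trnA-")
  expect_match(rep$units$gene_order, "-trnT-trnE-trnM_3$")
  expect_match(rep$units$gene_order, "rnl\\(rps3\\)", fixed = FALSE)
  ## empty evidence: every junction unsupported or bridge-only
  units0 <- infer_units(assess_junctions(ann, contigs = NULL,
                                         bridge_trna = FALSE,
                                         bridge_small_gap = FALSE))
  rep0 <- render_report(units0, ann)
  expect_equal(nrow(rep0$units), nrow(genes(ann)))
  ## writes parse back
  d <- file.path(tempdir(), "report_test")
  write_report(rep, d)
  jx <- read.delim(file.path(d, "junctions.tsv"))
  expect_equal(nrow(jx), nrow(genes(ann)))
  js <- jsonlite::read_json(file.path(d, "report.json"))
  expect_equal(length(js$units), 1L)
})
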