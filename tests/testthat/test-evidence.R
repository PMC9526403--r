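test_that("every aligned read receives exactly one class, by alignment geometry", {
  ann <- fixture_ann()
  ## single segment fully inside the cox1 exon
  r1 <- read_alignment("r1", data.frame(gstart = 15000L, gend = 15079L,
                                        rstart = 1L, rend = 80L))
  expect_equal(classify_read(r1, ann), "plain_exonic")
  ## segments abutting the donor/acceptor of the rnl intron (901-2782)
  r2 <- read_alignment("r2", data.frame(gstart = c(861L, 2783L),
                                        gend = c(900L, 2822L),
                                        rstart = c(1L, 41L),
                                        rend = c(40L, 80L)))
  expect_equal(classify_read(r2, ann), "splicing")
  ## jitter within tolerance still calls splicing; beyond does not
  r2b <- read_alignment("r2b", data.frame(gstart = c(861L, 2785L),
                                          gend = c(898L, 2822L),
                                          rstart = c(1L, 39L),
                                          rend = c(38L, 76L)))
  expect_equal(classify_read(r2b, ann), "splicing")
  ## segment spanning the exon/intron boundary
  r3 <- read_alignment("r3", data.frame(gstart = 870L, gend = 949L,
                                        rstart = 1L, rend = 80L))
  expect_equal(classify_read(r3, ann), "intron_containing")
  ## rnl tail then head: wraparound
  r4 <- read_alignment("r4", data.frame(gstart = c(5061L, 1L),
                                        gend = c(5100L, 40L),
                                        rstart = c(1L, 41L),
                                        rend = c(40L, 80L)))
  expect_equal(classify_read(r4, ann), "wraparound")
  ## short arms do not trigger wraparound
  r5 <- read_alignment("r5", data.frame(gstart = c(5091L, 3000L),
                                        gend = c(5100L, 3069L),
                                        rstart = c(1L, 11L),
                                        rend = c(10L, 80L)))
  expect_false(classify_read(r5, ann) == "wraparound")
  ## no segments
  r6 <- read_alignment("r6", data.frame(gstart = integer(), gend = integer(),
                                        rstart = integer(), rend = integer()))
  expect_equal(classify_read(r6, ann), "unaligned")
})

test_that("contig classification distinguishes spliced projections from intron carriers", {
  ann <- fixture_ann()
  ## contig inside one exon
  c1 <- data.frame(contig_id = "c1", start = 15000L, end = 16000L)
  expect_equal(classify_contig(c1, ann), "intron_free")
  ## span across the whole rnl including its intron
  c2 <- data.frame(contig_id = "c2", start = 1L, end = 5100L)
  expect_equal(classify_contig(c2, ann), "intron_containing")
  ## spliced projection: same span, gap at the intron
  c3 <- list(contig_id = "c3", start = 1L, end = 5100L,
             segments = data.frame(gstart = c(1L, 2783L),
                                   gend = c(900L, 5100L)))
  expect_equal(classify_contig(c3, ann), "intron_free")
})

test_that("intron-free contigs contain no base that locates to an intron", {
  ann <- fixture_ann()
  ev <- default_sim_evidence()
  sann <- ev$sim$annotation
  contigs <- ev$ev$contigs
  for (i in seq_len(min(nrow(contigs), 10L))) {
    if (classify_contig(contigs[i, ], sann) != "intron_free") next
    segs <- contigs$segments[[i]]
    probe <- unlist(lapply(seq_len(nrow(segs)), function(k)
      unique(round(seq(segs$gstart[k], segs$gend[k], length.out = 25)))))
    labs <- vapply(probe, function(p) locate_position(p, sann)$label,
                   character(1))
    expect_false(any(grepl("^intron", labs)))
  }
})

test_that("gene content labels match the printed table rows and are monotone", {
  ann <- fixture_ann()
  expect_equal(gene_content_label(c(14313, 17358), ann), "cox1")
  expect_equal(gene_content_label(c(22273, 23966), ann), c("rns", "trnY"))
  expect_equal(gene_content_label(c(24052, 24195), ann), c("trnS_1", "trnN"))
  ## wrap-around interval
  expect_equal(gene_content_label(c(26630, 100), ann), c("trnP", "rnl"))
  ## monotone under enlargement
  set.seed(31)
  L <- ann$genome$length
  for (i in 1:50) {
    s <- sample(L, 1); w <- sample(500:3000, 1)
    small <- c(s, circ_pos_test(s + w, L))
    big <- c(circ_pos_test(s - 200, L), circ_pos_test(s + w + 200, L))
    expect_true(all(gene_content_label(small, ann) %in%
                      gene_content_label(big, ann)))
  }
})

test_that("polyA detection requires a clean untemplated A-run", {
  ann <- fixture_ann()
  rnl_end <- 5100L
  r <- read_alignment("p1", data.frame(gstart = rnl_end - 59L, gend = rnl_end,
                                       rstart = 1L, rend = 60L),
                      clip3 = "AAAAAAAA")
  site <- detect_polyA(r, ann, min_tail = 6L)
  ## accepted unless the genome happens to continue in an A-run there
  nxt <- subseq_circular(ann$genome, rnl_end + 1L, rnl_end + 8L)
  if (sum(strsplit(nxt, "")[[1]] == "A") >= 7) {
    expect_null(site)
  } else {
    expect_equal(site$position, rnl_end)
    expect_equal(site$tail_length, 8L)
  }
  ## one mismatch tolerated, two rejected
  r2 <- read_alignment("p2", r$segments, clip3 = "AAGAAAAA")
  r3 <- read_alignment("p3", r$segments, clip3 = "AAGAAT")
  if (!is.null(site)) expect_false(is.null(detect_polyA(r2, ann)))
  expect_null(detect_polyA(r3, ann))
  ## empty soft clip
  r4 <- read_alignment("p4", r$segments, clip3 = "")
  expect_null(detect_polyA(r4, ann))
  ## templated A-run is not a polyA site
  g <- circular_genome("t", paste0(strrep("C", 100), strrep("A", 30),
                                   strrep("C", 70)))
  feats <- data.frame(name = c("g1", "control"), kind = c("rRNA", "control"),
                      start = c(41L, 150L), end = c(100L, 190L))
  annT <- genome_annotation(g, feats)
  rT <- read_alignment("t1", data.frame(gstart = 41L, gend = 100L,
                                        rstart = 1L, rend = 60L),
                       clip3 = "AAAAAAAA")
  expect_null(detect_polyA(rT, annT))
})

test_that("coverage flags reproduce the zero-read tRNA list from the printed contigs", {
  ann <- fixture_ann()
  contigs <- load_contig_fixture()
  bcontigs <- contigs[contigs$strain == "ATCC_90518", ]
  cov <- gene_read_coverage(bcontigs, ann)
  uncovered <- cov$per_gene$gene[!cov$per_gene$covered]
  expect_true(all(c("trnM_1", "trnR_2", "trnG", "trnP") %in% uncovered))
  covered <- cov$per_gene$gene[cov$per_gene$covered]
  expect_true(all(c("cox1", "nad1", "trnL_2", "trnY", "nad6") %in% covered))
  ## no evidence at all
  cov0 <- gene_read_coverage(bcontigs[0, ], ann)
  expect_true(all(!cov0$per_gene$covered))
  expect_equal(cov0$genome_fraction, 0)
  ## a single full-genome contig covers everything
  all_iv <- data.frame(contig_id = "x", start = 1L, end = ann$genome$length)
  cov1 <- gene_read_coverage(all_iv, ann)
  expect_equal(cov1$genome_fraction, 1)
  expect_true(all(cov1$per_gene$fraction == 1))
})
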