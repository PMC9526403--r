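test_that("splice boundary flags follow the group I and GT-AG rules", {
  ann <- fixture_ann()
  sb <- check_splice_boundaries("rnl", ann)
  expect_true(all(sb$group1_ok))
  expect_true(all(sb$gtag_ok))
  expect_equal(sb$upstream_exon_last, "T")
  expect_equal(sb$intron_last, "G")

  ## hand-built gene whose intron ends in C fails the group I rule
  seq <- paste0(strrep("A", 100),                  # pad
                "ATGAAATTA",                       # exon 1 (ends A, not T)
                "GTCCCCCCCCCCCCCCCCCCAC",          # intron ends ..AC
                "AAATTTTAA", strrep("A", 60))
  g <- circular_genome("t", paste0(seq, strrep("C", 300 - nchar(seq) %% 300)))
  feats <- data.frame(name = c("g1", "control"), kind = c("PCG", "control"),
                      start = c(101L, 250L), end = c(140L, 280L))
  introns <- data.frame(gene = "g1", start = 110L, end = 131L)
  ann2 <- genome_annotation(g, feats, introns = introns)
  sb2 <- check_splice_boundaries("g1", ann2)
  expect_false(sb2$group1_ok)   # exon ends A and intron ends C
  expect_false(sb2$gtag_ok)     # ends AC, not AG
  expect_error(check_splice_boundaries("control", ann2), "no annotated introns")
})

test_that("in-silico splicing conserves exon length and is identity without introns", {
  ann <- fixture_ann()
  rnl <- genes(ann)[genes(ann)$name == "rnl", ]
  expect_equal(nchar(splice_gene("rnl", ann)),
               (rnl$end - rnl$start + 1L) - 1882L)
  ## intronless gene returns the genomic substring unchanged
  expect_identical(splice_gene("cox1", ann),
                   subseq_circular(ann$genome, 14330L, 16711L))
  ## 10 + 20 bp exons around a 100 bp intron give a 30 bp transcript
  set.seed(5)
  seq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
  g <- circular_genome("t", seq)
  feats <- data.frame(name = c("g1", "control"), kind = c("PCG", "control"),
                      start = c(11L, 250L), end = c(140L, 300L))
  introns <- data.frame(gene = "g1", start = 21L, end = 120L)
  ann2 <- genome_annotation(g, feats, introns = introns)
  expect_equal(nchar(splice_gene("g1", ann2)), 30L)
})

test_that("generated coding genes splice back to clean reading frames", {
  sim <- default_sim_evidence()$sim
  ann <- sim$annotation
  with_introns <- unique(ann$introns$gene)
  for (g in with_introns) {
    tx <- splice_gene(g, ann)
    fr <- genes(ann)[genes(ann)$name == g, ]
    ilen <- sum(ann$introns$end[ann$introns$gene == g] -
                  ann$introns$start[ann$introns$gene == g] + 1L)
    expect_equal(nchar(tx), (fr$end - fr$start + 1L) - ilen)
    if (gene_kind(g) == "PCG") {
      expect_equal(substr(tx, 1, 3), "ATG")
      expect_true(substr(tx, nchar(tx) - 2, nchar(tx)) %in%
                    c("TAA", "TAG", "TGA"))
      ## no internal stops in frame
      codons <- substring(tx, seq(1, nchar(tx) - 3, 3),
                          seq(3, nchar(tx) - 1, 3))
      expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
    }
  }
  ## every generated intron shows canonical boundaries
  for (g in with_introns) {
    sb <- check_splice_boundaries(g, ann)
    expect_true(all(sb$group1_ok), info = g)
    expect_true(all(sb$gtag_ok), info = g)
  }
})

test_that("intron ORF scan finds the nested rps3 ORF and respects min_aa", {
  ann <- fixture_ann()
  orfs <- scan_intron_orfs("rnl", ann, min_aa = 50L)
  expect_gte(nrow(orfs), 1L)
  ## the planted rps3 ORF is recovered at its true interval
  rps3 <- fixture_sim()$truth$rps3
  expect_true(any(orfs$start == rps3[1] & orfs$length_aa >= 400))
  ## an intron of all C has no ORFs, and min_aa is enforced
  g <- circular_genome("t", paste0(strrep("A", 50), "T", "GT",
                                   strrep("C", 197), "AG",
                                   strrep("A", 148)))
  feats <- data.frame(name = c("g1", "control"), kind = c("rRNA", "control"),
                      start = c(31L, 320L), end = c(280L, 380L))
  introns <- data.frame(gene = "g1", start = 52L, end = 252L)
  ann2 <- genome_annotation(g, feats, introns = introns)
  expect_equal(nrow(scan_intron_orfs("g1", ann2, min_aa = 10L)), 0L)
  expect_error(scan_intron_orfs("g1", ann2, min_aa = 5L))
})

test_that("intron presence matrix aligns homologous sites across strains", {
  a1 <- fixture_ann()
  m <- intron_presence_matrix(list(a1, a1))
  expect_equal(nrow(m), 2L)
  expect_identical(m[1, ], m[2, ])
  expect_equal(rowSums(m), c(pseudobassiana_like = 1, pseudobassiana_like = 1))

  ## two strains differing by exactly one intron: Hamming distance 1
  set.seed(9)
  seq <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
               collapse = "")
  feats <- data.frame(name = c("cox2", "control"), kind = c("PCG", "control"),
                      start = c(101L, 2500L), end = c(1600L, 2800L))
  gA <- circular_genome("strainA", seq)
  annA <- genome_annotation(gA, feats,
                            introns = data.frame(gene = "cox2",
                                                 start = c(401L, 901L),
                                                 end = c(700L, 1200L)),
                            strain = "strainA")
  annB <- genome_annotation(circular_genome("strainB", seq), feats,
                            introns = data.frame(gene = "cox2", start = 401L,
                                                 end = 700L),
                            strain = "strainB")
  m2 <- intron_presence_matrix(list(annA, annB))
  expect_equal(sum(m2["strainA", ] != m2["strainB", ]), 1L)
  expect_equal(unname(rowSums(m2)), c(2, 1))
})

test_that("intron count totals from generated Table-style profiles match the plan", {
  sim <- default_sim_evidence()$sim   # default plan totals 8
  tab <- intron_count_table(list(sim$annotation))
  expect_equal(tab$Total, 8L)
  expect_equal(tab$rnl, 2L)
  expect_equal(tab$cox1, 2L)
  m <- intron_presence_matrix(list(sim$annotation, fixture_ann()))
  expect_equal(unname(rowSums(m)), c(8, 1))
})
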