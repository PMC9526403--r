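test_that("composition statistics match hand counts and handle N/degenerate input", {
  expect_equal(composition_stats("ATAT")$at_skew, 0)
  expect_equal(composition_stats("ATAT")$at_percent, 100)
  expect_equal(composition_stats("GGGC")$gc_skew, 0.5)
  cs <- composition_stats("AATG")
  expect_equal(cs$at_skew, (2 - 1) / 3, tolerance = 1e-12)
  expect_equal(cs$gc_skew, 1)
  ## N excluded from all denominators
  cs2 <- composition_stats("AANNT")
  expect_equal(cs2$at_percent, 100)
  expect_equal(cs2$counts[["N"]], 2)
  ## degenerate inputs
  expect_error(composition_stats(""), "empty")
  csN <- composition_stats("NNNN")
  expect_true(is.na(csN$at_skew) && is.na(csN$gc_skew))
  ## pure-GC sequence has undefined AT skew
  expect_true(is.na(composition_stats("GGCC")$at_skew))
})

test_that("skews are antisymmetric under reverse complement and AT+GC sums to 100", {
  set.seed(11)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    a <- composition_stats(s); b <- composition_stats(rc)
    expect_equal(b$at_skew, -a$at_skew, tolerance = 1e-12)
    expect_equal(b$gc_skew, -a$gc_skew, tolerance = 1e-12)
    expect_equal(a$at_percent + a$gc_percent, 100, tolerance = 1e-12)
  }
})

test_that("gap arithmetic reproduces printed anchors, abutting, overlap and wrapping", {
  ## bases strictly between: end 25,172 -> start 25,199 is 26 bp
  expect_equal(gap_between(c(25000, 25172), c(25199, 25400), 30000L), 26L)
  expect_equal(gap_between(c(31000, 31900), c(31954, 32191), 35000L), 53L)
  expect_equal(gap_between(c(10, 99), c(100, 150), 1000L), 0L)
  ## overlap reported as negative gap; brute-force position-set oracle
  a <- c(10540, 12490); b <- c(12470, 12830)
  ov <- length(intersect(seq(a[1], a[2]), seq(b[1], b[2])))
  expect_equal(ov, 21L)
  expect_equal(gap_between(a, b, 30000L), -21L)
  ## wrap through the origin
  ann <- fixture_ann()
  expect_equal(gap_between("trnP", "rnl", ann), 25L)
  expect_error(gap_between(c(5, 10), c(5, 10), 100L), "identical")
})

test_that("gap additivity holds for collinear non-wrapping triples", {
  set.seed(21)
  for (i in 1:200) {
    L <- 10000L
    s <- sort(sample(1:9000, 6))
    a <- c(s[1], s[2]); b <- c(s[3], s[4]); cc <- c(s[5], s[6])
    lhs <- gap_between(a, b, L) + (s[4] - s[3] + 1L) + gap_between(b, cc, L)
    expect_identical(lhs, s[5] - s[2] - 1L)
  }
})

test_that("region catalogue classifies every adjacent pair once and totals check out", {
  ann <- fixture_ann()
  rc <- region_catalogue(ann)
  n_pairs <- nrow(rc$intergenic) + nrow(rc$overlaps) + nrow(rc$abutting)
  expect_equal(n_pairs, nrow(ann$features))   # one class per circular pair
  expect_equal(sum(rc$intergenic$gap), rc$total_intergenic_bp)
  ## the two printed 1 bp overlaps
  expect_true(all(c("nad2", "nad4L") %in% rc$overlaps$upstream))
  expect_true(all(rc$overlaps$overlap == 1L))
  ## intron totals
  expect_equal(rc$intron_total_bp, 1882L)
  expect_equal(rc$intron_fraction, 100 * 1882 / ann$genome$length)
})

test_that("zero-intron annotations have intron fraction 0 and overlap errors are caught", {
  toy <- toy_annotation()
  no_introns <- genome_annotation(toy$genome,
                                  toy$features[, c("name", "kind", "start", "end")])
  expect_equal(region_catalogue(no_introns)$intron_fraction, 0)
  ## non-adjacent overlapping features are rejected with the offending pair
  bad <- toy$features[, c("name", "kind", "start", "end")]
  bad$end[1] <- 1000L   # geneA now overlaps geneB (non-adjacent)
  bad_ann <- genome_annotation(toy$genome, bad)
  expect_error(region_catalogue(bad_ann), "geneA.*geneB")
})

test_that("intron fraction agrees with brute-force position labelling", {
  toy <- toy_annotation()
  rc <- region_catalogue(toy)
  lab <- vapply(seq_len(toy$genome$length), function(p)
    locate_position(p, toy)$label, character(1))
  expect_equal(rc$intron_fraction,
               100 * sum(grepl("^intron", lab)) / toy$genome$length)
})

test_that("intron count table recomputes totals and accepts annotation lists", {
  df <- load_intron_count_fixture()
  printed_total <- df$Total
  recomputed <- intron_count_table(df)
  expect_identical(recomputed$Total, as.integer(printed_total))
  ## all-zero row
  z <- data.frame(strain = "none", rnl = 0, cox2 = 0, nad5 = 0, cob = 0,
                  cox1 = 0, nad1 = 0)
  expect_equal(intron_count_table(z)$Total, 0L)
  ## from annotations
  tab <- intron_count_table(list(fixture_ann()))
  expect_equal(tab$rnl, 1L)
  expect_equal(tab$Total, 1L)
})

test_that("locate_position labels exons, introns, control and nested genes", {
  ann <- fixture_ann()
  expect_equal(locate_position(17400, ann)$label, "exon of trnR_2")
  expect_equal(locate_position(5600, ann)$label, "control")
  expect_equal(locate_position(1000, ann)$label, "intron 1 of rnl")
  ## nested rps3 reports both the gene and the host intron
  loc <- locate_position(1500, ann)
  expect_equal(loc$nested, "rps3")
  expect_equal(loc$host, "rnl")
  expect_match(loc$label, "rps3")
  expect_match(loc$label, "intron 1 of rnl")
  expect_equal(locate_position(5200, ann)$label, "intergenic")
  expect_error(locate_position(0, ann), "range")
  expect_error(locate_position(ann$genome$length + 1, ann), "range")
})

test_that("origin rotation round-trips sequence and features", {
  ann <- fixture_ann()
  r <- rotate_origin(ann, 6052L)   # control region now ends at the origin
  expect_setequal(genes(r)$name, genes(ann)$name)
  expect_equal(feature_length <- r$genome$length, ann$genome$length)
  back <- rotate_origin(r, ann$genome$length - 6052L)
  expect_identical(back$genome$sequence, ann$genome$sequence)
  i <- match("trnR_2", back$features$name)
  expect_equal(back$features$start[i], 17359L)
})
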