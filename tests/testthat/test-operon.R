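toy_features <- function() {
  # one contig, seven genes; FNT gene in the middle
  data.frame(
    contig = "ctg1",
    start = c(1, 1501, 3001, 4501, 6001, 7501, 9001),
    end = c(1200, 2700, 4200, 5700, 7200, 8700, 10200),
    strand = c("+", "+", "+", "+", "+", "-", "+"),
    locus_tag = c("g1", "g2", "g3", "fnt1", "g5", "g6", "g7"),
    product = c("hypothetical protein", "ABC transporter permease",
                "hypothetical protein", "FNT family anion channel",
                "nitrite reductase large subunit", "pyruvate formate lyase",
                "hypothetical protein"),
    stringsAsFactors = FALSE)
}

test_that("neighborhood scan honours window, contig and strand", {
  feats <- toy_features()
  nb <- scan_neighborhood(feats, "fnt1")
  # g6 is opposite strand and filtered; the rest are within 3 genes
  expect_setequal(nb$locus_tag, c("g1", "g2", "g3", "g5", "g7"))
  # downstream positive on the + strand
  expect_equal(nb$gene_distance[nb$locus_tag == "g5"], 1)
  expect_equal(nb$gene_distance[nb$locus_tag == "g3"], -1)

  # window 1 keeps only adjacent genes
  nb1 <- scan_neighborhood(feats, "fnt1", window = 1)
  expect_setequal(nb1$locus_tag, c("g3", "g5"))

  # same_strand = FALSE returns the opposite-strand gene too
  nb2 <- scan_neighborhood(feats, "fnt1", same_strand = FALSE)
  expect_true("g6" %in% nb2$locus_tag)

  # a partner 4 genes away is out of the default window
  far <- feats
  far$product[far$locus_tag == "g5"] <- "hypothetical protein"
  far$product[far$locus_tag == "g1"] <- "sulfite reductase"  # distance -3
  nb3 <- scan_neighborhood(far, "fnt1", window = 2)
  expect_false("g1" %in% nb3$locus_tag)

  expect_error(scan_neighborhood(feats, "nope"), "not found")
})

test_that("minus-strand genes count downstream toward lower coordinates", {
  feats <- toy_features()
  feats$strand <- rep("-", 7)
  nb <- scan_neighborhood(feats, "fnt1")
  expect_equal(nb$gene_distance[nb$locus_tag == "g3"], 1)   # downstream
  expect_equal(nb$gene_distance[nb$locus_tag == "g5"], -1)  # upstream
})

test_that("operon support picks the nearest keyword match", {
  feats <- toy_features()
  ev <- assign_operon_support(scan_neighborhood(feats, "fnt1"))
  expect_identical(ev$partner_class, "nirBD")
  expect_identical(ev$partner_locus, "g5")
  expect_identical(ev$implied_support, "NirC-nitrite")
  expect_equal(ev$gene_distance, 1)

  # pfl match via product keyword
  feats2 <- toy_features()
  feats2$product[feats2$locus_tag == "g5"] <- "pyruvate formate lyase"
  ev2 <- assign_operon_support(scan_neighborhood(feats2, "fnt1"))
  expect_identical(ev2$partner_class, "pfl")
  expect_identical(ev2$implied_support, "FocA-formate")

  # no matching neighbour
  feats3 <- toy_features()
  feats3$product <- "hypothetical protein"
  feats3$product[4] <- "FNT family anion channel"
  ev3 <- assign_operon_support(scan_neighborhood(feats3, "fnt1"))
  expect_identical(ev3$partner_class, "none")
  expect_identical(ev3$implied_support, "none")

  # equidistant tie goes downstream
  feats4 <- toy_features()
  feats4$product[feats4$locus_tag == "g3"] <- "formate dehydrogenase"
  feats4$product[feats4$locus_tag == "g5"] <- "nitrite reductase"
  ev4 <- assign_operon_support(scan_neighborhood(feats4, "fnt1"))
  expect_identical(ev4$partner_class, "nirBD")
  expect_equal(ev4$gene_distance, 1)
})

test_that("evidence is independent of feature-table row order", {
  feats <- toy_features()
  set.seed(2)
  shuffled <- feats[sample(nrow(feats)), ]
  ev1 <- assign_operon_support(scan_neighborhood(feats, "fnt1"))
  ev2 <- assign_operon_support(scan_neighborhood(shuffled, "fnt1"))
  expect_identical(ev1, ev2)
})

test_that("feature tables round-trip through TSV and GFF3", {
  feats <- toy_features()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_features(feats, tsv, "tsv")
  write_features(feats, gff, "gff3")
  back_tsv <- read_features(tsv)
  back_gff <- read_features(gff)
  for (back in list(back_tsv, back_gff)) {
    ord <- order(back$start)
    expect_identical(back$locus_tag[ord], feats$locus_tag)
    expect_identical(back$product[ord], feats$product)
    expect_identical(back$strand[ord], feats$strand)
    expect_equal(back$start[ord], feats$start)
    expect_equal(back$end[ord], feats$end)
  }
})
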