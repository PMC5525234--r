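test_that("CHI and CVV reproduce the printed golden values exactly", {
  # golden residue strings with published scores
  expect_equal(chi("FFHA"), +4.2)
  expect_equal(chi("IIII"), +18.0)
  expect_equal(chi("YLTM"), +3.7)
  expect_equal(chi("YMANV"), +3.1)
  expect_equal(chi("YFQS"), -2.8)
  expect_equal(chi("FVHI"), +8.3)
  expect_equal(chi("LLVTL"), +14.9)
  expect_equal(cvv("FFHA"), 455)
  expect_equal(cvv("FFHY"), 529)
  expect_equal(cvv("VLSV"), 407)
  expect_equal(cvv("LLGNV"), 497)
  expect_equal(cvv("YLFNI"), 620)
})

test_that("CHI/CVV are additive over concatenation and reject bad input", {
  set.seed(9)
  for (i in 1:10) {
    s1 <- random_protein(sample(1:6, 1))
    s2 <- random_protein(sample(1:6, 1))
    expect_equal(chi(paste0(s1, s2)), chi(s1) + chi(s2))
    expect_equal(cvv(paste0(s1, s2)), cvv(s1) + cvv(s2))
  }
  expect_error(chi(""), "empty")
  expect_error(chi("FF-A"), "gap")
  expect_error(cvv("FFXA"), "X")
})

test_that("site scoring on mapped sequences handles completeness", {
  frame <- ref_frame()
  sc <- score_sites(ref_map(), frame)
  expect_identical(sc$residues, c("FFHA", "LLTV", "LLFNV"))
  expect_equal(sc$chi[1], 4.2)
  expect_equal(sc$cvv[1], 455)
  expect_true(all(sc$complete))

  # gap at 209 makes the central site incomplete, slit sites untouched
  m <- manual_map(ref_string_with(c(`209` = "-")), id = "gap209")
  sc2 <- score_sites(m, frame)
  expect_false(sc2$complete[sc2$site == "central"])
  expect_true(is.na(sc2$chi[sc2$site == "central"]))
  expect_true(all(sc2$complete[sc2$site == "slit"]))
})

test_that("cohort site scores match the generator's ground truth", {
  sc <- small_cohort()
  scores <- score_sites_cohort(sc$mapset)
  tr <- sc$cohort$truth
  for (st in c("central", "slit_closed", "slit_open")) {
    site <- if (st == "central") "central" else "slit"
    state <- c(central = "na", slit_closed = "closed",
               slit_open = "open")[[st]]
    got <- scores$residues[scores$site == site & scores$state == state]
    ids <- scores$sequence_id[scores$site == site & scores$state == state]
    expect_identical(got, tr[[st]][match(ids, tr$id)])
  }
})

test_that("z-score outlier flagging finds planted unusual sites", {
  mk_scores <- function(chis, ids = seq_along(chis)) {
    data.frame(sequence_id = as.character(ids), site = "central",
               state = "na", residues = "XXXX", chi = chis,
               cvv = 455, complete = TRUE, stringsAsFactors = FALSE)
  }
  # 99 typical values with slight jitter and one extreme low value
  set.seed(21)
  chis <- c(11 + rnorm(99, 0, 0.3), 3.1)
  fl <- flag_unusual(mk_scores(chis), k = 2.5)
  expect_identical(which(grepl("low_chi", fl$flags)), 100L)

  # zero spread: nothing flagged
  fl2 <- flag_unusual(mk_scores(rep(11, 20)))
  expect_true(all(fl2$flags == ""))

  # undersized stratum: skipped with warning, nothing flagged
  expect_warning(fl3 <- flag_unusual(mk_scores(c(1, 50, 3))), "skipped")
  expect_true(all(fl3$flags == ""))

  # order invariance
  ord <- sample(length(chis))
  fl4 <- flag_unusual(mk_scores(chis[ord], ids = ord))
  expect_identical(fl4$flags[match(fl$sequence_id, fl4$sequence_id)],
                   fl$flags)
})

test_that("a planted hydrophilic central site is flagged within a cohort", {
  frame <- ref_frame()
  # 30 canonical FFHA maps plus one YFQS carrier
  maps <- c(lapply(1:30, function(i) {
    m <- manual_map(ref_string_with(), id = paste0("wt", i))
    m
  }), list(manual_map(ref_string_with(c(`75` = "Y", `202` = "F",
                                        `209` = "Q", `212` = "S")),
                      id = "odd")))
  scores <- score_sites_cohort(map_set(maps, frame))
  fl <- flag_unusual(scores)
  central <- fl[fl$site == "central", ]
  expect_identical(central$residues[central$sequence_id == "odd"], "YFQS")
  expect_match(central$flags[central$sequence_id == "odd"], "low_chi")
  expect_true(all(central$flags[central$sequence_id != "odd"] == ""))
})

test_that("typical-constriction metadata is consistent with the scales", {
  ty <- typical_constrictions()
  expect_equal(ty$chi[ty$subfamily == "FocA" & ty$site == "central"], 4.2)
  expect_equal(ty$cvv[ty$subfamily == "FocA" & ty$site == "central"], 455)
  closed <- ty[ty$site == "slit" & ty$state == "closed", ]
  expect_true(all(closed$chi >= 7.8 & closed$chi <= 11.1))
  expect_identical(format_chi(c(4.2, -2.8)), c("+4.2", "-2.8"))
})
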