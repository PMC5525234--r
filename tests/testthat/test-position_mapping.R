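test_that("self-alignment of the reference gives the identity map", {
  frame <- ref_frame()
  m <- ref_map()
  expect_identical(unname(m$map), 31:275)
  expect_true(all(m$coverage == 1))
  expect_identical(extract_region(m, site_positions(frame, "central")), "FFHA")
  expect_identical(extract_region(m, site_positions(frame, "slit", "closed")),
                   "LLTV")
  expect_identical(extract_region(m, site_positions(frame, "slit", "open")),
                   "LLFNV")
})

test_that("an insertion between TM5b and TM6 lands in the loop", {
  frame <- ref_frame()
  s <- frame$sequence
  # insert 5 residues after reference position 230 (inside loop E, 225-246)
  q <- paste0(substr(s, 1, 230), "GSNPD", substr(s, 231, nchar(s)))
  m <- align_to_reference(q, frame, id = "ins5")
  segpos <- fntscan:::segment_positions(frame)
  idm <- ref_map()$map[as.character(segpos)]
  got <- m$map[as.character(segpos)]
  # every segment position before the insertion keeps its identity image,
  # everything after is shifted by exactly 5
  expect_identical(unname(got[segpos <= 230]), unname(idm[segpos <= 230]))
  expect_identical(unname(got[segpos > 230]), unname(idm[segpos > 230]) + 5L)
  expect_true(all(m$coverage == 1))
})

test_that("deleting TM3 yields zero coverage there and full elsewhere", {
  frame <- ref_frame()
  s <- frame$sequence
  q <- paste0(substr(s, 1, 106), substr(s, 135, nchar(s)))  # drop 107-134
  m <- align_to_reference(q, frame, id = "delTM3")
  # at most a stray flanking residue may be pulled into the deleted helix;
  # the segment is essentially uncovered and fails any coverage threshold
  expect_lt(unname(m$coverage["TM3"]), 0.1)
  expect_true(all(m$coverage[setdiff(names(m$coverage), "TM3")] == 1))
  expect_identical(extract_region(m, c(107L, 120L)), "--")
  # and the QC stage discards it as missing a segment
  rec <- data.frame(id = "delTM3", species = NA_character_, sequence = q,
                    stringsAsFactors = FALSE)
  expect_identical(qc_filter(rec, frame)$discarded$reason, "missing_segment")
})

test_that("maps are monotone and complete on generated sequences", {
  sc <- small_cohort()
  for (m in sc$mapset[1:12]) {
    expect_identical(sort(as.integer(names(m$map))), 31:275)
    idx <- m$map[!is.na(m$map)]
    expect_false(is.unsorted(idx, strictly = TRUE))
    expect_true(all(m$coverage >= 0 & m$coverage <= 1))
  }
})

test_that("production aligner matches the brute-force affine-gap oracle", {
  submat <- fntscan:::substitution_matrix("BLOSUM62")
  set.seed(101)
  for (trial in 1:12) {
    a <- random_protein(sample(30:80, 1))
    b <- random_protein(sample(30:80, 1))
    mult_del <- if (trial %% 2 == 0) rep(1, nchar(a)) else
      sample(c(1, 3), nchar(a), replace = TRUE)
    mult_ins <- c(1, mult_del[-1], 1)[seq_len(nchar(a) + 1)]
    got <- fntscan:::align_affine_cpp(
      fntscan:::encode_protein(a), fntscan:::encode_protein(b),
      submat, 11, 1, mult_del, mult_ins)$score
    want <- oracle_align_score(a, b, submat, 11, 1, mult_del, mult_ins)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("re-aligning an extracted region is a fixed point of extraction", {
  frame <- ref_frame()
  sc <- small_cohort()
  for (m in sc$mapset[c(1, 10, 25)]) {
    core <- gsub("-", "", extract_region(m, 31:275), fixed = TRUE)
    m2 <- align_to_reference(core, frame, id = "re")
    expect_identical(extract_region(m2, 31:275), extract_region(m, 31:275))
  }
})

test_that("degenerate inputs are rejected cleanly", {
  frame <- ref_frame()
  expect_error(align_to_reference("", frame), "empty")
  expect_error(align_to_reference("ACDE!FG", frame), "invalid residue")
  expect_error(align_to_reference(random_protein(200), frame,
                                  min_score = 1e6),
               class = "fnt_unalignable")
  m <- ref_map()
  expect_error(extract_region(m, 30L), "outside")
  expect_error(extract_region(m, 276L), "outside")
})

test_that("ambiguity codes are tolerated but never favoured", {
  frame <- ref_frame()
  s <- frame$sequence
  q <- paste0(substr(s, 1, 74), "X", substr(s, 76, nchar(s)))
  m <- align_to_reference(q, frame, id = "withX")
  expect_identical(unname(m$map), 31:275)  # X absorbed as mismatch in place
  expect_identical(extract_region(m, 75L), "X")
  expect_lt(m$score, ref_map()$score)
})
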