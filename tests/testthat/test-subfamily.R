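test_that("built-in profiles transcribe the diagnostic table faithfully", {
  p <- builtin_profiles()
  expect_setequal(names(p), all_subfamilies)
  # spot checks against published cells
  ya <- p[["YfdC-alpha"]]$diagnostics
  expect_identical(ya$residues[ya$position == 172], "G")
  expect_equal(ya$weight[ya$position == 172], 0.997)
  nb <- p[["NirC-beta"]]$diagnostics
  expect_identical(nb$residues[nb$position == 93], "H")
  expect_equal(nb$weight[nb$position == 93], 0.987)
  fo <- p[["FocA"]]$diagnostics
  expect_identical(fo$residues[fo$position == 202], "F")
  expect_identical(fo$residues[fo$position == 172], "N")
  expect_identical(fo$residues[fo$position == 93], "TS")
  na <- p[["NirC-alpha"]]$diagnostics
  expect_identical(na$residues[na$position == 212], "V")
  expect_identical(na$residues[na$position == 79], "FY")
  # transcription completeness: every profile has >= 8 diagnostic positions
  for (pr in p) {
    expect_gte(nrow(pr$diagnostics), 8)
    expect_true(all(pr$diagnostics$weight > 0 & pr$diagnostics$weight <= 1))
    expect_true(all(pr$diagnostics$position %in%
                      c(202, 212, 79, 90, 172, 86, 92, 93, 100, 208, 34, 37,
                        113, 167, 254)))
  }
})

consensus_map <- function(subfamily) {
  frame <- ref_frame()
  core <- attr(build_consensus(subfamily, frame), "core")
  res <- ref_residue(frame, 31:275)
  res[match(as.integer(names(core)), 31:275)] <- unname(core)
  manual_map(paste(res, collapse = ""), id = paste0(subfamily, "_cons"))
}

test_that("profile scoring separates own subfamily from the others", {
  p <- builtin_profiles()
  foca <- consensus_map("FocA")
  expect_equal(score_sequence(foca, p[["FocA"]]), 1.0)
  expect_lt(score_sequence(foca, p[["YfdC-alpha"]]), 0.5)

  # all-gap map scores at the gap penalty
  gap_map <- manual_map(strrep("-", 245), id = "allgap")
  expect_equal(score_sequence(gap_map, p[["FocA"]]), -0.5)
  expect_equal(score_sequence(gap_map, p[["FocA"]],
                              gap_penalty_factor = 0.25), -0.25)
})

test_that("score increases monotonically as diagnostics are corrected", {
  p <- builtin_profiles()
  frame <- ref_frame()
  target <- p[["NirC-beta"]]$diagnostics
  # start from the YfdC-alpha consensus, fix NirC-beta diagnostics one by one
  core <- attr(build_consensus("YfdC-alpha", frame), "core")
  res <- ref_residue(frame, 31:275)
  res[match(as.integer(names(core)), 31:275)] <- unname(core)
  prev <- -Inf
  for (k in 0:nrow(target)) {
    cur <- res
    if (k > 0) {
      for (i in seq_len(k)) {
        cur[match(target$position[i], 31:275)] <-
          substr(target$residues[i], 1, 1)
      }
    }
    s <- score_sequence(manual_map(paste(cur, collapse = "")),
                        p[["NirC-beta"]])
    expect_gte(s, prev)
    prev <- s
  }
  expect_equal(prev, 1.0)
})

test_that("classification recovers labels and respects the margin rule", {
  p <- builtin_profiles()
  # noiseless consensus of each subfamily classifies to itself
  for (sub in all_subfamilies) {
    cl <- classify(consensus_map(sub), p)
    expect_identical(cl$label, sub)
  }
  # a sequence equidistant between two profiles is unclassified
  two <- list(
    A = structure(list(name = "A",
                       diagnostics = data.frame(position = c(75L, 202L),
                                                residues = c("F", "F"),
                                                weight = c(1, 1)),
                       source = "paper_table"), class = "fnt_profile"),
    B = structure(list(name = "B",
                       diagnostics = data.frame(position = c(75L, 209L),
                                                residues = c("F", "H"),
                                                weight = c(1, 1)),
                       source = "paper_table"), class = "fnt_profile"))
  cl <- classify(manual_map(ref_string_with()), two, margin_min = 0.05)
  expect_identical(cl$label, "unclassified")
  expect_equal(cl$margin, 0)
})

test_that("classification accuracy does not increase with mutation rate", {
  frame <- ref_frame()
  acc <- vapply(c(0, 0.05, 0.1, 0.2), function(rate) {
    cfg <- generator_config(
      counts = setNames(rep(5L, 8), all_subfamilies),
      mutation_rate = rate, seed = 31)
    cohort <- generate_cohort(cfg)
    mapset <- align_cohort(cohort$records, frame)
    cls <- classify_cohort(mapset)
    truth <- cohort$truth$subfamily[match(cls$id, cohort$truth$id)]
    mean(cls$label == truth)
  }, numeric(1))
  expect_true(all(diff(acc) <= 0 | acc[-1] >= 0.95))
  expect_gte(acc[1], 0.95)  # fidelity 0.99 still perturbs diagnostics

  # with full fidelity and no mutation, recovery is exact
  cfg0 <- generator_config(counts = setNames(rep(3L, 8), all_subfamilies),
                           mutation_rate = 0, diagnostic_fidelity = 1,
                           seed = 31)
  cohort0 <- generate_cohort(cfg0)
  mapset0 <- align_cohort(cohort0$records, frame)
  cls0 <- classify_cohort(mapset0)
  expect_identical(cls0$label,
                   cohort0$truth$subfamily[match(cls0$id, cohort0$truth$id)])
})

test_that("profiles survive a TSV round trip", {
  p <- builtin_profiles()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profiles_tsv(p, path)
  p2 <- read_profiles_tsv(path)
  expect_setequal(names(p2), names(p))
  for (nm in names(p)) {
    expect_equal(p2[[nm]]$diagnostics[order(p2[[nm]]$diagnostics$position), ],
                 p[[nm]]$diagnostics[order(p[[nm]]$diagnostics$position), ],
                 ignore_attr = TRUE)
  }
})
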