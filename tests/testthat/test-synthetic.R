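test_that("consensus sequences carry the published site signatures", {
  frame <- ref_frame()
  central <- as.character(c(75, 202, 209, 212))
  core_of <- function(sub) attr(build_consensus(sub, frame), "core")
  expect_identical(paste(core_of("FocA")[central], collapse = ""), "FFHA")
  expect_identical(paste(core_of("NirC-alpha")[central], collapse = ""),
                   "FFHV")
  expect_identical(core_of("YfdC-alpha")[["172"]], "G")
  expect_identical(core_of("NirC-beta")[["93"]], "H")
  expect_error(build_consensus("NotAFamily", frame), "unknown subfamily")
  # deterministic
  expect_identical(build_consensus("HSC", frame), build_consensus("HSC", frame))
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- generator_config(counts = c(FocA = 5, HSC = 5), seed = 77)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_cohort(c1, d1, generate_feature_table(c1$truth, cfg))
  p2 <- write_cohort(c2, d2, generate_feature_table(c2$truth, cfg))
  for (f in names(p1)) {
    expect_identical(readBin(p1[[f]], "raw", file.size(p1[[f]])),
                     readBin(p2[[f]], "raw", file.size(p2[[f]])))
  }
})

test_that("zero mutation and full fidelity reproduce the consensus", {
  frame <- ref_frame()
  model <- default_loop_model()
  model$sd <- 0
  cfg <- generator_config(counts = c(FdhC = 3), mutation_rate = 0,
                          diagnostic_fidelity = 1, loop_length_model = model,
                          seed = 5)
  cohort <- generate_cohort(cfg)
  cons <- build_consensus("FdhC", frame, loop_length_model = model)
  expect_true(all(cohort$records$sequence == as.character(cons)))
})

test_that("labels are hidden from ids and preserved in ground truth", {
  cfg <- generator_config(counts = c(FocA = 4, `NirC-gamma` = 4), seed = 9)
  cohort <- generate_cohort(cfg)
  expect_false(any(grepl("Foc|Nir", cohort$records$id)))
  expect_setequal(cohort$truth$subfamily, c("FocA", "NirC-gamma"))
  expect_identical(cohort$records$id, cohort$truth$id)
  # ground truth consistent with emitted sequences after mapping
  mapset <- align_cohort(cohort$records, ref_frame())
  scores <- score_sites_cohort(mapset)
  central <- scores[scores$site == "central", ]
  expect_identical(central$residues,
                   cohort$truth$central[match(central$sequence_id,
                                              cohort$truth$id)])
})

test_that("operon placement fractions are realised exactly", {
  partnered <- c(FocA = 50, FdhC = 50, `NirC-beta` = 50, HSC = 50)
  for (f in c(0, 0.15, 1)) {
    cfg <- generator_config(counts = partnered, operon_fraction = f,
                            seed = 17)
    cohort <- generate_cohort(cfg)
    feats <- generate_feature_table(cohort$truth, cfg)
    sup <- operon_support_table(feats, cohort$truth$id)
    expect_equal(mean(sup$partner_class != "none"), f)
    # recovered classes and distances match the ground truth exactly
    expect_identical(sup$partner_class,
                     cohort$truth$partner_class[match(sup$fnt_locus,
                                                      cohort$truth$id)])
    placed <- sup$partner_class != "none"
    expect_equal(sup$gene_distance[placed],
                 cohort$truth$gene_distance[match(sup$fnt_locus[placed],
                                                  cohort$truth$id)])
  }
  # YfdC subfamilies carry no partner class under the default map
  cfg2 <- generator_config(counts = c(`YfdC-alpha` = 10, FocA = 10),
                           operon_fraction = 0.5, seed = 23)
  cohort2 <- generate_cohort(cfg2)
  expect_true(all(cohort2$truth$partner_class[
    cohort2$truth$subfamily == "YfdC-alpha"] == "none"))
})

test_that("an over-demanding operon fraction is capped with a warning", {
  cfg <- generator_config(counts = c(FocA = 4, `YfdC-beta` = 16),
                          operon_fraction = 0.5, seed = 3)
  expect_warning(cohort <- generate_cohort(cfg), "capping")
  expect_equal(sum(cohort$truth$partner_class != "none"), 4)
})

test_that("zero total count yields empty outputs without error", {
  cfg <- generator_config(counts = c(FocA = 0), seed = 1)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort$records), 0)
})
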