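test_that("routing sends each class through its own gates", {
  calls <- as.list(stats::setNames(rep("deleterious", 9),
                                   paste0("call_", predictor_tools())))
  cohort <- rbind_fill(
    do.call(toy_variant, c(list(variant_id = "1_1_A_T", gene_symbol = "G1",
                                consequence_terms = "missense_variant",
                                cadd_phred = 30, gerp = 5, phastcons = 0.9,
                                phylop = 6), calls)),
    do.call(toy_variant, c(list(variant_id = "1_2_A_T", gene_symbol = "G2",
                                consequence_terms = "stop_gained",
                                cadd_phred = 30, exon_index = 9,
                                exon_total = 9), calls)),
    do.call(toy_variant, c(list(variant_id = "1_3_A_T", gene_symbol = "G3",
                                consequence_terms = "splice_donor_variant",
                                cadd_phred = 30), calls)),
    do.call(toy_variant, c(list(variant_id = "1_4_A_T", gene_symbol = "G4",
                                consequence_terms = "synonymous_variant",
                                cadd_phred = 30), calls)),
    do.call(toy_variant, c(list(variant_id = "1_5_A_T", gene_symbol = "G5",
                                consequence_terms = "frameshift_variant",
                                cadd_phred = 30, exon_index = 2,
                                exon_total = 9), calls))
  )
  res <- run_cascade(cohort)
  v <- res$variants
  expect_true(v$survived[v$variant_id == "1_1_A_T"])   # missense, all gates
  expect_false(v$survived[v$variant_id == "1_2_A_T"])  # last-exon excluded
  expect_true(v$survived[v$variant_id == "1_3_A_T"])   # splice: no extra gate
  expect_false(v$survived[v$variant_id == "1_4_A_T"])  # OTHER dropped
  expect_true(v$survived[v$variant_id == "1_5_A_T"])
  # splice variants never face the last-exon or vote gates
  splice_trace <- res$trace[res$trace$variant_id == "1_3_A_T", ]
  expect_false(any(splice_trace$gate %in%
                     c("last_exon", "deleteriousness_vote")))
  # the excluded truncating variant's trace terminates at last_exon
  tr2 <- res$trace[res$trace$variant_id == "1_2_A_T", ]
  expect_equal(tr2$gate[nrow(tr2)], "last_exon")
  expect_equal(tr2$decision[nrow(tr2)], "EXCLUDED")
})

test_that("a failed gate terminates the trace and later gates are not attempted", {
  cohort <- surviving_missense()
  cohort$cadd_phred <- 10
  res <- run_cascade(cohort)
  tr <- res$trace
  expect_equal(tr$gate, c("maf", "cadd"))
  expect_equal(tr$decision, c("PASS", "FAIL"))
  expect_false(res$variants$survived)
})

test_that("summary counts are additive at every gate and partition classes", {
  sim <- generate_cohort(cohort_sim_config(
    n_families = 4, variants_per_family = 250, maf_pass = 0.5,
    cadd_pass = 0.5, vote_pass = 0.5, conservation_pass = 0.5,
    last_exon_frac = 0.3, seed = 42))
  res <- run_cascade(sim$cohort)
  s <- res$summary
  expect_true(all(s$entering == s$passing + s$failing))
  # every variant is in exactly one class bucket at the first gate
  first <- s[s$gate == "maf", ]
  expect_equal(sum(first$entering), nrow(sim$cohort))
  # survivors match the planted truth labels exactly
  expect_identical(res$variants$survived, sim$truth$survives)
})

test_that("lowering cadd_min or raising maf_max never decreases survivors", {
  sim <- generate_cohort(cohort_sim_config(
    n_families = 2, variants_per_family = 300, maf_pass = 0.5,
    cadd_pass = 0.5, vote_pass = 0.6, conservation_pass = 0.6, seed = 7))
  base <- sum(run_cascade(sim$cohort)$variants$survived)
  looser_cadd <- sum(run_cascade(sim$cohort,
                                 list(cadd_min = 10))$variants$survived)
  looser_maf <- sum(run_cascade(sim$cohort,
                                list(maf_max = 0.01))$variants$survived)
  expect_gte(looser_cadd, base)
  expect_gte(looser_maf, base)
})

test_that("identical input and config give byte-identical reports", {
  sim <- generate_cohort(cohort_sim_config(
    n_families = 2, variants_per_family = 100, seed = 11))
  res <- run_cascade(sim$cohort)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_report(res, f1)
  write_report(run_cascade(sim$cohort), f2)
  expect_identical(readLines(f1), readLines(f2))
  # the report round-trips through the table reader
  back <- read_variant_table(f1)
  expect_equal(nrow(back), sum(res$variants$survived))
})

test_that("an empty cohort produces empty output and an all-zero summary", {
  empty <- generate_cohort(cohort_sim_config(n_families = 1,
                                             variants_per_family = 0,
                                             seed = 1))
  res <- run_cascade(empty$cohort)
  expect_equal(nrow(res$variants), 0)
  expect_equal(nrow(res$trace), 0)
  expect_equal(sum(res$summary$entering), 0)
})

test_that("all packaged report-fixture rows survive their class gates", {
  res <- run_cascade(table2_variants())
  expect_true(all(res$variants$survived))
  expect_equal(as.integer(table(res$variants$variant_class)[
    c("MISSENSE", "STOP_GAIN", "FRAMESHIFT", "CANONICAL_SPLICE")]),
    c(20L, 6L, 3L, 2L))
})
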