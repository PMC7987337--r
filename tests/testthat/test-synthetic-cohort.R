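test_that("config validation rejects bad parameters", {
  expect_error(synth_config(n_cases = 0), "positive count")
  expect_error(synth_config(carrier_freq_cases = 1.2), "probability")
  expect_error(synth_config(background_burden_rate = -0.1), "probability")
  expect_error(synth_config(planted_gene_index = 500, n_genes = 10),
               "planted_gene_index")
  expect_error(synth_config(ct_noise_sd = -1), "ct_noise_sd")
  expect_error(synth_config(replicates = 0), "positive count")
})

test_that("cohort structure matches the study design", {
  cfg <- synth_config(n_cases = 30, n_controls = 25, n_genes = 40, seed = 11)
  coh <- generate_cohort(cfg)
  s <- coh$subjects
  expect_equal(nrow(s), 55)
  expect_true(all(s$sex == "M"))
  expect_true(all(s$age < 60))
  expect_true(all(s$pcr_confirmed))
  expect_equal(sum(s$clinical_category %in% c(3, 4)), 30)
  expect_equal(sum(s$clinical_category == 0), 25)
  arm <- classify_subjects(s)
  expect_equal(as.vector(table(arm)), c(30, 25, 0))
})

test_that("older subjects can be emitted to exercise the age filter", {
  cfg <- synth_config(n_cases = 10, n_controls = 10, n_genes = 5,
                      n_older = 6, seed = 3)
  coh <- generate_cohort(cfg)
  expect_equal(sum(coh$subjects$age >= 60), 6)
  arm <- classify_subjects(coh$subjects)
  expect_equal(sum(arm == "excluded"), 6)
})

test_that("zero rates give an empty qualifying burden", {
  cfg <- synth_config(n_cases = 12, n_controls = 12, n_genes = 20,
                      background_burden_rate = 0, carrier_freq_cases = 0,
                      carrier_freq_controls = 0, distractor_rate = 0.05,
                      seed = 5)
  coh <- generate_cohort(cfg)
  expect_false(any(qualifies_for_burden(coh$variants)))
  M <- build_boolean_matrix(coh$variants, coh$subjects)
  expect_true(all(M == 0))
})

test_that("identical seeds reproduce output bytes; different seeds differ", {
  cfg <- synth_config(n_cases = 15, n_controls = 15, n_genes = 25, seed = 42)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_cohort(generate_cohort(cfg), d1)
  p2 <- write_cohort(generate_cohort(cfg), d2)
  expect_identical(readLines(p1["vcf"]), readLines(p2["vcf"]))
  expect_identical(readLines(p1["subjects"]), readLines(p2["subjects"]))
  cfg43 <- synth_config(n_cases = 15, n_controls = 15, n_genes = 25,
                        seed = 43)
  b1 <- attr(generate_cohort(cfg), "burden")
  b2 <- attr(generate_cohort(cfg43), "burden")
  expect_false(identical(b1, b2))
})

test_that("planted-gene carrier counts are calibrated to the design", {
  # mean carrier count among cases over replicate cohorts stays within
  # 3 binomial SDs of n_cases * carrier_freq_cases
  n_rep <- 400
  cfg <- synth_config(n_cases = 79, n_controls = 77, n_genes = 15,
                      carrier_freq_cases = 0.0633, carrier_freq_controls = 0,
                      background_burden_rate = 0.02)
  counts <- vapply(seq_len(n_rep), function(i) {
    cfg$seed <- i
    coh <- generate_cohort(cfg)
    b <- attr(coh, "burden")
    case <- coh$subjects$clinical_category >= 3
    c(sum(b[case, cfg$planted_gene_index]),
      sum(b[!case, cfg$planted_gene_index]))
  }, numeric(2))
  mu <- 79 * 0.0633
  se <- sqrt(79 * 0.0633 * (1 - 0.0633) / n_rep)
  expect_lt(abs(mean(counts[1, ]) - mu), 3 * se)
  expect_equal(sum(counts[2, ]), 0)
})

test_that("every planted burden round-trips through encoding", {
  cfg <- synth_config(n_cases = 20, n_controls = 20, n_genes = 30,
                      distractor_rate = 0.05, missing_maf_rate = 0.3,
                      second_variant_rate = 0.5, seed = 8)
  coh <- generate_cohort(cfg)
  M <- build_boolean_matrix(coh$variants, coh$subjects,
                            genes = colnames(attr(coh, "burden")))
  expect_identical(M, attr(coh, "burden"))
})

test_that("VCF and subject tables round-trip through the readers", {
  cfg <- synth_config(n_cases = 10, n_controls = 10, n_genes = 12,
                      missing_maf_rate = 0.25, seed = 2)
  coh <- generate_cohort(cfg)
  d <- withr::local_tempdir()
  paths <- write_cohort(coh, d)
  v <- read_vcf_variants(paths["vcf"])
  expect_equal(nrow(v), nrow(coh$variants))
  expect_equal(v$gene, coh$variants$gene)
  expect_equal(v$consequence, coh$variants$consequence)
  expect_equal(v$nfe_af, coh$variants$nfe_af, tolerance = 1e-6)
  expect_equal(v$cadd, coh$variants$cadd, tolerance = 1e-6)
  expect_identical(v$carriers, coh$variants$carriers)
  s <- read_subjects(paths["subjects"])
  expect_equal(s$subject_id, coh$subjects$subject_id)
  expect_equal(s$clinical_category, coh$subjects$clinical_category)
})

test_that("qPCR plate follows the Livak generative model exactly at zero noise", {
  cfg <- synth_config(ct_noise_sd = 0, qpcr_baseline_log2 = 3,
                      qpcr_effect_log2 = 3, seed = 1)
  ct <- generate_qpcr_plate(cfg, c(A = "functional", B = "non_carrier",
                                   C = "neutral"))
  fc <- fold_change_ddct(ct)
  tl <- fc[fc$gene == "TLR7", ]
  expect_equal(tl$fold_change[tl$subject_id == "A"], 1.0)
  expect_equal(tl$fold_change[tl$subject_id == "B"], 8.0)
  expect_equal(tl$fold_change[tl$subject_id == "C"], 8.0)

  # null effect: carriers indistinguishable from non-carriers
  cfg0 <- synth_config(ct_noise_sd = 0, qpcr_effect_log2 = 0, seed = 1)
  fc0 <- fold_change_ddct(generate_qpcr_plate(cfg0, c(A = "functional",
                                                      B = "non_carrier")))
  expect_equal(fc0$fold_change[fc0$subject_id == "A"],
               fc0$fold_change[fc0$subject_id == "B"])
})

test_that("qPCR generator validates genotype labels and is seed-stable", {
  cfg <- synth_config(seed = 4)
  expect_error(generate_qpcr_plate(cfg, character(0)), "non-empty")
  expect_error(generate_qpcr_plate(cfg, c(A = "weird")), "unknown genotype")
  g <- c(A = "functional", B = "non_carrier")
  expect_identical(generate_qpcr_plate(cfg, g), generate_qpcr_plate(cfg, g))
})

test_that("log-t comparison has power at the planted expression deficit", {
  # 6 carriers vs 6 non-carriers, 2 log2-unit deficit, noise 0.2 Ct
  cfg <- synth_config(ct_noise_sd = 0.2, qpcr_effect_log2 = 2,
                      replicates = 3, target_genes = "TLR7")
  genotype <- c(setNames(rep("functional", 6), paste0("F", 1:6)),
                setNames(rep("non_carrier", 6), paste0("N", 1:6)))
  reject <- vapply(1:200, function(s) {
    ct <- generate_qpcr_plate(cfg, genotype, seed = s)
    fc <- fold_change_ddct(ct)
    carrier <- startsWith(fc$subject_id, "F")
    compare_groups_log_t(fc$fold_change[carrier],
                         fc$fold_change[!carrier])$p < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.95)
})
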