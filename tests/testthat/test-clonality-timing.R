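test_that("multiplicity follows the purity/copy-number formula with clipping", {
  m <- estimateMultiplicity(0.75, 1, 4, major = 3)
  expect_equal(m$copy_number, 3)
  expect_equal(m$m, 3L)
  m <- estimateMultiplicity(0.25, 0.5, 2, major = 1)
  expect_equal(m$copy_number, 1)
  expect_equal(m$m, 1L)
  # clip to major: rho=1, CNt=3, major=2, vaf=0.9 -> c=2.7, m=2
  m <- estimateMultiplicity(0.9, 1, 3, major = 2)
  expect_equal(m$copy_number, 2.7)
  expect_equal(m$m, 2L)
})

test_that("CCF and its Clopper-Pearson CI match the independent oracle", {
  # rho=.5, CNt=2, m=1, vaf=.25 -> CCF 1
  ci <- estimateCcf(25, 75, 0.5, 2, 1)
  expect_equal(ci$ccf_raw, 0.25 * (0.5 * 2 + 1) / (1 * 0.5))
  expect_equal(ci$ccf, 1)
  # rho=1, CNt=2, m=1, t_alt=25, depth=200 -> CCF 0.25, CI excludes 1
  ci <- estimateCcf(25, 175, 1, 2, 1)
  expect_equal(ci$ccf, 0.25)
  bt <- binom.test(25, 200)$conf.int  # independent exact CI on VAF
  expect_equal(ci$lower, bt[1] * 2, tolerance = 1e-9)
  expect_equal(ci$upper, bt[2] * 2, tolerance = 1e-9)
  expect_lt(ci$upper, 1)  # subclonal
  # rho=1, CNt=2, m=1, vaf=.5 -> CCF 1, clonal
  ci <- estimateCcf(100, 100, 1, 2, 1)
  expect_equal(ci$ccf, 1)
  expect_gte(ci$upper, 1)
  # shallow depth flags a wide CI
  expect_true(estimateCcf(2, 4, 1, 2, 1)$wide_ci)
})

test_that("timing classification follows the clonality/multiplicity rules", {
  expect_equal(classifyTiming("clonal", 3, 3L), "early")
  expect_equal(classifyTiming("clonal", 2, 1L), "late")
  expect_equal(classifyTiming("subclonal", 5, 2L), "late")
  expect_equal(classifyTiming("clonal", 1, 1L), "early")
  expect_equal(classifyTiming("clonal", 1, 1L, strict_timing = TRUE),
               "untimeable")
})

test_that("cohort timing conserves counts and respects truth", {
  sim <- sharedSim()
  tm <- timeMutations(sim$cohort)
  expect_equal(nrow(tm), nrow(mutations(sim$cohort)))
  expect_equal(sum(tm$timing %in% c("early", "late", "untimeable")),
               nrow(tm))
  tr <- sim$truth$mutations
  m <- merge(tm, tr, by = "mut_id", suffixes = c("", ".t"))
  acc <- mean(m$clonality == m$clonality.t, na.rm = TRUE)
  expect_gte(acc, 0.9)
  # strict mode relabels clonal major<2 mutations as untimeable only
  tmS <- timeMutations(sim$cohort, strict_timing = TRUE)
  moved <- tm$timing == "early" & tmS$timing == "untimeable"
  expect_true(all(tmS$timing[moved] == "untimeable"))
  expect_true(all(tm$timing[tmS$timing == "late"] == "late"))
})

test_that("early-enrichment permutation test is calibrated and powered", {
  set.seed(2)
  n <- 400
  timing <- data.frame(
    sample_id = "S", mut_id = sprintf("m%03d", 1:n),
    gene = c(rep("ALLEARLY", 5), rep("NULLG", 10),
             sample(sprintf("G%02d", 1:20), n - 15, replace = TRUE)),
    timing = c(rep("early", 5),
               sample(c("early", "late"), n - 5, replace = TRUE)),
    stringsAsFactors = FALSE)
  res <- earlyEnrichmentTest(timing, n_perm = 1000, seed = 4)
  expect_lte(res$p[res$gene == "ALLEARLY"], 0.1)
  expect_true(all(res$q >= res$p))
  # null gene: p behaves like a uniform draw over repeated seeds
  ps <- vapply(1:10, function(s) {
    r <- earlyEnrichmentTest(timing, genes = "NULLG", n_perm = 200,
                             seed = s)
    r$p
  }, numeric(1))
  expect_gt(mean(ps), 0.3)
  expect_error(earlyEnrichmentTest(timing, n_perm = 0), "n_perm")
  # genes below the minimum are skipped with a message
  expect_message(
    earlyEnrichmentTest(timing, genes = c("ALLEARLY", "ABSENT"),
                        n_perm = 50, seed = 1), "ABSENT")
})
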