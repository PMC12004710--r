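test_that("toy reference is deterministic and arms partition the genome", {
  r1 <- simulateReference(100000, seed = 3)
  r2 <- simulateReference(100000, seed = 3)
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  r3 <- simulateReference(100000, seed = 4)
  expect_false(identical(as.character(r1$genome), as.character(r3$genome)))
  expect_identical(r1$arms, r3$arms)
  # arms partition each chromosome exactly and total length is as requested
  expect_equal(sum(r1$arms$end - r1$arms$start + 1), 100000)
  for (c in unique(r1$arms$chrom)) {
    a <- r1$arms[r1$arms$chrom == c, ]
    expect_equal(a$start[2], a$end[1] + 1)
    expect_equal(a$start[1], 1)
  }
  expect_error(simulateReference(5000, seed = 1), "10 kb")
  gc <- Biostrings::letterFrequency(r1$genome, "GC", as.prob = TRUE)
  expect_true(all(gc > 0.4 & gc < 0.6))
})

test_that("expected VAF follows the purity/copy-number model", {
  # purity 1, clonal m=1 on 1+1: expected VAF exactly 0.5
  expect_equal(1 * 1 * 1 / (1 * 2 + 2 * 0), 0.5)
  # mean observed VAF of >= 1000 clonal m=1 mutations at rho=.5, CNt=2
  # within 3 standard errors of 0.25
  set.seed(1)
  depth <- pmax(rnbinom(2000, mu = 150, size = 8), 20)
  vaf <- rbinom(2000, depth, 0.25) / depth
  se <- sd(vaf) / sqrt(length(vaf))
  expect_lt(abs(mean(vaf) - 0.25), 3 * se)
  # and the generator reproduces it through its own truth table
  sim <- sharedSim()
  m <- mutations(sim$cohort)
  tr <- sim$truth$mutations
  segs <- segments(sim$cohort)
  prof <- profiles(sim$cohort)
  idx <- locateSegment(m, segs)
  rho <- prof$purity[match(m$sample_id, prof$sample_id)]
  sel <- which(!is.na(idx) & segs$cnt[idx] == 2 & segs$major[idx] == 1 &
                 tr$clonality == "clonal" & tr$multiplicity == 1)
  expv <- rho[sel] / (rho[sel] * 2 + 2 * (1 - rho[sel]))
  expect_gt(length(sel), 1000)
  expect_lt(mean(abs(m$vaf[sel] - expv)), 0.05)
})

test_that("archetype copy-number structure matches its truth", {
  ref <- nmibcGenomics:::prepareSimReference(simulationConfig(), 5)
  gi <- simulateSample("GI", simulationConfig(), seed = 6, reference = ref)
  gl <- gi$segments$end - gi$segments$start + 1
  fracMajor2 <- sum(gl[gi$segments$major >= 2]) / sum(gl)
  expect_true(gi$truth$sample$wgd)
  expect_gte(fracMajor2, 0.4)
  expect_gt(gi$profile$ploidy, 3)

  flat <- simulateSample("FGFR3_HRAS", simulationConfig(), seed = 6,
                         reference = ref)
  expect_true(all(flat$segments$major == 1 & flat$segments$minor == 1))
  expect_false(flat$truth$sample$wgd)

  nine <- simulateSample("FGFR3_chr9del", simulationConfig(), seed = 8,
                         reference = ref)
  s9 <- nine$segments[nine$segments$chrom == "chr9", ]
  expect_true(all(s9$minor == 0))
})

test_that("single-signature spectra recover the generating signature", {
  catl <- readSignatureCatalog(syntheticCatalogPath())
  w <- matrix(0, 1, 4, dimnames = list("AA_like", colnames(catl)))
  w[1, "SBS22s"] <- 1
  cfg <- simulationConfig(seed = 9,
                          n_per_archetype = c(AA_like = 1, FGFR3_HRAS = 0,
                                              FGFR3_chr9del = 0, GI = 0),
                          burden = c(AA_like = 10000, FGFR3_HRAS = 0,
                                     FGFR3_chr9del = 0, GI = 0),
                          signature_weights = rbind(
                            w, simulationConfig()$signature_weights[-1, ]),
                          with_expression = FALSE)
  sim <- suppressWarnings(simulateCohort(cfg))
  # drop the planted drivers: they are not drawn from the mixture
  m <- mutations(sim$cohort)
  drv <- sim$truth$mutations$mut_id[sim$truth$mutations$is_driver]
  mid <- paste0(m$sample_id, ":", m$chrom, ":", m$pos, ":", m$ref, ">",
                m$alt)
  sp <- buildSpectrum(m[!mid %in% drv, ])
  cs <- sum(sp * catl[, "SBS22s"]) /
    sqrt(sum(sp^2) * sum(catl[, "SBS22s"]^2))
  expect_gte(cs, 0.97)
})

test_that("identical seeds give bitwise-identical emitted cohorts", {
  cfg <- simulationConfig(seed = 21,
                          n_per_archetype = c(AA_like = 2, FGFR3_HRAS = 2,
                                              FGFR3_chr9del = 2, GI = 2))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  suppressWarnings({
    writeSimulation(simulateCohort(cfg), d1)
    writeSimulation(simulateCohort(cfg), d2)
  })
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("burden contrast and degenerate configs behave", {
  sim <- sharedSim()
  tr <- sim$truth$samples
  counts <- table(sim$truth$mutations$sample_id)
  byArch <- tapply(as.numeric(counts[tr$sample_id]), tr$archetype, mean)
  expect_gte(byArch[["AA_like"]], 5 * byArch[["FGFR3_HRAS"]])
  # zero-burden archetype accepted downstream
  cfg <- simulationConfig(seed = 33,
                          n_per_archetype = c(AA_like = 0, FGFR3_HRAS = 5,
                                              FGFR3_chr9del = 0, GI = 0),
                          burden = c(AA_like = 0, FGFR3_HRAS = 0,
                                     FGFR3_chr9del = 0, GI = 0),
                          with_expression = FALSE)
  sim0 <- suppressWarnings(simulateCohort(cfg))
  expect_true(all(table(factor(mutations(sim0$cohort)$sample_id,
                               sampleIds(sim0$cohort))) <= 10))
  expect_equal(length(sampleIds(sim0$cohort)), 5)
  # seed mandatory
  expect_error(simulateCohort(simulationConfig()), "seed")
})

test_that("survival generator recovers the configured hazard at large n", {
  skip_if_not_installed("survival")
  # covariate-linked exponential model, fitted directly at n = 800
  set.seed(13)
  cin <- rbinom(800, 1, 0.4)
  cfgS <- simulationConfig()$survival
  haz <- cfgS$base_rate * exp(log(2) * cin)
  t <- rexp(800, haz)
  cens <- runif(800, 12, 60)
  fit <- survival::coxph(survival::Surv(pmin(t, cens),
                                        as.integer(t <= cens)) ~ cin)
  expect_true(exp(coef(fit)) > 1.6 && exp(coef(fit)) < 2.5)
})
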