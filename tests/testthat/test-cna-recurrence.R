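test_that("log2 ratios are deterministic and capped at CN 0", {
  s <- data.frame(sample_id = "S", chrom = "chr1", start = c(1, 101, 201),
                  end = c(100, 200, 300), major = c(1, 2, 0),
                  minor = c(1, 2, 0))
  lr <- segmentLogRatios(s, 2)
  expect_equal(lr[1], 0)
  expect_equal(lr[2], 1)
  expect_true(is.finite(lr[3]))
  expect_equal(lr[3], log2(0.5 / 2))
})

test_that("event calling applies the 0.25 amplitude and 0.75 broad cutoffs", {
  arms <- toyArms()
  # deletion covering 80% of 1p (p arm = [1,400])
  s <- data.frame(sample_id = "S", chrom = "chr1",
                  start = c(1, 321), end = c(320, 1000),
                  major = c(1, 1), minor = c(0, 1))
  ev <- callCnaEvents(s, arms, ploidy = 2)
  expect_equal(ev$kind[1], "broad-del")
  expect_equal(ev$locus[1], "1p")
  # deletion covering 50% of the arm is focal
  s$end[1] <- 200; s$start[2] <- 201
  ev <- callCnaEvents(s, arms, ploidy = 2)
  expect_equal(ev$kind[1], "focal-del")
  # amplitude below 0.25 yields no event: CN 3 at ploidy 2.6
  s2 <- data.frame(sample_id = "S", chrom = "chr1", start = 1, end = 1000,
                   major = 2, minor = 1)
  expect_equal(nrow(callCnaEvents(s2, arms, ploidy = 2.6)), 0)
})

test_that("focal/broad arm fractions never contradict the 0.75 boundary", {
  arms <- toyArms()
  set.seed(14)
  for (rep in 1:20) {
    cuts <- sort(sample(2:999, 5))
    st <- c(1, cuts + 1); en <- c(cuts, 1000)
    s <- data.frame(sample_id = "S", chrom = "chr1", start = st, end = en,
                    major = sample(0:4, 6, replace = TRUE), minor = 0)
    s$minor <- pmin(s$major, sample(0:2, 6, replace = TRUE))
    ev <- callCnaEvents(s, arms, ploidy = 2)
    if (!nrow(ev)) next
    expect_true(all(ev$arm_fraction[grepl("focal", ev$kind)] < 0.75))
    expect_true(all(ev$arm_fraction[grepl("broad", ev$kind)] >= 0.75))
  }
})

test_that("planted recurrent loci reach q < 0.1 and random ones do not", {
  arms <- toyArms(len = 10000)
  samples <- sprintf("S%02d", 1:20)
  set.seed(6)
  mkDel <- function(sid, start, end)
    data.frame(sample_id = sid, kind = "focal-del",
               locus = paste0("chr1:", start, "-", end), chrom = "chr1",
               start = start, end = end, arm = "1p", amplitude = 1,
               arm_fraction = (end - start + 1) / 4000)
  planted <- do.call(rbind, lapply(samples[1:16], function(s)
    mkDel(s, 1200, 1600)))
  noise <- do.call(rbind, lapply(samples, function(s)
    mkDel(s, sample(5000, 1) + 4000, NA)))
  noise$end <- noise$start + 300
  ev <- rbind(planted, noise)
  rec <- recurrenceSignificance(ev, arms, samples, n_perm = 600, seed = 2,
                                bin_size = 400)
  hit <- rec[rec$direction == "del" & rec$chrom == "chr1" &
               rec$start <= 1400 & rec$end >= 1400, ]
  expect_true(all(hit$q < 0.1))
  # fully random events: at most ~10% of bins significant
  rnd <- do.call(rbind, lapply(samples, function(s) {
    st <- sample(9000, 2)
    rbind(mkDel(s, st[1], st[1] + 200), mkDel(s, st[2], st[2] + 200))
  }))
  rec2 <- recurrenceSignificance(rnd, arms, samples, n_perm = 200,
                                 seed = 3, bin_size = 400)
  expect_lte(mean(rec2$q[rec2$direction == "del"] < 0.1), 0.10)
  expect_error(recurrenceSignificance(ev, arms, samples[1], n_perm = 200),
               ">= 2")
})

test_that("significant loci collapse bins and the chr9 flag needs both arms", {
  arms <- rbind(toyArms(), toyArms(chroms = "chr9"))
  ev <- rbind(
    data.frame(sample_id = "S1", kind = "broad-del", locus = "9p",
               chrom = "chr9", start = 1, end = 400, arm = "9p",
               amplitude = 1, arm_fraction = 1),
    data.frame(sample_id = "S1", kind = "broad-del", locus = "9q",
               chrom = "chr9", start = 401, end = 1000, arm = "9q",
               amplitude = 1, arm_fraction = 1),
    data.frame(sample_id = "S2", kind = "broad-del", locus = "9p",
               chrom = "chr9", start = 1, end = 400, arm = "9p",
               amplitude = 1, arm_fraction = 1))
  fl <- chr9CodeletionFlag(ev, c("S1", "S2", "S3"))
  expect_true(fl[["S1"]])
  expect_false(fl[["S2"]])
  expect_false(fl[["S3"]])
})

test_that("cohort CNA pipeline recovers the planted chr9 deletion archetype", {
  sim <- sharedSim()
  ev <- cohortCnaEvents(sim$cohort, sim$reference$arms)
  fl <- chr9CodeletionFlag(ev, sampleIds(sim$cohort))
  arch <- sim$truth$samples$archetype
  expect_true(all(fl[arch == "FGFR3_chr9del"]))
  expect_true(all(!fl[arch == "FGFR3_HRAS"]))
})
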