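seg1 <- function(major, minor, start = 1, end = 1000, chrom = "chr1",
                 sample = "S") {
  data.frame(sample_id = sample, chrom = chrom, start = start, end = end,
             major = major, minor = minor)
}

test_that("wGD fraction method respects the strict 50% boundary", {
  expect_true(wgdFractionMethod(seg1(2, 2))$wgd)
  expect_false(wgdFractionMethod(seg1(1, 1))$wgd)
  # 49% of the genome at major 2 stays below the cutoff
  s <- rbind(seg1(2, 1, 1, 490), seg1(1, 1, 491, 1000))
  r <- wgdFractionMethod(s)
  expect_equal(r$fraction, 0.49)
  expect_false(r$wgd)
  s <- rbind(seg1(2, 1, 1, 500), seg1(1, 1, 501, 1000))
  expect_true(wgdFractionMethod(s)$wgd)
  expect_error(wgdFractionMethod(seg1(1, 1)[0, ]), "empty")
})

test_that("wGD fraction method equals a per-base brute force on toy genomes", {
  set.seed(11)
  for (rep in 1:10) {
    st <- sort(sample(1:900, 4))
    en <- c(st[-1] - 1, 1000)
    s <- data.frame(sample_id = "S", chrom = "chr1", start = st, end = en,
                    major = sample(0:3, 4, replace = TRUE), minor = 0)
    s$minor <- pmin(s$major, sample(0:1, 4, replace = TRUE))
    base <- rep(NA_integer_, 1000)
    for (i in seq_len(nrow(s))) base[s$start[i]:s$end[i]] <- s$major[i]
    brute <- mean(base >= 2, na.rm = TRUE)
    expect_equal(wgdFractionMethod(s)$fraction, brute)
  }
})

test_that("arm-level wGD method applies the modal-state and ploidy gates", {
  arms <- toyArms()
  tetr <- rbind(seg1(2, 2, 1, 1000, "chr1"), seg1(2, 2, 1, 1000, "chr2"))
  expect_true(wgdArmMethod(tetr, arms, ploidy = 4)$wgd)
  dipl <- rbind(seg1(1, 1, 1, 1000, "chr1"), seg1(1, 1, 1, 1000, "chr2"))
  expect_false(wgdArmMethod(dipl, arms, ploidy = 2)$wgd)
  # 2+0 on half the arms at ploidy 2: fraction passes, ploidy gate blocks
  half <- rbind(seg1(2, 0, 1, 1000, "chr1"), seg1(1, 1, 1, 1000, "chr2"))
  r <- wgdArmMethod(half, arms, ploidy = 2)
  expect_false(r$wgd)
  expect_gte(r$fraction, 0.5)
  # uncovered arms are skipped with a warning
  expect_warning(wgdArmMethod(seg1(2, 2, 1, 1000, "chr1"), arms, 4),
                 "coverage")
})

test_that("wGII is ploidy-relative and invariant to segment splitting", {
  expect_equal(computeWgii(seg1(1, 1), 2)$wgii, 0)
  r <- computeWgii(rbind(seg1(2, 1, 1, 500), seg1(1, 1, 501, 1000)), 2)
  expect_equal(r$wgii, 0.5)
  expect_true(r$cin)
  expect_equal(computeWgii(seg1(2, 2), 4)$wgii, 0)
  # splitting any segment leaves wGII unchanged
  set.seed(3)
  for (rep in 1:10) {
    s <- rbind(seg1(sample(0:3, 1), 0, 1, 400),
               seg1(sample(1:3, 1), 1, 401, 1000))
    s$minor <- pmin(s$minor, s$major)
    pl <- runif(1, 1.5, 4)
    w1 <- computeWgii(s, pl)$wgii
    cut <- sample(2:399, 1)
    split <- rbind(seg1(s$major[1], s$minor[1], 1, cut),
                   seg1(s$major[1], s$minor[1], cut + 1, 400),
                   s[2, ])
    expect_equal(computeWgii(split, pl)$wgii, w1)
  }
  expect_true(all(vapply(1:20, function(i) {
    s <- seg1(sample(0:4, 1), 0)
    w <- computeWgii(s, runif(1, 1, 5))$wgii
    w >= 0 && w <= 1
  }, logical(1))))
})

test_that("hypermutation gap rule matches hand-computed examples", {
  tmb <- c(A = 50, B = 48, C = 10, D = 9, E = 8, F = 7, G = 6, H = 5)
  r <- defineHypermutation(tmb)
  expect_equal(r$gap, 38)
  expect_equal(sum(r$flags), 2)
  expect_true(all(r$flags[c("A", "B")]))
  expect_false(any(defineHypermutation(
    c(a = 5, b = 5, c = 5, d = 5, e = 5))$flags))
  r1 <- defineHypermutation(c(x = 100, y = 5, z = 5, w = 5, v = 5))
  expect_equal(sum(r1$flags), 1)
  expect_true(r1$flags[["x"]])
  expect_error(defineHypermutation(c(1, 2, 3, 4)), ">= 5")
})

test_that("cohort instability profiles honour the AND rule and flag archetypes", {
  sim <- sharedSim()
  inst <- instabilityProfiles(sim$cohort, sim$reference$arms)
  expect_true(all(inst$wgd == (inst$wgd_method1 & inst$wgd_method2)))
  expect_true(all(inst$cin == (inst$wgii > 0.2)))
  arch <- sim$truth$samples$archetype[
    match(inst$sample_id, sim$truth$samples$sample_id)]
  expect_true(all(inst$wgd[arch == "GI"]))
  expect_true(all(!inst$wgd[arch == "FGFR3_HRAS"]))
  # hypermutated samples are the high-burden archetype
  expect_true(all(arch[inst$hypermutated] == "AA_like"))
})
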