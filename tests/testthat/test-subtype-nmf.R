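test_that("Brunet NMF reconstructs rank-1 structure and is deterministic", {
  V <- outer(c(1, 2, 3, 4), c(2, 1, 3))
  fit <- nmfBrunet(V, 1, restarts = 5, seed = 3)
  expect_lt(fit$kl, 1e-6)
  fit2 <- nmfBrunet(V, 1, restarts = 5, seed = 3)
  expect_identical(fit$W, fit2$W)
  expect_error(nmfBrunet(matrix(c(-1, 1, 1, 1), 2), 1), "non-negative")
  # KL objective is non-increasing along the trace
  set.seed(2)
  V2 <- matrix(rpois(20 * 8, 3), 20, 8)
  fit3 <- nmfBrunet(V2, 3, restarts = 1, seed = 4)
  expect_true(all(diff(fit3$trace) <= 1e-8))
})

test_that("block-diagonal binary matrices cluster perfectly at k = 4", {
  set.seed(5)
  blocks <- lapply(1:4, function(b) {
    m <- matrix(0L, 8, 5)
    m[, ] <- rbinom(40, 1, 0.9)
    m
  })
  m <- matrix(0L, 32, 20)
  for (b in 1:4) m[(b - 1) * 8 + 1:8, (b - 1) * 5 + 1:5] <- blocks[[b]]
  colnames(m) <- paste0("E", 1:20)
  rownames(m) <- paste0("S", 1:32)
  model <- fitSubtypes(m, k_range = 2:6, restarts = 15, seed = 6)
  expect_equal(model@rank, 4L)
  truthLab <- rep(1:4, each = 8)
  # ARI = 1 against the generating blocks
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(subtypeLabels(model), truthLab), 1)
  # consensus and cophenetic diagnostics are within bounds
  expect_true(all(consensusMatrix(model) >= 0 &
                    consensusMatrix(model) <= 1))
  expect_true(all(copheneticCoefficients(model) >= 0 &
                    copheneticCoefficients(model) <= 1))
})

test_that("rank selection flags structureless input and honours single k", {
  set.seed(7)
  m <- matrix(rbinom(60 * 15, 1, 0.5), 60, 15)
  expect_warning(selectRank(t(m), k_range = 2:4, restarts = 12, seed = 1,
                            max_iter = 400),
                 "structureless")
  expect_message(r <- suppressWarnings(
    selectRank(t(m), k_range = 3, restarts = 4, seed = 1, max_iter = 200)),
    "single candidate")
  expect_equal(r$k, 3)
  expect_error(selectRank(t(m), k_range = 70, restarts = 2, seed = 1),
               "smaller")
})

test_that("subtyping matrix construction counts, dedupes and validates", {
  ev <- matrix(rbinom(40, 1, 0.5), 8, 5,
               dimnames = list(paste0("S", 1:8), paste0("E", 1:5)))
  cna <- matrix(rbinom(24, 1, 0.5), 8, 3,
                dimnames = list(paste0("S", 1:8), paste0("C", 1:3)))
  m <- buildSubtypingMatrix(ev, cna)
  expect_equal(ncol(m), 8)
  dup <- cna; colnames(dup)[1] <- "E1"
  expect_warning(m2 <- buildSubtypingMatrix(ev, dup), "dedup")
  expect_equal(ncol(m2), 7)
  const <- matrix(1L, 8, 2, dimnames = list(paste0("S", 1:8), c("a", "b")))
  expect_error(buildSubtypingMatrix(const), "constant")
  expect_error(buildSubtypingMatrix(ev[, 1, drop = FALSE]), ">= 2")
})

test_that("subtype characterization reports Fisher enrichment and NA on constants", {
  labels <- stats::setNames(rep(1:2, each = 10), paste0("S", 1:20))
  feat <- cbind(hit = c(rep(1, 9), rep(0, 11)),
                const = rep(1, 20))
  rownames(feat) <- names(labels)
  ch <- characterizeSubtypes(labels, feat)
  hit1 <- ch$enrichment[ch$enrichment$subtype == 1 &
                          ch$enrichment$feature == "hit", ]
  expect_gt(hit1$or, 1)
  expect_lt(hit1$p, 0.05)
  expect_true(is.na(ch$enrichment$or[ch$enrichment$feature == "const"][1]))
  expect_true(all(ch$enrichment$q >= ch$enrichment$p, na.rm = TRUE))
})
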