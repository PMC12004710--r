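mut1 <- function(ref, alt, ctx, sample = "S1") {
  data.frame(sample_id = sample, chrom = "chr1", pos = 10, ref = ref,
             alt = alt, gene = "", consequence = "other", t_alt = 10,
             t_ref = 90, context3 = ctx, is_snv = nchar(ref) == 1,
             vaf = 0.1, stringsAsFactors = FALSE)
}

test_that("spectrum construction folds strands into pyrimidine channels", {
  sp <- buildSpectrum(mut1("C", "T", "ACA"))
  expect_equal(unname(sp["A[C>T]A"]), 1)
  expect_equal(sum(sp), 1)
  # purine reference on the + strand reverse-complements
  sp <- buildSpectrum(mut1("G", "A", "TGT"))
  expect_equal(unname(sp["A[C>T]A"]), 1)
  sp <- buildSpectrum(mut1("C", "T", "ACA")[0, ])
  expect_equal(sum(sp), 0)
  # non-SNVs are skipped and counted
  sp <- buildSpectrum(rbind(mut1("C", "T", "ACA"), mut1("CT", "C", "")))
  expect_equal(sum(sp), 1)
  expect_equal(attr(sp, "n_skipped_nonsnv"), 1)
})

test_that("EM exposure fitting is exact on identifiable mixtures", {
  ch <- sbsChannels()
  catalog <- matrix(0, 96, 2, dimnames = list(ch, c("s1", "s2")))
  catalog[1:48, 1] <- 1 / 48   # disjoint supports
  catalog[49:96, 2] <- 1 / 48
  sp <- 100 * catalog[, 1]
  fit <- fitExposuresEM(sp, catalog)
  expect_equal(unname(fit$counts), c(100, 0), tolerance = 1e-6)
  mix <- 60 * catalog[, 1] + 40 * catalog[, 2]
  fit <- fitExposuresEM(mix, catalog)
  expect_equal(unname(fit$counts), c(60, 40), tolerance = 0.5)
  # conservation: counts sum to the spectrum total
  expect_equal(sum(fit$counts), sum(mix), tolerance = 0.5)
  # log-likelihood is non-decreasing at every iteration
  real <- readSignatureCatalog(syntheticCatalogPath())
  set.seed(8)
  spec <- as.numeric(rmultinom(1, 500, 0.5 * real[, 1] + 0.5 * real[, 4]))
  fit2 <- fitExposuresEM(spec, real)
  expect_true(all(diff(fit2$loglik) >= -1e-8))
  # zero spectrum
  z <- fitExposuresEM(numeric(96), real)
  expect_true(all(z$counts == 0) && !any(z$present))
})

test_that("the presence rule requires 10 mutations and a 5% share", {
  ch <- sbsChannels()
  catalog <- matrix(0, 96, 2, dimnames = list(ch, c("s1", "s2")))
  catalog[1:48, 1] <- 1 / 48
  catalog[49:96, 2] <- 1 / 48
  # signature with 9 mutations at 30% share: absent
  sp <- 9 * catalog[, 1] + 21 * catalog[, 2]
  fit <- fitExposuresEM(sp, catalog)
  expect_false(fit$present[["s1"]])
  expect_true(fit$present[["s2"]])
  # 10 mutations but < 5%: absent
  sp <- 10 * catalog[, 1] + 290 * catalog[, 2]
  fit <- fitExposuresEM(sp, catalog)
  expect_false(fit$present[["s1"]])
})

test_that("early and late spectra add up to the timed total", {
  sim <- sharedSim()
  tm <- timeMutations(sim$cohort)
  spE <- cohortSpectra(sim$cohort, "early", timing = tm)
  spL <- cohortSpectra(sim$cohort, "late", timing = tm)
  tmTimed <- tm[tm$timing %in% c("early", "late"), ]
  muts <- mutations(sim$cohort)
  mid <- paste0(muts$sample_id, ":", muts$chrom, ":", muts$pos, ":",
                muts$ref, ">", muts$alt)
  spT <- cohortSpectra(
    methods::new("NmibcCohort",
                 mutations = muts[mid %in% tmTimed$mut_id, ],
                 segments = segments(sim$cohort),
                 profiles = profiles(sim$cohort),
                 clinical = clinical(sim$cohort),
                 annotations = annotations(sim$cohort),
                 exprCounts = exprCounts(sim$cohort)), "all")
  expect_equal(spE + spL, spT)
})

test_that("de novo NMF recovers a two-signature cohort", {
  ch <- sbsChannels()
  catalog <- readSignatureCatalog(syntheticCatalogPath())[, c(1, 4)]
  set.seed(10)
  mixW <- cbind(runif(12, 0, 0.2), 1)  # SBS22s-dominant half
  mixW[1:6, ] <- cbind(1, runif(6, 0, 0.2))
  spectra <- vapply(1:12, function(j) {
    w <- mixW[j, ] / sum(mixW[j, ])
    as.numeric(rmultinom(1, 800, catalog %*% w))
  }, numeric(96))
  rownames(spectra) <- ch
  res <- extractDenovoNMF(spectra, catalog, k_range = 2:4, restarts = 8,
                          seed = 5)
  expect_equal(res$k, 2)
  expect_setequal(res$matching$match, c("SBS2s", "SBS22s"))
  expect_true(all(res$matching$cosine >= 0.95))
  res2 <- extractDenovoNMF(spectra, catalog, k_range = 2:4, restarts = 8,
                           seed = 5)
  expect_identical(res$signatures, res2$signatures)
  expect_error(extractDenovoNMF(matrix(0, 96, 12), catalog), "zero")
  expect_error(extractDenovoNMF(spectra[, 1:4], catalog), ">= 10")
})

test_that("APOBEC enrichment matches direct ratio arithmetic", {
  # constructed genome: windows around each mutation have a known tCw share
  base <- paste(rep("TCAG", 250), collapse = "")   # 1000 nt, rich in TCA
  genome <- Biostrings::DNAStringSet(c(chr1 = base))
  pos <- seq(102, 302, by = 20)   # cytosines: the sequence is TCAG-periodic
  muts <- data.frame(sample_id = "S1", chrom = "chr1", pos = pos,
                     ref = "C", alt = "T", gene = "",
                     consequence = "other", t_alt = 10, t_ref = 90,
                     context3 = "TCA", stringsAsFactors = FALSE)
  segs <- data.frame(sample_id = "S1", chrom = "chr1", start = 1,
                     end = 1000, major = 1, minor = 1)
  prof <- data.frame(sample_id = "S1", purity = 0.5, ploidy = 2,
                     exome_size_mb = 1)
  co <- assembleCohort(muts, segs, prof)
  res <- apobecEnrichment(co, genome, w = 20)
  # every mutated C is tCw; compute the window ratio independently
  win <- substr(base, 102 - 20, 102 + 20)
  nC <- lengths(regmatches(win, gregexpr("[CG]", win)))
  nT <- sum(vapply(c("TCA", "TCT", "TGA", "AGA"), function(p) {
    g <- gregexpr(paste0("(?=", p, ")"), win, perl = TRUE)[[1]]
    sum(g > 0)
  }, numeric(1)))
  expect_equal(res$enrichment, (11 / 11) / (11 * nT / (11 * nC)))
  expect_gt(res$enrichment, 1)
  # no qualifying mutations: undefined E, group none
  co0 <- assembleCohort(transform(muts, ref = "A", alt = "G",
                                  context3 = "TAC"),
                        segs, prof)
  r0 <- apobecEnrichment(co0, genome)
  expect_true(is.na(r0$enrichment))
  expect_equal(r0$group, "none")
})

test_that("APOBEC load is zero at the null and groups split at the median", {
  sim <- sharedSim()
  res <- apobecEnrichment(sim$cohort, sim$reference$genome)
  expect_true(all(res$load >= 0))
  expect_true(all(res$group %in% c("none", "low", "high")))
  sig <- res$group != "none"
  if (any(sig)) {
    expect_true(all(res$q[sig] < 0.05))
    expect_equal(sum(res$group == "high"),
                 sum(res$load[sig] > median(res$load[sig])))
  }
  # E = 1 gives zero load by construction
  expect_equal(10 * max(0, (1 - 1) / 1), 0)
})
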