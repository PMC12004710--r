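test_that("opportunities match hand enumeration against the codon table", {
  # single ATG codon: all 9 substitutions are nonsynonymous
  opp <- mutationOpportunities("ATG")
  expect_equal(unname(opp["synonymous"]), 0)
  expect_equal(sum(opp), 9)
  # independent oracle: enumerate with the genetic code directly
  code <- Biostrings::GENETIC_CODE
  cds <- "ATGCTGAAA"
  want <- c(missense = 0, nonsense = 0, synonymous = 0)
  b <- strsplit(cds, "")[[1]]
  for (p in 1:9) {
    for (alt in setdiff(c("A", "C", "G", "T"), b[p])) {
      b2 <- b; b2[p] <- alt
      ci <- (p - 1) %/% 3
      aa1 <- code[[paste(b[(ci * 3 + 1):(ci * 3 + 3)], collapse = "")]]
      aa2 <- code[[paste(b2[(ci * 3 + 1):(ci * 3 + 3)], collapse = "")]]
      cls <- if (aa1 == aa2) "synonymous" else if (aa2 == "*") "nonsense"
      else "missense"
      want[cls] <- want[cls] + 1
    }
  }
  expect_equal(mutationOpportunities(cds), want)
  expect_error(mutationOpportunities("ATGC"), "divisible")
  expect_error(mutationOpportunities(""), "empty")
})

test_that("dN/dS has the saturation and algebraic identities", {
  # every possible substitution observed exactly once, uniform rates
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep("ACGTTGCAAGTC", 30), collapse = "")))
  genes <- data.frame(gene = "G1", chrom = "chr1", start = 1, end = 360)
  pool <- simulateNeutralMutations(genes, genome, 1, seed = 1)
  ch <- nmibcGenomics:::enumerateCdsChanges(
    as.character(Biostrings::subseq(genome[["chr1"]], 1, 360)))
  muts <- data.frame(sample_id = "S", gene = "G1", chrom = "chr1",
                     pos = ch$pos, ref = ch$ref, alt = ch$alt,
                     consequence = ch$class, context3 = "", is_snv = TRUE)
  tab <- dndsTable(muts, genes, genome, rates = uniformRates())
  for (cl in c("missense", "nonsense", "point-combined"))
    expect_equal(tab$global$dnds[tab$global$class == cl], 1,
                 tolerance = 1e-9)
  # n_non = 20, L_non = 2 L_syn, n_syn = 10 -> dN/dS = 1
  est <- estimateDnds(20, 10, 200, 100)
  expect_equal(est$dnds, 1)
  expect_true(est$lower < 1 && est$upper > 1)
  # zero synonymous flags instability
  expect_true(estimateDnds(5, 0, 10, 10)$unstable)
})

test_that("timing odds ratio classifies phases at the 2 / 0.5 cutoffs", {
  e <- function(w) data.frame(dnds = w, lower = w, upper = w, p = 1,
                              unstable = FALSE)
  expect_equal(timingOddsRatio(e(4), e(1))$phase, "early-favored")
  expect_equal(timingOddsRatio(e(1), e(4))$phase, "late-favored")
  expect_equal(timingOddsRatio(e(1), e(1))$phase, "none")
  expect_equal(timingOddsRatio(e(4), e(1))$or_timing, 4)
  bad <- e(1); bad$unstable <- TRUE
  expect_false(timingOddsRatio(e(4), bad)$evaluable)
})

test_that("pathway pooling reduces and conserves", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep("ACGTTGCAAGTC", 60), collapse = "")))
  genes <- data.frame(gene = c("G1", "G2"), chrom = "chr1",
                      start = c(1, 361), end = c(360, 720))
  muts <- simulateNeutralMutations(genes, genome, 300, seed = 2)
  one <- data.frame(pathway = "P1", gene = "G1")
  pw <- pathwayDnds(one, muts, genes, genome)
  gene <- dndsTable(muts[muts$gene == "G1", ], genes[1, ], genome,
                    rates = uniformRates())
  expect_equal(pw$dnds,
               gene$global$dnds[gene$global$class == "point-combined"],
               tolerance = 1e-9)
  # disjoint pathways partitioning all genes conserve pooled counts
  both <- data.frame(pathway = c("P1", "P2"), gene = c("G1", "G2"))
  pw2 <- pathwayDnds(both, muts, genes, genome)
  expect_equal(sum(pw2$n_class) + sum(pw2$n_syn), nrow(muts))
  # empty pathway is skipped
  expect_equal(nrow(pathwayDnds(data.frame(pathway = "PX", gene = "NOPE"),
                                muts, genes, genome)), 0)
})

test_that("the rate model estimated from synonymous sites is near-truth", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep("ACGTTGCAAGTCGATTGCCA", 60), collapse = "")))
  genes <- data.frame(gene = "G1", chrom = "chr1", start = 1, end = 1200)
  rates <- uniformRates()
  rates["C>T", ] <- 3   # elevated transitions at C
  muts <- simulateNeutralMutations(genes, genome, 4000, rates = rates,
                                   seed = 3)
  syn <- muts[muts$consequence == "synonymous", ]
  est <- estimateRateModel(
    data.frame(type = nmibcGenomics:::foldSubType(syn$ref, syn$alt),
               cpg = ifelse(nmibcGenomics:::isCpgSite(
                 syn$ref, substr(syn$context3, 3, 3),
                 substr(syn$context3, 1, 1)), "CpG", "nonCpG")),
    as.character(Biostrings::subseq(genome[["chr1"]], 1, 1200)))
  # C>T rates should exceed the others by roughly the planted factor
  expect_gt(mean(est["C>T", ]), 1.5 * mean(est[c("C>A", "T>G"), ]))
})
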