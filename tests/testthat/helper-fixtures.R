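# Shared fixtures: one cached simulated cohort reused by read-only tests,
# plus small hand-built tables.

.fixtureEnv <- new.env(parent = emptyenv())

sharedSim <- function() {
  if (is.null(.fixtureEnv$sim))
    .fixtureEnv$sim <- simulateCohort(simulationConfig(seed = 101))
  .fixtureEnv$sim
}

tinyMutations <- function() {
  data.frame(
    sample_id = c("S1", "S1", "S2"),
    chrom = c("chr1", "chr1", "chr2"),
    pos = c(100, 200, 50),
    ref = c("C", "G", "A"),
    alt = c("T", "A", "G"),
    gene = c("TP53", "FGFR3", "KDM6A"),
    consequence = c("missense", "missense", "synonymous"),
    t_alt = c(30, 20, 10),
    t_ref = c(70, 80, 90),
    stringsAsFactors = FALSE)
}

tinySegments <- function() {
  data.frame(
    sample_id = c("S1", "S1", "S2"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1, 101, 1),
    end = c(100, 200, 1000),
    major = c(1, 2, 1),
    minor = c(1, 1, 1),
    stringsAsFactors = FALSE)
}

tinyProfiles <- function() {
  data.frame(sample_id = c("S1", "S2"), purity = c(0.5, 0.8),
             ploidy = c(2, 2), exome_size_mb = c(30, 30),
             stringsAsFactors = FALSE)
}

tinyCohort <- function() {
  assembleCohort(tinyMutations(), tinySegments(), tinyProfiles())
}

toyArms <- function(len = 1000, chroms = c("chr1", "chr2")) {
  do.call(rbind, lapply(chroms, function(c) {
    p <- floor(len * 0.4)
    data.frame(chrom = c, start = c(1, p + 1), end = c(p, len),
               arm = paste0(sub("chr", "", c), c("p", "q")),
               stringsAsFactors = FALSE)
  }))
}
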