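test_that("mutation reader validates rows and preserves order", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTsv(tinyMutations(), path)
  m <- readMutationTable(path)
  expect_equal(nrow(m), 3)
  expect_equal(m$vaf, c(0.3, 0.2, 0.1))
  expect_equal(m$sample_id, c("S1", "S1", "S2"))

  bad <- tinyMutations()
  bad$t_alt[2] <- 0; bad$t_ref[2] <- 0
  writeTsv(bad, path)
  expect_error(readMutationTable(path), "row 2")

  extra <- tinyMutations()
  extra$note <- "x"
  writeTsv(extra, path)
  warns <- character(0)
  m2 <- withCallingHandlers(readMutationTable(path),
                            warning = function(w) {
                              warns <<- c(warns, conditionMessage(w))
                              invokeRestart("muffleWarning")
                            })
  expect_length(warns, 1)
  expect_false("note" %in% names(m2))
})

test_that("unknown consequence strings map to other with a warning", {
  m <- tinyMutations()
  m$consequence[1] <- "weird_thing"
  expect_warning(v <- validateMutations(m), "other")
  expect_equal(v$consequence[1], "other")
  expect_equal(validateMutations(tinyMutations())$consequence[2], "missense")
})

test_that("segment reader enforces sorting, overlap and major >= minor", {
  path <- withr::local_tempfile(fileext = ".tsv")
  ok <- data.frame(sample_id = "S1", chrom = "chr1",
                   start = c(1, 101), end = c(100, 200),
                   major = 1, minor = 1)
  writeTsv(ok, path)
  expect_equal(nrow(readSegmentTable(path)), 2)

  bad <- ok; bad$start[2] <- 50
  writeTsv(bad, path)
  expect_error(readSegmentTable(path), "overlap")

  bad2 <- ok; bad2$major[1] <- 1; bad2$minor[1] <- 2
  writeTsv(bad2, path)
  expect_error(readSegmentTable(path), "major < minor")
})

test_that("locateSegment respects closed intervals and matches brute force", {
  segs <- validateSegments(tinySegments())
  q <- data.frame(sample_id = c("S1", "S1", "S1", "S2"),
                  chrom = c("chr1", "chr1", "chr1", "chr2"),
                  pos = c(50, 100, 250, 1500))
  idx <- locateSegment(q, segs)
  expect_equal(segs$start[idx[1]], 1)
  expect_equal(segs$end[idx[2]], 100)  # boundary inclusive
  expect_true(is.na(idx[3]))
  expect_true(is.na(idx[4]))

  # brute-force agreement on random fixtures
  set.seed(42)
  for (rep in 1:5) {
    st <- sort(sample(1:900, 6))
    en <- c(st[-1] - 1, 1000)
    segs2 <- validateSegments(data.frame(
      sample_id = "X", chrom = "chr1", start = st, end = en,
      major = 2, minor = 1))
    qs <- data.frame(sample_id = "X", chrom = "chr1",
                     pos = sample(1:1100, 50, replace = TRUE))
    got <- locateSegment(qs, segs2)
    brute <- vapply(qs$pos, function(p) {
      hit <- which(segs2$start <= p & segs2$end >= p)
      if (length(hit)) hit[1] else NA_integer_
    }, integer(1))
    expect_equal(got, brute)
  }
})

test_that("cohort assembly validates sample consistency", {
  co <- tinyCohort()
  expect_s4_class(co, "NmibcCohort")
  expect_equal(length(sampleIds(co)), 2)

  orphan <- tinyMutations()
  orphan$sample_id[3] <- "S99"
  expect_error(assembleCohort(orphan, tinySegments(), tinyProfiles()),
               "S99")
  # zero-mutation sample allowed
  co2 <- assembleCohort(tinyMutations()[0, ], tinySegments(),
                        tinyProfiles())
  expect_equal(nrow(mutations(co2)), 0)
})

test_that("write-then-read round-trip is identity on fields", {
  sim <- sharedSim()
  dir <- withr::local_tempdir()
  paths <- writeCohortTables(sim$cohort, dir)
  m2 <- readMutationTable(paths[["mutations"]])
  m1 <- mutations(sim$cohort)
  expect_equal(m2[names(m2)], m1[names(m2)])
  s2 <- readSegmentTable(paths[["segments"]])
  s1 <- segments(sim$cohort)
  expect_equal(s2, s1)
  p2 <- readPurityTable(paths[["profiles"]])
  expect_equal(p2, profiles(sim$cohort))
  c2 <- readClinicalTable(paths[["clinical"]])
  expect_equal(c2, clinical(sim$cohort))
})

test_that("clinical and annotation readers enforce invariants", {
  path <- withr::local_tempfile(fileext = ".tsv")
  clin <- data.frame(sample_id = "S1", stage = "Ta", grade = "HG",
                     therapy = "chemo", rfs_months = 0, event = 1)
  writeTsv(clin, path)
  expect_error(readClinicalTable(path), "rfs_months > 0")
  ann <- data.frame(gene = "TP53", role = "tumour")
  writeTsv(ann, path)
  expect_error(readGeneAnnotation(path), "role")
})
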