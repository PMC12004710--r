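test_that("deleteriousness rule follows stop-gain and 2-of-3 logic", {
  expect_true(isDeleterious("nonsense"))
  expect_true(isDeleterious("missense", "deleterious", "deleterious",
                            "tolerated"))
  expect_false(isDeleterious("missense", "deleterious", "tolerated",
                             "tolerated"))
  expect_warning(
    r <- isDeleterious("missense", "missing", "missing", "missing"),
    "indeterminate")
  expect_false(r)
  # frameshift indels count as stop-gain equivalents unless disabled
  expect_true(isDeleterious("indel"))
  expect_warning(expect_false(
    isDeleterious("indel", frameshift_as_stopgain = FALSE)))
})

test_that("driver classification fires the documented rules", {
  tsg <- data.frame(gene = "TP53", role = "TSG", oncogenic_variants = "",
                    cosmic_counts = "")
  onc3 <- data.frame(gene = "FGFR3", role = "oncogene",
                     oncogenic_variants = "",
                     cosmic_counts = "FGFR3:chr4:1:A>G:3")
  onc2 <- data.frame(gene = "FGFR3", role = "oncogene",
                     oncogenic_variants = "",
                     cosmic_counts = "FGFR3:chr4:1:A>G:2")
  okb <- data.frame(gene = "HRAS", role = "oncogene",
                    oncogenic_variants = "HRAS:chr1:5:C>T",
                    cosmic_counts = "")
  r <- classifyDriver("TP53", "TP53:chr7:9:G>T", TRUE, tsg)
  expect_true(r$is_driver); expect_equal(r$rule_fired, "TSG-deleterious")
  r <- classifyDriver("FGFR3", "FGFR3:chr4:1:A>G", FALSE, onc3)
  expect_true(r$is_driver); expect_equal(r$rule_fired, "oncogene-recurrent")
  r <- classifyDriver("FGFR3", "FGFR3:chr4:1:A>G", FALSE, onc2)
  expect_false(r$is_driver)
  r <- classifyDriver("HRAS", "HRAS:chr1:5:C>T", FALSE, okb)
  expect_true(r$is_driver); expect_equal(r$rule_fired, "oncokb-oncogenic")
  # unannotated gene is never a driver
  expect_false(classifyDriver("X", "X:1:1:A>C", TRUE, NULL)$is_driver)
  # "both"-role ties resolve TSG first
  both <- data.frame(gene = "G", role = "both",
                     oncogenic_variants = "G:c:1:A>C", cosmic_counts = "")
  expect_equal(classifyDriver("G", "G:c:1:A>C", TRUE, both)$rule_fired,
               "TSG-deleterious")
})

test_that("adding a deleterious verdict never flips a driver off", {
  set.seed(5)
  verd <- c("deleterious", "tolerated", "missing")
  ann <- data.frame(gene = "G", role = "TSG", oncogenic_variants = "",
                    cosmic_counts = "")
  for (i in 1:200) {
    v <- sample(verd, 3, replace = TRUE)
    cons <- sample(c("missense", "nonsense"), 1)
    base <- suppressWarnings(isDeleterious(cons, v[1], v[2], v[3]))
    for (j in 1:3) {
      v2 <- v; v2[j] <- "deleterious"
      up <- suppressWarnings(isDeleterious(cons, v2[1], v2[2], v2[3]))
      expect_true(up >= base)
      d1 <- classifyDriver("G", "k", base, ann)$is_driver
      d2 <- classifyDriver("G", "k", up, ann)$is_driver
      expect_true(d2 >= d1)
    }
  }
})

test_that("rule engine equals brute-force clause evaluation on random variants", {
  set.seed(7)
  roles <- c("TSG", "oncogene", "both", "none")
  for (i in 1:1000) {
    role <- sample(roles, 1)
    cons <- sample(c("missense", "nonsense", "indel"), 1)
    v <- sample(c("deleterious", "tolerated", "missing"), 3, replace = TRUE)
    inOkb <- runif(1) < 0.3
    cc <- sample(0:5, 1)
    key <- "G:c:1:A>C"
    ann <- data.frame(gene = "G", role = role,
                      oncogenic_variants = if (inOkb) key else "",
                      cosmic_counts = paste0(key, ":", cc))
    del <- suppressWarnings(isDeleterious(cons, v[1], v[2], v[3]))
    got <- classifyDriver("G", key, del, ann)$is_driver
    # independent clause-by-clause re-evaluation
    delB <- (cons %in% c("nonsense", "indel")) ||
      sum(v == "deleterious") >= 2
    want <- (delB && role %in% c("TSG", "both")) ||
      (role %in% c("oncogene", "both") && (cc >= 3 || inOkb))
    expect_equal(got, want)
  }
})

test_that("cohort driver catalog is deterministic and counts qualifiers", {
  ann <- data.frame(
    gene = c("TP53", "FGFR3"),
    role = c("TSG", "oncogene"),
    oncogenic_variants = c("", "FGFR3:chr1:200:G>A"),
    cosmic_counts = c("", ""), stringsAsFactors = FALSE)
  muts <- data.frame(
    sample_id = c("S1", "S1", "S1", "S2", "S2"),
    chrom = "chr1", pos = c(10, 200, 30, 40, 200),
    ref = c("C", "G", "C", "C", "G"), alt = c("T", "A", "A", "G", "A"),
    gene = c("TP53", "FGFR3", "TP53", "OTHER", "FGFR3"),
    consequence = c("nonsense", "missense", "missense", "nonsense",
                    "missense"),
    t_alt = 20, t_ref = 80,
    sift = c("", "", "tolerated", "", ""),
    polyphen = c("", "", "tolerated", "", ""),
    mutationtaster = c("", "", "deleterious", "", ""),
    stringsAsFactors = FALSE)
  segs <- data.frame(sample_id = c("S1", "S2"), chrom = "chr1",
                     start = 1, end = 1000, major = 1, minor = 1)
  prof <- data.frame(sample_id = c("S1", "S2"), purity = 0.5, ploidy = 2,
                     exome_size_mb = 30)
  co <- assembleCohort(muts, segs, prof, annotations = ann)
  dc <- suppressWarnings(buildDriverCatalog(co))
  # qualifying: TP53 nonsense (TSG-deleterious), FGFR3 oncogenic (x2 samples)
  expect_equal(nrow(dc$catalog), 2)
  expect_equal(sum(dc$calls$is_driver), 3)
  dc2 <- suppressWarnings(buildDriverCatalog(co))
  expect_identical(dc, dc2)
  # empty cohort gives an empty catalog
  co0 <- assembleCohort(muts[0, ], segs, prof, annotations = ann)
  expect_equal(nrow(buildDriverCatalog(co0)$catalog), 0)
})
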