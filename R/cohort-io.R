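# Validated readers/writers for every table the pipeline touches, plus cohort
# assembly. All tables are tab-separated UTF-8 with a header row (see
# writeTsv); coordinates are 1-based, fully closed intervals for both
# mutations and segments (the ASCAT convention). Sex chromosomes are retained
# at ingest; timing and wGII exclude them by default downstream.

CONSEQUENCE_LEVELS <- c("missense", "nonsense", "splice", "synonymous",
                        "indel", "other")

normalizeConsequence <- function(x) {
  x0 <- tolower(trimws(x))
  map <- c(
    missense = "missense", missense_variant = "missense",
    nonsense = "nonsense", `stop-gain` = "nonsense", stopgain = "nonsense",
    stop_gained = "nonsense", stop_gain = "nonsense",
    splice = "splice", splice_site = "splice", splice_region = "splice",
    synonymous = "synonymous", silent = "synonymous",
    synonymous_variant = "synonymous",
    indel = "indel", frameshift = "indel", frameshift_variant = "indel",
    insertion = "indel", deletion = "indel", inframe_indel = "indel",
    other = "other"
  )
  out <- unname(map[x0])
  unknown <- is.na(out)
  if (any(unknown)) {
    warning(sum(unknown), " mutation row(s) with unknown consequence mapped",
            " to 'other'", call. = FALSE)
    out[unknown] <- "other"
  }
  out
}

normalizeSampleColumn <- function(df) {
  if (!"sample_id" %in% names(df) && "sample" %in% names(df))
    names(df)[names(df) == "sample"] <- "sample_id"
  df
}

#' Read a MAF-like somatic mutation table
#'
#' Required columns: `sample_id` (or `sample`), `chrom`, `pos` (1-based),
#' `ref`, `alt`, `gene`, `consequence`, `t_alt`, `t_ref`. Optional columns
#' `context3` (+-strand trinucleotide around the site) and the precomputed
#' predictor verdicts `sift`, `polyphen`, `mutationtaster` are kept; any
#' other column is ignored with a single warning. Every row is validated
#' (pos >= 1, t_alt + t_ref >= 1, ref != alt, SNV iff both alleles are one
#' base) and violations raise an error naming the first offending row.
#'
#' @param path path to the TSV file.
#' @return data.frame of validated mutation records, input order preserved,
#'   with a `vaf` column `t_alt / (t_alt + t_ref)` appended.
#' @export
readMutationTable <- function(path) {
  df <- normalizeSampleColumn(readTsv(path))
  validateMutations(df, what = basename(path))
}

#' @noRd
validateMutations <- function(df, what = "mutations") {
  req <- c("sample_id", "chrom", "pos", "ref", "alt", "gene", "consequence",
           "t_alt", "t_ref")
  requireColumns(df, req, what)
  opt <- c("context3", "sift", "polyphen", "mutationtaster")
  extra <- setdiff(names(df), c(req, opt))
  if (length(extra)) {
    warning("ignoring unknown column(s) in ", what, ": ",
            paste(extra, collapse = ", "), call. = FALSE)
    df <- df[, setdiff(names(df), extra), drop = FALSE]
  }
  if (!nrow(df)) {
    df$vaf <- numeric(0)
    return(df)
  }
  df$pos <- asCount(df$pos, "pos", what)
  df$t_alt <- asCount(df$t_alt, "t_alt", what)
  df$t_ref <- asCount(df$t_ref, "t_ref", what)
  bad <- function(cond, msgf) {
    i <- which(cond)
    if (length(i)) stop("invalid mutation row ", i[1L], ": ", msgf,
                        call. = FALSE)
  }
  bad(is.na(df$pos) | df$pos < 1 | df$pos != round(df$pos),
      "pos must be a positive integer")
  bad(is.na(df$t_alt) | is.na(df$t_ref) | df$t_alt < 0 | df$t_ref < 0,
      "read counts must be non-negative")
  bad(df$t_alt + df$t_ref < 1, "t_alt + t_ref must be >= 1")
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  bad(!isDnaString(df$ref) | !isDnaString(df$alt), "ref/alt must be A/C/G/T")
  bad(df$ref == df$alt, "ref must differ from alt")
  df$consequence <- normalizeConsequence(df$consequence)
  if (!"context3" %in% names(df)) df$context3 <- ""
  df$context3[is.na(df$context3)] <- ""
  df$is_snv <- nchar(df$ref) == 1L & nchar(df$alt) == 1L
  df$vaf <- df$t_alt / (df$t_alt + df$t_ref)
  rownames(df) <- NULL
  df
}

#' Read an ASCAT-style allele-specific copy-number segment table
#'
#' Required columns: `sample_id` (or `sample`), `chrom`, `start`, `end`
#' (1-based inclusive), `major`, `minor`. Segments are sorted per sample and
#' chromosome; overlapping segments or `major < minor` raise an error naming
#' the offending pair/row.
#'
#' @param path path to the TSV file.
#' @return validated, sorted data.frame with a `cnt` (total copy number)
#'   column appended.
#' @export
readSegmentTable <- function(path) {
  df <- normalizeSampleColumn(readTsv(path))
  validateSegments(df, what = basename(path))
}

#' @noRd
validateSegments <- function(df, what = "segments") {
  requireColumns(df, c("sample_id", "chrom", "start", "end", "major",
                       "minor"), what)
  if (!nrow(df)) {
    df$cnt <- numeric(0)
    return(df)
  }
  for (col in c("start", "end", "major", "minor"))
    df[[col]] <- asCount(df[[col]], col, what)
  if (any(df$start > df$end))
    stop("segment with start > end at row ", which(df$start > df$end)[1L],
         call. = FALSE)
  if (any(df$major < 0 | df$minor < 0))
    stop("negative allele copy number", call. = FALSE)
  i <- which(df$major < df$minor)
  if (length(i))
    stop("segment invariant violated (major < minor) at row ", i[1L],
         call. = FALSE)
  df <- df[order(df$sample_id, df$chrom, df$start), , drop = FALSE]
  key <- paste(df$sample_id, df$chrom)
  same <- key[-1L] == key[-nrow(df)]
  ovl <- which(same & df$start[-1L] <= df$end[-nrow(df)])
  if (length(ovl))
    stop("overlapping segments for ", key[ovl[1L]], ": [",
         df$start[ovl[1L]], ",", df$end[ovl[1L]], "] and [",
         df$start[ovl[1L] + 1L], ",", df$end[ovl[1L] + 1L], "]",
         call. = FALSE)
  df$cnt <- df$major + df$minor
  rownames(df) <- NULL
  df
}

#' Read the purity/ploidy sample-profile table
#'
#' Required columns: `sample_id`, `purity` (rho in (0,1]), `ploidy` (psi > 0).
#' Optional `exome_size_mb` defaults to 30.
#'
#' @param path path to the TSV file.
#' @return validated data.frame.
#' @export
readPurityTable <- function(path) {
  df <- normalizeSampleColumn(readTsv(path))
  requireColumns(df, c("sample_id", "purity", "ploidy"), basename(path))
  df$purity <- asCount(df$purity, "purity", basename(path))
  df$ploidy <- asCount(df$ploidy, "ploidy", basename(path))
  if (!"exome_size_mb" %in% names(df)) df$exome_size_mb <- 30
  if (any(!is.finite(df$purity)) || any(df$purity <= 0 | df$purity > 1))
    stop("purity must lie in (0, 1]", call. = FALSE)
  if (any(!is.finite(df$ploidy)) || any(df$ploidy <= 0))
    stop("ploidy must be finite and positive", call. = FALSE)
  if (any(df$exome_size_mb <= 0))
    stop("exome_size_mb must be positive", call. = FALSE)
  df
}

#' Read the clinical table
#'
#' Required columns: `sample_id`, `stage` (Ta/T1/Tis), `grade`
#' (HG/LG/PUNLMP), `therapy` (chemo/BCG/none), `rfs_months` (>= 0), `event`
#' (0/1; an event requires positive follow-up time).
#'
#' @param path path to the TSV file.
#' @return validated data.frame.
#' @export
readClinicalTable <- function(path) {
  df <- normalizeSampleColumn(readTsv(path))
  validateClinical(df, basename(path))
}

#' @noRd
validateClinical <- function(df, what = "clinical") {
  requireColumns(df, c("sample_id", "stage", "grade", "therapy",
                       "rfs_months", "event"), what)
  if (!nrow(df)) return(df)
  df$rfs_months <- asCount(df$rfs_months, "rfs_months", what)
  df$event <- asCount(df$event, "event", what)
  if (!all(df$stage %in% c("Ta", "T1", "Tis")))
    stop("stage must be one of Ta, T1, Tis", call. = FALSE)
  if (!all(df$grade %in% c("HG", "LG", "PUNLMP")))
    stop("grade must be one of HG, LG, PUNLMP", call. = FALSE)
  if (!all(df$therapy %in% c("chemo", "BCG", "none")))
    stop("therapy must be one of chemo, BCG, none", call. = FALSE)
  if (any(df$rfs_months < 0) || !all(df$event %in% c(0, 1)))
    stop("rfs_months must be >= 0 and event in {0,1}", call. = FALSE)
  i <- which(df$event == 1 & df$rfs_months <= 0)
  if (length(i))
    stop("event = 1 requires rfs_months > 0 (row ", i[1L], ")",
         call. = FALSE)
  df
}

#' Read the gene-role annotation table
#'
#' Required columns: `gene`, `role` (TSG/oncogene/both/none). Optional
#' `oncogenic_variants` is a semicolon-separated list of variant keys
#' (`gene:chrom:pos:ref>alt` or protein changes) and `cosmic_counts` a
#' semicolon-separated `key:count` list of exact COSMIC match counts.
#'
#' @param path path to the TSV file.
#' @return validated data.frame.
#' @export
readGeneAnnotation <- function(path) {
  df <- readTsv(path)
  requireColumns(df, c("gene", "role"), basename(path))
  if (!all(df$role %in% c("TSG", "oncogene", "both", "none")))
    stop("role must be one of TSG, oncogene, both, none", call. = FALSE)
  if (!"oncogenic_variants" %in% names(df)) df$oncogenic_variants <- ""
  if (!"cosmic_counts" %in% names(df)) df$cosmic_counts <- ""
  df$oncogenic_variants[is.na(df$oncogenic_variants)] <- ""
  df$cosmic_counts[is.na(df$cosmic_counts)] <- ""
  cnts <- unlist(lapply(strsplit(df$cosmic_counts, ";", fixed = TRUE),
                        function(x) {
                          x <- x[nzchar(x)]
                          as.numeric(sub("^.*:", "", x))
                        }))
  if (length(cnts) && (anyNA(cnts) || any(cnts < 0)))
    stop("cosmic_counts entries must be 'key:count' with count >= 0",
         call. = FALSE)
  df
}

#' Locate the copy-number segment covering a position
#'
#' Returns, for each mutation, the row index into `segments` of the unique
#' segment of the same sample and chromosome whose closed interval
#' `[start, end]` contains `pos`, or `NA` when no segment covers the site
#' (a legal outcome; such mutations are untimeable downstream).
#'
#' @param muts data.frame with `sample_id`, `chrom`, `pos`.
#' @param segs validated segment data.frame (see [readSegmentTable()]).
#' @return integer vector of row indices into `segs`, `NA` where uncovered.
#' @export
locateSegment <- function(muts, segs) {
  if (!nrow(muts)) return(integer(0))
  out <- rep(NA_integer_, nrow(muts))
  if (!nrow(segs)) return(out)
  skey <- paste(segs$sample_id, segs$chrom)
  mkey <- paste(muts$sample_id, muts$chrom)
  for (k in unique(mkey)) {
    si <- which(skey == k)
    if (!length(si)) next
    mi <- which(mkey == k)
    # segments are validated non-overlapping and sorted; findInterval on
    # starts then check the end bound
    o <- si[order(segs$start[si])]
    j <- findInterval(muts$pos[mi], segs$start[o])
    hit <- j >= 1L & muts$pos[mi] <= segs$end[o[pmax(j, 1L)]]
    out[mi[hit]] <- o[j[hit]]
  }
  out
}

#' Assemble a validated cohort object
#'
#' Binds the five tables (plus an optional expression count matrix) into an
#' [NmibcCohort]. Mutation, segment and clinical sample sets must be subsets
#' of the profile table; violations raise an error listing the offending
#' samples. Samples with zero mutations are allowed (their TMB is 0).
#'
#' @param mutations,segments,profiles,clinical,annotations data.frames as
#'   returned by the corresponding readers (re-validated here).
#' @param exprCounts optional numeric matrix, genes x samples.
#' @return an [NmibcCohort].
#' @export
assembleCohort <- function(mutations, segments, profiles,
                           clinical = NULL, annotations = NULL,
                           exprCounts = NULL) {
  mutations <- validateMutations(normalizeSampleColumn(mutations))
  segments <- validateSegments(normalizeSampleColumn(segments))
  clinical <- if (is.null(clinical)) data.frame() else
    validateClinical(normalizeSampleColumn(clinical))
  annotations <- annotations %||% data.frame()
  exprCounts <- exprCounts %||% matrix(numeric(0), 0, 0)
  obj <- methods::new("NmibcCohort",
                      mutations = mutations, segments = segments,
                      profiles = profiles, clinical = clinical,
                      annotations = annotations,
                      exprCounts = as.matrix(exprCounts))
  methods::validObject(obj)
  obj
}

#' Write all cohort tables to a directory
#'
#' Emits the same TSV dialect the readers parse, so a write-then-read
#' round-trip is identity on fields.
#'
#' @param cohort an [NmibcCohort].
#' @param dir output directory (created if absent).
#' @return named character vector of the files written, invisibly.
#' @export
writeCohortTables <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    mutations = file.path(dir, "mutations.tsv"),
    segments = file.path(dir, "segments.tsv"),
    profiles = file.path(dir, "profiles.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    annotations = file.path(dir, "annotations.tsv")
  )
  writeTsv(mutations(cohort)[setdiff(names(mutations(cohort)),
                                     c("vaf", "is_snv"))], paths["mutations"])
  writeTsv(segments(cohort)[setdiff(names(segments(cohort)), "cnt")],
           paths["segments"])
  writeTsv(profiles(cohort), paths["profiles"])
  if (nrow(clinical(cohort))) writeTsv(clinical(cohort), paths["clinical"])
  if (nrow(annotations(cohort)))
    writeTsv(annotations(cohort), paths["annotations"])
  if (length(exprCounts(cohort))) {
    ex <- data.frame(gene = rownames(exprCounts(cohort)),
                     exprCounts(cohort), check.names = FALSE)
    paths <- c(paths, expression = file.path(dir, "expression.tsv"))
    writeTsv(ex, paths["expression"])
  }
  invisible(paths)
}

# ---- accessors and show ----------------------------------------------------

#' @rdname NmibcCohort-class
#' @export
setMethod("mutations", "NmibcCohort", function(x) x@mutations)

#' @rdname NmibcCohort-class
#' @export
setMethod("segments", "NmibcCohort", function(x) x@segments)

#' @rdname NmibcCohort-class
#' @export
setMethod("profiles", "NmibcCohort", function(x) x@profiles)

#' @rdname NmibcCohort-class
#' @export
setMethod("clinical", "NmibcCohort", function(x) x@clinical)

#' @rdname NmibcCohort-class
#' @export
setMethod("annotations", "NmibcCohort", function(x) x@annotations)

#' @rdname NmibcCohort-class
#' @export
setMethod("exprCounts", "NmibcCohort", function(x) x@exprCounts)

#' @rdname NmibcCohort-class
#' @export
setMethod("sampleIds", "NmibcCohort", function(x) x@profiles$sample_id)

setMethod("show", "NmibcCohort", function(object) {
  cat("NmibcCohort with", nrow(object@profiles), "samples\n")
  cat("  mutations :", nrow(object@mutations), "\n")
  cat("  segments  :", nrow(object@segments), "\n")
  cat("  clinical  :", nrow(object@clinical), "records\n")
  cat("  expression:",
      if (length(object@exprCounts))
        paste(nrow(object@exprCounts), "genes x",
              ncol(object@exprCounts), "samples")
      else "absent", "\n")
})

#' @rdname SubtypeModel-class
#' @export
setMethod("subtypeLabels", "SubtypeModel", function(x) x@labels)

#' @rdname SubtypeModel-class
#' @export
setMethod("consensusMatrix", "SubtypeModel", function(x) x@consensus)

#' @rdname SubtypeModel-class
#' @export
setMethod("copheneticCoefficients", "SubtypeModel",
          function(x) x@cophenetic)

#' @rdname SubtypeModel-class
#' @export
setMethod("subtypeEnrichment", "SubtypeModel", function(x) x@enrichment)

setMethod("show", "SubtypeModel", function(object) {
  cat("SubtypeModel: rank", object@rank, "over",
      length(object@labels), "samples\n")
  if (length(object@cophenetic)) {
    cat("  cophenetic:",
        paste(sprintf("k=%s %.3f", names(object@cophenetic),
                      object@cophenetic), collapse = ", "), "\n")
  }
  if (length(object@labels))
    cat("  sizes:", paste(tabulate(object@labels, object@rank),
                          collapse = "/"), "\n")
})
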