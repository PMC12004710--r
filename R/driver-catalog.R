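# Driver-mutation rule engine. A nonsynonymous variant is a driver when
# (a) it is deleterious (stop-gain, or >= 2 of the SIFT/PolyPhen/
# MutationTaster verdicts say deleterious) AND the gene is a curated tumor
# suppressor, or (b) the gene is a curated oncogene AND the exact variant has
# >= 3 COSMIC matches or is listed oncogenic (OncoKB-style set). Predictor
# verdicts are ingested as precomputed columns; the engine implements only
# the combination rule. Frameshift indels are treated as stop-gain
# equivalents by default (`frameshift_as_stopgain = FALSE` disables this).

#' Deleteriousness rule for one variant class
#'
#' TRUE iff the variant is a stop-gain (or, by default, a frameshift indel)
#' or at least two of the three predictor verdicts are "deleterious". When a
#' non-stop-gain variant carries no verdict at all the call is indeterminate:
#' FALSE with a warning.
#'
#' @param consequence normalized consequence string(s).
#' @param sift,polyphen,mutationtaster verdicts, each one of
#'   `"deleterious"`, `"tolerated"`, `"missing"` (empty/NA count as missing).
#' @param frameshift_as_stopgain treat indels as stop-gain equivalents.
#' @return logical vector.
#' @export
isDeleterious <- function(consequence, sift = "missing",
                          polyphen = "missing",
                          mutationtaster = "missing",
                          frameshift_as_stopgain = TRUE) {
  n <- length(consequence)
  norm <- function(x) {
    x <- as.character(rep_len(x, n))
    x[is.na(x) | !nzchar(x)] <- "missing"
    x
  }
  v <- cbind(norm(sift), norm(polyphen), norm(mutationtaster))
  nDel <- rowSums(v == "deleterious")
  nMiss <- rowSums(v == "missing")
  stopGain <- consequence == "nonsense" |
    (frameshift_as_stopgain & consequence == "indel")
  indet <- !stopGain & nMiss == 3L
  if (any(indet))
    warning(sum(indet), " variant(s) with all predictor verdicts missing: ",
            "indeterminate, treated as not deleterious", call. = FALSE)
  stopGain | nDel >= 2L
}

#' Classify one variant against the driver rules
#'
#' @param gene gene symbol.
#' @param variantKey genomic variant key `gene:chrom:pos:ref>alt` (the key
#'   convention used in annotation `oncogenic_variants`/`cosmic_counts`).
#' @param deleterious logical from [isDeleterious()].
#' @param annotation one row of the gene-annotation table (or NULL when the
#'   gene is not annotated: non-driver).
#' @return list with `is_driver` and `rule_fired` (one of
#'   `"TSG-deleterious"`, `"oncokb-oncogenic"`, `"oncogene-recurrent"`,
#'   `"none"`). Genes with role `"both"` may fire either path; for reporting
#'   ties resolve in the fixed order TSG-deleterious > oncokb-oncogenic >
#'   oncogene-recurrent.
#' @export
classifyDriver <- function(gene, variantKey, deleterious, annotation) {
  if (is.null(annotation) || !nrow(annotation))
    return(list(is_driver = FALSE, rule_fired = "none"))
  role <- annotation$role[1L]
  if (deleterious && role %in% c("TSG", "both"))
    return(list(is_driver = TRUE, rule_fired = "TSG-deleterious"))
  if (role %in% c("oncogene", "both")) {
    oncSet <- strsplit(annotation$oncogenic_variants[1L], ";",
                       fixed = TRUE)[[1]]
    if (variantKey %in% oncSet)
      return(list(is_driver = TRUE, rule_fired = "oncokb-oncogenic"))
    cc <- strsplit(annotation$cosmic_counts[1L], ";", fixed = TRUE)[[1]]
    cc <- cc[nzchar(cc)]
    if (length(cc)) {
      keys <- sub(":[0-9]+$", "", cc)
      counts <- as.numeric(sub("^.*:", "", cc))
      i <- match(variantKey, keys)
      if (!is.na(i) && counts[i] >= 3)
        return(list(is_driver = TRUE, rule_fired = "oncogene-recurrent"))
    }
  }
  list(is_driver = FALSE, rule_fired = "none")
}

#' Build the cohort driver catalog
#'
#' Applies [isDeleterious()] + [classifyDriver()] to every nonsynonymous
#' variant of the cohort. Deterministic: identical input yields an identical
#' catalog.
#'
#' @param cohort an [NmibcCohort] (annotations slot must be populated).
#' @param frameshift_as_stopgain see [isDeleterious()].
#' @return list with `calls` (per-variant data.frame: sample_id, gene,
#'   variant_key, is_driver, rule_fired), `catalog` (unique driver (gene,
#'   variant) pairs), and `per_gene` (driver counts per gene).
#' @export
buildDriverCatalog <- function(cohort, frameshift_as_stopgain = TRUE) {
  muts <- mutations(cohort)
  ann <- annotations(cohort)
  nonsyn <- muts[muts$consequence %in% c("missense", "nonsense", "splice",
                                         "indel"), , drop = FALSE]
  if (!nrow(nonsyn)) {
    empty <- data.frame(sample_id = character(0), gene = character(0),
                        variant_key = character(0), is_driver = logical(0),
                        rule_fired = character(0), stringsAsFactors = FALSE)
    return(list(calls = empty,
                catalog = empty[, c("gene", "variant_key")],
                per_gene = data.frame(gene = character(0),
                                      n_driver = integer(0))))
  }
  key <- paste0(nonsyn$gene, ":", nonsyn$chrom, ":", nonsyn$pos, ":",
                nonsyn$ref, ">", nonsyn$alt)
  del <- suppressWarnings(isDeleterious(
    nonsyn$consequence,
    nonsyn$sift %||% "missing",
    nonsyn$polyphen %||% "missing",
    nonsyn$mutationtaster %||% "missing",
    frameshift_as_stopgain = frameshift_as_stopgain))
  isDrv <- logical(nrow(nonsyn))
  rule <- character(nrow(nonsyn))
  annIdx <- if (nrow(ann)) match(nonsyn$gene, ann$gene) else
    rep(NA_integer_, nrow(nonsyn))
  for (i in seq_len(nrow(nonsyn))) {
    a <- if (is.na(annIdx[i])) NULL else ann[annIdx[i], , drop = FALSE]
    r <- classifyDriver(nonsyn$gene[i], key[i], del[i], a)
    isDrv[i] <- r$is_driver
    rule[i] <- r$rule_fired
  }
  calls <- data.frame(sample_id = nonsyn$sample_id, gene = nonsyn$gene,
                      variant_key = key, is_driver = isDrv,
                      rule_fired = rule, stringsAsFactors = FALSE)
  cat0 <- unique(calls[calls$is_driver, c("gene", "variant_key")])
  cat0 <- cat0[order(cat0$gene, cat0$variant_key), , drop = FALSE]
  rownames(cat0) <- NULL
  perGene <- as.data.frame(table(calls$gene[calls$is_driver]),
                           stringsAsFactors = FALSE)
  names(perGene) <- c("gene", "n_driver")
  list(calls = calls, catalog = cat0, per_gene = perGene)
}

#' Per-sample driver gene flags
#'
#' @param driverCalls `calls` element of [buildDriverCatalog()].
#' @param samples character vector of sample ids (matrix row order).
#' @return logical matrix samples x driver genes.
#' @export
driverFlagMatrix <- function(driverCalls, samples) {
  drv <- driverCalls[driverCalls$is_driver, , drop = FALSE]
  genes <- sort(unique(drv$gene))
  m <- matrix(FALSE, length(samples), length(genes),
              dimnames = list(samples, genes))
  if (nrow(drv))
    m[cbind(match(drv$sample_id, samples), match(drv$gene, genes))] <- TRUE
  m
}
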