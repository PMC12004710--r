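# S4 containers. The cohort container holds the five validated tables the
# pipeline consumes; the subtype model holds NMF factors and diagnostics.

#' NmibcCohort: validated container for a sequenced NMIBC cohort
#'
#' Binds the per-variant mutation table, allele-specific copy-number
#' segments, purity/ploidy sample profiles, clinical records, gene-role
#' annotations and (optionally) a gene-by-sample expression count matrix into
#' a single validated object. Construct with [assembleCohort()]; slots are
#' reached through the accessors ([mutations()], [segments()], [profiles()],
#' [clinical()], [annotations()], [exprCounts()]), never directly.
#'
#' @slot mutations data.frame of somatic variants (one row per variant).
#' @slot segments data.frame of allele-specific copy-number segments.
#' @slot profiles data.frame of per-sample purity, ploidy and exome size.
#' @slot clinical data.frame of stage/grade/therapy/recurrence records.
#' @slot annotations data.frame of gene roles and oncogenic-variant lists.
#' @slot exprCounts numeric matrix (genes x samples) of expression counts,
#'   or a 0 x 0 matrix when expression was not profiled.
#'
#' @name NmibcCohort-class
#' @aliases NmibcCohort
#' @export
setClass("NmibcCohort",
  representation(
    mutations   = "data.frame",
    segments    = "data.frame",
    profiles    = "data.frame",
    clinical    = "data.frame",
    annotations = "data.frame",
    exprCounts  = "matrix"
  ),
  prototype(
    mutations   = data.frame(),
    segments    = data.frame(),
    profiles    = data.frame(),
    clinical    = data.frame(),
    annotations = data.frame(),
    exprCounts  = matrix(numeric(0), 0, 0)
  )
)

setValidity("NmibcCohort", function(object) {
  msg <- character(0)
  prof <- object@profiles
  if (nrow(prof)) {
    if (anyDuplicated(prof$sample_id))
      msg <- c(msg, "duplicated sample_id in profiles")
    if (any(!is.finite(prof$purity)) || any(prof$purity <= 0 | prof$purity > 1))
      msg <- c(msg, "purity must lie in (0, 1]")
    if (any(!is.finite(prof$ploidy)) || any(prof$ploidy <= 0))
      msg <- c(msg, "ploidy must be finite and > 0")
  }
  for (tab in c("mutations", "segments", "clinical")) {
    df <- slot(object, tab)
    if (nrow(df)) {
      extra <- setdiff(unique(df$sample_id), prof$sample_id)
      if (length(extra))
        msg <- c(msg, paste0(tab, " contain sample(s) absent from profiles: ",
                             paste(extra, collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' SubtypeModel: NMF consensus-subtyping result
#'
#' Holds the Brunet-NMF factors at the selected rank, consensus-clustering
#' diagnostics over the candidate ranks, per-sample subtype labels and the
#' per-subtype feature-enrichment table. Produced by [fitSubtypes()] /
#' [selectRank()]; inspect with [subtypeLabels()], [consensusMatrix()],
#' [copheneticCoefficients()] and [subtypeEnrichment()].
#'
#' @slot basis numeric matrix, events x rank.
#' @slot coef numeric matrix, rank x samples.
#' @slot rank integer, the selected factorization rank.
#' @slot labels named integer vector of per-sample subtype labels (1..rank).
#' @slot consensus numeric samples x samples consensus matrix at the
#'   selected rank.
#' @slot cophenetic named numeric vector of cophenetic correlation per
#'   candidate rank.
#' @slot enrichment data.frame of per-subtype feature enrichment (Fisher OR,
#'   p, BH q), possibly empty until [characterizeSubtypes()] is run.
#'
#' @name SubtypeModel-class
#' @aliases SubtypeModel
#' @export
setClass("SubtypeModel",
  representation(
    basis      = "matrix",
    coef       = "matrix",
    rank       = "integer",
    labels     = "integer",
    consensus  = "matrix",
    cophenetic = "numeric",
    enrichment = "data.frame"
  )
)

setValidity("SubtypeModel", function(object) {
  msg <- character(0)
  if (any(object@basis < 0) || any(object@coef < 0))
    msg <- c(msg, "NMF factors must be non-negative")
  if (length(object@labels) &&
      (any(object@labels < 1L) || any(object@labels > object@rank)))
    msg <- c(msg, "labels must lie in 1..rank")
  cm <- object@consensus
  if (length(cm)) {
    if (!isTRUE(all.equal(cm, t(cm), tolerance = 1e-8)))
      msg <- c(msg, "consensus matrix must be symmetric")
    if (any(cm < -1e-8 | cm > 1 + 1e-8))
      msg <- c(msg, "consensus entries must lie in [0, 1]")
    if (nrow(cm) && any(abs(diag(cm) - 1) > 1e-8))
      msg <- c(msg, "consensus diagonal must be 1")
  }
  if (length(msg)) msg else TRUE
})
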