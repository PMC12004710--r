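# Integrative pathway alteration frequencies: a pathway is altered in a
# sample iff at least one member gene carries a driver mutation or a
# qualifying CNA (amplification = log2 ratio >= 1, i.e. about twice the
# ploidy; deep deletion = total copy number 0).

#' Path to the bundled pathway definitions
#'
#' Sixteen gene sets: the six urothelial-cancer pathways (histone
#' modification, SWI/SNF, DNA damage, cohesin complex, oxidative stress,
#' alternative splicing) plus the ten TCGA oncogenic signaling pathways with
#' representative member genes. KMT2C/D- and ASXL1/2-style shorthands are
#' expanded to individual genes.
#'
#' @return file path inside the installed package.
#' @export
pathwayDefinitionsPath <- function() {
  system.file("extdata", "pathway_definitions.tsv",
              package = "nmibcGenomics", mustWork = TRUE)
}

#' Read pathway definitions
#'
#' @param path TSV with columns `pathway`, `gene`.
#' @return data.frame.
#' @export
readPathwayDefinitions <- function(path = pathwayDefinitionsPath()) {
  df <- readTsv(path)
  requireColumns(df, c("pathway", "gene"), basename(path))
  df
}

#' Gene-level amplification / deep-deletion calls from segments
#'
#' A gene is deep-deleted in a sample when its interval lies inside total
#' copy number 0, and amplified when its covering segment has
#' `log2(CN / ploidy) >= amp_log2` (default 1). Genes outside all segments
#' get no call.
#'
#' @param cohort an [NmibcCohort].
#' @param genes gene coordinate table (gene, chrom, start, end).
#' @param amp_log2 amplification threshold on the log2 ratio.
#' @return data.frame sample_id, gene, call ("amp"/"deep-del").
#' @export
mapCnaToGenes <- function(cohort, genes, amp_log2 = 1) {
  segs <- segments(cohort)
  prof <- profiles(cohort)
  rows <- list()
  for (i in seq_len(nrow(prof))) {
    sid <- prof$sample_id[i]
    s <- segs[segs$sample_id == sid, , drop = FALSE]
    if (!nrow(s)) next
    lr <- segmentLogRatios(s, prof$ploidy[i])
    for (j in seq_len(nrow(genes))) {
      g <- genes[j, ]
      ov <- which(s$chrom == g$chrom & s$start <= g$start & s$end >= g$end)
      if (!length(ov)) next
      k <- ov[1L]
      if (s$cnt[k] == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, gene = g$gene, call = "deep-del",
          stringsAsFactors = FALSE)
      } else if (lr[k] >= amp_log2) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, gene = g$gene, call = "amp",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(sample_id = character(0), gene = character(0),
                      call = character(0)))
  do.call(rbind, rows)
}

#' Pathway alteration fractions
#'
#' A sample alters a pathway iff at least one member gene carries a driver
#' mutation (from the driver catalog) or a gene-level CNA call. Fractions
#' are reported per pathway, and per subtype when labels are given. Unknown
#' genes in the sets are ignored with a warning.
#'
#' @param driverCalls `calls` element of [buildDriverCatalog()].
#' @param cnaGeneCalls output of [mapCnaToGenes()].
#' @param pathways data.frame (pathway, gene).
#' @param samples all sample ids.
#' @param known_genes optional universe of genes; set members outside it are
#'   warned about.
#' @param labels optional per-sample subtype labels.
#' @return list with `fractions` (pathway, n_altered, fraction),
#'   `per_sample` (samples x pathways logical matrix), `per_subtype`
#'   (optional long data.frame).
#' @export
pathwayAlterationFraction <- function(driverCalls, cnaGeneCalls, pathways,
                                      samples, known_genes = NULL,
                                      labels = NULL) {
  if (!is.null(known_genes)) {
    unk <- setdiff(unique(pathways$gene), known_genes)
    if (length(unk))
      warning("pathway gene(s) not in the cohort universe ignored: ",
              paste(utils::head(unk, 10), collapse = ", "), call. = FALSE)
  }
  altered <- rbind(
    data.frame(sample_id = driverCalls$sample_id[driverCalls$is_driver],
               gene = driverCalls$gene[driverCalls$is_driver],
               stringsAsFactors = FALSE),
    cnaGeneCalls[, c("sample_id", "gene")]
  )
  pws <- unique(pathways$pathway)
  m <- matrix(FALSE, length(samples), length(pws),
              dimnames = list(samples, pws))
  for (pw in pws) {
    gs <- pathways$gene[pathways$pathway == pw]
    hit <- unique(altered$sample_id[altered$gene %in% gs])
    m[intersect(hit, samples), pw] <- TRUE
  }
  frac <- data.frame(pathway = pws, n_altered = colSums(m),
                     fraction = colMeans(m), stringsAsFactors = FALSE)
  rownames(frac) <- NULL
  perSubtype <- NULL
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(samples))
    perSubtype <- do.call(rbind, lapply(sort(unique(labels)), function(s) {
      sel <- labels == s
      data.frame(subtype = s, pathway = pws,
                 fraction = colMeans(m[sel, , drop = FALSE]),
                 stringsAsFactors = FALSE)
    }))
    rownames(perSubtype) <- NULL
  }
  list(fractions = frac, per_sample = m, per_subtype = perSubtype)
}
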