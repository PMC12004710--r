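# Temporal dissection of mutations. Per mutation: multiplicity and cancer
# cell fraction (CCF) from VAF, purity and local copy number; clonal vs
# subclonal from a Clopper-Pearson 95% CI on VAF propagated through the
# linear CCF map (clonal iff the CI overlaps 1); early vs late from
# multiplicity on regions with major allele >= 2; per-gene early enrichment
# by permutation against the cohort background.
#
# Conventions: normal copy number is 2 (autosomes); sex chromosomes (chrX,
# chrY) are excluded by default. Clonal mutations on major < 2 regions are
# "early" by default (strict_timing = TRUE labels them "untimeable"
# instead). CCF is reported capped at 1; clonality uses the uncapped CI.

#' Multiplicity from VAF, purity and local copy number
#'
#' Continuous mutation copy number `c = vaf * (rho * CNt + 2 (1 - rho)) /
#' rho`; integer multiplicity is `round(c)` clipped to `[1, major]`.
#'
#' @param vaf variant allele fraction.
#' @param purity tumor purity rho in (0, 1].
#' @param cnt local total copy number (>= 1; 0 is untimeable upstream).
#' @param major local major allele copy number.
#' @return list with `copy_number` (continuous) and `m` (integer).
#' @export
estimateMultiplicity <- function(vaf, purity, cnt, major = cnt) {
  stopifnot(all(purity > 0 & purity <= 1))
  cc <- vaf * (purity * cnt + 2 * (1 - purity)) / purity
  m <- pmin(pmax(round(cc), 1L), pmax(major, 1L))
  list(copy_number = cc, m = as.integer(m))
}

#' CCF with a 95% confidence interval
#'
#' `CCF = vaf * (rho * CNt + 2 (1 - rho)) / (m * rho)`, reported capped at 1
#' with the raw value retained. The CI is the exact Clopper-Pearson binomial
#' interval on VAF transformed through the same linear map. Depth < 8 sets a
#' wide-CI flag.
#'
#' @param t_alt,t_ref alt/ref read counts.
#' @param purity tumor purity.
#' @param cnt local total copy number.
#' @param m multiplicity from [estimateMultiplicity()].
#' @param conf confidence level.
#' @return data.frame with ccf (capped), ccf_raw, lower, upper (uncapped CI),
#'   wide_ci flag.
#' @export
estimateCcf <- function(t_alt, t_ref, purity, cnt, m, conf = 0.95) {
  depth <- t_alt + t_ref
  a <- (1 - conf) / 2
  lo <- ifelse(t_alt == 0, 0, stats::qbeta(a, t_alt, depth - t_alt + 1))
  hi <- ifelse(t_alt == depth, 1,
               stats::qbeta(1 - a, t_alt + 1, depth - t_alt))
  scale <- (purity * cnt + 2 * (1 - purity)) / (m * purity)
  raw <- (t_alt / depth) * scale
  data.frame(ccf = pmin(raw, 1), ccf_raw = raw,
             lower = lo * scale, upper = hi * scale,
             wide_ci = depth < 8)
}

#' Early/late/untimeable call for one timing context
#'
#' Subclonal mutations are late. Clonal mutations on regions with major
#' allele >= 2 are early iff the mutation copy number exceeds 1, late
#' otherwise; the mutation copy number is taken as the integer multiplicity
#' (the rounded estimate), since the continuous estimate of a
#' single-multiplicity mutation is centred exactly on the 1-copy boundary
#' and would make the call read-noise dominated. Clonal mutations on
#' major < 2 regions are early by default, or untimeable under
#' `strict_timing`.
#'
#' @param clonality `"clonal"` or `"subclonal"`.
#' @param major local major allele copy number.
#' @param m integer mutation multiplicity (see [estimateMultiplicity()]).
#' @param strict_timing label clonal major<2 mutations untimeable.
#' @return character vector in {early, late, untimeable}.
#' @export
classifyTiming <- function(clonality, major, m, strict_timing = FALSE) {
  ifelse(clonality == "subclonal", "late",
         ifelse(major >= 2,
                ifelse(m > 1, "early", "late"),
                if (strict_timing) "untimeable" else "early"))
}

#' Time every mutation of a cohort
#'
#' Runs segment lookup, multiplicity, CCF/CI, clonality and early/late
#' classification for every SNV (and indel with usable counts) of the
#' cohort. Mutations with no covering segment, total copy number 0, or on
#' sex chromosomes (unless `include_sex`) are untimeable.
#'
#' @param cohort an [NmibcCohort].
#' @param strict_timing see [classifyTiming()].
#' @param include_sex include chrX/chrY mutations.
#' @return data.frame, one row per mutation, with mut_id, gene, consequence,
#'   m, copy_number, ccf, ccf_raw, CI bounds, clonality, timing.
#' @export
timeMutations <- function(cohort, strict_timing = FALSE,
                          include_sex = FALSE) {
  muts <- mutations(cohort)
  segs <- segments(cohort)
  prof <- profiles(cohort)
  n <- nrow(muts)
  out <- data.frame(
    sample_id = muts$sample_id,
    mut_id = paste0(muts$sample_id, ":", muts$chrom, ":", muts$pos, ":",
                    muts$ref, ">", muts$alt),
    gene = muts$gene, consequence = muts$consequence,
    chrom = muts$chrom,
    m = NA_integer_, copy_number = NA_real_,
    ccf = NA_real_, ccf_raw = NA_real_, lower = NA_real_, upper = NA_real_,
    clonality = NA_character_, timing = "untimeable",
    stringsAsFactors = FALSE)
  if (!n) return(out)
  segRow <- locateSegment(muts, segs)
  purity <- prof$purity[match(muts$sample_id, prof$sample_id)]
  cnt <- segs$cnt[segRow]
  major <- segs$major[segRow]
  sex <- muts$chrom %in% c("chrX", "chrY", "X", "Y")
  ok <- !is.na(segRow) & cnt > 0 & (include_sex | !sex)
  if (any(ok)) {
    vaf <- muts$vaf[ok]
    mm <- estimateMultiplicity(vaf, purity[ok], cnt[ok], major[ok])
    ci <- estimateCcf(muts$t_alt[ok], muts$t_ref[ok], purity[ok], cnt[ok],
                      mm$m)
    clon <- ifelse(ci$upper >= 1, "clonal", "subclonal")
    out$m[ok] <- mm$m
    out$copy_number[ok] <- mm$copy_number
    out$ccf[ok] <- ci$ccf
    out$ccf_raw[ok] <- ci$ccf_raw
    out$lower[ok] <- ci$lower
    out$upper[ok] <- ci$upper
    out$clonality[ok] <- clon
    out$timing[ok] <- classifyTiming(clon, major[ok], mm$m, strict_timing)
  }
  out
}

#' Per-gene early-enrichment permutation test
#'
#' For every gene with at least `min_mutations` timed (early/late) mutations,
#' compares the gene's early mutation ratio with background ratios obtained
#' by drawing the same number of mutations from the cohort's timed non-gene
#' mutations. `p = (1 + #{perm >= observed}) / (n_perm + 1)`; BH-adjusted
#' across tested genes.
#'
#' @param timing result of [timeMutations()].
#' @param genes genes to test (default: all with enough mutations).
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed.
#' @param min_mutations minimum timed mutations per gene.
#' @return data.frame gene, n, early_ratio, background_ratio, p, q.
#' @export
earlyEnrichmentTest <- function(timing, genes = NULL, n_perm = 1000,
                                seed = 1, min_mutations = 3) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  timed <- timing[timing$timing %in% c("early", "late") &
                    nzchar(timing$gene), , drop = FALSE]
  tab <- table(timed$gene)
  cand <- names(tab)[tab >= min_mutations]
  if (!is.null(genes)) {
    skipped <- setdiff(genes, cand)
    if (length(skipped))
      message("skipping gene(s) with < ", min_mutations,
              " timed mutations: ", paste(skipped, collapse = ", "))
    cand <- intersect(genes, cand)
  }
  if (!length(cand))
    return(data.frame(gene = character(0), n = integer(0),
                      early_ratio = numeric(0),
                      background_ratio = numeric(0),
                      p = numeric(0), q = numeric(0)))
  isEarly <- timed$timing == "early"
  withSeed(seed, {
    res <- lapply(cand, function(g) {
      inGene <- timed$gene == g
      nG <- sum(inGene)
      obs <- mean(isEarly[inGene])
      bg <- isEarly[!inGene]
      perm <- vapply(seq_len(n_perm), function(i)
        mean(sample(bg, nG, replace = FALSE)), numeric(1))
      data.frame(gene = g, n = nG, early_ratio = obs,
                 background_ratio = mean(bg),
                 p = (1 + sum(perm >= obs)) / (n_perm + 1),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$q <- stats::p.adjust(out$p, method = "BH")
    out
  })
}
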