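# Genome-instability metrics: whole-genome doubling by two concordant
# methods (a sample is wGD only when both fire), the weighted genome
# instability index (wGII) with the 0.2 CIN threshold, nonsynonymous TMB,
# and the descending-TMB gap rule for hypermutation.

segLengths <- function(segs) segs$end - segs$start + 1

autosomalSegs <- function(segs) {
  segs[!segs$chrom %in% c("chrX", "chrY", "X", "Y"), , drop = FALSE]
}

#' wGD method 1: genome fraction with major allele >= 2
#'
#' TRUE iff the major allele has copy number at least 2 across at least 50%
#' of the (length-weighted, autosomal) genome.
#'
#' @param segs validated segments of one sample.
#' @return list with `wgd` (logical) and `fraction`.
#' @export
wgdFractionMethod <- function(segs) {
  segs <- autosomalSegs(segs)
  if (!nrow(segs)) stop("empty segment set", call. = FALSE)
  len <- segLengths(segs)
  frac <- sum(len[segs$major >= 2]) / sum(len)
  list(wgd = frac >= 0.5, fraction = frac)
}

# length-weighted modal (major, minor) state of one arm
armModalState <- function(segs, armStart, armEnd) {
  ov <- segs[segs$end >= armStart & segs$start <= armEnd, , drop = FALSE]
  if (!nrow(ov)) return(NULL)
  w <- pmin(ov$end, armEnd) - pmax(ov$start, armStart) + 1
  key <- paste(ov$major, ov$minor)
  agg <- tapply(w, key, sum)
  st <- strsplit(names(agg)[which.max(agg)], " ", fixed = TRUE)[[1]]
  list(major = as.integer(st[1]), minor = as.integer(st[2]),
       length = armEnd - armStart + 1)
}

#' wGD method 2: arm-level aberration profile
#'
#' Represents the sample as the length-weighted modal major/minor state per
#' autosomal chromosome arm; wGD is called iff arms with modal major >= 2
#' cover at least 50% of the autosomal arm length AND ploidy exceeds 2.5.
#' Arms not covered by any segment are skipped with a warning.
#'
#' @param segs validated segments of one sample.
#' @param arms arm table (chrom, start, end, arm).
#' @param ploidy sample ploidy.
#' @return list with `wgd`, `fraction`, `arm_states`.
#' @export
wgdArmMethod <- function(segs, arms, ploidy) {
  segs <- autosomalSegs(segs)
  arms <- autosomalSegs(arms)
  states <- lapply(seq_len(nrow(arms)), function(i) {
    st <- armModalState(segs[segs$chrom == arms$chrom[i], , drop = FALSE],
                        arms$start[i], arms$end[i])
    if (is.null(st)) return(NULL)
    data.frame(arm = arms$arm[i], major = st$major, minor = st$minor,
               length = st$length, stringsAsFactors = FALSE)
  })
  miss <- vapply(states, is.null, logical(1))
  if (any(miss))
    warning("no segment coverage for arm(s): ",
            paste(arms$arm[miss], collapse = ", "), call. = FALSE)
  st <- do.call(rbind, states[!miss])
  if (is.null(st)) stop("no arm has segment coverage", call. = FALSE)
  frac <- sum(st$length[st$major >= 2]) / sum(st$length)
  list(wgd = frac >= 0.5 && ploidy > 2.5, fraction = frac, arm_states = st)
}

#' wGII and the CIN flag
#'
#' wGII is the length-weighted fraction of the (autosomal) genome whose
#' total copy number differs from the rounded sample ploidy; CIN iff
#' wGII > 0.2. With `allele_aware = TRUE` a segment is aberrant when either
#' allele differs from the balanced rounded-ploidy split.
#'
#' @param segs validated segments of one sample.
#' @param ploidy sample ploidy (> 0).
#' @param allele_aware use allele-specific aberration.
#' @return list with `wgii` and `cin`.
#' @export
computeWgii <- function(segs, ploidy, allele_aware = FALSE) {
  stopifnot(ploidy > 0)
  segs <- autosomalSegs(segs)
  len <- segLengths(segs)
  base <- round(ploidy)
  if (allele_aware) {
    expMinor <- base %/% 2L
    expMajor <- base - expMinor
    aberrant <- segs$major != expMajor | segs$minor != expMinor
  } else {
    aberrant <- (segs$major + segs$minor) != base
  }
  wgii <- sum(len[aberrant]) / sum(len)
  list(wgii = wgii, cin = wgii > 0.2)
}

#' Nonsynonymous tumor mutational burden
#'
#' Nonsynonymous mutations (missense, nonsense, splice, indel) per megabase
#' of exome.
#'
#' @param muts mutation table of one sample (or cohort slice).
#' @param exome_size_mb exome size in Mb.
#' @return TMB (numeric scalar).
#' @export
computeTmb <- function(muts, exome_size_mb) {
  sum(muts$consequence %in% c("missense", "nonsense", "splice", "indel")) /
    exome_size_mb
}

#' Hypermutation cutoff by the descending-TMB gap rule
#'
#' Samples are ranked by TMB in descending order and the degree of
#' variability at each rank is the difference in TMB with the next sample.
#' The cut is placed at the maximal difference within the top quartile of
#' ranks (restricting to the top quartile avoids flagging the bulk of the
#' cohort at a mid-distribution gap); all samples above the cut are flagged.
#' A zero maximal gap flags nobody.
#'
#' @param tmb named numeric vector of per-sample TMB (>= 5 samples).
#' @return list with `flags` (named logical), `threshold` (TMB of the last
#'   flagged sample, or Inf when none), `gap`, `cut_rank`.
#' @export
defineHypermutation <- function(tmb) {
  if (length(tmb) < 5) stop("need >= 5 samples", call. = FALSE)
  ord <- order(tmb, decreasing = TRUE)
  sorted <- tmb[ord]
  diffs <- sorted[-length(sorted)] - sorted[-1]
  topQ <- max(1L, ceiling(length(tmb) / 4))
  window <- diffs[seq_len(min(topQ, length(diffs)))]
  gap <- max(window)
  flags <- stats::setNames(rep(FALSE, length(tmb)), names(tmb))
  if (gap > 0) {
    cutRank <- which.max(window)
    flags[ord[seq_len(cutRank)]] <- TRUE
    return(list(flags = flags, threshold = sorted[cutRank], gap = gap,
                cut_rank = cutRank))
  }
  list(flags = flags, threshold = Inf, gap = 0, cut_rank = NA_integer_)
}

#' Per-sample instability profiles for a cohort
#'
#' Computes both wGD methods (wGD = method1 AND method2), wGII/CIN, TMB and
#' the hypermutation flags for every sample.
#'
#' @param cohort an [NmibcCohort].
#' @param arms arm table (chrom, start, end, arm).
#' @param allele_aware see [computeWgii()].
#' @return data.frame, one row per sample: wgd_method1, wgd_method2, wgd,
#'   wgii, cin, tmb, hypermutated.
#' @export
instabilityProfiles <- function(cohort, arms, allele_aware = FALSE) {
  prof <- profiles(cohort)
  segs <- segments(cohort)
  muts <- mutations(cohort)
  rows <- lapply(seq_len(nrow(prof)), function(i) {
    sid <- prof$sample_id[i]
    s <- segs[segs$sample_id == sid, , drop = FALSE]
    m1 <- wgdFractionMethod(s)
    m2 <- wgdArmMethod(s, arms, prof$ploidy[i])
    w <- computeWgii(s, prof$ploidy[i], allele_aware)
    data.frame(sample_id = sid,
               wgd_method1 = m1$wgd, wgd_method2 = m2$wgd,
               wgd = m1$wgd && m2$wgd,
               wgii = w$wgii, cin = w$cin,
               tmb = computeTmb(muts[muts$sample_id == sid, , drop = FALSE],
                                prof$exome_size_mb[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  hyp <- defineHypermutation(stats::setNames(out$tmb, out$sample_id))
  out$hypermutated <- unname(hyp$flags[out$sample_id])
  attr(out, "tmb_threshold") <- hyp$threshold
  attr(out, "tmb_gap") <- hyp$gap
  out
}
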