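# CNA event calling and recurrence. Segments become events when
# |log2(CN / ploidy)| >= 0.25; events covering >= 0.75 of a chromosome arm
# are broad (arm-level), the rest focal. Recurrence significance is a
# GISTIC-like permutation scheme: per-locus score = sum over samples of
# event amplitude, null by circularly permuting each sample's event
# positions along the concatenated genome (per-sample event structure
# preserved exactly), empirical p and BH q per direction. Lists will differ
# from GISTIC2 (no semi-parametric background or peel-off) and are labelled
# GISTIC-like.

#' Per-segment log2 copy-number ratios
#'
#' `log2(CN_total / ploidy)`, with CN 0 capped at `log2(0.5 / ploidy)` so the
#' transform stays finite.
#'
#' @param segs validated segments.
#' @param ploidy sample ploidy (> 0).
#' @return numeric vector of log2 ratios.
#' @export
segmentLogRatios <- function(segs, ploidy) {
  stopifnot(ploidy > 0)
  cn <- segs$major + segs$minor
  log2(pmax(cn, 0.5) / ploidy)
}

# overlap length of [s1,e1] with [s2,e2], closed intervals
overlapLen <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
}

#' Call focal and broad CNA events for one sample
#'
#' Qualifying segments (`|log2 ratio| >= threshold`) are merged when adjacent
#' and same-signed, then classified per arm: arms whose qualifying coverage
#' in one direction reaches `broad_cutoff` of the arm length yield a broad
#' event (locus = arm); remaining merged runs yield focal events (locus =
#' `chrom:start-end`). Event amplitude is the length-weighted mean |log2
#' ratio| over the event.
#'
#' @param segs segments of one sample.
#' @param arms arm table.
#' @param ploidy sample ploidy.
#' @param threshold amplitude threshold (default 0.25).
#' @param broad_cutoff broad length cutoff (default 0.75).
#' @return data.frame of events: sample_id, kind (focal-amp/focal-del/
#'   broad-amp/broad-del), locus, chrom, start, end, arm, amplitude,
#'   arm_fraction.
#' @export
callCnaEvents <- function(segs, arms, ploidy, threshold = 0.25,
                          broad_cutoff = 0.75) {
  lr <- segmentLogRatios(segs, ploidy)
  qual <- abs(lr) >= threshold
  empty <- data.frame(sample_id = character(0), kind = character(0),
                      locus = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      arm = character(0), amplitude = numeric(0),
                      arm_fraction = numeric(0), stringsAsFactors = FALSE)
  if (!any(qual)) return(empty)
  q <- segs[qual, , drop = FALSE]
  q$lr <- lr[qual]
  q$dir <- ifelse(q$lr > 0, "amp", "del")
  q <- q[order(q$chrom, q$start), , drop = FALSE]
  # merge abutting same-direction runs within a chromosome
  runId <- cumsum(c(TRUE, !(q$chrom[-1] == q$chrom[-nrow(q)] &
                              q$dir[-1] == q$dir[-nrow(q)] &
                              q$start[-1] == q$end[-nrow(q)] + 1)))
  merged <- do.call(rbind, lapply(split(seq_len(nrow(q)), runId),
                                  function(ii) {
    len <- q$end[ii] - q$start[ii] + 1
    data.frame(sample_id = q$sample_id[ii[1]], chrom = q$chrom[ii[1]],
               start = min(q$start[ii]), end = max(q$end[ii]),
               dir = q$dir[ii[1]],
               amplitude = sum(abs(q$lr[ii]) * len) / sum(len),
               stringsAsFactors = FALSE)
  }))
  out <- list()
  for (i in seq_len(nrow(arms))) {
    a <- arms[i, ]
    armLen <- a$end - a$start + 1
    for (d in c("amp", "del")) {
      sel <- merged$chrom == a$chrom & merged$dir == d &
        merged$end >= a$start & merged$start <= a$end
      if (!any(sel)) next
      ev <- merged[sel, , drop = FALSE]
      ov <- overlapLen(ev$start, ev$end, a$start, a$end)
      frac <- sum(ov) / armLen
      if (frac >= broad_cutoff) {
        out[[length(out) + 1L]] <- data.frame(
          sample_id = ev$sample_id[1], kind = paste0("broad-", d),
          locus = a$arm, chrom = a$chrom, start = a$start, end = a$end,
          arm = a$arm, amplitude = sum(ev$amplitude * ov) / sum(ov),
          arm_fraction = frac, stringsAsFactors = FALSE)
      } else {
        for (j in seq_len(nrow(ev))) {
          s0 <- max(ev$start[j], a$start); e0 <- min(ev$end[j], a$end)
          out[[length(out) + 1L]] <- data.frame(
            sample_id = ev$sample_id[j], kind = paste0("focal-", d),
            locus = paste0(ev$chrom[j], ":", s0, "-", e0),
            chrom = ev$chrom[j], start = s0, end = e0, arm = a$arm,
            amplitude = ev$amplitude[j], arm_fraction = ov[j] / armLen,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call CNA events for every sample of a cohort
#'
#' @param cohort an [NmibcCohort].
#' @param arms arm table.
#' @param ... passed to [callCnaEvents()].
#' @return combined event data.frame.
#' @export
cohortCnaEvents <- function(cohort, arms, ...) {
  prof <- profiles(cohort)
  segs <- segments(cohort)
  do.call(rbind, lapply(seq_len(nrow(prof)), function(i) {
    callCnaEvents(segs[segs$sample_id == prof$sample_id[i], , drop = FALSE],
                  arms, prof$ploidy[i], ...)
  }))
}

# genome binning along concatenated arm coordinates
makeBins <- function(arms, bin_size) {
  bins <- do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
    st <- seq(arms$start[i], arms$end[i], by = bin_size)
    data.frame(chrom = arms$chrom[i], start = st,
               end = pmin(st + bin_size - 1, arms$end[i]),
               arm = arms$arm[i], stringsAsFactors = FALSE)
  }))
  bins$bin <- seq_len(nrow(bins))
  bins
}

eventBinMatrix <- function(events, bins, samples) {
  m <- matrix(0, length(samples), nrow(bins),
              dimnames = list(samples, NULL))
  if (is.null(events) || !nrow(events)) return(m)
  for (i in seq_len(nrow(events))) {
    sel <- bins$chrom == events$chrom[i] & bins$end >= events$start[i] &
      bins$start <= events$end[i]
    si <- events$sample_id[i]
    m[si, sel] <- pmax(m[si, sel], events$amplitude[i])
  }
  m
}

#' Recurrence significance of CNA loci (GISTIC-like)
#'
#' Scores each genomic bin as the sum over samples of event amplitude
#' (amplifications and deletions separately); the null circularly shifts
#' each sample's amplitude track along the concatenated genome, preserving
#' that sample's event sizes and amplitudes exactly. Empirical
#' `p = (1 + #{perm >= obs}) / (n_perm + 1)` per bin, BH across bins within
#' direction; q < 0.1 is the significance cutoff.
#'
#' @param events cohort event table ([cohortCnaEvents()]).
#' @param arms arm table.
#' @param samples all cohort sample ids (>= 10 for a meaningful null).
#' @param n_perm permutations (warning below 100).
#' @param seed RNG seed.
#' @param bin_size bin width in bp.
#' @return data.frame per bin x direction: chrom, start, end, arm,
#'   direction, score, freq, p, q.
#' @export
recurrenceSignificance <- function(events, arms, samples, n_perm = 500,
                                   seed = 1, bin_size = 10000) {
  if (length(samples) < 2) stop("need >= 2 samples", call. = FALSE)
  if (n_perm < 100) warning("n_perm < 100: q-values will be coarse",
                            call. = FALSE)
  bins <- makeBins(arms, bin_size)
  out <- withSeed(seed, {
    res <- lapply(c("amp", "del"), function(d) {
      ev <- events[grepl(d, events$kind), , drop = FALSE]
      m <- eventBinMatrix(ev, bins, samples)
      obs <- colSums(m)
      B <- ncol(m)
      ge <- numeric(B)
      for (k in seq_len(n_perm)) {
        sh <- sample.int(B, nrow(m), replace = TRUE)
        perm <- vapply(seq_len(nrow(m)), function(r) {
          v <- m[r, ]
          if (sh[r] == B) v else c(v[(sh[r] + 1):B], v[1:sh[r]])
        }, numeric(B))
        ge <- ge + (colSums(t(perm)) >= obs)
      }
      p <- (1 + ge) / (n_perm + 1)
      data.frame(bins, direction = d, score = obs,
                 freq = colMeans(m > 0), p = p,
                 q = stats::p.adjust(p, method = "BH"),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  rownames(out) <- NULL
  out
}

#' Significant recurrent loci
#'
#' Collapses adjacent significant bins (q < cutoff, same direction and arm)
#' into loci, annotated broad/focal by their arm fraction.
#'
#' @param recurrence output of [recurrenceSignificance()].
#' @param arms arm table.
#' @param q_cutoff significance cutoff (default 0.1).
#' @param broad_cutoff arm-fraction cutoff for broad loci.
#' @return data.frame locus, chrom, start, end, arm, direction, kind,
#'   peak_score.
#' @export
significantCnaLoci <- function(recurrence, arms, q_cutoff = 0.1,
                               broad_cutoff = 0.75) {
  sig <- recurrence[recurrence$q < q_cutoff, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(locus = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      arm = character(0), direction = character(0),
                      kind = character(0), peak_score = numeric(0)))
  sig <- sig[order(sig$direction, sig$chrom, sig$start), , drop = FALSE]
  runId <- cumsum(c(TRUE, !(sig$arm[-1] == sig$arm[-nrow(sig)] &
                              sig$direction[-1] == sig$direction[-nrow(sig)] &
                              sig$start[-1] == sig$end[-nrow(sig)] + 1)))
  out <- do.call(rbind, lapply(split(seq_len(nrow(sig)), runId),
                               function(ii) {
    a <- arms[arms$arm == sig$arm[ii[1]], ]
    st <- min(sig$start[ii]); en <- max(sig$end[ii])
    frac <- (en - st + 1) / (a$end - a$start + 1)
    kind <- if (frac >= broad_cutoff) "broad" else "focal"
    data.frame(
      locus = if (kind == "broad") a$arm else
        paste0(sig$chrom[ii[1]], ":", st, "-", en),
      chrom = sig$chrom[ii[1]], start = st, end = en, arm = a$arm,
      direction = sig$direction[ii[1]], kind = kind,
      peak_score = max(sig$score[ii]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' chr9 p+q co-deletion flag
#'
#' TRUE per sample iff the sample carries broad deletions of both the 9p and
#' 9q arms.
#'
#' @param events cohort event table.
#' @param samples sample ids.
#' @return named logical vector.
#' @export
chr9CodeletionFlag <- function(events, samples) {
  has <- function(sid, arm) {
    any(events$sample_id == sid & events$kind == "broad-del" &
          events$arm == arm)
  }
  stats::setNames(vapply(samples, function(s) has(s, "9p") && has(s, "9q"),
                         logical(1)), samples)
}
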