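# Co-occurrence / mutual-exclusivity testing over the binary genomic event
# matrix, and early -> late ordering interactions. The null model preserves
# both per-sample event loads and per-event frequencies exactly
# (margin-preserving curveball randomization, a DISCOVER-like background);
# per-pair overlap is compared with the sampled null in each direction.

#' Assemble the binary event matrix
#'
#' Binds named feature blocks (driver-gene mutation flags, focal/broad CNA
#' indicators, signature presence, instability flags) into one samples x
#' events binary matrix and applies the frequency filter: events present in
#' fewer than `min_freq` of samples (or in all samples) are dropped and
#' logged. Duplicate event names are an error.
#'
#' @param features named list of samples x features logical/0-1 matrices,
#'   all with identical row order.
#' @param min_freq minimum event frequency (default 0.10).
#' @return binary integer matrix samples x events, attribute `"dropped"`
#'   listing filtered columns.
#' @export
assembleEventMatrix <- function(features, min_freq = 0.10) {
  stopifnot(is.list(features), length(features) > 0)
  mats <- lapply(features, function(f) {
    m <- as.matrix(f) * 1L
    storage.mode(m) <- "integer"
    m
  })
  ns <- unique(vapply(mats, nrow, integer(1)))
  if (length(ns) != 1) stop("feature blocks disagree on sample count",
                            call. = FALSE)
  m <- do.call(cbind, mats)
  if (anyDuplicated(colnames(m)))
    stop("duplicate event names: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]),
               collapse = ", "), call. = FALSE)
  freq <- colMeans(m)
  keep <- freq >= min_freq & freq < 1
  dropped <- colnames(m)[!keep]
  if (length(dropped))
    message(length(dropped), " event(s) below the ", min_freq * 100,
            "% frequency filter (or constant) dropped")
  m <- m[, keep, drop = FALSE]
  if (!ncol(m)) stop("no event passes the frequency filter", call. = FALSE)
  attr(m, "dropped") <- dropped
  m
}

#' CNA event indicator matrix over recurrent loci
#'
#' One column per significant locus x direction: a sample is positive when
#' it carries an event of the same direction and kind overlapping the locus.
#'
#' @param events cohort event table ([cohortCnaEvents()]).
#' @param loci significant loci ([significantCnaLoci()]).
#' @param samples sample ids (row order).
#' @return logical matrix samples x loci.
#' @export
cnaEventMatrix <- function(events, loci, samples) {
  if (is.null(loci) || !nrow(loci))
    return(matrix(logical(0), length(samples), 0,
                  dimnames = list(samples, NULL)))
  cols <- paste0(ifelse(loci$kind == "broad", "BROAD_", "FOCAL_"),
                 loci$locus, "_", loci$direction)
  m <- matrix(FALSE, length(samples), nrow(loci),
              dimnames = list(samples, cols))
  if (is.null(events) || !nrow(events)) return(m)
  for (j in seq_len(nrow(loci))) {
    l <- loci[j, ]
    kindPat <- paste0(l$kind, "-", l$direction)
    sel <- events$kind == kindPat & events$chrom == l$chrom &
      events$end >= l$start & events$start <= l$end
    m[unique(events$sample_id[sel]), j] <- TRUE
  }
  m
}

#' Margin-preserving randomization of a binary matrix
#'
#' One curveball-randomized matrix after `steps` trades; every row and
#' column sum of the input is preserved exactly.
#'
#' @param m binary matrix.
#' @param steps number of trades (default `10 * sum(m)`).
#' @param seed RNG seed.
#' @return randomized binary matrix with identical margins.
#' @export
curveballRandomize <- function(m, steps = NULL, seed = NULL) {
  m <- as.matrix(m) * 1L
  storage.mode(m) <- "integer"
  steps <- steps %||% (10L * sum(m))
  withSeed(seed, .curveballRandomizeCpp(m, as.integer(steps)))
}

#' Pairwise co-occurrence / mutual-exclusivity test
#'
#' For every pair of event columns, compares the observed overlap (number of
#' samples carrying both) with its curveball null distribution (burn-in
#' `10 * sum(m)` trades, `n_perm` sampled matrices). One-sided empirical p
#' in each direction; the reported direction is the sign of the effect
#' (observed minus expected overlap), with BH adjustment within direction.
#' Null margins are asserted to match exactly on every run.
#'
#' @param m binary event matrix (samples x events, >= 2 non-constant
#'   columns).
#' @param n_perm number of sampled null matrices (>= 1000 recommended).
#' @param seed RNG seed.
#' @param gap trades between consecutive sampled matrices.
#' @return data.frame event_a, event_b, observed, expected, effect,
#'   direction, p, q.
#' @export
testEventPairs <- function(m, n_perm = 1000, seed = 1, gap = NULL) {
  m <- as.matrix(m) * 1L
  storage.mode(m) <- "integer"
  freq <- colMeans(m)
  if (all(freq == 0) || all(freq == 1))
    stop("degenerate event matrix (all zeros or all ones)", call. = FALSE)
  if (ncol(m) < 2) stop("need >= 2 events", call. = FALSE)
  burnin <- 10L * sum(m)
  gap <- as.integer(gap %||% max(nrow(m), 20L))
  null <- withSeed(seed, .curveballNullOverlapsCpp(m, as.integer(n_perm),
                                                   burnin, gap))
  # margin preservation check on one randomized draw
  chk <- curveballRandomize(m, steps = burnin, seed = seed)
  stopifnot(identical(rowSums(chk), rowSums(m)),
            identical(colSums(chk), colSums(m)))
  p <- ncol(m)
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  # the C++ kernel emits pairs with the first index outer: (1,2), (1,3),
  # ..., (1,p), (2,3), ...
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  obs <- vapply(seq_len(nrow(pairs)), function(k)
    sum(m[, pairs[k, 1]] & m[, pairs[k, 2]]), numeric(1))
  expc <- colMeans(null)
  pCo <- (1 + colSums(null >= rep(obs, each = nrow(null)))) / (n_perm + 1)
  pEx <- (1 + colSums(null <= rep(obs, each = nrow(null)))) / (n_perm + 1)
  eff <- obs - expc
  dir <- ifelse(eff > 0, "co-occurrence",
                ifelse(eff < 0, "exclusivity",
                       ifelse(pCo <= pEx, "co-occurrence", "exclusivity")))
  pv <- ifelse(dir == "co-occurrence", pCo, pEx)
  out <- data.frame(
    event_a = colnames(m)[pairs[, 1]],
    event_b = colnames(m)[pairs[, 2]],
    observed = obs, expected = expc, effect = eff,
    direction = dir, p = pv, q = NA_real_, stringsAsFactors = FALSE)
  for (d in unique(out$direction)) {
    sel <- out$direction == d
    out$q[sel] <- stats::p.adjust(out$p[sel], method = "BH")
  }
  out
}

#' Early -> late ordering interactions
#'
#' For each (early event, late event) pair, Fisher's exact test on the 2x2
#' table of early presence x late presence across samples. OR > 1 means the
#' early event increases the probability of the late event. Zero cells get
#' the Haldane-Anscombe +0.5 correction reported alongside the raw
#' (possibly infinite) OR; constant columns are skipped; BH adjustment over
#' all tested pairs.
#'
#' @param earlyM,lateM binary matrices (same samples, same row order).
#' @return data.frame early_event, late_event, or (raw), or_corrected, p,
#'   q.
#' @export
orderingInteractions <- function(earlyM, lateM) {
  stopifnot(nrow(earlyM) == nrow(lateM))
  keepE <- colMeans(earlyM) > 0 & colMeans(earlyM) < 1
  keepL <- colMeans(lateM) > 0 & colMeans(lateM) < 1
  earlyM <- earlyM[, keepE, drop = FALSE]
  lateM <- lateM[, keepL, drop = FALSE]
  rows <- list()
  for (i in seq_len(ncol(earlyM))) {
    for (j in seq_len(ncol(lateM))) {
      e <- earlyM[, i] > 0
      l <- lateM[, j] > 0
      a <- sum(e & l); b <- sum(e & !l)
      c0 <- sum(!e & l); d0 <- sum(!e & !l)
      orRaw <- (a * d0) / (b * c0)
      orCor <- ((a + 0.5) * (d0 + 0.5)) / ((b + 0.5) * (c0 + 0.5))
      p <- stats::fisher.test(matrix(c(a, b, c0, d0), 2L,
                                     byrow = TRUE))$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        early_event = colnames(earlyM)[i], late_event = colnames(lateM)[j],
        or = orRaw, or_corrected = orCor, p = p, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(early_event = character(0), late_event = character(0),
                      or = numeric(0), or_corrected = numeric(0),
                      p = numeric(0), q = numeric(0)))
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
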