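# Mutational-signature analysis: 96-channel spectrum construction (with
# early/late strata), exposure fitting by EM against a known catalog, de novo
# extraction by KL-NMF with catalog matching, the presence rule (>= 10
# mutations and >= 5% of the sample's total), and APOBEC tCw enrichment with
# +/- 20 nt reference context windows.

#' Build a 96-channel spectrum
#'
#' Counts SNVs into the 96 pyrimidine-centred channels ([sbsChannels()]).
#' Contexts come from the `context3` column when present, otherwise from the
#' reference genome; purine-reference mutations are reverse-complemented.
#' Non-SNVs are skipped (count reported as an attribute); SNVs whose
#' context3 disagrees with the reference (when both are available) are
#' skipped and logged.
#'
#' @param muts mutation table (one sample or any slice).
#' @param genome optional [Biostrings::DNAStringSet] reference.
#' @return named numeric vector of length 96, attributes `n_skipped_nonsnv`
#'   and `n_skipped_context`.
#' @export
buildSpectrum <- function(muts, genome = NULL) {
  v <- stats::setNames(numeric(96), sbsChannels())
  if (!nrow(muts)) {
    attr(v, "n_skipped_nonsnv") <- 0L
    attr(v, "n_skipped_context") <- 0L
    return(v)
  }
  snv <- nchar(muts$ref) == 1L & nchar(muts$alt) == 1L
  nNon <- sum(!snv)
  m <- muts[snv, , drop = FALSE]
  ctx <- if ("context3" %in% names(m)) as.character(m$context3) else
    rep("", nrow(m))
  ctx[is.na(ctx)] <- ""
  nCtxSkip <- 0L
  if (!is.null(genome) && nrow(m)) {
    refCtx <- rep(NA_character_, nrow(m))
    for (ch in intersect(unique(m$chrom), names(genome))) {
      ii <- which(m$chrom == ch)
      L <- Biostrings::width(genome[ch])
      okPos <- m$pos[ii] >= 2 & m$pos[ii] <= L - 1
      jj <- ii[okPos]
      if (length(jj)) {
        refCtx[jj] <- as.character(Biostrings::extractAt(
          genome[[ch]], IRanges::IRanges(m$pos[jj] - 1L, m$pos[jj] + 1L)))
      }
    }
    mismatch <- nzchar(ctx) & !is.na(refCtx) & ctx != refCtx
    if (any(mismatch)) {
      nCtxSkip <- sum(mismatch)
      message(nCtxSkip, " SNV(s) skipped: context3 disagrees with reference")
    }
    use <- ifelse(nzchar(ctx), ctx, refCtx)
    use[mismatch] <- NA_character_
    ctx <- use
  }
  ctx[!nzchar(ctx)] <- NA_character_
  chan <- snvChannel(m$ref, m$alt, ifelse(is.na(ctx), "", ctx))
  tab <- table(chan[!is.na(chan)])
  v[names(tab)] <- as.numeric(tab)
  attr(v, "n_skipped_nonsnv") <- nNon
  attr(v, "n_skipped_context") <- nCtxSkip
  v
}

#' Per-sample spectra for a cohort stratum
#'
#' @param cohort an [NmibcCohort].
#' @param stratum `"all"`, `"early"` or `"late"`; strata other than `"all"`
#'   require `timing`.
#' @param timing result of [timeMutations()] (matched by mut_id).
#' @param genome optional reference for context resolution.
#' @return numeric matrix, 96 channels x samples.
#' @export
cohortSpectra <- function(cohort, stratum = c("all", "early", "late"),
                          timing = NULL, genome = NULL) {
  stratum <- match.arg(stratum)
  muts <- mutations(cohort)
  if (stratum != "all") {
    if (is.null(timing)) stop("timing required for stratified spectra",
                              call. = FALSE)
    keep <- timing$mut_id[timing$timing == stratum]
    mid <- paste0(muts$sample_id, ":", muts$chrom, ":", muts$pos, ":",
                  muts$ref, ">", muts$alt)
    muts <- muts[mid %in% keep, , drop = FALSE]
  }
  samples <- sampleIds(cohort)
  out <- vapply(samples, function(s)
    as.numeric(buildSpectrum(muts[muts$sample_id == s, , drop = FALSE],
                             genome)),
    numeric(96))
  rownames(out) <- sbsChannels()
  out
}

#' Fit signature exposures by EM
#'
#' Maximum-likelihood multinomial mixture fit of a 96-channel spectrum to a
#' catalog of signature probability vectors. The EM update is iterated until
#' the relative log-likelihood change falls below `tol` (or `max_iter`); the
#' log-likelihood is non-decreasing at every step. The presence rule flags a
#' signature present iff its exposure accounts for at least
#' `min_mutations` mutations (counts rounded half-up) and at least
#' `min_fraction` of the sample total.
#'
#' @param spectrum numeric vector of 96 channel counts.
#' @param catalog 96 x K probability matrix (see [readSignatureCatalog()]).
#' @param tol relative log-likelihood tolerance.
#' @param max_iter iteration cap.
#' @param min_mutations,min_fraction presence rule (defaults 10 and 0.05).
#' @return list with `counts`, `fractions` (sum to 1 over fitted
#'   signatures), `present`, `loglik` (trace), `n_iter`.
#' @export
fitExposuresEM <- function(spectrum, catalog, tol = 1e-8, max_iter = 10000,
                           min_mutations = 10, min_fraction = 0.05) {
  stopifnot(length(spectrum) == nrow(catalog))
  K <- ncol(catalog)
  total <- sum(spectrum)
  if (total == 0) {
    z <- stats::setNames(numeric(K), colnames(catalog))
    return(list(counts = z, fractions = z,
                present = stats::setNames(rep(FALSE, K), colnames(catalog)),
                loglik = -Inf, n_iter = 0L))
  }
  w <- rep(1 / K, K)
  eps <- 1e-300
  ll <- numeric(0)
  for (it in seq_len(max_iter)) {
    p <- as.vector(catalog %*% w) + eps
    ll[it] <- sum(spectrum * log(p))
    resp <- sweep(catalog, 2L, w, "*") / p
    w <- as.vector(spectrum %*% resp) / total
    if (it > 1 && abs(ll[it] - ll[it - 1]) <
        tol * (abs(ll[it - 1]) + eps)) break
  }
  counts <- stats::setNames(w * total, colnames(catalog))
  fractions <- stats::setNames(w, colnames(catalog))
  present <- floor(counts + 0.5) >= min_mutations & fractions >= min_fraction
  list(counts = counts, fractions = fractions, present = present,
       loglik = ll, n_iter = length(ll))
}

#' Fit exposures for every sample of a spectra matrix
#'
#' @param spectra 96 x samples matrix (see [cohortSpectra()]).
#' @param catalog 96 x K probability matrix.
#' @param ... passed to [fitExposuresEM()].
#' @return list with `counts`, `fractions`, `present` (samples x signatures
#'   matrices).
#' @export
fitCohortExposures <- function(spectra, catalog, ...) {
  fits <- lapply(seq_len(ncol(spectra)), function(j)
    fitExposuresEM(spectra[, j], catalog, ...))
  list(
    counts = do.call(rbind, lapply(fits, `[[`, "counts")) |>
      `rownames<-`(colnames(spectra)),
    fractions = do.call(rbind, lapply(fits, `[[`, "fractions")) |>
      `rownames<-`(colnames(spectra)),
    present = do.call(rbind, lapply(fits, `[[`, "present")) |>
      `rownames<-`(colnames(spectra))
  )
}

cosineSim <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' De novo signature extraction by KL-NMF
#'
#' Factorizes the cohort spectra matrix (96 x samples) with Brunet-style
#' KL-divergence NMF over a range of ranks; the rank is selected by the
#' cophenetic coefficient of the restart-consensus clustering (ties to the
#' smaller rank), with the reconstruction-error curve attached. Each de novo
#' component is matched to the catalog signature of maximal cosine
#' similarity.
#'
#' @param spectra 96 x samples matrix with at least 10 samples.
#' @param catalog 96 x K probability matrix for matching.
#' @param k_range candidate ranks.
#' @param restarts NMF restarts per rank.
#' @param seed RNG seed (factorization is deterministic given the seed).
#' @return list with `signatures` (96 x k, columns sum to 1), `exposures`
#'   (k x samples), `k`, `matching` (data.frame component, best catalog
#'   match, cosine), `cophenetic`, `kl_error`.
#' @export
extractDenovoNMF <- function(spectra, catalog, k_range = 2:5, restarts = 10,
                             seed = 1) {
  if (ncol(spectra) < 10)
    stop("de novo extraction needs >= 10 samples", call. = FALSE)
  if (any(k_range >= ncol(spectra)))
    stop("k must be smaller than the number of samples", call. = FALSE)
  if (all(colSums(spectra) == 0)) stop("all spectra are zero", call. = FALSE)
  sel <- selectRank(spectra, k_range = k_range, restarts = restarts,
                    seed = seed)
  fit <- nmfBrunet(spectra, sel$k, restarts = restarts, seed = seed)
  W <- sweep(fit$W, 2L, colSums(fit$W), "/")
  H <- sweep(fit$H, 1L, colSums(fit$W), "*")
  colnames(W) <- paste0("denovo", seq_len(ncol(W)))
  match <- do.call(rbind, lapply(seq_len(ncol(W)), function(j) {
    cs <- apply(catalog, 2L, cosineSim, a = W[, j])
    data.frame(component = colnames(W)[j],
               match = names(which.max(cs)),
               cosine = max(cs), stringsAsFactors = FALSE)
  }))
  list(signatures = W, exposures = H, k = sel$k, matching = match,
       cophenetic = sel$cophenetic, kl_error = sel$kl_error)
}

# ---- APOBEC ------------------------------------------------------------------

countOverlapping <- function(x, patterns) {
  sum(vapply(patterns, function(p)
    sum(vapply(gregexpr(paste0("(?=", p, ")"), x, perl = TRUE),
               function(g) sum(g > 0), numeric(1))), numeric(1)))
}

#' APOBEC tCw enrichment
#'
#' Per sample, quantifies APOBEC mutagenesis from C>T and C>G SNVs at
#' cytosines (G-reference mutations reverse-complemented): the enrichment is
#' `E = (mut_tCw / mut_C) / (ctx_tCw / ctx_C)` where the context counts are
#' taken over the +/- `w` nt reference windows around each mutated cytosine
#' (cytosines and tCw motifs counted on both strands). Significance per
#' sample by Fisher's exact test on the 2x2 table (mut_tCw, mut_C -
#' mut_tCw; ctx_tCw, ctx_C - ctx_tCw), BH-adjusted across samples. The
#' APOBEC load is `mut_tCw * max(0, (E - 1) / E)`; samples with q >= 0.05
#' (or undefined E) form the "none" group, the rest split into low/high at
#' the cohort median load.
#'
#' @param cohort an [NmibcCohort].
#' @param genome [Biostrings::DNAStringSet] reference.
#' @param w window half-width in nt (default 20).
#' @return data.frame per sample: mut_tcw, mut_c, ctx_tcw, ctx_c,
#'   enrichment, p, q, load, group.
#' @export
apobecEnrichment <- function(cohort, genome, w = 20) {
  muts <- mutations(cohort)
  samples <- sampleIds(cohort)
  rows <- lapply(samples, function(sid) {
    m <- muts[muts$sample_id == sid & muts$is_snv, , drop = FALSE]
    # C>T / C>G at cytosines, either strand
    sel <- (m$ref == "C" & m$alt %in% c("T", "G")) |
      (m$ref == "G" & m$alt %in% c("A", "C"))
    m <- m[sel, , drop = FALSE]
    mutC <- nrow(m)
    if (!mutC)
      return(data.frame(sample_id = sid, mut_tcw = 0, mut_c = 0,
                        ctx_tcw = 0, ctx_c = 0, enrichment = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    ctx <- m$context3
    pyrCtx <- ifelse(m$ref == "C", ctx, revComp(ctx))
    mutTcw <- sum(substr(pyrCtx, 1L, 1L) == "T" &
                    substr(pyrCtx, 3L, 3L) %in% c("A", "T"))
    ctxTcw <- 0; ctxC <- 0
    for (ch in intersect(unique(m$chrom), names(genome))) {
      ii <- which(m$chrom == ch)
      L <- Biostrings::width(genome[ch])
      st <- pmax(1L, m$pos[ii] - w)
      en <- pmin(L, m$pos[ii] + w)
      win <- as.character(Biostrings::extractAt(
        genome[[ch]], IRanges::IRanges(st, en)))
      for (s in win) {
        ctxC <- ctxC + countOverlapping(s, c("C", "G"))
        ctxTcw <- ctxTcw + countOverlapping(s, c("TCA", "TCT", "TGA", "AGA"))
      }
    }
    E <- if (mutC > 0 && ctxTcw > 0 && ctxC > ctxTcw)
      (mutTcw / mutC) / (ctxTcw / ctxC) else NA_real_
    p <- if (!is.na(E))
      stats::fisher.test(matrix(c(mutTcw, mutC - mutTcw,
                                  ctxTcw, ctxC - ctxTcw), 2L,
                                byrow = TRUE))$p.value else NA_real_
    data.frame(sample_id = sid, mut_tcw = mutTcw, mut_c = mutC,
               ctx_tcw = ctxTcw, ctx_c = ctxC, enrichment = E, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out$load <- ifelse(is.na(out$enrichment), 0,
                     out$mut_tcw * pmax(0, (out$enrichment - 1) /
                                          out$enrichment))
  out$group <- "none"
  sig <- ok & out$q < 0.05 & !is.na(out$enrichment)
  if (any(sig)) {
    med <- stats::median(out$load[sig])
    out$group[sig] <- ifelse(out$load[sig] > med, "high", "low")
  }
  out
}
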