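# Brunet-NMF consensus subtyping of the binary genomic event matrix.
# Factorization minimizes the (generalized) KL divergence with multiplicative
# updates; the objective is non-increasing at every step. Rank selection uses
# the cophenetic correlation of the restart-consensus clustering (maximum,
# ties to the smaller rank). Samples are assigned by the argmax of their
# coefficient column, ties to the lowest factor index.

klDivergence <- function(V, WH) {
  eps <- 1e-12
  sum(ifelse(V > 0, V * log(V / (WH + eps)), 0) - V + WH)
}

nmfBrunetOnce <- function(V, k, tol, max_iter) {
  n <- nrow(V); p <- ncol(V)
  eps <- 1e-12
  W <- matrix(stats::runif(n * k, 0.1, 1), n, k)
  H <- matrix(stats::runif(k * p, 0.1, 1), k, p)
  klPrev <- Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    WH <- W %*% H + eps
    H <- H * (t(W) %*% (V / WH)) / pmax(colSums(W), eps)
    WH <- W %*% H + eps
    W <- W * ((V / WH) %*% t(H)) / rep(pmax(rowSums(H), eps), each = n)
    kl <- klDivergence(V, W %*% H)
    trace[it] <- kl
    if (is.finite(klPrev) && abs(klPrev - kl) < tol * (abs(klPrev) + eps))
      break
    klPrev <- kl
  }
  list(W = W, H = H, kl = kl, trace = trace)
}

#' Brunet KL-divergence NMF
#'
#' Factorizes a non-negative matrix `V ~ W H` (features x samples) with
#' KL-divergence multiplicative updates, keeping the best of `restarts`
#' random initializations by final KL. Deterministic given `seed`.
#'
#' @param V non-negative numeric matrix.
#' @param k factorization rank (`1 <= k < min(dim(V))` recommended).
#' @param restarts random restarts (best kept).
#' @param seed RNG seed.
#' @param tol relative KL tolerance for convergence.
#' @param max_iter iteration cap per restart.
#' @return list with `W`, `H`, `kl`, `trace` (KL per iteration of the best
#'   restart).
#' @export
nmfBrunet <- function(V, k, restarts = 30, seed = 1, tol = 1e-6,
                      max_iter = 5000) {
  V <- as.matrix(V)
  if (any(V < 0)) stop("NMF input must be non-negative", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  withSeed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      fit <- nmfBrunetOnce(V, k, tol, max_iter)
      if (is.null(best) || fit$kl < best$kl) best <- fit
    }
    best
  })
}

# argmax assignment of samples (columns of H) after rescaling each factor
# to a unit-sum basis column (assignment must not depend on the arbitrary
# W/H scale split); ties to lowest factor index
assignFromCoef <- function(H, W = NULL) {
  if (!is.null(W)) {
    s <- pmax(colSums(W), 1e-12)
    H <- H * s
  }
  apply(H, 2L, which.max)
}

#' Consensus rank selection
#'
#' For each candidate rank, clusters the samples by `restarts` independently
#' initialized factorizations, averages the connectivity matrices into a
#' consensus matrix, and computes the cophenetic correlation between the
#' consensus dissimilarity and its average-linkage dendrogram.
#'
#' On binary event matrices the consensus is frequently near-perfect for
#' several nested partitions at once (a merge of two true groups is exactly
#' as reproducible as the full split), so stability alone cannot order the
#' candidate ranks. A rank is therefore *supported* when the reconstruction
#' error curve has a genuine elbow there - the KL reduction gained by its
#' last factor is at least `elbow_ratio` times the reduction the next factor
#' would add - and its consensus is stable (cophenetic >= `min_stability`).
#' The largest supported rank (the finest resolution the error curve
#' supports) is selected; when no rank is supported the maximal cophenetic
#' coefficient decides (ties to the smaller rank). A flat/low cophenetic
#' curve (all below 0.9) additionally triggers a structureless-matrix
#' warning.
#'
#' @param V non-negative matrix, features x samples.
#' @param k_range candidate ranks (within `[2, 8]`).
#' @param restarts factorizations per rank.
#' @param seed RNG seed.
#' @param tol,max_iter per-factorization convergence control.
#' @param elbow_ratio minimal ratio of consecutive error drops for a
#'   supported elbow (default 1.7).
#' @param min_stability minimal cophenetic coefficient of a supported rank.
#' @return list with `k`, `cophenetic` (named numeric), `kl_error` (named;
#'   best KL per rank, including the flanking ranks used for the elbow),
#'   `elbow_ratio` (named; the drop ratio per candidate rank), `consensus`
#'   (list of consensus matrices per rank).
#' @export
selectRank <- function(V, k_range = 2:6, restarts = 30, seed = 1,
                       tol = 1e-6, max_iter = 2000, elbow_ratio = 1.7,
                       min_stability = 0.95) {
  V <- as.matrix(V)
  n <- ncol(V)
  if (any(k_range >= n))
    stop("k must be smaller than the number of samples", call. = FALSE)
  if (length(k_range) == 1L)
    message("single candidate rank: k = ", k_range, " returned as given")
  coph <- stats::setNames(numeric(length(k_range)), k_range)
  consensus <- list()
  # error curve over the candidates plus one flanking rank on each side,
  # so every candidate has both drops of its elbow ratio
  kErr <- max(1L, min(k_range) - 1L):min(max(k_range) + 1L, n - 1L)
  klBest <- stats::setNames(rep(Inf, length(kErr)), kErr)
  for (ki in seq_along(kErr)) {
    k <- kErr[ki]
    inCand <- k %in% k_range
    C <- matrix(0, n, n)
    withSeed(childSeed(seed, k), {
      for (r in seq_len(restarts)) {
        fit <- nmfBrunetOnce(V, k, tol, max_iter)
        klBest[ki] <- min(klBest[ki], fit$kl)
        if (inCand) {
          lab <- assignFromCoef(fit$H, fit$W)
          C <- C + outer(lab, lab, "==")
        }
      }
    })
    if (!inCand) next
    C <- C / restarts
    diag(C) <- 1
    d <- stats::as.dist(1 - C)
    ci <- which(k_range == k)
    if (stats::sd(d) < 1e-12) {
      coph[ci] <- 1  # perfectly stable single structure
    } else {
      hc <- stats::hclust(d, method = "average")
      coph[ci] <- stats::cor(d, stats::cophenetic(hc))
    }
    consensus[[as.character(k)]] <- C
  }
  if (all(coph < 0.9))
    warning("no rank reaches cophenetic 0.9: the matrix may be ",
            "structureless", call. = FALSE)
  # elbow ratios: drop entering k over drop entering k + 1
  eps <- 1e-9 + 1e-4 * abs(klBest[1])
  drops <- pmax(-diff(klBest), eps)
  ratio <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  for (ci in seq_along(k_range)) {
    k <- k_range[ci]
    i <- match(k, kErr)
    if (!is.na(i) && i > 1 && i < length(kErr))
      ratio[ci] <- drops[i - 1] / drops[i]
  }
  supported <- !is.na(ratio) & ratio >= elbow_ratio &
    coph >= min_stability
  kSel <- if (any(supported)) max(k_range[supported]) else
    k_range[which.max(coph)]
  list(k = kSel, cophenetic = coph, kl_error = klBest,
       elbow_ratio = ratio, consensus = consensus)
}

#' Build the binary subtyping matrix
#'
#' Union of the frequency-filtered event matrix and the significant
#' focal/broad CNA indicator columns, deduplicated by column name (with a
#' warning). Fewer than 2 columns, or all-constant columns, is an error.
#'
#' @param eventMatrix binary matrix from [assembleEventMatrix()].
#' @param cnaMatrix optional binary matrix of significant CNA indicators
#'   ([cnaEventMatrix()]).
#' @return binary integer matrix samples x events.
#' @export
buildSubtypingMatrix <- function(eventMatrix, cnaMatrix = NULL) {
  m <- as.matrix(eventMatrix) * 1L
  if (!is.null(cnaMatrix) && ncol(cnaMatrix)) {
    m <- cbind(m, as.matrix(cnaMatrix) * 1L)
  }
  dup <- duplicated(colnames(m))
  if (any(dup)) {
    warning("deduplicating repeated event column(s): ",
            paste(unique(colnames(m)[dup]), collapse = ", "),
            call. = FALSE)
    m <- m[, !dup, drop = FALSE]
  }
  if (ncol(m) < 2) stop("subtyping needs >= 2 event columns", call. = FALSE)
  cs <- colMeans(m)
  if (all(cs == 0 | cs == 1))
    stop("all event columns are constant", call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

#' Fit the NMF subtype model
#'
#' Selects the rank by [selectRank()] over `k_range`, refits Brunet NMF at
#' the selected rank (events x samples orientation) and assigns each sample
#' to the argmax of its coefficient column.
#'
#' @param m binary subtyping matrix (samples x events).
#' @param k_range candidate ranks.
#' @param restarts NMF restarts.
#' @param seed RNG seed.
#' @return a [SubtypeModel].
#' @export
fitSubtypes <- function(m, k_range = 2:6, restarts = 30, seed = 1) {
  V <- t(as.matrix(m))
  sel <- selectRank(V, k_range = k_range, restarts = restarts, seed = seed)
  fit <- nmfBrunet(V, sel$k, restarts = restarts, seed = childSeed(seed, 99))
  labels <- assignFromCoef(fit$H, fit$W)
  names(labels) <- rownames(m)
  methods::new("SubtypeModel",
               basis = fit$W, coef = fit$H, rank = as.integer(sel$k),
               labels = as.integer(labels) |>
                 stats::setNames(rownames(m)),
               consensus = sel$consensus[[as.character(sel$k)]],
               cophenetic = sel$cophenetic,
               enrichment = data.frame())
}

#' Characterize subtypes by feature enrichment
#'
#' One-vs-rest Fisher exact test (with odds ratio) per subtype x binary
#' feature, BH-adjusted within feature family; TMB compared across subtypes
#' by the Kruskal-Wallis rank-sum test. Subtypes smaller than 3 samples are
#' flagged but still reported. Constant features yield NA.
#'
#' @param model a [SubtypeModel] (or named integer label vector).
#' @param features binary matrix samples x features (same order as labels).
#' @param tmb optional named per-sample TMB vector.
#' @param family optional feature -> family grouping for the BH adjustment
#'   (defaults to one family).
#' @return list with `enrichment` data.frame (subtype, feature, or, p, q,
#'   small_subtype) and `tmb_p` (Kruskal-Wallis p or NA).
#' @export
characterizeSubtypes <- function(model, features, tmb = NULL,
                                 family = NULL) {
  labels <- if (methods::is(model, "SubtypeModel")) subtypeLabels(model)
  else model
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  family <- family %||% rep("all", ncol(features))
  rows <- list()
  for (s in sort(unique(labels))) {
    inS <- labels == s
    for (j in seq_len(ncol(features))) {
      f <- features[, j] > 0
      if (all(f) || all(!f)) {
        orv <- NA_real_; p <- NA_real_
      } else {
        ft <- stats::fisher.test(table(factor(inS, c(TRUE, FALSE)),
                                       factor(f, c(TRUE, FALSE))))
        orv <- unname(ft$estimate); p <- ft$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subtype = s, feature = colnames(features)[j],
        family = family[j], or = orv, p = p,
        small_subtype = sum(inS) < 3, stringsAsFactors = FALSE)
    }
  }
  enr <- do.call(rbind, rows)
  enr$q <- NA_real_
  for (fam in unique(enr$family)) {
    sel <- enr$family == fam & !is.na(enr$p)
    enr$q[sel] <- stats::p.adjust(enr$p[sel], method = "BH")
  }
  tmbP <- NA_real_
  if (!is.null(tmb) && length(unique(labels)) > 1)
    tmbP <- stats::kruskal.test(tmb[names(labels)], factor(labels))$p.value
  list(enrichment = enr, tmb_p = tmbP)
}
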