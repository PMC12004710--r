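# Expression-based scoring: median-of-ratios normalization, a one-vs-rest
# differential ranker (rank-sum test + shrunken log2 fold change), rank-based
# single-sample gene-set scores (ssGSEA-style weighted running sum, linearly
# rescaled to [-1, 1] across the cohort), subtype scores (up minus down),
# and canonical bladder-cancer marker panels. Externally computed DE tables
# can be supplied in place of the built-in ranker.

#' Median-of-ratios normalization
#'
#' DESeq-style size factors: per sample the median ratio of counts to the
#' per-gene geometric mean (over genes expressed everywhere), deterministic.
#'
#' @param counts genes x samples count matrix.
#' @return normalized matrix of the same shape.
#' @export
normalizeCounts <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) return(counts)
  logGeo <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2L, function(x)
    exp(stats::median(log(x) - logGeo)))
  sf[sf <= 0 | !is.finite(sf)] <- 1
  sweep(counts, 2L, sf, "/")
}

#' One-vs-rest subtype marker ranking
#'
#' For each subtype with at least 3 samples, ranks genes by the BH-adjusted
#' Wilcoxon rank-sum p (subtype vs rest, on median-of-ratios normalized
#' counts) and takes the top `n_top`, split into up/down sets by the sign of
#' the shrunken log2 fold change `log2((mean_in + c) / (mean_out + c))`.
#'
#' @param counts genes x samples count matrix.
#' @param labels per-sample subtype labels (column order).
#' @param n_top genes per subtype (default 30; capped at the number of
#'   genes with a warning).
#' @param pseudo shrinkage pseudocount `c`.
#' @return named list per subtype: `up`, `down` (gene sets) and `table`
#'   (gene, lfc, p, q ordered by q).
#' @export
rankSubtypeGenes <- function(counts, labels, n_top = 30, pseudo = 5) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == length(labels))
  if (n_top > nrow(counts)) {
    warning("n_top exceeds available genes; using all ", nrow(counts),
            call. = FALSE)
    n_top <- nrow(counts)
  }
  norm <- normalizeCounts(counts)
  out <- list()
  for (s in sort(unique(labels))) {
    inS <- labels == s
    if (sum(inS) < 3) {
      warning("subtype ", s, " has < 3 samples: skipped", call. = FALSE)
      next
    }
    p <- vapply(seq_len(nrow(norm)), function(i)
      stats::wilcox.test(norm[i, inS], norm[i, !inS],
                         exact = FALSE)$p.value, numeric(1))
    lfc <- log2((rowMeans(norm[, inS, drop = FALSE]) + pseudo) /
                  (rowMeans(norm[, !inS, drop = FALSE]) + pseudo))
    q <- stats::p.adjust(p, method = "BH")
    tab <- data.frame(gene = rownames(norm), lfc = lfc, p = p, q = q,
                      stringsAsFactors = FALSE)
    tab <- tab[order(tab$q, tab$p), , drop = FALSE]
    top <- tab[seq_len(n_top), , drop = FALSE]
    out[[as.character(s)]] <- list(
      up = top$gene[top$lfc > 0],
      down = top$gene[top$lfc < 0],
      table = tab)
  }
  out
}

#' Rank-based single-sample gene-set score
#'
#' ssGSEA-style score: per sample, genes are walked in decreasing expression
#' order; in-set genes add their rank weight `rank^alpha` (normalized over
#' the set), out-of-set genes subtract `1 / (N - n)`; the score is the sum
#' of the running sum, linearly rescaled across the cohort to `[-1, 1]`.
#' Being rank-based, the score is invariant under any monotone within-sample
#' transform of expression.
#'
#' @param expr genes x samples matrix (counts or normalized).
#' @param geneSet character vector of gene names; genes absent from `expr`
#'   are ignored, but an empty intersection is an error naming the missing
#'   genes.
#' @param alpha rank-weight exponent (default 0.25).
#' @param rescale linearly rescale to \[-1, 1\] across the cohort.
#' @return named numeric vector of per-sample scores.
#' @export
geneSetScore <- function(expr, geneSet, alpha = 0.25, rescale = TRUE) {
  expr <- as.matrix(expr)
  set <- intersect(unique(geneSet), rownames(expr))
  if (!length(set))
    stop("no gene of the set is in the matrix; missing: ",
         paste(utils::head(setdiff(geneSet, rownames(expr)), 10),
               collapse = ", "), call. = FALSE)
  N <- nrow(expr)
  n <- length(set)
  if (n == N)  # no out-of-set genes: enrichment is degenerate by definition
    return(stats::setNames(rep(0, ncol(expr)), colnames(expr)))
  inSet <- rownames(expr) %in% set
  raw <- vapply(seq_len(ncol(expr)), function(j) {
    r <- rank(expr[, j], ties.method = "average")
    ord <- order(expr[, j], decreasing = TRUE)
    inOrd <- inSet[ord]
    w <- r[ord]^alpha
    inc <- ifelse(inOrd, w, 0)
    inc <- inc / sum(inc)
    dec <- if (N > n) ifelse(inOrd, 0, 1 / (N - n)) else 0
    sum(cumsum(inc - dec))
  }, numeric(1))
  names(raw) <- colnames(expr)
  if (!rescale) return(raw)
  rng <- range(raw)
  if (diff(rng) < 1e-9 * max(1, abs(rng[2])))
    return(stats::setNames(rep(0, length(raw)), names(raw)))
  2 * (raw - rng[1]) / diff(rng) - 1
}

#' Subtype score
#'
#' Difference between the subtype-up and subtype-down gene-set scores;
#' exactly antisymmetric under swapping the sets. For survival validation
#' the cohort is dichotomized at the median score.
#'
#' @param up,down per-sample scores ([geneSetScore()]).
#' @return list with `score` and `group` (`"high"`/`"low"` at the median).
#' @export
subtypeScore <- function(up, down) {
  sc <- up - down
  med <- stats::median(sc)
  list(score = sc, group = ifelse(sc > med, "high", "low"))
}

#' Path to the bundled marker-panel definitions
#' @return file path inside the installed package.
#' @export
panelDefinitionsPath <- function() {
  system.file("extdata", "expression_panels.tsv",
              package = "nmibcGenomics", mustWork = TRUE)
}

#' Read panel definitions
#'
#' @param path TSV with columns `panel`, `gene`.
#' @return data.frame.
#' @export
readPanelDefinitions <- function(path = panelDefinitionsPath()) {
  df <- readTsv(path)
  requireColumns(df, c("panel", "gene"), basename(path))
  df
}

#' Canonical marker-panel scores
#'
#' Applies [geneSetScore()] to each panel; when group labels are given,
#' panels are compared across groups by the Wilcoxon/Kruskal rank-sum test
#' with BH adjustment.
#'
#' @param expr genes x samples matrix.
#' @param panels data.frame (panel, gene), default the bundled panels.
#' @param groups optional per-sample group labels.
#' @return list with `scores` (samples x panels matrix) and `tests`
#'   (data.frame panel, p, q; NULL without groups).
#' @export
panelScores <- function(expr, panels = readPanelDefinitions(),
                        groups = NULL) {
  pn <- unique(panels$panel)
  scores <- vapply(pn, function(p) {
    geneSetScore(expr, panels$gene[panels$panel == p])
  }, numeric(ncol(expr)))
  rownames(scores) <- colnames(expr)
  tests <- NULL
  if (!is.null(groups)) {
    stopifnot(length(groups) == ncol(expr))
    p <- vapply(pn, function(pp) {
      s <- scores[, pp]
      if (stats::sd(s) < 1e-12 || length(unique(groups)) < 2)
        return(NA_real_)
      if (length(unique(groups)) == 2)
        stats::wilcox.test(s ~ factor(groups), exact = FALSE)$p.value
      else stats::kruskal.test(s, factor(groups))$p.value
    }, numeric(1))
    tests <- data.frame(panel = pn, p = p,
                        q = stats::p.adjust(p, method = "BH"),
                        stringsAsFactors = FALSE)
  }
  list(scores = scores, tests = tests)
}
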