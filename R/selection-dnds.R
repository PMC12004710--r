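# dN/dS selection. Opportunities are computed by enumerating every possible
# single-base change of each coding sequence, classifying its consequence
# against the genetic code, and weighting by a trinucleotide-free rate model
# (6 pyrimidine substitution types x CpG flag) estimated from synonymous
# sites (uniform by default). dN/dS for a class is the ratio of observed/
# expected nonsynonymous to observed/expected synonymous rates; the CI is
# the exact conditional-binomial interval for a ratio of Poisson rates.
# The point-mutation estimate combines missense, nonsense and splice. The
# timing odds ratio is dN/dS(early) / dN/dS(late) with the > 2 / < 0.5
# early-/late-favored cutoffs.

SUB_TYPES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' @noRd
#' Consequence of substituting `alt` at position `pos` of an in-frame CDS
#' given as a character vector of bases.
classifyCodonChange <- function(cdsChars, pos, alt) {
  L <- length(cdsChars)
  if (L %% 3L != 0L) stop("CDS length not divisible by 3", call. = FALSE)
  if (pos < 1L || pos > L) stop("position outside CDS", call. = FALSE)
  ci <- (pos - 1L) %/% 3L
  off <- (pos - 1L) %% 3L
  refCodon <- paste(cdsChars[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
  altChars <- cdsChars[(ci * 3L + 1L):(ci * 3L + 3L)]
  altChars[off + 1L] <- alt
  altCodon <- paste(altChars, collapse = "")
  code <- Biostrings::GENETIC_CODE
  aaRef <- code[[refCodon]]
  aaAlt <- code[[altCodon]]
  if (aaRef == aaAlt) "synonymous"
  else if (aaAlt == "*") "nonsense"
  else "missense"
}

#' Uniform substitution-rate model
#'
#' 6 pyrimidine substitution types x (non-CpG, CpG), all rates 1.
#' @return numeric matrix 6 x 2.
#' @export
uniformRates <- function() {
  matrix(1, 6, 2, dimnames = list(SUB_TYPES, c("nonCpG", "CpG")))
}

# pyrimidine-folded substitution type and CpG flag of a genomic change
foldSubType <- function(ref, alt) {
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, complementBase(ref), ref)
  a <- ifelse(pur, complementBase(alt), alt)
  paste0(r, ">", a)
}

# CpG flag: the site is part of a CG dinucleotide on either strand
isCpgSite <- function(base, nextBase, prevBase) {
  (base == "C" & !is.na(nextBase) & nextBase == "G") |
    (base == "G" & !is.na(prevBase) & prevBase == "C")
}

#' @noRd
#' Enumerate all 3L single-base changes of an in-frame CDS: one row per
#' (position, alt) with consequence class, folded substitution type and CpG
#' flag. Vectorized; shared by opportunities, rate estimation and the
#' neutral simulator.
enumerateCdsChanges <- function(cds) {
  if (!nzchar(cds)) stop("empty coding sequence", call. = FALSE)
  b <- strsplit(toupper(cds), "", fixed = TRUE)[[1]]
  L <- length(b)
  if (L %% 3L != 0L) stop("CDS length not divisible by 3", call. = FALSE)
  code <- Biostrings::GENETIC_CODE
  pos <- rep(seq_len(L), each = 3L)
  ref <- b[pos]
  altOf <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))
  alt <- as.vector(t(altOf[ref[seq(1, length(pos), by = 3L)], ,
                           drop = FALSE]))
  off <- (pos - 1L) %% 3L
  cs <- pos - off
  c1 <- b[cs]; c2 <- b[cs + 1L]; c3 <- b[cs + 2L]
  refCodon <- paste0(c1, c2, c3)
  a1 <- ifelse(off == 0L, alt, c1)
  a2 <- ifelse(off == 1L, alt, c2)
  a3 <- ifelse(off == 2L, alt, c3)
  altCodon <- paste0(a1, a2, a3)
  aaRef <- unname(code[refCodon])
  aaAlt <- unname(code[altCodon])
  cls <- ifelse(aaRef == aaAlt, "synonymous",
                ifelse(aaAlt == "*", "nonsense", "missense"))
  nb <- c(b[-1L], NA_character_)[pos]
  pb <- c(NA_character_, b[-L])[pos]
  cpg <- ifelse(isCpgSite(ref, nb, pb), "CpG", "nonCpG")
  data.frame(pos = pos, ref = ref, alt = alt, class = cls,
             type = foldSubType(ref, alt), cpg = cpg,
             stringsAsFactors = FALSE)
}

#' Per-gene mutation opportunities
#'
#' Enumerates all `3 * L` single-base changes of an in-frame CDS, classifies
#' each against the genetic code, and sums the rate-model weight per
#' consequence class. Opportunities are additive over sites.
#'
#' @param cds coding sequence (single character string, length divisible
#'   by 3).
#' @param rates 6 x 2 rate matrix (see [uniformRates()]).
#' @return named numeric vector: missense, nonsense, synonymous.
#' @export
mutationOpportunities <- function(cds, rates = uniformRates()) {
  ch <- enumerateCdsChanges(cds)
  w <- rates[cbind(match(ch$type, SUB_TYPES),
                   ifelse(ch$cpg == "CpG", 2L, 1L))]
  out <- c(missense = 0, nonsense = 0, synonymous = 0)
  agg <- tapply(w, ch$class, sum)
  out[names(agg)] <- agg
  out
}

#' Estimate a rate model from synonymous mutations
#'
#' Rates per substitution type x CpG stratum are observed synonymous counts
#' divided by synonymous opportunities of that stratum (computed with unit
#' rates), rescaled to mean 1. Strata with no opportunity keep rate 1.
#'
#' @param synTypes data.frame with `type` (folded substitution) and `cpg`
#'   ("CpG"/"nonCpG") of observed synonymous mutations.
#' @param cdsList character vector of the coding sequences in scope.
#' @return 6 x 2 rate matrix.
#' @export
estimateRateModel <- function(synTypes, cdsList) {
  opp <- matrix(0, 6, 2, dimnames = list(SUB_TYPES, c("nonCpG", "CpG")))
  for (cds in cdsList) {
    ch <- enumerateCdsChanges(cds)
    ch <- ch[ch$class == "synonymous", , drop = FALSE]
    if (!nrow(ch)) next
    t0 <- table(factor(ch$type, SUB_TYPES),
                factor(ch$cpg, c("nonCpG", "CpG")))
    opp <- opp + unclass(t0)
  }
  obs <- matrix(0, 6, 2, dimnames = dimnames(opp))
  if (nrow(synTypes)) {
    t0 <- table(factor(synTypes$type, SUB_TYPES),
                factor(synTypes$cpg, c("nonCpG", "CpG")))
    obs <- obs + unclass(t0)
  }
  rates <- ifelse(opp > 0, obs / pmax(opp, 1e-12), NA)
  mean0 <- mean(rates[opp > 0 & obs > 0])
  if (!is.finite(mean0) || mean0 <= 0) return(uniformRates())
  rates <- rates / mean0
  rates[!is.finite(rates)] <- 1
  rates[rates <= 0] <- min(rates[rates > 0], 0.05) / 2
  rates
}

#' dN/dS point estimate with exact CI
#'
#' `dN/dS = (n_class / L_class) / (n_syn / L_syn)`. Conditional on the total
#' count, `n_class` is binomial with success probability
#' `L_class w / (L_class w + L_syn)`; the Clopper-Pearson interval on that
#' probability transforms into the exact CI for `w`. Zero synonymous counts
#' flag the estimate unstable (CI upper unbounded).
#'
#' @param n_class,n_syn observed counts in the class and synonymous.
#' @param L_class,L_syn opportunity totals.
#' @param conf confidence level.
#' @return data.frame dnds, lower, upper, p (two-sided test of w = 1),
#'   unstable.
#' @export
estimateDnds <- function(n_class, n_syn, L_class, L_syn, conf = 0.95) {
  stopifnot(L_class > 0, L_syn > 0)
  N <- n_class + n_syn
  if (N == 0)
    return(data.frame(dnds = NA_real_, lower = NA_real_, upper = NA_real_,
                      p = NA_real_, unstable = TRUE))
  a <- (1 - conf) / 2
  pl <- if (n_class == 0) 0 else stats::qbeta(a, n_class, N - n_class + 1)
  pu <- if (n_class == N) 1 else stats::qbeta(1 - a, n_class + 1, N - n_class)
  toOmega <- function(p) p * L_syn / ((1 - p) * L_class)
  w <- (n_class / L_class) / max(n_syn, 1e-12) * L_syn
  p0 <- L_class / (L_class + L_syn)
  pval <- stats::binom.test(n_class, N, p = p0)$p.value
  data.frame(dnds = if (n_syn == 0) Inf else w,
             lower = toOmega(pl),
             upper = if (n_class == N) Inf else toOmega(pu),
             p = pval, unstable = n_syn == 0)
}

#' Classify cohort SNVs against gene CDS models and tally per-gene counts
#'
#' @param muts mutation table slice (SNVs in genes are classified from the
#'   codon change; splice consequences are kept as labelled).
#' @param genes gene model table (gene, chrom, start, end).
#' @param genome [Biostrings::DNAStringSet].
#' @return data.frame per gene x class counts (missense, nonsense,
#'   synonymous, splice).
#' @export
tallyGeneClasses <- function(muts, genes, genome) {
  classes <- c("missense", "nonsense", "synonymous", "splice")
  m <- muts[muts$gene %in% genes$gene &
              muts$consequence %in% classes, , drop = FALSE]
  tab <- table(factor(m$gene, genes$gene),
               factor(m$consequence, classes))
  out <- as.data.frame.matrix(tab)
  out$gene <- rownames(out)
  rownames(out) <- NULL
  out[, c("gene", classes)]
}

geneCds <- function(gene, genes, genome) {
  g <- genes[genes$gene == gene, ]
  as.character(Biostrings::subseq(genome[[g$chrom]], g$start, g$end))
}

#' Gene-level and global dN/dS table
#'
#' Computes per-gene (and pooled "global") dN/dS for missense, nonsense,
#' truncating (nonsense + splice) and the point-combined class
#' (missense + nonsense + splice), with BH q-values across genes per class.
#' The rate model defaults to one estimated from the scope's synonymous
#' mutations.
#'
#' @param muts mutation table slice (e.g. one timing stratum).
#' @param genes gene model table.
#' @param genome reference [Biostrings::DNAStringSet].
#' @param rates 6 x 2 rate matrix, or NULL to estimate from synonymous
#'   mutations in `muts`.
#' @param opportunities optional precomputed per-gene opportunity matrix
#'   (from a previous call with the same genes and rates), to avoid
#'   re-enumeration across timing strata.
#' @return list with `per_gene` (long data.frame gene/class/counts/dnds/CI/
#'   p/q), `global` (per-class pooled estimates), `opportunities`, `rates`.
#' @export
dndsTable <- function(muts, genes, genome, rates = NULL,
                      opportunities = NULL) {
  chars <- NULL
  if (is.null(rates)) {
    syn <- muts[muts$consequence == "synonymous" &
                  muts$gene %in% genes$gene & muts$is_snv, , drop = FALSE]
    synTypes <- data.frame(
      type = foldSubType(syn$ref, syn$alt),
      cpg = ifelse(
        isCpgSite(syn$ref,
                  substr(syn$context3, 3L, 3L),
                  substr(syn$context3, 1L, 1L)),
        "CpG", "nonCpG"),
      stringsAsFactors = FALSE)
    cdsList <- vapply(genes$gene, geneCds, character(1),
                      genes = genes, genome = genome)
    rates <- estimateRateModel(synTypes, cdsList)
  }
  opp <- opportunities %||% t(vapply(genes$gene, function(g)
    mutationOpportunities(geneCds(g, genes, genome), rates), numeric(3)))
  counts <- tallyGeneClasses(muts, genes, genome)
  classes <- list(
    missense = "missense",
    nonsense = "nonsense",
    truncating = c("nonsense", "splice"),
    `point-combined` = c("missense", "nonsense", "splice")
  )
  # splice opportunities are not modelled for single-exon gene models; the
  # splice share of a combined class falls back to nonsense-like weighting
  oppOf <- function(members) {
    members <- setdiff(members, "splice")
    rowSums(opp[, members, drop = FALSE])
  }
  perGene <- do.call(rbind, lapply(names(classes), function(cl) {
    mem <- classes[[cl]]
    nc <- rowSums(counts[, intersect(mem, names(counts)), drop = FALSE])
    Lc <- oppOf(mem)
    do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
      est <- estimateDnds(nc[i], counts$synonymous[i], Lc[i],
                          opp[i, "synonymous"])
      cbind(data.frame(gene = counts$gene[i], class = cl,
                       n_class = nc[i], n_syn = counts$synonymous[i],
                       stringsAsFactors = FALSE), est)
    }))
  }))
  perGene$q <- NA_real_
  for (cl in names(classes)) {
    sel <- perGene$class == cl & !is.na(perGene$p)
    perGene$q[sel] <- stats::p.adjust(perGene$p[sel], method = "BH")
  }
  globalRows <- do.call(rbind, lapply(names(classes), function(cl) {
    mem <- classes[[cl]]
    nc <- sum(counts[, intersect(mem, names(counts))])
    est <- estimateDnds(nc, sum(counts$synonymous), sum(oppOf(mem)),
                        sum(opp[, "synonymous"]))
    cbind(data.frame(class = cl, n_class = nc,
                     n_syn = sum(counts$synonymous),
                     stringsAsFactors = FALSE), est)
  }))
  list(per_gene = perGene, global = globalRows, opportunities = opp,
       rates = rates)
}

#' Timing odds ratio and favored phase
#'
#' `OR = dN/dS(early) / dN/dS(late)`; phase is early-favored iff OR > 2,
#' late-favored iff OR < 0.5, else none. An unstable late estimate makes the
#' OR not evaluable.
#'
#' @param early,late single-row estimates (from [estimateDnds()] or rows of
#'   [dndsTable()]'s output).
#' @return data.frame or_timing, phase, evaluable.
#' @export
timingOddsRatio <- function(early, late) {
  if (isTRUE(late$unstable) || is.na(late$dnds) || late$dnds <= 0 ||
      is.na(early$dnds))
    return(data.frame(or_timing = NA_real_, phase = NA_character_,
                      evaluable = FALSE))
  or <- early$dnds / late$dnds
  phase <- if (or > 2) "early-favored" else if (or < 0.5) "late-favored"
  else "none"
  data.frame(or_timing = or, phase = phase, evaluable = TRUE)
}

#' Pathway-level dN/dS
#'
#' Pools mutations and opportunities over the member genes of each pathway,
#' then estimates as for genes. A pathway of a single gene equals that
#' gene's estimate; empty pathways are skipped.
#'
#' @param pathways data.frame with `pathway` and `gene` columns.
#' @param muts,genes,genome,rates as in [dndsTable()].
#' @param class class to estimate (default point-combined).
#' @return data.frame pathway, n_class, n_syn, dnds, lower, upper, p, q.
#' @export
pathwayDnds <- function(pathways, muts, genes, genome,
                        rates = uniformRates(),
                        class = c("point-combined", "missense", "nonsense",
                                  "truncating")) {
  class <- match.arg(class)
  mem <- list(missense = "missense", nonsense = "nonsense",
              truncating = c("nonsense", "splice"),
              `point-combined` = c("missense", "nonsense",
                                   "splice"))[[class]]
  counts <- tallyGeneClasses(muts, genes, genome)
  opp <- t(vapply(genes$gene, function(g)
    mutationOpportunities(geneCds(g, genes, genome), rates), numeric(3)))
  rows <- lapply(unique(pathways$pathway), function(pw) {
    gs <- intersect(pathways$gene[pathways$pathway == pw], genes$gene)
    if (!length(gs)) return(NULL)
    sel <- counts$gene %in% gs
    nc <- sum(counts[sel, intersect(mem, names(counts))])
    ns <- sum(counts$synonymous[sel])
    Lc <- sum(opp[gs, setdiff(mem, "splice"), drop = FALSE])
    Ls <- sum(opp[gs, "synonymous"])
    cbind(data.frame(pathway = pw, n_class = nc, n_syn = ns,
                     stringsAsFactors = FALSE),
          estimateDnds(nc, ns, Lc, Ls))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(pathway = character(0), n_class = numeric(0),
                      n_syn = numeric(0), dnds = numeric(0),
                      lower = numeric(0), upper = numeric(0),
                      p = numeric(0), unstable = logical(0),
                      q = numeric(0)))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Simulate mutations under the neutral rate model
#'
#' Draws `n` SNVs over the gene models with site/alt probabilities
#' proportional to the rate model and no selection; used for dN/dS
#' calibration. Optionally multiplies the nonsynonymous acceptance rate in
#' designated genes (`positive_genes`, `excess` > 1) to plant positive
#' selection.
#'
#' @param genes gene model table.
#' @param genome reference.
#' @param n number of mutations.
#' @param rates rate model.
#' @param seed RNG seed.
#' @param positive_genes genes with planted excess nonsynonymous mutations.
#' @param excess nonsynonymous excess factor for `positive_genes`.
#' @return mutation-table-like data.frame (gene, chrom, pos, ref, alt,
#'   consequence, context3, is_snv).
#' @export
simulateNeutralMutations <- function(genes, genome, n, rates = uniformRates(),
                                     seed = 1, positive_genes = character(0),
                                     excess = 1) {
  withSeed(seed, {
    # enumerate all possible changes once
    pool <- lapply(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      cds <- geneCds(g$gene, genes, genome)
      b <- strsplit(cds, "", fixed = TRUE)[[1]]
      L <- length(b)
      ch <- enumerateCdsChanges(cds)
      wt <- rates[cbind(match(ch$type, SUB_TYPES),
                        ifelse(ch$cpg == "CpG", 2L, 1L))]
      if (g$gene %in% positive_genes)
        wt <- ifelse(ch$class == "synonymous", wt, wt * excess)
      pb <- c("N", b[-L])[ch$pos]
      nb <- c(b[-1L], "N")[ch$pos]
      data.frame(gene = g$gene, chrom = g$chrom, pos = g$start + ch$pos - 1L,
                 ref = ch$ref, alt = ch$alt, consequence = ch$class,
                 weight = wt, context3 = paste0(pb, ch$ref, nb),
                 stringsAsFactors = FALSE)
    })
    pool <- do.call(rbind, pool)
    idx <- sample.int(nrow(pool), n, replace = TRUE, prob = pool$weight)
    out <- pool[idx, setdiff(names(pool), "weight")]
    out$is_snv <- TRUE
    out$sample_id <- "SIM"
    rownames(out) <- NULL
    out
  })
}
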