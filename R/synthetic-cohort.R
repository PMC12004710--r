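# Synthetic-cohort generator. Emits cohorts with known ground truth that
# reproduce the statistical structure the analysis assumes: purity 0.2-0.9,
# WES-like negative-binomial depth (mean 150), clonal + one-subclone CCF
# structure, signature-mixed trinucleotide spectra drawn against a toy
# reference genome, four copy-number/driver archetypes (AA-like hypermutated,
# FGFR3/HRAS flat, FGFR3 & chr9 deletion, genome-instability with wGD), an
# archetype-structured expression matrix and covariate-linked recurrence
# outcomes. Every emitted mutation has exactly one truth row.

ARCHETYPES <- c("AA_like", "FGFR3_HRAS", "FGFR3_chr9del", "GI")

#' Simulation configuration
#'
#' Returns the default simulation configuration, optionally overriding any
#' top-level entry. Defaults define the study conditions the generator
#' emulates: 10 samples per archetype, purity uniform on \[0.2, 0.9\],
#' negative-binomial depth (mean 150, size 8), one subclone per sample with
#' CCF uniform on \[0.15, 0.6\] carrying 25% of mutations, expected
#' mutation burdens 600/80/120/200 for the AA-like / FGFR3-HRAS /
#' FGFR3-chr9del / GI archetypes (the AA-like burden is >= 5x the
#' FGFR3/HRAS burden), archetype-specific signature mixtures over the
#' bundled catalog, and an exponential recurrence model with log-HR(CIN) =
#' log 2.
#'
#' @param ... named overrides of top-level config entries.
#' @return a list of class `nmibc_sim_config`.
#' @export
simulationConfig <- function(...) {
  sw <- rbind(
    AA_like       = c(SBS2s = 0.10, SBS5s = 0.20, SBS13s = 0.05, SBS22s = 0.65),
    FGFR3_HRAS    = c(SBS2s = 0.25, SBS5s = 0.60, SBS13s = 0.15, SBS22s = 0.00),
    FGFR3_chr9del = c(SBS2s = 0.20, SBS5s = 0.65, SBS13s = 0.10, SBS22s = 0.05),
    GI            = c(SBS2s = 0.35, SBS5s = 0.40, SBS13s = 0.25, SBS22s = 0.00)
  )
  cfg <- list(
    n_per_archetype = c(AA_like = 10, FGFR3_HRAS = 10,
                        FGFR3_chr9del = 10, GI = 10),
    seed = NULL,
    genome_length = 1e6,
    n_chromosomes = 10,
    gc = 0.45,
    n_genes = 150,
    depth_mean = 150,
    depth_size = 8,
    min_depth = 20,
    purity_range = c(0.2, 0.9),
    subclone_fraction = 0.25,
    subclone_ccf_range = c(0.15, 0.6),
    early_multiplicity_prob = 0.5,
    burden = c(AA_like = 600, FGFR3_HRAS = 80,
               FGFR3_chr9del = 120, GI = 200),
    signature_weights = sw,
    catalog = NULL,  # defaults to the bundled synthetic catalog
    with_expression = TRUE,
    expression = list(n_de = 30, n_filler = 150, fold = 4, panel_fold = 3,
                      nb_size = 10),
    survival = list(base_rate = 0.02, log_hr_cin = log(2),
                    log_hr_subtype = c(AA_like = 0, FGFR3_HRAS = 0,
                                       FGFR3_chr9del = 0, GI = 0),
                    censor_range = c(12, 60))
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown config entries: ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  validateSimConfig(cfg)
}

validateSimConfig <- function(cfg) {
  sw <- cfg$signature_weights
  if (any(sw < 0)) stop("signature weights must be >= 0", call. = FALSE)
  rs <- rowSums(sw)
  if (any(abs(rs - 1) > 1e-6)) {
    if (any(rs <= 0)) stop("signature weights must sum to 1", call. = FALSE)
    cfg$signature_weights <- sw / rs
  }
  if (!all(names(cfg$n_per_archetype) %in% ARCHETYPES))
    stop("unknown archetype in n_per_archetype", call. = FALSE)
  if (any(cfg$burden < 0)) stop("burden must be >= 0", call. = FALSE)
  class(cfg) <- "nmibc_sim_config"
  cfg
}

#' Simulate a toy reference genome
#'
#' Deterministically generates a toy genome of `n_chromosomes` chromosomes
#' (named `chr1..chrN`) with the requested total length and GC content, plus
#' a chromosome-arm table: each chromosome is split into a p arm (first 40%)
#' and a q arm. Arm intervals partition each chromosome exactly.
#'
#' @param length total genome length in bp (>= 10000).
#' @param seed RNG seed (mandatory).
#' @param n_chromosomes number of chromosomes.
#' @param gc target GC fraction.
#' @return list with `genome` (a [Biostrings::DNAStringSet]) and `arms`
#'   (data.frame chrom/start/end/arm).
#' @export
simulateReference <- function(length, seed, n_chromosomes = 10, gc = 0.45) {
  if (length < 10000) stop("genome length must be >= 10 kb", call. = FALSE)
  if (is.null(seed)) stop("seed is mandatory", call. = FALSE)
  withSeed(seed, {
    len <- rep(floor(length / n_chromosomes), n_chromosomes)
    len[n_chromosomes] <- len[n_chromosomes] + length - sum(len)
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(len, function(L) {
      paste(sample(names(probs), L, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
    names(seqs) <- paste0("chr", seq_len(n_chromosomes))
    arms <- do.call(rbind, lapply(seq_len(n_chromosomes), function(i) {
      pEnd <- floor(len[i] * 0.4)
      data.frame(chrom = names(seqs)[i],
                 start = c(1L, pEnd + 1L),
                 end = c(pEnd, len[i]),
                 arm = paste0(sub("chr", "", names(seqs)[i]), c("p", "q")))
    }))
    list(genome = Biostrings::DNAStringSet(seqs), arms = arms)
  })
}

# Named driver genes the generator plants. CDKN2A must land on chr9p (focal
# deep-deletion target); the amplification target lands on chr5.
SIM_DRIVER_GENES <- data.frame(
  gene = c("FGFR3", "HRAS", "PIK3CA", "TP53", "KDM6A", "KMT2D", "CREBBP",
           "STAG2", "ARID1A", "EP300", "RB1", "ERCC2", "LATS1", "CDKN1A",
           "ZFP36L1", "CDKN2A", "CCND1", "E2F3"),
  role = c("oncogene", "oncogene", "oncogene", "TSG", "TSG", "TSG", "TSG",
           "TSG", "TSG", "TSG", "TSG", "TSG", "TSG", "TSG", "TSG", "TSG",
           "oncogene", "oncogene"),
  stringsAsFactors = FALSE
)

# Archetype -> (gene, probability of carrying the planted driver)
simDriverPlan <- function() {
  list(
    AA_like = c(TP53 = 0.7, KDM6A = 0.7, KMT2D = 0.8, CREBBP = 0.6,
                ARID1A = 0.5, LATS1 = 0.6, CDKN1A = 0.5, ZFP36L1 = 0.5),
    FGFR3_HRAS = c(FGFR3 = 0.9, HRAS = 0.6, PIK3CA = 0.6, KDM6A = 0.4,
                   KMT2D = 0.3),
    FGFR3_chr9del = c(FGFR3 = 0.85, STAG2 = 0.5, KDM6A = 0.3,
                      KMT2D = 0.3, PIK3CA = 0.2),
    GI = c(TP53 = 0.7, RB1 = 0.4, EP300 = 0.4, ERCC2 = 0.25)
  )
}

# ---- reference preparation --------------------------------------------------

# Character vectors of the genome plus a folded-trinucleotide position index
# used to draw mutation sites matching a signature channel.
indexReference <- function(ref) {
  chroms <- names(ref$genome)
  tabs <- lapply(seq_along(chroms), function(i) {
    b <- strsplit(as.character(ref$genome[[i]]), "", fixed = TRUE)[[1]]
    L <- length(b)
    ctr <- b[2:(L - 1)]
    l <- b[1:(L - 2)]
    r <- b[3:L]
    raw <- paste0(l, ctr, r)
    pur <- ctr %in% c("A", "G")
    folded <- raw
    folded[pur] <- paste0(complementBase(r[pur]), complementBase(ctr[pur]),
                          complementBase(l[pur]))
    data.frame(chrom = chroms[i], pos = 2:(L - 1), base = ctr,
               trinuc = raw, folded = folded, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  list(table = tab, index = split(seq_len(nrow(tab)), tab$folded),
       chars = lapply(seq_along(chroms), function(i)
         strsplit(as.character(ref$genome[[i]]), "", fixed = TRUE)[[1]]))
}

# Place n_genes non-overlapping single-exon genes (CDS length a multiple of
# 3) and assign the planted driver names under their placement constraints.
placeGenes <- function(ref, n_genes) {
  arms <- ref$arms
  chroms <- unique(arms$chrom)
  chromLen <- vapply(chroms, function(c)
    max(arms$end[arms$chrom == c]), numeric(1))
  perChrom <- rep(ceiling(n_genes / length(chroms)), length(chroms))
  rows <- list()
  k <- 0L
  for (i in seq_along(chroms)) {
    cursor <- 500L
    for (j in seq_len(perChrom[i])) {
      glen <- 3L * sample(100:300, 1L)
      gap <- sample(1500:4500, 1L)
      start <- cursor + gap
      end <- start + glen - 1L
      if (end > chromLen[i] - 500L) break
      k <- k + 1L
      rows[[k]] <- data.frame(gene = sprintf("GENE%03d", k),
                              chrom = chroms[i], start = start, end = end,
                              stringsAsFactors = FALSE)
      cursor <- end
    }
  }
  genes <- do.call(rbind, rows)
  # driver-name assignment: CDKN2A on chr9p, CCND1 on chr5, rest elsewhere
  pEnd9 <- arms$end[arms$chrom == "chr9" & grepl("p$", arms$arm)]
  cand9 <- which(genes$chrom == "chr9" & genes$end <= pEnd9)
  genes$gene[cand9[1L]] <- "CDKN2A"
  cand5 <- which(genes$chrom == "chr5" & genes$gene != "CDKN2A")
  genes$gene[cand5[1L]] <- "CCND1"
  others <- setdiff(SIM_DRIVER_GENES$gene, c("CDKN2A", "CCND1"))
  pool <- which(genes$chrom != "chr9" & !genes$gene %in% c("CCND1"))
  pick <- sample(pool, length(others))
  genes$gene[pick] <- others
  genes
}

# Deterministic per-gene planted driver variant: first position/alt giving
# the requested consequence when the gene interval is read as an in-frame
# + strand CDS.
findDriverVariant <- function(geneRow, chars, wanted) {
  chrIdx <- as.integer(sub("chr", "", geneRow$chrom))
  cds <- chars[[chrIdx]][geneRow$start:geneRow$end]
  for (p in seq_along(cds)) {
    for (alt in setdiff(c("A", "C", "G", "T"), cds[p])) {
      if (classifyCodonChange(cds, p, alt) == wanted) {
        return(data.frame(gene = geneRow$gene, chrom = geneRow$chrom,
                          pos = geneRow$start + p - 1L, ref = cds[p],
                          alt = alt, consequence = wanted,
                          stringsAsFactors = FALSE))
      }
    }
  }
  NULL
}

# Full prepared reference: genome, arms, genes, trinucleotide index and the
# planted driver variants + annotation table.
prepareSimReference <- function(cfg, seed) {
  ref <- simulateReference(cfg$genome_length, seed, cfg$n_chromosomes,
                           cfg$gc)
  withSeed(childSeed(seed, 1L), {
    idx <- indexReference(ref)
    ref$genes <- placeGenes(ref, cfg$n_genes)
    ref$ctx <- idx
    drv <- SIM_DRIVER_GENES[SIM_DRIVER_GENES$gene != "CCND1", ]
    vars <- lapply(seq_len(nrow(drv)), function(i) {
      g <- ref$genes[ref$genes$gene == drv$gene[i], ]
      wanted <- if (drv$role[i] == "oncogene") "missense" else "nonsense"
      findDriverVariant(g, idx$chars, wanted)
    })
    ref$driver_variants <- do.call(rbind, vars)
    key <- with(ref$driver_variants,
                paste0(gene, ":", chrom, ":", pos, ":", ref, ">", alt))
    roleOf <- stats::setNames(SIM_DRIVER_GENES$role, SIM_DRIVER_GENES$gene)
    ref$annotations <- data.frame(
      gene = ref$genes$gene,
      role = ifelse(ref$genes$gene %in% names(roleOf),
                    roleOf[ref$genes$gene], "none"),
      oncogenic_variants = "", cosmic_counts = "",
      stringsAsFactors = FALSE
    )
    onc <- ref$driver_variants$gene[
      roleOf[ref$driver_variants$gene] == "oncogene"]
    for (g in onc) {
      i <- which(ref$annotations$gene == g)
      k <- key[ref$driver_variants$gene == g]
      ref$annotations$oncogenic_variants[i] <- k
      ref$annotations$cosmic_counts[i] <- paste0(k, ":", 12L)
    }
    ref$exome_size_mb <- sum(ref$genes$end - ref$genes$start + 1) / 1e6
    ref
  })
}

# ---- copy-number archetypes -------------------------------------------------

# Split any segments overlapping [start, end] on chrom and overlay the focal
# major/minor there; keeps 1-based closed, non-overlapping segments.
overlaySegment <- function(segs, chrom, start, end, major, minor) {
  out <- list()
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    if (s$chrom != chrom || s$end < start || s$start > end) {
      out[[length(out) + 1L]] <- s
      next
    }
    if (s$start < start) {
      left <- s; left$end <- start - 1L
      out[[length(out) + 1L]] <- left
    }
    if (s$end > end) {
      right <- s; right$start <- end + 1L
      out[[length(out) + 1L]] <- right
    }
  }
  out[[length(out) + 1L]] <- data.frame(
    sample_id = segs$sample_id[1L], chrom = chrom, start = start, end = end,
    major = major, minor = minor, stringsAsFactors = FALSE)
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

simulateSegments <- function(archetype, sampleId, ref) {
  arms <- ref$arms
  segs <- data.frame(sample_id = sampleId, chrom = arms$chrom,
                     start = arms$start, end = arms$end,
                     major = 1L, minor = 1L, stringsAsFactors = FALSE)
  if (archetype == "AA_like") {
    for (i in seq_len(nrow(segs))) {
      u <- stats::runif(1)
      if (u < 0.15) { segs$major[i] <- 2L; segs$minor[i] <- 0L }
      else if (u < 0.20) { segs$major[i] <- 2L; segs$minor[i] <- 1L }
    }
  } else if (archetype == "FGFR3_chr9del") {
    nine <- segs$chrom == "chr9"
    segs$major[nine] <- 1L; segs$minor[nine] <- 0L
    if (stats::runif(1) < 0.2) {
      i <- sample(which(!nine), 1L)
      segs$major[i] <- 1L; segs$minor[i] <- 0L
    }
    if (stats::runif(1) < 0.6) {
      g <- ref$genes[ref$genes$gene == "CDKN2A", ]
      segs <- overlaySegment(segs, g$chrom, max(1L, g$start - 200L),
                             g$end + 200L, 0L, 0L)
    }
  } else if (archetype == "GI") {
    segs$major <- 2L; segs$minor <- 2L
    states <- rbind(c(2L, 1L), c(3L, 2L), c(2L, 0L), c(3L, 1L), c(4L, 2L))
    for (i in seq_len(nrow(segs))) {
      if (stats::runif(1) < 0.5) {
        st <- states[sample(nrow(states), 1L), ]
        segs$major[i] <- st[1L]; segs$minor[i] <- st[2L]
      }
    }
    for (ampGene in c("CCND1", "E2F3")) {
      if (stats::runif(1) < 0.5) {
        g <- ref$genes[ref$genes$gene == ampGene, ]
        segs <- overlaySegment(segs, g$chrom, max(1L, g$start - 500L),
                               g$end + 500L, 8L, 3L)
      }
    }
    if (stats::runif(1) < 0.4) {
      g <- ref$genes[ref$genes$gene == "RB1", ]
      segs <- overlaySegment(segs, g$chrom, max(1L, g$start - 300L),
                             g$end + 300L, 0L, 0L)
    }
  }
  segs
}

# ---- per-sample mutation generation ----------------------------------------

channelParts <- function(channels) {
  data.frame(
    five = substr(channels, 1L, 1L),
    ref = substr(channels, 3L, 3L),
    alt = substr(channels, 5L, 5L),
    three = substr(channels, 7L, 7L),
    stringsAsFactors = FALSE
  )
}

geneAt <- function(chrom, pos, genes) {
  out <- rep(NA_character_, length(pos))
  for (c in unique(chrom)) {
    gi <- genes[genes$chrom == c, ]
    if (!nrow(gi)) next
    gi <- gi[order(gi$start), ]
    mi <- which(chrom == c)
    j <- findInterval(pos[mi], gi$start)
    hit <- j >= 1L & pos[mi] <= gi$end[pmax(j, 1L)]
    out[mi[hit]] <- gi$gene[j[hit]]
  }
  out
}

# consequence of an in-gene SNV when the gene is read as +-strand CDS
snvConsequence <- function(chrom, pos, alt, genes, chars) {
  gene <- geneAt(chrom, pos, genes)
  out <- rep("other", length(pos))
  idx <- which(!is.na(gene))
  for (i in idx) {
    g <- genes[genes$gene == gene[i], ]
    chrIdx <- as.integer(sub("chr", "", g$chrom))
    cds <- chars[[chrIdx]][g$start:g$end]
    out[i] <- classifyCodonChange(cds, pos[i] - g$start + 1L, alt[i])
  }
  list(gene = ifelse(is.na(gene), "", gene), consequence = out)
}

#' Simulate one sample
#'
#' Generates mutations, allele-specific segments, the sample profile and the
#' per-mutation truth table for one archetype. Read counts are binomial
#' around the expected VAF `m * rho * CCF / (rho * CNt + 2 (1 - rho))`,
#' trinucleotide contexts are drawn from the archetype's signature mixture
#' against the toy reference, and the copy-number archetype is realized as
#' arm-level segments (plus the planted focal events).
#'
#' @param archetype one of `"AA_like"`, `"FGFR3_HRAS"`, `"FGFR3_chr9del"`,
#'   `"GI"`.
#' @param config a [simulationConfig()].
#' @param seed RNG seed.
#' @param reference prepared reference (internal; built from
#'   `childSeed(seed, 0)` when omitted).
#' @param sampleId sample name.
#' @return list with `mutations`, `segments`, `profile`, `truth`.
#' @export
simulateSample <- function(archetype, config, seed, reference = NULL,
                           sampleId = "S1") {
  archetype <- match.arg(archetype, ARCHETYPES)
  config <- validateSimConfig(unclass(config))
  if (is.null(reference))
    reference <- prepareSimReference(config, childSeed(seed, 0L))
  catalog <- config$catalog %||%
    readSignatureCatalog(syntheticCatalogPath())
  withSeed(seed, {
    purity <- stats::runif(1, config$purity_range[1], config$purity_range[2])
    segs <- simulateSegments(archetype, sampleId, reference)
    segs$cnt <- segs$major + segs$minor
    ploidy <- sum(segs$cnt * (segs$end - segs$start + 1)) /
      sum(segs$end - segs$start + 1)
    subCcf <- stats::runif(1, config$subclone_ccf_range[1],
                           config$subclone_ccf_range[2])
    nMut <- stats::rpois(1, config$burden[[archetype]])
    sigw <- config$signature_weights[archetype, colnames(catalog)]

    muts <- truth <- NULL
    if (nMut > 0) {
      sig <- sample(colnames(catalog), nMut, replace = TRUE, prob = sigw)
      chanIdx <- integer(nMut)
      for (s in unique(sig)) {
        ii <- which(sig == s)
        chanIdx[ii] <- sample.int(96L, length(ii), replace = TRUE,
                                  prob = catalog[, s])
      }
      parts <- channelParts(sbsChannels()[chanIdx])
      ctx <- paste0(parts$five, parts$ref, parts$three)
      rows <- integer(nMut)
      for (cx in unique(ctx)) {
        ii <- which(ctx == cx)
        pool <- reference$ctx$index[[cx]]
        rows[ii] <- sample(pool, length(ii), replace = TRUE)
      }
      tab <- reference$ctx$table[rows, ]
      pyr <- tab$base %in% c("C", "T")
      refb <- tab$base
      altb <- ifelse(pyr, parts$alt, complementBase(parts$alt))
      keep <- !duplicated(paste(tab$chrom, tab$pos))
      df <- data.frame(sample_id = sampleId, chrom = tab$chrom,
                       pos = tab$pos, ref = refb, alt = altb,
                       context3 = tab$trinuc, signature = sig,
                       stringsAsFactors = FALSE)[keep, ]
      segRow <- locateSegment(df, segs)
      cnt <- segs$cnt[segRow]
      major <- segs$major[segRow]
      ok <- !is.na(cnt) & cnt > 0
      df <- df[ok, ]; cnt <- cnt[ok]; major <- major[ok]
      n <- nrow(df)
      subclonal <- stats::runif(n) < config$subclone_fraction
      ccf <- ifelse(subclonal, subCcf, 1)
      m <- rep(1L, n)
      amp <- !subclonal & major >= 2L
      mk <- amp & stats::runif(n) < config$early_multiplicity_prob
      m[mk] <- major[mk]
      vaf <- m * purity * ccf / (purity * cnt + 2 * (1 - purity))
      depth <- pmax(stats::rnbinom(n, mu = config$depth_mean,
                                   size = config$depth_size),
                    config$min_depth)
      tAlt <- stats::rbinom(n, depth, vaf)
      det <- tAlt >= 1L
      df <- df[det, ]; m <- m[det]; ccf <- ccf[det]
      subclonal <- subclonal[det]; major <- major[det]
      depth <- depth[det]; tAlt <- tAlt[det]
      cons <- snvConsequence(df$chrom, df$pos, df$alt, reference$genes,
                             reference$ctx$chars)
      df$gene <- cons$gene
      df$consequence <- cons$consequence
      df$t_alt <- tAlt
      df$t_ref <- depth - tAlt
      mis <- df$consequence == "missense"
      for (p in c("sift", "polyphen", "mutationtaster")) {
        df[[p]] <- ""
        df[[p]][mis] <- sample(c("deleterious", "tolerated", "missing"),
                               sum(mis), replace = TRUE,
                               prob = c(0.15, 0.70, 0.15))
      }
      timing <- ifelse(subclonal, "late",
                       ifelse(major >= 2L, ifelse(m > 1L, "early", "late"),
                              "early"))
      truth <- data.frame(
        sample_id = sampleId,
        mut_id = paste0(sampleId, ":", df$chrom, ":", df$pos, ":",
                        df$ref, ">", df$alt),
        ccf = ccf,
        clonality = ifelse(subclonal, "subclonal", "clonal"),
        multiplicity = m, signature = df$signature, timing = timing,
        is_driver = FALSE, stringsAsFactors = FALSE)
      df$signature <- NULL
      muts <- df
    }

    # planted drivers
    plan <- simDriverPlan()[[archetype]]
    dv <- reference$driver_variants
    for (g in names(plan)) {
      if (stats::runif(1) >= plan[[g]]) next
      v <- dv[dv$gene == g, ]
      if (!nrow(v)) next
      if (!is.null(muts) &&
          any(muts$chrom == v$chrom & muts$pos == v$pos)) next
      segRow <- locateSegment(
        data.frame(sample_id = sampleId, chrom = v$chrom, pos = v$pos), segs)
      if (is.na(segRow)) next
      cnt <- segs$cnt[segRow]; major <- segs$major[segRow]
      if (cnt == 0) next
      m <- if (major >= 2L && stats::runif(1) < 0.7) major else 1L
      vaf <- m * purity / (purity * cnt + 2 * (1 - purity))
      depth <- max(stats::rnbinom(1, mu = config$depth_mean,
                                  size = config$depth_size),
                   config$min_depth)
      tAlt <- max(1L, stats::rbinom(1, depth, vaf))
      chrIdx <- as.integer(sub("chr", "", v$chrom))
      b <- reference$ctx$chars[[chrIdx]]
      ctx3 <- paste0(b[v$pos - 1L], b[v$pos], b[v$pos + 1L])
      row <- data.frame(sample_id = sampleId, chrom = v$chrom, pos = v$pos,
                        ref = v$ref, alt = v$alt, context3 = ctx3,
                        gene = g, consequence = v$consequence,
                        t_alt = tAlt, t_ref = depth - tAlt,
                        sift = "", polyphen = "", mutationtaster = "",
                        stringsAsFactors = FALSE)
      muts <- rbind(muts, row)
      truth <- rbind(truth, data.frame(
        sample_id = sampleId,
        mut_id = paste0(sampleId, ":", v$chrom, ":", v$pos, ":",
                        v$ref, ">", v$alt),
        ccf = 1, clonality = "clonal", multiplicity = m,
        signature = "driver",
        timing = if (major >= 2L) ifelse(m > 1L, "early", "late") else
          "early",
        is_driver = TRUE, stringsAsFactors = FALSE))
    }
    if (is.null(muts)) {
      muts <- data.frame(sample_id = character(0), chrom = character(0),
                         pos = numeric(0), ref = character(0),
                         alt = character(0), context3 = character(0),
                         gene = character(0), consequence = character(0),
                         t_alt = numeric(0), t_ref = numeric(0),
                         sift = character(0), polyphen = character(0),
                         mutationtaster = character(0),
                         stringsAsFactors = FALSE)
      truth <- data.frame(sample_id = character(0), mut_id = character(0),
                          ccf = numeric(0), clonality = character(0),
                          multiplicity = integer(0), signature = character(0),
                          timing = character(0), is_driver = logical(0),
                          stringsAsFactors = FALSE)
    }
    rownames(muts) <- rownames(truth) <- NULL
    gl <- segs$end - segs$start + 1
    profile <- data.frame(
      sample_id = sampleId, purity = purity, ploidy = ploidy,
      exome_size_mb = reference$exome_size_mb, stringsAsFactors = FALSE)
    truthSample <- data.frame(
      sample_id = sampleId, archetype = archetype,
      wgd = sum(gl[segs$major >= 2]) / sum(gl) >= 0.5,
      wgii = sum(gl[segs$cnt != round(ploidy)]) / sum(gl),
      subclone_ccf = subCcf, purity = purity, ploidy = ploidy,
      stringsAsFactors = FALSE)
    list(mutations = muts, segments = segs[, c("sample_id", "chrom",
                                               "start", "end", "major",
                                               "minor")],
         profile = profile,
         truth = list(mutations = truth, sample = truthSample))
  })
}

# ---- expression + clinical --------------------------------------------------

simulateExpression <- function(archetypes, cfg, seed) {
  panels <- readPanelDefinitions(panelDefinitionsPath())
  withSeed(seed, {
    degGenes <- unlist(lapply(ARCHETYPES, function(a)
      sprintf("DEG_%s_%02d", a, seq_len(cfg$expression$n_de))))
    filler <- sprintf("FILLER%03d", seq_len(cfg$expression$n_filler))
    genes <- unique(c(panels$gene, degGenes, filler, "APOBEC3B"))
    mu <- stats::setNames(stats::rlnorm(length(genes), log(150), 0.7), genes)
    basal <- panels$gene[panels$panel == "basal"]
    luminal <- panels$gene[panels$panel == "luminal"]
    mu[intersect(basal, genes)] <- mu[intersect(basal, genes)] * 0.4
    mu[intersect(luminal, genes)] <- mu[intersect(luminal, genes)] * 2
    n <- length(archetypes)
    fold <- matrix(1, length(genes), n, dimnames = list(genes, NULL))
    aaGi <- archetypes %in% c("AA_like", "GI")
    up <- function(set, cols, f) {
      set <- intersect(set, genes)
      fold[set, cols] <<- fold[set, cols] * f
    }
    for (a in ARCHETYPES)
      up(sprintf("DEG_%s_%02d", a, seq_len(cfg$expression$n_de)),
         archetypes == a, cfg$expression$fold)
    pf <- cfg$expression$panel_fold
    for (p in c("p53", "stroma", "inflammation", "claudin_low",
                "bcg_response"))
      up(panels$gene[panels$panel == p], aaGi, pf)
    for (p in c("immune_checkpoint", "interferon"))
      up(panels$gene[panels$panel == p], archetypes == "AA_like", pf)
    up("APOBEC3B", archetypes == "FGFR3_chr9del", 1.6)
    up("APOBEC3B", archetypes == "GI", 2.5)
    counts <- matrix(stats::rnbinom(length(genes) * n,
                                    mu = as.vector(fold * mu),
                                    size = cfg$expression$nb_size),
                     length(genes), n, dimnames = list(genes, NULL))
    counts
  })
}

simulateClinical <- function(samples, archetypes, cinTruth, cfg, seed) {
  sv <- cfg$survival
  withSeed(seed, {
    n <- length(samples)
    hi <- archetypes %in% c("AA_like", "GI")
    stage <- ifelse(hi,
                    sample(c("Ta", "T1", "Tis"), n, TRUE, c(0.4, 0.55, 0.05)),
                    sample(c("Ta", "T1"), n, TRUE, c(0.8, 0.2)))
    grade <- ifelse(hi,
                    sample(c("HG", "LG", "PUNLMP"), n, TRUE,
                           c(0.7, 0.25, 0.05)),
                    sample(c("HG", "LG", "PUNLMP"), n, TRUE,
                           c(0.3, 0.55, 0.15)))
    therapy <- sample(c("chemo", "BCG", "none"), n, TRUE,
                      c(0.7, 0.17, 0.13))
    hazard <- sv$base_rate *
      exp(sv$log_hr_cin * cinTruth +
            sv$log_hr_subtype[archetypes])
    t <- stats::rexp(n, rate = hazard)
    cens <- stats::runif(n, sv$censor_range[1], sv$censor_range[2])
    event <- as.integer(t <= cens)
    rfs <- round(pmax(pmin(t, cens), 0.1), 2)
    data.frame(sample_id = samples, stage = stage, grade = grade,
               therapy = therapy, rfs_months = rfs, event = event,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a full cohort with ground truth
#'
#' Draws `n_per_archetype` samples per archetype, assembles them into an
#' [NmibcCohort] (with expression counts and covariate-linked recurrence
#' outcomes) and returns the truth tables the generator used. Identical
#' seeds give identical cohorts.
#'
#' @param config a [simulationConfig()]; `config$seed` is mandatory.
#' @return list with `cohort` ([NmibcCohort]), `truth` (list of `mutations`,
#'   `samples`, `exposures` data.frames), `reference` (prepared toy
#'   reference) and `config`.
#' @export
simulateCohort <- function(config = simulationConfig()) {
  config <- validateSimConfig(unclass(config))
  if (is.null(config$seed))
    stop("config$seed is mandatory", call. = FALSE)
  seed <- config$seed
  nPer <- config$n_per_archetype
  if (sum(nPer > 0) >= 2 && any(nPer[nPer > 0] < 4))
    warning("fewer than 4 samples in an archetype; subtyping tests may be ",
            "underpowered", call. = FALSE)
  ref <- prepareSimReference(config, childSeed(seed, 0L))
  archetypes <- rep(names(nPer), nPer)
  samples <- sprintf("S%02d", seq_along(archetypes))
  res <- lapply(seq_along(samples), function(i)
    simulateSample(archetypes[i], config, childSeed(seed, 10L + i), ref,
                   samples[i]))
  mutations <- do.call(rbind, lapply(res, `[[`, "mutations"))
  segments <- do.call(rbind, lapply(res, `[[`, "segments"))
  profilesDf <- do.call(rbind, lapply(res, `[[`, "profile"))
  truthMut <- do.call(rbind, lapply(res, function(r) r$truth$mutations))
  truthSample <- do.call(rbind, lapply(res, function(r) r$truth$sample))
  rownames(mutations) <- rownames(segments) <- NULL
  rownames(profilesDf) <- rownames(truthMut) <- rownames(truthSample) <- NULL
  clin <- simulateClinical(samples, archetypes,
                           as.numeric(truthSample$wgii > 0.2), config,
                           childSeed(seed, 2L))
  expr <- if (isTRUE(config$with_expression)) {
    e <- simulateExpression(archetypes, config, childSeed(seed, 3L))
    colnames(e) <- samples
    e
  } else NULL
  cohort <- assembleCohort(mutations, segments, profilesDf, clin,
                           ref$annotations, expr)
  expos <- table(factor(truthMut$sample_id, levels = samples),
                 truthMut$signature)
  truth <- list(mutations = truthMut, samples = truthSample,
                exposures = as.data.frame.matrix(expos),
                genes = ref$driver_variants)
  list(cohort = cohort, truth = truth, reference = ref, config = config)
}

#' Write a simulated cohort to disk
#'
#' Emits exactly the TSV/FASTA formats the package readers consume: cohort
#' tables via [writeCohortTables()], the toy genome as FASTA, the arm table
#' and truth tables as TSV.
#'
#' @param sim result of [simulateCohort()].
#' @param dir output directory.
#' @return character vector of files written, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- writeCohortTables(sim$cohort, dir)
  fa <- file.path(dir, "reference.fasta")
  Biostrings::writeXStringSet(sim$reference$genome, fa)
  writeTsv(sim$reference$arms, file.path(dir, "arms.tsv"))
  writeTsv(sim$reference$genes, file.path(dir, "genes.tsv"))
  writeTsv(sim$truth$mutations, file.path(dir, "truth_mutations.tsv"))
  writeTsv(sim$truth$samples, file.path(dir, "truth_samples.tsv"))
  invisible(c(paths, fa))
}
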