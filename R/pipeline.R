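# End-to-end orchestration. A single config (list or YAML file) drives the
# stages in dependency order: io -> drivers/timing/instability/signatures ->
# selection/cna -> dependency -> subtyping -> expression/clinical/pathways.
# Every random stage takes an explicit seed derived from config$seed; a
# re-run with the same config and seed is bit-identical. Stage outputs are
# written as TSV under outdir and a manifest JSON records versions, seeds,
# thresholds and input checksums.

#' Pipeline configuration
#'
#' Defaults carry the published thresholds: CNA amplitude 0.25 and broad
#' cutoff 0.75, wGII CIN threshold 0.2, the 10% event-frequency filter, the
#' signature presence rule (>= 10 mutations and >= 5%), and q < 0.1
#' significance. Unknown keys are rejected.
#'
#' @param ... named overrides of the defaults.
#' @return list of class `nmibc_pipeline_config`.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    input = list(mutations = NULL, segments = NULL, profiles = NULL,
                 clinical = NULL, annotations = NULL, expression = NULL,
                 reference_fasta = NULL, arms = NULL, genes = NULL,
                 catalog = NULL),
    simulate = NULL,
    stages = c("drivers", "timing", "instability", "signatures",
               "selection", "cna", "dependency", "subtype", "expression",
               "clinical", "pathways"),
    thresholds = list(cna_amplitude = 0.25, broad_cutoff = 0.75,
                      wgii_cin = 0.2, event_min_freq = 0.10,
                      presence_min_mutations = 10,
                      presence_min_fraction = 0.05, q_cutoff = 0.1),
    n_perm = list(recurrence = 300, pairs = 1000, early = 500),
    nmf = list(k_range = 2:6, restarts = 20),
    denovo = FALSE,
    seed = 1,
    outdir = NULL
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (k in names(over)) {
    if (is.list(cfg[[k]]) && is.list(over[[k]])) {
      badSub <- setdiff(names(over[[k]]), names(cfg[[k]]))
      if (length(badSub))
        stop("unknown config key(s): ",
             paste(paste0(k, "$", badSub), collapse = ", "), call. = FALSE)
      cfg[[k]][names(over[[k]])] <- over[[k]]
    } else cfg[[k]] <- over[[k]]
  }
  class(cfg) <- "nmibc_pipeline_config"
  cfg
}

#' Read a pipeline config from a YAML file
#'
#' @param path YAML file with top-level keys matching [pipelineConfig()].
#' @return validated config.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, y)
}

loadPipelineInputs <- function(cfg) {
  inp <- cfg$input
  need <- c("mutations", "segments", "profiles")
  miss <- need[vapply(inp[need], is.null, logical(1))]
  if (length(miss))
    stop("config validation: missing input path(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if ("timing" %in% cfg$stages && is.null(inp$segments))
    stop("config validation: timing enabled but no segments path",
         call. = FALSE)
  expr <- NULL
  if (!is.null(inp$expression)) {
    ex <- readTsv(inp$expression)
    expr <- as.matrix(ex[, -1, drop = FALSE])
    rownames(expr) <- ex[[1]]
  }
  cohort <- assembleCohort(
    readMutationTable(inp$mutations),
    readSegmentTable(inp$segments),
    readPurityTable(inp$profiles),
    if (!is.null(inp$clinical)) readClinicalTable(inp$clinical),
    if (!is.null(inp$annotations)) readGeneAnnotation(inp$annotations),
    expr)
  genome <- if (!is.null(inp$reference_fasta))
    Biostrings::readDNAStringSet(inp$reference_fasta) else NULL
  if (!is.null(genome)) names(genome) <- sub("\\s.*$", "", names(genome))
  arms <- if (!is.null(inp$arms)) readTsv(inp$arms) else NULL
  genes <- if (!is.null(inp$genes)) readTsv(inp$genes) else NULL
  catalog <- if (!is.null(inp$catalog)) readSignatureCatalog(inp$catalog)
  else readSignatureCatalog(syntheticCatalogPath())
  list(cohort = cohort, genome = genome, arms = arms, genes = genes,
       catalog = catalog)
}

#' Run the full pipeline
#'
#' Executes the configured stages in dependency order on either a simulated
#' cohort (`config$simulate` = overrides for [simulationConfig()]) or tables
#' read from `config$input`. Results are returned as a named list and, when
#' `config$outdir` is set, written as TSV plus a `manifest.json` recording
#' package version, seeds, thresholds, stage order and output checksums.
#' A stage failure aborts with the stage name; outputs of completed stages
#' are preserved on disk.
#'
#' @param config a [pipelineConfig()], or path to a YAML file.
#' @return named list of stage results (invisibly when writing to outdir).
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "nmibc_pipeline_config"))
  seed <- config$seed
  th <- config$thresholds
  res <- list(config = config)

  if (!is.null(config$simulate)) {
    simCfg <- do.call(simulationConfig, config$simulate)
    if (is.null(simCfg$seed)) simCfg$seed <- childSeed(seed, 1000L)
    sim <- simulateCohort(simCfg)
    cohort <- sim$cohort
    genome <- sim$reference$genome
    arms <- sim$reference$arms
    genes <- sim$reference$genes
    catalog <- readSignatureCatalog(syntheticCatalogPath())
    res$truth <- sim$truth
  } else {
    inp <- loadPipelineInputs(config)
    cohort <- inp$cohort; genome <- inp$genome; arms <- inp$arms
    genes <- inp$genes; catalog <- inp$catalog
  }
  res$cohort <- cohort
  samples <- sampleIds(cohort)

  stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- Sys.time()
    out <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("stage %-12s %.2fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    out
  }

  res$drivers <- stage("drivers", function()
    buildDriverCatalog(cohort))
  res$timing <- stage("timing", function() {
    tm <- timeMutations(cohort)
    enr <- earlyEnrichmentTest(tm, n_perm = config$n_perm$early,
                               seed = childSeed(seed, 2L))
    list(calls = tm, early_enrichment = enr)
  })
  res$instability <- stage("instability", function() {
    if (is.null(arms)) stop("arm table required")
    instabilityProfiles(cohort, arms)
  })
  res$signatures <- stage("signatures", function() {
    sp <- cohortSpectra(cohort, "all", genome = genome)
    fits <- fitCohortExposures(
      sp, catalog, min_mutations = th$presence_min_mutations,
      min_fraction = th$presence_min_fraction)
    out <- list(spectra = sp, exposures = fits)
    if (!is.null(res$timing)) {
      for (st in c("early", "late")) {
        spS <- cohortSpectra(cohort, st, timing = res$timing$calls,
                             genome = genome)
        out[[paste0("exposures_", st)]] <- fitCohortExposures(
          spS, catalog, min_mutations = th$presence_min_mutations,
          min_fraction = th$presence_min_fraction)
      }
    }
    if (!is.null(genome))
      out$apobec <- apobecEnrichment(cohort, genome)
    if (isTRUE(config$denovo) && length(samples) >= 10)
      out$denovo <- extractDenovoNMF(sp, catalog,
                                     restarts = config$nmf$restarts,
                                     seed = childSeed(seed, 3L))
    out
  })
  res$selection <- stage("selection", function() {
    if (is.null(genes) || is.null(genome))
      stop("gene models and reference required")
    muts <- mutations(cohort)
    all <- dndsTable(muts, genes, genome)
    out <- list(all = all)
    if (!is.null(res$timing)) {
      tm <- res$timing$calls
      mid <- paste0(muts$sample_id, ":", muts$chrom, ":", muts$pos, ":",
                    muts$ref, ">", muts$alt)
      for (st in c("early", "late")) {
        out[[st]] <- dndsTable(muts[mid %in% tm$mut_id[tm$timing == st], ,
                                    drop = FALSE],
                               genes, genome, rates = all$rates,
                               opportunities = all$opportunities)
      }
      pg <- function(x, cl) x$per_gene[x$per_gene$class == cl, ]
      e <- pg(out$early, "point-combined"); l <- pg(out$late,
                                                    "point-combined")
      ors <- do.call(rbind, lapply(seq_len(nrow(e)), function(i) {
        cbind(gene = e$gene[i],
              timingOddsRatio(e[i, ], l[l$gene == e$gene[i], ]))
      }))
      qe <- stats::setNames(e$q, e$gene)
      ql <- stats::setNames(l$q, l$gene)
      ors$reported <- !is.na(qe[ors$gene]) & (
        pmin(qe[ors$gene], ql[ors$gene], na.rm = TRUE) < th$q_cutoff)
      out$timing_or <- ors
    }
    out$pathways <- pathwayDnds(readPathwayDefinitions(), muts, genes,
                                genome, rates = all$rates)
    out
  })
  res$cna <- stage("cna", function() {
    if (is.null(arms)) stop("arm table required")
    ev <- cohortCnaEvents(cohort, arms, threshold = th$cna_amplitude,
                          broad_cutoff = th$broad_cutoff)
    rec <- recurrenceSignificance(ev, arms, samples,
                                  n_perm = config$n_perm$recurrence,
                                  seed = childSeed(seed, 4L))
    loci <- significantCnaLoci(rec, arms, q_cutoff = th$q_cutoff,
                               broad_cutoff = th$broad_cutoff)
    list(events = ev, recurrence = rec, loci = loci,
         chr9_codeletion = chr9CodeletionFlag(ev, samples))
  })

  eventFeatures <- function() {
    feats <- list()
    if (!is.null(res$drivers))
      feats$mut <- driverFlagMatrix(res$drivers$calls, samples) |>
        (\(m) { colnames(m) <- paste0("MUT_", colnames(m)); m })()
    if (!is.null(res$cna))
      feats$cna <- cnaEventMatrix(res$cna$events, res$cna$loci, samples)
    if (!is.null(res$signatures)) {
      pres <- res$signatures$exposures$present
      colnames(pres) <- paste0("SIG_", colnames(pres))
      feats$sig <- pres
    }
    if (!is.null(res$instability)) {
      fl <- cbind(wGD = res$instability$wgd,
                  CIN = res$instability$cin,
                  HYPERMUT = res$instability$hypermutated)
      rownames(fl) <- res$instability$sample_id
      fl <- fl[samples, , drop = FALSE]
      if (!is.null(res$signatures$apobec)) {
        ap <- res$signatures$apobec
        fl <- cbind(fl, APOBEC = (ap$group[match(samples, ap$sample_id)]
                                  != "none"))
      }
      feats$flags <- fl
    }
    feats
  }

  res$dependency <- stage("dependency", function() {
    m <- assembleEventMatrix(eventFeatures(),
                             min_freq = th$event_min_freq)
    pairs <- testEventPairs(m, n_perm = config$n_perm$pairs,
                            seed = childSeed(seed, 5L))
    out <- list(matrix = m, pairs = pairs)
    if (!is.null(res$timing) && !is.null(res$signatures$exposures_early)) {
      mkStrat <- function(st) {
        tm <- res$timing$calls
        drvKeys <- res$drivers$calls$variant_key[res$drivers$calls$is_driver]
        sel <- tm$timing == st &
          paste0(tm$gene, ":", sub("^[^:]+:", "", tm$mut_id)) %in% drvKeys
        genesSt <- unique(tm$gene[sel])
        mm <- matrix(FALSE, length(samples), length(genesSt),
                     dimnames = list(samples,
                                     paste0("MUT_", genesSt)))
        if (length(genesSt))
          for (g in genesSt)
            mm[unique(tm$sample_id[sel & tm$gene == g]), paste0("MUT_", g)] <-
              TRUE
        pres <- res$signatures[[paste0("exposures_", st)]]$present
        colnames(pres) <- paste0("SIG_", colnames(pres))
        cbind(mm, pres[samples, , drop = FALSE])
      }
      out$ordering <- orderingInteractions(mkStrat("early"),
                                           mkStrat("late"))
    }
    out
  })
  res$subtype <- stage("subtype", function() {
    if (is.null(res$dependency)) stop("dependency stage required")
    m <- buildSubtypingMatrix(res$dependency$matrix)
    model <- fitSubtypes(m, k_range = config$nmf$k_range,
                         restarts = config$nmf$restarts,
                         seed = childSeed(seed, 6L))
    tmb <- NULL
    if (!is.null(res$instability))
      tmb <- stats::setNames(res$instability$tmb,
                             res$instability$sample_id)
    ch <- characterizeSubtypes(model, m, tmb = tmb)
    model@enrichment <- ch$enrichment
    list(model = model, matrix = m, tmb_p = ch$tmb_p)
  })
  res$expression <- stage("expression", function() {
    expr <- exprCounts(cohort)
    if (!length(expr)) return(NULL)
    out <- list()
    labs <- if (!is.null(res$subtype))
      subtypeLabels(res$subtype$model)[colnames(expr)] else NULL
    if (!is.null(labs)) {
      sets <- rankSubtypeGenes(expr, labs)
      out$subtype_sets <- sets
      out$subtype_scores <- lapply(sets, function(s) {
        zero <- stats::setNames(rep(0, ncol(expr)), colnames(expr))
        up <- if (length(s$up)) geneSetScore(expr, s$up) else zero
        down <- if (length(s$down)) geneSetScore(expr, s$down) else zero
        subtypeScore(up, down)
      })
    }
    out$panels <- panelScores(expr, groups = labs)
    out
  })
  res$clinical <- stage("clinical", function() {
    out <- list()
    counts <- readTsv(cohortCountsPath())
    out$cohort_comparison <- fisherCohortTable(counts)
    clin <- clinical(cohort)
    if (nrow(clin) && !is.null(res$instability)) {
      covs <- data.frame(
        cin = as.numeric(res$instability$cin[
          match(clin$sample_id, res$instability$sample_id)]),
        stage = factor(clin$stage))
      out$survival <- tryCatch(survivalModels(clin, covs),
                               error = function(e) NULL)
    }
    out
  })
  res$pathways <- stage("pathways", function() {
    if (is.null(res$drivers) || is.null(genes)) return(NULL)
    cnaG <- mapCnaToGenes(cohort, genes)
    labs <- if (!is.null(res$subtype))
      unname(subtypeLabels(res$subtype$model)[samples]) else NULL
    pathwayAlterationFraction(res$drivers$calls, cnaG,
                              readPathwayDefinitions(), samples,
                              known_genes = genes$gene, labels = labs)
  })

  if (!is.null(config$outdir)) writePipelineOutputs(res, config$outdir)
  invisible(res)
}

writePipelineOutputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(x, name) {
    if (is.null(x)) return(NULL)
    writeTsv(x, file.path(outdir, paste0(name, ".tsv")))
  }
  if (!is.null(res$drivers)) {
    emit(res$drivers$calls, "driver_calls")
    emit(res$drivers$catalog, "driver_catalog")
  }
  if (!is.null(res$timing)) {
    emit(res$timing$calls, "timing_calls")
    emit(res$timing$early_enrichment, "early_enrichment")
  }
  emit(res$instability, "instability")
  if (!is.null(res$signatures)) {
    sp <- as.data.frame(res$signatures$spectra)
    sp <- cbind(channel = rownames(res$signatures$spectra), sp)
    emit(sp, "spectra")
    ex <- as.data.frame(res$signatures$exposures$counts)
    emit(cbind(sample_id = rownames(ex), ex), "exposures")
    emit(res$signatures$apobec, "apobec")
  }
  if (!is.null(res$selection)) {
    emit(res$selection$all$per_gene, "dnds_per_gene")
    emit(res$selection$all$global, "dnds_global")
    emit(res$selection$timing_or, "dnds_timing_or")
    emit(res$selection$pathways, "dnds_pathways")
  }
  if (!is.null(res$cna)) {
    emit(res$cna$events, "cna_events")
    emit(res$cna$loci, "cna_loci")
  }
  if (!is.null(res$dependency)) {
    m <- as.data.frame(res$dependency$matrix)
    emit(cbind(sample_id = rownames(res$dependency$matrix), m),
         "event_matrix")
    emit(res$dependency$pairs, "dependency_pairs")
    emit(res$dependency$ordering, "ordering_interactions")
  }
  if (!is.null(res$subtype)) {
    emit(data.frame(sample_id = names(subtypeLabels(res$subtype$model)),
                    subtype = subtypeLabels(res$subtype$model)),
         "subtype_labels")
    emit(subtypeEnrichment(res$subtype$model), "subtype_enrichment")
  }
  if (!is.null(res$clinical$cohort_comparison))
    emit(res$clinical$cohort_comparison, "cohort_comparison")
  if (!is.null(res$pathways)) emit(res$pathways$fractions,
                                   "pathway_fractions")
  files <- list.files(outdir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package = "nmibcGenomics",
    version = as.character(utils::packageVersion("nmibcGenomics")),
    seed = res$config$seed,
    thresholds = res$config$thresholds,
    stages = res$config$stages,
    checksums = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}
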