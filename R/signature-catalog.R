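# SBS signature catalogs: reader for 96 x K probability tables (COSMIC-style
# TSVs are accepted) and the bundled synthetic 4-signature catalog used by the
# simulator and the examples. The bundled catalog is NOT COSMIC: it is a
# synthetic stand-in whose four columns imitate the channel concentrations of
# APOBEC C>T (SBS2-like), flat/aging (SBS5-like), APOBEC C>G (SBS13-like) and
# aristolochic-acid T>A (SBS22-like) processes.

#' Read a mutational-signature catalog
#'
#' Expects a TSV with a channel column (96 pyrimidine-centred trinucleotide
#' channels, any order; header `channel`, `Type`, `MutationType` or first
#' column) and one column per signature. Columns are renormalized to sum to 1
#' and rows are reordered into the package channel order ([sbsChannels()]).
#'
#' @param path path to the TSV file.
#' @return numeric matrix, 96 rows (named by channel) x K signature columns.
#' @export
readSignatureCatalog <- function(path) {
  df <- readTsv(path)
  chanCol <- intersect(c("channel", "Type", "MutationType"), names(df))
  chanCol <- if (length(chanCol)) chanCol[1L] else names(df)[1L]
  chan <- as.character(df[[chanCol]])
  if (!setequal(chan, sbsChannels()) || anyDuplicated(chan))
    stop("catalog must contain exactly the 96 SBS channels", call. = FALSE)
  m <- as.matrix(df[, setdiff(names(df), chanCol), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- chan
  m <- m[sbsChannels(), , drop = FALSE]
  if (any(m < 0) || any(colSums(m) <= 0))
    stop("signature columns must be non-negative with positive sum",
         call. = FALSE)
  sweep(m, 2L, colSums(m), "/")
}

#' Bundled synthetic signature catalog
#'
#' Builds the package's synthetic 4-signature catalog in code. The shipped
#' fixture `inst/extdata/signature_catalog_synthetic.tsv` is this matrix
#' written as TSV. Channel concentrations:
#' * `SBS2s`  - C>T concentrated at tCw (T\[C>T\]A, T\[C>T\]T);
#' * `SBS5s`  - broad, mildly elevated T>C and C>T (clock-like);
#' * `SBS13s` - C>G concentrated at tCw;
#' * `SBS22s` - T>A concentrated at cTg-type contexts.
#'
#' These are stand-ins so that no external (COSMIC) download is required;
#' real COSMIC v3.3 TSVs are accepted by [readSignatureCatalog()].
#'
#' @return numeric matrix, 96 x 4, columns summing to 1.
#' @export
syntheticSignatureCatalog <- function() {
  ch <- sbsChannels()
  mk <- function() stats::setNames(numeric(96), ch)

  sbs2 <- mk()
  sbs2[c("T[C>T]A", "T[C>T]T")] <- 0.35
  sbs2[c("T[C>T]C", "T[C>T]G")] <- 0.10
  restCT <- setdiff(grep("C>T", ch, fixed = TRUE, value = TRUE),
                    c("T[C>T]A", "T[C>T]T", "T[C>T]C", "T[C>T]G"))
  sbs2[restCT] <- 0.10 / length(restCT)

  sbs13 <- mk()
  sbs13[c("T[C>G]A", "T[C>G]T")] <- 0.35
  sbs13[c("T[C>G]C", "T[C>G]G")] <- 0.10
  restCG <- setdiff(grep("C>G", ch, fixed = TRUE, value = TRUE),
                    c("T[C>G]A", "T[C>G]T", "T[C>G]C", "T[C>G]G"))
  sbs13[restCG] <- 0.10 / length(restCG)

  sbs22 <- mk()
  sbs22["C[T>A]G"] <- 0.45
  sbs22[c("C[T>A]A", "T[T>A]G")] <- 0.15
  sbs22["G[T>A]G"] <- 0.10
  restTA <- setdiff(grep("T>A", ch, fixed = TRUE, value = TRUE),
                    c("C[T>A]G", "C[T>A]A", "T[T>A]G", "G[T>A]G"))
  sbs22[restTA] <- 0.15 / length(restTA)

  sbs5 <- stats::setNames(rep(1, 96), ch)
  sbs5[grep("T>C", ch, fixed = TRUE)] <- 2.5
  sbs5[grep("C>T", ch, fixed = TRUE)] <- 1.8
  sbs5 <- sbs5 / sum(sbs5)

  cbind(SBS2s = sbs2, SBS5s = sbs5, SBS13s = sbs13, SBS22s = sbs22)
}

#' Path to the bundled synthetic catalog fixture
#' @return file path inside the installed package.
#' @export
syntheticCatalogPath <- function() {
  system.file("extdata", "signature_catalog_synthetic.tsv",
              package = "nmibcGenomics", mustWork = TRUE)
}
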