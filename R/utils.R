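# Shared low-level helpers: trinucleotide channel space, sequence utilities,
# deterministic RNG scoping, and the TSV dialect used by every reader/writer.

#' The 96 single-base-substitution channels
#'
#' Channel labels follow the conventional pyrimidine-centred order: the six
#' substitution classes C>A, C>G, C>T, T>A, T>C, T>G in that order, and within
#' each class the 16 flanking contexts ordered by 5' base (A, C, G, T) then
#' 3' base (A, C, G, T). Example: `"A[C>A]A"` is channel 1, `"T[T>G]T"` is
#' channel 96. All spectrum and catalog objects in this package use this
#' order.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(sbsChannels())
sbsChannels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(bases, bases,
                      function(f, t3) paste0(f, "[", s, "]", t3))))
  }), use.names = FALSE)
}

# complement / reverse-complement for plain character vectors of DNA.
# Biostrings handles XStringSet objects; these are for scalar field work.
complementBase <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

revComp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(complementBase(s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

isDnaString <- function(x) {
  grepl("^[ACGT]+$", x)
}

#' @noRd
#' Map (ref, alt, context3) of an SNV to its pyrimidine-centred channel label,
#' or NA if the context is unresolvable. context3 is the +-strand trinucleotide
#' around the mutated base; purine references are reverse-complemented.
snvChannel <- function(ref, alt, context3) {
  out <- rep(NA_character_, length(ref))
  ok <- nchar(ref) == 1L & nchar(alt) == 1L & nchar(context3) == 3L &
    isDnaString(context3) & substr(context3, 2L, 2L) == ref
  pur <- ok & ref %in% c("A", "G")
  ref2 <- ref; alt2 <- alt; ctx2 <- context3
  if (any(pur)) {
    ref2[pur] <- complementBase(ref[pur])
    alt2[pur] <- complementBase(alt[pur])
    ctx2[pur] <- revComp(context3[pur])
  }
  out[ok] <- paste0(substr(ctx2[ok], 1L, 1L), "[", ref2[ok], ">", alt2[ok],
                    "]", substr(ctx2[ok], 3L, 3L))
  out[!out %in% sbsChannels()] <- NA_character_
  out
}

# Run code under a temporary RNG state; the caller's .Random.seed is
# restored afterwards so seeded package functions do not perturb user RNG.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed deterministically; kept below 2^31 - 1.
childSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647)
}

# ---- TSV dialect -----------------------------------------------------------
# All external tables are tab-separated UTF-8 with a header row, no quoting,
# "." never used as NA. Writers emit the identical dialect so write->read
# round-trips are identity on fields.

#' Read a table in the package's TSV dialect
#'
#' Tab-separated UTF-8 with a header row, no quoting; the dialect every
#' reader and writer of this package uses.
#'
#' @param path path to the TSV file.
#' @return data.frame.
#' @export
readTsv <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Write a table in the package's TSV dialect
#'
#' Tab-separated, header row, no quoting or row names. All package writers
#' use this dialect and [readTsv-style readers] parse it back unchanged.
#'
#' @param x data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

requireColumns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("schema error in ", what, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

asCount <- function(x, col, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad))
    stop("parse error in ", what, ": non-numeric ", col, " at row ",
         bad[1L], call. = FALSE)
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a
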