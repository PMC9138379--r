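# Sequence and coordinate primitives shared by every stage.
# Coordinates are 0-based half-open everywhere internally; 1-based display
# happens only in formatting code.

#' IUPAC nucleotide expansions
#'
#' Named list mapping each one-letter IUPAC nucleotide code to the set of
#' concrete bases it stands for. Concrete bases expand to themselves.
#'
#' @format Named list of character vectors.
#' @export
IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"),
  K = c("G", "T"), M = c("A", "C"),
  W = c("A", "T"), S = c("C", "G"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

.IUPAC_CODES <- names(IUPAC_EXPANSION)

# complement table covering the full IUPAC alphabet
.IUPAC_FROM <- "ACGTRYKMWSBDHVN"
.IUPAC_TO   <- "TGCAYRMKWSVHDBN"

#' Construct a reference locus
#'
#' A reference locus is a named DNA sequence (typically a promoter plus the
#' 5' part of the gene body) against which islands, motifs and methylation
#' positions are reported, always in 0-based half-open coordinates.
#'
#' @param id Character label for the locus (e.g. a gene name).
#' @param sequence DNA sequence over `{A,C,G,T,N}`; lowercase is accepted and
#'   uppercased, `U` is mapped to `T`.
#' @param source Free-text provenance, e.g. an accession string.
#' @return An object of class `reference_locus` with fields `id`, `sequence`
#'   and `source`.
#' @export
reference_locus <- function(id, sequence, source = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- chartr("Uu", "Tt", toupper(sequence))
  if (!nzchar(sequence)) {
    stop("reference locus '", id, "': sequence is empty")
  }
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L) {
    stop("reference locus '", id, "': invalid character '",
         substr(sequence, bad, bad), "' at position ", bad - 1L)
  }
  structure(list(id = id, sequence = sequence, source = source),
            class = "reference_locus")
}

#' @export
print.reference_locus <- function(x, ...) {
  cat("<reference_locus> ", x$id, " (", nchar(x$sequence), " bp",
      if (!is.na(x$source)) paste0(", source: ", x$source), ")\n", sep = "")
  invisible(x)
}

#' Length of a reference locus in base pairs
#' @param locus A `reference_locus`.
#' @return Integer length.
#' @export
locus_length <- function(locus) nchar(locus$sequence)

.as_locus <- function(x) {
  if (inherits(x, "reference_locus")) return(x)
  stop("expected a reference_locus object")
}

#' Read a multi-record FASTA file into reference loci
#'
#' Record order is preserved, sequences are uppercased and `U` is mapped to
#' `T`. The description line after the first whitespace is kept as `source`.
#'
#' @param path Path to a FASTA file.
#' @return List of [reference_locus()] objects, one per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    stop("FASTA format error in ", path, ": file is empty (line 1)")
  }
  if (!startsWith(first, ">")) {
    stop("FASTA format error in ", path,
         ": line 1 does not start with '>': ", substr(first, 1, 40))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA format error in ", path, ": no records")
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), NA_character_)
  lapply(seq_along(set), function(i) {
    reference_locus(ids[i], as.character(set[[i]]), source = desc[i])
  })
}

#' Write reference loci or clone reads to FASTA
#'
#' @param loci List of `reference_locus` objects (or any list of objects with
#'   `id` and `sequence` fields; a `description` field, if present, is
#'   appended to the header).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(loci, path) {
  seqs <- vapply(loci, function(x) x$sequence, character(1))
  ids <- vapply(loci, function(x) x$id, character(1))
  desc <- vapply(loci, function(x) {
    if (!is.null(x$description) && !is.na(x$description)) x$description else ""
  }, character(1))
  headers <- ifelse(nzchar(desc), paste(ids, desc), ids)
  set <- Biostrings::BStringSet(seqs)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Reverse complement of a DNA sequence, IUPAC-aware
#'
#' Complements honour the full degenerate alphabet (R<->Y, K<->M, W<->W,
#' S<->S, B<->V, D<->H, N<->N).
#'
#' @param seq Character scalar over the IUPAC alphabet.
#' @return The reverse complement, same length.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  bad <- regexpr(paste0("[^", .IUPAC_FROM, "]"), s)
  if (bad > 0L) {
    stop("invalid nucleotide '", substr(s, bad, bad),
         "' at position ", bad - 1L)
  }
  comp <- chartr(.IUPAC_FROM, .IUPAC_TO, s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Match a window against an IUPAC-degenerate pattern
#'
#' TRUE iff every base of `window` is contained in the expansion of the
#' corresponding pattern code. `N` in the window (as opposed to the pattern)
#' matches nothing: an ambiguous reference base is never accepted as evidence
#' for a concrete pattern base.
#'
#' @param pattern IUPAC pattern, same length as `window`.
#' @param window Concrete DNA window over `{A,C,G,T,N}`.
#' @return Logical scalar.
#' @export
iupac_match <- function(pattern, window) {
  stopifnot(is.character(pattern), is.character(window),
            length(pattern) == 1L, length(window) == 1L)
  if (nchar(pattern) != nchar(window)) {
    stop("pattern and window lengths differ (", nchar(pattern),
         " vs ", nchar(window), ")")
  }
  p <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  w <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  if (!all(p %in% .IUPAC_CODES)) {
    stop("invalid IUPAC code in pattern: ", pattern)
  }
  all(mapply(function(pc, wc) wc %in% IUPAC_EXPANSION[[pc]], p, w))
}

# Translate an IUPAC pattern into a regex over concrete bases. An N in the
# scanned sequence can never match because classes only contain A/C/G/T.
iupac_to_regex <- function(pattern) {
  p <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  if (!all(p %in% .IUPAC_CODES)) {
    stop("invalid IUPAC code in pattern: ", pattern)
  }
  paste(vapply(p, function(pc) {
    exp <- IUPAC_EXPANSION[[pc]]
    if (length(exp) == 1L) exp else paste0("[", paste(exp, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Construct a genomic interval
#'
#' @param start 0-based inclusive start.
#' @param end Exclusive end.
#' @param strand `"+"` or `"-"`.
#' @param locus_length Optional upper bound to validate against.
#' @return A one-row data.frame with columns `start`, `end`, `strand`.
#' @export
new_interval <- function(start, end, strand = "+", locus_length = NULL) {
  stopifnot(start >= 0, start < end, strand %in% c("+", "-"))
  if (!is.null(locus_length) && end > locus_length) {
    stop("interval [", start, ", ", end, ") exceeds locus length ",
         locus_length)
  }
  data.frame(start = as.integer(start), end = as.integer(end),
             strand = strand, stringsAsFactors = FALSE)
}

#' Extract a subsequence by 0-based half-open interval
#' @param locus A `reference_locus` (or character scalar).
#' @param start,end 0-based half-open bounds.
#' @return Character subsequence.
#' @export
subseq0 <- function(locus, start, end) {
  s <- if (inherits(locus, "reference_locus")) locus$sequence else locus
  stopifnot(start >= 0, end <= nchar(s), start < end)
  substr(s, start + 1L, end)
}

#' Write intervals as BED6
#'
#' @param df Data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand` (0-based half-open, i.e. already BED-convention).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  need <- c("chrom", "start", "end", "name", "score", "strand")
  stopifnot(all(need %in% names(df)))
  utils::write.table(df[, need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
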