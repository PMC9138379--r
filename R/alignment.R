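# Bisulfite-aware alignment of cloned Sanger reads to the unconverted
# reference amplicon, and per-cytosine methylation calling.
#
# The key asymmetry: at a reference C the read may legitimately show C
# (methylated, protected from conversion) or T (unmethylated, converted), so
# both are scored as matches; a reference T in the read reading C is an
# ordinary mismatch.

# Substitution matrix: rows = reference (pattern), cols = read (subject).
.bisulfite_submat <- function(match = 1, mismatch = -1) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m["C", "T"] <- match   # converted unmethylated C
  m["N", ] <- mismatch   # ambiguous reference base is never evidence
  m[, "N"] <- mismatch
  m["N", "N"] <- mismatch
  m
}

#' Construct a clone read
#'
#' @param id Clone identifier.
#' @param sequence Read sequence over `{A,C,G,T,N}`.
#' @param sample Sample / tissue label (e.g. `"coleoptile"`, `"root"`).
#' @return An object of class `clone_read`.
#' @export
clone_read <- function(id, sequence, sample = NA_character_) {
  sequence <- toupper(sequence)
  stopifnot(nzchar(id), nzchar(sequence))
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L) {
    stop("clone '", id, "': invalid character '", substr(sequence, bad, bad),
         "' at position ", bad - 1L)
  }
  structure(list(id = id, sequence = sequence, sample = sample),
            class = "clone_read")
}

#' Read clone reads from FASTA
#'
#' The sample label is taken from a `sample=<label>` key in the record
#' description, e.g. `>TaCHI_B1_root_clone01 sample=root`.
#'
#' @param path Path to a FASTA file of cloned bisulfite reads.
#' @return List of [clone_read()] objects.
#' @export
read_clone_fasta <- function(path) {
  loci <- read_fasta(path)
  lapply(loci, function(x) {
    sample <- NA_character_
    if (!is.na(x$source)) {
      m <- regmatches(x$source, regexpr("sample=\\S+", x$source))
      if (length(m) == 1L) sample <- sub("^sample=", "", m)
    }
    clone_read(x$id, x$sequence, sample = sample)
  })
}

#' Align a clone read to the unconverted reference amplicon
#'
#' Global (Needleman-Wunsch) alignment with bisulfite-asymmetric scoring: at
#' a reference C the read may show C or T at full match score. Reads whose
#' length deviates from the amplicon by more than `max_len_dev`, or whose
#' alignment identity (bisulfite-aware) falls below `min_identity`, are
#' rejected with an error, mirroring manual curation of bad clones.
#'
#' @param read A [clone_read()].
#' @param locus The [reference_locus()] the amplicon lies on.
#' @param amplicon The `amplicon` (from [in_silico_pcr()]).
#' @param min_identity Identity threshold for clone acceptance.
#' @param max_len_dev Maximum fractional length deviation of the read.
#' @param match,mismatch,gap_opening,gap_extension Scoring parameters.
#' @return An object of class `clone_alignment` with fields `clone_id`,
#'   `sample`, `amplicon`, `ref_pos` (0-based locus positions of non-gap
#'   reference columns), `read_base` (read character in each such column, or
#'   NA at a read gap), `mismatches` (non-bisulfite mismatches), `gaps`,
#'   `identity`.
#' @export
align_clone <- function(read, locus, amplicon, min_identity = 0.9,
                        max_len_dev = 0.2, match = 1, mismatch = -1,
                        gap_opening = 3, gap_extension = 1) {
  stopifnot(inherits(read, "clone_read"), inherits(amplicon, "amplicon"))
  locus <- .as_locus(locus)
  ref_seq <- subseq0(locus, amplicon$start, amplicon$end)
  len_ratio <- nchar(read$sequence) / nchar(ref_seq)
  if (abs(len_ratio - 1) > max_len_dev) {
    stop("clone '", read$id, "' rejected: read length ",
         nchar(read$sequence), " deviates more than ",
         round(max_len_dev * 100), "% from amplicon length ", nchar(ref_seq))
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(ref_seq),
    subject = Biostrings::DNAString(read$sequence),
    substitutionMatrix = .bisulfite_submat(match, mismatch),
    gapOpening = gap_opening, gapExtension = gap_extension,
    type = "global")
  ref_chars <- strsplit(as.character(Biostrings::alignedPattern(aln)),
                        "", fixed = TRUE)[[1]]
  read_chars <- strsplit(as.character(Biostrings::alignedSubject(aln)),
                         "", fixed = TRUE)[[1]]
  ref_cursor <- amplicon$start - 1L  # last emitted 0-based reference pos
  n <- length(ref_chars)
  ref_pos <- integer(0)
  read_base <- character(0)
  mismatches <- 0L
  gaps <- 0L
  matches <- 0L
  for (i in seq_len(n)) {
    rc <- ref_chars[i]
    qc <- read_chars[i]
    if (rc == "-") {           # insertion in the read
      gaps <- gaps + 1L
      next
    }
    ref_cursor <- ref_cursor + 1L
    if (qc == "-") {           # deletion in the read
      gaps <- gaps + 1L
      ref_pos <- c(ref_pos, ref_cursor)
      read_base <- c(read_base, NA_character_)
      next
    }
    ref_pos <- c(ref_pos, ref_cursor)
    read_base <- c(read_base, qc)
    ok <- (qc == rc) || (rc == "C" && qc == "T")
    if (ok && rc != "N" && qc != "N") matches <- matches + 1L
    else mismatches <- mismatches + 1L
  }
  identity <- matches / n
  if (identity < min_identity) {
    stop("clone '", read$id, "' rejected: bisulfite-aware identity ",
         sprintf("%.3f", identity), " below threshold ", min_identity)
  }
  structure(list(clone_id = read$id, sample = read$sample,
                 amplicon = amplicon, ref_pos = ref_pos,
                 read_base = read_base, mismatches = mismatches,
                 gaps = gaps, identity = identity),
            class = "clone_alignment")
}

#' Call methylation from a clone alignment
#'
#' For every reference-C position inside the amplicon but outside both
#' primer footprints: read C is called methylated, read T unmethylated, and
#' a gap or any other base uncallable. Each call carries the cytosine
#' context from [classify_context()]; positions with ambiguous context are
#' skipped.
#'
#' @param aln A `clone_alignment` from [align_clone()].
#' @param locus The [reference_locus()].
#' @return Data.frame with columns `locus`, `pos` (0-based), `context`,
#'   `status` (`"methylated"`, `"unmethylated"`, `"uncallable"`),
#'   `clone_id`, `sample`.
#' @export
call_methylation <- function(aln, locus) {
  stopifnot(inherits(aln, "clone_alignment"))
  locus <- .as_locus(locus)
  region <- callable_region(aln$amplicon)
  all_c <- c_positions(locus)
  sites <- all_c[all_c >= region[1] & all_c < region[2]]
  if (length(sites) == 0L) {
    return(data.frame(locus = character(0), pos = integer(0),
                      context = character(0), status = character(0),
                      clone_id = character(0), sample = character(0),
                      stringsAsFactors = FALSE))
  }
  context <- classify_context(locus, sites)
  keep <- context != "ambiguous"
  sites <- sites[keep]
  context <- context[keep]
  base_at <- rep(NA_character_, length(sites))
  idx <- match(sites, aln$ref_pos)
  got <- !is.na(idx)
  base_at[got] <- aln$read_base[idx[got]]
  status <- ifelse(is.na(base_at), "uncallable",
                   ifelse(base_at == "C", "methylated",
                          ifelse(base_at == "T", "unmethylated",
                                 "uncallable")))
  data.frame(locus = locus$id, pos = sites, context = context,
             status = status, clone_id = aln$clone_id, sample = aln$sample,
             stringsAsFactors = FALSE)
}
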