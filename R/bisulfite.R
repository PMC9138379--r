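# In-silico bisulfite conversion, cytosine context classification, and
# degenerate-primer PCR against the converted template.
#
# The assay is single-stranded: conversion, primer placement and calling all
# act on the top strand of the given locus, mirroring bisulfite primer sets
# designed against the cytosine-converted top strand.

.CONTEXTS <- c("CpG", "CpHpG", "CpHpH")

#' 0-based positions of cytosines on the top strand
#' @param locus A [reference_locus()].
#' @return Integer vector of 0-based positions.
#' @export
c_positions <- function(locus) {
  locus <- .as_locus(locus)
  which(strsplit(locus$sequence, "", fixed = TRUE)[[1]] == "C") - 1L
}

#' Construct a methylation profile
#'
#' A profile records, for every cytosine of the top strand, whether it is
#' methylated (5mC) or not. Positions not listed in `methylated_pos` are
#' unmethylated.
#'
#' @param locus A [reference_locus()].
#' @param methylated_pos Integer vector of 0-based positions carrying 5mC;
#'   every position must hold a C on the top strand.
#' @param tissue Optional sample/tissue label.
#' @return An object of class `methylation_profile` with fields `locus_id`,
#'   `pos` (all C positions), `methylated` (logical, parallel to `pos`) and
#'   `tissue`.
#' @export
methylation_profile <- function(locus, methylated_pos = integer(0),
                                tissue = NA_character_) {
  locus <- .as_locus(locus)
  pos <- c_positions(locus)
  methylated_pos <- as.integer(methylated_pos)
  if (!all(methylated_pos %in% pos)) {
    bad <- setdiff(methylated_pos, pos)
    stop("positions not holding a top-strand C: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(list(locus_id = locus$id, pos = pos,
                 methylated = pos %in% methylated_pos, tissue = tissue),
            class = "methylation_profile")
}

#' Methylated positions of a profile
#' @param profile A `methylation_profile`.
#' @return Integer vector of 0-based positions.
#' @export
methylated_positions <- function(profile) {
  profile$pos[profile$methylated]
}

# Convert a character vector of bases given a logical mask of methylated
# positions (parallel to the vector). Unmethylated C -> T with probability
# `efficiency`; 5mC always stays C. RNG state is the caller's concern.
.convert_chars <- function(chars, methylated_mask, efficiency) {
  is_c <- chars == "C"
  target <- is_c & !methylated_mask
  if (any(target)) {
    flip <- stats::runif(sum(target)) <= efficiency
    idx <- which(target)[flip]
    chars[idx] <- "T"
  }
  chars
}

#' In-silico bisulfite conversion of a locus
#'
#' Each unmethylated top-strand cytosine deaminates to T with probability
#' `efficiency` (independent Bernoulli draws); 5mC is protected and always
#' reads C; all other bases are untouched. `efficiency = 1` is fully
#' deterministic.
#'
#' @param locus A [reference_locus()].
#' @param profile A [methylation_profile()] for the locus.
#' @param efficiency Conversion efficiency in `[0, 1]`.
#' @param seed Optional integer seed; when given, conversion is reproducible
#'   and the caller's RNG state is untouched.
#' @return Converted top-strand sequence (character scalar).
#' @export
convert_bisulfite <- function(locus, profile, efficiency = 1, seed = NULL) {
  locus <- .as_locus(locus)
  stopifnot(inherits(profile, "methylation_profile"),
            efficiency >= 0, efficiency <= 1)
  if (profile$locus_id != locus$id) {
    stop("profile is for locus '", profile$locus_id, "', not '",
         locus$id, "'")
  }
  chars <- strsplit(locus$sequence, "", fixed = TRUE)[[1]]
  mask <- logical(length(chars))
  mask[methylated_positions(profile) + 1L] <- TRUE
  run <- function() .convert_chars(chars, mask, efficiency)
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  paste(out, collapse = "")
}

#' Fully-converted reference under the all-unmethylated assumption
#'
#' Every top-strand C becomes T. This is the template bisulfite primers are
#' designed against.
#'
#' @param locus A [reference_locus()] or character sequence.
#' @return Converted sequence (character scalar).
#' @export
converted_reference <- function(locus) {
  s <- if (inherits(locus, "reference_locus")) locus$sequence else locus
  chartr("C", "T", s)
}

#' Classify the sequence context of a cytosine
#'
#' Plant methylation contexts on the top strand: `CpG` when the next base is
#' G; `CpHpG` when the next base is H (A/C/T) and the one after is G; `CpHpH`
#' when both following bases are H. The context is `"ambiguous"` when it
#' would extend past the locus end or touches an N.
#'
#' @param locus A [reference_locus()].
#' @param pos Integer vector of 0-based positions, each holding a C.
#' @return Character vector: `"CpG"`, `"CpHpG"`, `"CpHpH"` or `"ambiguous"`.
#' @export
classify_context <- function(locus, pos) {
  locus <- .as_locus(locus)
  chars <- strsplit(locus$sequence, "", fixed = TRUE)[[1]]
  len <- length(chars)
  pos <- as.integer(pos)
  stopifnot(all(pos >= 0), all(pos < len))
  if (!all(chars[pos + 1L] == "C")) {
    bad <- pos[chars[pos + 1L] != "C"][1]
    stop("position ", bad, " does not hold a C (found '",
         chars[bad + 1L], "')")
  }
  vapply(pos, function(p) {
    b1 <- if (p + 1L < len) chars[p + 2L] else NA_character_
    if (is.na(b1) || b1 == "N") return("ambiguous")
    if (b1 == "G") return("CpG")
    b2 <- if (p + 2L < len) chars[p + 3L] else NA_character_
    if (is.na(b2) || b2 == "N") return("ambiguous")
    if (b2 == "G") "CpHpG" else "CpHpH"
  }, character(1))
}

#' Construct a bisulfite primer pair
#'
#' Primers are written 5'->3' against the converted top strand (forward) and
#' its reverse complement (reverse); `R`/`Y` degeneracies accommodate
#' cytosines of unknown methylation state within the primer.
#'
#' @param forward,reverse Primer sequences (IUPAC allowed), each >= 15 nt.
#' @param expected_bp Expected product length including both primers.
#' @param annealing_c Annealing temperature in degrees Celsius (metadata).
#' @param gene Optional gene/locus label the pair targets.
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse, expected_bp,
                        annealing_c = NA_real_, gene = NA_character_) {
  forward <- toupper(gsub("\\s", "", forward))
  reverse <- toupper(gsub("\\s", "", reverse))
  for (p in c(forward, reverse)) {
    bad <- regexpr(paste0("[^", .IUPAC_FROM, "]"), p)
    if (bad > 0L) stop("invalid primer character '", substr(p, bad, bad),
                       "' in ", p)
  }
  if (nchar(forward) < 15L || nchar(reverse) < 15L) {
    stop("primers must be at least 15 nt (got ", nchar(forward), " and ",
         nchar(reverse), ")")
  }
  expected_bp <- as.integer(expected_bp)
  if (expected_bp <= nchar(forward) + nchar(reverse)) {
    stop("expected product length ", expected_bp,
         " is not longer than the two primers combined")
  }
  structure(list(gene = gene, forward = forward, reverse = reverse,
                 expected_bp = expected_bp, annealing_c = annealing_c),
            class = "primer_pair")
}

#' Read a primer table (TSV)
#'
#' Expected columns: `gene`, `forward`, `reverse`, `expected_bp`,
#' `annealing_c`. An empty `gene` cell inherits the gene of the row above,
#' so multi-row-per-gene tables can be written the way primer tables are
#' usually printed.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return List of [primer_pair()] objects.
#' @export
read_primer_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "forward", "reverse", "expected_bp", "annealing_c")
  if (!all(need %in% names(df))) {
    stop("primer table must have columns: ", paste(need, collapse = ", "))
  }
  gene <- df$gene
  for (i in seq_along(gene)) {
    if (!nzchar(gene[i]) && i > 1L) gene[i] <- gene[i - 1L]
  }
  lapply(seq_len(nrow(df)), function(i) {
    primer_pair(df$forward[i], df$reverse[i], df$expected_bp[i],
                df$annealing_c[i], gene = gene[i])
  })
}

#' Locate primer binding sites on the converted template
#'
#' The forward primer is matched against the fully-converted top strand, the
#' reverse primer against its reverse complement; degenerate primer bases
#' (R/Y etc.) match any base in their expansion, ambiguous template bases
#' are treated literally. Only orientation-consistent pairs (forward start
#' before reverse end) are reported.
#'
#' @param pair A [primer_pair()].
#' @param converted_top Fully-converted top strand (see
#'   [converted_reference()]).
#' @param max_mismatch Maximum mismatches tolerated per primer.
#' @return Data.frame with 0-based columns `fwd_start`, `rev_end`
#'   (exclusive) and `product_bp`; zero rows when no site pairs exist.
#' @export
find_primer_sites <- function(pair, converted_top, max_mismatch = 0L) {
  stopifnot(inherits(pair, "primer_pair"))
  subject <- Biostrings::DNAString(converted_top)
  len <- length(subject)
  fwd <- Biostrings::matchPattern(Biostrings::DNAString(pair$forward),
                                  subject, max.mismatch = max_mismatch,
                                  fixed = "subject")
  rc <- Biostrings::reverseComplement(subject)
  rev <- Biostrings::matchPattern(Biostrings::DNAString(pair$reverse),
                                  rc, max.mismatch = max_mismatch,
                                  fixed = "subject")
  fwd_starts <- BiocGenerics::start(fwd) - 1L           # 0-based
  # a reverse hit at [s, e] (1-based) on the reverse complement ends at
  # top-strand coordinate len - s + 1 (0-based exclusive)
  rev_ends <- len - BiocGenerics::start(rev) + 1L
  if (length(fwd_starts) == 0L || length(rev_ends) == 0L) {
    return(data.frame(fwd_start = integer(0), rev_end = integer(0),
                      product_bp = integer(0)))
  }
  combos <- expand.grid(fwd_start = fwd_starts, rev_end = rev_ends)
  combos <- combos[combos$fwd_start < combos$rev_end, , drop = FALSE]
  combos$product_bp <- combos$rev_end - combos$fwd_start
  rownames(combos) <- NULL
  combos
}

#' In-silico PCR of a bisulfite primer pair on a locus
#'
#' The locus is converted under the all-unmethylated assumption and both
#' primers are located; exactly one orientation-consistent site pair must
#' exist. The amplicon interval spans the forward-primer start to the
#' reverse-primer end, primers included.
#'
#' @param pair A [primer_pair()].
#' @param locus A [reference_locus()].
#' @param max_mismatch Maximum mismatches tolerated per primer.
#' @return An object of class `amplicon` with fields `locus_id`, `start`,
#'   `end` (0-based half-open, primer-inclusive), `product_bp`,
#'   `fwd_len`, `rev_len` and `pair`.
#' @export
in_silico_pcr <- function(pair, locus, max_mismatch = 0L) {
  locus <- .as_locus(locus)
  sites <- find_primer_sites(pair, converted_reference(locus), max_mismatch)
  if (nrow(sites) == 0L) {
    stop("no product: primer pair ",
         if (!is.na(pair$gene)) paste0("for ", pair$gene, " "),
         "finds no orientation-consistent sites on '", locus$id, "'")
  }
  if (nrow(sites) > 1L) {
    stop("non-specific primers on '", locus$id, "': ", nrow(sites),
         " candidate products (",
         paste(sprintf("[%d,%d)", sites$fwd_start, sites$rev_end),
               collapse = ", "), ")")
  }
  structure(list(locus_id = locus$id,
                 start = sites$fwd_start[1],
                 end = sites$rev_end[1],
                 product_bp = sites$product_bp[1],
                 expected_bp = pair$expected_bp,
                 fwd_len = nchar(pair$forward),
                 rev_len = nchar(pair$reverse),
                 pair = pair),
            class = "amplicon")
}

#' @export
print.amplicon <- function(x, ...) {
  cat("<amplicon> ", x$locus_id, ":[", x$start, ", ", x$end, ") ",
      x$product_bp, " bp (expected ", x$expected_bp, ")\n", sep = "")
  invisible(x)
}

#' Primer footprints of an amplicon
#'
#' The intervals covered by the forward and reverse primers. Template
#' methylation state under a primer is overwritten by the synthesized primer
#' bases, so these positions are unobservable and are excluded from calling
#' and from denominators.
#'
#' @param amplicon An `amplicon`.
#' @return Data.frame of 0-based half-open intervals (`start`, `end`).
#' @export
primer_footprints <- function(amplicon) {
  stopifnot(inherits(amplicon, "amplicon"))
  data.frame(
    start = c(amplicon$start, amplicon$end - amplicon$rev_len),
    end = c(amplicon$start + amplicon$fwd_len, amplicon$end)
  )
}

#' Callable region of an amplicon
#'
#' The amplicon interval minus both primer footprints.
#'
#' @param amplicon An `amplicon`.
#' @return 0-based half-open `c(start, end)`.
#' @export
callable_region <- function(amplicon) {
  c(amplicon$start + amplicon$fwd_len, amplicon$end - amplicon$rev_len)
}
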