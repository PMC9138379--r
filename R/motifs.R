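# IUPAC-degenerate cis-regulatory motif scanning and per-tissue methylation
# status of each motif instance.

#' Load a motif catalogue (TSV)
#'
#' Expected named columns: `name`, `pattern`, `function`, `place_id` (the
#' PLACE database identifier, e.g. S000176). Duplicate (name, pattern) rows
#' are rejected. An optional `strand` column (`+`, `-` or `both`) overrides
#' the scan orientation per motif.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return Data.frame of motif definitions.
#' @export
load_motif_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (nrow(df) == 0L) {
    warning("motif table ", path, " is empty")
    return(data.frame(name = character(0), pattern = character(0),
                      `function` = character(0), place_id = character(0),
                      check.names = FALSE, stringsAsFactors = FALSE))
  }
  need <- c("name", "pattern", "function", "place_id")
  if (!all(need %in% names(df))) {
    stop("motif table must have columns: ", paste(need, collapse = ", "))
  }
  df$pattern <- toupper(df$pattern)
  for (i in seq_len(nrow(df))) {
    p <- df$pattern[i]
    bad <- regexpr(paste0("[^", .IUPAC_FROM, "]"), p)
    if (bad > 0L) {
      stop("motif table row ", i, " (", df$name[i],
           "): invalid IUPAC character '", substr(p, bad, bad), "' in ", p)
    }
    if (nchar(p) < 3L) {
      stop("motif table row ", i, " (", df$name[i],
           "): pattern shorter than 3 nt")
    }
  }
  dup <- duplicated(df[, c("name", "pattern")])
  if (any(dup)) {
    stop("duplicate motif definitions: ",
         paste(unique(df$name[dup]), collapse = ", "))
  }
  if (!"strand" %in% names(df)) df$strand <- "both"
  df
}

#' The bundled cis-element catalogue
#'
#' A compact promoter-element catalogue (PLACE-style identifiers, IUPAC
#' patterns) of flavonoid-pathway-relevant motifs: MYB and bZIP binding
#' cores, light-responsive elements (GATABOX, SORLIP), dehydration /
#' low-temperature elements (CBFHV, DRECRTCOREAT, LTRE), and others. Users
#' may substitute any larger PLACE export with the same columns.
#'
#' @return Data.frame of motif definitions (see [load_motif_table()]).
#' @export
builtin_motif_catalog <- function() {
  load_motif_table(system.file("extdata", "place_motif_catalog.tsv",
                               package = "cloneMeth", mustWork = TRUE))
}

# All start positions (0-based) of an IUPAC pattern on a concrete sequence,
# overlapping matches included (zero-width lookahead trick).
.scan_one_strand <- function(sequence, pattern) {
  rx <- paste0("(?=", iupac_to_regex(pattern), ")")
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

#' Scan a locus for motif instances
#'
#' Every position where a window of the locus matches the IUPAC pattern
#' yields one instance; on the minus strand the reverse complement of the
#' window must match. Overlapping instances of the same motif are all
#' reported. `N` in the locus never matches a concrete pattern base.
#'
#' @param locus A [reference_locus()].
#' @param motifs Motif data.frame from [load_motif_table()] /
#'   [builtin_motif_catalog()].
#' @param strands `"both"` (default), `"+"` or `"-"`; a per-motif `strand`
#'   column, when not `"both"`, takes precedence.
#' @return Data.frame with columns `locus`, `name`, `pattern`, `place_id`,
#'   `start`, `end` (0-based half-open on the top strand), `strand`, sorted
#'   by start then name.
#' @export
scan_motifs <- function(locus, motifs, strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  locus <- .as_locus(locus)
  len <- locus_length(locus)
  rc <- revcomp(locus$sequence)
  out <- list()
  for (i in seq_len(nrow(motifs))) {
    pattern <- motifs$pattern[i]
    w <- nchar(pattern)
    motif_strand <- if ("strand" %in% names(motifs) &&
                        motifs$strand[i] %in% c("+", "-")) {
      motifs$strand[i]
    } else {
      strands
    }
    if (motif_strand %in% c("both", "+")) {
      starts <- .scan_one_strand(locus$sequence, pattern)
      if (length(starts) > 0L) {
        out[[length(out) + 1L]] <- data.frame(
          locus = locus$id, name = motifs$name[i], pattern = pattern,
          place_id = motifs$place_id[i], start = starts, end = starts + w,
          strand = "+", stringsAsFactors = FALSE)
      }
    }
    if (motif_strand %in% c("both", "-")) {
      rc_starts <- .scan_one_strand(rc, pattern)
      if (length(rc_starts) > 0L) {
        # a hit at [s, s+w) on the reverse complement maps to
        # [len - s - w, len - s) on the top strand
        starts <- len - rc_starts - w
        out[[length(out) + 1L]] <- data.frame(
          locus = locus$id, name = motifs$name[i], pattern = pattern,
          place_id = motifs$place_id[i], start = starts, end = starts + w,
          strand = "-", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(locus = character(0), name = character(0),
                      pattern = character(0), place_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$name, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-sample methylation status of motif instances
#'
#' A motif instance is marked `"+"` for a sample when some cytosine position
#' inside its interval is called methylated in at least `min_clones` clones
#' of that sample, `"-"` otherwise. Methylated cytosines of any context
#' (CpG, CpHpG or CpHpH) count. The supporting clone count is the maximum
#' per-position methylated-clone count inside the instance.
#'
#' @param instances Data.frame from [scan_motifs()].
#' @param calls Data.frame of calls from [call_methylation()], pooled over
#'   clones, with a `sample` column covering one or more samples.
#' @param min_clones Minimum methylated-clone support for a `"+"`.
#' @return `instances` expanded by `sample`, `status` (`"+"`/`"-"`) and
#'   `support` (clones behind the best position).
#' @export
motif_methylation_status <- function(instances, calls, min_clones = 1L) {
  stopifnot(min_clones >= 0L)
  samples <- sort(unique(calls$sample))
  if (length(samples) == 0L) samples <- NA_character_
  meth <- calls[calls$status == "methylated", , drop = FALSE]
  out <- list()
  for (smp in samples) {
    sub <- meth[!is.na(meth$sample) & meth$sample == smp, , drop = FALSE]
    support_by_pos <- if (nrow(sub) > 0L) {
      tapply(sub$clone_id, sub$pos, function(x) length(unique(x)))
    } else {
      integer(0)
    }
    pos_keys <- as.integer(names(support_by_pos))
    block <- instances
    block$sample <- smp
    block$support <- vapply(seq_len(nrow(instances)), function(i) {
      hit <- pos_keys >= instances$start[i] & pos_keys < instances$end[i]
      if (!any(hit)) 0L else as.integer(max(support_by_pos[hit]))
    }, integer(1))
    block$status <- ifelse(block$support >= min_clones & block$support > 0L,
                           "+", "-")
    out[[length(out) + 1L]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
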