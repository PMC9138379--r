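# Sliding-window CpG island prediction.
#
# An island is a run of overlapping fixed-size windows that each pass both a
# G+C content threshold and a CpG observed/expected threshold, merged and
# filtered by a minimum length, with the summary statistics recomputed on the
# merged region itself.

#' G+C fraction of a sequence
#'
#' `N` bases are excluded from both numerator and denominator.
#'
#' @param seq DNA character scalar.
#' @return Fraction in `[0, 1]`.
#' @export
gc_fraction <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  informative <- chars != "N"
  if (!any(informative)) {
    stop("gc_fraction is undefined for an all-N sequence")
  }
  sum(chars == "G" | chars == "C") / sum(informative)
}

#' CpG observed/expected ratio
#'
#' The Gardiner-Garden and Frommer convention:
#' `(#CpG * length) / (#C * #G)`, defined as 0 when the sequence lacks either
#' C or G.
#'
#' @param seq DNA character scalar.
#' @return Non-negative ratio.
#' @export
obs_exp_cpg <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  s <- toupper(seq)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  nc <- sum(chars == "C")
  ng <- sum(chars == "G")
  if (nc == 0L || ng == 0L) return(0)
  ncg <- sum(chars[-length(chars)] == "C" & chars[-1L] == "G")
  ncg * nchar(s) / (nc * ng)
}

#' Island-prediction parameters
#'
#' Defaults follow the classical MethPrimer-style criteria: 100 bp windows
#' slid 1 bp at a time, minimum island length 100 bp, G+C >= 0.50 and CpG
#' observed/expected >= 0.60.
#'
#' @param min_length Minimum merged-region length in bp.
#' @param min_gc Minimum G+C fraction.
#' @param min_obs_exp Minimum CpG observed/expected ratio.
#' @param window Window size in bp.
#' @param step Window step in bp.
#' @return A list of class `island_params`.
#' @export
island_params <- function(min_length = 100L, min_gc = 0.5,
                          min_obs_exp = 0.6, window = 100L, step = 1L) {
  stopifnot(min_length >= window, window >= 1L, step >= 1L,
            min_gc >= 0, min_gc <= 1, min_obs_exp > 0)
  structure(list(min_length = as.integer(min_length), min_gc = min_gc,
                 min_obs_exp = min_obs_exp, window = as.integer(window),
                 step = as.integer(step)),
            class = "island_params")
}

#' Predict CpG islands on a reference locus
#'
#' Windows of size `params$window` are slid by `params$step`; windows passing
#' both the GC and observed/expected thresholds are merged when they overlap
#' or are adjacent, merged regions shorter than `params$min_length` are
#' discarded, and GC / observed-expected are recomputed on each surviving
#' region. Islands are numbered 1, 2, ... by start coordinate ("Island 1",
#' "Island 2").
#'
#' @param locus A [reference_locus()].
#' @param params An [island_params()] object.
#' @return Data.frame with columns `locus`, `ordinal`, `start`, `end`
#'   (0-based half-open), `length`, `gc`, `obs_exp`, sorted by `start`.
#' @export
find_cpg_islands <- function(locus, params = island_params()) {
  locus <- .as_locus(locus)
  len <- locus_length(locus)
  empty <- data.frame(locus = character(0), ordinal = integer(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), gc = numeric(0),
                      obs_exp = numeric(0), stringsAsFactors = FALSE)
  if (len < params$window) {
    warning("locus '", locus$id, "' (", len,
            " bp) is shorter than the window (", params$window,
            " bp); no islands can be called")
    return(empty)
  }
  chars <- strsplit(locus$sequence, "", fixed = TRUE)[[1]]
  is_c <- chars == "C"
  is_g <- chars == "G"
  is_n <- chars == "N"
  is_cg <- c(is_c[-len] & is_g[-1L], FALSE)  # CpG starting at each position
  cum_c <- c(0L, cumsum(is_c))
  cum_g <- c(0L, cumsum(is_g))
  cum_n <- c(0L, cumsum(is_n))
  cum_cg <- c(0L, cumsum(is_cg))

  w <- params$window
  starts <- seq.int(1L, len - w + 1L, by = params$step)  # 1-based
  ends <- starts + w - 1L
  n_c <- cum_c[ends + 1L] - cum_c[starts]
  n_g <- cum_g[ends + 1L] - cum_g[starts]
  n_n <- cum_n[ends + 1L] - cum_n[starts]
  # CpG dinucleotides fully inside the window: starts in [start, end-1]
  n_cg <- cum_cg[ends] - cum_cg[starts]
  informative <- w - n_n
  gc <- ifelse(informative > 0L, (n_c + n_g) / informative, NA_real_)
  oe <- ifelse(n_c > 0L & n_g > 0L, n_cg * w / (n_c * n_g), 0)
  pass <- !is.na(gc) & gc >= params$min_gc & oe >= params$min_obs_exp
  if (!any(pass)) return(empty)

  merged <- IRanges::reduce(IRanges::IRanges(start = starts[pass],
                                             end = ends[pass]))
  keep <- IRanges::width(merged) >= params$min_length
  merged <- merged[keep]
  if (length(merged) == 0L) return(empty)

  res <- data.frame(
    locus = locus$id,
    ordinal = seq_along(merged),
    start = IRanges::start(merged) - 1L,
    end = IRanges::end(merged),
    length = IRanges::width(merged),
    stringsAsFactors = FALSE
  )
  res$gc <- vapply(seq_len(nrow(res)), function(i) {
    gc_fraction(subseq0(locus, res$start[i], res$end[i]))
  }, numeric(1))
  res$obs_exp <- vapply(seq_len(nrow(res)), function(i) {
    obs_exp_cpg(subseq0(locus, res$start[i], res$end[i]))
  }, numeric(1))
  res
}

#' Export islands as BED6
#'
#' The name column carries the island ordinal ("Island_1", ...), the score
#' column the observed/expected ratio scaled to 0-1000.
#'
#' @param islands Result of [find_cpg_islands()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
islands_to_bed <- function(islands, path) {
  bed <- data.frame(
    chrom = islands$locus,
    start = islands$start,
    end = islands$end,
    name = paste0("Island_", islands$ordinal),
    score = pmin(1000L, as.integer(round(islands$obs_exp * 500))),
    strand = "+",
    stringsAsFactors = FALSE
  )
  write_bed(bed, path)
}
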