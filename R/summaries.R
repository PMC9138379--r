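# Per-colony summaries in the style of clone-based bisulfite studies: for
# each context, "k methylated of D potential sites in m colonies".

#' Count potential methylation sites per context
#'
#' Distinct reference-C positions in the union of the amplicon intervals,
#' minus all primer footprints, partitioned by cytosine context. Positions
#' covered by more than one amplicon are counted once. Ambiguous-context
#' cytosines are excluded from all three counts.
#'
#' @param locus A [reference_locus()].
#' @param amplicons List of `amplicon` objects on the locus (a single
#'   amplicon may be passed bare).
#' @param include_primer_footprints Keep cytosines under primer footprints
#'   (default FALSE: primer bases overwrite template state).
#' @return A list of class `context_counts`: integer fields `CpG`, `CpHpG`,
#'   `CpHpH` and a data.frame `sites` (`pos`, `context`).
#' @export
count_potential_sites <- function(locus, amplicons,
                                  include_primer_footprints = FALSE) {
  locus <- .as_locus(locus)
  if (inherits(amplicons, "amplicon")) amplicons <- list(amplicons)
  stopifnot(length(amplicons) >= 1L,
            all(vapply(amplicons, inherits, logical(1), "amplicon")))
  if (!all(vapply(amplicons, function(a) a$locus_id, character(1)) ==
           locus$id)) {
    stop("all amplicons must lie on locus '", locus$id, "'")
  }
  covered <- IRanges::reduce(IRanges::IRanges(
    start = vapply(amplicons, function(a) a$start + 1L, integer(1)),
    end = vapply(amplicons, function(a) a$end, integer(1))))
  if (!include_primer_footprints) {
    fp <- do.call(rbind, lapply(amplicons, primer_footprints))
    fp_ranges <- IRanges::reduce(IRanges::IRanges(start = fp$start + 1L,
                                                  end = fp$end))
    covered <- IRanges::setdiff(covered, fp_ranges)
  }
  all_c <- c_positions(locus)
  inside <- IRanges::overlapsAny(IRanges::IRanges(start = all_c + 1L,
                                                  width = 1L), covered)
  sites <- all_c[inside]
  if (length(sites) > 0L) {
    context <- classify_context(locus, sites)
    keep <- context != "ambiguous"
    sites <- sites[keep]
    context <- context[keep]
  } else {
    context <- character(0)
  }
  structure(list(
    CpG = sum(context == "CpG"),
    CpHpG = sum(context == "CpHpG"),
    CpHpH = sum(context == "CpHpH"),
    sites = data.frame(pos = sites, context = context,
                       stringsAsFactors = FALSE)
  ), class = "context_counts")
}

#' @export
print.context_counts <- function(x, ...) {
  cat("<context_counts> CpG:", x$CpG, " CpHpG:", x$CpHpG,
      " CpHpH:", x$CpHpH, "\n")
  invisible(x)
}

#' Summarize methylation calls over clones, colony-table style
#'
#' For each context, every clone contributes k = number of distinct
#' positions it shows as methylated; clones with identical k are grouped,
#' and each group is reported as "k/D in m" where D is the number of
#' potential sites of that context and m the group size.
#'
#' @param calls Data.frame of calls from [call_methylation()], pooled over
#'   the clones of one gene x sample. Every clone must appear (unmethylated
#'   and uncallable rows count as appearances).
#' @param denominators A `context_counts` from [count_potential_sites()].
#' @param n_clones Expected number of clones.
#' @return A list of class `clone_summary`: `n_clones`, a data.frame
#'   `groups` (`context`, `k`, `denominator`, `m`) and a named character
#'   vector `formatted` with one "k/D in m [; ...]" cell per context.
#' @export
summarize_clones <- function(calls, denominators, n_clones) {
  stopifnot(inherits(denominators, "context_counts"))
  clones <- unique(calls$clone_id)
  if (length(clones) != n_clones) {
    stop("expected ", n_clones, " clones but calls cover ",
         length(clones))
  }
  groups <- do.call(rbind, lapply(.CONTEXTS, function(ctx) {
    d <- denominators[[ctx]]
    k_per_clone <- vapply(clones, function(cl) {
      sub <- calls[calls$clone_id == cl & calls$context == ctx &
                     calls$status == "methylated", , drop = FALSE]
      length(unique(sub$pos))
    }, integer(1))
    if (any(k_per_clone > d)) {
      stop("clone reports more methylated ", ctx,
           " sites than the denominator ", d)
    }
    tab <- table(k_per_clone)
    data.frame(context = ctx, k = as.integer(names(tab)), denominator = d,
               m = as.integer(tab), stringsAsFactors = FALSE)
  }))
  groups <- groups[order(match(groups$context, .CONTEXTS), groups$k), ,
                   drop = FALSE]
  rownames(groups) <- NULL
  formatted <- vapply(.CONTEXTS, function(ctx) {
    g <- groups[groups$context == ctx, , drop = FALSE]
    paste(sprintf("%d/%d in %d", g$k, g$denominator, g$m), collapse = "; ")
  }, character(1))
  structure(list(n_clones = as.integer(n_clones), groups = groups,
                 formatted = formatted),
            class = "clone_summary")
}

#' @export
print.clone_summary <- function(x, ...) {
  cat("<clone_summary> ", x$n_clones, " clones\n", sep = "")
  for (ctx in names(x$formatted)) {
    cat("  ", format(ctx, width = 6), x$formatted[[ctx]], "\n")
  }
  invisible(x)
}

#' Stable methylation sites across clones
#'
#' Positions methylated in at least `min_fraction` of the clones. The
#' default 1.0 requires every clone (a "stable" mark, as opposed to
#' "individual" marks carried by only a few clones); `min_fraction = 0`
#' degenerates to every ever-methylated site (at least one clone).
#'
#' @param calls Data.frame of calls from [call_methylation()] pooled over
#'   clones.
#' @param n_clones Total number of clones.
#' @param min_fraction Required methylated-clone fraction in `[0, 1]`.
#' @return Integer vector of 0-based positions, sorted.
#' @export
stable_sites <- function(calls, n_clones, min_fraction = 1.0) {
  stopifnot(n_clones >= 1L, min_fraction >= 0, min_fraction <= 1)
  meth <- calls[calls$status == "methylated", , drop = FALSE]
  if (nrow(meth) == 0L) return(integer(0))
  support <- tapply(meth$clone_id, meth$pos,
                    function(x) length(unique(x)))
  need <- max(1L, ceiling(min_fraction * n_clones))
  sort(as.integer(names(support)[support >= need]))
}
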