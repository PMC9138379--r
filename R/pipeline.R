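# End-to-end orchestration: islands -> PCR -> align/call -> summaries ->
# motif status -> per-site track, with every output written as
# tab-separated UTF-8 text so two runs of the same config diff clean.

#' Build a run configuration
#'
#' @param reference_fasta Path to the reference loci FASTA.
#' @param clones_fasta Path to the clone reads FASTA; each record's
#'   description must carry a `sample=<label>` key, and the clone id must
#'   contain its locus id as a prefix (`<locus>_...`).
#' @param primer_tsv Path to the primer table (see [read_primer_table()]).
#' @param motif_tsv Path to the motif catalogue; `NULL` uses the bundled
#'   one.
#' @param out_dir Output directory.
#' @param island_params An [island_params()] object.
#' @param min_identity Clone-acceptance identity threshold.
#' @param min_clones Methylated-clone support required for a motif `"+"`.
#' @param max_mismatch Mismatches tolerated per primer in in-silico PCR.
#' @param seed Seed echoed into the run log (the analysis itself is
#'   deterministic).
#' @return A list of class `run_config`.
#' @export
run_config <- function(reference_fasta, clones_fasta, primer_tsv,
                       motif_tsv = NULL, out_dir = "clonemeth_run",
                       island_params = cloneMeth::island_params(),
                       min_identity = 0.9, min_clones = 1L,
                       max_mismatch = 0L, seed = 1L) {
  for (p in c(reference_fasta, clones_fasta, primer_tsv, motif_tsv)) {
    if (!is.null(p) && !file.exists(p)) stop("input path not found: ", p)
  }
  structure(list(reference_fasta = reference_fasta,
                 clones_fasta = clones_fasta, primer_tsv = primer_tsv,
                 motif_tsv = motif_tsv, out_dir = out_dir,
                 island_params = island_params,
                 min_identity = min_identity,
                 min_clones = as.integer(min_clones),
                 max_mismatch = as.integer(max_mismatch),
                 seed = as.integer(seed)),
            class = "run_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  path
}

# pick, for a clone read, the amplicon whose length it fits best
.match_amplicon <- function(read, amplicons, max_len_dev = 0.2) {
  lens <- vapply(amplicons, function(a) a$product_bp, numeric(1))
  dev <- abs(nchar(read$sequence) / lens - 1)
  if (min(dev) > max_len_dev) {
    stop("clone '", read$id, "' (", nchar(read$sequence),
         " bp) fits no amplicon (products: ",
         paste(lens, collapse = ", "), ")")
  }
  amplicons[[which.min(dev)]]
}

#' Run the full clone-based methylation pipeline
#'
#' Executes, per locus: CpG-island prediction, in-silico PCR of every
#' primer pair for that locus, bisulfite-aware alignment and methylation
#' calling of every clone, colony-style summaries per sample, motif
#' scanning with per-sample methylation status, and a per-site track.
#'
#' Outputs written to `config$out_dir`:
#' `islands.bed`, `islands.tsv`, `amplicons.tsv`, `calls.tsv`,
#' `summary.tsv` (one "k/D in m" cell per context), `summary_long.tsv`
#' (tidy groups), `motif_status.tsv`, `sites.bed`, `track.txt`,
#' `run_log.txt`.
#'
#' @param config A [run_config()].
#' @return Named character vector of output paths, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  loci <- stage("read_reference", read_fasta(config$reference_fasta))
  names(loci) <- vapply(loci, function(x) x$id, character(1))
  reads <- stage("read_clones", read_clone_fasta(config$clones_fasta))
  pairs <- stage("read_primers", read_primer_table(config$primer_tsv))
  motifs <- stage("read_motifs", if (is.null(config$motif_tsv)) {
    builtin_motif_catalog()
  } else {
    load_motif_table(config$motif_tsv)
  })

  islands <- stage("islands", do.call(rbind, lapply(loci, function(lc) {
    find_cpg_islands(lc, config$island_params)
  })))
  rownames(islands) <- NULL

  amplicons <- stage("pcr", {
    res <- list()
    for (pp in pairs) {
      if (!pp$gene %in% names(loci)) next
      amp <- in_silico_pcr(pp, loci[[pp$gene]], config$max_mismatch)
      res[[length(res) + 1L]] <- amp
    }
    res
  })
  amp_by_locus <- split(amplicons,
                        vapply(amplicons, function(a) a$locus_id,
                               character(1)))
  amp_df <- do.call(rbind, lapply(amplicons, function(a) {
    data.frame(locus = a$locus_id, start = a$start, end = a$end,
               product_bp = a$product_bp, expected_bp = a$expected_bp,
               stringsAsFactors = FALSE)
  }))

  calls <- stage("align_call", {
    out <- list()
    for (rd in reads) {
      locus_id <- names(loci)[startsWith(rd$id, names(loci))]
      if (length(locus_id) == 0L) {
        stop("clone '", rd$id, "' matches no reference locus id")
      }
      locus_id <- locus_id[which.max(nchar(locus_id))]
      amp <- .match_amplicon(rd, amp_by_locus[[locus_id]])
      aln <- align_clone(rd, loci[[locus_id]], amp,
                         min_identity = config$min_identity)
      out[[length(out) + 1L]] <- call_methylation(aln, loci[[locus_id]])
    }
    do.call(rbind, out)
  })

  summaries <- stage("summarize", {
    rows <- list()
    long <- list()
    for (locus_id in unique(calls$locus)) {
      counts <- count_potential_sites(loci[[locus_id]],
                                      amp_by_locus[[locus_id]])
      lc_calls <- calls[calls$locus == locus_id, , drop = FALSE]
      for (smp in sort(unique(lc_calls$sample))) {
        sc <- lc_calls[lc_calls$sample == smp, , drop = FALSE]
        n <- length(unique(sc$clone_id))
        sm <- summarize_clones(sc, counts, n)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = locus_id, tissue = smp,
          CpG = sm$formatted[["CpG"]], CpHpG = sm$formatted[["CpHpG"]],
          CpHpH = sm$formatted[["CpHpH"]], n_clones = n,
          stringsAsFactors = FALSE)
        gl <- sm$groups
        gl$gene <- locus_id
        gl$tissue <- smp
        long[[length(long) + 1L]] <- gl
      }
    }
    list(wide = do.call(rbind, rows), long = do.call(rbind, long))
  })

  motif_status <- stage("motifs", {
    out <- list()
    for (locus_id in unique(calls$locus)) {
      inst <- scan_motifs(loci[[locus_id]], motifs)
      if (nrow(inst) == 0L) next
      out[[length(out) + 1L]] <- motif_methylation_status(
        inst, calls[calls$locus == locus_id, , drop = FALSE],
        min_clones = config$min_clones)
    }
    do.call(rbind, out)
  })

  track <- stage("track", {
    out_bed <- list()
    out_txt <- character(0)
    for (locus_id in unique(calls$locus)) {
      inst <- if (!is.null(motif_status)) {
        motif_status[motif_status$locus == locus_id, , drop = FALSE]
      } else NULL
      tr <- render_track(calls[calls$locus == locus_id, , drop = FALSE],
                         islands[islands$locus == locus_id, , drop = FALSE],
                         inst, loci[[locus_id]],
                         amp_by_locus[[locus_id]])
      out_bed[[length(out_bed) + 1L]] <- tr$bed
      out_txt <- c(out_txt, tr$text)
    }
    list(bed = do.call(rbind, out_bed), text = out_txt)
  })

  paths <- c(islands_bed = file.path(config$out_dir, "islands.bed"),
             islands = file.path(config$out_dir, "islands.tsv"),
             amplicons = file.path(config$out_dir, "amplicons.tsv"),
             calls = file.path(config$out_dir, "calls.tsv"),
             summary = file.path(config$out_dir, "summary.tsv"),
             summary_long = file.path(config$out_dir, "summary_long.tsv"),
             motif_status = file.path(config$out_dir, "motif_status.tsv"),
             sites_bed = file.path(config$out_dir, "sites.bed"),
             track = file.path(config$out_dir, "track.txt"),
             log = file.path(config$out_dir, "run_log.txt"))
  islands_to_bed(islands, paths[["islands_bed"]])
  .write_tsv(islands, paths[["islands"]])
  .write_tsv(amp_df, paths[["amplicons"]])
  .write_tsv(calls, paths[["calls"]])
  .write_tsv(summaries$wide, paths[["summary"]])
  .write_tsv(summaries$long, paths[["summary_long"]])
  .write_tsv(motif_status, paths[["motif_status"]])
  write_bed(track$bed, paths[["sites_bed"]])
  writeLines(track$text, paths[["track"]])
  writeLines(c(
    paste0("cloneMeth version: ",
           as.character(utils::packageVersion("cloneMeth"))),
    paste0("seed: ", config$seed),
    paste0("min_identity: ", config$min_identity),
    paste0("min_clones: ", config$min_clones),
    paste0("island window/step/min_length/min_gc/min_obs_exp: ",
           paste(config$island_params$window, config$island_params$step,
                 config$island_params$min_length, config$island_params$min_gc,
                 config$island_params$min_obs_exp, sep = "/")),
    paste0("reference: ", config$reference_fasta),
    paste0("clones: ", config$clones_fasta),
    paste0("primers: ", config$primer_tsv),
    paste0("motifs: ", if (is.null(config$motif_tsv)) "builtin"
           else config$motif_tsv)
  ), paths[["log"]])
  invisible(paths)
}

#' Render a per-site methylation track
#'
#' One BED record per potential cytosine site of the callable region, with
#' the name column encoding `context|predicted|detected` where `predicted`
#' is 1 when the site lies inside a predicted CpG island (the "predicted
#' methylation" strokes of a lollipop figure) and `detected` is `CpG`,
#' `nonCpG` or `0`; the score column carries the methylated-clone support
#' (summed over samples' maxima). A text lollipop line per sample marks
#' each site `.` (unmethylated), `*` (methylated CpG) or `o` (methylated
#' non-CpG, the non-canonical marks).
#'
#' @param calls Calls for one locus (all samples pooled).
#' @param islands Island data.frame for the locus.
#' @param instances Motif-status rows for the locus (may be `NULL`; only
#'   used for the run log, not the track itself).
#' @param locus The [reference_locus()].
#' @param amplicons List of amplicons for the locus.
#' @return List with `bed` (data.frame) and `text` (character lines).
#' @export
render_track <- function(calls, islands, instances, locus, amplicons) {
  locus <- .as_locus(locus)
  counts <- count_potential_sites(locus, amplicons)
  sites <- counts$sites
  in_island <- function(p) {
    nrow(islands) > 0L && any(p >= islands$start & p < islands$end)
  }
  samples <- sort(unique(calls$sample))
  support <- matrix(0L, nrow = nrow(sites), ncol = length(samples),
                    dimnames = list(NULL, samples))
  for (si in seq_along(samples)) {
    sub <- calls[calls$sample == samples[si] &
                   calls$status == "methylated", , drop = FALSE]
    if (nrow(sub) == 0L) next
    tab <- tapply(sub$clone_id, sub$pos, function(x) length(unique(x)))
    idx <- match(sites$pos, as.integer(names(tab)))
    got <- !is.na(idx)
    support[got, si] <- as.integer(tab[idx[got]])
  }
  total_support <- if (ncol(support) > 0L) {
    as.integer(rowSums(support))
  } else {
    integer(nrow(sites))
  }
  predicted <- vapply(sites$pos, in_island, logical(1))
  detected <- ifelse(total_support == 0L, "0",
                     ifelse(sites$context == "CpG", "CpG", "nonCpG"))
  bed <- data.frame(
    chrom = locus$id,
    start = sites$pos,
    end = sites$pos + 1L,
    name = paste(sites$context, as.integer(predicted), detected,
                 sep = "|"),
    score = total_support,
    strand = "+",
    stringsAsFactors = FALSE)
  text <- character(0)
  for (si in seq_along(samples)) {
    glyphs <- ifelse(support[, si] == 0L, ".",
                     ifelse(sites$context == "CpG", "*", "o"))
    text <- c(text,
              sprintf("%s %s [%d sites] %s", locus$id, samples[si],
                      nrow(sites), paste(glyphs, collapse = "")))
  }
  list(bed = bed, text = text)
}
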