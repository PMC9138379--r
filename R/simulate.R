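# Synthetic data with the statistical structure of a clone-based bisulfite
# promoter study: a GC-structured reference with planted CpG islands and
# planted cis-elements, a per-tissue methylome with context-dependent rates,
# and cloned reads produced by imperfect bisulfite conversion plus Sanger
# sequencing error. Everything is a pure function of (params, seed).

#' Simulation parameters
#'
#' Defaults mirror a typical clone-based promoter assay of a wheat
#' flavonoid-pathway gene: a ~1.6 kb analysed region (promoter plus the 5'
#' gene body) with two CpG islands, two tissues sampled at 10 clones each,
#' CpG >> CpHpG > CpHpH methylation rates in the methylated tissue, high
#' bisulfite conversion efficiency and a small Sanger per-base error rate.
#'
#' @param locus_length Reference length in bp.
#' @param background_gc G+C fraction of the non-island background.
#' @param islands List of island specs, each a list with `start`, `length`,
#'   `gc` and `obs_exp` (minimum targets for rejection sampling).
#' @param planted_motifs List of specs, each a list with `name`, `pattern`
#'   (IUPAC), `start`, and optional `strand` (`"+"`/`"-"`).
#' @param methylation_rates Named list per tissue of named numeric vectors
#'   with entries `CpG`, `CpHpG`, `CpHpH` (per-site probabilities).
#' @param n_clones Clones sequenced per tissue.
#' @param conversion_efficiency Bisulfite conversion efficiency.
#' @param sequencing_error Per-base substitution error probability.
#' @param amplicon_start,amplicon_length Region assayed by the simulated
#'   primer pair (primers are taken from the converted reference at the
#'   region's ends).
#' @param primer_length Length of each simulated primer.
#' @param seed Integer seed reproducing every stochastic output.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(locus_length = 1600L,
                       background_gc = 0.44,
                       islands = list(
                         list(start = 350L, length = 250L,
                              gc = 0.55, obs_exp = 0.65),
                         list(start = 900L, length = 300L,
                              gc = 0.55, obs_exp = 0.65)),
                       planted_motifs = list(
                         list(name = "MYBCORE", pattern = "CNGTTR",
                              start = 420L, strand = "+"),
                         list(name = "GATABOX", pattern = "GATA",
                              start = 620L, strand = "+"),
                         list(name = "CBFHV", pattern = "RYCGAC",
                              start = 960L, strand = "+")),
                       methylation_rates = list(
                         coleoptile = c(CpG = 0, CpHpG = 0, CpHpH = 0),
                         root = c(CpG = 0.14, CpHpG = 0.048,
                                  CpHpH = 0.0085)),
                       n_clones = 10L,
                       conversion_efficiency = 0.99,
                       sequencing_error = 0.001,
                       amplicon_start = 320L,
                       amplicon_length = 420L,
                       primer_length = 28L,
                       seed = 1L) {
  params <- list(locus_length = as.integer(locus_length),
                 background_gc = background_gc, islands = islands,
                 planted_motifs = planted_motifs,
                 methylation_rates = methylation_rates,
                 n_clones = as.integer(n_clones),
                 conversion_efficiency = conversion_efficiency,
                 sequencing_error = sequencing_error,
                 amplicon_start = as.integer(amplicon_start),
                 amplicon_length = as.integer(amplicon_length),
                 primer_length = as.integer(primer_length),
                 seed = as.integer(seed))
  stopifnot(locus_length >= 200L,
            background_gc >= 0, background_gc <= 1,
            conversion_efficiency >= 0, conversion_efficiency <= 1,
            sequencing_error >= 0, sequencing_error < 1,
            n_clones >= 1L,
            amplicon_start >= 0L,
            amplicon_start + amplicon_length <= locus_length,
            primer_length >= 15L)
  for (tissue in names(methylation_rates)) {
    r <- methylation_rates[[tissue]]
    stopifnot(all(c("CpG", "CpHpG", "CpHpH") %in% names(r)),
              all(r >= 0), all(r <= 1))
  }
  for (isl in islands) {
    stopifnot(isl$start >= 0, isl$start + isl$length <= locus_length)
  }
  for (pm in planted_motifs) {
    stopifnot(pm$start >= 0,
              pm$start + nchar(pm$pattern) <= locus_length)
  }
  structure(params, class = "sim_params")
}

# Draw an island-like segment: iid bases at the island GC, with extra CG
# dinucleotides stitched in to raise the observed/expected ratio.
.draw_island_segment <- function(len, gc_target, oe_target) {
  p_cg_step <- min(0.35, oe_target * gc_target^2 / 2 + 0.05)
  out <- character(0)
  n <- 0L
  while (n < len) {
    if (stats::runif(1) < p_cg_step && n + 2L <= len) {
      out <- c(out, "C", "G"); n <- n + 2L
    } else {
      b <- sample(c("G", "C", "A", "T"), 1L,
                  prob = c(gc_target / 2, gc_target / 2,
                           (1 - gc_target) / 2, (1 - gc_target) / 2))
      out <- c(out, b); n <- n + 1L
    }
  }
  paste(out[seq_len(len)], collapse = "")
}

#' Generate a synthetic reference locus with planted islands and motifs
#'
#' Background bases are drawn iid at `background_gc`; each island segment is
#' rejection-sampled until it meets its GC and observed/expected targets
#' (checked with [gc_fraction()] / [obs_exp_cpg()]); planted motif letters
#' are stamped last, with degenerate codes resolved uniformly. Fully
#' deterministic per `(params, seed)`.
#'
#' @param params A [sim_params()] object.
#' @param id Locus id.
#' @param max_tries Rejection-sampling budget per island.
#' @return A list: `locus` ([reference_locus()]), `islands` (data.frame of
#'   planted intervals with realized `gc`, `obs_exp`), `motifs` (data.frame
#'   of planted instances).
#' @export
generate_reference <- function(params, id = "synthetic_locus",
                               max_tries = 500L) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(params$seed, {
    gc <- params$background_gc
    chars <- sample(c("G", "C", "A", "T"), params$locus_length,
                    replace = TRUE,
                    prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
    islands <- do.call(rbind, lapply(params$islands, function(isl) {
      seg <- NULL
      for (i in seq_len(max_tries)) {
        cand <- .draw_island_segment(isl$length, isl$gc, isl$obs_exp)
        if (gc_fraction(cand) >= isl$gc &&
            obs_exp_cpg(cand) >= isl$obs_exp) { seg <- cand; break }
      }
      if (is.null(seg)) {
        stop("island spec infeasible after ", max_tries,
             " tries: gc>=", isl$gc, ", obs_exp>=", isl$obs_exp)
      }
      chars[(isl$start + 1L):(isl$start + isl$length)] <<-
        strsplit(seg, "", fixed = TRUE)[[1]]
      data.frame(start = isl$start, end = isl$start + isl$length,
                 gc = gc_fraction(seg), obs_exp = obs_exp_cpg(seg))
    }))
    motifs <- do.call(rbind, lapply(params$planted_motifs, function(pm) {
      strand <- if (is.null(pm$strand)) "+" else pm$strand
      word <- paste(vapply(
        strsplit(toupper(pm$pattern), "", fixed = TRUE)[[1]],
        function(code) {
          exp <- IUPAC_EXPANSION[[code]]
          if (is.null(exp)) stop("invalid IUPAC code in planted motif: ",
                                 pm$pattern)
          if (length(exp) == 1L) exp else sample(exp, 1L)
        }, character(1)), collapse = "")
      stamped <- if (strand == "-") revcomp(word) else word
      w <- nchar(stamped)
      chars[(pm$start + 1L):(pm$start + w)] <<-
        strsplit(stamped, "", fixed = TRUE)[[1]]
      data.frame(name = pm$name, pattern = toupper(pm$pattern),
                 start = pm$start, end = pm$start + w, strand = strand,
                 stringsAsFactors = FALSE)
    }))
    locus <- reference_locus(id, paste(chars, collapse = ""),
                             source = "synthetic")
    list(locus = locus, islands = islands, motifs = motifs)
  })
}

#' Generate a tissue methylome with context-dependent rates
#'
#' Each top-strand cytosine is methylated independently with the probability
#' of its context; ambiguous-context cytosines are never methylated.
#'
#' @param locus A [reference_locus()].
#' @param rates Named numeric vector with entries `CpG`, `CpHpG`, `CpHpH`.
#' @param tissue Tissue label stored on the profile.
#' @param seed Integer seed.
#' @return A [methylation_profile()].
#' @export
generate_methylome <- function(locus, rates, tissue, seed) {
  locus <- .as_locus(locus)
  stopifnot(all(c("CpG", "CpHpG", "CpHpH") %in% names(rates)))
  pos <- c_positions(locus)
  context <- classify_context(locus, pos)
  p <- ifelse(context == "ambiguous", 0, as.numeric(rates[context]))
  meth <- withr::with_seed(seed, stats::runif(length(pos)) < p)
  methylation_profile(locus, pos[meth], tissue = tissue)
}

#' Simulate cloned bisulfite reads for one amplicon
#'
#' Each clone is an independent bisulfite conversion of the amplicon region
#' under the tissue methylome (unmethylated C -> T with probability
#' `efficiency`), followed by independent per-base substitution errors at
#' `error_rate` (a hit base is replaced by one of the three other bases,
#' uniformly).
#'
#' @param locus A [reference_locus()].
#' @param amplicon An `amplicon` on the locus.
#' @param profile A [methylation_profile()] for the locus.
#' @param n_clones Number of clones.
#' @param efficiency Conversion efficiency.
#' @param error_rate Per-base sequencing error probability.
#' @param seed Integer seed.
#' @param sample Sample label for the reads (defaults to the profile
#'   tissue).
#' @return List of [clone_read()] objects.
#' @export
simulate_clones <- function(locus, amplicon, profile, n_clones = 10L,
                            efficiency = 0.99, error_rate = 0.001, seed = 1L,
                            sample = profile$tissue) {
  locus <- .as_locus(locus)
  stopifnot(inherits(amplicon, "amplicon"),
            inherits(profile, "methylation_profile"))
  region_chars <- strsplit(subseq0(locus, amplicon$start, amplicon$end),
                           "", fixed = TRUE)[[1]]
  mask <- logical(length(region_chars))
  mpos <- methylated_positions(profile)
  inside <- mpos[mpos >= amplicon$start & mpos < amplicon$end]
  mask[inside - amplicon$start + 1L] <- TRUE
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    lapply(seq_len(n_clones), function(i) {
      chars <- .convert_chars(region_chars, mask, efficiency)
      if (error_rate > 0) {
        hit <- which(stats::runif(length(chars)) < error_rate)
        for (j in hit) {
          chars[j] <- sample(setdiff(bases, chars[j]), 1L)
        }
      }
      clone_read(sprintf("%s_%s_clone%02d", locus$id,
                         ifelse(is.na(sample), "sample", sample), i),
                 paste(chars, collapse = ""), sample = sample)
    })
  })
}

# Derive a unique primer pair for the configured amplicon region from the
# fully-converted reference, the way bisulfite primers are designed.
.design_sim_primers <- function(locus, params) {
  conv <- converted_reference(locus)
  a <- params$amplicon_start
  b <- params$amplicon_start + params$amplicon_length
  k <- params$primer_length
  fwd <- substr(conv, a + 1L, a + k)
  rev <- revcomp(substr(conv, b - k + 1L, b))
  primer_pair(fwd, rev, expected_bp = b - a, gene = locus$id)
}

#' Run a full recovery experiment against simulated truth
#'
#' Generates a reference, designs primers on the converted template, runs
#' in-silico PCR, simulates clone reads for every tissue, aligns and calls
#' each clone, and compares calls with the simulated truth on the callable
#' region (amplicon minus primer footprints, ambiguous contexts excluded).
#'
#' Sensitivity and specificity are call-level: over all (clone, site) pairs
#' whose site is truly methylated (resp. unmethylated), the fraction called
#' methylated (resp. unmethylated); uncallable calls count against both.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `recovery_report`: `overall` and `per_context`
#'   sensitivity/specificity (pooled over tissues), `per_tissue` data.frame,
#'   `denominator_match` (logical: [count_potential_sites()] equals the
#'   truth enumeration), `counts` (the `context_counts`), `amplicon`,
#'   `truth` (profiles per tissue), `calls` (all calls), `locus`.
#' @export
recovery_experiment <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  ref <- generate_reference(params)
  locus <- ref$locus
  pair <- .design_sim_primers(locus, params)
  amp <- in_silico_pcr(pair, locus)
  counts <- count_potential_sites(locus, list(amp))

  tissues <- names(params$methylation_rates)
  profiles <- list()
  all_calls <- list()
  for (ti in seq_along(tissues)) {
    tissue <- tissues[ti]
    profile <- generate_methylome(locus, params$methylation_rates[[tissue]],
                                  tissue, seed = params$seed + ti)
    profiles[[tissue]] <- profile
    reads <- simulate_clones(locus, amp, profile,
                             n_clones = params$n_clones,
                             efficiency = params$conversion_efficiency,
                             error_rate = params$sequencing_error,
                             seed = params$seed + 100L + ti,
                             sample = tissue)
    for (rd in reads) {
      aln <- align_clone(rd, locus, amp)
      all_calls[[length(all_calls) + 1L]] <- call_methylation(aln, locus)
    }
  }
  calls <- do.call(rbind, all_calls)

  truth_state <- function(tissue, pos) {
    pos %in% methylated_positions(profiles[[tissue]])
  }
  calls$truth <- mapply(truth_state, calls$sample, calls$pos)

  rate_block <- function(sub) {
    pos_meth <- sub$truth
    sens <- if (any(pos_meth)) {
      mean(sub$status[pos_meth] == "methylated")
    } else NA_real_
    spec <- if (any(!pos_meth)) {
      mean(sub$status[!pos_meth] == "unmethylated")
    } else NA_real_
    c(sensitivity = sens, specificity = spec)
  }
  overall <- rate_block(calls)
  per_context <- do.call(rbind, lapply(.CONTEXTS, function(ctx) {
    data.frame(context = ctx,
               t(rate_block(calls[calls$context == ctx, , drop = FALSE])),
               stringsAsFactors = FALSE)
  }))
  per_tissue <- do.call(rbind, lapply(tissues, function(tissue) {
    data.frame(tissue = tissue,
               t(rate_block(calls[calls$sample == tissue, , drop = FALSE])),
               stringsAsFactors = FALSE)
  }))

  # denominators must equal a direct enumeration of truth sites and be
  # independent of the methylation profile
  region <- callable_region(amp)
  all_c <- c_positions(locus)
  region_c <- all_c[all_c >= region[1] & all_c < region[2]]
  truth_ctx <- classify_context(locus, region_c)
  truth_counts <- table(factor(truth_ctx[truth_ctx != "ambiguous"],
                               levels = .CONTEXTS))
  denominator_match <-
    counts$CpG == truth_counts[["CpG"]] &&
    counts$CpHpG == truth_counts[["CpHpG"]] &&
    counts$CpHpH == truth_counts[["CpHpH"]]

  structure(list(overall = overall, per_context = per_context,
                 per_tissue = per_tissue,
                 denominator_match = denominator_match,
                 counts = counts, amplicon = amp, truth = profiles,
                 calls = calls, locus = locus, params = params),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  cat(sprintf("  overall sensitivity %.4f, specificity %.4f\n",
              x$overall[["sensitivity"]], x$overall[["specificity"]]))
  cat("  denominators match truth:", x$denominator_match, "\n")
  print(x$per_context)
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes the reference FASTA, one clones FASTA per tissue (with `sample=`
#' description keys), a truth TSV (position, context, tissue, state), and a
#' YAML echo of the parameters.
#'
#' @param params A [sim_params()] object.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulated_dataset <- function(params, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- generate_reference(params)
  locus <- ref$locus
  pair <- .design_sim_primers(locus, params)
  amp <- in_silico_pcr(pair, locus)
  paths <- c(reference = file.path(out_dir, "reference.fa"),
             clones = file.path(out_dir, "clones.fa"),
             truth = file.path(out_dir, "truth.tsv"),
             primers = file.path(out_dir, "primers.tsv"),
             params = file.path(out_dir, "params.yaml"))
  write_fasta(list(locus), paths[["reference"]])

  tissues <- names(params$methylation_rates)
  truth_rows <- list()
  clone_records <- list()
  for (ti in seq_along(tissues)) {
    tissue <- tissues[ti]
    profile <- generate_methylome(locus, params$methylation_rates[[tissue]],
                                  tissue, seed = params$seed + ti)
    pos <- profile$pos
    truth_rows[[tissue]] <- data.frame(
      locus = locus$id, pos = pos,
      context = classify_context(locus, pos),
      tissue = tissue,
      state = ifelse(profile$methylated, "methylated", "unmethylated"),
      stringsAsFactors = FALSE)
    reads <- simulate_clones(locus, amp, profile,
                             n_clones = params$n_clones,
                             efficiency = params$conversion_efficiency,
                             error_rate = params$sequencing_error,
                             seed = params$seed + 100L + ti,
                             sample = tissue)
    clone_records <- c(clone_records, lapply(reads, function(r) {
      list(id = r$id, sequence = r$sequence,
           description = paste0("sample=", r$sample))
    }))
  }
  write_fasta(clone_records, paths[["clones"]])
  utils::write.table(do.call(rbind, truth_rows), paths[["truth"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = locus$id, forward = pair$forward,
               reverse = pair$reverse, expected_bp = pair$expected_bp,
               annealing_c = NA),
    paths[["primers"]], sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(
    params[setdiff(names(params), c("islands", "planted_motifs",
                                    "methylation_rates"))],
    paths[["params"]])
  invisible(paths)
}
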