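test_that("reference generation is deterministic and plants its features", {
  p <- sim_params(seed = 5)
  ref1 <- generate_reference(p)
  ref2 <- generate_reference(p)
  expect_equal(ref1$locus$sequence, ref2$locus$sequence)
  expect_equal(locus_length(ref1$locus), p$locus_length)
  # a different seed changes the sequence
  ref3 <- generate_reference(sim_params(seed = 6))
  expect_false(ref1$locus$sequence == ref3$locus$sequence)
  # planted motifs are present at their coordinates
  for (i in seq_len(nrow(ref1$motifs))) {
    win <- subseq0(ref1$locus, ref1$motifs$start[i], ref1$motifs$end[i])
    if (ref1$motifs$strand[i] == "-") win <- revcomp(win)
    expect_true(iupac_match(ref1$motifs$pattern[i], win))
  }
  # island detection recovers at least one island overlapping each planted
  isl <- find_cpg_islands(ref1$locus)
  for (i in seq_len(nrow(ref1$islands))) {
    expect_true(any(isl$start < ref1$islands$end[i] &
                      isl$end > ref1$islands$start[i]))
  }
})

test_that("an AT-rich background with no islands yields none", {
  p <- sim_params(background_gc = 0.25, islands = list(),
                  planted_motifs = list(), seed = 8)
  ref <- generate_reference(p)
  expect_equal(nrow(find_cpg_islands(ref$locus)), 0)
})

test_that("infeasible island targets raise a feasibility error", {
  p <- sim_params(islands = list(list(start = 100L, length = 120L,
                                      gc = 0.99, obs_exp = 3.9)), seed = 2)
  expect_error(generate_reference(p, max_tries = 5L), "infeasible")
})

test_that("methylomes follow per-context rates", {
  p <- sim_params(seed = 10)
  lc <- generate_reference(p)$locus
  # degenerate rates: all CpG, nothing else
  prof <- generate_methylome(lc, c(CpG = 1, CpHpG = 0, CpHpH = 0),
                             "root", seed = 3)
  pos <- methylated_positions(prof)
  expect_true(all(classify_context(lc, pos) == "CpG"))
  cpos <- c_positions(lc)
  all_cpg <- cpos[classify_context(lc, cpos) == "CpG"]
  expect_setequal(pos, all_cpg)
  # all-zero rates: empty methylome
  empty <- generate_methylome(lc, c(CpG = 0, CpHpG = 0, CpHpH = 0),
                              "x", seed = 3)
  expect_length(methylated_positions(empty), 0)
})

test_that("methylated counts fall in the binomial envelope", {
  lc <- reference_locus("cgs", strrep("CGAT", 1000))  # 1000 CpG cytosines
  prof <- generate_methylome(lc, c(CpG = 0.3, CpHpG = 0, CpHpH = 0),
                             "root", seed = 17)
  k <- length(methylated_positions(prof))
  expect_gte(k, qbinom(0.005, 1000, 0.3))
  expect_lte(k, qbinom(0.995, 1000, 0.3))
})

test_that("clone simulation is deterministic and sized correctly", {
  p <- sim_params(seed = 12)
  ref <- generate_reference(p)
  pair <- cloneMeth:::.design_sim_primers(ref$locus, p)
  amp <- in_silico_pcr(pair, ref$locus)
  prof <- generate_methylome(ref$locus, p$methylation_rates$root, "root",
                             seed = 13)
  reads <- simulate_clones(ref$locus, amp, prof, n_clones = 10,
                           efficiency = 1, error_rate = 0, seed = 14)
  expect_length(reads, 10)
  # lossless regime: all clones identical to deterministic conversion
  seqs <- vapply(reads, function(r) r$sequence, character(1))
  expect_equal(length(unique(seqs)), 1)
  det <- substr(convert_bisulfite(ref$locus, prof, efficiency = 1),
                amp$start + 1L, amp$end)
  expect_equal(seqs[[1]], det)
  # same seed reproduces bit-for-bit, different seed does not
  reads2 <- simulate_clones(ref$locus, amp, prof, n_clones = 10,
                            efficiency = 0.95, error_rate = 0.01, seed = 14)
  reads3 <- simulate_clones(ref$locus, amp, prof, n_clones = 10,
                            efficiency = 0.95, error_rate = 0.01, seed = 14)
  expect_equal(vapply(reads2, function(r) r$sequence, character(1)),
               vapply(reads3, function(r) r$sequence, character(1)))
})

test_that("sequencing errors accumulate at the binomial-expected rate", {
  p <- sim_params(seed = 20)
  ref <- generate_reference(p)
  pair <- cloneMeth:::.design_sim_primers(ref$locus, p)
  amp <- in_silico_pcr(pair, ref$locus)
  prof <- generate_methylome(ref$locus, p$methylation_rates$root, "root",
                             seed = 21)
  clean <- simulate_clones(ref$locus, amp, prof, n_clones = 10,
                           efficiency = 1, error_rate = 0, seed = 22)
  noisy <- simulate_clones(ref$locus, amp, prof, n_clones = 10,
                           efficiency = 1, error_rate = 0.01, seed = 22)
  total_mismatch <- sum(vapply(seq_len(10), function(i) {
    a <- strsplit(clean[[i]]$sequence, "", fixed = TRUE)[[1]]
    b <- strsplit(noisy[[i]]$sequence, "", fixed = TRUE)[[1]]
    sum(a != b)
  }, numeric(1)))
  n <- nchar(clean[[1]]$sequence) * 10
  expect_gte(total_mismatch, qbinom(0.005, n, 0.01))
  expect_lte(total_mismatch, qbinom(0.995, n, 0.01))
})

test_that("the recovery experiment is lossless at perfect settings", {
  rep <- recovery_experiment(sim_params(conversion_efficiency = 1,
                                        sequencing_error = 0, seed = 31))
  expect_equal(unname(rep$overall[["sensitivity"]]), 1.0)
  expect_equal(unname(rep$overall[["specificity"]]), 1.0)
  expect_true(rep$denominator_match)
})

test_that("denominators do not depend on the methylation profile", {
  for (seed in c(41, 42)) {
    p_lo <- sim_params(seed = seed)
    p_hi <- sim_params(methylation_rates = list(
      root = c(CpG = 0.9, CpHpG = 0.5, CpHpH = 0.3)), seed = seed)
    r_lo <- recovery_experiment(p_lo)
    r_hi <- recovery_experiment(p_hi)
    expect_equal(r_lo$counts$CpG, r_hi$counts$CpG)
    expect_equal(r_lo$counts$CpHpG, r_hi$counts$CpHpG)
    expect_equal(r_lo$counts$CpHpH, r_hi$counts$CpHpH)
    expect_true(r_lo$denominator_match)
    expect_true(r_hi$denominator_match)
  }
})

test_that("simulated datasets round-trip through disk", {
  out <- file.path(tempdir(), "simds")
  paths <- write_simulated_dataset(sim_params(seed = 51), out)
  expect_true(all(file.exists(paths)))
  loci <- read_fasta(paths[["reference"]])
  expect_length(loci, 1)
  reads <- read_clone_fasta(paths[["clones"]])
  expect_length(reads, 20)  # 10 clones x 2 tissues
  expect_setequal(unique(vapply(reads, function(r) r$sample,
                                character(1))),
                  c("coleoptile", "root"))
  truth <- read.delim(paths[["truth"]])
  expect_true(all(c("pos", "context", "tissue", "state") %in%
                    names(truth)))
})
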