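# A small assay built by construction: a locus with a known amplicon, a
# truth methylome, and clones derived deterministically from it.
make_assay <- function(seed = 1, len = 500, meth_cpg = 3L) {
  withr::with_seed(seed, {
    lc <- reference_locus("assay", random_dna(len, gc = 0.45))
  })
  conv <- converted_reference(lc)
  pair <- primer_pair(substr(conv, 51, 75), revcomp(substr(conv, 426, 450)),
                      expected_bp = 400)
  amp <- in_silico_pcr(pair, lc)
  region <- callable_region(amp)
  cpos <- c_positions(lc)
  cpos <- cpos[cpos >= region[1] & cpos < region[2]]
  ctx <- classify_context(lc, cpos)
  planted <- head(cpos[ctx == "CpG"], meth_cpg)
  profile <- methylation_profile(lc, planted, tissue = "root")
  list(locus = lc, amplicon = amp, profile = profile, planted = planted)
}

test_that("a fully converted clone aligns cleanly and calls unmethylated", {
  a <- make_assay()
  read_seq <- convert_bisulfite(
    reference_locus("amp", subseq0(a$locus, a$amplicon$start,
                                   a$amplicon$end)),
    methylation_profile(reference_locus(
      "amp", subseq0(a$locus, a$amplicon$start, a$amplicon$end))),
    efficiency = 1)
  rd <- clone_read("assay_c1", read_seq, sample = "root")
  aln <- align_clone(rd, a$locus, a$amplicon)
  expect_equal(aln$mismatches, 0)
  expect_equal(aln$gaps, 0)
  calls <- call_methylation(aln, a$locus)
  expect_true(all(calls$status == "unmethylated"))
})

test_that("retained 5mC reads as C/C with zero non-bisulfite mismatches", {
  a <- make_assay(seed = 5)
  read_seq <- substr(convert_bisulfite(a$locus, a$profile, efficiency = 1),
                     a$amplicon$start + 1L, a$amplicon$end)
  rd <- clone_read("assay_c2", read_seq, sample = "root")
  aln <- align_clone(rd, a$locus, a$amplicon)
  expect_equal(aln$mismatches, 0)
  calls <- call_methylation(aln, a$locus)
  meth <- calls[calls$status == "methylated", ]
  expect_setequal(meth$pos, a$planted)
  expect_true(all(meth$context == "CpG"))
  expect_true(all(calls$status[!calls$pos %in% a$planted] ==
                    "unmethylated"))
})

test_that("a single substitution error counts as one mismatch", {
  a <- make_assay(seed = 9)
  read_seq <- substr(convert_bisulfite(a$locus, a$profile, efficiency = 1),
                     a$amplicon$start + 1L, a$amplicon$end)
  # force an A -> G error away from any cytosine site
  chars <- strsplit(read_seq, "", fixed = TRUE)[[1]]
  i <- which(chars == "A")[50]
  chars[i] <- "G"
  rd <- clone_read("assay_c3", paste(chars, collapse = ""), sample = "root")
  aln <- align_clone(rd, a$locus, a$amplicon)
  expect_equal(aln$mismatches, 1)
})

test_that("alignment agrees with direct comparison on indel-free reads", {
  for (seed in c(3, 13, 23)) {
    a <- make_assay(seed = seed)
    withr::with_seed(seed + 1000, {
      read_seq <- substr(
        convert_bisulfite(a$locus, a$profile, efficiency = 0.97),
        a$amplicon$start + 1L, a$amplicon$end)
    })
    rd <- clone_read("c", read_seq, sample = "root")
    aln <- align_clone(rd, a$locus, a$amplicon)
    expect_equal(aln$gaps, 0)
    # positional identity: column i of the alignment is read base i
    expect_equal(aln$ref_pos,
                 seq.int(a$amplicon$start, a$amplicon$end - 1L))
    expect_equal(paste(aln$read_base, collapse = ""), read_seq)
  }
})

test_that("length deviation and low identity reject the clone", {
  a <- make_assay()
  short <- clone_read("tiny", strrep("AT", 40), sample = "root")
  expect_error(align_clone(short, a$locus, a$amplicon), "deviates")
  junk <- clone_read("junk", random_dna(400, seed = 2), sample = "root")
  expect_error(align_clone(junk, a$locus, a$amplicon), "identity")
})

test_that("cytosines under primer footprints are never called", {
  a <- make_assay()
  read_seq <- substr(convert_bisulfite(a$locus, a$profile, efficiency = 1),
                     a$amplicon$start + 1L, a$amplicon$end)
  rd <- clone_read("c", read_seq, sample = "root")
  calls <- call_methylation(align_clone(rd, a$locus, a$amplicon), a$locus)
  region <- callable_region(a$amplicon)
  expect_true(all(calls$pos >= region[1] & calls$pos < region[2]))
  # at least one cytosine does lie under a primer on this locus
  cpos <- c_positions(a$locus)
  under <- cpos[(cpos >= a$amplicon$start & cpos < region[1]) |
                  (cpos >= region[2] & cpos < a$amplicon$end)]
  expect_gt(length(under), 0)
  expect_false(any(under %in% calls$pos))
})

test_that("call counts conserve the callable cytosines of the amplicon", {
  a <- make_assay(seed = 41)
  withr::with_seed(77, {
    read_seq <- substr(
      convert_bisulfite(a$locus, a$profile, efficiency = 0.95),
      a$amplicon$start + 1L, a$amplicon$end)
  })
  rd <- clone_read("c", read_seq, sample = "root")
  calls <- call_methylation(align_clone(rd, a$locus, a$amplicon), a$locus)
  region <- callable_region(a$amplicon)
  cpos <- c_positions(a$locus)
  cpos <- cpos[cpos >= region[1] & cpos < region[2]]
  expected_n <- sum(classify_context(a$locus, cpos) != "ambiguous")
  expect_equal(nrow(calls), expected_n)
  expect_equal(sum(calls$status %in%
                     c("methylated", "unmethylated", "uncallable")),
               expected_n)
})
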