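test_that("the bundled catalogue loads with valid IUPAC patterns", {
  cat <- builtin_motif_catalog()
  expect_gt(nrow(cat), 20)
  expect_true(all(nchar(cat$pattern) >= 3))
  expect_true("MYBCORE" %in% cat$name)
  expect_equal(cat$pattern[cat$name == "MYBCORE"], "CNGTTR")
  expect_equal(cat$place_id[cat$name == "GATABOX"], "S000039")
  expect_false(any(duplicated(cat$place_id)))
})

test_that("motif tables reject bad IUPAC characters and duplicates", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("name\tpattern\tfunction\tplace_id",
               "BAD\tCXGT\tnone\tS999999"), bad)
  expect_error(load_motif_table(bad), "invalid IUPAC character 'X'")

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("name\tpattern\tfunction\tplace_id",
               "M\tGATA\tf\tS1", "M\tGATA\tf\tS1"), dup)
  expect_error(load_motif_table(dup), "duplicate")

  empty <- tempfile(fileext = ".tsv")
  writeLines("name\tpattern\tfunction\tplace_id", empty)
  expect_warning(res <- load_motif_table(empty), "empty")
  expect_equal(nrow(res), 0)
})

simple_motifs <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(name = r[1], pattern = r[2], `function` = "",
               place_id = r[3], check.names = FALSE,
               stringsAsFactors = FALSE)
  }))
}

test_that("motif scanning places instances by construction", {
  lc <- reference_locus("t", "TTGATATT")
  hits <- scan_motifs(lc, simple_motifs(c("GATABOX", "GATA", "S000039")))
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1)
  expect_equal(plus$start, 2)
  expect_equal(plus$end, 6)

  # no C-containing motif can hit a C-free locus on the plus strand
  lc2 <- reference_locus("a", "AAAA")
  expect_equal(nrow(scan_motifs(
    lc2, simple_motifs(c("LTRECOREATCOR15", "CCGAC", "S000153")))), 0)

  # a reverse-complement palindrome hits both strands at one interval
  lc3 <- reference_locus("p", "GTAC")
  hits3 <- scan_motifs(lc3, simple_motifs(c("CURECORECR", "GTAC",
                                            "S000493")))
  expect_equal(nrow(hits3), 2)
  expect_setequal(hits3$strand, c("+", "-"))
  expect_equal(unique(hits3$start), 0)
  expect_equal(unique(hits3$end), 4)
})

test_that("overlapping instances of one motif are all reported", {
  lc <- reference_locus("ov", "AAAAAA")
  hits <- scan_motifs(lc, simple_motifs(c("DOFCOREZM", "AAAG", "S000265")),
                      strands = "+")
  expect_equal(nrow(hits), 0)
  lc2 <- reference_locus("ov2", "GATATA")  # GATA at 0; ATAT revcomp ATAT
  hits2 <- scan_motifs(lc2, simple_motifs(c("GATABOX", "GATA", "S000039")),
                       strands = "+")
  expect_equal(hits2$start, 0)
  lc3 <- reference_locus("ov3", "CGCGCG")
  hits3 <- scan_motifs(lc3, simple_motifs(c("X", "CGC", "S1")),
                       strands = "+")
  expect_equal(hits3$start, c(0, 2))
})

test_that("scanning agrees with full IUPAC expansion over the catalogue", {
  cat <- builtin_motif_catalog()
  lc <- random_structured_locus(991, len = 1000L)
  hits <- scan_motifs(lc, cat)
  for (i in seq_len(nrow(cat))) {
    want <- oracle_scan(lc, cat$pattern[i])
    sub <- hits[hits$name == cat$name[i] & hits$pattern == cat$pattern[i], ]
    expect_equal(sort(sub$start[sub$strand == "+"]), want$plus,
                 info = cat$name[i])
    expect_equal(sort(sub$start[sub$strand == "-"]), want$minus,
                 info = cat$name[i])
  }
})

test_that("scanning the reverse complement mirrors strands", {
  cat <- builtin_motif_catalog()
  lc <- random_structured_locus(37, len = 600L)
  rc <- reference_locus(lc$id, revcomp(lc$sequence))
  len <- locus_length(lc)
  fwd <- scan_motifs(lc, cat)
  rev <- scan_motifs(rc, cat)
  # a + hit at [s, e) on L is a - hit at [len - e, len - s) on revcomp(L)
  mirrored <- data.frame(name = rev$name,
                         start = len - rev$end, end = len - rev$start,
                         strand = ifelse(rev$strand == "+", "-", "+"))
  key <- function(df) sort(paste(df$name, df$start, df$end, df$strand))
  expect_equal(key(fwd), key(mirrored))
})

test_that("motif status turns on with methylated clones and is monotone", {
  inst <- data.frame(locus = "g", name = "MYBCORE", pattern = "CNGTTR",
                     place_id = "S000176", start = 100L, end = 106L,
                     strand = "+", stringsAsFactors = FALSE)
  calls <- rbind(
    data.frame(locus = "g", pos = 102L, context = "CpHpH",
               status = "methylated", clone_id = paste0("r", 1:3),
               sample = "root"),
    data.frame(locus = "g", pos = 102L, context = "CpHpH",
               status = "unmethylated", clone_id = paste0("k", 1:10),
               sample = "coleoptile"))
  st <- motif_methylation_status(inst, calls, min_clones = 1)
  expect_equal(st$status[st$sample == "coleoptile"], "-")
  expect_equal(st$status[st$sample == "root"], "+")
  expect_equal(st$support[st$sample == "root"], 3L)
  # raising min_clones never converts - to +
  for (mc in 1:5) {
    st_mc <- motif_methylation_status(inst, calls, min_clones = mc)
    if (mc > 3) expect_equal(st_mc$status[st_mc$sample == "root"], "-")
  }
  # unreachable threshold: everything -
  st11 <- motif_methylation_status(inst, calls, min_clones = 11)
  expect_true(all(st11$status == "-"))
  # methylation outside the instance interval never flips it
  far <- calls
  far$pos <- 500L
  st_far <- motif_methylation_status(inst, far, min_clones = 1)
  expect_true(all(st_far$status == "-"))
})
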