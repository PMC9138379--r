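# Shared fixtures and independent brute-force oracles. The oracles
# deliberately avoid the package's own code paths (no cumsum windows, no
# regex, no IRanges) so that agreement is evidence, not tautology.

random_dna <- function(n, gc = 0.5, seed = NULL) {
  draw <- function() {
    paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
                 prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
          collapse = "")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# a locus with CG-enriched chunks so island tests are non-trivial
random_structured_locus <- function(seed, len = 1500L) {
  withr::with_seed(seed, {
    base <- strsplit(random_dna(len, gc = 0.45), "", fixed = TRUE)[[1]]
    n_chunks <- sample(1:3, 1)
    for (i in seq_len(n_chunks)) {
      w <- sample(80:220, 1)
      s <- sample(1:(len - w), 1)
      chunk <- unlist(lapply(seq_len(ceiling(w / 2)), function(j) {
        if (runif(1) < 0.45) c("C", "G") else
          sample(c("G", "C", "A", "T"), 2, replace = TRUE)
      }))
      base[s:(s + w - 1L)] <- chunk[seq_len(w)]
    }
    reference_locus(paste0("rnd", seed), paste(base, collapse = ""))
  })
}

# -- island oracle: direct substring statistics for every window position
# (step 1), maximal runs of passing windows, minimum-length filter.
oracle_islands <- function(locus, params) {
  s <- locus$sequence
  len <- nchar(s)
  w <- params$window
  if (len < w) return(data.frame(start = integer(0), end = integer(0)))
  pass <- logical(len - w + 1L)
  for (st in seq_len(len - w + 1L)) {
    win <- substr(s, st, st + w - 1L)
    chars <- strsplit(win, "", fixed = TRUE)[[1]]
    inf <- sum(chars != "N")
    if (inf == 0L) next
    gc <- sum(chars %in% c("G", "C")) / inf
    nc <- sum(chars == "C"); ng <- sum(chars == "G")
    ncg <- 0L
    for (k in seq_len(w - 1L)) {
      if (chars[k] == "C" && chars[k + 1L] == "G") ncg <- ncg + 1L
    }
    oe <- if (nc > 0L && ng > 0L) ncg * w / (nc * ng) else 0
    pass[st] <- gc >= params$min_gc && oe >= params$min_obs_exp
  }
  # union the coverage of every passing window, then take maximal covered
  # runs (a different route from the interval arithmetic in the package)
  covered <- rep(FALSE, len)
  for (st in which(pass)) covered[st:(st + w - 1L)] <- TRUE
  runs <- rle(covered)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  out <- data.frame(start = starts[keep] - 1L,  # 0-based half-open
                    end = ends[keep])
  out[out$end - out$start >= params$min_length, , drop = FALSE]
}

# -- IUPAC expansion oracle: enumerate every concrete word of a pattern
expand_iupac <- function(pattern) {
  sets <- lapply(strsplit(toupper(pattern), "", fixed = TRUE)[[1]],
                 function(code) IUPAC_EXPANSION[[code]])
  words <- ""
  for (set in sets) words <- as.vector(outer(words, set, paste0))
  words
}

# all 0-based start positions of fixed word hits (overlaps allowed)
fixed_word_hits <- function(sequence, word) {
  hits <- integer(0)
  start <- 1L
  repeat {
    p <- regexpr(word, substr(sequence, start, nchar(sequence)),
                 fixed = TRUE)
    if (p == -1L) break
    hit <- start + p - 1L
    hits <- c(hits, hit - 1L)
    start <- hit + 1L
  }
  hits
}

oracle_scan <- function(locus, pattern) {
  words <- expand_iupac(pattern)
  plus <- sort(unique(unlist(lapply(words, function(wd) {
    fixed_word_hits(locus$sequence, wd)
  }))))
  w <- nchar(pattern)
  len <- nchar(locus$sequence)
  # minus strand: the top-strand window whose reverse complement is a word
  minus <- integer(0)
  for (st in 0:(len - w)) {
    win <- substr(locus$sequence, st + 1L, st + w)
    if (revcomp(win) %in% words) minus <- c(minus, st)
  }
  list(plus = plus, minus = minus)
}

# -- context oracle: direct trinucleotide inspection
oracle_contexts <- function(locus, pos0) {
  s <- locus$sequence
  len <- nchar(s)
  vapply(pos0, function(p) {
    b1 <- if (p + 2L <= len) substr(s, p + 2L, p + 2L) else "?"
    b2 <- if (p + 3L <= len) substr(s, p + 3L, p + 3L) else "?"
    if (b1 == "G") return("CpG")
    if (b1 %in% c("A", "C", "T")) {
      if (b2 == "G") return("CpHpG")
      if (b2 %in% c("A", "C", "T")) return("CpHpH")
    }
    "ambiguous"
  }, character(1))
}

# -- denominator oracle: enumerate every C in the covered set by hand
oracle_potential_sites <- function(locus, amplicons,
                                   include_primer_footprints = FALSE) {
  len <- nchar(locus$sequence)
  covered <- rep(FALSE, len)
  for (a in amplicons) {
    covered[(a$start + 1L):a$end] <- TRUE
  }
  # footprints are removed after all amplicons are painted, so a footprint
  # of one amplicon also masks the interior of an overlapping one
  if (!include_primer_footprints) {
    for (a in amplicons) {
      if (a$fwd_len > 0L) {
        covered[(a$start + 1L):(a$start + a$fwd_len)] <- FALSE
      }
      if (a$rev_len > 0L) {
        covered[(a$end - a$rev_len + 1L):a$end] <- FALSE
      }
    }
  }
  pos <- which(covered & strsplit(locus$sequence, "",
                                  fixed = TRUE)[[1]] == "C") - 1L
  ctx <- oracle_contexts(locus, pos)
  list(CpG = sum(ctx == "CpG"), CpHpG = sum(ctx == "CpHpG"),
       CpHpH = sum(ctx == "CpHpH"),
       pos = pos[ctx != "ambiguous"])
}

# write a small FASTA fixture in a temp file
tmp_fasta <- function(records) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}

# a deterministic amplicon on a locus without running PCR, for unit tests
make_amplicon <- function(locus, start, end, fwd_len = 0L, rev_len = 0L) {
  structure(list(locus_id = locus$id, start = start, end = end,
                 product_bp = end - start, expected_bp = end - start,
                 fwd_len = fwd_len, rev_len = rev_len, pair = NULL),
            class = "amplicon")
}
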