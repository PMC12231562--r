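ev <- function(contig, pos, ref, alt) {
  list(contig = contig, pos = pos, ref = ref, alt = alt)
}

test_that("junction microhomology matches worked examples", {
  # deleting AT from C[AT]ATG: the deleted bases recur 3' of the junction
  g <- c(chr1 = "CATATG")
  mh <- junction_microhomology(ev("chr1", 1L, "CAT", "C"), g)
  expect_identical(mh$mh_len, 2L)
  expect_identical(mh$mh_side, "right")

  # no shared bases between allele and flanks
  g2 <- c(chr1 = "GGGTCACCC")
  mh2 <- junction_microhomology(ev("chr1", 3L, "GTCA", "G"), g2)
  expect_identical(mh2$mh_len, 0L)
  expect_identical(mh2$mh_side, "none")

  # tandem-duplication insertion: inserted CAG next to a CAG copy
  g3 <- c(chr1 = "TTCAGTAA")
  mh3 <- junction_microhomology(ev("chr1", 2L, "T", "TCAG"), g3)
  expect_identical(mh3$mh_len, 3L)
  expect_identical(mh3$mh_side, "right")
})

test_that("homopolymer runs count deleted bases and insertion flanks", {
  expect_identical(homopolymer_run(ev("chr1", 2L, "CA", "C"),
                                   c(chr1 = "GCAAATG")), 3L)
  expect_identical(homopolymer_run(ev("chr1", 2L, "GAA", "G"),
                                   c(chr1 = "GGAAAACC")), 4L)
  # insertion point inside a run
  expect_identical(homopolymer_run(ev("chr1", 3L, "A", "AT"),
                                   c(chr1 = "GCAAAAG")), 4L)
  expect_error(homopolymer_run(ev("chr1", 2L, "C", "T"),
                               c(chr1 = "GCAAATG")), "not an InDel")
})

test_that("tandem-repeat context finds the shortest covering unit", {
  g <- c(chr1 = "GGCATATATATGCC")
  expect_identical(tandem_repeat_context(ev("chr1", 4L, "AT", "A"), g),
                   "AT")
  g2 <- c(chr1 = "TTCAGCAGCAGTT")
  expect_identical(tandem_repeat_context(ev("chr1", 2L, "TCAG", "T"), g2),
                   "CAG")
  g3 <- c(chr1 = "GGGTCACCC")
  expect_identical(tandem_repeat_context(ev("chr1", 3L, "GT", "G"), g3),
                   NA_character_)
})

test_that("dependency classes follow the documented priority rule", {
  # mononucleotide allele inside a >=3 bp run -> homopoly
  s1 <- classify_dependency(ev("chr1", 2L, "CA", "C"),
                            c(chr1 = "GCAAATG"))
  expect_identical(s1$dependency_class, "homopoly")

  # AT deletion in CATATG: covering repeat + 2 bp microhomology -> repeat
  s2 <- classify_dependency(ev("chr1", 1L, "CAT", "C"),
                            c(chr1 = "CATATG"))
  expect_identical(s2$dependency_class, "polynucleotide_repeat")
  expect_identical(s2$mh_len, 2L)

  # >=2 bp allele, no microhomology, no repeat -> independent
  s3 <- classify_dependency(ev("chr1", 3L, "GTCA", "G"),
                            c(chr1 = "GGGTCACCC"))
  expect_identical(s3$dependency_class, "independent")

  # N in the scan window forces independent + ambiguous flag
  s4 <- classify_dependency(ev("chr1", 3L, "CA", "C"),
                            c(chr1 = "GNCAAATG"))
  expect_identical(s4$dependency_class, "independent")
  expect_true(s4$ambiguous_context)
})

test_that("deleting one unit of a 2-copy tandem yields mh_len = unit size", {
  set.seed(5)
  for (i in 1:50) {
    u <- sample(2:6, 1)
    unit <- random_genome(u)
    while (length(unique(strsplit(unit, "")[[1]])) == 1) {
      unit <- random_genome(u)
    }
    left <- random_genome(15)
    right <- random_genome(15)
    seq <- paste0(left, strrep(unit, 2), right)
    g <- c(chr1 = seq)
    pos <- nchar(left)                    # anchor base before the array
    call <- normalize_one("chr1", pos,
                          paste0(substr(seq, pos, pos), unit),
                          substr(seq, pos, pos), g)
    mh <- junction_microhomology(ev("chr1", call$pos, call$ref, call$alt),
                                 g)
    expect_identical(mh$mh_len, nchar(unit))
  }
})

test_that("scanners agree with naive brute-force string scans (fuzz)", {
  set.seed(9)
  cfg <- mh_config()
  for (i in 1:300) {
    seq <- random_genome(120)
    g <- c(chr1 = seq)
    is_del <- runif(1) < 0.6
    if (is_del) {
      dlen <- sample(1:8, 1)
      s <- sample(30:(120 - dlen - 30), 1)
      pos <- s - 1L
      call <- ev("chr1", pos, substr(seq, pos, s + dlen - 1L),
                 substr(seq, pos, pos))
      A <- substr(seq, s, s + dlen - 1L)
      left <- substr(seq, s - cfg$mh_cap, s - 1L)
      right <- substr(seq, s + dlen, s + dlen + cfg$mh_cap - 1L)
      ja <- s; jb <- s + dlen - 1L
    } else {
      p <- sample(30:90, 1)
      A <- random_genome(sample(1:8, 1))
      call <- ev("chr1", p, substr(seq, p, p),
                 paste0(substr(seq, p, p), A))
      left <- substr(seq, p - cfg$mh_cap + 1L, p)
      right <- substr(seq, p + 1L, p + cfg$mh_cap)
      ja <- p; jb <- p + 1L
    }
    got <- junction_microhomology(call, g, cfg)
    want <- brute_mh(A, left, right, cfg$mh_cap)
    expect_identical(got$mh_len, as.integer(want$mh_len))
    expect_identical(got$mh_side, want$mh_side)

    rs <- max(1L, ja - cfg$flank_window)
    region <- substr(seq, rs, min(nchar(seq), jb + cfg$flank_window))
    got_u <- tandem_repeat_context(call, g, cfg)
    want_u <- brute_tandem(region, ja - rs + 1L, jb - rs + 1L,
                           cfg$repeat_unit_min, cfg$repeat_unit_max,
                           cfg$repeat_min_copies)
    expect_identical(is.na(got_u), is.na(want_u))
    if (!is.na(got_u)) expect_identical(nchar(got_u), nchar(want_u))
  }
})

test_that("signatures are invariant to the input representation", {
  # same 1 bp A-deletion presented at different placements in the run
  g <- c(chr1 = "TTGCAAAAGTT")
  reps <- list(ev("chr1", 4L, "CA", "C"), ev("chr1", 5L, "AA", "A"),
               ev("chr1", 7L, "AA", "A"))
  sigs <- lapply(reps, function(r) {
    n <- normalize_one(r$contig, r$pos, r$ref, r$alt, g)
    classify_dependency(ev("chr1", n$pos, n$ref, n$alt), g)
  })
  for (s in sigs[-1]) expect_identical(s, sigs[[1]])
})

test_that("classify_microhomology covers exactly the simple InDel events", {
  g <- c(chr1 = "TTGCAAAAGTCGGCTAGGCTTACGGATCATATATATGGCCTTAACC")
  # one SBS, one homopolymer deletion, one repeat-array deletion, each on
  # its own line (so no complex chaining)
  calls <- variant_calls("chr1", c(2L, 4L, 28L), c("T", "CA", "CAT"),
                         c("C", "C", "C"), c("L1", "L2", "L3"))
  events <- classify_events(normalize_variants(calls, g))
  sig <- classify_microhomology(events, g)
  expect_identical(nrow(sig), 2L)
  expect_setequal(sig$dependency_class,
                  c("homopoly", "polynucleotide_repeat"))
})
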