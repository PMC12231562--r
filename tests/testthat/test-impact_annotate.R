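# hand-built fixture: one + strand two-exon gene and one - strand gene on
# a 20 kb contig with known codons
impact_fixture <- function() {
  chars <- rep(c("A", "C", "G", "T"), length.out = 20000L)
  # + strand gene g1: span 101-400, exons 101-220 / 301-400,
  # CDS 131-220 + 301-369 (159 bp); start codon ATG at 131, TGG at 134
  chars[131:139] <- c("A", "T", "G", "T", "G", "G", "C", "C", "T")
  # - strand gene g2: span 501-700, one exon, CDS 521-679; the + strand
  # bases 677-679 = C,A,T give the start codon ATG in transcript space
  chars[677:679] <- c("C", "A", "T")
  genome <- c(chr1 = paste(chars, collapse = ""))
  models <- data.frame(
    gene_id = c("g1", "g2"), contig = "chr1", strand = c("+", "-"),
    start = c(101, 501), end = c(400, 700), tss = c(101, 700),
    exons = I(list(data.frame(start = c(101, 301), end = c(220, 400)),
                   data.frame(start = 501, end = 700))),
    cds = I(list(data.frame(start = c(131, 301), end = c(220, 369),
                            phase = c(0L, 0L)),
                 data.frame(start = 521, end = 679, phase = 0L))),
    stringsAsFactors = FALSE)
  list(genome = genome, models = models)
}

annotate_one <- function(fix, pos, ref, alt, flank = 5000L) {
  calls <- variant_calls("chr1", pos, ref, alt, "L1")
  ev <- classify_events(normalize_variants(calls, fix$genome))
  annotate_impact(ev, fix$models, fix$genome, flank = flank)
}

test_that("the tier map is total and fixed", {
  subs <- c("frameshift", "stop_gained", "stop_lost", "start_lost",
            "splice_donor", "splice_acceptor", "missense", "inframe_indel",
            "utr5", "utr3", "synonymous", "intron", "upstream",
            "downstream", "intergenic")
  tiers <- impact_tier(subs)
  expect_identical(tiers[1:6], rep("HIGH", 6))
  expect_identical(tiers[7:10], rep("MODERATE", 4))
  expect_identical(tiers[11:12], rep("LOW", 2))
  expect_identical(tiers[13:15], rep("MODIFIER", 3))
  expect_error(impact_tier("nonsense_class"), "unknown")
})

test_that("CDS InDels split into frameshift vs in-frame by length mod 3", {
  fix <- impact_fixture()
  base <- function(p) substr(fix$genome[["chr1"]], p, p)
  del2 <- annotate_one(fix, 150L,
                       substr(fix$genome[["chr1"]], 150, 152), base(150))
  expect_identical(del2$subclass, "frameshift")
  expect_identical(del2$tier, "HIGH")

  del3 <- annotate_one(fix, 150L,
                       substr(fix$genome[["chr1"]], 150, 153), base(150))
  expect_identical(del3$subclass, "inframe_indel")
  expect_identical(del3$tier, "MODERATE")
})

test_that("coding SBS effects come from codon translation", {
  fix <- impact_fixture()
  # TGG -> TGA at codon 2 of g1 (positions 134-136)
  stopg <- annotate_one(fix, 136L, "G", "A")
  # independent check with the standard-code translator
  expect_identical(
    as.character(Biostrings::translate(Biostrings::DNAString("TGA"))), "*")
  expect_identical(stopg$subclass, "stop_gained")
  expect_identical(stopg$tier, "HIGH")
  expect_identical(stopg$gene_id, "g1")

  # ATG -> ATC on the minus-strand gene destroys the start codon:
  # + strand base 677 (C) pairs with the codon's third base
  startl <- annotate_one(fix, 677L, "C", "G")
  expect_identical(startl$subclass, "start_lost")
  expect_identical(startl$gene_id, "g2")

  # synonymous third-position change: TGG codon1? use GCC 137-139 (Ala)
  syn <- annotate_one(fix, 139L, "T", "A")
  expect_identical(syn$subclass, "synonymous")
  expect_identical(syn$tier, "LOW")
})

test_that("feature boundaries map to splice/intron/UTR/flank classes", {
  fix <- impact_fixture()
  base <- function(p) substr(fix$genome[["chr1"]], p, p)
  sub_at <- function(p) {
    alt <- setdiff(c("A", "C", "G", "T"), base(p))[1]
    annotate_one(fix, p, base(p), alt)$subclass
  }
  expect_identical(sub_at(221L), "splice_donor")
  expect_identical(sub_at(222L), "splice_donor")
  expect_identical(sub_at(223L), "intron")
  expect_identical(sub_at(298L), "intron")
  expect_identical(sub_at(299L), "splice_acceptor")
  expect_identical(sub_at(300L), "splice_acceptor")
  expect_identical(sub_at(110L), "utr5")
  expect_identical(sub_at(380L), "utr3")
  expect_identical(sub_at(90L), "upstream")
  expect_identical(sub_at(450L), "downstream")
  # - strand flips the flank orientation: 5' of g2 lies above its end
  expect_identical(sub_at(720L), "upstream")
  # 12 kb beyond every gene -> intergenic, MODIFIER, no gene id
  far <- annotate_one(fix, 18000L, base(18000L),
                      setdiff(c("A", "C", "G", "T"), base(18000L))[1])
  expect_identical(far$subclass, "intergenic")
  expect_identical(far$tier, "MODIFIER")
  expect_true(is.na(far$gene_id))
})

test_that("complex events take the most severe member subclass", {
  fix <- impact_fixture()
  base <- function(p) substr(fix$genome[["chr1"]], p, p)
  # an intronic SBS plus a CDS frameshift deletion 6 bp apart
  calls <- variant_calls("chr1", c(215L, 223L),
                         c(substr(fix$genome[["chr1"]], 215, 217),
                           base(223)),
                         c(base(215), "A"), "L1")
  ev <- classify_events(normalize_variants(calls, fix$genome))
  expect_identical(ev$category, "complex")
  ann <- annotate_impact(ev, fix$models, fix$genome)
  expect_identical(ann$subclass, "frameshift")
  expect_identical(ann$tier, "HIGH")
})

test_that("impact proportions use per-plant averaging", {
  ann <- data.frame(
    line_id = c(rep("L1", 4), rep("L2", 5), rep("L3", 5)),
    subclass = c("frameshift", "missense", "intron", "upstream",
                 "frameshift", rep("missense", 4),
                 "frameshift", "frameshift", rep("intron", 3)),
    stringsAsFactors = FALSE)
  ann$tier <- impact_tier(ann$subclass)
  meta <- toy_meta(c("L1", "L2", "L3"))
  res <- impact_proportions(ann, meta)
  expect_equal(unname(unlist(
    res$per_line[res$per_line$line_id == "L1",
                 c("HIGH", "MODERATE", "LOW", "MODIFIER")])),
    rep(0.25, 4))
  # genotype mean of per-plant HIGH proportions: (0.25 + 0.2 + 0.4) / 3
  expect_equal(res$per_genotype$mean_HIGH, mean(c(0.25, 0.2, 0.4)))
  expect_equal(res$per_genotype$mean_frameshift_per_plant,
               mean(c(1, 1, 2)))
  # per-line tier proportions always sum to 1
  sums <- rowSums(res$per_line[c("HIGH", "MODERATE", "LOW", "MODIFIER")])
  expect_equal(unname(sums), rep(1, 3))
})

test_that("tier-probability recovery on simulated annotations", {
  set.seed(21)
  p <- c(HIGH = 0.1, MODERATE = 0.3, LOW = 0.2, MODIFIER = 0.4)
  sub_for <- c(HIGH = "frameshift", MODERATE = "missense", LOW = "intron",
               MODIFIER = "upstream")
  n_lines <- 30L; n_events <- 30L
  ann <- do.call(rbind, lapply(seq_len(n_lines), function(i) {
    tiers <- sample(names(p), n_events, replace = TRUE, prob = p)
    data.frame(line_id = sprintf("L%02d", i), subclass = sub_for[tiers],
               tier = tiers, stringsAsFactors = FALSE)
  }))
  meta <- toy_meta(sprintf("L%02d", seq_len(n_lines)))
  res <- impact_proportions(ann, meta)
  for (t in names(p)) {
    m <- res$per_genotype[[paste0("mean_", t)]]
    se <- res$per_genotype[[paste0("sem_", t)]]
    expect_lt(abs(m - p[[t]]), 3 * se)
  }
})
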