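test_that("FASTA read/write round trip uppercases and preserves lengths", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1 some description", "acgt", ">c2", "GGGG"), fa)
  g <- read_genome(fa)
  expect_named(g, c("c1", "c2"))
  expect_identical(unname(g["c1"]), "ACGT")
  expect_identical(genome_length(g), 8L)

  out <- withr::local_tempfile(fileext = ".fa")
  write_genome(g, out)
  expect_identical(read_genome(out), g)
})

test_that("empty FASTA yields an empty genome with a warning", {
  fa <- withr::local_tempfile(fileext = ".fa")
  file.create(fa)
  expect_warning(g <- read_genome(fa), "empty")
  expect_length(g, 0)
})

gff_fixture <- function() {
  c("##gff-version 3",
    "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t1001\t2000\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr1\tsrc\texon\t1001\t1400\t.\t+\t.\tID=gA.e1;Parent=gA.1",
    "chr1\tsrc\texon\t1601\t2000\t.\t+\t.\tID=gA.e2;Parent=gA.1",
    "chr1\tsrc\tCDS\t1101\t1400\t.\t+\t0\tID=gA.c;Parent=gA.1",
    "chr1\tsrc\tCDS\t1601\t1900\t.\t+\t0\tID=gA.c;Parent=gA.1",
    "chr1\tsrc\tgene\t3001\t4000\t.\t-\t.\tID=gB",
    "chr1\tsrc\tmRNA\t3001\t4000\t.\t-\t.\tID=gB.1;Parent=gB",
    "chr1\tsrc\texon\t3001\t4000\t.\t-\t.\tID=gB.e1;Parent=gB.1",
    "chr1\tsrc\tCDS\t3101\t3901\t.\t-\t0\tID=gB.c;Parent=gB.1")
}

test_that("gene models derive the TSS from strand and keep one isoform", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff_fixture(), gff)
  m <- read_gene_models(gff)
  expect_identical(m$tss[m$gene_id == "gA"], 1001)
  expect_identical(m$tss[m$gene_id == "gB"], 4000)
  # minus-strand exon/CDS lists come back in transcription order
  expect_equal(m$exons[m$gene_id == "gB"][[1]]$start, 3001)

  two <- c(gff_fixture(),
           "chr1\tsrc\tmRNA\t1001\t2000\t.\t+\t.\tID=gA.2;Parent=gA",
           "chr1\tsrc\texon\t1001\t2000\t.\t+\t.\tID=gA2.e;Parent=gA.2")
  gff2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(two, gff2)
  expect_message(m2 <- read_gene_models(gff2), "isoforms")
  expect_identical(nrow(m2), 2L)
  # first isoform in file order defines the structure
  expect_identical(nrow(m2$exons[m2$gene_id == "gA"][[1]]), 2L)
})

test_that("CDS outside any exon is rejected with the gene id", {
  bad <- c("##gff-version 3",
           "chr1\tsrc\tgene\t100\t400\t.\t+\t.\tID=gX",
           "chr1\tsrc\tmRNA\t100\t400\t.\t+\t.\tID=gX.1;Parent=gX",
           "chr1\tsrc\texon\t100\t200\t.\t+\t.\tID=e;Parent=gX.1",
           "chr1\tsrc\tCDS\t250\t300\t.\t+\t0\tID=c;Parent=gX.1")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(bad, gff)
  expect_error(read_gene_models(gff), "gX")
})

test_that("gene-model GFF3 write/read round trip preserves structure", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff_fixture(), gff)
  m <- read_gene_models(gff)
  out <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(m, out)
  m2 <- read_gene_models(out)
  expect_identical(m2$tss, m$tss)
  expect_identical(m2$exons[[1]], m$exons[[1]])
  expect_identical(m2$cds[[2]], m$cds[[2]])
})

vcf_fixture <- function() {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tL1\tL2",
    "chr1\t100\t.\tG\tA\t.\tPASS\t.\tGT:AD\t0/1:6,4\t0/0:10,0",
    "chr1\t200\t.\tC\tA,T\t.\tPASS\t.\tGT:AD\t0/1:5,5,0\t0/1:4,0,4",
    "chr1\t300\t.\tT\t<DEL>\t.\tPASS\t.\tGT:AD\t0/1:3,3\t0/0:6,0")
}

test_that("VCF calls carry per-line AD-derived fractions and split ALTs", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_fixture(), vcf)
  expect_message(calls <- read_variant_table(vcf), "symbolic")
  # record 1: only L1 carries, af 4/10
  r1 <- calls[calls$pos == 100, ]
  expect_identical(nrow(r1), 1L)
  expect_identical(r1$line_id, "L1")
  expect_equal(r1$af_L1, 0.4)
  expect_equal(r1$af_L2, 0)
  # record 2 splits into per-ALT, per-carrier rows
  r2 <- calls[calls$pos == 200, ]
  expect_setequal(paste(r2$alt, r2$line_id), c("A L1", "T L2"))
  # symbolic ALT skipped
  expect_false(any(calls$pos == 300))
})

test_that("missing allele-fraction FORMAT fields are reported", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                      "Description=\"GT\">"),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tL1",
               "chr1\t100\t.\tG\tA\t.\tPASS\t.\tGT\t0/1"), vcf)
  expect_error(read_variant_table(vcf), "AD|FREQ")
})

test_that("call tables round trip through TSV", {
  calls <- variant_calls("chr1", c(10L, 20L), c("A", "CT"), c("G", "C"),
                         c("L1", "L2"),
                         af_by_line = matrix(c(0.5, 0, 0, 0.4), 2, 2,
                                             dimnames = list(NULL,
                                                             c("L1",
                                                               "L2"))))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(calls, tsv)
  back <- read_variant_table(tsv)
  expect_equal(back, calls)
})

test_that("VCF writer emits fractions recoverable from AD", {
  calls <- variant_calls("chr1", c(10L, 25L), c("A", "C"), c("G", "CAT"),
                         c("L1", "L2"),
                         af_by_line = matrix(c(0.5, 0, 0, 0.5), 2, 2,
                                             dimnames = list(NULL,
                                                             c("L1",
                                                               "L2"))))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, vcf, depth = 60L)
  back <- read_variant_table(vcf)
  back <- back[order(back$pos), ]
  expect_equal(back$pos, calls$pos)
  expect_equal(back$af_L1, calls$af_L1, tolerance = 1 / 60)
  expect_equal(back$af_L2, calls$af_L2, tolerance = 1 / 60)
})

test_that("normalization trims, left-aligns and stays idempotent", {
  g <- c(chr1 = "TTTCAAAGTT")
  # deleting one A of the A-run left-aligns to the run start
  n <- normalize_one("chr1", 6L, "AA", "A", g)
  expect_identical(n$pos, 4L)
  expect_identical(n$ref, "CA")
  expect_identical(n$alt, "C")
  # brute-force haplotype-equality oracle agrees
  expect_identical(leftmost_deletion(g[[1]], 7L, 1L), 5L)

  # SBS untouched
  s <- normalize_one("chr1", 8L, "G", "T", g)
  expect_identical(s, data.frame(pos = 8L, ref = "G", alt = "T",
                                 stringsAsFactors = FALSE))

  # shared flanking bases trim to a 2 bp deletion
  n2 <- normalize_one("chr1", 3L, "ATA", "A", c(chr1 = "GGATACC"))
  expect_identical(nchar(n2$ref) - nchar(n2$alt), 2L)

  # reference mismatch is an error naming the locus
  expect_error(normalize_one("chr1", 2L, "GG", "G", g), "chr1:2")
})

test_that("MNVs decompose into per-base SBS calls", {
  g <- c(chr1 = "AACGTT")
  n <- normalize_one("chr1", 3L, "CG", "GA", g)
  expect_identical(nrow(n), 2L)
  expect_identical(n$ref, c("C", "G"))
  expect_identical(n$alt, c("G", "A"))
  expect_identical(n$pos, c(3L, 4L))
})

test_that("normalization preserves the alternate haplotype (fuzz)", {
  set.seed(42)
  for (i in 1:300) {
    seq <- random_genome(60)
    g <- c(chr1 = seq)
    if (runif(1) < 0.5) {                 # deletion
      dlen <- sample(1:6, 1)
      s <- sample(5:(60 - dlen - 4), 1)
      pos <- s - 1L
      ref <- substr(seq, pos, s + dlen - 1L)
      alt <- substr(seq, pos, pos)
    } else {                              # insertion
      pos <- sample(5:55, 1)
      ins <- random_genome(sample(1:6, 1))
      ref <- substr(seq, pos, pos)
      alt <- paste0(ref, ins)
    }
    n <- normalize_one("chr1", pos, ref, alt, g)
    expect_identical(apply_variant(seq, n$pos, n$ref, n$alt),
                     apply_variant(seq, pos, ref, alt))
    n2 <- normalize_one("chr1", n$pos, n$ref, n$alt, g)
    expect_identical(n2, n)               # idempotent
  }
})
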