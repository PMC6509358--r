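# Format readers/writers and coordinate conventions.

test_that("FASTA reading, writing and round-tripping", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a extra tokens ignored", "ACGT"), f)
  expect_identical(read_fasta(f), c(a = "ACGT"))

  seqs <- c(a = strrep("ACGT", 40), b = "GGGCCCTTT")
  write_fasta(seqs, f)
  expect_identical(read_fasta(f), seqs)

  # write o read is byte-identical at 60-column wrap
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(read_fasta(f), f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("GFF3 coordinate conversion, defaults and round trip", {
  g <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tx\tgene\t1\t100\t.\t+\t.\tID=g1;biotype=tRNA",
               "chr\tx\tgene\t201\t300\t.\t-\t.\tID=g2"), g)
  feats <- read_gff3(g)
  # 1-based closed (1, 100) becomes 0-based half-open [0, 100)
  expect_identical(feats$start, c(0L, 200L))
  expect_identical(feats$end, c(100L, 300L))
  # missing biotype defaults to "other"
  expect_identical(feats$biotype, c("tRNA", "other"))

  # round trip is the identity on the domain model
  feats0 <- gene_features(
    c("gA", "gB", "gC"), "chr", c(5L, 50L, 500L), c(45L, 400L, 900L),
    c("+", "-", "+"), c("protein_coding", "pre_miRNA", "other"),
    list(c(30, 40), 350, 2))
  g2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(feats0, g2)
  feats1 <- read_gff3(g2)
  for (col in c("gene_id", "reference", "start", "end", "strand", "biotype"))
    expect_identical(feats1[[col]], feats0[[col]])
  expect_equal(feats1$transcript_lengths, feats0$transcript_lengths,
               ignore_attr = TRUE)
  # re-emission reproduces the file
  g3 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(feats1, g3)
  expect_identical(readLines(g2), readLines(g3))
})

test_that("GFF3 features beyond sequence bounds are rejected", {
  g <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tx\tgene\t1\t500\t.\t+\t.\tID=g1;biotype=other"), g)
  expect_error(read_gff3(g, reference = c(chr = "ACGT")), "bounds")
})

test_that("minimal SAM dialect decodes flags and round-trips", {
  rd <- aligned_reads(
    read_id = c("f1/1", "f1/2", "f2/1", "f3/1"),
    fragment_id = c("f1", "f1", "f2", "f3"),
    mate = c(1L, 2L, 1L, 1L),
    reference = "chr",
    start = c(0L, 150L, 300L, 700L),
    end = c(100L, 250L, 400L, 790L),
    strand = c("+", "-", "-", "+"),
    sample = "s1")
  s <- withr::local_tempfile(fileext = ".sam")
  write_sam_minimal(rd, c(chr = 1000L), s)
  rd2 <- read_alignments(s, "sam", sample = "s1")
  i <- match(rd$read_id, rd2$read_id)
  for (col in c("fragment_id", "mate", "reference", "start", "end",
                "strand", "sample"))
    expect_identical(rd2[[col]][i], rd[[col]])

  # FLAG 99 (paired, proper, mate unmapped? no: 99 = 1+2+32+64): mate 1,
  # plus strand, POS 1 CIGAR 100M -> [0, 100)
  s2 <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr\tLN:1000",
               "q1\t99\tchr\t1\t60\t100M\t*\t0\t0\t*\t*",
               "q1\t147\tchr\t151\t60\t100M\t*\t0\t0\t*\t*",
               "q2\t16\tchr\t11\t60\t50M\t*\t0\t0\t*\t*"), s2)
  got <- read_alignments(s2, "sam", sample = "x")
  r1 <- got[got$read_id == "q1/1", ]
  expect_identical(r1$start, 0L)
  expect_identical(r1$end, 100L)
  expect_identical(r1$strand, "+")
  expect_identical(r1$mate, 1L)
  expect_identical(got[got$fragment_id == "q2", ]$strand, "-")
})

test_that("minimal SAM dialect rejects non-M CIGARs and skips unmapped", {
  s <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr\tLN:1000",
               "q1\t0\tchr\t1\t60\t50M10N50M\t*\t0\t0\t*\t*"), s)
  expect_error(read_alignments(s, "sam"), "CIGAR")

  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr\tLN:1000",
               "q1\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
               "q2\t0\tchr\t5\t60\t20M\t*\t0\t0\t*\t*"), s)
  expect_message(got <- read_alignments(s, "sam", sample = "x"),
                 "1 unmapped")
  expect_identical(nrow(got), 1L)
})

test_that("fragment-BED dialect parses intervals and strands", {
  b <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t110\tfrag7/1\t.\t-", b)
  got <- read_alignments(b, "bed", sample = "s")
  expect_identical(got$start, 10L)
  expect_identical(got$end, 110L)
  expect_identical(got$strand, "-")
  expect_identical(got$fragment_id, "frag7")
})

test_that("BED6 output carries overlap length as score, sorted", {
  p <- withr::local_tempfile(fileext = ".bed")
  write_bed(data.frame(), p)
  expect_identical(length(readLines(p)), 0L)

  cand <- data.frame(
    reference = c("ref", "ref"), fwd_read = c("a/1", "b/1"),
    rev_read = c("c/1", "d/1"), overlap_start = c(300L, 60L),
    overlap_end = c(360L, 100L), overlap_len = c(60L, 40L))
  write_bed(cand, p)
  lines <- readLines(p)
  expect_identical(length(lines), 2L)
  expect_identical(lines[1], "ref\t60\t100\tb/1|d/1\t40\t+")
  starts <- as.integer(vapply(strsplit(lines, "\t"), `[`, "", 2))
  expect_false(is.unsorted(starts))
})

test_that("count-matrix TSV round-trips", {
  m <- matrix(c(1, 2, 3, 4.5, 0, 7), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(m, p)
  expect_equal(read_counts_tsv(p), m)
})

test_that("mate merging infers the dUTP fragment sense strand", {
  rd <- aligned_reads(
    read_id = c("f1/1", "f1/2"), fragment_id = "f1", mate = c(1L, 2L),
    reference = "chr", start = c(200L, 0L), end = c(300L, 100L),
    strand = c("-", "+"), sample = "s1")
  fr <- merge_mates(rd, "dutp")
  expect_identical(fr$start, 0L)
  expect_identical(fr$end, 300L)
  expect_identical(fr$strand, "+")  # mate 2 carries the sense strand
  expect_identical(merge_mates(rd, "fr")$strand, "-")
})
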