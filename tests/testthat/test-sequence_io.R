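test_that("FASTA reading normalizes DNA input to RNA and preserves order", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">t1", "acgt", ">t2 some description", "GGCC"), fa)
  recs <- read_fasta(fa)
  expect_length(recs, 2)
  expect_equal(recs[[1]]$sequence, "ACGU")
  expect_equal(recs[[2]]$transcript_id, "t2")
  expect_equal(vapply(recs, `[[`, "", "label"),
               c(t1 = "unknown", t2 = "unknown"))
  labs <- c(t1 = "positive")
  expect_equal(read_fasta(fa, labels = labs)[[1]]$label, "positive")
})

test_that("FASTA reading rejects duplicates, collapses ambiguity codes, rejects junk", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">t1", "ACGU", ">t1", "GGCC"), fa)
  expect_error(read_fasta(fa), "duplicate")

  writeLines(c(">t1", "ACGRY"), fa)
  expect_warning(recs <- read_fasta(fa), "ambiguity")
  expect_equal(recs[[1]]$sequence, "ACGNN")

  writeLines(c(">t1", "ACGX1"), fa)
  expect_error(suppressWarnings(read_fasta(fa)), "non-nucleotide")

  writeLines(character(0), fa)
  expect_error(read_fasta(fa))
})

test_that("FASTA round-trips through write_fasta", {
  fa <- withr::local_tempfile(fileext = ".fa")
  out <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">t1", "ACGUACGU", ">t2", "GGGCCCAAA"), fa)
  recs <- read_fasta(fa)
  write_fasta(recs, out)
  again <- read_fasta(out)
  expect_equal(vapply(again, `[[`, "", "sequence"),
               vapply(recs, `[[`, "", "sequence"))
  expect_equal(names(again), names(recs))
})

test_that("transcript records validate exon structure", {
  ex <- data.frame(chrom = "chr1", start = c(10, 40), end = c(20, 50),
                   strand = "+")
  r <- transcript_record("t1", strrep("A", 20), exons = ex)
  expect_equal(nrow(r$exons), 2)
  expect_error(transcript_record("t1", strrep("A", 19), exons = ex),
               "exon lengths")
  bad <- data.frame(chrom = "chr1", start = c(10, 15), end = c(20, 25),
                    strand = "+")
  expect_error(transcript_record("t1", strrep("A", 20), exons = bad),
               "overlapping")
  rev_ex <- data.frame(chrom = "chr1", start = 20, end = 10, strand = "+")
  expect_error(transcript_record("t1", strrep("A", 10), exons = rev_ex),
               "end <= start")
})

test_that("BED parsing is 0-based half-open with line-numbered errors", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20\tx\t0\t+", bed)
  df <- read_bed_intervals(bed)
  expect_equal(df$start, 10)
  expect_equal(df$end, 20)
  expect_equal(df$strand, "+")

  writeLines(c("chr1\t10\t20\tok", "chr1\t20\t10\tx"), bed)
  expect_error(read_bed_intervals(bed), "line 2")

  writeLines(character(0), bed)
  expect_equal(nrow(read_bed_intervals(bed)), 0)
})

test_that("conservation tracks expand half-open intervals per base", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chr1\t5\t7\t0.4", f)
  tr <- read_conservation(f)
  expect_equal(conservation_lookup(tr, "chr1", c(5, 6)), c(0.4, 0.4))
  expect_true(is.na(conservation_lookup(tr, "chr1", 7)))
  expect_true(is.na(conservation_lookup(tr, "chr2", 5)))

  writeLines("chr1\t5\t6\t1.5", f)
  expect_error(read_conservation(f), "outside")

  writeLines(c("chr1\t5\t8\t0.2", "chr1\t7\t9\t0.9"), f)
  expect_warning(tr <- read_conservation(f), "overlap")
  expect_equal(conservation_lookup(tr, "chr1", 7), 0.9)  # last wins
  expect_equal(conservation_lookup(tr, "chr1", 6), 0.2)
})

test_that("dot-bracket reader parses the RNAfold dialect and validates", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(">t1", "GGGAAACCC", "(((...))) (-1.20)"), f)
  st <- read_dotbracket(f)
  expect_named(st, "t1")
  expect_equal(st$t1$dotbracket, "(((...)))")
  expect_equal(st$t1$mfe, -1.2)
  expect_false(st$t1$surrogate)

  writeLines(c(">t1", "GGGAAACCC", "(((...)). (-1.20)"), f)
  expect_error(read_dotbracket(f), "unbalanced|unmatched")

  writeLines(c(">t1", "GGG", "(((...))) (-1.20)"), f)
  expect_error(read_dotbracket(f), "length")
})

test_that("interaction tables deduplicate partner sets", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("lncrna_id\tprotein_id", "g1\tP1", "g1\tP2", "g1\tP1",
               "g2\tP9"), f)
  tab <- read_interactions(f)
  expect_setequal(tab$g1, c("P1", "P2"))
  expect_equal(length(tab$g2), 1)
})
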