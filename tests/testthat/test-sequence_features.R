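test_that("k-mer frequencies match direct window counts", {
  v <- kmer_frequencies("ACGUACGU", 3)
  expect_equal(unname(v["kmer3_ACG"]), 2/6)
  expect_equal(unname(v["kmer3_CGU"]), 2/6)
  expect_equal(unname(v["kmer3_GUA"]), 1/6)
  expect_equal(unname(v["kmer3_UAC"]), 1/6)
  expect_equal(sum(v), 1)
  expect_equal(sum(v > 0), 4)

  v2 <- kmer_frequencies("AAAA", 2)
  expect_equal(unname(v2["kmer2_AA"]), 1)
  expect_equal(sum(v2), 1)

  expect_error(kmer_frequencies("AC", 3), "length")
})

test_that("k-mer frequencies equal the brute-force oracle and handle N", {
  set.seed(5)
  seq200 <- random_rna(200)
  expect_equal(kmer_frequencies(seq200, 2), oracle_kmer(seq200, 2))
  expect_equal(kmer_frequencies(seq200, 3), oracle_kmer(seq200, 3))

  withN <- random_rna(60, alphabet = c("A", "C", "G", "U", "N"))
  expect_equal(kmer_frequencies(withN, 2), oracle_kmer(withN, 2))

  expect_warning(z <- kmer_frequencies("NNNN", 2), "N")
  expect_equal(sum(z), 0)
})

test_that("k-mer frequency vectors sum to 1 over random N-free sequences", {
  set.seed(17)
  for (rep in 1:50) {
    s <- random_rna(sample(10:80, 1))
    for (k in 2:3)
      expect_equal(sum(kmer_frequencies(s, k)), 1, tolerance = 1e-12)
  }
})

test_that("psednc follows the literal formula on a toy property table", {
  raw <- toy_props()
  got <- psednc("GACUGAACUGAC", lam = 3, w = 0.5, props = raw)
  want <- oracle_psednc("GACUGAACUGAC", lam = 3, w = 0.5, props_raw = raw)
  expect_equal(unname(got), want, tolerance = 1e-12)
  expect_length(got, 19)

  set.seed(23)
  for (rep in 1:10) {
    s <- random_rna(sample(15:40, 1))
    lam <- sample(1:6, 1)
    w <- runif(1, 0, 1)
    expect_equal(unname(psednc(s, lam, w, props = raw)),
                 oracle_psednc(s, lam, w, props_raw = raw),
                 tolerance = 1e-12)
  }
})

test_that("psednc limit cases: homopolymer, constant table, w = 0", {
  p <- psednc(strrep("A", 30), lam = 10, w = 0.05)
  expect_equal(unname(p[1]), 1)               # all dinucleotides AA
  expect_equal(sum(p[-1]), 0)

  const <- matrix(5, 16, 3,
                  dimnames = list(lncdisc:::.dinucleotides(), NULL))
  s <- "GACUGAACUGACGGA"
  p2 <- psednc(s, lam = 4, w = 0.5, props = const)
  f <- kmer_frequencies(substr(s, 1, nchar(s)), 2)
  expect_equal(unname(p2[1:16]), unname(f), tolerance = 1e-12)
  expect_equal(sum(p2[17:20]), 0)

  p3 <- psednc(s, lam = 4, w = 0, props = toy_props())
  expect_equal(unname(p3[1:16]), unname(f), tolerance = 1e-12)

  expect_error(psednc("ACGU", lam = 10), "too short")
})

test_that("psednc sums to 1 and is invariant to affine property changes", {
  raw <- toy_props()
  affine <- sweep(sweep(raw, 2, c(3, -0.5), `*`), 2, c(10, 2), `+`)
  set.seed(29)
  for (rep in 1:20) {
    s <- random_rna(sample(15:60, 1))
    a <- psednc(s, lam = 5, w = 0.1, props = raw)
    b <- psednc(s, lam = 5, w = 0.1, props = affine)
    expect_equal(sum(a), 1, tolerance = 1e-9)
    expect_true(all(a >= 0))
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("GC content excludes N and validates input", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("AUGC"), 0.5)
  expect_equal(gc_content("GNC"), 1)
  expect_error(gc_content("NNN"), "unambiguous")
  expect_error(gc_content(""), "empty")
})

test_that("conservation feature is the mean of exon means", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t10\t11\t0.2", "chr1\t11\t12\t0.4",
               "chr1\t40\t41\t0.8"), f)
  tr <- read_conservation(f)
  ex <- data.frame(chrom = "chr1", start = c(10, 40), end = c(12, 41),
                   strand = "+")
  rec <- transcript_record("t1", "ACG", exons = ex)
  expect_equal(conservation_feature(rec, tr), (0.3 + 0.8) / 2)

  # single exon fully covered
  ex1 <- data.frame(chrom = "chr1", start = 10, end = 12, strand = "+")
  rec1 <- transcript_record("t1", "AC", exons = ex1)
  expect_equal(conservation_feature(rec1, tr), 0.3)

  # uncovered exon dropped from the outer mean
  ex2 <- data.frame(chrom = "chr1", start = c(40, 100), end = c(41, 102),
                    strand = "+")
  rec2 <- transcript_record("t1", "ACG", exons = ex2)
  expect_equal(conservation_feature(rec2, tr), 0.8)

  # nothing covered -> 0 with warning
  ex3 <- data.frame(chrom = "chr9", start = 0, end = 3, strand = "+")
  rec3 <- transcript_record("t1", "ACG", exons = ex3)
  expect_warning(v <- conservation_feature(rec3, tr), "coverage")
  expect_equal(v, 0)

  rec4 <- transcript_record("t1", "ACG")
  expect_error(conservation_feature(rec4, tr), "exon")
})

test_that("mutation counting restricts to exons and matches a linear scan", {
  ex <- data.frame(chrom = "chr1", start = 10, end = 20, strand = "+")
  rec <- transcript_record("t1", strrep("A", 10), exons = ex)
  v <- structure(data.frame(chrom = c("chr1", "chr1", "chr2"),
                            position = c(12L, 25L, 12L),
                            variant_id = c("v1", "v2", "v3")),
                 class = c("variant_table", "data.frame"))
  expect_equal(mutation_count(rec, v), 1L)
  empty <- structure(data.frame(chrom = character(), position = integer(),
                                variant_id = character()),
                     class = c("variant_table", "data.frame"))
  expect_equal(mutation_count(rec, empty), 0L)

  # 50 random variants vs brute-force membership scan on a 2-exon transcript
  set.seed(41)
  ex2 <- data.frame(chrom = "chr5", start = c(100, 300), end = c(150, 340),
                    strand = "+")
  rec2 <- transcript_record("t2", strrep("G", 90), exons = ex2)
  vr <- structure(data.frame(chrom = sample(c("chr5", "chr6"), 50, TRUE),
                             position = sample(80:360, 50, TRUE),
                             variant_id = sprintf("v%02d", 1:50)),
                  class = c("variant_table", "data.frame"))
  brute <- sum(vapply(seq_len(50), function(i) {
    any(vr$chrom[i] == ex2$chrom & vr$position[i] >= ex2$start &
        vr$position[i] < ex2$end)
  }, logical(1)))
  expect_equal(mutation_count(rec2, vr), brute)

  rec3 <- transcript_record("t3", "ACGU")
  expect_warning(m <- mutation_count(rec3, v), "no exons")
  expect_equal(m, 0L)
})

test_that("interaction counting is gene-keyed with set semantics", {
  tab <- structure(list(g1 = c("P1", "P2", "P3"), t9 = "P4"),
                   class = "interaction_table")
  rec <- transcript_record("t1", "ACGU", gene_id = "g1")
  expect_equal(interaction_count(rec, tab), 3L)
  rec2 <- transcript_record("t2", "ACGU", gene_id = "gX")
  expect_equal(interaction_count(rec2, tab), 0L)
  rec3 <- transcript_record("t9", "ACGU")      # falls back to transcript id
  expect_equal(interaction_count(rec3, tab), 1L)
})
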