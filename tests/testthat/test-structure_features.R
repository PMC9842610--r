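test_that("dot-bracket parsing produces the nested pair map", {
  pm <- parse_pairs("(((...)))")
  expect_equal(pm[, "i"], c(0, 1, 2))
  expect_equal(pm[, "j"], c(8, 7, 6))
  expect_equal(nrow(parse_pairs(".........")), 0)
  expect_error(parse_pairs("(()"), "unmatched '\\('")
  expect_error(parse_pairs("())"), "unmatched '\\)'")
  expect_error(parse_pairs("((x))"), "invalid")
})

test_that("pair types are counted directionally; non-canonical pairs ignored", {
  c1 <- pair_type_counts("GGGAAACCC", parse_pairs("(((...)))"))
  expect_equal(unname(c1["bp_GC"]), 3)
  expect_equal(sum(c1), 3)

  c2 <- pair_type_counts("AUGCAU", parse_pairs("......"))
  expect_equal(sum(c2), 0)

  expect_warning(c3 <- pair_type_counts("ACGUGA", parse_pairs("((..))")),
                 "non-canonical")
  expect_equal(unname(c3["bp_CG"]), 1)
  expect_equal(attr(c3, "ignored"), 1)

  # directional: AU at (0,5) vs UA at (1,4)
  c4 <- pair_type_counts("AUGCAU", parse_pairs("((..))"))
  expect_equal(unname(c4["bp_AU"]), 1)
  expect_equal(unname(c4["bp_UA"]), 1)
})

test_that("unpaired bases are classified into hairpin/bulge/other loops", {
  u1 <- unpaired_class_counts(pair_map = "(((...)))")
  expect_equal(unname(u1), c(3, 0, 0))

  u2 <- unpaired_class_counts(pair_map = "..(((...))).")
  expect_equal(unname(u2["unp_hairpin"]), 3)
  expect_equal(unname(u2["unp_other"]), 3)   # exterior bases
  expect_equal(unname(u2["unp_bulge"]), 0)

  u3 <- unpaired_class_counts(pair_map = "((.((...))))")
  expect_equal(unname(u3), c(3, 1, 0))
  expect_equal(u3, oracle_unpaired_classes("((.((...))))"))

  # internal loop (both sides) and multibranch count as other
  u4 <- unpaired_class_counts(pair_map = "((.((...)).))")
  expect_equal(unname(u4["unp_other"]), 2)
  u5 <- unpaired_class_counts(pair_map = "((((...)).((...))))")
  expect_equal(unname(u5["unp_hairpin"]), 6)
  expect_equal(u5, oracle_unpaired_classes("((((...)).((...))))"))
})

test_that("unpaired classification agrees with the enclosing-pair-scan oracle on folded structures", {
  set.seed(61)
  for (rep in 1:40) {
    s <- random_rna(sample(20:50, 1))
    st <- fold_fallback(s)
    got <- unpaired_class_counts(pair_map = st)
    expect_equal(got, oracle_unpaired_classes(st$dotbracket))
    # conservation: classes partition the dots
    expect_equal(sum(got),
                 sum(strsplit(st$dotbracket, "")[[1]] == "."))
  }
})

test_that("pair-type counts + ignored equals the pair-map size", {
  set.seed(67)
  for (rep in 1:30) {
    s <- random_rna(sample(15:40, 1), alphabet = c("A","C","G","U","N"))
    db <- fold_fallback(gsub("N", "A", s))$dotbracket  # structure shape
    pm <- parse_pairs(db)
    cnt <- suppressWarnings(pair_type_counts(s, pm))
    expect_equal(sum(cnt) + attr(cnt, "ignored"), nrow(pm))
  }
})

test_that("the fallback folder attains the exhaustive-enumeration optimum", {
  st <- fold_fallback("GGGAAACCC")
  expect_equal(st$dotbracket, "(((...)))")
  expect_equal(st$mfe, -9)
  expect_true(st$surrogate)

  st2 <- fold_fallback("AAAA")
  expect_equal(st2$dotbracket, "....")
  expect_equal(st2$mfe, 0)

  set.seed(71)
  for (rep in 1:60) {
    s <- random_rna(sample(5:12, 1))
    st <- fold_fallback(s)
    expect_equal(-st$mfe, oracle_fold_best(s))
    # structure is valid and its weight equals the reported score
    w <- sum(pair_type_counts(s, st$pair_map) *
               c(2, 3, 1, 2, 3, 1))
    expect_equal(w, -st$mfe)
  }
})

test_that("folding respects the minimum hairpin size and is deterministic", {
  st <- fold_fallback("GCGC", min_hairpin = 3)
  expect_equal(st$dotbracket, "....")
  st5 <- fold_fallback("GAAAAAC", min_hairpin = 5)
  expect_equal(st5$dotbracket, "(.....)")
  expect_identical(fold_fallback("GGGAAAUUUCCC"),
                   fold_fallback("GGGAAAUUUCCC"))
})

test_that("structure featurization emits the 10-column block", {
  recs <- make_records(c("GGGAAACCCAAA", "ACGUACGUACGUACGU"))
  m <- featurize_structures(recs)
  expect_equal(ncol(m), 10)
  expect_equal(colnames(m)[1], "mfe")
  expect_true(attr(m, "surrogate_mfe"))

  # supplied structures short-circuit folding and carry true energies
  sts <- list(t01 = secondary_structure("(((...)))...", mfe = -4.2),
              t02 = secondary_structure(strrep(".", 16), mfe = 0))
  m2 <- featurize_structures(recs, structures = sts)
  expect_equal(unname(m2[1, "mfe"]), -4.2)
  expect_false(attr(m2, "surrogate_mfe"))

  # truncation cap applies to fallback folding
  long <- make_records(paste(rep("ACGU", 30), collapse = ""))
  expect_warning(featurize_structures(long, max_fold_len = 50), "truncated")
})
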