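# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check: plain matrix Needleman-Wunsch, explicit
# structure enumeration, literal-formula loops.

random_rna <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# full Needleman-Wunsch matrix, match = 1 / mismatch = 0 / gap = 0;
# returns the identical-column count of the optimal global alignment
nw_match_count <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  F <- matrix(0L, length(x) + 1, length(y) + 1)
  for (i in seq_along(x)) {
    for (j in seq_along(y)) {
      F[i + 1, j + 1] <- max(F[i, j] + (x[i] == y[j]),
                             F[i, j + 1], F[i + 1, j])
    }
  }
  F[length(x) + 1, length(y) + 1]
}

oracle_identity <- function(a, b) nw_match_count(a, b) / min(nchar(a), nchar(b))

# exhaustive enumeration of all nested pairings: returns the scores of every
# structure of chars[i..j] (weights GC=3, AU=2, GU=1, hairpin >= minh).
# Decomposition by the status of position i enumerates each structure once.
enum_fold_scores <- function(chars, i, j, minh = 3) {
  if (i > j) return(0)
  if (i == j) return(0)
  pw <- function(x, y) {
    p <- paste0(x, y)
    if (p %in% c("GC", "CG")) 3 else if (p %in% c("AU", "UA")) 2
    else if (p %in% c("GU", "UG")) 1 else 0
  }
  scores <- enum_fold_scores(chars, i + 1, j, minh)   # i unpaired
  ks <- seq_len(j)
  ks <- ks[ks > i + minh]
  for (k in ks) {
    w <- pw(chars[i], chars[k])
    if (w == 0) next
    inner <- enum_fold_scores(chars, i + 1, k - 1, minh)
    rest <- enum_fold_scores(chars, k + 1, j, minh)
    scores <- c(scores, as.vector(outer(inner, rest, `+`)) + w)
  }
  scores
}

oracle_fold_best <- function(seq, minh = 3) {
  chars <- strsplit(seq, "")[[1]]
  max(enum_fold_scores(chars, 1, length(chars), minh))
}

# brute-force k-mer frequencies by explicit window loop
oracle_kmer <- function(seq, k) {
  n <- nchar(seq)
  counts <- new.env()
  total <- 0
  for (i in 1:(n - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (grepl("N", w, fixed = TRUE)) next
    counts[[w]] <- (counts[[w]] %||% 0) + 1
    total <- total + 1
  }
  words <- lncdisc:::all_kmers(k)
  out <- setNames(numeric(length(words)), paste0("kmer", k, "_", words))
  for (w in ls(counts)) out[[paste0("kmer", k, "_", w)]] <- counts[[w]] / total
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# literal-formula pseudo dinucleotide composition: enumerates every (i, i+j)
# pair and applies the definition step by step
oracle_psednc <- function(seq, lam, w, props_raw) {
  dn <- as.vector(t(outer(c("A","C","G","U"), c("A","C","G","U"), paste0)))
  props_raw <- props_raw[dn, , drop = FALSE]
  P <- apply(props_raw, 2, function(col) {
    s <- sqrt(mean((col - mean(col))^2))
    if (s < 1e-12) rep(0, length(col)) else (col - mean(col)) / s
  })
  rownames(P) <- dn
  L <- nchar(seq)
  D <- substring(seq, 1:(L - 1), 2:L)
  Theta <- function(r1, r2) mean((P[r1, ] - P[r2, ])^2)
  theta <- numeric(lam)
  for (j in 1:lam) {
    acc <- 0; m <- 0
    for (i in 1:(L - 1 - j)) {
      acc <- acc + Theta(D[i], D[i + j])
      m <- m + 1
    }
    theta[j] <- acc / m
  }
  f <- sapply(dn, function(d) sum(D == d)) / length(D)
  denom <- 1 + w * sum(theta)
  unname(c(f / denom, w * theta / denom))
}

# classify every '.' by explicit enclosing-pair scan over the pair list
oracle_unpaired_classes <- function(dotbracket) {
  chars <- strsplit(dotbracket, "")[[1]]
  pm <- parse_pairs(dotbracket)   # trusted: checked by its own trivial tests
  n <- length(chars)
  counts <- c(unp_hairpin = 0, unp_bulge = 0, unp_other = 0)
  if (nrow(pm) == 0) {
    counts["unp_other"] <- sum(chars == ".")
    return(counts)
  }
  pairs <- lapply(seq_len(nrow(pm)), function(r) pm[r, ])
  encloses <- function(p, pos0) p[["i"]] < pos0 && pos0 < p[["j"]]
  children_of <- function(p) {
    Filter(function(q) {
      if (q[["i"]] == p[["i"]]) return(FALSE)
      if (!(p[["i"]] < q[["i"]] && q[["j"]] < p[["j"]])) return(FALSE)
      # directly inside: no third pair strictly between p and q
      !any(vapply(pairs, function(r)
        r[["i"]] > p[["i"]] && r[["j"]] < p[["j"]] &&
        r[["i"]] < q[["i"]] && r[["j"]] > q[["j"]], logical(1)))
    }, pairs)
  }
  for (pos in which(chars == ".")) {
    pos0 <- pos - 1
    enclosing <- Filter(function(p) encloses(p, pos0), pairs)
    if (length(enclosing) == 0) {
      counts["unp_other"] <- counts["unp_other"] + 1
      next
    }
    spans <- vapply(enclosing, function(p) p[["j"]] - p[["i"]], numeric(1))
    p <- enclosing[[which.min(spans)]]
    kids <- children_of(p)
    if (length(kids) == 0) {
      counts["unp_hairpin"] <- counts["unp_hairpin"] + 1
    } else if (length(kids) == 1) {
      q <- kids[[1]]
      left <- q[["i"]] - p[["i"]] - 1
      right <- p[["j"]] - q[["j"]] - 1
      if ((left > 0) != (right > 0))
        counts["unp_bulge"] <- counts["unp_bulge"] + 1
      else counts["unp_other"] <- counts["unp_other"] + 1
    } else {
      counts["unp_other"] <- counts["unp_other"] + 1
    }
  }
  counts
}

# toy 2-property raw table for psednc oracle comparisons
toy_props <- function() {
  dn <- as.vector(t(outer(c("A","C","G","U"), c("A","C","G","U"), paste0)))
  m <- cbind(p1 = seq(-1, 2, length.out = 16),
             p2 = c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 9, 7, 9, 3))
  rownames(m) <- dn
  m
}

make_records <- function(seqs, ids = sprintf("t%02d", seq_along(seqs)),
                         labels = rep("unknown", length(seqs))) {
  recs <- Map(function(s, id, lab) transcript_record(id, s, label = lab),
              seqs, ids, labels)
  names(recs) <- ids
  structure(unname(recs), class = "transcript_set") -> out
  names(out) <- ids
  out
}
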