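#' Dinucleotide physicochemical property table
#'
#' Six base-step properties (tilt, rise, roll, slide, twist, shift) for the
#' 16 RNA dinucleotides, used by [psednc()]. The table shipped with the
#' package (`inst/extdata/dinuc_properties_synthetic.csv`) is a constructed
#' stand-in with the right shape and realistic variation — it is *not* a
#' measured reference set, and is labelled synthetic for that reason. Because
#' the pseudo-composition standardizes every property to zero mean and unit
#' variance across the 16 dinucleotides (and is therefore invariant to
#' per-property affine changes), all structural contracts of the feature
#' vector hold for any table of this shape; users with a preferred measured
#' table can pass it via the `props` argument of [psednc()].
#'
#' @param path optional path to a CSV with a `dinucleotide` column and one
#'   column per property; defaults to the packaged synthetic table.
#' @param standardize return the standardized (zero mean, unit SD per
#'   property) form (default `TRUE`).
#' @return numeric matrix, 16 rows (dinucleotides AA..UU, lexicographic),
#'   one column per property.
#' @export
dinuc_property_table <- function(path = NULL, standardize = TRUE) {
  if (is.null(path))
    path <- system.file("extdata", "dinuc_properties_synthetic.csv",
                        package = "lncdisc", mustWork = TRUE)
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  stopifnot("dinucleotide" %in% names(df))
  m <- as.matrix(df[, setdiff(names(df), "dinucleotide"), drop = FALSE])
  rownames(m) <- df$dinucleotide
  dn <- .dinucleotides()
  if (!setequal(rownames(m), dn) || nrow(m) != 16)
    stopf("property table must have exactly the 16 dinucleotides")
  m <- m[dn, , drop = FALSE]
  if (standardize) m <- standardize_properties(m)
  m
}

# zero mean / unit (population) SD per property across the 16 dinucleotides;
# zero-variance properties map to all-zero columns rather than dividing by 0
standardize_properties <- function(m) {
  apply(m, 2, function(col) {
    mu <- mean(col)
    s <- sqrt(mean((col - mu)^2))
    if (s < 1e-12) rep(0, length(col)) else (col - mu) / s
  })
}

#' k-mer frequency vector
#'
#' Overlapping window counts: a sequence of length `L` has `L - k + 1`
#' k-mers. Windows containing `N` are skipped; the remaining counts are
#' normalized to frequencies summing to 1. If every window contains `N`, an
#' all-zero vector is returned with a warning.
#'
#' @param seq RNA sequence string.
#' @param k word length (>= 1); `nchar(seq) >= k` required.
#' @return named numeric vector of length `4^k`, names `kmer<k>_<word>` in
#'   lexicographic order over `A < C < G < U`.
#' @examples
#' kmer_frequencies("ACGUACGU", 3)[c("kmer3_ACG", "kmer3_CGU")]
#' @export
kmer_frequencies <- function(seq, k) {
  stopifnot(is_count(k), k >= 1)
  L <- nchar(seq)
  if (L < k) stopf("sequence length %d < k = %d", L, k)
  words <- all_kmers(k)
  out <- setNames(numeric(length(words)), paste0("kmer", k, "_", words))
  wins <- substring(seq, 1:(L - k + 1), k:L)
  wins <- wins[!grepl("N", wins, fixed = TRUE)]
  if (length(wins) == 0) {
    warnf("all %d-mer windows contain N; returning zero vector", k)
    return(out)
  }
  t <- table(factor(wins, levels = words))
  out[] <- as.numeric(t) / length(wins)
  out
}

#' Parallel-correlation pseudo dinucleotide composition
#'
#' The PC-PseDNC-General encoding: 16 normalized dinucleotide frequencies
#' plus `lam` sequence-order correlation factors. With standardized
#' properties \eqn{P_q}, the correlation between two dinucleotides is
#' \eqn{\Theta(R_1, R_2) = \frac{1}{n_p}\sum_q (P_q(R_1) - P_q(R_2))^2},
#' the tier-`j` factor is the average of \eqn{\Theta} over all dinucleotide
#' positions `j` apart, and the vector is
#' \eqn{d_u = f_u / (1 + w\sum_j \theta_j)} for the 16 frequency slots and
#' \eqn{d_{16+j} = w\theta_j / (1 + w\sum_j \theta_j)} for the correlation
#' slots. All entries are non-negative and sum to 1.
#'
#' Positions whose dinucleotide contains `N` are skipped in both the
#' frequency and the correlation sums.
#'
#' @param seq RNA sequence; must satisfy `nchar(seq) >= lam + 2`.
#' @param lam number of correlation tiers \eqn{\lambda} (default 10).
#' @param w correlation weight (default 0.05).
#' @param props standardized property matrix from [dinuc_property_table()]
#'   (16 dinucleotides x properties). A raw (unstandardized) matrix is
#'   standardized on entry.
#' @return named numeric vector of length `16 + lam`
#'   (`psednc_01` ... `psednc_<16+lam>`).
#' @export
psednc <- function(seq, lam = 10, w = 0.05, props = dinuc_property_table()) {
  stopifnot(is_count(lam), lam >= 1, is.numeric(w), w >= 0)
  L <- nchar(seq)
  if (L < lam + 2)
    stopf("sequence length %d too short for lambda = %d (need >= %d)",
          L, lam, lam + 2)
  dn <- .dinucleotides()
  props <- as.matrix(props)
  if (nrow(props) != 16 || !setequal(rownames(props), dn))
    stopf("props must be a 16-row matrix over the dinucleotides")
  props <- props[dn, , drop = FALSE]
  # re-standardize defensively: idempotent for already-standardized tables
  props <- standardize_properties(props)

  dinucs <- substring(seq, 1:(L - 1), 2:L)
  valid <- !grepl("N", dinucs, fixed = TRUE)
  idx <- match(dinucs, dn)              # NA for N-containing

  # normalized dinucleotide frequencies over valid positions
  if (!any(valid)) stopf("no N-free dinucleotide in sequence")
  f <- as.numeric(table(factor(dinucs[valid], levels = dn)))
  f <- f / sum(f)

  # theta_j: mean squared-property distance over pairs (i, i+j), both valid
  theta <- numeric(lam)
  for (j in seq_len(lam)) {
    i1 <- seq_len(L - 1 - j)
    ok <- valid[i1] & valid[i1 + j]
    if (!any(ok)) { theta[j] <- 0; next }
    a <- idx[i1][ok]; b <- idx[i1 + j][ok]
    d2 <- rowMeans((props[a, , drop = FALSE] - props[b, , drop = FALSE])^2)
    theta[j] <- mean(d2)
  }

  denom <- 1 + w * sum(theta)
  out <- c(f / denom, w * theta / denom)
  names(out) <- sprintf("psednc_%02d", seq_len(16 + lam))
  out
}

#' GC content of a transcript sequence
#'
#' `(#G + #C) / (#A + #C + #G + #U)`; `N` is excluded from both numerator
#' and denominator.
#'
#' @param seq non-empty RNA sequence.
#' @return proportion in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  if (!nzchar(seq)) stopf("empty sequence")
  counts <- .letter_counts(seq)         # A, C, G, U, other
  known <- sum(counts[1:4])
  if (known == 0) stopf("sequence has no unambiguous bases")
  (counts[2] + counts[3]) / known
}

#' Exon-averaged conservation score of a transcript
#'
#' Per-exon mean of per-base conservation scores (over covered bases only),
#' then the unweighted mean of exon means. Exons with no covered base are
#' dropped from the outer mean; if no exon has coverage the feature is 0
#' with a warning.
#'
#' @param record a `transcript_record` with at least one exon.
#' @param track a `conservation_track`.
#' @return mean conservation in `[0, 1]`.
#' @export
conservation_feature <- function(record, track) {
  if (nrow(record$exons) == 0)
    stopf("transcript %s has no exons", record$transcript_id)
  exon_means <- numeric(0)
  for (e in seq_len(nrow(record$exons))) {
    ex <- record$exons[e, ]
    scores <- conservation_lookup(track, ex$chrom, ex$start:(ex$end - 1))
    scores <- scores[!is.na(scores)]
    if (length(scores) > 0) exon_means <- c(exon_means, mean(scores))
  }
  if (length(exon_means) == 0) {
    warnf("transcript %s: no conserved-base coverage; conservation = 0",
          record$transcript_id)
    return(0)
  }
  mean(exon_means)
}

#' Exonic mutation count of a transcript
#'
#' Number of variant records whose position falls inside any exon of the
#' transcript (each record counts once, duplicates included).
#'
#' @param record a `transcript_record`.
#' @param variants a `variant_table`.
#' @return non-negative integer count.
#' @export
mutation_count <- function(record, variants) {
  if (nrow(record$exons) == 0) {
    warnf("transcript %s has no exons; mutation count = 0",
          record$transcript_id)
    return(0L)
  }
  if (nrow(variants) == 0) return(0L)
  n <- 0L
  for (e in seq_len(nrow(record$exons))) {
    ex <- record$exons[e, ]
    n <- n + sum(variants$chrom == ex$chrom &
                 variants$position >= ex$start &
                 variants$position < ex$end)
  }
  as.integer(n)
}

#' Protein-interaction partner count of a transcript
#'
#' Size of the protein partner set keyed by the transcript's gene id
#' (falling back to the transcript id when the gene id is empty); 0 when the
#' id is absent from the table.
#'
#' @param record a `transcript_record`.
#' @param interactions an `interaction_table`.
#' @return non-negative integer count.
#' @export
interaction_count <- function(record, interactions) {
  key <- if (nzchar(record$gene_id)) record$gene_id else record$transcript_id
  partners <- interactions[[key]]
  if (is.null(partners)) return(0L)
  length(unique(partners))
}

#' Sequence-derived feature block for a set of transcripts
#'
#' Emits the 110 sequence features per transcript in canonical order:
#' 2-mer frequencies (16), 3-mer frequencies (64), pseudo dinucleotide
#' composition (26 with the default `lam = 10`), exon-averaged conservation
#' (`cons_mean`), `gc_content`, interaction partners (`ppi_count`), and
#' exonic mutations (`mut_count`). Annotation inputs may be `NULL`; the
#' corresponding features are imputed as 0 with a warning.
#'
#' @param records a `transcript_set`.
#' @param track optional `conservation_track`.
#' @param variants optional `variant_table`.
#' @param interactions optional `interaction_table`.
#' @param k k-mer sizes (default `c(2, 3)`).
#' @param lam,w,props passed to [psednc()].
#' @return numeric matrix, one row per transcript, named columns.
#' @export
featurize_sequences <- function(records, track = NULL, variants = NULL,
                                interactions = NULL, k = c(2, 3),
                                lam = 10, w = 0.05,
                                props = dinuc_property_table()) {
  ids <- unname(vapply(records, `[[`, "", "transcript_id"))
  rows <- vector("list", length(records))
  missing_warned <- character(0)
  for (r in seq_along(records)) {
    rec <- records[[r]]
    kvecs <- lapply(k, function(kk) kmer_frequencies(rec$sequence, kk))
    ps <- psednc(rec$sequence, lam = lam, w = w, props = props)
    cons <- if (is.null(track)) {
      missing_warned <- union(missing_warned, "conservation")
      0
    } else conservation_feature(rec, track)
    gc <- gc_content(rec$sequence)
    ppi <- if (is.null(interactions)) {
      missing_warned <- union(missing_warned, "interactions")
      0L
    } else interaction_count(rec, interactions)
    mut <- if (is.null(variants)) {
      missing_warned <- union(missing_warned, "variants")
      0L
    } else mutation_count(rec, variants)
    rows[[r]] <- c(unlist(kvecs), ps,
                   cons_mean = cons, gc_content = gc,
                   ppi_count = as.numeric(ppi), mut_count = as.numeric(mut))
  }
  if (length(missing_warned) > 0)
    warnf("missing annotation input(s) imputed as 0: %s",
          paste(missing_warned, collapse = ", "))
  out <- do.call(rbind, rows)
  rownames(out) <- ids
  out
}
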