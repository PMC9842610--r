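#' Configuration for the synthetic benchmark generator
#'
#' Defines the study conditions for desk-scale experiments: a labelled set
#' of transcripts with class signal carried by the same channels the real
#' task uses — k-mer enrichment in the positive class, class-specific
#' Poisson means for exonic mutation and protein-interaction counts, and a
#' positive-class shift of per-base conservation. A fraction of sequences
#' are near-copies of others to exercise redundancy filtering.
#'
#' @param n_pos,n_neg class sizes (default 60 each).
#' @param length_range transcript length range in nt (default c(150, 300)).
#' @param enriched_kmers named numeric vector: per-position excess
#'   probability of emitting each motif in positive sequences (default
#'   `c(GGC = 0.15)`).
#' @param mutation_rates Poisson means `c(positive, negative)` for exonic
#'   mutation counts (default `c(8, 1)`).
#' @param interaction_rates Poisson means `c(positive, negative)` for
#'   protein-partner counts (default `c(6, 2)`).
#' @param conservation_shift additive shift of positive-class conservation
#'   scores, clipped to `[0, 1]` (default 0.25).
#' @param duplicate_fraction fraction of sequences replaced by near-copies
#'   (2% point mutations) of earlier ones (default 0).
#' @param n_exons_range exons per transcript (default c(1, 4)).
#' @param seed master seed; generation is deterministic given it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_pos = 60, n_neg = 60,
                             length_range = c(150, 300),
                             enriched_kmers = c(GGC = 0.15),
                             mutation_rates = c(8, 1),
                             interaction_rates = c(6, 2),
                             conservation_shift = 0.25,
                             duplicate_fraction = 0,
                             n_exons_range = c(1, 4),
                             seed = 1) {
  stopifnot(is_count(n_pos), is_count(n_neg),
            length(length_range) == 2, length_range[1] >= 20,
            length_range[2] >= length_range[1],
            all(enriched_kmers >= 0), all(enriched_kmers <= 1),
            all(mutation_rates >= 0), all(interaction_rates >= 0),
            duplicate_fraction >= 0, duplicate_fraction <= 1)
  structure(list(n_pos = n_pos, n_neg = n_neg, length_range = length_range,
                 enriched_kmers = enriched_kmers,
                 mutation_rates = mutation_rates,
                 interaction_rates = interaction_rates,
                 conservation_shift = conservation_shift,
                 duplicate_fraction = duplicate_fraction,
                 n_exons_range = n_exons_range, seed = seed),
            class = "synthetic_config")
}

#' Generate a labelled synthetic dataset
#'
#' Sequences come from a uniform ACGU background; positive-class sequences
#' additionally emit the enriched motifs at elevated per-position
#' probability. Each transcript gets non-overlapping exons on its own
#' chromosome whose lengths sum to the sequence length, a per-base
#' conservation profile (positives shifted by `conservation_shift`),
#' Poisson-distributed exonic variants, and Poisson-distributed protein
#' partners. With `duplicate_fraction > 0` the chosen tail of each class is
#' replaced by 2%-mutated copies of earlier members (tagged in
#' `copies`).
#'
#' @param config a [synthetic_config()].
#' @return list with `records` (`transcript_set` with labels), `track`
#'   (`conservation_track`), `variants` (`variant_table`), `interactions`
#'   (`interaction_table`), `labels` (named vector), `copies` (data frame
#'   `copy_id`, `source_id`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_pos + config$n_neg
  labels <- c(rep("positive", config$n_pos), rep("negative", config$n_neg))
  empty <- structure(data.frame(chrom = character(), position = integer(),
                                variant_id = character(),
                                stringsAsFactors = FALSE),
                     class = c("variant_table", "data.frame"))
  if (n == 0)
    return(list(records = structure(list(), class = "transcript_set"),
                track = structure(list(), class = "conservation_track"),
                variants = empty,
                interactions = structure(list(), class = "interaction_table"),
                labels = setNames(character(0), character(0)),
                copies = data.frame(copy_id = character(),
                                    source_id = character())))

  sample_range <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

  ids <- sprintf("synth_t%04d", seq_len(n))
  seqs <- character(n)
  for (i in seq_len(n)) {
    L <- sample_range(config$length_range[1], config$length_range[2])
    seqs[i] <- random_sequence(L,
      motifs = if (labels[i] == "positive") config$enriched_kmers else NULL)
  }

  # near-copies: tag the last duplicate_fraction of each class as 2%-mutated
  # copies of a same-class source, to exercise the redundancy filter
  copies <- data.frame(copy_id = character(), source_id = character(),
                       stringsAsFactors = FALSE)
  if (config$duplicate_fraction > 0) {
    for (cls in c("positive", "negative")) {
      members <- which(labels == cls)
      n_dup <- round(config$duplicate_fraction * length(members))
      if (n_dup == 0 || length(members) - n_dup < 1) next
      dup_idx <- utils::tail(members, n_dup)
      src_pool <- utils::head(members, length(members) - n_dup)
      for (d in dup_idx) {
        src <- src_pool[sample.int(length(src_pool), 1)]
        seqs[d] <- point_mutate(seqs[src], rate = 0.02)
        copies <- rbind(copies,
                        data.frame(copy_id = ids[d], source_id = ids[src],
                                   stringsAsFactors = FALSE))
      }
    }
  }

  # exons: each transcript on its own chromosome, gapped intervals whose
  # lengths sum to the sequence length
  records <- vector("list", n)
  cons_lines <- list()
  var_rows <- list()
  inter_rows <- list()
  for (i in seq_len(n)) {
    L <- nchar(seqs[i])
    chrom <- sprintf("chrS%04d", i)
    n_ex <- sample_range(config$n_exons_range[1], config$n_exons_range[2])
    n_ex <- min(n_ex, max(1L, L %/% 30L))
    cuts <- sort(sample(seq_len(L - 1), n_ex - 1))
    lens <- diff(c(0L, cuts, L))
    gaps <- sample(50:500, n_ex)
    starts <- cumsum(gaps) + c(0L, cumsum(utils::head(lens, -1)))
    exons <- data.frame(chrom = chrom, start = starts,
                        end = starts + lens, strand = "+",
                        stringsAsFactors = FALSE)
    records[[i]] <- transcript_record(ids[i], seqs[i],
                                      gene_id = sprintf("synth_g%04d", i),
                                      exons = exons, label = labels[i])

    # conservation: exon-wise beta-ish noise, positives shifted then clipped
    base <- runif(1, 0.2, 0.5)
    shift <- if (labels[i] == "positive") config$conservation_shift else 0
    for (e in seq_len(n_ex)) {
      score <- pmin(1, pmax(0, base + shift + rnorm(1, 0, 0.05)))
      cons_lines[[length(cons_lines) + 1L]] <-
        sprintf("%s\t%d\t%d\t%.4f", chrom, exons$start[e], exons$end[e],
                score)
    }

    lambda_m <- if (labels[i] == "positive") config$mutation_rates[1]
                else config$mutation_rates[2]
    n_mut <- rpois(1, lambda_m)
    if (n_mut > 0) {
      tx_pos <- sample(seq_len(L), n_mut, replace = TRUE)
      gpos <- transcript_to_genomic(tx_pos, exons)
      var_rows[[length(var_rows) + 1L]] <-
        data.frame(chrom = chrom, position = gpos,
                   variant_id = sprintf("%s_v%03d", ids[i], seq_len(n_mut)),
                   stringsAsFactors = FALSE)
    }

    lambda_i <- if (labels[i] == "positive") config$interaction_rates[1]
                else config$interaction_rates[2]
    n_int <- rpois(1, lambda_i)
    if (n_int > 0)
      inter_rows[[length(inter_rows) + 1L]] <-
        data.frame(lncrna_id = sprintf("synth_g%04d", i),
                   protein_id = sprintf("P%05d", sample.int(99999, n_int)),
                   stringsAsFactors = FALSE)
  }
  names(records) <- ids

  track <- parse_conservation_lines(unlist(cons_lines))
  variants <- if (length(var_rows))
    structure(do.call(rbind, var_rows),
              class = c("variant_table", "data.frame")) else empty
  interactions <- if (length(inter_rows)) {
    df <- do.call(rbind, inter_rows)
    structure(lapply(split(df$protein_id, df$lncrna_id), unique),
              class = "interaction_table")
  } else structure(list(), class = "interaction_table")

  list(records = structure(records, class = "transcript_set"),
       track = track, variants = variants, interactions = interactions,
       labels = setNames(labels, ids), copies = copies)
}

#' Generate a signal-free (null) dataset
#'
#' Both classes are drawn from one distribution: no motif enrichment, equal
#' mutation and interaction means (the averages of the strong-signal pair),
#' no conservation shift. Labels are assigned but carry no information, so
#' cross-validated F1 should sit near chance.
#'
#' @param config a [synthetic_config()]; its signal fields are neutralized.
#' @return same structure as [generate_dataset()].
#' @export
null_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  config$enriched_kmers <- setNames(numeric(0), character(0))
  config$mutation_rates <- rep(mean(config$mutation_rates), 2)
  config$interaction_rates <- rep(mean(config$interaction_rates), 2)
  config$conservation_shift <- 0
  generate_dataset(config)
}

# uniform ACGU sequence with optional motif over-emission: at each position,
# with probability `excess` the motif is written instead of a single base
random_sequence <- function(L, motifs = NULL) {
  out <- character(0)
  len <- 0L
  if (is.null(motifs) || length(motifs) == 0) {
    return(paste(sample(RNA_BASES, L, replace = TRUE), collapse = ""))
  }
  p_any <- sum(motifs)
  while (len < L) {
    if (runif(1) < p_any) {
      m <- names(motifs)[sample.int(length(motifs), 1,
                                    prob = motifs / p_any)]
      out <- c(out, m); len <- len + nchar(m)
    } else {
      out <- c(out, sample(RNA_BASES, 1)); len <- len + 1L
    }
  }
  substr(paste(out, collapse = ""), 1, L)
}

# substitute a `rate` fraction of positions with random different bases
point_mutate <- function(seq, rate = 0.02) {
  chars <- seq_chars(seq)
  n_mut <- max(1L, round(rate * length(chars)))
  at <- sample(seq_along(chars), n_mut)
  for (p in at) chars[p] <- sample(setdiff(RNA_BASES, chars[p]), 1)
  paste(chars, collapse = "")
}

# map 1-based transcript positions to 0-based genomic positions via exons
transcript_to_genomic <- function(tx_pos, exons) {
  lens <- exons$end - exons$start
  offsets <- c(0L, cumsum(lens))
  vapply(tx_pos, function(p) {
    e <- findInterval(p - 1L, offsets, rightmost.closed = FALSE)
    exons$start[e] + (p - 1L - offsets[e])
  }, numeric(1))
}

# build a conservation_track from bedGraph-like lines without touching disk
parse_conservation_lines <- function(lines) {
  tmp <- tempfile(fileext = ".bedgraph")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  read_conservation(tmp)
}

#' Write a synthetic dataset to disk in the pipeline's input dialects
#'
#' Emits `transcripts.fa`, `exons.bed`, `conservation.bedgraph`,
#' `variants.bed`, `interactions.tsv`, and `labels.tsv` so that the real
#' readers are exercised end to end.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$records, file.path(dir, "transcripts.fa"))
  bed <- do.call(rbind, lapply(dataset$records, function(r) {
    if (nrow(r$exons) == 0) return(NULL)
    data.frame(chrom = r$exons$chrom, start = r$exons$start,
               end = r$exons$end, name = r$transcript_id, score = 0,
               strand = r$exons$strand, stringsAsFactors = FALSE)
  }))
  write.table(bed, file.path(dir, "exons.bed"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  cons <- unlist(lapply(names(dataset$track), function(chrom) {
    ch <- dataset$track[[chrom]]
    # emit runs of constant score as intervals
    brk <- c(0, which(diff(ch$pos) != 1 | diff(ch$score) != 0),
             length(ch$pos))
    vapply(seq_len(length(brk) - 1), function(b) {
      i1 <- brk[b] + 1; i2 <- brk[b + 1]
      sprintf("%s\t%d\t%d\t%.4f", chrom, ch$pos[i1], ch$pos[i2] + 1L,
              ch$score[i1])
    }, character(1))
  }))
  writeLines(cons, file.path(dir, "conservation.bedgraph"))
  v <- dataset$variants
  writeLines(sprintf("%s\t%d\t%s", v$chrom, v$position, v$variant_id),
             file.path(dir, "variants.bed"))
  inter <- do.call(rbind, lapply(names(dataset$interactions), function(g)
    data.frame(lncrna_id = g, protein_id = dataset$interactions[[g]],
               stringsAsFactors = FALSE)))
  if (is.null(inter))
    inter <- data.frame(lncrna_id = character(), protein_id = character())
  write.table(inter, file.path(dir, "interactions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  labs <- data.frame(transcript_id = names(dataset$labels),
                     gene_id = vapply(dataset$records, `[[`, "", "gene_id"),
                     label = unname(dataset$labels))
  write.table(labs, file.path(dir, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
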