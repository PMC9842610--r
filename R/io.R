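#' Read lncRNA transcript sequences from a FASTA file
#'
#' Sequences are normalized to the RNA alphabet: letters are uppercased and
#' `T` is mapped to `U`. IUPAC ambiguity codes other than `N`
#' (`R`, `Y`, `S`, `W`, `K`, `M`, `B`, `D`, `H`, `V`) are collapsed to `N`
#' with a warning; any other character is an error. Record order follows the
#' file.
#'
#' @param path path to a FASTA file.
#' @param labels optional named character vector mapping transcript ids to
#'   class labels (`"positive"`/`"negative"`); unlisted ids get `"unknown"`.
#' @return A `transcript_set`: a list of transcript records, each a list with
#'   elements `transcript_id`, `gene_id`, `sequence`, `exons` (a data frame
#'   with columns `chrom`, `start`, `end`, `strand`; 0-based half-open), and
#'   `label`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1", "acgt"), fa)
#' read_fasta(fa)[[1]]$sequence  # "ACGU"
#' @export
read_fasta <- function(path, labels = NULL) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stopf("empty FASTA file: %s", path)
  # id = first whitespace-delimited token of the header
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids))
    stopf("duplicate transcript id(s) in %s: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- vapply(as.character(set), normalize_rna, character(1),
                 USE.NAMES = FALSE)
  records <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    lab <- "unknown"
    if (!is.null(labels) && ids[i] %in% names(labels))
      lab <- as.character(labels[[ids[i]]])
    records[[i]] <- transcript_record(ids[i], sequence = seqs[i], label = lab)
  }
  names(records) <- ids
  structure(records, class = "transcript_set")
}

# uppercase, T->U, ambiguity codes (except N) -> N with warning;
# anything outside IUPAC nucleotide codes is an error
normalize_rna <- function(seq) {
  s <- chartr("T", "U", toupper(seq))
  bad <- gsub("[ACGUN]", "", s)
  if (nchar(bad) > 0) {
    amb <- "RYSWKMBDHV"
    non_iupac <- gsub(sprintf("[%s]", amb), "", bad)
    if (nchar(non_iupac) > 0)
      stopf("non-nucleotide character(s) in sequence: %s",
            paste(unique(seq_chars(non_iupac)), collapse = ", "))
    warnf("%d IUPAC ambiguity code(s) collapsed to N", nchar(bad))
    s <- chartr(amb, strrep("N", nchar(amb)), s)
  }
  if (nchar(s) < 1) stopf("empty sequence")
  s
}

#' Construct a single transcript record
#'
#' @param transcript_id transcript identifier (unique within a set).
#' @param sequence RNA sequence over `A C G U N` (normalized on input).
#' @param gene_id gene identifier; may be `""`.
#' @param exons data frame with columns `chrom`, `start`, `end`, `strand`
#'   (0-based half-open genomic intervals) or `NULL` for sequence-only use.
#'   Exons must be sorted, non-overlapping, and sum to the sequence length.
#' @param label one of `"positive"`, `"negative"`, `"unknown"`.
#' @return A list of class `transcript_record`.
#' @export
transcript_record <- function(transcript_id, sequence, gene_id = "",
                              exons = NULL, label = "unknown") {
  sequence <- normalize_rna(sequence)
  label <- match.arg(label, c("positive", "negative", "unknown"))
  if (is.null(exons)) {
    exons <- data.frame(chrom = character(), start = integer(),
                        end = integer(), strand = character(),
                        stringsAsFactors = FALSE)
  } else {
    exons <- as.data.frame(exons, stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "start", "end", "strand") %in% names(exons)))
    if (any(exons$end <= exons$start))
      stopf("transcript %s: exon with end <= start", transcript_id)
    o <- order(exons$chrom, exons$start)
    exons <- exons[o, , drop = FALSE]
    same <- exons$chrom[-1] == exons$chrom[-nrow(exons)]
    if (nrow(exons) > 1 &&
        any(same & exons$start[-1] < exons$end[-nrow(exons)]))
      stopf("transcript %s: overlapping exons", transcript_id)
    if (sum(exons$end - exons$start) != nchar(sequence))
      stopf("transcript %s: exon lengths (%d) != sequence length (%d)",
            transcript_id, sum(exons$end - exons$start), nchar(sequence))
    rownames(exons) <- NULL
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 sequence = sequence, exons = exons, label = label),
            class = "transcript_record")
}

#' @export
print.transcript_record <- function(x, ...) {
  cat(sprintf("<transcript %s> %d nt, %d exon(s), label=%s\n",
              x$transcript_id, nchar(x$sequence), nrow(x$exons), x$label))
  invisible(x)
}

#' @export
print.transcript_set <- function(x, ...) {
  labs <- table(factor(vapply(x, `[[`, "", "label"),
                       c("positive", "negative", "unknown")))
  cat(sprintf("<transcript_set> %d records (%d positive, %d negative, %d unknown)\n",
              length(x), labs[["positive"]], labs[["negative"]],
              labs[["unknown"]]))
  invisible(x)
}

#' Write transcript records to FASTA
#'
#' @param records a `transcript_set` or list of `transcript_record`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqs <- Biostrings::BStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, `[[`, "", "transcript_id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' Accepts BED4 (name, no strand) or BED6. Coordinates are 0-based half-open
#' and kept that way. Malformed lines are reported with their line number.
#'
#' @param path path to a BED file.
#' @return data frame with columns `chrom`, `start`, `end`, `name`, `strand`
#'   (strand `"+"` when absent). Empty file gives an empty data frame.
#' @export
read_bed_intervals <- function(path) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      strand = character(), stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4)
      stopf("BED line %d: expected >= 4 tab-separated columns, got %d",
            i, length(f))
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end))
      stopf("BED line %d: non-integer coordinates", i)
    if (end <= start)
      stopf("BED line %d: end (%d) <= start (%d)", i, end, start)
    if (start < 0) stopf("BED line %d: negative start", i)
    strand <- if (length(f) >= 6 && f[6] %in% c("+", "-")) f[6] else "+"
    out[[i]] <- data.frame(chrom = f[1], start = start, end = end,
                           name = f[4], strand = strand,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Read a per-base conservation track
#'
#' Parses a bedGraph-like text dialect: tab-separated
#' `chrom  start  end  score` with 0-based half-open intervals, expanded to
#' per-base scores in `[0, 1]` (the phastCons scale). When intervals overlap,
#' the later line wins for the shared bases and a warning is emitted.
#'
#' @param path path to the track file.
#' @return A `conservation_track`: per chromosome, sorted integer positions
#'   with their scores. Query with [conservation_lookup()]; absent positions
#'   return `NA`, which is distinct from a score of 0.
#' @export
read_conservation <- function(path) {
  if (!file.exists(path)) stopf("conservation file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|#)", lines)]
  pos <- list()
  overlap_warned <- FALSE
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4)
      stopf("conservation line %d: expected chrom, start, end, score", i)
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    score <- suppressWarnings(as.numeric(f[4]))
    if (is.na(start) || is.na(end) || is.na(score))
      stopf("conservation line %d: unparseable fields", i)
    if (end <= start) stopf("conservation line %d: end <= start", i)
    if (score < 0 || score > 1)
      stopf("conservation line %d: score %.3f outside [0, 1]", i, score)
    p <- start:(end - 1)
    chrom <- f[1]
    if (is.null(pos[[chrom]])) {
      pos[[chrom]] <- list(pos = p, score = rep(score, length(p)))
    } else {
      hit <- p %in% pos[[chrom]]$pos
      if (any(hit) && !overlap_warned) {
        warnf("overlapping conservation intervals; later lines win")
        overlap_warned <- TRUE
      }
      # last wins: drop previously stored copies of overlapping bases
      keep <- !(pos[[chrom]]$pos %in% p)
      pos[[chrom]]$pos <- c(pos[[chrom]]$pos[keep], p)
      pos[[chrom]]$score <- c(pos[[chrom]]$score[keep], rep(score, length(p)))
    }
  }
  for (chrom in names(pos)) {
    o <- order(pos[[chrom]]$pos)
    pos[[chrom]]$pos <- pos[[chrom]]$pos[o]
    pos[[chrom]]$score <- pos[[chrom]]$score[o]
  }
  structure(pos, class = "conservation_track")
}

#' Look up per-base conservation scores
#'
#' @param track a `conservation_track` from [read_conservation()].
#' @param chrom chromosome name.
#' @param positions integer vector of 0-based positions.
#' @return numeric vector of scores; `NA` for uncovered positions.
#' @export
conservation_lookup <- function(track, chrom, positions) {
  ch <- track[[chrom]]
  if (is.null(ch)) return(rep(NA_real_, length(positions)))
  ch$score[match(positions, ch$pos)]
}

#' Read noncoding variant positions
#'
#' BED-like text: `chrom  pos  id` (3 columns, 0-based positions) or standard
#' BED with `chrom  start  end  id` where the variant position is `start`.
#'
#' @param path path to the variant file.
#' @return A `variant_table` data frame with columns `chrom`, `position`,
#'   `variant_id`. Duplicate records are kept (each counts once).
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stopf("variant file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(structure(data.frame(chrom = character(), position = integer(),
                                variant_id = character(),
                                stringsAsFactors = FALSE),
                     class = c("variant_table", "data.frame")))
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("variant line %d: expected >= 3 columns", i)
    p <- suppressWarnings(as.integer(f[2]))
    if (is.na(p) || p < 0) stopf("variant line %d: bad position", i)
    id <- if (length(f) >= 4 && !is.na(suppressWarnings(as.integer(f[3]))))
      f[4] else f[3]
    out[[i]] <- data.frame(chrom = f[1], position = p, variant_id = id,
                           stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, out), class = c("variant_table", "data.frame"))
}

#' Read lncRNA-protein interaction pairs
#'
#' Tab-separated file with a header line naming columns `lncrna_id` and
#' `protein_id`. Duplicate pairs collapse (set semantics).
#'
#' @param path path to the TSV file.
#' @return An `interaction_table`: a named list mapping lncRNA (gene-level)
#'   ids to character vectors of unique protein ids.
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) stopf("interaction file not found: %s", path)
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, quote = "")
  if (!all(c("lncrna_id", "protein_id") %in% names(df)))
    stopf("interaction TSV must have columns lncrna_id and protein_id")
  tab <- lapply(split(df$protein_id, df$lncrna_id), unique)
  structure(tab, class = "interaction_table")
}

#' Read RNAfold-style dot-bracket structures
#'
#' Parses the plain RNAfold output dialect: a `>id` header, the sequence
#' line, then the structure line ending with the minimum free energy in
#' parentheses, e.g. `(((...))) (-1.20)`.
#'
#' @param path path to the structure file.
#' @return named list of [secondary_structure()] objects keyed by id.
#' @export
read_dotbracket <- function(path) {
  if (!file.exists(path)) stopf("dot-bracket file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stopf("empty dot-bracket file: %s", path)
  headers <- grep("^>", lines)
  if (length(headers) == 0) stopf("no '>' headers in %s", path)
  out <- list()
  for (h in seq_along(headers)) {
    i <- headers[h]
    last <- if (h < length(headers)) headers[h + 1] - 1 else length(lines)
    if (last - i < 2)
      stopf("record at line %d: expected sequence and structure lines", i)
    id <- sub("^>\\s*", "", lines[i])
    id <- strsplit(id, "\\s+")[[1]][1]
    seq <- normalize_rna(trimws(lines[i + 1]))
    m <- regmatches(lines[i + 2],
                    regexec("^([().]+)\\s*\\((\\s*-?[0-9.]+)\\)\\s*$",
                            lines[i + 2]))[[1]]
    if (length(m) != 3)
      stopf("record %s: cannot parse structure line %d (need 'dotbracket (energy)')",
            id, i + 2)
    db <- m[2]
    mfe <- as.numeric(m[3])
    if (nchar(db) != nchar(seq))
      stopf("record %s: structure length %d != sequence length %d",
            id, nchar(db), nchar(seq))
    out[[id]] <- secondary_structure(db, mfe = mfe, sequence = seq)
  }
  out
}
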