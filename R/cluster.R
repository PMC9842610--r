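#' Pairwise sequence identity
#'
#' Identity between two RNA sequences, defined as the number of identical
#' aligned columns in the optimal global alignment (match = 1, mismatch = 0,
#' gap = 0) divided by the length of the shorter sequence — the convention
#' used by greedy redundancy-removal tools. With this scoring the optimal
#' column count equals the length of the longest common subsequence, which
#' is computed exactly by dynamic programming. Symmetric in its arguments.
#'
#' @param a,b non-empty RNA sequence strings.
#' @return identity in `[0, 1]`.
#' @examples
#' pairwise_identity("ACGU", "ACGU")       # 1
#' pairwise_identity("AAAAAAAA", "UUUUUUUU") # 0
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stopf("sequences must be non-empty")
  .lcs_length(a, b) / min(nchar(a), nchar(b))
}

#' Greedy identity-based redundancy clustering
#'
#' CD-HIT-style greedy incremental clustering: sequences are sorted longest
#' first (ties broken lexicographically by id so the run is deterministic),
#' and each sequence joins the first existing cluster whose representative
#' has identity `>= threshold` with it; otherwise it founds a new cluster.
#' Representatives — the longest member of each cluster — form the
#' non-redundant retained set.
#'
#' A letter-composition bound (the identical-column count of any alignment
#' is at most the summed per-base minimum counts of the two sequences) can
#' skip alignments that provably cannot reach the threshold; it never
#' changes the result, only the work done.
#'
#' @param records a `transcript_set` (or list of `transcript_record`s) with
#'   unique ids.
#' @param threshold identity threshold in `(0, 1]`; sequences at or above it
#'   are merged (default 0.6).
#' @param prefilter logical; use the exact composition bound to skip
#'   hopeless alignments (default `TRUE`).
#' @return A `cluster_report`: list with `clusters` (named list
#'   representative id -> character vector of member ids, representative
#'   first), `threshold`, `retained_ids` (ordered as founded), and
#'   `assignments` data frame (`member_id`, `representative_id`,
#'   `identity`).
#' @examples
#' recs <- list(transcript_record("a", "ACGUACGUACGU"),
#'              transcript_record("b", "ACGUACGUACGU"))
#' greedy_cluster(recs, threshold = 0.6)$retained_ids  # "a"
#' @export
greedy_cluster <- function(records, threshold = 0.6, prefilter = TRUE) {
  ids <- vapply(records, `[[`, "", "transcript_id")
  if (anyDuplicated(ids)) stopf("duplicate transcript ids")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stopf("threshold must be in (0, 1]")
  seqs <- vapply(records, `[[`, "", "sequence")
  o <- order(-nchar(seqs), ids)
  ids <- ids[o]; seqs <- seqs[o]

  comp <- lapply(seqs, .letter_counts)
  rep_ids <- character(0)
  rep_seqs <- character(0)
  rep_comp <- list()
  members <- list()
  assign_rep <- character(length(ids))
  assign_ident <- numeric(length(ids))
  for (s in seq_along(ids)) {
    hit <- NA_integer_
    hit_ident <- NA_real_
    for (r in seq_along(rep_ids)) {
      short <- min(nchar(seqs[s]), nchar(rep_seqs[r]))
      need <- threshold * short
      if (prefilter) {
        # identical columns <= summed per-letter minimum counts (A,C,G,U only;
        # N never matches anything meaningfully but counts conservatively)
        if (sum(pmin(comp[[s]], rep_comp[[r]])) < need) next
      }
      ident <- pairwise_identity(seqs[s], rep_seqs[r])
      if (ident >= threshold) { hit <- r; hit_ident <- ident; break }
    }
    if (is.na(hit)) {
      rep_ids <- c(rep_ids, ids[s])
      rep_seqs <- c(rep_seqs, seqs[s])
      rep_comp[[length(rep_ids)]] <- comp[[s]]
      members[[ids[s]]] <- ids[s]
      assign_rep[s] <- ids[s]
      assign_ident[s] <- 1
    } else {
      members[[rep_ids[hit]]] <- c(members[[rep_ids[hit]]], ids[s])
      assign_rep[s] <- rep_ids[hit]
      assign_ident[s] <- hit_ident
    }
  }
  structure(list(clusters = members, threshold = threshold,
                 retained_ids = rep_ids,
                 assignments = data.frame(member_id = ids,
                                          representative_id = assign_rep,
                                          identity = assign_ident,
                                          stringsAsFactors = FALSE)),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  n <- nrow(x$assignments)
  cat(sprintf("<cluster_report> %d sequence(s) -> %d cluster(s) at identity >= %.0f%%\n",
              n, length(x$retained_ids), 100 * x$threshold))
  sizes <- lengths(x$clusters)
  if (any(sizes > 1))
    cat(sprintf("  %d cluster(s) with >1 member; largest has %d\n",
                sum(sizes > 1), max(sizes)))
  invisible(x)
}

#' @export
summary.cluster_report <- function(object, ...) {
  sizes <- lengths(object$clusters)
  structure(list(n_input = nrow(object$assignments),
                 n_retained = length(object$retained_ids),
                 threshold = object$threshold,
                 cluster_sizes = sizes), class = "summary.cluster_report")
}

#' @export
print.summary.cluster_report <- function(x, ...) {
  cat(sprintf("Greedy identity clustering at %.0f%%\n", 100 * x$threshold))
  cat(sprintf("  input sequences : %d\n", x$n_input))
  cat(sprintf("  retained        : %d\n", x$n_retained))
  cat(sprintf("  removed         : %d\n", x$n_input - x$n_retained))
  invisible(x)
}

#' Subset transcript records to the retained representatives
#'
#' @param records the `transcript_set` that was clustered.
#' @param report a `cluster_report` from [greedy_cluster()].
#' @return the retained records as a `transcript_set`, in input order.
#' @export
retained_records <- function(records, report) {
  ids <- vapply(records, `[[`, "", "transcript_id")
  structure(records[ids %in% report$retained_ids], class = "transcript_set")
}
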