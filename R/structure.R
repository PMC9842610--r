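#' Construct a secondary-structure object
#'
#' @param dotbracket structure string over `(`, `)`, `.`.
#' @param mfe minimum free energy in kcal/mol (or a surrogate score).
#' @param sequence optional RNA sequence of the same length.
#' @param surrogate logical; `TRUE` when `mfe` is a surrogate produced by
#'   [fold_fallback()] rather than a thermodynamic energy.
#' @return list of class `secondary_structure` with elements `dotbracket`,
#'   `pair_map` (two-column matrix of 0-based indices `i < j`), `mfe`,
#'   `sequence`, `surrogate`.
#' @export
secondary_structure <- function(dotbracket, mfe = NA_real_, sequence = NULL,
                                surrogate = FALSE) {
  pm <- parse_pairs(dotbracket)
  if (!is.null(sequence) && nchar(sequence) != nchar(dotbracket))
    stopf("structure length %d != sequence length %d",
          nchar(dotbracket), nchar(sequence))
  structure(list(dotbracket = dotbracket, pair_map = pm, mfe = mfe,
                 sequence = sequence, surrogate = surrogate),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> %d nt, %d pairs, mfe=%.2f%s\n",
              nchar(x$dotbracket), nrow(x$pair_map), x$mfe,
              if (x$surrogate) " (surrogate)" else ""))
  invisible(x)
}

#' Parse dot-bracket notation into a pair map
#'
#' Stack-based matching of nested parentheses.
#'
#' @param dotbracket string over `(`, `)`, `.`.
#' @return integer matrix with columns `i`, `j` (0-based, `i < j`), one row
#'   per base pair, ordered by `i`.
#' @examples
#' parse_pairs("(((...)))")
#' @export
parse_pairs <- function(dotbracket) {
  chars <- seq_chars(dotbracket)
  bad <- setdiff(unique(chars), c("(", ")", "."))
  if (length(bad) > 0)
    stopf("invalid character(s) in dot-bracket string: %s",
          paste(bad, collapse = ", "))
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  rows <- list()
  for (idx in seq_along(chars)) {
    c <- chars[idx]
    if (c == "(") {
      stack <- c(stack, idx - 1L)
    } else if (c == ")") {
      if (length(stack) == 0)
        stopf("unbalanced dot-bracket string: unmatched ')' at index %d",
              idx - 1L)
      rows[[length(rows) + 1L]] <- c(stack[length(stack)], idx - 1L)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0)
    stopf("unbalanced dot-bracket string: unmatched '(' at index %d",
          stack[length(stack)])
  if (length(rows) > 0) {
    pairs <- do.call(rbind, rows)
    colnames(pairs) <- c("i", "j")
    pairs <- pairs[order(pairs[, "i"]), , drop = FALSE]
  }
  pairs
}

#' Count base pairs by directional type
#'
#' Each pair `(i, j)` with `i < j` is classified by its 5' and 3' bases as
#' one of the six canonical directional categories `AU`, `GC`, `GU`, `UA`,
#' `CG`, `UG`. Non-canonical pairs (including pairs involving `N`) are not
#' counted; their number is returned in the `ignored` attribute with a
#' warning.
#'
#' @param seq RNA sequence.
#' @param pair_map pair matrix from [parse_pairs()] or a
#'   `secondary_structure`.
#' @return named numeric vector `bp_AU, bp_GC, bp_GU, bp_UA, bp_CG, bp_UG`
#'   with attribute `ignored`.
#' @export
pair_type_counts <- function(seq, pair_map) {
  if (inherits(pair_map, "secondary_structure")) pair_map <- pair_map$pair_map
  chars <- seq_chars(seq)
  if (nrow(pair_map) > 0 && max(pair_map) >= length(chars))
    stopf("pair map indices exceed sequence length %d", length(chars))
  types <- c("AU", "GC", "GU", "UA", "CG", "UG")
  counts <- setNames(numeric(6), paste0("bp_", types))
  ignored <- 0L
  if (nrow(pair_map) > 0) {
    lab <- paste0(chars[pair_map[, "i"] + 1L], chars[pair_map[, "j"] + 1L])
    ok <- lab %in% types
    ignored <- sum(!ok)
    if (ignored > 0)
      warnf("%d non-canonical pair(s) ignored", ignored)
    t <- table(factor(lab[ok], levels = types))
    counts[] <- as.numeric(t)
  }
  attr(counts, "ignored") <- ignored
  counts
}

#' Classify unpaired bases into hairpin, bulge, and other loops
#'
#' Standard loop decomposition of a nested structure: an unpaired base
#' belongs to the loop closed by its nearest enclosing pair. A loop with no
#' interior pairs is a hairpin; a loop with exactly one interior pair and
#' unpaired bases on exactly one side is a bulge; internal loops (both
#' sides), multibranch loops, and exterior unpaired bases count as "other".
#' The three counts always sum to the number of `.` characters.
#'
#' @param seq RNA sequence (used only for length checking; may be `NULL`).
#' @param pair_map pair matrix or `secondary_structure`; the structure
#'   string is required, so passing a `secondary_structure` (or the
#'   dot-bracket string itself) is easiest.
#' @param dotbracket dot-bracket string; required when `pair_map` is a bare
#'   matrix.
#' @return named numeric vector `unp_hairpin, unp_bulge, unp_other`.
#' @export
unpaired_class_counts <- function(seq = NULL, pair_map, dotbracket = NULL) {
  if (inherits(pair_map, "secondary_structure")) {
    dotbracket <- pair_map$dotbracket
    pair_map <- pair_map$pair_map
  } else if (is.character(pair_map) && is.null(dotbracket)) {
    dotbracket <- pair_map
    pair_map <- parse_pairs(dotbracket)
  }
  if (is.null(dotbracket)) stopf("dotbracket string required")
  n <- nchar(dotbracket)
  if (!is.null(seq) && nchar(seq) != n)
    stopf("sequence length %d != structure length %d", nchar(seq), n)
  chars <- seq_chars(dotbracket)
  counts <- c(unp_hairpin = 0, unp_bulge = 0, unp_other = 0)
  if (n == 0) return(counts)

  # enclosing pair of every position: scan with a stack of open pairs
  partner <- rep(NA_integer_, n)
  if (nrow(pair_map) > 0) {
    partner[pair_map[, "i"] + 1L] <- pair_map[, "j"]
    partner[pair_map[, "j"] + 1L] <- pair_map[, "i"]
  }
  enclosing <- rep(NA_integer_, n)   # 0-based open index of nearest enclosing pair
  stack <- integer(0)
  for (p in seq_len(n)) {
    c <- chars[p]
    if (c == "(") {
      enclosing[p] <- if (length(stack)) stack[length(stack)] else NA_integer_
      stack <- c(stack, p - 1L)
    } else if (c == ")") {
      stack <- stack[-length(stack)]
      enclosing[p] <- if (length(stack)) stack[length(stack)] else NA_integer_
    } else {
      enclosing[p] <- if (length(stack)) stack[length(stack)] else NA_integer_
    }
  }

  dots <- which(chars == ".")
  if (length(dots) == 0) return(counts)

  # loop type per closing pair: children = pairs whose enclosing pair is it
  loop_type <- function(open0) {
    close0 <- partner[open0 + 1L]
    kids_open <- which(chars == "(" & enclosing == open0)  # 1-based
    n_kids <- length(kids_open)
    if (n_kids == 0) return("hairpin")
    if (n_kids == 1) {
      k_open0 <- kids_open[1] - 1L
      k_close0 <- partner[k_open0 + 1L]
      left <- k_open0 - open0 - 1L           # unpaired bases 5' of the child
      right <- close0 - k_close0 - 1L        # unpaired bases 3' of the child
      if ((left > 0) != (right > 0)) return("bulge")
      return("other")                        # internal loop (or stacked: no dots)
    }
    "other"                                  # multibranch
  }

  types <- c(hairpin = 0, bulge = 0, other = 0)
  encl_of_dots <- enclosing[dots]
  exterior <- sum(is.na(encl_of_dots))
  types["other"] <- types["other"] + exterior
  for (open0 in unique(encl_of_dots[!is.na(encl_of_dots)])) {
    k <- sum(encl_of_dots == open0, na.rm = TRUE)
    lt <- loop_type(open0)
    types[lt] <- types[lt] + k
  }
  counts[] <- c(types[["hairpin"]], types[["bulge"]], types[["other"]])
  counts
}

#' Fold an RNA sequence with a maximum-weight nested-pairing model
#'
#' A self-contained Nussinov-style dynamic programme maximizing the total
#' weight of canonical pairs (GC = 3, AU = 2, GU = 1), with hairpin loops
#' forced to enclose at least `min_hairpin` unpaired bases. The reported
#' `mfe` is the negated total pair weight, a *surrogate* stability score —
#' not a thermodynamic energy. For production work, feed true RNAfold output
#' through [read_dotbracket()] instead; this folder exists so the complete
#' pipeline runs with no external dependencies.
#'
#' Traceback is deterministic: the 5' base of an interval pairs with its
#' smallest admissible partner whenever pairing attains the optimum.
#'
#' @param seq RNA sequence (bases other than `A C G U` never pair).
#' @param min_hairpin minimum unpaired bases enclosed by a hairpin
#'   (default 3, the standard steric constraint).
#' @return a [secondary_structure()] with `surrogate = TRUE` and
#'   `mfe = -total pair weight`.
#' @examples
#' fold_fallback("GGGAAACCC")$dotbracket  # "(((...)))"
#' @export
fold_fallback <- function(seq, min_hairpin = 3) {
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) < 1)
    stopf("seq must be a non-empty string")
  stopifnot(is_count(min_hairpin))
  res <- .nussinov_fold(seq, as.integer(min_hairpin))
  secondary_structure(res$structure, mfe = -as.numeric(res$score),
                      sequence = seq, surrogate = TRUE)
}

#' Structure-derived feature block for a set of transcripts
#'
#' Emits the 10 structural features per transcript: `mfe`, six directional
#' base-pair counts, and three unpaired-loop class counts.
#'
#' @param records a `transcript_set`.
#' @param structures optional named list of `secondary_structure` objects
#'   (e.g. from [read_dotbracket()]); transcripts without an entry fall back
#'   to [fold_fallback()].
#' @param max_fold_len sequences longer than this are truncated to their
#'   first `max_fold_len` bases before fallback folding (the dynamic
#'   programme is cubic); a warning reports how many were truncated. Ignored
#'   for supplied structures.
#' @param min_hairpin passed to [fold_fallback()].
#' @return numeric matrix, one row per transcript, 10 named columns, with
#'   attribute `surrogate_mfe` = TRUE if any `mfe` came from the fallback
#'   folder.
#' @export
featurize_structures <- function(records, structures = NULL,
                                 max_fold_len = 300, min_hairpin = 3) {
  ids <- unname(vapply(records, `[[`, "", "transcript_id"))
  cols <- c("mfe", "bp_AU", "bp_GC", "bp_GU", "bp_UA", "bp_CG", "bp_UG",
            "unp_hairpin", "unp_bulge", "unp_other")
  out <- matrix(NA_real_, nrow = length(records), ncol = length(cols),
                dimnames = list(ids, cols))
  truncated <- 0L
  any_surrogate <- FALSE
  for (r in seq_along(records)) {
    seq <- records[[r]]$sequence
    st <- structures[[ids[r]]]
    if (is.null(st)) {
      if (nchar(seq) > max_fold_len) {
        seq <- substr(seq, 1, max_fold_len)
        truncated <- truncated + 1L
      }
      st <- fold_fallback(seq, min_hairpin = min_hairpin)
      any_surrogate <- TRUE
    } else {
      if (nchar(st$dotbracket) != nchar(seq))
        stopf("transcript %s: supplied structure length mismatch", ids[r])
    }
    bp <- suppressWarnings(pair_type_counts(seq, st$pair_map))
    unp <- unpaired_class_counts(seq, st)
    out[r, ] <- c(st$mfe, as.numeric(bp), as.numeric(unp))
  }
  if (truncated > 0)
    warnf("%d sequence(s) truncated to %d nt for fallback folding",
          truncated, max_fold_len)
  attr(out, "surrogate_mfe") <- any_surrogate
  out
}
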