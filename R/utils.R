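# internal helpers shared across modules

RNA_BASES <- c("A", "C", "G", "U")

# all k-mers over A<C<G<U in lexicographic order (first position most
# significant, so the last position varies fastest)
all_kmers <- function(k) {
  grid <- expand.grid(rep(list(RNA_BASES), k), stringsAsFactors = FALSE)
  do.call(paste0, rev(grid))
}

# the 16 dinucleotides, lexicographic: AA, AC, AG, AU, CA, ...
.dinucleotides <- function() as.vector(t(outer(RNA_BASES, RNA_BASES, paste0)))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x == round(x)

# split a sequence string into single characters
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# deterministic sub-seed derivation, kept within 32-bit integer range
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 48271 + offset) %% 2147483647L)
}
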