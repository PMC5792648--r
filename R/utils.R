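#' @importFrom methods as is
#' @importFrom stats rnorm rlnorm runif rbinom cor sd t.test aggregate setNames
#' @importFrom utils head tail write.table read.table
NULL

RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

BASES <- c("A", "C", "G", "T")

# run `expr` under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  withr::with_seed(as.integer(seed), expr)
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement; IUPAC ambiguity codes are handled.
#'
#' @param x character vector of sequences over the IUPAC alphabet.
#' @return character vector of reverse complements.
#' @export
rev_comp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

seq_to_int <- function(s) {
  # A=0 C=1 G=2 T=3, anything else NA
  m <- match(strsplit(s, NULL)[[1L]], BASES)
  m - 1L
}

int_to_seq <- function(v) paste(BASES[v + 1L], collapse = "")

# substitute each position independently with probability `rate` (never to
# the same base); returns the mutated integer vector
mutate_positions <- function(v, idx, rate) {
  if (rate <= 0 || length(idx) == 0L) return(v)
  hit <- idx[runif(length(idx)) < rate]
  if (length(hit) > 0L) {
    shift <- sample(1:3, length(hit), replace = TRUE)
    v[hit] <- (v[hit] + shift) %% 4L
  }
  v
}

phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

int_to_phred <- function(q) {
  vapply(q, function(x) intToUtf8(x + 33L), character(1L))
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# deepest common prefix length of two lineage character vectors (NA = unassigned)
common_prefix_depth <- function(a, b) {
  n <- min(length(a), length(b))
  d <- 0L
  for (i in seq_len(n)) {
    if (is.na(a[i]) || is.na(b[i]) || a[i] != b[i]) break
    d <- i
  }
  d
}
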