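DNA_BASES <- c("A", "C", "G", "T")

#' Run code with a private, reproducible RNG stream
#'
#' Saves the caller's `.Random.seed`, seeds the generator with `seed`, runs
#' `code`, and restores the previous RNG state on exit so library calls do not
#' perturb user-level randomness.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  code
}

# Pairwise Hamming distance between equal-length DNA strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Character matrix (one row per sequence, one column per position).
seq_matrix <- function(seqs, width = nchar(seqs[1])) {
  stopifnot(all(nchar(seqs) == width))
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), ncol = width, byrow = TRUE)
}

# Minimum pairwise Hamming distance over a set of equal-length strings.
min_pairwise_hamming <- function(seqs) {
  n <- length(seqs)
  if (n < 2L) return(NA_integer_)
  m <- seq_matrix(seqs)
  best <- nchar(seqs[1])
  for (i in seq_len(n - 1L)) {
    d <- rowSums(m[(i + 1L):n, , drop = FALSE] !=
                   matrix(m[i, ], nrow = n - i, ncol = ncol(m), byrow = TRUE))
    best <- min(best, d)
  }
  as.integer(best)
}

# round() uses banker's rounding; decile sizes need round-half-up.
round_half_up <- function(x) floor(x + 0.5)

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n, width) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * width, replace = TRUE), nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
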