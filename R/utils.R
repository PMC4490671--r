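# Internal helpers shared across modules.

# Evaluate `expr` with a temporary RNG state seeded by `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb the
# session RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a per-item child seed from a root seed
#'
#' Mixes a root seed with an item index (and an optional salt) so that
#' each item gets an independent RNG stream: adding a scaffold to a
#' community does not perturb the sequences of the others. The result
#' stays within the 32-bit signed integer range `set.seed()` accepts.
#'
#' @param root Root integer seed.
#' @param index Item index.
#' @param salt Optional stream salt separating uses of the same index.
#' @return An integer seed.
#' @export
child_seed <- function(root, index, salt = 0L) {
  m <- 2147483647 # 2^31 - 1 (prime)
  x <- (as.numeric(root) %% m)
  x <- (x * 48271 + as.numeric(index) * 9973 + as.numeric(salt) * 7919) %% m
  as.integer(x)
}

# sample() without the scalar-x surprise: always samples elements of x.
sample_vec <- function(x, n) x[sample.int(length(x), n)]

# Uniform random DNA as a plain character string.
random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Reverse complement for plain character vectors (delegates to Biostrings).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Replace a substring in place, keeping total length constant.
splice_substr <- function(seq, start, replacement) {
  stopifnot(start >= 1, start + nchar(replacement) - 1 <= nchar(seq))
  substr(seq, start, start + nchar(replacement) - 1) <- replacement
  seq
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce a named character vector / DNAStringSet to a named character vector.
as_seq_vector <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    out <- as.character(x)
    names(out) <- names(x)
    out
  } else if (is.character(x)) {
    x
  } else {
    stop("expected a DNAStringSet or a named character vector of sequences")
  }
}
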