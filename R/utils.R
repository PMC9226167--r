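# Internal helpers shared across modules.

vp_assert <- function(cond, msg, class = "viromeprofiler_error") {
  if (!isTRUE(cond)) rlang::abort(msg, class = class)
  invisible(TRUE)
}

vp_assert_fields <- function(df, fields, what) {
  missing <- setdiff(fields, names(df))
  vp_assert(
    length(missing) == 0,
    sprintf("%s is missing required column(s): %s", what,
            paste(missing, collapse = ", "))
  )
}

#' Derive a reproducible sub-seed from a global seed and a stream name
#'
#' Every stochastic draw in the package flows from one integer seed through
#' named substreams, so that adding a new draw to one stage never perturbs
#' another stage's stream.
#'
#' @param seed Integer master seed.
#' @param stream Character stream name.
#' @return An integer seed below 2^31.
#' @export
substream_seed <- function(seed, stream) {
  vp_assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
            "`seed` must be a single integer")
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147480009
  as.integer((abs(as.numeric(seed)) * 7919 + h + 1) %% 2147480009)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

DNA_ALPHABET <- c("A", "C", "G", "T")
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_dna <- function(len) {
  paste(sample(DNA_ALPHABET, len, replace = TRUE), collapse = "")
}

random_protein <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

#' Reverse-complement a nucleotide string
#' @param x Character vector of ACGT sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# i.i.d. per-site substitution at `rate`; substitutions always change the
# residue (draws from the remaining alphabet)
mutate_sequence <- function(seq, rate, alphabet) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(ch) {
      sample(setdiff(alphabet, ch), 1)
    }, character(1))
  }
  paste(chars, collapse = "")
}

mutate_protein <- function(seq, rate) mutate_sequence(seq, rate, AA_ALPHABET)
mutate_dna <- function(seq, rate) mutate_sequence(seq, rate, DNA_ALPHABET)

# convert 1-based inclusive coordinates to the package's 0-based half-open
# convention
#' Convert 1-based inclusive intervals to 0-based half-open
#' @param start,end 1-based inclusive coordinates.
#' @return A list with `start` and `end` in 0-based half-open convention.
#' @export
from_one_based <- function(start, end) list(start = start - 1L, end = end)

#' Convert 0-based half-open intervals to 1-based inclusive
#' @param start,end 0-based half-open coordinates.
#' @return A list with `start` and `end` in 1-based inclusive convention.
#' @export
to_one_based <- function(start, end) list(start = start + 1L, end = end)
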