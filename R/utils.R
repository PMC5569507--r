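## Sequence helpers shared across modules. All sequences are handled
## internally in the RNA alphabet {A,C,G,U}; DNA input is converted on read.

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. Errors on characters outside
#' \{A,C,G,U,T,N\}.
#'
#' @param x character vector of sequences.
#' @param name label used in error messages.
#' @return character vector over \{A,C,G,U,N\}.
#' @export
as_rna <- function(x, name = "sequence") {
  x <- chartr("t", "u", toupper(as.character(x)))
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGUN]", x)
  if (any(bad)) {
    stop("non-ACGTUN characters in ", name, " (record ",
         which(bad)[1], ")", call. = FALSE)
  }
  x
}

#' Reverse complement in the RNA alphabet
#'
#' @param x character vector over \{A,C,G,U,N\}.
#' @return reverse complements, 5' to 3'.
#' @export
rc <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGUN", "UGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## Run code with a transient RNG state: seeds locally, restores the caller's
## .Random.seed on exit, so generators never leak global state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## TRUE iff two RNA bases form a Watson-Crick or G:U pair.
is_pair <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G") |
    (a == "G" & b == "U") | (a == "U" & b == "G")
}

## Hamming distance of two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

random_rna <- function(n, len, weights = NULL) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE, prob = weights),
          collapse = "")
  }, character(1))
}
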