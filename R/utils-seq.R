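#' Sequence string utilities
#'
#' Small helpers shared across the pipeline. Sequences are plain character
#' vectors; DNA and RNA are treated as equivalent under T == U wherever two
#' sequences are compared.
#'
#' @param x character vector of sequences.
#' @return character vector of the same length.
#' @name seq-utils
NULL

#' @describeIn seq-utils reverse complement (DNA alphabet; U accepted as T).
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTUNacgtun", "TGCAANtgcaan", x))
}

#' @describeIn seq-utils coerce to uppercase DNA (U -> T).
#' @export
as_dna <- function(x) chartr("U", "T", toupper(x))

#' @describeIn seq-utils coerce to uppercase RNA (T -> U).
#' @export
as_rna <- function(x) chartr("T", "U", toupper(x))

## 0-based half-open substring of a single sequence
substr0 <- function(seq, start, end) {
  if (end <= start) return("")
  substr(seq, start + 1L, end)
}

## in-place 0-based replacement, returns modified sequence
replace0 <- function(seq, start, motif) {
  substr(seq, start + 1L, start + nchar(motif)) <- motif
  seq
}

## random DNA string(s) from the current RNG stream
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

## all occurrences of fixed pattern in subject, 0-based start positions
find_fixed <- function(pattern, subject) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
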