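#' Reverse complement of DNA sequences
#'
#' Vectorised over `x`; strict ACGT alphabet.
#'
#' @param x Character vector of DNA sequences (5'→3').
#' @return Character vector of reverse complements (5'→3').
#' @examples
#' revcomp("GGCGCG") # "CGCGCC"
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    s <- validate_dna(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Validate and normalise a DNA sequence
#'
#' Uppercases, strips whitespace, and rejects anything outside ACGT with a
#' message naming the first offending position. `U` is rejected explicitly:
#' this is a DNA tool and RNA input is treated as an error, not silently
#' converted.
#'
#' @param seq A single character string.
#' @param what Label used in error messages.
#' @return The normalised sequence (uppercase, no whitespace).
#' @export
validate_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string", call. = FALSE)
  s <- toupper(gsub("[[:space:]]", "", seq))
  if (nchar(s) == 0L)
    stop(what, " is empty", call. = FALSE)
  bad <- regexpr("[^ACGT]", s)
  if (bad > 0L) {
    ch <- substr(s, bad, bad)
    if (ch == "U")
      stop(what, ": 'U' at position ", bad,
           " — RNA alphabet not supported (DNA tool)", call. = FALSE)
    stop(what, ": invalid character '", ch, "' at position ", bad,
         call. = FALSE)
  }
  s
}

# TRUE iff bases a and b form a Watson-Crick pair (no wobble)
wc_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
}

# run code with a private RNG stream, restoring the caller's .Random.seed
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
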