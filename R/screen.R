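#' Does a fragment carry a strategy-usable stable hairpin?
#'
#' A fragment is positive when at least one of its hairpins is stable
#' enough to serve as a terminal hairpin after a suitable circular
#' permutation: melting temperature strictly above `tm_floor` and folding
#' free energy strictly below `dG_ceiling` (i.e. −ΔG > 3 kcal/mol at the
#' defaults). Position is deliberately ignored — the scission site of a
#' future ring can be placed wherever the hairpin sits.
#'
#' @param seq DNA sequence.
#' @param tm_floor °C; a qualifying hairpin must melt above this. Default 50.
#' @param dG_ceiling kcal/mol; a qualifying hairpin must be below this.
#'   Default −3.
#' @param temperature °C for free-energy evaluation. Default 25.
#' @param params A [thermo_params()] object.
#' @return List with `positive` (logical) and `best` (one-row data.frame:
#'   the lowest-ΔG qualifying hairpin, or `NULL` if none).
#' @export
classify_fragment <- function(seq, tm_floor = 50, dG_ceiling = -3,
                              temperature = 25, params = thermo_params()) {
  hp <- find_hairpins(seq, temperature = temperature, params = params)
  if (nrow(hp) == 0L) return(list(positive = FALSE, best = NULL))
  qual <- hp[!is.na(hp$tm) & hp$tm > tm_floor & hp$dG < dG_ceiling, ,
             drop = FALSE]
  if (nrow(qual) == 0L) return(list(positive = FALSE, best = NULL))
  list(positive = TRUE, best = qual[1L, , drop = FALSE])  # already dG-sorted
}

#' Screen a collection of fragments for usable hairpins
#'
#' Classifies every fragment with [classify_fragment()] and aggregates the
#' positive fraction — the question being: for how many sequences of this
#' length would the terminal-hairpin route to a ring work without any
#' sequence change?
#'
#' @param seqs Named character vector of DNA sequences (names become ids).
#' @inheritParams classify_fragment
#' @return A `screen_report`: list with `n_fragments`, `fragment_length`
#'   (common length, or `NA` if mixed), `n_positive`, `fraction_positive`,
#'   `thresholds`, and `per_fragment` (data.frame: id, positive, and the
#'   best hairpin's geometry/energetics where present).
#' @export
screen_fragments <- function(seqs, tm_floor = 50, dG_ceiling = -3,
                             temperature = 25, params = thermo_params()) {
  if (length(seqs) == 0L) stop("no fragments to screen", call. = FALSE)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- sprintf("frag_%03d", seq_along(seqs))
  per <- lapply(seq_along(seqs), function(i) {
    cl <- classify_fragment(seqs[[i]], tm_floor, dG_ceiling,
                            temperature, params)
    if (cl$positive)
      data.frame(id = names(seqs)[i], positive = TRUE,
                 start = cl$best$start, stem_len = cl$best$stem_len,
                 loop_len = cl$best$loop_len, dG = cl$best$dG,
                 tm = cl$best$tm)
    else
      data.frame(id = names(seqs)[i], positive = FALSE,
                 start = NA_integer_, stem_len = NA_integer_,
                 loop_len = NA_integer_, dG = NA_real_, tm = NA_real_)
  })
  per <- do.call(rbind, per)
  lens <- nchar(seqs)
  structure(list(
    n_fragments = length(seqs),
    fragment_length = if (length(unique(lens)) == 1L) unname(lens[1L])
                      else NA_integer_,
    n_positive = sum(per$positive),
    fraction_positive = mean(per$positive),
    thresholds = list(tm_floor = tm_floor, dG_ceiling = dG_ceiling),
    per_fragment = per
  ), class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %d fragments (%s nt): %d positive (%.1f%%) at Tm > %g C, dG < %g kcal/mol\n",
              x$n_fragments,
              ifelse(is.na(x$fragment_length), "mixed",
                     as.character(x$fragment_length)),
              x$n_positive, 100 * x$fraction_positive,
              x$thresholds$tm_floor, x$thresholds$dG_ceiling))
  invisible(x)
}

#' Screen a multi-FASTA file
#'
#' @param path Path to a multi-FASTA file of DNA fragments.
#' @inheritParams classify_fragment
#' @return A `screen_report`; see [screen_fragments()].
#' @export
screen_fasta <- function(path, tm_floor = 50, dG_ceiling = -3,
                         temperature = 25, params = thermo_params()) {
  seqs <- read_fasta(path)
  screen_fragments(seqs, tm_floor, dG_ceiling, temperature, params)
}

#' Seedable random DNA fragment generator
#'
#' Generates `n` i.i.d. fragments with independent per-base GC probability
#' `gc` (G and C equiprobable within GC, likewise A/T). A stand-in for a
#' genomic fragment sample: base composition is controlled but none of the
#' repeat structure, CpG depletion or isochore heterogeneity of real
#' genomes is emulated.
#'
#' @param n Number of fragments.
#' @param length Fragment length, nt.
#' @param gc Per-base GC probability in `[0, 1]`. Default 0.5.
#' @param seed Integer seed for reproducibility; `NULL` uses (and advances)
#'   the session RNG. The caller's RNG state is restored when a seed is
#'   given.
#' @param path Optional path: write the fragments as FASTA.
#' @return Named character vector of sequences (invisibly also written to
#'   `path` if given).
#' @examples
#' random_fragments(3, 50, seed = 1)
#' @export
random_fragments <- function(n, length, gc = 0.5, seed = NULL, path = NULL) {
  n <- as.integer(n); length <- as.integer(length)
  stopifnot(n > 0L, length > 0L, gc >= 0, gc <= 1)
  seqs <- with_seed(seed, {
    vapply(seq_len(n), function(i) {
      is_gc <- runif(length) < gc
      half <- runif(length) < 0.5
      paste(ifelse(is_gc, ifelse(half, "G", "C"),
                   ifelse(half, "A", "T")), collapse = "")
    }, character(1))
  })
  names(seqs) <- sprintf("frag_%03d", seq_len(n))
  if (!is.null(path)) write_fasta(seqs, path)
  seqs
}
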