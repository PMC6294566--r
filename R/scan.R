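#' Enumerate perfect-stem hairpins in a linear sequence
#'
#' Finds every maximal perfect Watson–Crick stem-loop in `seq`. A hairpin is
#' reported as `(start, stem_len, loop_len, end)` with 1-based inclusive
#' coordinates on the first and last paired bases; maximality means the stem
#' can be extended neither outward (no WC pair flanking the helix) nor
#' inward (blocked by a non-pairing step or by the minimum loop). Nested
#' sub-stems of a maximal helix are suppressed unless `nested = TRUE`.
#'
#' Each hairpin carries its folding thermodynamics from [hairpin_energy()]
#' and its unimolecular melting temperature. Results are sorted by ascending
#' free energy (most stable first), ties broken by `(start, stem_len)`, so
#' the output order is deterministic.
#'
#' @param seq DNA sequence (5'→3', ACGT).
#' @param min_stem Minimum stem length, bp. Default 3.
#' @param min_loop Minimum loop length, nt. Default 3.
#' @param max_loop Maximum loop length, nt. Default 30.
#' @param temperature °C at which free energies are evaluated. Default 25.
#' @param params A [thermo_params()] object.
#' @param nested If `TRUE`, also report hairpins whose stem is a sub-helix
#'   of a longer one (inner truncations and outward-extendable helices).
#' @return A data.frame with columns `start`, `stem_len`, `loop_len`, `end`,
#'   `dH`, `dS`, `dG`, `tm`; zero rows if no hairpin exists.
#' @examples
#' find_hairpins("ACGCGCACCAGCGCACAAC")
#' find_hairpins("AAAAAAAAAAAAAAAA") # no self-complementarity: empty
#' @export
find_hairpins <- function(seq, min_stem = 3, min_loop = 3, max_loop = 30,
                          temperature = 25, params = thermo_params(),
                          nested = FALSE) {
  seq <- validate_dna(seq)
  min_stem <- as.integer(min_stem); min_loop <- as.integer(min_loop)
  max_loop <- as.integer(max_loop)
  stopifnot(min_stem >= 2L, min_loop >= 3L, max_loop >= min_loop)
  n <- nchar(seq)
  empty <- data.frame(start = integer(), stem_len = integer(),
                      loop_len = integer(), end = integer(),
                      dH = numeric(), dS = numeric(), dG = numeric(),
                      tm = numeric())
  if (n < 2L * min_stem + min_loop) return(empty)

  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  # M[i, j]: bases i and j form a WC pair
  M <- outer(b, b, wc_pair)
  # D[i, j]: length of the perfect helix starting at outer pair (i, j) and
  # growing inward; D[i, j] = 0 where (i, j) do not pair
  D <- matrix(0L, n, n)
  for (w in seq(2L, n - 1L)) {            # w = j - i
    i <- seq_len(n - w); j <- i + w
    inner <- if (w >= 3L) D[cbind(i + 1L, j - 1L)] else 0L
    D[cbind(i, j)] <- ifelse(M[cbind(i, j)], 1L + inner, 0L)
  }

  rows <- list(); k <- 0L
  for (i in seq_len(n)) {
    jmin <- i + 2L * min_stem + min_loop - 1L
    if (jmin > n) break
    for (j in seq(jmin, n)) {
      if (!M[i, j]) next
      extendable_out <- i > 1L && j < n && M[i - 1L, j + 1L]
      if (extendable_out && !nested) next
      window <- j - i + 1L
      s_max <- min(D[i, j], (window - min_loop) %/% 2L)
      if (s_max < min_stem) next
      s_set <- if (nested) seq(min_stem, s_max) else s_max
      for (s in s_set) {
        loop <- window - 2L * s
        if (loop < min_loop || loop > max_loop) next
        k <- k + 1L
        rows[[k]] <- c(start = i, stem_len = s, loop_len = loop, end = j)
      }
    }
  }
  if (k == 0L) return(empty)
  hp <- as.data.frame(do.call(rbind, rows))
  en <- lapply(seq_len(nrow(hp)), function(r) {
    hairpin_energy(substr(seq, hp$start[r], hp$end[r]),
                   hp$stem_len[r], hp$loop_len[r],
                   temperature = temperature, params = params)
  })
  hp$dH <- vapply(en, `[[`, numeric(1), "dH")
  hp$dS <- vapply(en, `[[`, numeric(1), "dS")
  hp$dG <- vapply(en, `[[`, numeric(1), "dG")
  hp$tm <- vapply(en, function(e) {
    if (e$dH < 0 && e$dS < 0) 1000 * e$dH / e$dS - 273.15 else NA_real_
  }, numeric(1))
  hp <- hp[order(hp$dG, hp$start, hp$stem_len), , drop = FALSE]
  rownames(hp) <- NULL
  hp
}

#' Greedy non-overlapping structure assignment
#'
#' Approximates the folded solution structure of a linear strand as a set of
#' mutually non-overlapping hairpins: candidates from [find_hairpins()] are
#' taken in order of ascending free energy and kept if their `[start, end]`
#' footprint does not intersect any hairpin already kept. Deterministic; not
#' a minimum-free-energy fold (no multiloops, bulges or pseudoknots), but
#' adequate for locating which hairpins coexist along a precursor.
#'
#' @inheritParams find_hairpins
#' @return A data.frame with the columns of [find_hairpins()], mutually
#'   non-overlapping, sorted by `start`.
#' @export
assign_structure <- function(seq, min_stem = 3, min_loop = 3, max_loop = 30,
                             temperature = 25, params = thermo_params()) {
  hp <- find_hairpins(seq, min_stem, min_loop, max_loop,
                      temperature = temperature, params = params)
  if (nrow(hp) == 0L) return(hp)
  keep <- logical(nrow(hp))
  occupied <- integer(0)
  for (r in seq_len(nrow(hp))) {
    span <- hp$start[r]:hp$end[r]
    if (!any(span %in% occupied)) {
      keep[r] <- TRUE
      occupied <- c(occupied, span)
    }
  }
  out <- hp[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
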