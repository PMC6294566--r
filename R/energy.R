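#' Enthalpy/entropy/free-energy triple
#'
#' Constructor for the value returned by [stem_energy()] and
#' [hairpin_energy()]. The free energy is always derived from the stored
#' enthalpy and entropy, \eqn{\Delta G = \Delta H - T \Delta S / 1000}, so
#' the three components stay mutually consistent.
#'
#' @param dH Enthalpy, kcal/mol.
#' @param dS Entropy, cal/(mol·K).
#' @param T_kelvin Temperature at which `dG` is evaluated, K.
#' @return An `energy_triple`: list with `dH`, `dS`, `dG`, `T_kelvin`.
#' @export
energy_triple <- function(dH, dS, T_kelvin) {
  stopifnot(is.finite(dH), is.finite(dS), T_kelvin > 0)
  structure(list(dH = dH, dS = dS, dG = dH - T_kelvin * dS / 1000,
                 T_kelvin = T_kelvin),
            class = "energy_triple")
}

#' @export
print.energy_triple <- function(x, ...) {
  cat(sprintf("dH = %.2f kcal/mol, dS = %.2f cal/(mol K), dG(%.2f K) = %.2f kcal/mol\n",
              x$dH, x$dS, x$T_kelvin, x$dG))
  invisible(x)
}

# sum of NN stack dH/dS along a top strand paired with its exact complement;
# n-1 steps for an n-bp helix
stack_sum <- function(top, params) {
  n <- nchar(top)
  dH <- 0; dS <- 0
  for (i in seq_len(n - 1L)) {
    st <- params$stacks[[substr(top, i, i + 1L)]]
    dH <- dH + st$dH
    dS <- dS + st$dS
  }
  list(dH = dH, dS = dS)
}

salt_dS <- function(n_bp, params) {
  params$salt_coef * n_bp * log(params$monovalent_eq)
}

#' Thermodynamics of a perfect Watson–Crick stem
#'
#' Sums nearest-neighbor stack terms over a fully complementary duplex
#' region, adds the terminal A·T penalty at each helix end whose pair is
#' A·T, and applies the entropy salt correction for the bound condition.
#' Only perfect stems are modeled: the two strands must be exact reverse
#' complements.
#'
#' @param top,bottom DNA sequences (5'→3'), equal length >= 2, exact
#'   reverse complements of each other.
#' @param temperature Temperature in °C at which the free energy is
#'   evaluated. Default 25.
#' @param params A [thermo_params()] object.
#' @return An [energy_triple()].
#' @examples
#' stem_energy("GCGC", "GCGC") # GCGC is its own reverse complement
#' @export
stem_energy <- function(top, bottom, temperature = 25,
                        params = thermo_params()) {
  top <- validate_dna(top, "top strand")
  bottom <- validate_dna(bottom, "bottom strand")
  n <- nchar(top)
  if (n < 2L)
    stop("not a valid stem: need >= 2 bp (no dinucleotide step in 1 bp)",
         call. = FALSE)
  if (nchar(bottom) != n || bottom != revcomp(top))
    stop("not a valid stem: strands are not exact reverse complements",
         call. = FALSE)
  ss <- stack_sum(top, params)
  dH <- ss$dH; dS <- ss$dS
  for (end_base in c(substr(top, 1L, 1L), substr(top, n, n))) {
    if (end_base %in% c("A", "T")) {
      dH <- dH + params$terminal_AT$dH
      dS <- dS + params$terminal_AT$dS
    }
  }
  dS <- dS + salt_dS(n, params)
  energy_triple(dH, dS, temperature + 273.15)
}

#' Thermodynamics of a perfect-stem hairpin
#'
#' Free energy of folding a single strand into a stem-loop: nearest-neighbor
#' stack terms over the stem, the loop-closure penalty for `loop_len`
#' (entropic, taken from the loop table via [loop_penalty()]), an A·T
#' closing-pair adjustment at the loop side, the terminal A·T penalty at the
#' open end, and the salt correction. The strand is
#' `arm1 (stem_len) + loop (loop_len) + arm2 (stem_len)` with
#' `arm2 == revcomp(arm1)`.
#'
#' @param seq The full hairpin-forming sequence, 5'→3'.
#' @param stem_len Stem length, bp (>= 2).
#' @param loop_len Loop length, nt (>= 3).
#' @param temperature °C; default 25.
#' @param params A [thermo_params()] object.
#' @return An [energy_triple()] for the folding transition (negative `dG`
#'   means the folded hairpin is favored).
#' @examples
#' hairpin_energy("GCGCACCAGCGC", stem_len = 4, loop_len = 4)
#' @export
hairpin_energy <- function(seq, stem_len, loop_len, temperature = 25,
                           params = thermo_params()) {
  seq <- validate_dna(seq)
  stem_len <- as.integer(stem_len); loop_len <- as.integer(loop_len)
  if (loop_len < 3L)
    stop("loop length must be >= 3 nt (sterically impossible otherwise)",
         call. = FALSE)
  if (stem_len < 2L)
    stop("not a valid stem: need >= 2 bp", call. = FALSE)
  if (nchar(seq) != 2L * stem_len + loop_len)
    stop("sequence length must equal 2*stem_len + loop_len", call. = FALSE)
  arm1 <- substr(seq, 1L, stem_len)
  arm2 <- substr(seq, stem_len + loop_len + 1L, nchar(seq))
  if (arm2 != revcomp(arm1))
    stop("not a valid stem: hairpin arms are not reverse complements",
         call. = FALSE)
  ss <- stack_sum(arm1, params)
  dH <- ss$dH; dS <- ss$dS
  # open (terminal) end of the helix
  if (substr(arm1, 1L, 1L) %in% c("A", "T")) {
    dH <- dH + params$terminal_AT$dH
    dS <- dS + params$terminal_AT$dS
  }
  # loop-side closing pair: entropic A·T adjustment
  if (substr(arm1, stem_len, stem_len) %in% c("A", "T"))
    dS <- dS - params$closing_AT_dG37 * 1000 / params$loop_ref_T
  # loop closure, entropic at the table's reference temperature
  dS <- dS - loop_penalty(loop_len, params) * 1000 / params$loop_ref_T
  dS <- dS + salt_dS(stem_len, params)
  energy_triple(dH, dS, temperature + 273.15)
}

#' Unimolecular hairpin melting temperature
#'
#' For a two-state unimolecular transition the melting temperature is the
#' point where \eqn{\Delta G = 0}: \eqn{T_m = 1000\,\Delta H/\Delta S}
#' (no concentration term, unlike duplex Tm).
#'
#' @param e An [energy_triple()] with `dH < 0` and `dS < 0` (stable-hairpin
#'   regime); anything else has no defined melting transition.
#' @return Melting temperature, °C.
#' @export
hairpin_tm <- function(e) {
  stopifnot(inherits(e, "energy_triple"))
  if (!(e$dS < 0 && e$dH < 0))
    stop("Tm undefined: requires dH < 0 and dS < 0 (two-state folding)",
         call. = FALSE)
  1000 * e$dH / e$dS - 273.15
}
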