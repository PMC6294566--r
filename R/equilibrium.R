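#' Folded/open equilibrium constant of a terminal hairpin
#'
#' For the two-state equilibrium `open <-> folded` with hairpin-folding
#' free energy `dG` (negative for a stable hairpin),
#' \deqn{K = [folded]/[open] = \exp(-\Delta G / RT)}
#' with R = 1.987e-3 kcal/(mol·K). A stable hairpin (`dG < 0`) gives
#' `K > 1`: the ligase-inactive folded form dominates.
#'
#' @param dG Folding free energy, kcal/mol.
#' @param temperature °C. Default 25.
#' @return Dimensionless folded:open ratio.
#' @examples
#' equilibrium_constant(-3.16) # ~ 210: folded form dominates ~200:1
#' @export
equilibrium_constant <- function(dG, temperature = 25) {
  T_k <- temperature + 273.15
  if (any(T_k <= 0)) stop("temperature must be above absolute zero",
                          call. = FALSE)
  exp(-dG / (1.987e-3 * T_k))
}

#' Open-form (ligase-reactive) concentration
#'
#' Exact two-state partition of the total precursor between folded and open
#' forms: `open = total / (1 + K)`. Only the open form is a T4 ligase
#' substrate, so this is the effective reactive concentration however much
#' precursor is added.
#'
#' @param total Total precursor concentration, μM.
#' @param K Folded:open ratio from [equilibrium_constant()].
#' @return Open-form concentration, μM.
#' @examples
#' open_concentration(5, equilibrium_constant(-3.16))   # ~0.024 uM
#' open_concentration(100, equilibrium_constant(-3.16)) # ~0.48 uM
#' @export
open_concentration <- function(total, K) {
  if (any(total < 0) || any(K < 0))
    stop("total and K must be non-negative", call. = FALSE)
  total / (1 + K)
}

#' Maximum preparative concentration for high selectivity
#'
#' Inverts [open_concentration()]: the largest total precursor
#' concentration at which the open form stays at or below
#' `open_threshold`, `max_total = threshold * (1 + K)`. Keeping the open
#' form at or under ~0.1 μM is the working criterion for >85% ring
#' selectivity, so this is the predicted preparative ceiling for a given
#' hairpin stability.
#'
#' @param K Folded:open ratio.
#' @param open_threshold Open-form cap, μM. Default 0.1.
#' @return Maximum total concentration, μM.
#' @examples
#' max_total_concentration(equilibrium_constant(-3.16)) # ~20 uM
#' @export
max_total_concentration <- function(K, open_threshold = 0.1) {
  if (any(K < 0)) stop("K must be non-negative", call. = FALSE)
  if (any(open_threshold <= 0))
    stop("open_threshold must be positive", call. = FALSE)
  open_threshold * (1 + K)
}

#' Threshold classifier for predicted ring selectivity
#'
#' `TRUE` iff the open-form concentration is at or below `open_threshold`
#' (boundary counts as passing). This is a classifier anchored at the
#' 0.1 μM / >85%-selectivity working point, not a continuous
#' selectivity-versus-concentration curve.
#'
#' @param open_conc Open-form concentration, μM.
#' @param open_threshold μM. Default 0.1.
#' @return Logical: predicted high (>85%) selectivity.
#' @export
predict_selectivity_class <- function(open_conc, open_threshold = 0.1) {
  if (any(open_conc < 0)) stop("open_conc must be non-negative",
                               call. = FALSE)
  open_conc <= open_threshold
}

#' Full two-state equilibrium summary for one precursor
#'
#' Convenience wrapper chaining [equilibrium_constant()],
#' [open_concentration()], [max_total_concentration()] and
#' [predict_selectivity_class()]. `K` is propagated unrounded throughout;
#' round only for display.
#'
#' @param dG Hairpin folding free energy, kcal/mol.
#' @param total_conc Total precursor concentration, μM. Default 5.
#' @param temperature °C. Default 25.
#' @param open_threshold μM. Default 0.1.
#' @return An `equilibrium_result`: list with `K`, `fraction_open`,
#'   `open_conc`, `total_conc`, `temperature_K`, `max_total_for_threshold`,
#'   `open_threshold`, `predicted_high_selectivity`.
#' @examples
#' fold_equilibrium(-3.16, total_conc = 5)
#' @export
fold_equilibrium <- function(dG, total_conc = 5, temperature = 25,
                             open_threshold = 0.1) {
  K <- equilibrium_constant(dG, temperature)
  open <- open_concentration(total_conc, K)
  structure(list(
    K = K,
    fraction_open = 1 / (1 + K),
    open_conc = open,
    total_conc = total_conc,
    temperature_K = temperature + 273.15,
    max_total_for_threshold = max_total_concentration(K, open_threshold),
    open_threshold = open_threshold,
    predicted_high_selectivity = predict_selectivity_class(open,
                                                           open_threshold)
  ), class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("<equilibrium_result> K = %.4g (folded:open), open fraction = %.3g\n",
              x$K, x$fraction_open))
  cat(sprintf("  [open] = %.4g uM of %.4g uM total; max total for [open] <= %.3g uM: %.4g uM\n",
              x$open_conc, x$total_conc, x$open_threshold,
              x$max_total_for_threshold))
  cat(sprintf("  predicted high (>85%%) selectivity: %s\n",
              x$predicted_high_selectivity))
  invisible(x)
}
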