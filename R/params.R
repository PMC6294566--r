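#' Nearest-neighbor thermodynamic parameter set
#'
#' Loads the unified DNA nearest-neighbor parameters shipped with the package
#' (stack enthalpies/entropies per dinucleotide step, terminal A·T penalty,
#' hairpin-loop free-energy increments at 37°C, and salt-correction
#' coefficients) and binds them to a solution condition. The defaults are the
#' ligase-buffer condition used throughout the design workflow:
#' \eqn{[\mathrm{Mg}^{2+}]} = 10 mM, no added monovalent salt, 25°C.
#'
#' Divalent magnesium is folded into an effective monovalent concentration
#' \eqn{[\mathrm{Mon}^+] = [\mathrm{Na}^+] + 3.3\sqrt{[\mathrm{Mg}^{2+}]}}
#' and the stem entropy is corrected by
#' \eqn{0.368 \cdot N_{bp} \cdot \ln[\mathrm{Mon}^+]} cal/(mol·K), the
#' standard entropy-only salt correction relative to the 1 M NaCl reference
#' state of the table.
#'
#' @param file Optional path to an alternative parameter JSON with the same
#'   schema as `system.file("extdata", "nn_unified_v1.json", package =
#'   "ringforge")`; `NULL` loads the shipped table.
#' @param mg Magnesium concentration, mol/L. Default 0.010 (10 mM).
#' @param na Monovalent cation concentration, mol/L. Default 0.
#' @return An object of class `thermo_params`: a list with elements `stacks`
#'   (per-step `dH` kcal/mol and `dS` cal/(mol·K)), `terminal_AT` penalty,
#'   `closing_AT_dG37`, `loop_dG37` table, `js_coef`, `loop_ref_T`,
#'   `R` (1.987e-3 kcal/(mol·K)), `na`, `mg`, `monovalent_eq`.
#' @examples
#' p <- thermo_params()
#' p$stacks[["GC"]]
#' @export
thermo_params <- function(file = NULL, mg = 0.010, na = 0) {
  if (is.null(file))
    file <- system.file("extdata", "nn_unified_v1.json", package = "ringforge")
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  stopifnot(mg >= 0, na >= 0)
  mon <- na + raw$mg_to_monovalent_factor * sqrt(mg)
  if (mon <= 0)
    stop("no counterions: supply mg > 0 or na > 0", call. = FALSE)
  loops <- raw$hairpin_loop_dG37
  loop_tab <- data.frame(size = as.integer(names(loops)),
                         dG37 = as.numeric(unlist(loops)))
  loop_tab <- loop_tab[order(loop_tab$size), , drop = FALSE]
  if (any(loop_tab$dG37 <= 0) || min(loop_tab$size) > 3L)
    stop("loop table must cover size 3 with positive increments",
         call. = FALSE)
  stacks <- lapply(raw$stacks, function(e) list(dH = e$dH, dS = e$dS))
  steps <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           paste0))
  missing <- setdiff(steps, names(stacks))
  if (length(missing))
    stop("parameter table lacks NN steps: ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(list(
    name = raw$name, version = raw$version,
    stacks = stacks,
    terminal_AT = list(dH = raw$terminal_AT_penalty$dH,
                       dS = raw$terminal_AT_penalty$dS),
    closing_AT_dG37 = raw$hairpin_closing_AT_dG37,
    loop_dG37 = loop_tab,
    js_coef = raw$loop_extrapolation_coefficient,
    loop_ref_T = raw$loop_reference_temperature_K,
    R = raw$gas_constant_kcal,
    salt_coef = raw$salt_dS_coefficient,
    na = na, mg = mg, monovalent_eq = mon
  ), class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("<thermo_params> %s v%s | [Mg2+] = %g M, [Na+] = %g M (mono-eq %.3f M)\n",
              x$name, x$version, x$mg, x$na, x$monovalent_eq))
  invisible(x)
}

#' Hairpin-loop free-energy increment
#'
#' Free-energy penalty (kcal/mol, at the table's 37°C reference) for closing
#' a single-stranded loop of `n` nucleotides. Tabulated sizes are used
#' directly; gaps inside the table are interpolated linearly in `log(n)`;
#' sizes beyond the table are extrapolated with the Jacobson–Stockmayer form
#' \eqn{\Delta G(n) = \Delta G(n_{max}) + c \, R \, T \ln(n/n_{max})}.
#'
#' Loops shorter than 3 nt are sterically impossible and rejected.
#'
#' @param n Integer vector of loop lengths (nt), all >= 3.
#' @param params A [thermo_params()] object.
#' @return Numeric vector of loop penalties, kcal/mol (positive).
#' @export
loop_penalty <- function(n, params = thermo_params()) {
  n <- as.integer(n)
  if (any(is.na(n)) || any(n < 3L))
    stop("loop length must be >= 3 nt (sterically impossible otherwise)",
         call. = FALSE)
  tab <- params$loop_dG37
  nmax <- max(tab$size)
  vapply(n, function(k) {
    if (k <= nmax) {
      hit <- match(k, tab$size)
      if (!is.na(hit)) return(tab$dG37[hit])
      lo <- max(tab$size[tab$size < k]); hi <- min(tab$size[tab$size > k])
      glo <- tab$dG37[tab$size == lo]; ghi <- tab$dG37[tab$size == hi]
      glo + (ghi - glo) * (log(k) - log(lo)) / (log(hi) - log(lo))
    } else {
      tab$dG37[tab$size == nmax] +
        params$js_coef * params$R * params$loop_ref_T * log(k / nmax)
    }
  }, numeric(1))
}
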