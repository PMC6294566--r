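# Gel band-intensity quantification.
#
# One dPAGE lane of a cyclization reaction resolves three species:
#   C - circular monomeric ring, P - polymeric byproducts (linear and
#   multi-cyclic pooled), R - remaining linear substrate.
# All three formulas are scale-invariant in (C, P, R).

check_lane <- function(C, P, R = NULL) {
  vals <- c(C, P, R)
  if (any(is.na(vals)) || any(vals < 0))
    stop("band intensities must be non-negative numbers", call. = FALSE)
}

#' Conversion of linear substrate
#'
#' Fraction of substrate consumed by ligation:
#' \deqn{Conversion(\%) = (1 - R/(P + C + R)) \times 100.}
#'
#' @param C,P,R Band intensities (arbitrary units, >= 0) of the circular
#'   ring, the pooled polymeric byproducts, and the remaining linear
#'   substrate. Vectorised.
#' @return Percent in `[0, 100]`.
#' @examples
#' conversion(C = 50, P = 30, R = 20) # 80
#' @export
conversion <- function(C, P, R) {
  check_lane(C, P, R)
  tot <- C + P + R
  if (any(tot == 0))
    stop("all-zero lane: conversion undefined", call. = FALSE)
  (1 - R / tot) * 100
}

#' Selectivity for the monomeric ring
#'
#' Fraction of the ligated product that is the monomeric circle:
#' `C / (C + P) * 100`. Lanes with no ligated product at all (`C + P = 0`)
#' have no defined selectivity and return `NA` (distinct from 0, which
#' means "all product is polymeric").
#'
#' @inheritParams conversion
#' @return Percent in `[0, 100]`, or `NA` where `C + P = 0`.
#' @examples
#' selectivity(C = 45, P = 55) # 45
#' @export
selectivity <- function(C, P) {
  check_lane(C, P)
  out <- ifelse(C + P > 0, C / (C + P) * 100, NA_real_)
  if (any(is.na(out)))
    warning("lane(s) with C + P = 0: selectivity undefined, returning NA",
            call. = FALSE)
  out
}

#' Yield of the monomeric ring
#'
#' `C / (C + P + R) * 100`; satisfies the identity
#' `yield = selectivity * conversion / 100` exactly.
#'
#' @inheritParams conversion
#' @return Percent in `[0, 100]`.
#' @examples
#' yield_pct(C = 50, P = 30, R = 20) # 50
#' @export
yield_pct <- function(C, P, R) {
  check_lane(C, P, R)
  tot <- C + P + R
  if (any(tot == 0))
    stop("all-zero lane: yield undefined", call. = FALSE)
  C / tot * 100
}

#' Quantify a table of gel lanes
#'
#' Adds `conversion`, `selectivity` and `yield` columns to a data.frame of
#' band intensities.
#'
#' @param lanes data.frame with columns `C`, `P`, `R` (and optionally
#'   `lane_id`).
#' @return The input with three derived percent columns appended.
#' @export
quantify_gel <- function(lanes) {
  stopifnot(is.data.frame(lanes), all(c("C", "P", "R") %in% names(lanes)))
  lanes$conversion <- conversion(lanes$C, lanes$P, lanes$R)
  lanes$selectivity <- suppressWarnings(selectivity(lanes$C, lanes$P))
  lanes$yield <- yield_pct(lanes$C, lanes$P, lanes$R)
  lanes
}
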