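#' All circular permutations of a target ring
#'
#' A covalently closed single-stranded ring can be opened ("hypothetically
#' cut") at any of its n phosphodiester bonds; every resulting linear
#' precursor re-ligates to the same ring. This enumerates all n rotations.
#'
#' @param ring_seq Ring sequence, 5'→3' (any rotation; circular, so the
#'   starting point is arbitrary).
#' @param min_len Warn if the ring is shorter than this (cyclization
#'   selectivity degrades sharply for short precursors). Default 44.
#' @return A data.frame with columns `offset` (0-based rotation) and `seq`;
#'   row `offset = k` is `ring_seq` rotated left by `k`.
#' @examples
#' rotations("ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT")[1:3, ]
#' @export
rotations <- function(ring_seq, min_len = 44) {
  s <- validate_dna(ring_seq, "ring")
  n <- nchar(s)
  if (n < min_len)
    warning("ring shorter than ", min_len,
            " nt: cyclization selectivity is typically poor for short precursors",
            call. = FALSE)
  off <- 0:(n - 1L)
  seqs <- vapply(off, function(k) {
    if (k == 0L) s else paste0(substr(s, k + 1L, n), substr(s, 1L, k))
  }, character(1))
  data.frame(offset = off, seq = seqs)
}

#' Design rules for terminal-hairpin precursor selection
#'
#' Thresholds applied by [design_ring()] to the hairpin nearest each
#' terminus of every circular permutation:
#' \itemize{
#'   \item `d_min`–`d_max`: accepted number of unpaired nucleotides between
#'     the terminus and the first paired base of the stem (default 1–3;
#'     selectivity collapses at 4–5).
#'   \item `dG_ceiling`: the folding free energy must be at most this
#'     (default −3 kcal/mol, i.e. −ΔG > 3) so the folded form dominates.
#'   \item `tm_floor`/`tm_ceiling`: hairpin melting temperature window in °C
#'     (default 50–80). Too unstable and the open form is abundant; too
#'     stable (7-bp-stem territory, Tm ≥ 85°C) and selectivity drops again.
#'   \item `stem_len_preferred`: stem lengths flagged as ideal (default
#'     4–6 bp); informational, not a hard filter.
#'   \item `splint_arm`: nucleotides of splint complementary to each
#'     terminus (default 6, i.e. a 12-nt splint).
#'   \item `min_precursor_len`: warn-below length (default 44 nt).
#' }
#'
#' @param d_min,d_max Distance window, nt.
#' @param dG_ceiling kcal/mol.
#' @param tm_floor,tm_ceiling °C.
#' @param stem_len_preferred Integer vector of preferred stem lengths, bp.
#' @param splint_arm nt per splint arm.
#' @param min_precursor_len nt.
#' @return An object of class `design_rules`.
#' @export
design_rules <- function(d_min = 1, d_max = 3, dG_ceiling = -3,
                         tm_floor = 50, tm_ceiling = 80,
                         stem_len_preferred = c(4, 5, 6),
                         splint_arm = 6, min_precursor_len = 44) {
  stopifnot(d_min <= d_max, tm_floor < tm_ceiling, splint_arm >= 1)
  structure(list(d_min = as.integer(d_min), d_max = as.integer(d_max),
                 dG_ceiling = dG_ceiling, tm_floor = tm_floor,
                 tm_ceiling = tm_ceiling,
                 stem_len_preferred = as.integer(stem_len_preferred),
                 splint_arm = as.integer(splint_arm),
                 min_precursor_len = as.integer(min_precursor_len)),
            class = "design_rules")
}

#' Design the ligation splint for a linear precursor
#'
#' The splint is a single oligonucleotide complementary to the `arm` 3'-most
#' and `arm` 5'-most nucleotides of the precursor, juxtaposing the two ends
#' across the nick: it is the reverse complement of the concatenation
#' `last arm nt ++ first arm nt`.
#'
#' @param linear_seq Precursor sequence, 5'→3'.
#' @param arm Nucleotides hybridised per terminus. Default 6 (12-nt splint).
#' @return The splint sequence, 5'→3', of length `2 * arm`.
#' @examples
#' # a precursor starting GGCGCG... is bound by splint arm CGCGCC
#' design_splint(paste0("GGCGCG", strrep("A", 20), "GGCCGC"))
#' @export
design_splint <- function(linear_seq, arm = 6) {
  s <- validate_dna(linear_seq, "precursor")
  arm <- as.integer(arm)
  n <- nchar(s)
  if (n < 2L * arm)
    stop("precursor must be at least 2*arm nt long", call. = FALSE)
  revcomp(paste0(substr(s, n - arm + 1L, n), substr(s, 1L, arm)))
}

#' Pick the best linear precursor for a target single-stranded DNA ring
#'
#' Implements the terminal-hairpin design protocol. Every circular
#' permutation of the ring is examined: for each rotation the hairpins near
#' the 5' and the 3' terminus are located, and a (rotation, side) candidate
#' passes when its terminal hairpin satisfies all three rules of
#' [design_rules()] — distance to the ligation site within `d_min..d_max`
#' nt, folding free energy at or below `dG_ceiling`, and melting temperature
#' inside the `tm_floor..tm_ceiling` window. Each passing candidate carries
#' its splint and the two-state equilibrium predictions at `total_conc`
#' (equilibrium constant, open-form concentration, maximum preparative
#' concentration for the `open_threshold` open-form cap).
#'
#' Candidates are ranked by predicted maximum preparative concentration
#' (descending), then by more negative folding free energy, then by offset.
#' Rotations whose terminal hairpins fail one or more rules are returned as
#' near-misses with per-rule pass flags, so a failed design explains itself.
#'
#' @param ring_seq Ring sequence (any rotation).
#' @param rules A [design_rules()] object.
#' @param total_conc Intended total precursor concentration, μM. Default 5.
#' @param temperature Reaction temperature, °C. Default 25.
#' @param open_threshold Open-form concentration cap used for the maximum
#'   preparative concentration, μM. Default 0.1.
#' @param permissive_distance0 Accept distance 0 (stem starting at the very
#'   terminus) as passing. Default `FALSE`.
#' @param params A [thermo_params()] object.
#' @param note Free-text note carried into the report header (e.g. buffer
#'   remarks); not interpreted.
#' @return An object of class `ring_design`: list with `candidates` and
#'   `near_misses` data.frames (columns `offset`, `side`, `distance`,
#'   `start`, `stem_len`, `loop_len`, `dG`, `tm`, `splint`, `K`,
#'   `open_conc_uM`, `max_conc_uM`, `pass_distance`, `pass_stability`,
#'   `pass_tm`, `pass`, `preferred_stem`), plus `ring_len`, `rules`,
#'   `total_conc`, `temperature`, `note`.
#' @export
design_ring <- function(ring_seq, rules = design_rules(), total_conc = 5,
                        temperature = 25, open_threshold = 0.1,
                        permissive_distance0 = FALSE,
                        params = thermo_params(), note = NULL) {
  s <- validate_dna(ring_seq, "ring")
  n <- nchar(s)
  floor_len <- 2L * rules$splint_arm + 2L * 3L + 3L
  if (n < floor_len)
    stop("ring of ", n, " nt is below the hard floor of ", floor_len,
         " nt (splint footprint + minimal hairpin)", call. = FALSE)
  rot <- rotations(s, min_len = rules$min_precursor_len)

  near_window <- rules$d_max + 3L  # report near-misses this far out
  rows <- list(); k <- 0L
  for (r in seq_len(nrow(rot))) {
    lin <- rot$seq[r]
    hp <- find_hairpins(lin, temperature = temperature, params = params)
    if (nrow(hp) == 0L) next
    splint <- design_splint(lin, rules$splint_arm)
    for (side in c("5prime", "3prime")) {
      dist <- if (side == "5prime") hp$start - 1L else n - hp$end
      sel <- which(dist <= near_window)
      for (idx in sel) {
        d <- dist[idx]
        pass_distance <- (d >= rules$d_min && d <= rules$d_max) ||
          (permissive_distance0 && d == 0L)
        pass_stability <- hp$dG[idx] <= rules$dG_ceiling
        pass_tm <- !is.na(hp$tm[idx]) &&
          hp$tm[idx] >= rules$tm_floor && hp$tm[idx] <= rules$tm_ceiling
        K <- equilibrium_constant(hp$dG[idx], temperature = temperature)
        k <- k + 1L
        rows[[k]] <- data.frame(
          offset = rot$offset[r], side = side, distance = d,
          start = hp$start[idx], stem_len = hp$stem_len[idx],
          loop_len = hp$loop_len[idx], dG = hp$dG[idx], tm = hp$tm[idx],
          splint = splint, K = K,
          open_conc_uM = open_concentration(total_conc, K),
          max_conc_uM = max_total_concentration(K, open_threshold),
          pass_distance = pass_distance, pass_stability = pass_stability,
          pass_tm = pass_tm,
          pass = pass_distance && pass_stability && pass_tm,
          preferred_stem = hp$stem_len[idx] %in% rules$stem_len_preferred)
      }
    }
  }
  cols <- c("offset", "side", "distance", "start", "stem_len", "loop_len",
            "dG", "tm", "splint", "K", "open_conc_uM", "max_conc_uM",
            "pass_distance", "pass_stability", "pass_tm", "pass",
            "preferred_stem")
  all_rows <- if (k == 0L) {
    stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  } else do.call(rbind, rows)

  cand <- all_rows[all_rows$pass, , drop = FALSE]
  if (nrow(cand) > 0L) {
    # one candidate per (offset, side): keep the most stable qualifier
    cand <- cand[order(cand$dG, cand$start), , drop = FALSE]
    cand <- cand[!duplicated(cand[c("offset", "side")]), , drop = FALSE]
    cand <- cand[order(-cand$max_conc_uM, cand$dG, cand$offset,
                       cand$side), , drop = FALSE]
  }
  near <- all_rows[!all_rows$pass, , drop = FALSE]
  near <- near[order(near$offset, near$side, near$distance), , drop = FALSE]
  rownames(cand) <- NULL; rownames(near) <- NULL
  structure(list(candidates = cand, near_misses = near, ring_len = n,
                 rules = rules, total_conc = total_conc,
                 temperature = temperature,
                 open_threshold = open_threshold, note = note),
            class = "ring_design")
}

#' @export
print.ring_design <- function(x, ...) {
  cat(sprintf("<ring_design> %d-nt ring | %d passing candidate(s), %d near-miss row(s)\n",
              x$ring_len, nrow(x$candidates), nrow(x$near_misses)))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  if (nrow(x$candidates) > 0L) {
    cat("top candidates:\n")
    print(utils::head(x$candidates[, c("offset", "side", "distance",
                                       "stem_len", "loop_len", "dG", "tm",
                                       "max_conc_uM")], 5L))
  } else if (nrow(x$near_misses) > 0L) {
    fails <- colSums(!x$near_misses[c("pass_distance", "pass_stability",
                                      "pass_tm")])
    cat("no rotation passes; rule failures among near-misses:\n")
    print(fails)
  }
  invisible(x)
}

#' Synthetic 64-nt test ring with a designed terminal hairpin
#'
#' Builds a 64-nt ring whose offset-0 linear precursor carries a 4-bp
#' GC-stem hairpin starting at nucleotide `distance + 1` from the 5' end
#' (so `distance` unpaired nucleotides sit between terminus and stem) and a
#' second, internal 4-bp hairpin with a 13-nt loop starting at nucleotide
#' 24 — the two-hairpin layout of the precursors used to establish the
#' terminal-hairpin effect. All non-stem positions are adenine: with no T
#' anywhere in the sequence only G·C pairs can form, so the two designed
#' GC stems are the only hairpins present in any rotation.
#'
#' This is a synthetic construct for tests and examples, not a sequence
#' from any published experiment.
#'
#' @param distance Unpaired nucleotides between the 5' terminus and the
#'   stem, 0–8. Default 2.
#' @return A 64-nt DNA string (the ring, written from the scission site).
#' @examples
#' find_hairpins(synthetic_terminal_ring())[, 1:4]
#' @export
synthetic_terminal_ring <- function(distance = 2) {
  distance <- as.integer(distance)
  stopifnot(distance >= 0L, distance <= 8L)
  bg <- function(k) strrep("A", k)                # inert filler: A never pairs
  h1 <- paste0("GCGC", bg(4L), "GCGC")            # 4-bp stem, 4-nt loop
  h2 <- paste0("GGCC", bg(13L), "GGCC")           # 4-bp stem, 13-nt loop
  pre <- bg(distance)
  gap <- 23L - (distance + nchar(h1))             # h2 starts at nt 24
  stopifnot(gap >= 0L)
  body <- paste0(pre, h1, bg(gap), h2)
  paste0(body, bg(64L - nchar(body)))
}
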