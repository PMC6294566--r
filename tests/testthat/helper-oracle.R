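# Independent brute-force hairpin oracle.
#
# Enumerates every (start, stem_len, loop_len) triple by string comparison
# and computes energies by its own summation straight from the parameter
# JSON -- no code shared with find_hairpins()/hairpin_energy() beyond the
# parameter file itself.

oracle_raw <- jsonlite::read_json(
  system.file("extdata", "nn_unified_v1.json", package = "ringforge"),
  simplifyVector = TRUE)

oracle_pairs <- c(A = "T", T = "A", G = "C", C = "G")

oracle_loop_dG37 <- function(l) {
  tab <- oracle_raw$hairpin_loop_dG37
  sizes <- as.integer(names(tab))
  vals <- as.numeric(unlist(tab))
  if (l %in% sizes) return(vals[match(l, sizes)])
  if (l > max(sizes))
    return(vals[which.max(sizes)] +
             oracle_raw$loop_extrapolation_coefficient *
             oracle_raw$gas_constant_kcal *
             oracle_raw$loop_reference_temperature_K * log(l / max(sizes)))
  lo <- max(sizes[sizes < l]); hi <- min(sizes[sizes > l])
  glo <- vals[match(lo, sizes)]; ghi <- vals[match(hi, sizes)]
  glo + (ghi - glo) * (log(l) - log(lo)) / (log(hi) - log(lo))
}

oracle_hairpin_energy <- function(b, i, s, l, mg = 0.010, na = 0) {
  arm1 <- b[i:(i + s - 1L)]
  dH <- 0; dS <- 0
  for (k in seq_len(s - 1L)) {
    st <- oracle_raw$stacks[[paste0(arm1[k], arm1[k + 1L])]]
    dH <- dH + st$dH; dS <- dS + st$dS
  }
  if (arm1[1L] %in% c("A", "T")) {
    dH <- dH + oracle_raw$terminal_AT_penalty$dH
    dS <- dS + oracle_raw$terminal_AT_penalty$dS
  }
  if (arm1[s] %in% c("A", "T"))
    dS <- dS - oracle_raw$hairpin_closing_AT_dG37 * 1000 /
      oracle_raw$loop_reference_temperature_K
  dS <- dS - oracle_loop_dG37(l) * 1000 /
    oracle_raw$loop_reference_temperature_K
  mon <- na + oracle_raw$mg_to_monovalent_factor * sqrt(mg)
  dS <- dS + oracle_raw$salt_dS_coefficient * s * log(mon)
  c(dH = dH, dS = dS, dG = dH - 298.15 * dS / 1000)
}

# all maximal hairpins by exhaustive triple loop
brute_hairpins <- function(seq, min_stem = 3L, min_loop = 3L,
                           max_loop = 30L) {
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  wc <- function(x, y) !is.na(x) && !is.na(y) && oracle_pairs[[x]] == y
  rows <- list(); k <- 0L
  s_hi <- (n - min_loop) %/% 2L
  if (s_hi < min_stem)
    return(data.frame(start = integer(), stem_len = integer(),
                      loop_len = integer(), end = integer(),
                      dH = numeric(), dS = numeric(), dG = numeric()))
  for (i in seq_len(n)) for (s in min_stem:s_hi) {
    for (l in min_loop:max_loop) {
      end <- i + 2L * s + l - 1L
      if (end > n) next
      arm1 <- b[i:(i + s - 1L)]
      arm2 <- b[(i + s + l):end]
      if (!all(oracle_pairs[arm1] == rev(arm2))) next
      # outward maximality
      if (i > 1L && end < n && wc(b[i - 1L], b[end + 1L])) next
      # inward maximality (loop must stay >= min_loop)
      if (l - 2L >= min_loop && wc(b[i + s], b[i + s + l - 1L])) next
      en <- oracle_hairpin_energy(b, i, s, l)
      k <- k + 1L
      rows[[k]] <- data.frame(start = i, stem_len = s, loop_len = l,
                              end = end, dH = en[["dH"]], dS = en[["dS"]],
                              dG = en[["dG"]])
    }
  }
  if (k == 0L)
    return(data.frame(start = integer(), stem_len = integer(),
                      loop_len = integer(), end = integer(),
                      dH = numeric(), dS = numeric(), dG = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$dG, out$start, out$stem_len), , drop = FALSE]
}

# uniform random ACGT string
random_dna <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
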