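p <- thermo_params()

test_that("stem energy is the hand-summed table value plus salt correction", {
  raw <- oracle_raw
  # GCGC paired with its own reverse complement: steps GC, CG, GC
  dH_exp <- raw$stacks$GC$dH + raw$stacks$CG$dH + raw$stacks$GC$dH
  dS_exp <- raw$stacks$GC$dS + raw$stacks$CG$dS + raw$stacks$GC$dS +
    raw$salt_dS_coefficient * 4 * log(raw$mg_to_monovalent_factor * sqrt(0.01))
  e <- stem_energy("GCGC", "GCGC", temperature = 25, params = p)
  expect_equal(e$dH, dH_exp, tolerance = 1e-12)
  expect_equal(e$dS, dS_exp, tolerance = 1e-12)
  expect_equal(e$dG, e$dH - 298.15 * e$dS / 1000, tolerance = 1e-9)

  # A/T helix ends pick up the terminal penalty at both ends
  e2 <- stem_energy("ACGT", "ACGT", params = p)
  dH2 <- raw$stacks$AC$dH + raw$stacks$CG$dH + raw$stacks$GT$dH +
    2 * raw$terminal_AT_penalty$dH
  expect_equal(e2$dH, dH2, tolerance = 1e-12)
})

test_that("invalid stems are rejected", {
  expect_error(stem_energy("G", "C"), "no dinucleotide step")
  expect_error(stem_energy("GGGG", "GGGG"), "not.*reverse complements")
  expect_error(stem_energy("GCNC", "GNGC"), "invalid character")
})

test_that("free energy rises with temperature when entropy is negative", {
  temps <- c(10, 25, 37, 60, 90)
  dgs <- vapply(temps,
                function(t) stem_energy("GCGCGC", "GCGCGC",
                                        temperature = t, params = p)$dG,
                numeric(1))
  expect_true(all(diff(dgs) > 0))
})

test_that("stem energy is symmetric in the two strands", {
  withr::with_seed(7, {
    for (i in 1:20) {
      top <- random_dna(sample(2:10, 1))
      bottom <- revcomp(top)
      a <- stem_energy(top, bottom, params = p)
      b <- stem_energy(bottom, top, params = p)
      expect_equal(a$dH, b$dH, tolerance = 1e-9)
      expect_equal(a$dS, b$dS, tolerance = 1e-9)
    }
  })
})

test_that("hairpin energy validates geometry and signs", {
  expect_error(hairpin_energy("GCGCAAGCGC", 4, 2), "loop length")
  expect_error(hairpin_energy("GCGCAAAAGGGG", 4, 4), "not a valid stem")
  # 4-bp stem + 11-nt loop: stacks stabilise, loop destabilises
  seq11 <- paste0("GCGC", strrep("A", 11), "GCGC")
  e <- hairpin_energy(seq11, 4, 11, params = p)
  expect_true(is.finite(e$dG))
  expect_true(e$dH < 0)                      # stacking enthalpy
  expect_gt(loop_penalty(11, p), 0)          # loop term destabilizing
  # loop closure costs: same stem with a loop is less stable than the
  # bare duplex stem
  expect_gt(e$dG, stem_energy("GCGC", "GCGC", params = p)$dG)
})

test_that("longer loops at fixed stem trend destabilising", {
  # the published loop increments are monotone except for shallow dips at
  # sizes 5 and 10 (3.5, 3.5, 3.3 ... 4.5, 4.4); the trend must rise and
  # any local dip must stay within the table's granularity
  pen <- loop_penalty(3:60, p)
  expect_true(all(diff(pen) >= -0.2 - 1e-9))
  expect_gt(pen[length(pen)], pen[1])
  expect_true(all(loop_penalty(31:100, p) == cummax(loop_penalty(31:100, p))))
  dgs <- vapply(3:30, function(l) {
    hairpin_energy(paste0("GCGCGC", strrep("A", l), "GCGCGC"), 6, l,
                   params = p)$dG
  }, numeric(1))
  expect_true(all(diff(dgs) >= -0.2 - 1e-9))
  expect_gt(dgs[length(dgs)], dgs[1])
  expect_error(loop_penalty(2, p), "loop length")
})

test_that("unimolecular Tm depends only on the dH/dS ratio", {
  for (a in c(0.5, 1, 2, 7)) {
    e <- energy_triple(-59.248 * a, -198.7 * a, 298.15)
    expect_equal(hairpin_tm(e), 1000 * 59.248 / 198.7 - 273.15,
                 tolerance = 1e-9)
  }
})

test_that("Tm ranks nested stems: longer perfect stem, higher Tm", {
  loop <- strrep("A", 4)
  tms <- vapply(c(4, 6, 7), function(s) {
    arm <- substr("GCGCGCG", 1, s)
    hairpin_tm(hairpin_energy(paste0(arm, loop, revcomp(arm)), s, 4,
                              params = p))
  }, numeric(1))
  expect_true(all(diff(tms) > 0))
})

test_that("Tm is undefined outside the stable-folding regime", {
  expect_error(hairpin_tm(energy_triple(-10, 0, 298.15)), "Tm undefined")
  expect_error(hairpin_tm(energy_triple(-10, 5, 298.15)), "Tm undefined")
  expect_error(hairpin_tm(energy_triple(10, -5, 298.15)), "Tm undefined")
})

test_that("parameter table loads with full WC coverage and sane loops", {
  expect_s3_class(p, "thermo_params")
  steps <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           paste0))
  expect_true(all(steps %in% names(p$stacks)))
  expect_true(all(p$loop_dG37$dG37 > 0))
  expect_true(min(p$loop_dG37$size) == 3L)
  expect_error(thermo_params(mg = 0, na = 0), "counterions")
})
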