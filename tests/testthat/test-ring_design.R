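p <- thermo_params()

test_that("a ring yields one precursor per scission site", {
  ring <- synthetic_terminal_ring()
  rot <- rotations(ring)
  expect_equal(nrow(rot), 64L)
  expect_true(all(nchar(rot$seq) == 64L))
  expect_equal(rot$offset, 0:63)
  # rotating the offset-0 precursor by k gives the offset-k precursor
  k <- 17L
  expect_identical(rot$seq[k + 1L],
                   paste0(substr(ring, k + 1, 64), substr(ring, 1, k)))
  # all rotations conserve the nucleotide multiset
  counts <- table(strsplit(ring, "")[[1]])
  expect_identical(table(strsplit(rot$seq[40], "")[[1]]), counts)
  expect_error(rotations("ACGTN"), "invalid character")
  expect_warning(rotations(strrep("ACGT", 8)), "44")
})

test_that("splint arms are exact complements of the two termini", {
  lin <- paste0("GGCGCG", strrep("A", 30), "GGCCGC")
  splint <- design_splint(lin, arm = 6)
  expect_equal(nchar(splint), 12L)
  # published duplex arms: 5'-end GGCGCG pairs CGCGCC, 3'-end GGCCGC
  # pairs GCGGCC
  expect_identical(substr(splint, 1, 6), "CGCGCC")
  expect_identical(substr(splint, 7, 12), "GCGGCC")
  # round-trip: each arm is the WC complement of its target terminus
  expect_identical(revcomp(substr(splint, 1, 6)), "GGCGCG")
  expect_identical(revcomp(substr(splint, 7, 12)), "GGCCGC")
  expect_error(design_splint("ACGTACGT", arm = 6), "2\\*arm")
})

test_that("the terminal-hairpin rotation passes with distance 2; distances 4-5 fail", {
  ring <- synthetic_terminal_ring()
  des <- design_ring(ring, params = p)
  hit <- des$candidates[des$candidates$offset == 0L &
                          des$candidates$side == "5prime", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$distance, 2L)
  expect_equal(hit$stem_len, 4L)
  expect_true(hit$pass_distance && hit$pass_stability && hit$pass_tm)

  # rotations placing the stem 5 or 6 nt from the terminus (4 or 5
  # intervening nucleotides) fail the positional rule only
  for (off in c(62L, 61L)) {
    expect_false(off %in%
                   des$candidates$offset[des$candidates$side == "5prime"])
    nm <- des$near_misses[des$near_misses$offset == off &
                            des$near_misses$side == "5prime", ]
    expect_equal(nrow(nm), 1L)
    expect_equal(nm$distance, 66L - off)  # 4 then 5
    expect_false(nm$pass_distance)
    expect_true(nm$pass_stability)
    expect_true(nm$pass_tm)
  }
})

test_that("distance 0 passes only under the permissive flag", {
  ring <- synthetic_terminal_ring()
  strict <- design_ring(ring, params = p)
  expect_false(any(strict$candidates$offset == 2L &
                     strict$candidates$side == "5prime"))
  lax <- design_ring(ring, permissive_distance0 = TRUE, params = p)
  expect_true(any(lax$candidates$offset == 2L &
                    lax$candidates$side == "5prime" &
                    lax$candidates$distance == 0L))
})

test_that("passing candidates satisfy every threshold when re-checked independently", {
  des <- design_ring(synthetic_terminal_ring(), params = p)
  r <- des$rules
  cand <- des$candidates
  expect_gt(nrow(cand), 0L)
  expect_true(all(cand$distance >= r$d_min & cand$distance <= r$d_max))
  expect_true(all(cand$dG <= r$dG_ceiling))
  expect_true(all(cand$tm >= r$tm_floor & cand$tm <= r$tm_ceiling))
  # equilibrium numbers agree with a direct recomputation
  expect_equal(cand$K, exp(-cand$dG / (1.987e-3 * 298.15)),
               tolerance = 1e-9)
  expect_equal(cand$open_conc_uM, des$total_conc / (1 + cand$K),
               tolerance = 1e-9)
  expect_equal(cand$max_conc_uM, 0.1 * (1 + cand$K), tolerance = 1e-9)
  # splint arms pair the termini of each candidate's precursor
  rot <- rotations(synthetic_terminal_ring())
  for (i in seq_len(nrow(cand))) {
    lin <- rot$seq[rot$offset == cand$offset[i]]
    expect_identical(cand$splint[i], design_splint(lin, r$splint_arm))
  }
})

test_that("design output is invariant under rotation of the input ring", {
  # 40-nt ring: terminal 4-bp hairpin + inert background
  ring40 <- paste0("AA", "GCGC", "AAAA", "GCGC", strrep("A", 26))
  expect_equal(nchar(ring40), 40L)
  base <- suppressWarnings(design_ring(ring40, params = p))
  expect_gt(nrow(base$candidates), 0L)
  key <- function(df) {
    df <- df[order(df$offset, df$side, df$start), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  for (k in 0:39) {
    rot_ring <- paste0(substr(ring40, k + 1, 40), substr(ring40, 1, k))
    des_k <- suppressWarnings(design_ring(rot_ring, params = p))
    shifted <- des_k$candidates
    shifted$offset <- (shifted$offset + k) %% 40L
    expect_equal(key(shifted), key(base$candidates), info = paste("k =", k))
  }
})

test_that("a hairpin-free ring returns an empty candidate list", {
  des <- design_ring(strrep("AC", 32), params = p)
  expect_equal(nrow(des$candidates), 0L)
  expect_equal(nrow(des$near_misses), 0L)
})

test_that("rule and length guards hold", {
  expect_error(design_rules(d_min = 4, d_max = 3))
  expect_error(design_rules(tm_floor = 80, tm_ceiling = 50))
  expect_error(design_ring(strrep("A", 20)), "hard floor")
})
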