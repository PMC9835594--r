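test_that("required numbers reproduce the published power-of-alphabet forms", {
  panel <- ds_aptamer_panel()
  expect_equal(signif(as.numeric(required_number(panel$anti_VEGF165$motif,
                                                 "dp")), 2),
               2.9e17)                                    # 4^(21+8)
  expect_equal(signif(as.numeric(required_number(panel$anti_DEN3_NS1$motif,
                                                 "dp")), 2),
               3.0e20)                                    # 4^(28+6)
  expect_equal(signif(as.numeric(required_number(panel$anti_vWF$motif,
                                                 "dr")), 2),
               1.9e13)                                    # 5^(13+6)
  expect_identical(attr(required_number(panel$anti_DEN4_NS1$motif, "dp"),
                        "exponent"), 22L)

  # no constraints -> required number 1
  expect_equal(as.numeric(required_number(aptamer_motif(4), "natural")), 1)
  # unnatural bases cannot occur in a natural library
  expect_error(required_number(panel$anti_VEGF165$motif, "natural"),
               "cannot occur")
})

test_that("strict mode inverts the exact match probability", {
  m <- toy_motif_5()
  p <- motif_match_prob(m, "natural")
  expect_equal(p, (1 / 4)^3 * (1 / 4))        # 3 essential + 1 WC stem bp
  expect_equal(as.numeric(required_number(m, "natural", "strict")), 1 / p)
  # 4-letter: strict and power coincide
  expect_equal(as.numeric(required_number(m, "natural", "strict")),
               as.numeric(required_number(m, "natural", "power")))

  # 5-letter: per-stem-bp probability is 4 * 0.225^2 = 0.2025, not 1/5
  stem_only <- aptamer_motif(4, stem_pairs = list(c(1, 4), c(2, 3)),
                             alphabet = dna_alphabet(expanded = TRUE))
  freqs <- c(A = 0.225, C = 0.225, G = 0.225, T = 0.225, X = 0.10)
  expect_equal(motif_match_prob(stem_only, "dr", freqs), 0.2025^2)
  expect_equal(as.numeric(required_number(stem_only, "dr", "power")), 5^2)
})

test_that("sliding placements count the offsets of the essential core", {
  m19 <- design_stem_loop_motif(19, terminal_stem_bp = 4)
  expect_identical(placements(m19, 30), 12L)            # 30 - 19 + 1
  expect_identical(placements(m19, 19), 1L)             # core fills region
  expect_identical(placements(m19, 30, anchored = TRUE), 1L)
  expect_warning(w <- placements(m19, 10), "does not fit")
  expect_identical(w, 0L)
})

test_that("hit sublibraries require the motif's Ds spacing at a feasible offset", {
  # motif: Ds at 2 and 6 (gap 4), essential core spanning positions 2..6
  m <- aptamer_motif(6, essential = c("3" = "A", "4" = "C", "5" = "G"),
                     essential_ub = c("2" = "Ds", "6" = "Ds"))
  subs <- list(
    dp_sublibrary(10, c(3, 7)),    # gap 4, core fits (offset +1)      -> hit
    dp_sublibrary(10, c(6, 10)),   # gap 4, core fits exactly at edge  -> hit
    dp_sublibrary(10, c(7, 11 - 1)),  # gap 3                          -> miss
    dp_sublibrary(10, c(2, 6, 9)), # three Ds                          -> miss
    dp_sublibrary(10, 5))          # one Ds                            -> miss
  set <- dp_library_set(subs, 1e14)
  expect_identical(hit_sublibraries(m, set), 2L)

  # a motif needing at most one Ds is compatible with every sublibrary
  # holding at least one
  m1 <- aptamer_motif(3, essential_ub = c("2" = "Ds"))
  expect_identical(hit_sublibraries(m1, set), 5L)
  m0 <- aptamer_motif(3, essential = c("2" = "A"))
  expect_identical(hit_sublibraries(m0, set), 5L)

  # infeasible offset: gap matches but the core cannot fit
  far <- dp_library_set(list(dp_sublibrary(6, c(1, 5))), 1e14)
  m_edge <- aptamer_motif(7, essential = c("1" = "A", "7" = "T"),
                          essential_ub = c("2" = "Ds", "6" = "Ds"))
  expect_identical(hit_sublibraries(m_edge, far), 0L)
})

test_that("DP occurrence equals complexity over required number times hit fraction", {
  # toy checked against the exhaustive oracle: N5 natural region,
  # 3 essential + 1 stem bp, molecules = 4^5
  m <- toy_motif_5()
  lib <- natural_library(5, molecules = 4^5)
  oracle <- count_candidates_exhaustive(m, lib)
  expect_identical(oracle$count, 4L)                    # 4^5 / 4^4
  res <- occurrence_dp(m, dp_library_set(list(dp_sublibrary(5, integer(0))),
                                         molecules = 4^5), hits = 1)
  expect_equal(res$occurrence, oracle$expected_in_library)
  expect_equal(res$occurrence, 4)

  # zero hits give zero occurrence
  res0 <- occurrence_dp(m, synthetic_dp_set(), hits = 0)
  expect_identical(res0$occurrence, 0)
})

test_that("natural-library occurrence reproduces the N30 worked example", {
  panel <- ds_aptamer_panel()
  lib <- natural_library(30, molecules = nmol_to_molecules(1))
  res <- occurrence_natural(panel$pegaptanib_precursor$motif, lib)
  expect_identical(res$placements, 12L)
  expect_equal(round(res$occurrence), 103)
  expect_equal(round(res$occurrence_printed), 103)

  # molecules = R, single placement -> exactly one expected candidate
  m <- design_stem_loop_motif(5, terminal_stem_bp = 0)
  lib1 <- natural_library(5, molecules = 4^5)
  expect_equal(occurrence_natural(m, lib1)$occurrence, 1)
})

test_that("DR occurrence reports the power and strict readings side by side", {
  panel <- ds_aptamer_panel()
  lib <- dr_library(30, molecules = 1.1e15)
  res <- occurrence_dr(panel$anti_vWF$motif, lib)
  expect_equal(signif(res$occurrence_power, 2), 58)     # 1.1e15 / 5^19
  expect_gt(res$occurrence_strict, 0)
  expect_false(isTRUE(all.equal(res$occurrence_power, res$occurrence_strict)))

  # an unconstrained motif occurs once per molecule
  expect_equal(occurrence_dr(aptamer_motif(4), lib)$occurrence,
               lib$molecules)
})

test_that("required complexity inverts DP occurrence", {
  # toy arithmetic: R = 4^4, S = 2, h = 1, target 1 -> 512
  m <- toy_motif_5()
  set2 <- dp_library_set(list(dp_sublibrary(5, integer(0)),
                              dp_sublibrary(5, c(1, 3))), molecules = 1e6)
  expect_equal(required_complexity(m, set2, 1, hits = 1), 512)

  set.seed(13)
  for (i in 1:20) {
    target <- stats::runif(1, 0.1, 50)
    h <- sample(1:2, 1)
    mol <- required_complexity(m, set2, target, hits = h)
    res <- occurrence_dp(m, dp_library_set(set2$sublibraries, mol), hits = h)
    expect_equal(res$occurrence, target, tolerance = 1e-9)
  }
  expect_error(required_complexity(m, set2, 1, hits = 0), "no hit sublibrary")
})

test_that("occurrence decreases as essential bases and stems accumulate", {
  lib <- natural_library(30, molecules = 1e15)
  occ <- vapply(5:15, function(k) {
    occurrence_natural(design_stem_loop_motif(k, terminal_stem_bp = 2),
                       lib)$occurrence
  }, numeric(1))
  expect_true(all(diff(occ) < 0))
  occ_bp <- vapply(0:5, function(bp) {
    occurrence_natural(design_stem_loop_motif(10, terminal_stem_bp = bp),
                       lib)$occurrence
  }, numeric(1))
  expect_true(all(diff(occ_bp) < 0))
})
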