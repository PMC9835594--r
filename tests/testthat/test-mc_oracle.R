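test_that("sampling is reproducible under a seed and respects the library model", {
  lib <- dr_library(30, 1e15)
  s1 <- sample_sequences(lib, n = 5, seed = 99)
  s2 <- sample_sequences(lib, n = 5, seed = 99)
  expect_identical(s1$sequences, s2$sequences)
  expect_true(all(nchar(s1$sequences) == 30))

  # natural library: roughly uniform per-position letter usage
  nat <- sample_sequences(natural_library(8, 1e14), n = 4000, seed = 3)
  first <- substr(nat$sequences, 1, 1)
  expect_true(all(abs(table(first) / 4000 - 0.25) < 0.05))
  expect_false(any(grepl("X", nat$sequences)))

  # DP library: every sequence carries its sublibrary's Ds layout
  dp <- dp_library_set(list(dp_sublibrary(10, c(2, 7)),
                            dp_sublibrary(10, c(4, 9))), 1e14)
  sdp <- sample_sequences(dp, n = 500, seed = 17)
  ds_count <- nchar(sdp$sequences) - nchar(gsub("X", "", sdp$sequences))
  expect_true(all(ds_count == 2))
  at27 <- substr(sdp$sequences, 2, 2) == "X" & substr(sdp$sequences, 7, 7) == "X"
  at49 <- substr(sdp$sequences, 4, 4) == "X" & substr(sdp$sequences, 9, 9) == "X"
  expect_true(all(at27 | at49))

  # constant flanks are appended verbatim
  fl <- sample_sequences(natural_library(4, 1e12, flank5 = "GGG",
                                         flank3 = "TT"), n = 3, seed = 1)
  expect_true(all(startsWith(fl$sequences, "GGG")))
  expect_true(all(endsWith(fl$sequences, "TT")))
})

test_that("motif matching checks essential letters and stem complementarity", {
  m <- toy_motif_5()                       # stem (1,5), essential G A C
  expect_true(matches_motif("AGACT", m))   # A-T stem
  expect_true(matches_motif("GGACC", m))   # G-C stem
  expect_false(matches_motif("AGACG", m))  # A-G is not a pair
  expect_false(matches_motif("ATACT", m))  # essential mismatch
  # offset shifts the window
  expect_true(matches_motif("TTAGACT", m, offset = 3))
  expect_error(matches_motif("AGACT", m, offset = 2), "outside the sequence")

  # Ds-Px stem pair only under the extended rule
  ms <- aptamer_motif(2, stem_pairs = list(c(1, 2)),
                      alphabet = dna_alphabet(expanded = TRUE))
  expect_false(matches_motif("XP", ms, stem_rule = "wc"))
  expect_true(matches_motif("XP", ms, stem_rule = "wc_ds_px"))
})

test_that("exhaustive enumeration equals the analytic match probability on toys", {
  set.seed(23)
  for (i in 1:40) {
    m <- random_toy_motif()
    lib <- natural_library(m$length, molecules = 4^m$length)
    ex <- count_candidates_exhaustive(m, lib)
    p <- motif_match_prob(m, "natural")
    expect_equal(ex$frequency, p, tolerance = 1e-12)
    expect_equal(ex$expected_in_library,
                 lib$molecules / as.numeric(required_number(m, "natural",
                                                            "strict")),
                 tolerance = 1e-9)
  }
})

test_that("weighted enumeration matches strict probabilities for doped libraries", {
  set.seed(29)
  for (i in 1:10) {
    m <- random_toy_motif(len = sample(4:5, 1), with_ub = TRUE)
    lib <- dr_library(m$length, molecules = 5^m$length)
    ex <- count_candidates_exhaustive(m, lib)
    p <- motif_match_prob(m, "dr", lib$letter_freqs)
    expect_equal(ex$probability, p, tolerance = 1e-12)
  }
})

test_that("multi-offset inclusion counting is bounded by, and near, W times p", {
  # 2 essential positions sliding in N6: W = 5 placements overlap, so the
  # exhaustive union count must not exceed the W * p product
  m <- aptamer_motif(2, essential = c("1" = "A", "2" = "C"),
                     alphabet = dna_alphabet())
  lib <- natural_library(6, molecules = 4^6)
  ex <- count_candidates_exhaustive(m, lib)
  W <- placements(m, 6)
  p1 <- motif_match_prob(m, "natural")
  expect_identical(W, 5L)
  expect_lt(ex$frequency, W * p1)
  expect_gt(ex$frequency, W * p1 - choose(W, 2) * p1^2)  # Bonferroni bounds
})

test_that("sampled candidate frequencies agree with enumeration within 3 SE", {
  m <- toy_motif_5()
  lib <- natural_library(7, molecules = 4^7)
  truth <- count_candidates_exhaustive(m, lib)$frequency
  s <- sample_sequences(lib, n = 20000, seed = 5)
  cc <- count_candidates(s, m)
  se <- sqrt(truth * (1 - truth) / cc$n)
  expect_lt(abs(cc$frequency - truth), 3 * se)
})

test_that("degenerate and guarded cases are handled", {
  big <- natural_library(11, molecules = 1e15)
  expect_error(count_candidates_exhaustive(toy_motif_5(), big),
               "exceeds the 4\\^10")
  # motif longer than the region matches nothing
  long <- aptamer_motif(8, essential = c("1" = "A"))
  shrt <- natural_library(4, molecules = 256)
  expect_identical(count_candidates_exhaustive(long, shrt)$count, 0)
  s <- sample_sequences(shrt, n = 10, seed = 2)
  expect_identical(count_candidates(s, long)$count, 0L)
})

test_that("FASTA export round-trips sequences with the Ds legend", {
  lib <- dr_library(12, 1e14)
  s <- sample_sequences(lib, n = 20, seed = 8)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_sample_fasta(s, path)
  back <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  expect_identical(unname(vapply(back, as.character, "")), s$sequences)
  expect_true(any(grepl("Ds=X", readLines(path))))
})
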