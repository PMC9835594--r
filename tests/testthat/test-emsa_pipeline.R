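emsa_row <- function(gel, id, cx, fr, orig = FALSE, pos = NA_integer_) {
  data.frame(gel_id = gel, variant_id = id, position = pos,
             complex_density = cx, free_density = fr, is_original = orig,
             stringsAsFactors = FALSE)
}

test_that("shifted fraction is complex over total", {
  expect_equal(shifted_fraction(50, 50), 0.5)
  expect_equal(shifted_fraction(0, 80), 0)
  expect_equal(shifted_fraction(80, 0), 1)
  expect_error(shifted_fraction(0, 0), "empty lane")
  expect_error(shifted_fraction(-1, 5), "non-negative")
})

test_that("relative binding normalizes to the original aptamer within gel", {
  tab <- rbind(emsa_row("g1", "orig", 60, 40, orig = TRUE),
               emsa_row("g1", "v1", 30, 70, pos = 3),
               emsa_row("g2", "orig", 40, 60, orig = TRUE),
               emsa_row("g2", "v2", 30, 70, pos = 5))
  rb <- relative_binding(tab)
  expect_equal(rb$relative_binding[rb$variant_id == "orig"], c(100, 100))
  expect_equal(rb$relative_binding[rb$variant_id == "v1"], 50)   # 0.30/0.60
  expect_equal(rb$relative_binding[rb$variant_id == "v2"], 75)   # 0.30/0.40

  # a variant can out-bind the original and is reported unclipped
  over <- rbind(emsa_row("g", "orig", 50, 50, orig = TRUE),
                emsa_row("g", "v", 80, 20, pos = 1))
  expect_gt(relative_binding(over)$relative_binding[2], 100)
})

test_that("relative binding is invariant to per-gel density rescaling", {
  set.seed(31)
  for (i in 1:20) {
    tab <- rbind(emsa_row("g1", "orig", runif(1, 10, 90), runif(1, 10, 90),
                          orig = TRUE),
                 emsa_row("g1", "v1", runif(1, 1, 90), runif(1, 1, 90),
                          pos = 2),
                 emsa_row("g1", "v2", runif(1, 1, 90), runif(1, 1, 90),
                          pos = 4))
    scaled <- tab
    cc <- runif(1, 0.01, 50)
    scaled$complex_density <- scaled$complex_density * cc
    scaled$free_density <- scaled$free_density * cc
    expect_equal(relative_binding(scaled)$relative_binding,
                 relative_binding(tab)$relative_binding)
  }
})

test_that("multiple original lanes are averaged into the denominator", {
  tab <- rbind(emsa_row("g", "o1", 80, 20, orig = TRUE),   # 0.8
               emsa_row("g", "o2", 40, 60, orig = TRUE),   # 0.4 -> mean 0.6
               emsa_row("g", "v", 30, 70, pos = 1))        # 0.3
  rb <- relative_binding(tab)
  expect_equal(rb$relative_binding[3], 50)
  expect_equal(mean(rb$relative_binding[1:2]), 100)
})

test_that("tables without a per-gel original, or with empty lanes, are rejected", {
  bad <- rbind(emsa_row("g1", "orig", 60, 40, orig = TRUE),
               emsa_row("g2", "v", 30, 70, pos = 1))
  expect_error(relative_binding(bad), "g2")
  zero_ref <- rbind(emsa_row("g", "orig", 0, 50, orig = TRUE),
                    emsa_row("g", "v", 30, 70, pos = 1))
  expect_error(relative_binding(zero_ref), "shifted fraction is 0")
  empty <- rbind(emsa_row("g", "orig", 60, 40, orig = TRUE),
                 emsa_row("g", "v", 0, 0, pos = 1))
  expect_error(relative_binding(empty), "empty lane")
})

test_that("importance calls threshold the per-position mean relative binding", {
  tab <- rbind(emsa_row("g", "orig", 60, 40, orig = TRUE),
               emsa_row("g", "p3a", 60 * 0.40, 100 - 60 * 0.40, pos = 3),
               emsa_row("g", "p3b", 60 * 0.60, 100 - 60 * 0.60, pos = 3),
               emsa_row("g", "p5a", 60, 40, pos = 5))
  calls <- call_important(relative_binding(tab))
  p3 <- calls$per_position[calls$per_position$position == 3, ]
  expect_equal(p3$relative_binding, 50)        # mean of 40% and 60%
  expect_true(p3$important)
  expect_identical(calls$important_positions, 3L)

  # all variants at 100% -> nothing called
  flat <- rbind(emsa_row("g", "orig", 60, 40, orig = TRUE),
                emsa_row("g", "v1", 60, 40, pos = 1),
                emsa_row("g", "v2", 60, 40, pos = 2))
  expect_length(call_important(relative_binding(flat))$important_positions, 0)

  # untested positions are surfaced, not silently dropped
  calls2 <- call_important(relative_binding(tab), positions = c(3, 5, 7, 9))
  expect_identical(calls2$untested_positions, c(7L, 9L))
  expect_error(call_important(relative_binding(tab), tau = 0), "tau")
  expect_error(call_important(relative_binding(tab), tau = 101), "tau")
})

test_that("the important set grows monotonically with the threshold", {
  set.seed(37)
  truth <- emsa_ground_truth(
    effects = stats::setNames(round(runif(12, 0.2, 1.1), 2), 1:12),
    sigma = 0.05)
  rb <- relative_binding(generate_emsa_table(truth, seed = 101))
  taus <- c(30, 50, 65, 80, 95)
  sets <- lapply(taus, function(t) call_important(rb, tau = t)$important_positions)
  for (i in seq_along(taus)[-1]) {
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
  }
})

test_that("median aggregation is available for replicate summaries", {
  tab <- rbind(emsa_row("g", "orig", 60, 40, orig = TRUE),
               emsa_row("g", "a", 6, 94, pos = 1),     # 10%
               emsa_row("g", "b", 54, 46, pos = 1),    # 90%
               emsa_row("g", "c", 57, 43, pos = 1))    # 95%
  rb <- relative_binding(tab)
  expect_equal(call_important(rb, stat = "median")$per_position$relative_binding,
               90)
  expect_equal(call_important(rb, stat = "mean")$per_position$relative_binding,
               65)
})

test_that("transition variants swap A<->G and C<->T at requested positions", {
  v <- transition_variants("AT", c(1, 2))
  expect_identical(v$sequence, c("GT", "AC"))
  expect_identical(v$variant_id, c("A1G", "T2C"))

  # Ds positions are skipped with a warning, not mutated
  expect_warning(v2 <- transition_variants("AXG", 1:3), "transition undefined")
  expect_identical(v2$sequence, c("GXG", "AXA"))

  expect_error(transition_variants("ACGT", 2, constant = 1:2), "constant")
  expect_error(transition_variants("ACGT", 9), "out of range")
  expect_identical(nrow(transition_variants("ACGT", integer(0))), 0L)
})

test_that("Ds-substitution variants scan the single-stranded positions", {
  seq41 <- paste(rep(c("A", "C", "G", "T"), length.out = 41), collapse = "")
  pos <- c(7, 8, 10, 21, 22, 27:31)
  v <- ub_substitution_variants(seq41, pos)
  expect_identical(nrow(v), 10L)
  expect_true(all(grepl("Ds$", v$variant_id)))
  for (i in seq_len(nrow(v))) {
    diffs <- which(strsplit(v$sequence[i], "")[[1]] !=
                     strsplit(seq41, "")[[1]])
    expect_identical(diffs, as.integer(pos[i]))
    expect_identical(substr(v$sequence[i], pos[i], pos[i]), "X")
  }
})
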