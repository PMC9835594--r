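# Required-number and occurrence calculations.
#
# The required number R for an aptamer candidate motif is the sequence-space
# size within which one candidate is expected: in the convention used
# throughout the published calculations ("power" mode), R = A^(counted
# essential bases + stem bp) with A = 4 for natural-randomized and
# Ds-predetermined (DP) libraries and A = 5 for Ds-doped (DR) libraries.
# "strict" mode instead inverts the exact per-placement match probability
# implied by the library's letter frequencies and the allowed complementary
# stem pairs; for four-letter libraries the two coincide (4 Watson-Crick
# pairs / 16 combinations = 1/4 per stem bp), for five-letter libraries they
# do not (1/5 per bp vs 4 * 0.225^2 = 0.2025), and both are exposed so the
# approximation is visible.
#
# The expected occurrence O of candidates in an initial library is then
#   natural:  O = molecules * W / R        (W = sliding placements)
#   DP:       O = (molecules / R) * h / S  (h hit sublibraries of S)
#   DR:       O = molecules / R            (terminal stem embedded: anchored)
# O is an expectation, not a probability; P(at least one candidate) is
# reported alongside as 1 - exp(-O).

#' Exact per-placement match probability of a motif
#'
#' Probability that a single placement of the motif is realized by a random
#' library sequence: the product of the letter frequencies at every essential
#' position and, per stem bp, the total probability of the allowed
#' complementary pairs. For DP libraries the predetermined Ds positions
#' contribute no factor (they are certain within a hit sublibrary).
#'
#' @param motif An [aptamer_motif()].
#' @param library_kind `"natural"`, `"dp"` or `"dr"`.
#' @param letter_freqs Named letter frequencies (required for `"dr"`).
#' @return Probability in `[0, 1]`.
#' @export
motif_match_prob <- function(motif, library_kind = c("natural", "dp", "dr"),
                             letter_freqs = NULL) {
  library_kind <- match.arg(library_kind)
  cts <- motif$counts
  if (library_kind == "dr") {
    if (is.null(letter_freqs)) {
      stop("dr libraries need letter frequencies")
    }
    names(letter_freqs) <- normalize_base(names(letter_freqs))
  } else {
    letter_freqs <- stats::setNames(rep(0.25, 4), NATURAL_BASES)
  }
  freq_of <- function(b) {
    f <- letter_freqs[b]
    f[is.na(f)] <- 0
    unname(f)
  }

  p <- prod(freq_of(motif$bases[motif$roles == "essential"]))

  ub_bases <- motif$bases[motif$roles == "essential_ub"]
  if (length(ub_bases) > 0) {
    if (library_kind == "natural") {
      warning("motif requires unnatural bases absent from a natural library; ",
              "match probability is 0")
      return(0)
    }
    if (library_kind == "dr") p <- p * prod(freq_of(ub_bases))
    # dp: predetermined, factor 1
  }

  if (cts$n_stem_bp > 0) {
    pairs <- allowed_stem_pairs(motif$alphabet)
    pair_p <- sum(freq_of(pairs[, 1]) * freq_of(pairs[, 2]))
    p <- p * pair_p^cts$n_stem_bp
  }
  p
}

#' Required number for an aptamer candidate motif
#'
#' @param motif An [aptamer_motif()].
#' @param library_kind `"natural"`, `"dp"` or `"dr"`. In a DP library the
#'   essential Ds positions are predetermined by the sublibrary and are *not*
#'   counted in the exponent; in a DR library they are.
#' @param mode `"power"` (power-of-alphabet convention used in the published
#'   calculations) or `"strict"` (reciprocal exact match probability).
#' @param letter_freqs For `"dr"`: named letter frequencies (defaults to the
#'   standard doped design, 10% Ds, 22.5% each natural base).
#' @return The required number as a double, with attributes `base` and
#'   `exponent` (power mode), `exact` (a [bigcount()], power mode) or
#'   `match_prob` (strict mode).
#' @examples
#' m <- design_stem_loop_motif(21, 2, terminal_stem_bp = 4,
#'                             internal_stem_bp = 4)
#' required_number(m, "dp")    # 4^(21+8) = 2.9e17
#' @export
required_number <- function(motif, library_kind = c("natural", "dp", "dr"),
                            mode = c("power", "strict"),
                            letter_freqs = NULL) {
  library_kind <- match.arg(library_kind)
  mode <- match.arg(mode)
  cts <- motif$counts
  if (library_kind == "natural" && cts$n_essential_ub > 0) {
    stop("motif requires unnatural bases; it cannot occur in a natural library")
  }
  if (mode == "power") {
    if (library_kind == "dr") {
      a <- 5L
      e <- cts$n_essential_natural + cts$n_essential_ub + cts$n_stem_bp
    } else {
      a <- 4L
      e <- cts$n_essential_natural + cts$n_stem_bp
    }
    exact <- big_pow(a, e)
    structure(as.numeric(exact), base = a, exponent = e, exact = exact,
              mode = "power")
  } else {
    if (library_kind == "dr" && is.null(letter_freqs)) {
      letter_freqs <- c(A = 0.225, C = 0.225, G = 0.225, T = 0.225, X = 0.10)
    }
    p <- motif_match_prob(motif, library_kind, letter_freqs)
    structure(1 / p, match_prob = p, mode = "strict")
  }
}

#' Number of sliding placements of a motif's essential core
#'
#' The contiguous essential core can sit at any offset inside the randomized
#' region (stems may extend into the constant flanks), giving
#' `random_len - core_span + 1` placements; an anchored motif (e.g. when the
#' terminal stem is embedded in the library as a constant sequence) has
#' exactly one.
#'
#' @param motif An [aptamer_motif()].
#' @param random_len Randomized-region length of the library.
#' @param anchored Motif position fixed by library design.
#' @return Integer placement count (0, with a warning, if the core does not
#'   fit).
#' @examples
#' m <- design_stem_loop_motif(19, terminal_stem_bp = 4)
#' placements(m, 30)   # 30 - 19 + 1 = 12
#' @export
placements <- function(motif, random_len, anchored = FALSE) {
  if (anchored) return(1L)
  if (motif$core_span > random_len) {
    warning("essential core (", motif$core_span,
            " nt) does not fit in the randomized region (", random_len,
            " nt); 0 placements")
    return(0L)
  }
  as.integer(random_len - motif$core_span + 1L)
}

#' Count DP sublibraries compatible with a motif
#'
#' A sublibrary "hits" when its predetermined Ds positions reproduce the
#' motif's Ds spacing at an offset that keeps the essential core inside the
#' randomized region. A motif requiring at most one Ds is compatible with
#' every sublibrary carrying at least that many Ds bases.
#'
#' @param motif An [aptamer_motif()].
#' @param dp_set A [dp_library_set()].
#' @return Integer count of hit sublibraries.
#' @export
hit_sublibraries <- function(motif, dp_set) {
  stopifnot(inherits(dp_set, "dp_library_set"))
  ub <- motif$ub_positions
  k <- length(ub)
  if (k <= 1) {
    return(sum(vapply(dp_set$sublibraries,
                      function(s) length(s$ub_positions) >= k, logical(1))))
  }
  gaps <- diff(ub)
  hit_one <- function(s) {
    if (length(s$ub_positions) != k) return(FALSE)
    if (!identical(diff(s$ub_positions), gaps)) return(FALSE)
    offset <- s$ub_positions[1] - ub[1]
    motif$core_start + offset >= 1 && motif$core_end + offset <= s$random_len
  }
  sum(vapply(dp_set$sublibraries, hit_one, logical(1)))
}

# Assemble an occurrence result. `occurrence` is the exact expectation;
# `occurrence_printed` repeats the quotient with the required number rounded
# to 2 significant figures, the precision at which required numbers are
# conventionally quoted, so that reported occurrences can be reproduced
# digit-for-digit.
occurrence_result <- function(library_kind, mode, molecules, required,
                              W = 1L, hits = 1L, total_sublibraries = 1L,
                              extra = list()) {
  occ <- molecules * W * (hits / total_sublibraries) / as.numeric(required)
  occ_printed <- molecules * W * (hits / total_sublibraries) /
    signif(as.numeric(required), 2)
  if (hits == 0) occ <- occ_printed <- 0
  structure(
    c(list(library_kind = library_kind, mode = mode, molecules = molecules,
           required = as.numeric(required),
           required_attr = attributes(required),
           placements = W, hits = hits,
           total_sublibraries = total_sublibraries,
           occurrence = occ, occurrence_printed = occ_printed,
           p_at_least_one = -expm1(-occ)),
      extra),
    class = "occurrence_result")
}

#' @export
print.occurrence_result <- function(x, ...) {
  cat(sprintf("Occurrence in %s library (%s mode)\n",
              toupper(x$library_kind), x$mode))
  cat(sprintf("  molecules        %.3g\n", x$molecules))
  cat(sprintf("  required number  %.3g", x$required))
  ex <- x$required_attr$exponent
  if (!is.null(ex)) cat(sprintf("  (= %d^%d)", x$required_attr$base, ex))
  cat("\n")
  if (x$placements != 1) cat(sprintf("  placements       %d\n", x$placements))
  if (x$total_sublibraries != 1) {
    cat(sprintf("  hit sublibraries %d / %d\n", x$hits, x$total_sublibraries))
  }
  cat(sprintf("  occurrence       %.4g   (as printed: %.3g)\n",
              x$occurrence, x$occurrence_printed))
  cat(sprintf("  P(>=1 candidate) %.3g\n", x$p_at_least_one))
  invisible(x)
}

#' Expected occurrence in a natural randomized library
#'
#' `O = molecules * W / R`, with `W` the sliding-placement count of the
#' essential core in the randomized region.
#'
#' @param motif An [aptamer_motif()].
#' @param library A [natural_library()].
#' @param mode `"power"` or `"strict"` (identical for four-letter libraries).
#' @param anchored Passed to [placements()].
#' @return An `occurrence_result`.
#' @examples
#' lib <- natural_library(30, molecules = nmol_to_molecules(1))
#' m <- design_stem_loop_motif(19, terminal_stem_bp = 4)
#' occurrence_natural(m, lib)   # ~103 candidates
#' @export
occurrence_natural <- function(motif, library, mode = c("power", "strict"),
                               anchored = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(library, "natural_library"))
  R <- required_number(motif, "natural", mode)
  W <- placements(motif, library$random_len, anchored)
  occurrence_result("natural", mode, library$molecules, R, W = W)
}

#' Expected occurrence in a pooled DP library
#'
#' `O = (molecules / R) * h / S`: the pooled complexity divided by the
#' required number, scaled by the fraction of sublibraries whose
#' predetermined Ds layout is compatible with the motif.
#'
#' @param motif An [aptamer_motif()].
#' @param dp_set A [dp_library_set()].
#' @param mode `"power"` or `"strict"`.
#' @param hits Override the hit-sublibrary count (use when the published
#'   sublibrary layout is not available but its hit count is).
#' @return An `occurrence_result`.
#' @export
occurrence_dp <- function(motif, dp_set, mode = c("power", "strict"),
                          hits = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(dp_set, "dp_library_set"))
  R <- required_number(motif, "dp", mode)
  h <- if (is.null(hits)) hit_sublibraries(motif, dp_set) else as.integer(hits)
  occurrence_result("dp", mode, dp_set$molecules, R,
                    hits = h, total_sublibraries = dp_set$n_sublibraries)
}

#' Expected occurrence in a Ds-doped (DR) library
#'
#' The motif is anchored (the terminal stem is embedded in the library), so
#' `O = molecules / R`. Power mode uses `R = 5^(essential incl. Ds + stem
#' bp)`; strict mode uses the exact match probability under the library's
#' letter frequencies. Both values are carried in the result
#' (`occurrence_power`, `occurrence_strict`) regardless of the selected mode.
#'
#' @param motif An [aptamer_motif()].
#' @param library A [dr_library()].
#' @param mode Which value `occurrence` reports.
#' @param anchored Default `TRUE` (constant terminal stem in the library).
#' @return An `occurrence_result`.
#' @export
occurrence_dr <- function(motif, library, mode = c("power", "strict"),
                          anchored = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(library, "dr_library"))
  W <- placements(motif, library$random_len, anchored)
  R_power <- required_number(motif, "dr", "power")
  R_strict <- required_number(motif, "dr", "strict",
                              letter_freqs = library$letter_freqs)
  R <- if (mode == "power") R_power else R_strict
  occurrence_result("dr", mode, library$molecules, R, W = W,
    extra = list(
      occurrence_power = library$molecules * W / as.numeric(R_power),
      occurrence_strict = library$molecules * W / as.numeric(R_strict)))
}

#' Library complexity required for a target occurrence (DP design)
#'
#' Inverse of [occurrence_dp()]: the pooled molecule count at which the
#' expected candidate occurrence reaches `target_occurrence`.
#'
#' @param motif An [aptamer_motif()].
#' @param dp_set A [dp_library_set()].
#' @param target_occurrence Desired expected candidate count.
#' @param mode `"power"` or `"strict"`.
#' @param hits Override the hit-sublibrary count.
#' @return Required molecule count (double).
#' @export
required_complexity <- function(motif, dp_set, target_occurrence,
                                mode = c("power", "strict"), hits = NULL) {
  mode <- match.arg(mode)
  stopifnot(target_occurrence >= 0)
  R <- required_number(motif, "dp", mode)
  h <- if (is.null(hits)) hit_sublibraries(motif, dp_set) else as.integer(hits)
  if (h == 0) stop("no hit sublibrary: the motif's Ds layout matches none of ",
                   "the sublibraries")
  target_occurrence * as.numeric(R) * dp_set$n_sublibraries / h
}
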