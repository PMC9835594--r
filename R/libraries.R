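# The three initial-library designs used for (unnatural-base) DNA aptamer
# selection, and their complexity / composition arithmetic.
#
# "Complexity" here is the *physical* number of molecules in the selection
# pool (typically 1e12-1e15), which is distinct from the combinatorial
# sequence-space size (4^30 ~ 1.15e18 for a natural N30 region). Occurrence
# calculations use the physical count; sequence-space sizes are kept exact.

AVOGADRO <- 6.02214e23

#' Sequence-space size of a randomized region
#'
#' Number of distinct sequences of a given length over an alphabet, as an
#' exact big integer ([bigcount()]; `4^40` already overflows 64-bit floats'
#' exact range). Use `as.numeric()` for a float view.
#'
#' @param alphabet_size Number of letters (4 natural, 5 with Ds).
#' @param length Randomized-region length in nt.
#' @return A [bigcount()].
#' @examples
#' as.numeric(sequence_space(4, 30))   # ~1.15e18
#' as.numeric(sequence_space(5, 30))   # ~9.31e20
#' @export
sequence_space <- function(alphabet_size, length) {
  stopifnot(alphabet_size >= 1)
  if (length < 0) stop("length must be non-negative")
  big_pow(alphabet_size, length)
}

#' Convert an amount of library (nmol) to a molecule count
#'
#' One nanomole of a pool contains `1e-9 * N_A` = 6.02e14 molecules, the
#' practical ceiling on initial-library complexity at bench scale.
#'
#' @param amount_nmol Amount in nanomoles (non-negative).
#' @return Molecule count (double).
#' @examples
#' nmol_to_molecules(1)   # 6.02e14
#' @export
nmol_to_molecules <- function(amount_nmol) {
  if (any(amount_nmol < 0)) stop("amount must be non-negative")
  amount_nmol * 1e-9 * AVOGADRO
}

#' Distribution of unnatural-base counts in a doped library
#'
#' Probability that a doped (DR) randomized region of `random_len` positions,
#' each independently Ds with probability `ub_freq`, carries exactly `k` Ds
#' bases: the binomial pmf. At the standard design (N30, 10% Ds) only 22.8%
#' of molecules carry exactly two Ds bases.
#'
#' @param random_len Randomized-region length.
#' @param ub_freq Per-position Ds frequency.
#' @param k Number of Ds bases (vectorized).
#' @return Binomial probability/ies.
#' @examples
#' ub_count_pmf(30, 0.10, 2)   # 0.2277
#' @export
ub_count_pmf <- function(random_len, ub_freq, k) {
  stopifnot(ub_freq >= 0, ub_freq <= 1)
  if (any(k < 0 | k > random_len)) {
    stop("k must lie in 0..random_len")
  }
  stats::dbinom(k, size = random_len, prob = ub_freq)
}

#' Natural randomized library (e.g. N30)
#'
#' @param random_len Randomized-region length in nt.
#' @param molecules Physical molecule count (complexity) of the pool.
#' @param flank5,flank3 Fixed flanking sequences (primers/stems), as strings.
#' @return Object of class `natural_library` (also `selex_library`).
#' @examples
#' natural_library(30, molecules = nmol_to_molecules(1))
#' @export
natural_library <- function(random_len, molecules, flank5 = "", flank3 = "") {
  stopifnot(random_len >= 1, molecules > 0)
  structure(
    list(kind = "natural", random_len = as.integer(random_len),
         molecules = molecules, flank5 = flank5, flank3 = flank3,
         alphabet = dna_alphabet(expanded = FALSE),
         letter_freqs = stats::setNames(rep(0.25, 4), NATURAL_BASES)),
    class = c("natural_library", "selex_library"))
}

#' Ds-predetermined sublibrary
#'
#' One member of a DP library set: Ds bases fixed at stated positions inside
#' an otherwise natural-randomized region.
#'
#' @param random_len Region length in nt (randomized positions + fixed Ds).
#' @param ub_positions 1-based positions of the predetermined Ds bases.
#' @param ub_base Unnatural base symbol (default Ds).
#' @return Object of class `dp_sublibrary`.
#' @export
dp_sublibrary <- function(random_len, ub_positions, ub_base = "X") {
  ub_positions <- sort(as.integer(ub_positions))
  stopifnot(random_len >= 1)
  if (any(ub_positions < 1 | ub_positions > random_len)) {
    stop("ub_positions out of range 1..", random_len)
  }
  if (anyDuplicated(ub_positions)) stop("duplicated ub_positions")
  structure(
    list(random_len = as.integer(random_len), ub_positions = ub_positions,
         ub_base = normalize_base(ub_base)),
    class = "dp_sublibrary")
}

#' Sequence-space size of one DP sublibrary
#'
#' The Ds positions are fixed letters, so the space is `4^(randomized
#' positions)`: for a 42-mer with two predetermined Ds bases, `4^40` (~1.2e24)
#' sequence contexts per sublibrary.
#'
#' @param sub A [dp_sublibrary()].
#' @return A [bigcount()].
#' @export
dp_sublibrary_space <- function(sub) {
  stopifnot(inherits(sub, "dp_sublibrary"))
  sequence_space(4, sub$random_len - length(sub$ub_positions))
}

#' Pooled set of Ds-predetermined sublibraries (DP library)
#'
#' @param sublibraries List of [dp_sublibrary()] objects.
#' @param molecules Physical complexity of the pooled set.
#' @param weights Pool proportions per sublibrary (default uniform).
#' @return Object of class `dp_library_set` (also `selex_library`).
#' @export
dp_library_set <- function(sublibraries, molecules, weights = NULL) {
  stopifnot(length(sublibraries) >= 1, molecules > 0)
  lapply(sublibraries, function(s) stopifnot(inherits(s, "dp_sublibrary")))
  if (is.null(weights)) weights <- rep(1, length(sublibraries))
  stopifnot(length(weights) == length(sublibraries), all(weights > 0))
  structure(
    list(kind = "dp", sublibraries = sublibraries,
         n_sublibraries = length(sublibraries),
         molecules = molecules, weights = weights / sum(weights),
         random_len = sublibraries[[1]]$random_len,
         alphabet = dna_alphabet(expanded = TRUE)),
    class = c("dp_library_set", "selex_library"))
}

#' Ds-doped five-letter randomized library (DR library)
#'
#' Every randomized position draws independently from the five-letter
#' distribution, by default 10% Ds and 22.5% each natural base. The terminal
#' stem can be embedded in the library as constant flanks, in which case
#' candidate motifs are anchored (no sliding placement).
#'
#' @param random_len Randomized-region length in nt.
#' @param molecules Physical complexity of the pool.
#' @param letter_freqs Named per-letter probabilities over A, C, G, T and Ds
#'   (`"X"`); must sum to 1.
#' @param flank5,flank3 Constant flanking sequences (e.g. the embedded stem).
#' @return Object of class `dr_library` (also `selex_library`).
#' @examples
#' dr_library(30, molecules = 1.1e15)
#' @export
dr_library <- function(random_len, molecules,
                       letter_freqs = c(A = 0.225, C = 0.225, G = 0.225,
                                        T = 0.225, X = 0.10),
                       flank5 = "", flank3 = "") {
  stopifnot(random_len >= 1, molecules > 0)
  names(letter_freqs) <- normalize_base(names(letter_freqs))
  if (any(letter_freqs < 0) || abs(sum(letter_freqs) - 1) > 1e-9) {
    stop("letter_freqs must be non-negative and sum to 1")
  }
  structure(
    list(kind = "dr", random_len = as.integer(random_len),
         molecules = molecules, letter_freqs = letter_freqs,
         flank5 = flank5, flank3 = flank3,
         alphabet = dna_alphabet(expanded = TRUE)),
    class = c("dr_library", "selex_library"))
}

#' @export
print.selex_library <- function(x, ...) {
  cat(sprintf("%s library: N%d region, %.3g molecules\n",
              toupper(x$kind), x$random_len, x$molecules))
  if (x$kind == "dp") {
    cat(sprintf("  %d sublibraries, Ds counts %s\n", x$n_sublibraries,
                paste(sort(unique(vapply(x$sublibraries,
                  function(s) length(s$ub_positions), 1L))), collapse = "/")))
  }
  if (x$kind == "dr") {
    cat("  letter frequencies:",
        paste(sprintf("%s=%.3g", display_base(names(x$letter_freqs)),
                      x$letter_freqs), collapse = " "), "\n")
  }
  invisible(x)
}

#' Parse a library model from a structured-text (YAML) config
#'
#' Config keys: `type` (`natural` | `dp` | `dr`), `random_len`, `molecules`,
#' and per type: `flank5`/`flank3` (natural, dr), `letter_freqs` (dr, named
#' map), `sublibraries` (dp, list of `ub_positions` vectors).
#'
#' @param text YAML string.
#' @param file Path to a YAML file.
#' @return A `selex_library` object.
#' @export
parse_library <- function(text = NULL, file = NULL) {
  cfg <- read_yaml_config(text, file)
  type <- tolower(cfg$type %||% stop("library config must declare 'type'"))
  switch(type,
    natural = natural_library(cfg$random_len, cfg$molecules,
                              flank5 = cfg$flank5 %||% "",
                              flank3 = cfg$flank3 %||% ""),
    dp = {
      subs <- lapply(cfg$sublibraries, function(s) {
        dp_sublibrary(cfg$random_len, unlist(s$ub_positions %||% s))
      })
      dp_library_set(subs, cfg$molecules)
    },
    dr = {
      freqs <- unlist(cfg$letter_freqs %||% NULL)
      if (is.null(freqs)) {
        dr_library(cfg$random_len, cfg$molecules,
                   flank5 = cfg$flank5 %||% "", flank3 = cfg$flank3 %||% "")
      } else {
        dr_library(cfg$random_len, cfg$molecules, letter_freqs = freqs,
                   flank5 = cfg$flank5 %||% "", flank3 = cfg$flank3 %||% "")
      }
    },
    stop("unknown library type '", type, "' (natural|dp|dr)"))
}
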