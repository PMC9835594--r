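# Sequence-level ground truth: sample or exhaustively enumerate library
# sequences and count motif matches directly. This is the package's
# independent check on the closed-form occurrence arithmetic -- the two are
# implemented against different representations (strings / digit vectors vs
# counting exponents) on purpose.

#' Sample sequences from a library model
#'
#' Draws `n` full-length sequences (constant flanks included) from a
#' [natural_library()], [dp_library_set()] or [dr_library()]: natural
#' positions uniform over A/C/G/T; DP draws a sublibrary (by pool weight)
#' then fixes its Ds positions; DR draws every randomized position from the
#' library's letter frequencies. Reproducible under `seed`.
#'
#' @param library A `selex_library`.
#' @param n Number of sequences.
#' @param seed Integer seed (RNG: Mersenne-Twister via `set.seed`).
#' @return Object of class `sequence_sample`: `sequences` (character vector),
#'   `library`, `n`, `seed`.
#' @examples
#' s <- sample_sequences(dr_library(30, 1e15), n = 5, seed = 1)
#' s$sequences
#' @export
sample_sequences <- function(library, n, seed) {
  stopifnot(inherits(library, "selex_library"), n >= 1)
  set.seed(seed)
  L <- library$random_len
  m <- switch(library$kind,
    natural = matrix(sample(NATURAL_BASES, n * L, replace = TRUE),
                     nrow = n),
    dr = matrix(sample(names(library$letter_freqs), n * L, replace = TRUE,
                       prob = library$letter_freqs), nrow = n),
    dp = {
      mm <- matrix(sample(NATURAL_BASES, n * L, replace = TRUE), nrow = n)
      which_sub <- sample.int(library$n_sublibraries, n, replace = TRUE,
                              prob = library$weights)
      for (si in seq_len(library$n_sublibraries)) {
        rows <- which(which_sub == si)
        if (length(rows) == 0) next
        s <- library$sublibraries[[si]]
        mm[rows, s$ub_positions] <- s$ub_base
      }
      mm
    })
  seqs <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  f5 <- library$flank5 %||% ""; f3 <- library$flank3 %||% ""
  if (nzchar(f5) || nzchar(f3)) seqs <- paste0(f5, seqs, f3)
  structure(list(sequences = seqs, library = library, n = n, seed = seed),
            class = "sequence_sample")
}

#' @export
print.sequence_sample <- function(x, ...) {
  cat(sprintf("%d sequences sampled from a %s library (seed %d)\n",
              x$n, toupper(x$library$kind), x$seed))
  utils::head(x$sequences, 3) |> cat(sep = "\n")
  if (x$n > 3) cat("...\n")
  invisible(x)
}

#' Does a sequence realize a motif at a given offset?
#'
#' True iff every essential position carries its required letter and every
#' stem pair is complementary under the selected rule. Vectorized over
#' `sequences`.
#'
#' @param sequences Character vector of sequences.
#' @param motif An [aptamer_motif()].
#' @param offset 1-based position of the motif's first position in the
#'   sequence.
#' @param stem_rule `"wc"`: Watson-Crick pairs only; `"wc_ds_px"`: also
#'   accept a Ds--Px stem pair.
#' @return Logical vector.
#' @export
matches_motif <- function(sequences, motif, offset = 1,
                          stem_rule = c("wc", "wc_ds_px")) {
  stem_rule <- match.arg(stem_rule)
  lens <- nchar(sequences)
  if (offset < 1 || any(offset + motif$length - 1 > lens)) {
    stop("offset ", offset, " places the motif outside the sequence bounds")
  }
  ok <- rep(TRUE, length(sequences))
  at <- function(p) substr(sequences, offset + p - 1, offset + p - 1)

  for (p in which(motif$roles %in% c("essential", "essential_ub"))) {
    ok <- ok & (at(p) == motif$bases[p])
  }
  pairs <- allowed_stem_pairs(
    if (stem_rule == "wc_ds_px") {
      dna_alphabet(expanded = TRUE, allow_ds_px_stem = TRUE)
    } else motif$alphabet)
  pair_key <- paste0(pairs[, 1], pairs[, 2])
  stem_i <- which(motif$roles == "stem" & seq_len(motif$length) < motif$partner)
  for (i in stem_i) {
    ok <- ok & (paste0(at(i), at(motif$partner[i])) %in% pair_key)
  }
  ok
}

# Offsets at which the essential core stays inside the randomized region
# (stems may extend into the constant flanks) and the motif fits in the full
# sequence.
candidate_offsets <- function(motif, library, total_len) {
  f5 <- nchar(library$flank5 %||% "")
  lo <- max(1L, f5 + 1L - (motif$core_start - 1L))
  hi <- min(total_len - motif$length + 1L,
            f5 + library$random_len - motif$core_end + 1L)
  if (is.na(motif$core_start)) {           # no essential positions
    lo <- 1L; hi <- total_len - motif$length + 1L
  }
  if (hi < lo) integer(0) else lo:hi
}

#' Count candidate sequences in a sample
#'
#' A sequence is a candidate when it realizes the motif at one or more
#' allowed offsets (inclusion at >= 1 offset -- overlapping placements are
#' not double-counted, unlike the analytic sliding-placement multiplier `W`).
#'
#' @param sample A [sample_sequences()] result.
#' @param motif An [aptamer_motif()].
#' @param stem_rule Passed to [matches_motif()].
#' @return List with `count`, `n`, `frequency`, and `expected_in_library`
#'   (frequency scaled to the library's molecule count).
#' @export
count_candidates <- function(sample, motif, stem_rule = c("wc", "wc_ds_px")) {
  stem_rule <- match.arg(stem_rule)
  stopifnot(inherits(sample, "sequence_sample"))
  seqs <- sample$sequences
  offs <- candidate_offsets(motif, sample$library, nchar(seqs[1]))
  hit <- rep(FALSE, length(seqs))
  for (o in offs) {
    hit <- hit | matches_motif(seqs, motif, offset = o, stem_rule = stem_rule)
  }
  freq <- mean(hit)
  list(count = sum(hit), n = length(seqs), frequency = freq,
       expected_in_library = freq * sample$library$molecules)
}

#' Exhaustively count motif matches over a full sequence space
#'
#' Enumerates every sequence of the library's randomized region (guarded to
#' spaces of at most 4^10 = 1,048,576 sequences) and counts those matching
#' the motif at >= 1 offset. Sequences are enumerated as base-`A` digit
#' vectors, entirely independently of the analytic occurrence path. For
#' non-uniform letter frequencies (DR libraries) the probability-weighted
#' match mass is returned alongside the raw count.
#'
#' @param motif An [aptamer_motif()].
#' @param library A flankless [natural_library()] or [dr_library()].
#' @param stem_rule `"wc"` or `"wc_ds_px"`.
#' @return List with `count`, `space`, `frequency` (`count/space`) and
#'   `probability` (weighted by letter frequencies; equals `frequency` for
#'   uniform libraries), plus `expected_in_library`.
#' @export
count_candidates_exhaustive <- function(motif, library,
                                        stem_rule = c("wc", "wc_ds_px")) {
  stem_rule <- match.arg(stem_rule)
  stopifnot(inherits(library, "selex_library"),
            library$kind %in% c("natural", "dr"))
  if (nzchar(library$flank5 %||% "") || nzchar(library$flank3 %||% "")) {
    stop("exhaustive enumeration supports flankless libraries only")
  }
  letters <- if (library$kind == "natural") NATURAL_BASES else
    names(library$letter_freqs)
  A <- length(letters)
  L <- library$random_len
  N <- A^L
  if (N > 4^10) {
    stop("sequence space ", format(N, big.mark = ","),
         " exceeds the 4^10 exhaustive guard; use sample_sequences() + ",
         "count_candidates() instead")
  }
  if (motif$length > L) {
    return(list(count = 0, space = N, frequency = 0, probability = 0,
                expected_in_library = 0))
  }
  v <- seq_len(N) - 1
  digit <- function(p) (v %/% A^(p - 1)) %% A      # 0-based letter index
  idx <- function(b) match(b, letters) - 1

  # complement letter index (or NA) under the stem rule
  comp_letters <- COMPLEMENT_MAP[letters]
  if (stem_rule == "wc") comp_letters[letters == UB_DS] <- NA
  comp_idx <- match(comp_letters, letters) - 1     # NA if partner not a letter

  offs <- candidate_offsets(motif, library, L)
  hit <- rep(FALSE, N)
  ess <- which(motif$roles %in% c("essential", "essential_ub"))
  stem_i <- which(motif$roles == "stem" & seq_len(motif$length) < motif$partner)
  for (o in offs) {
    ok <- rep(TRUE, N)
    for (p in ess) {
      want <- idx(motif$bases[p])
      ok <- ok & if (is.na(want)) FALSE else digit(o + p - 1) == want
    }
    for (i in stem_i) {
      di <- digit(o + i - 1)
      dj <- digit(o + motif$partner[i] - 1)
      cmp <- comp_idx[di + 1]
      ok <- ok & !is.na(cmp) & (dj == cmp)
    }
    hit <- hit | ok
  }

  freqs <- library$letter_freqs[letters]
  uniform <- all(abs(freqs - 1 / A) < 1e-12)
  prob <- if (uniform) {
    sum(hit) / N
  } else {
    w <- rep(1, N)
    for (p in seq_len(L)) w <- w * freqs[digit(p) + 1]
    sum(w[hit])
  }
  list(count = sum(hit), space = N, frequency = sum(hit) / N,
       probability = unname(prob),
       expected_in_library = unname(prob) * library$molecules)
}

#' Write a sequence sample to FASTA
#'
#' There is no community FASTA letter for Ds or Px; by default they are
#' written as `X` and `P` and the mapping is recorded in every record's
#' description.
#'
#' @param sample A [sample_sequences()] result.
#' @param path Output file.
#' @param ds_symbol,px_symbol Symbols to write for Ds and Px.
#' @return `path`, invisibly.
#' @export
write_sample_fasta <- function(sample, path, ds_symbol = "X",
                               px_symbol = "P") {
  seqs <- sample$sequences
  seqs <- chartr(paste0(UB_DS, UB_PX), paste0(ds_symbol, px_symbol), seqs)
  legend <- sprintf("Ds=%s Px=%s seed=%d", ds_symbol, px_symbol, sample$seed)
  seqinr::write.fasta(as.list(seqs),
                      names = sprintf("seq%06d %s", seq_along(seqs), legend),
                      file.out = path, as.string = TRUE, nbchar = 80)
  invisible(path)
}
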