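# Small random motifs for property-style tests. Motif length equals the
# library's randomized-region length, so there is exactly one allowed
# placement and analytic and enumerated match probabilities are directly
# comparable.

random_toy_motif <- function(len = sample(4:6, 1), expanded = FALSE,
                             with_ub = FALSE) {
  pos <- sample(len)
  n_ess <- sample(1:max(1, len - 3), 1)
  ess_pos <- sort(pos[seq_len(n_ess)])
  remaining <- setdiff(seq_len(len), ess_pos)

  essential_ub <- character()
  if (with_ub && length(ess_pos) > 1) {
    ubp <- ess_pos[1]
    ess_pos <- ess_pos[-1]
    essential_ub <- stats::setNames("X", ubp)
  }
  essential <- stats::setNames(
    sample(c("A", "C", "G", "T"), length(ess_pos), replace = TRUE),
    ess_pos)

  stem_pairs <- list()
  if (length(remaining) >= 2 && stats::runif(1) < 0.7) {
    pr <- sort(sample(remaining, 2))
    stem_pairs <- list(pr)
  }
  aptamer_motif(len, essential = essential, essential_ub = essential_ub,
                stem_pairs = stem_pairs,
                alphabet = dna_alphabet(expanded = expanded || with_ub))
}

# A concrete, fully specified 5-mer toy: 3 essential bases + 1 stem bp,
# spanning the whole region. Required number 4^4.
toy_motif_5 <- function() {
  aptamer_motif(5, essential = c("2" = "G", "3" = "A", "4" = "C"),
                stem_pairs = list(c(1, 5)),
                alphabet = dna_alphabet(expanded = FALSE))
}
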