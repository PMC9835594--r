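# Expanded genetic alphabet: the four natural bases plus the hydrophobic
# unnatural base pair Ds-Px. Sequences are plain character strings; Ds is the
# single character "X" and Px is "P" (there is no community FASTA letter for
# either, so the symbol is a package convention, configurable on export).

UB_DS <- "X"
UB_PX <- "P"
NATURAL_BASES <- c("A", "C", "G", "T")
COMPLEMENT_MAP <- c(A = "T", T = "A", C = "G", G = "C", X = "P", P = "X")

#' DNA alphabets with the Ds--Px unnatural base pair
#'
#' Constructs the alphabet a library or motif is defined over. A natural
#' alphabet has the four letters A, C, G, T; the expanded alphabet adds Ds
#' (symbol `"X"`) as a fifth library letter. Px (symbol `"P"`) is always
#' representable as a pairing partner -- it arises in motifs through PCR
#' misincorporation -- but is only a *library* letter when `include_px = TRUE`,
#' which no selection design described here uses.
#'
#' @param expanded Include Ds as a library letter (five-letter alphabet).
#' @param include_px Also include Px as a library letter (off by default).
#' @param allow_ds_px_stem Whether a Ds--Px pair counts as an allowed stem
#'   base pair. Off by default: a Ds--Px stem pair cannot form in a Px-free
#'   library.
#' @return An object of class `dna_alphabet` with fields `letters`,
#'   `natural`, `complement` (named character map), `size`, and the two flags.
#' @examples
#' dna_alphabet()                  # A C G T
#' dna_alphabet(expanded = TRUE)   # A C G T X (Ds)
#' @export
dna_alphabet <- function(expanded = FALSE, include_px = FALSE,
                         allow_ds_px_stem = FALSE) {
  letters <- NATURAL_BASES
  if (expanded) letters <- c(letters, UB_DS)
  if (include_px) letters <- c(letters, UB_PX)
  structure(
    list(letters = letters,
         natural = NATURAL_BASES,
         complement = COMPLEMENT_MAP,
         size = length(letters),
         expanded = expanded,
         allow_ds_px_stem = allow_ds_px_stem),
    class = "dna_alphabet")
}

#' @export
print.dna_alphabet <- function(x, ...) {
  cat("DNA alphabet:", paste(display_base(x$letters), collapse = " "),
      sprintf("(%d letters)\n", x$size))
  invisible(x)
}

#' Normalize base symbols
#'
#' Accepts the long names `"Ds"` and `"Px"` (any case) as synonyms for the
#' internal single-character symbols.
#' @param base Character vector of base symbols.
#' @return Single-character symbols.
#' @export
normalize_base <- function(base) {
  base <- as.character(base)
  base[tolower(base) == "ds"] <- UB_DS
  base[tolower(base) == "px"] <- UB_PX
  toupper(base)
}

# Long names for user-facing output.
display_base <- function(base) {
  out <- base
  out[base == UB_DS] <- "Ds"
  out[base == UB_PX] <- "Px"
  out
}

#' Complement of a base under the expanded alphabet
#'
#' A pairs with T, G with C, and Ds with Px. The map is an involution:
#' `complement_base(complement_base(b))` returns `b`.
#'
#' @param base Character vector of base symbols (`"Ds"`/`"Px"` accepted).
#' @param alphabet A [dna_alphabet()]; used to validate symbols.
#' @return The complementary symbols.
#' @examples
#' complement_base("A")    # "T"
#' complement_base("Ds")   # "P" (Px)
#' @export
complement_base <- function(base, alphabet = dna_alphabet(expanded = TRUE)) {
  base <- normalize_base(base)
  known <- names(alphabet$complement)
  bad <- setdiff(unique(base), known)
  if (length(bad) > 0) {
    stop("unknown base symbol(s): ", paste(bad, collapse = ", "))
  }
  unname(alphabet$complement[base])
}

# Allowed stem base pairs for an alphabet, as a 2-column matrix of symbols.
# Watson-Crick pairs always; Ds-Px only when the alphabet allows it.
allowed_stem_pairs <- function(alphabet) {
  pairs <- rbind(c("A", "T"), c("T", "A"), c("G", "C"), c("C", "G"))
  if (isTRUE(alphabet$allow_ds_px_stem)) {
    pairs <- rbind(pairs, c(UB_DS, UB_PX), c(UB_PX, UB_DS))
  }
  pairs
}
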