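# Aptamer candidate motifs: per-position roles over an (expanded) alphabet.
# Positions are 1-based throughout, matching how aptamer positions are
# reported in the literature ("position 29").

#' Aptamer candidate motif
#'
#' A motif is a positional template for an aptamer candidate class: each
#' position is an essential natural base (identity fixed), an essential
#' unnatural base (Ds or Px, identity fixed), one arm of a stem base pair
#' (any allowed complementary pair acceptable), or a wildcard. Stems are
#' declared as index pairs; each pair is counted once as one stem bp.
#'
#' @param length Motif length in nucleotides.
#' @param essential Named character vector of essential *natural* bases;
#'   names are 1-based positions, values are bases, e.g. `c("3" = "A")`.
#' @param essential_ub Named character vector of essential unnatural bases
#'   (`"Ds"`/`"X"` or `"Px"`/`"P"`), same convention.
#' @param stem_pairs Stem base pairs: a list of length-2 integer vectors or a
#'   2-column matrix of 1-based position pairs.
#' @param alphabet A [dna_alphabet()]. Defaults to the expanded (Ds) alphabet.
#' @return An object of class `aptamer_motif` with per-position `roles`
#'   (`"essential"`, `"essential_ub"`, `"stem"`, `"wildcard"`), fixed `bases`,
#'   stem `partner` indices, derived counts (`n_essential_natural`,
#'   `n_essential_ub`, `n_stem_bp`, `n_wildcard`), and the essential core:
#'   `core_start`, `core_end`, `core_span` (minimal contiguous window holding
#'   every essential position).
#' @examples
#' # 3 essential bases flanked by a 1-bp stem, length 5
#' m <- aptamer_motif(5, essential = c("2" = "G", "3" = "A", "4" = "C"),
#'                    stem_pairs = list(c(1, 5)))
#' m$counts$n_stem_bp    # 1
#' m$core_span           # 3
#' @export
aptamer_motif <- function(length, essential = character(),
                          essential_ub = character(),
                          stem_pairs = list(),
                          alphabet = dna_alphabet(expanded = TRUE)) {
  stopifnot(is.numeric(length), length >= 1, length == floor(length))
  length <- as.integer(length)

  if (is.matrix(stem_pairs)) {
    stem_pairs <- lapply(seq_len(nrow(stem_pairs)), function(i) stem_pairs[i, ])
  }

  roles <- rep("wildcard", length)
  bases <- rep(NA_character_, length)
  partner <- rep(NA_integer_, length)

  check_pos <- function(p, what) {
    if (any(p < 1 | p > length | p != floor(p))) {
      stop(what, " position out of range 1..", length, ": ",
           paste(p[p < 1 | p > length], collapse = ", "))
    }
  }

  ess_pos <- as.integer(names(essential))
  if (length(essential) > 0) {
    if (anyNA(ess_pos)) stop("essential positions must be named by index")
    check_pos(ess_pos, "essential")
    b <- normalize_base(essential)
    bad <- setdiff(b, alphabet$natural)
    if (length(bad) > 0) {
      stop("essential natural base not in {A,C,G,T}: ",
           paste(display_base(bad), collapse = ", "),
           " (use essential_ub for unnatural bases)")
    }
    roles[ess_pos] <- "essential"
    bases[ess_pos] <- b
  }

  ub_pos <- as.integer(names(essential_ub))
  if (length(essential_ub) > 0) {
    if (anyNA(ub_pos)) stop("essential_ub positions must be named by index")
    check_pos(ub_pos, "essential_ub")
    b <- normalize_base(essential_ub)
    bad <- b[b %in% alphabet$natural | !b %in% names(alphabet$complement)]
    if (length(bad) > 0) {
      stop("essential_ub base must be an unnatural base (Ds/Px), got: ",
           paste(display_base(bad), collapse = ", "))
    }
    if (any(roles[ub_pos] != "wildcard")) stop("position declared twice")
    roles[ub_pos] <- "essential_ub"
    bases[ub_pos] <- b
  }

  for (pair in stem_pairs) {
    pair <- as.integer(pair)
    if (length(pair) != 2) stop("each stem pair must have exactly 2 positions")
    check_pos(pair, "stem")
    if (pair[1] == pair[2]) stop("stem pair cannot pair position ", pair[1],
                                 " with itself")
    if (any(roles[pair] != "wildcard")) {
      dup <- pair[roles[pair] != "wildcard"][1]
      stop("position ", dup, " assigned more than one role")
    }
    roles[pair] <- "stem"
    partner[pair[1]] <- pair[2]
    partner[pair[2]] <- pair[1]
  }

  counts <- list(
    n_essential_natural = sum(roles == "essential"),
    n_essential_ub = sum(roles == "essential_ub"),
    n_stem_bp = sum(roles == "stem") %/% 2L,
    n_wildcard = sum(roles == "wildcard"))

  ess_all <- which(roles %in% c("essential", "essential_ub"))
  if (length(ess_all) > 0) {
    core_start <- min(ess_all); core_end <- max(ess_all)
  } else {
    core_start <- NA_integer_; core_end <- NA_integer_
  }
  core_span <- if (length(ess_all) > 0) core_end - core_start + 1L else 0L

  structure(
    list(length = length, roles = roles, bases = bases, partner = partner,
         alphabet = alphabet, counts = counts,
         core_start = core_start, core_end = core_end, core_span = core_span,
         ub_positions = which(roles == "essential_ub")),
    class = "aptamer_motif")
}

#' @export
print.aptamer_motif <- function(x, ...) {
  cat(sprintf("Aptamer motif, %d nt: %d essential natural, %d essential UB, %d stem bp, %d wildcard; essential core span %d nt\n",
              x$length, x$counts$n_essential_natural, x$counts$n_essential_ub,
              x$counts$n_stem_bp, x$counts$n_wildcard, x$core_span))
  glyph <- ifelse(x$roles == "wildcard", ".",
           ifelse(x$roles == "stem", "(",
                  display_base(x$bases)))
  cat(" ", paste(glyph, collapse = ""), "\n")
  invisible(x)
}

#' Parse a motif from a structured-text (YAML) config
#'
#' The config declares `length`, optionally `alphabet` (`natural` or `ds`),
#' and a `positions` list; every position not listed is a wildcard. Each
#' entry has `index` (1-based), `role` (`essential`, `essential_ub`, `stem`),
#' `base` (for essential roles) and `partner` (for stems). Stem pairings must
#' be declared at *both* partner positions and agree; an asymmetric
#' declaration is a validation error naming the offending position.
#'
#' @param text Config as a YAML string.
#' @param file Path to a YAML file (alternative to `text`).
#' @param allow_ds_px_stem Passed to [dna_alphabet()].
#' @return An [aptamer_motif()].
#' @examples
#' parse_motif(text = "
#' length: 5
#' alphabet: ds
#' positions:
#'   - {index: 1, role: stem, partner: 5}
#'   - {index: 5, role: stem, partner: 1}
#'   - {index: 2, role: essential, base: G}
#'   - {index: 3, role: essential_ub, base: Ds}
#' ")
#' @export
parse_motif <- function(text = NULL, file = NULL, allow_ds_px_stem = FALSE) {
  cfg <- read_yaml_config(text, file)
  if (is.null(cfg$length)) stop("motif config must declare 'length'")
  alpha_key <- tolower(cfg$alphabet %||% "ds")
  if (!alpha_key %in% c("natural", "ds")) {
    stop("alphabet must be 'natural' or 'ds', got '", cfg$alphabet, "'")
  }
  alphabet <- dna_alphabet(expanded = alpha_key == "ds",
                           allow_ds_px_stem = allow_ds_px_stem)

  essential <- character(); essential_ub <- character()
  partner_decl <- list()
  for (p in cfg$positions %||% list()) {
    if (is.null(p$index) || is.null(p$role)) {
      stop("every position entry needs 'index' and 'role'")
    }
    idx <- as.character(p$index)
    switch(as.character(p$role),
      essential = {
        if (is.null(p$base)) stop("position ", idx, ": essential needs 'base'")
        essential[idx] <- p$base
      },
      essential_ub = {
        if (is.null(p$base)) stop("position ", idx,
                                  ": essential_ub needs 'base'")
        essential_ub[idx] <- p$base
      },
      stem = {
        if (is.null(p$partner)) stop("position ", idx, ": stem needs 'partner'")
        partner_decl[[idx]] <- as.integer(p$partner)
      },
      wildcard = NULL,
      stop("position ", idx, ": unknown role '", p$role, "'"))
  }

  # stems must be declared symmetrically
  stem_pairs <- list()
  for (idx in names(partner_decl)) {
    i <- as.integer(idx); j <- partner_decl[[idx]]
    back <- partner_decl[[as.character(j)]]
    if (is.null(back) || back != i) {
      stop("asymmetric stem pairing at position ", idx,
           ": partner ", j, " does not declare ", idx, " back")
    }
    if (i < j) stem_pairs[[length(stem_pairs) + 1L]] <- c(i, j)
  }

  aptamer_motif(cfg$length, essential = essential,
                essential_ub = essential_ub, stem_pairs = stem_pairs,
                alphabet = alphabet)
}

#' Build a stem--loop motif from its published summary counts
#'
#' Occurrence calculations depend only on a motif's counts (essential natural
#' bases, essential unnatural bases, stem bp) and the span of its essential
#' core -- not on the concrete base identities. This helper lays out a
#' canonical motif realizing given counts: a terminal stem enclosing a
#' contiguous essential loop (with any internal stem bp placed inside the
#' loop), Ds bases separated by `ub_gap` natural bases. Concrete natural base
#' identities are filled cyclically (A, C, G, T) and are arbitrary.
#'
#' @param n_essential_natural Number of essential/important natural bases.
#' @param n_essential_ub Number of essential unnatural (Ds) bases.
#' @param terminal_stem_bp,internal_stem_bp Stem base pairs outside and
#'   inside the essential core.
#' @param ub_gap Natural bases between consecutive Ds bases (default 7,
#'   within the 5--10 spacing typical of high-affinity Ds-DNA aptamers).
#' @param alphabet A [dna_alphabet()].
#' @return An [aptamer_motif()] whose counts match the arguments and whose
#'   `core_span` is `n_essential_natural + n_essential_ub +
#'   2 * internal_stem_bp`.
#' @export
design_stem_loop_motif <- function(n_essential_natural, n_essential_ub = 0,
                                   terminal_stem_bp = 0, internal_stem_bp = 0,
                                   ub_gap = 7,
                                   alphabet = dna_alphabet(expanded = n_essential_ub > 0)) {
  n_loop <- n_essential_natural + n_essential_ub
  if (n_essential_ub > 0 && n_essential_natural < (n_essential_ub - 1) * ub_gap) {
    stop("not enough natural bases for ub_gap = ", ub_gap)
  }
  len <- 2L * terminal_stem_bp + 2L * internal_stem_bp + n_loop
  # terminal stem arms at the ends, internal stem arms just inside them,
  # essential loop in the middle
  t5 <- seq_len(terminal_stem_bp)
  i5 <- terminal_stem_bp + seq_len(internal_stem_bp)
  loop <- (terminal_stem_bp + internal_stem_bp) + seq_len(n_loop)
  i3 <- max(loop) + seq_len(internal_stem_bp)
  t3 <- max(c(loop, i3)) + seq_len(terminal_stem_bp)
  stem_pairs <- c(
    lapply(seq_len(terminal_stem_bp), function(k) c(t5[k], rev(t3)[k])),
    lapply(seq_len(internal_stem_bp), function(k) c(i5[k], rev(i3)[k])))

  # Ds bases spaced ub_gap apart from the start of the loop
  ub_local <- if (n_essential_ub > 0) {
    1L + (seq_len(n_essential_ub) - 1L) * (ub_gap + 1L)
  } else integer(0)
  ub_pos <- loop[ub_local]
  nat_pos <- setdiff(loop, ub_pos)
  essential <- stats::setNames(
    rep(c("A", "C", "G", "T"), length.out = length(nat_pos)),
    nat_pos)
  essential_ub <- stats::setNames(rep("X", length(ub_pos)), ub_pos)

  aptamer_motif(len, essential = essential, essential_ub = essential_ub,
                stem_pairs = stem_pairs, alphabet = alphabet)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_yaml_config <- function(text, file) {
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of 'text' or 'file'")
  }
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file)
    yaml::read_yaml(file)
  } else {
    yaml::yaml.load(text)
  }
}
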