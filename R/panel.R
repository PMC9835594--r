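# Case-study panel: the aptamer motifs and library designs whose occurrence
# arithmetic is fully determined by main-text parameters. Each entry stores
# only the *inputs* (motif counts, library complexity, hit counts); every
# derived quantity is computed by the occurrence engine.

#' Reported Ds-DNA aptamer case studies
#'
#' The selection campaigns whose motif and library parameters are published
#' as text: the pegaptanib precursor (natural N30 selection, 19 essential
#' stem--loop bases + 4-bp terminal stem), anti-VEGF165 (DP, 21 important
#' natural bases + 2 Ds + 8 stem bp), anti-DEN3-NS1 (DP, all 28 loop natural
#' bases + 2 Ds treated as important + 6 stem bp), anti-DEN4-NS1 (DP, 14
#' important natural bases + 2 Ds + 8 stem bp; 2 of 74 sublibraries
#' compatible) and anti-vWF (DR, 13 important single-stranded bases
#' including 2 Ds + 6 internal stem bp, terminal stem embedded in the
#' library, hence anchored).
#'
#' For the DP entries the published sublibrary Ds layouts themselves are not
#' part of the panel (they are reported elsewhere); the printed hit /
#' sublibrary counts are carried as inputs instead (`hits`, or `NA` where no
#' hit count is published).
#'
#' @return Named list of case studies; each holds `motif`, `library_kind`,
#'   `molecules`, `anchored`, and for DP entries `hits` and
#'   `total_sublibraries`.
#' @examples
#' panel <- ds_aptamer_panel()
#' required_number(panel$anti_VEGF165$motif, "dp")   # 2.9e17
#' @export
ds_aptamer_panel <- function() {
  list(
    pegaptanib_precursor = list(
      description = "anti-VEGF165 modified-RNA aptamer precursor, natural N30 selection from 1 nmol",
      motif = design_stem_loop_motif(19, terminal_stem_bp = 4),
      library_kind = "natural",
      random_len = 30L,
      molecules = nmol_to_molecules(1),
      anchored = FALSE),
    anti_VEGF165 = list(
      description = "anti-VEGF165 Ds-DNA aptamer, 22-sublibrary DP selection",
      motif = design_stem_loop_motif(21, 2, terminal_stem_bp = 4,
                                     internal_stem_bp = 4),
      library_kind = "dp",
      molecules = 1.8e14,
      total_sublibraries = 22L,
      hits = NA_integer_),
    anti_DEN3_NS1 = list(
      description = "anti-DEN3-NS1 Ds-DNA aptamer, 74-sublibrary DP selection; all loop bases treated as important",
      motif = design_stem_loop_motif(28, 2, terminal_stem_bp = 6),
      library_kind = "dp",
      molecules = 6.0e15,
      total_sublibraries = 74L,
      hits = NA_integer_),
    anti_DEN4_NS1 = list(
      description = "anti-DEN4-NS1 Ds-DNA aptamer, 74-sublibrary DP selection; 3-bp terminal + 5-bp internal stems",
      motif = design_stem_loop_motif(14, 2, terminal_stem_bp = 3,
                                     internal_stem_bp = 5),
      library_kind = "dp",
      molecules = 6.0e15,
      total_sublibraries = 74L,
      hits = 2L),
    anti_vWF = list(
      description = "anti-vWF Ds-DNA aptamer, doped DR N30 selection; terminal stem embedded in the library",
      motif = design_stem_loop_motif(11, 2, internal_stem_bp = 6,
                                     ub_gap = 5),
      library_kind = "dr",
      random_len = 30L,
      molecules = 1.1e15,
      anchored = TRUE)
  )
}

#' Occurrence summary for the case-study panel
#'
#' Runs the occurrence engine over [ds_aptamer_panel()] and tabulates the
#' required number and, where the needed inputs are published (hit counts
#' for DP designs), the expected occurrence.
#'
#' @param panel Output of [ds_aptamer_panel()].
#' @param mode `"power"` or `"strict"` required-number convention.
#' @return `data.frame` with one row per aptamer: motif counts, library
#'   kind, complexity, required number, hit fraction, occurrence (exact and
#'   as-printed), and P(at least one candidate).
#' @export
panel_occurrence_table <- function(panel = ds_aptamer_panel(),
                                   mode = "power") {
  rows <- lapply(names(panel), function(nm) {
    cs <- panel[[nm]]
    cts <- cs$motif$counts
    R <- required_number(cs$motif, cs$library_kind, mode = mode)
    res <- switch(cs$library_kind,
      natural = occurrence_natural(
        cs$motif, natural_library(cs$random_len, cs$molecules), mode = mode),
      dp = if (is.na(cs$hits)) NULL else occurrence_result(
        "dp", mode, cs$molecules, R,
        hits = cs$hits, total_sublibraries = cs$total_sublibraries),
      dr = occurrence_dr(cs$motif, dr_library(cs$random_len, cs$molecules),
                         mode = mode, anchored = cs$anchored))
    data.frame(
      aptamer = nm, library = cs$library_kind,
      n_essential_natural = cts$n_essential_natural,
      n_essential_ub = cts$n_essential_ub,
      n_stem_bp = cts$n_stem_bp,
      molecules = cs$molecules,
      required_number = as.numeric(R),
      hits = cs$hits %||% NA_integer_,
      total_sublibraries = cs$total_sublibraries %||% NA_integer_,
      occurrence = if (is.null(res)) NA_real_ else res$occurrence,
      occurrence_printed = if (is.null(res)) NA_real_ else
        res$occurrence_printed,
      p_at_least_one = if (is.null(res)) NA_real_ else res$p_at_least_one,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
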