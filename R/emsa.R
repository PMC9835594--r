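# EMSA quantification and important-base calling.
#
# Input is a table of already-quantified band densities (one row per lane):
# the shifted (protein-complexed) band and the free band. Per lane, the
# shifted fraction is complex / (complex + free); per gel, every variant is
# normalized to the original aptamer run on the same gel, giving relative
# binding (%); positions whose variants average below the threshold
# (default 65%) are called important for high-affinity binding.

EMSA_REQUIRED_COLS <- c("gel_id", "variant_id", "complex_density",
                        "free_density", "is_original")

#' Read an EMSA band-density table from TSV
#'
#' Expected columns: `gel_id`, `variant_id`, `position` (mutated position,
#' empty/NA for original lanes), `variant_class`
#' (`transition`/`ub_sub`/`original`; optional), `complex_density`,
#' `free_density`, `is_original` (logical or 0/1).
#'
#' @param path TSV file path.
#' @return A validated `data.frame`.
#' @export
read_emsa_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_emsa_table(tab)
}

#' @rdname read_emsa_table
#' @param tab An EMSA table as a `data.frame`.
#' @export
validate_emsa_table <- function(tab) {
  missing_cols <- setdiff(EMSA_REQUIRED_COLS, names(tab))
  if (length(missing_cols) > 0) {
    stop("EMSA table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  tab$is_original <- as.logical(tab$is_original)
  if (any(tab$complex_density < 0) || any(tab$free_density < 0)) {
    stop("band densities must be non-negative")
  }
  empty <- tab$complex_density + tab$free_density <= 0
  if (any(empty)) {
    stop("empty lane (complex + free = 0): ",
         paste(tab$variant_id[empty], collapse = ", "))
  }
  no_orig <- setdiff(unique(tab$gel_id), unique(tab$gel_id[tab$is_original]))
  if (length(no_orig) > 0) {
    stop("gel(s) without an original-aptamer lane: ",
         paste(no_orig, collapse = ", "))
  }
  tab
}

#' Shifted-band fraction of a lane
#'
#' `complex / (complex + free)`, the proportion of the DNA that ran as the
#' protein-bound complex.
#'
#' @param complex_density,free_density Non-negative band densities
#'   (vectorized).
#' @return Fraction in `[0, 1]`.
#' @examples
#' shifted_fraction(50, 50)   # 0.5
#' @export
shifted_fraction <- function(complex_density, free_density) {
  if (any(complex_density < 0) || any(free_density < 0)) {
    stop("band densities must be non-negative")
  }
  total <- complex_density + free_density
  if (any(total <= 0)) stop("empty lane: complex + free must be positive")
  complex_density / total
}

#' Relative binding of every variant, normalized within gel
#'
#' Each lane's shifted fraction is divided by the original aptamer's shifted
#' fraction on the same gel (the mean, if the gel carries several original
#' lanes) and expressed as a percentage. A lone original lane reports exactly
#' 100%. Values above 100% (variant binding better than the original) are
#' reported unclipped.
#'
#' @param tab An EMSA table (see [read_emsa_table()]).
#' @return The table with `shifted_fraction` and `relative_binding` (%)
#'   columns added.
#' @export
relative_binding <- function(tab) {
  tab <- validate_emsa_table(tab)
  tab$shifted_fraction <- shifted_fraction(tab$complex_density,
                                           tab$free_density)
  ref <- tapply(tab$shifted_fraction[tab$is_original],
                tab$gel_id[tab$is_original], mean)
  if (any(ref == 0)) {
    stop("original aptamer shifted fraction is 0 on gel(s): ",
         paste(names(ref)[ref == 0], collapse = ", "))
  }
  tab$relative_binding <- as.numeric(100 * tab$shifted_fraction /
                                       ref[as.character(tab$gel_id)])
  # a single original lane is its own reference
  single <- tab$is_original &
    tab$gel_id %in% names(which(table(tab$gel_id[tab$is_original]) == 1))
  tab$relative_binding[single] <- 100
  tab
}

#' Call important base positions from relative bindings
#'
#' Aggregates variant relative bindings per mutated position (mean by
#' default; the published rule averages replicate measurements) and flags
#' positions whose aggregate falls below the threshold as important for
#' high-affinity binding.
#'
#' @param tab Output of [relative_binding()], with a `position` column
#'   mapping each non-original variant to its mutated position. When the
#'   table carries a `variant_class` column, classes can be called
#'   separately by filtering beforehand.
#' @param tau Importance threshold in percent (default 65: positions whose
#'   variants average below 65% relative binding are called important).
#' @param stat `"mean"` (default) or `"median"` aggregation.
#' @param positions Optional full set of positions of interest; those with
#'   no variants in the table are listed as `untested`.
#' @return Object of class `binding_call_set`: `per_variant` (the input
#'   rows), `per_position` (position, aggregate relative binding, number of
#'   variant lanes, importance flag), `tau`, `important_positions`,
#'   `untested_positions`.
#' @examples
#' tab <- data.frame(gel_id = 1, variant_id = c("orig", "m3", "m5"),
#'                   position = c(NA, 3, 5), is_original = c(TRUE, FALSE, FALSE),
#'                   complex_density = c(60, 15, 55), free_density = c(40, 85, 45))
#' calls <- call_important(relative_binding(tab))
#' calls$important_positions   # 3
#' @export
call_important <- function(tab, tau = 65, stat = c("mean", "median"),
                           positions = NULL) {
  stat <- match.arg(stat)
  if (tau <= 0 || tau > 100) stop("tau must lie in (0, 100]")
  if (is.null(tab$relative_binding)) tab <- relative_binding(tab)
  if (is.null(tab$position)) stop("table needs a 'position' column")
  var_rows <- tab[!tab$is_original & !is.na(tab$position), , drop = FALSE]
  agg_fun <- if (stat == "mean") mean else stats::median
  agg <- tapply(var_rows$relative_binding, var_rows$position, agg_fun)
  n_lanes <- tapply(var_rows$relative_binding, var_rows$position, length)
  per_position <- data.frame(
    position = as.integer(names(agg)),
    relative_binding = unname(agg),
    n_lanes = as.integer(unname(n_lanes)),
    important = unname(agg) < tau)
  per_position <- per_position[order(per_position$position), , drop = FALSE]
  untested <- if (is.null(positions)) integer(0) else
    sort(setdiff(as.integer(positions), per_position$position))
  structure(
    list(per_variant = var_rows, per_position = per_position,
         tau = tau, stat = stat,
         important_positions = per_position$position[per_position$important],
         untested_positions = untested),
    class = "binding_call_set")
}

#' @export
print.binding_call_set <- function(x, ...) {
  cat(sprintf("Important-base calls at tau = %g%% (%s over variant lanes)\n",
              x$tau, x$stat))
  print(x$per_position, row.names = FALSE)
  cat("important positions:",
      if (length(x$important_positions)) paste(x$important_positions,
                                               collapse = ", ") else "none",
      "\n")
  if (length(x$untested_positions) > 0) {
    cat("untested positions:", paste(x$untested_positions, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Point-transition variant set
#'
#' One variant per requested position, carrying the transition mutation
#' (A<->G, C<->T) at that position. Positions holding an unnatural base are
#' skipped with a warning (transitions are defined for natural bases only);
#' positions inside a constant region are an error.
#'
#' @param sequence Aptamer sequence (Ds as `"X"`, Px as `"P"`).
#' @param positions 1-based positions to mutate.
#' @param constant Positions that must not be mutated (e.g. primer flanks).
#' @return `data.frame` with `variant_id` (e.g. `"A5G"`), `position`,
#'   `original_base`, `variant_base`, `sequence`, `variant_class`.
#' @examples
#' transition_variants("GCAT", c(2, 3))
#' @export
transition_variants <- function(sequence, positions, constant = integer(0)) {
  TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
  build_variants(sequence, positions, constant, "transition",
                 function(b) {
                   if (!b %in% names(TRANSITION)) return(NA_character_)
                   TRANSITION[[b]]
                 },
                 skip_msg = "unnatural base; transition undefined")
}

#' Single-position unnatural-base substitution variant set
#'
#' One variant per requested position, with the base replaced by the
#' unnatural base (Ds by default) -- the scanning design used to probe which
#' positions of a natural-base aptamer tolerate or exploit a hydrophobic
#' base.
#'
#' @inheritParams transition_variants
#' @param ub Unnatural base to substitute (`"Ds"` or `"Px"`).
#' @return As [transition_variants()]; `variant_id` like `"T10Ds"`.
#' @export
ub_substitution_variants <- function(sequence, positions, ub = "Ds",
                                     constant = integer(0)) {
  ub <- normalize_base(ub)
  build_variants(sequence, positions, constant, "ub_sub",
                 function(b) if (b == ub) NA_character_ else ub,
                 skip_msg = "already the substituted base")
}

build_variants <- function(sequence, positions, constant, variant_class,
                           substitute_fun, skip_msg) {
  positions <- as.integer(positions)
  n <- nchar(sequence)
  if (any(positions < 1 | positions > n)) {
    stop("position(s) out of range 1..", n, ": ",
         paste(positions[positions < 1 | positions > n], collapse = ", "))
  }
  in_const <- positions %in% as.integer(constant)
  if (any(in_const)) {
    stop("position(s) marked constant: ",
         paste(positions[in_const], collapse = ", "))
  }
  rows <- lapply(positions, function(p) {
    b <- substr(sequence, p, p)
    v <- substitute_fun(b)
    if (is.na(v)) {
      warning("position ", p, " (", display_base(b), ") skipped: ", skip_msg)
      return(NULL)
    }
    s <- sequence
    substr(s, p, p) <- v
    data.frame(variant_id = paste0(display_base(b), p, display_base(v)),
               position = p, original_base = b, variant_base = v,
               sequence = s, variant_class = variant_class,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(variant_id = character(), position = integer(),
                      original_base = character(), variant_base = character(),
                      sequence = character(), variant_class = character(),
                      stringsAsFactors = FALSE)
  }
  out
}
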