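# Synthetic EMSA data with known ground truth.
#
# The generator emulates the measurement process behind a band-density
# table: the original aptamer shifts a fraction f0 of its DNA into the
# complex band; a variant mutated at position p shifts clamp(e_p * f0, 0, 1),
# where e_p is the position's true binding effect (1 = indistinguishable
# from the original, < tau/100 = planted important). Densitometry noise is
# multiplicative log-normal on each band density (intensity-proportional
# noise), sdlog sigma, default 5%.

#' Ground truth for a synthetic EMSA table
#'
#' @param effects Named numeric vector: true per-position binding effect
#'   `e_p` (relative to the original, on the fraction scale), names are
#'   mutated positions.
#' @param f0 Shifted-band fraction of the original aptamer, in `(0, 1]`.
#' @param sigma Log-normal sdlog of the multiplicative density noise
#'   (0 = noiseless).
#' @param lanes_per_variant Replicate lanes per variant.
#' @param originals_per_gel Original-aptamer lanes on each gel.
#' @param lanes_per_gel Variant lanes per gel before a new gel is started.
#' @param mean_total_density Mean total (complex + free) density per lane,
#'   arbitrary densitometry units.
#' @return Object of class `emsa_ground_truth`.
#' @export
emsa_ground_truth <- function(effects, f0 = 0.6, sigma = 0.05,
                              lanes_per_variant = 2, originals_per_gel = 1,
                              lanes_per_gel = 16, mean_total_density = 1000) {
  if (f0 <= 0 || f0 > 1) stop("f0 must lie in (0, 1]")
  stopifnot(sigma >= 0, lanes_per_variant >= 1, originals_per_gel >= 1,
            all(effects >= 0))
  if (is.null(names(effects))) stop("effects must be named by position")
  structure(
    list(effects = effects, f0 = f0, sigma = sigma,
         lanes_per_variant = lanes_per_variant,
         originals_per_gel = originals_per_gel,
         lanes_per_gel = lanes_per_gel,
         mean_total_density = mean_total_density),
    class = "emsa_ground_truth")
}

#' Positions a caller should flag, given the truth
#'
#' @param truth An [emsa_ground_truth()].
#' @param tau Importance threshold in percent.
#' @return Integer positions with true relative binding below `tau`.
#' @export
planted_important <- function(truth, tau = 65) {
  eff_frac <- pmin(truth$effects * truth$f0, 1) / truth$f0
  sort(as.integer(names(truth$effects)[100 * eff_frac < tau]))
}

#' Generate a synthetic EMSA band-density table
#'
#' Lays variant lanes out on gels (each gel carrying its own original
#' lanes), draws a total density per lane, and splits it into complex and
#' free bands by the true shifted fraction; both band densities then receive
#' independent multiplicative log-normal noise. With `sigma = 0` the table
#' is exactly invertible: [relative_binding()] returns `100 * e_p` for every
#' variant.
#'
#' @param truth An [emsa_ground_truth()].
#' @param seed Integer seed.
#' @param variants Optional variant table (`variant_id`, `position`,
#'   `variant_class`) as produced by [transition_variants()]; defaults to
#'   one synthetic variant per entry of `truth$effects`.
#' @return An EMSA `data.frame` accepted by [relative_binding()].
#' @examples
#' truth <- emsa_ground_truth(effects = c("3" = 0.3, "5" = 1, "7" = 0.3),
#'                            sigma = 0)
#' calls <- call_important(relative_binding(generate_emsa_table(truth, seed = 1)))
#' calls$important_positions   # 3 and 7
#' @export
generate_emsa_table <- function(truth, seed, variants = NULL) {
  stopifnot(inherits(truth, "emsa_ground_truth"))
  set.seed(seed)
  if (is.null(variants)) {
    variants <- data.frame(
      variant_id = paste0("pos", names(truth$effects), "mut"),
      position = as.integer(names(truth$effects)),
      variant_class = "transition", stringsAsFactors = FALSE)
  }
  eff <- truth$effects[as.character(variants$position)]
  if (anyNA(eff)) stop("variants at positions without a declared effect: ",
                       paste(variants$position[is.na(eff)], collapse = ", "))

  lane <- data.frame(
    variant_id = rep(variants$variant_id, each = truth$lanes_per_variant),
    position = rep(variants$position, each = truth$lanes_per_variant),
    variant_class = rep(variants$variant_class,
                        each = truth$lanes_per_variant),
    frac = pmin(rep(unname(eff), each = truth$lanes_per_variant) * truth$f0, 1),
    is_original = FALSE, stringsAsFactors = FALSE)
  lane$gel_id <- paste0("gel", (seq_len(nrow(lane)) - 1) %/%
                          truth$lanes_per_gel + 1)

  orig <- do.call(rbind, lapply(unique(lane$gel_id), function(g) {
    data.frame(variant_id = "original", position = NA_integer_,
               variant_class = "original", frac = truth$f0,
               is_original = TRUE, gel_id = g,
               stringsAsFactors = FALSE)[rep(1, truth$originals_per_gel), ]
  }))
  lane <- rbind(orig, lane)

  total <- truth$mean_total_density *
    stats::rlnorm(nrow(lane), sdlog = truth$sigma)
  noise <- function() if (truth$sigma == 0) 1 else
    stats::rlnorm(nrow(lane), sdlog = truth$sigma)
  lane$complex_density <- total * lane$frac * noise()
  lane$free_density <- total * (1 - lane$frac) * noise()
  lane$frac <- NULL
  rownames(lane) <- NULL
  lane[, c("gel_id", "variant_id", "position", "variant_class",
           "complex_density", "free_density", "is_original")]
}

#' A synthetic Ds-predetermined sublibrary set
#'
#' Stand-in for a published pooled DP design whose exact Ds layout is not
#' printed: `n_sublibraries` two-Ds sublibraries over a 42-mer region,
#' enumerating Ds-Ds gaps (smallest first) and 5' start offsets on a fixed
#' grid. Purely synthetic; used to exercise [hit_sublibraries()] with hits
#' known by construction.
#'
#' @param n_sublibraries Number of sublibraries (default 74).
#' @param random_len Region length (default 42).
#' @param molecules Pooled complexity (default 6e15).
#' @param gaps Candidate Ds--Ds gaps, cycled smallest-first.
#' @param start_by Grid spacing of the 5' Ds start positions.
#' @return A [dp_library_set()].
#' @export
synthetic_dp_set <- function(n_sublibraries = 74, random_len = 42,
                             molecules = 6e15, gaps = 2:12, start_by = 5) {
  layouts <- list()
  for (g in gaps) {
    starts <- seq(2, random_len - g - 1, by = start_by)
    for (s in starts) layouts[[length(layouts) + 1]] <- c(s, s + g)
  }
  if (length(layouts) < n_sublibraries) {
    stop("grid yields only ", length(layouts), " layouts")
  }
  subs <- lapply(layouts[seq_len(n_sublibraries)],
                 function(p) dp_sublibrary(random_len, p))
  dp_library_set(subs, molecules)
}
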