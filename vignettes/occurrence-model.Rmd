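---
title: "Candidate occurrence in unnatural-base SELEX libraries: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate occurrence in unnatural-base SELEX libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubselex)
```

## The model

A SELEX experiment can only isolate an aptamer whose sequence (or an
equivalent one) was present in the starting pool. `ubselex` quantifies that
premise. An aptamer *candidate class* is described by a motif: essential
base positions whose identity is fixed (natural bases, or the unnatural
hydrophobic base Ds), stem base pairs for which any complementary pairing is
acceptable, and wildcards. The **required number**

$$R = A^{\,n_\text{essential} + n_\text{stem bp}}$$

is the sequence-space size within which one candidate is expected; each
fully constrained position contributes a factor $A$ (the alphabet size, 4 or
5) and each stem bp one factor $A$ as well, because the second strand of the
pair is determined by the first. The **occurrence**

$$O = M \cdot W \cdot \frac{h}{S} \cdot \frac{1}{R}$$

is the expected number of candidate molecules in a pool of $M$ molecules
(`molecules`, the *physical complexity* — distinct from the combinatorial
space size, which the package keeps as an exact big integer because $4^{40}$
already exceeds the exact range of doubles). $W$ is the number of sliding
placements of the essential core; $h/S$ is the fraction of Ds-predetermined
(DP) sublibraries whose fixed Ds layout is compatible with the motif. $O$ is
an expectation, not a probability; results also carry
$P(\ge 1\text{ candidate}) = 1 - e^{-O}$, a Poisson convenience field added
by this package.

Per library design:

* **Natural randomized** (e.g. N30): $A = 4$, $W = L - \text{core span} + 1$,
  $h = S = 1$.
* **DP library**: $A = 4$ and the essential Ds positions are *excluded* from
  the exponent — within a compatible sublibrary they are certain, and their
  constraint enters through $h/S$ instead. A sublibrary is compatible when
  its Ds spacing equals the motif's at an offset that keeps the essential
  core inside the randomized region; a motif needing at most one Ds is
  compatible with every sublibrary carrying at least that many.
* **DR (doped) library**: $A = 5$ with Ds counted in the exponent; the
  terminal stem is embedded in the library as a constant sequence, so the
  motif is anchored ($W = 1$).

## Power mode, strict mode, and the as-printed convention

The power-of-alphabet form is a convention, not an exact probability. In
`mode = "strict"` the package instead inverts the exact per-placement match
probability: each essential position contributes its letter frequency
(0.225 per natural base and 0.10 for Ds in the standard doped design) and
each stem bp the summed probability of the allowed complementary pairs. For
four-letter libraries the two coincide exactly (4 Watson–Crick pairs / 16
combinations = 1/4). For five-letter libraries they do not: the per-bp pair
probability is $4 \times 0.225^2 = 0.2025$ against the convention's $1/5$,
and a Ds–Px stem pair is excluded by default (`allow_ds_px_stem`) because it
cannot form in a Px-free library. Both readings are computed side by side in
DR results so the size of the approximation is always visible. The published
DR occurrence figure for the anti-vWF aptamer was derived by a further
method whose details are not available alongside the headline values; the
two modes bracket the plausible readings and neither is asserted to
reproduce that figure.

Every `occurrence_result` reports two numbers: `occurrence`, the exact
expectation, and `occurrence_printed`, the same quotient with $R$ first
rounded to two significant figures. Required numbers are conventionally
quoted at that precision (e.g. $4^{22} = 1.7592\times10^{13}$ quoted as
$1.8\times10^{13}$), and downstream occurrence figures in this literature
are computed from the quoted values; carrying both makes such figures
reproducible digit-for-digit while keeping the exact value primary.

```{r}
panel <- ds_aptamer_panel()
res <- occurrence_dp(panel$anti_DEN4_NS1$motif, synthetic_dp_set(), hits = 2)
c(exact = res$occurrence, as_printed = res$occurrence_printed)
```

## The sliding-placement multiplier is an approximation

$W$ multiplies the single-placement probability, which over-counts
sequences matching at several overlapping offsets. The package's oracle
therefore counts *inclusion at one or more offsets* and never uses
$W \times p$: on toy spaces the exhaustive union count is strictly below the
$W p$ product but above its Bonferroni lower bound, and the tests pin both.
For realistic motifs (19 essential bases) the overlap term is of order
$p^2 \approx 10^{-28}$ and entirely negligible; the worked N30 example keeps
the multiplicative convention.

## Validation strategy

Two independent routes to every analytic quantity:

* **Exhaustive enumeration** over toy spaces (guarded at $4^{10}$
  sequences), implemented against base-$A$ digit vectors rather than the
  counting exponents, with probability weighting for non-uniform (doped)
  letter frequencies. Agreement with strict-mode occurrence is exact for
  four-letter toys (all quantities are dyadic rationals) and to $10^{-12}$
  for doped toys (0.225 is not exactly representable).
* **Seeded Monte Carlo sampling** at library scale (Mersenne–Twister,
  seeds recorded in the sample objects). The doped design's Ds-count
  composition is binomial — $P(k \text{ Ds}) = \binom{30}{k} 0.1^k 0.9^{30-k}$,
  so 22.8% of molecules carry exactly two Ds — and the sampled fraction is
  required to sit within three standard errors at $n = 10^5$ draws.

Problem sizes were chosen so the full suite runs in seconds: toys of length
4–6 (spaces up to $5^6$), 40–60 random motifs per property loop, $10^5$
sampled sequences for composition checks.

## EMSA quantification and important-base calling

Band densities arrive already quantified (one row per lane: complexed and
free DNA); image densitometry is out of scope. Per lane the shifted fraction
is $c/(c+f)$; per gel every lane is normalized to the original aptamer on
the same gel (mean, if several original lanes), giving relative binding in
percent — unclipped, since a variant may out-bind the original. Positions
whose variants average below $\tau = 65\%$ are called important. Choices
made where the procedure is under-specified:

* *Mean vs median*: replicate aggregation uses the mean (the published rule
  says "average"); the median is available via `stat = "median"`.
* Variant classes (transition mutations vs Ds substitutions) are called
  separately by filtering the table, since the two scans answer different
  questions about the same positions.
* A position with no variants is listed as *untested*, never silently
  treated as unimportant.

The synthetic generator emulates exactly this measurement process: a true
original shifted fraction $f_0$, per-position effects $e_p$ (variant
fraction $\min(e_p f_0, 1)$), and multiplicative log-normal noise on each
band density — densitometry noise scales with intensity, hence
multiplicative; the default $\sigma = 5\%$ reflects typical gel-to-gel
variability. With $\sigma = 0$ the pipeline inverts the table exactly
($100\,e_p$ per variant), which the tests assert with zero tolerance. What
the generator does **not** emulate: gel-position artefacts, saturated bands,
correlated lane-loading errors, or any relationship between binding and
sequence — so recovery results validate the quantification arithmetic, not
EMSA as an assay.

```{r}
truth <- emsa_ground_truth(effects = c("3" = 0.3, "5" = 1, "7" = 0.3),
                           sigma = 0)
calls <- call_important(relative_binding(generate_emsa_table(truth, seed = 1)))
calls$important_positions
```

## Motifs, coordinates and degenerate inputs

Positions are 1-based everywhere, matching how aptamer positions are
reported ("position 29"). Stem pairings in text configs must be declared at
both partner positions; an asymmetric declaration is rejected naming the
offending position. A motif whose essential core exceeds the randomized
region has zero placements (warning, not error); an empty essential set
gives a core span of zero and a required number of one; a motif requiring
Ds cannot occur in a natural library and says so. Internal and terminal stem
base pairs are treated identically in the exponent, as the published
exponents do.

The case-study panel (`ds_aptamer_panel()`) stores only published *inputs*
(motif counts, complexities, hit counts); every derived number is computed
at call time. Where a published input is unavailable — the exact Ds layouts
of the pooled DP sublibraries are published elsewhere — the hit/sublibrary
counts are carried as inputs and a clearly-labelled synthetic sublibrary set
(`synthetic_dp_set()`) exercises the layout-matching machinery instead. The
anti-DEN3-NS1 entry treats all loop bases as important (the tentative
reading forced by its single isolated clone) as an ordinary motif, not a
special case.

## Known limitations

* Selection dynamics (round-to-round enrichment, washing stringency, PCR
  mutation and amplification bias against high Ds counts) are outside the
  model; occurrence describes the starting pool only.
* The placement multiplier ignores overlapping-match correlations
  (negligible for realistic motifs, quantified on toys).
* Required numbers assume independence across positions; real aptamer
  function may tolerate alternative sequence contexts, which is precisely
  why occurrence values below one do not preclude a successful selection.
* FASTA export writes Ds as `X` and Px as `P` with a legend in each record
  description; these symbols are a package convention, not a community
  standard.
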