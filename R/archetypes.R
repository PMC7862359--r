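# Generative archetypes for the 17 herd types. Nominal values are
# calibration constants of the generator, chosen once to sit centrally
# inside each type's leaf region of the default classification tree; the
# five printed thresholds (0.25 breeding, 0.70/0.30 dairy/beef, 0.5
# slaughter, 30-day trading window) are the only externally fixed numbers.

#' The 17 herd types and their six main groups
#'
#' @return Tibble with columns `herd_type` and `main_group`
#'   (dairy, beef, mixed, store/rearing, fattening, trading).
#' @export
herd_types <- function() {
  tibble::tribble(
    ~herd_type, ~main_group,
    "D",      "dairy",
    "DnR-C",  "dairy",
    "DnR-nC", "dairy",
    "DRm",    "dairy",
    "BP",     "beef",
    "BSW",    "beef",
    "BSY",    "beef",
    "BSY-nR", "beef",
    "BSB",    "beef",
    "M",      "mixed",
    "Sdm",    "store/rearing",
    "Sbm",    "store/rearing",
    "Sbf",    "store/rearing",
    "Sbmx",   "store/rearing",
    "Rdf",    "store/rearing",
    "F",      "fattening",
    "T",      "trading"
  )
}

#' Construct an archetype specification
#'
#' An `archetype_spec` holds the generative parameters for one herd type:
#' herd-size range, breed composition, calving level, age structure
#' (calf/yearling/adult fractions at the May snapshot), per-age-class male
#' fractions, and yearly movement intensities with their destination mix.
#' `female_fraction` is derived from the age/sex profile so the stored
#' nominal equals the generative nominal exactly.
#'
#' @param herd_type One of the 17 labels in [herd_types()].
#' @param herd_size_range Integer interval for the resident (core) herd size.
#' @param dairy_fraction,cross_fraction Breed-type composition (remainder is
#'   pure beef); must sum to at most 1.
#' @param calved_fraction Target proportion of ever-calved animals.
#' @param calf_fraction,yearling_fraction Age-class fractions at 1 May
#'   (adults are the remainder; calves < 1 y, yearlings 1 to < 2 y).
#' @param male_1to2_fraction Male fraction among yearlings (this *is* the
#'   nominal `pMalesBetween1and2Years`).
#' @param calf_male_fraction,adult_male_fraction Male fractions in the other
#'   two age classes.
#' @param out_rate,in_rate Yearly out-/in-moves per core animal.
#' @param slaughter_out_fraction,birth_herd_out_fraction,short_stay_fraction
#'   Fractions of planned out-moves that go to slaughter, return an animal
#'   to its birth herd, or close a < 30-day trading stay.
#' @param birth_herd_in_fraction Fraction of planned in-moves that return an
#'   animal to this (its birth) herd, emulating contract-reared heifers.
#' @return Object of class `archetype_spec` (a named list).
#' @export
archetype_spec <- function(herd_type, herd_size_range,
                           dairy_fraction, cross_fraction, calved_fraction,
                           calf_fraction, yearling_fraction,
                           male_1to2_fraction, calf_male_fraction,
                           adult_male_fraction,
                           out_rate, in_rate,
                           slaughter_out_fraction = 0,
                           birth_herd_out_fraction = 0,
                           birth_herd_in_fraction = 0,
                           short_stay_fraction = 0) {
  herd_size_range <- as.integer(herd_size_range)
  stopifnot(
    length(herd_size_range) == 2, all(herd_size_range > 0),
    herd_size_range[1] <= herd_size_range[2],
    dairy_fraction + cross_fraction <= 1,
    calf_fraction + yearling_fraction <= 1
  )
  adult_fraction <- 1 - calf_fraction - yearling_fraction
  props <- c(dairy_fraction, cross_fraction, calved_fraction, calf_fraction,
             yearling_fraction, male_1to2_fraction, calf_male_fraction,
             adult_male_fraction, slaughter_out_fraction,
             birth_herd_out_fraction, birth_herd_in_fraction,
             short_stay_fraction)
  stopifnot(all(props >= 0 & props <= 1), out_rate >= 0, in_rate >= 0)
  female_fraction <- 1 - (calf_fraction * calf_male_fraction +
                            yearling_fraction * male_1to2_fraction +
                            adult_fraction * adult_male_fraction)
  structure(
    list(
      herd_type = herd_type, herd_size_range = herd_size_range,
      female_fraction = female_fraction,
      dairy_fraction = dairy_fraction, cross_fraction = cross_fraction,
      calved_fraction = calved_fraction,
      calf_fraction = calf_fraction, yearling_fraction = yearling_fraction,
      adult_fraction = adult_fraction,
      male_1to2_fraction = male_1to2_fraction,
      calf_male_fraction = calf_male_fraction,
      adult_male_fraction = adult_male_fraction,
      out_rate = out_rate, in_rate = in_rate,
      slaughter_out_fraction = slaughter_out_fraction,
      birth_herd_out_fraction = birth_herd_out_fraction,
      birth_herd_in_fraction = birth_herd_in_fraction,
      short_stay_fraction = short_stay_fraction
    ),
    class = "archetype_spec"
  )
}

#' Default archetypes for the 17 herd types
#'
#' One generative specification per herd type, expressing each type's
#' management signature: e.g. DRm dairy herds rear their male calves (high
#' male yearling share), BSB herds send most out-moves to slaughter, Rdf
#' contract rearers return most out-moves to the animals' birth herds, and
#' trading herds turn most animals around within 30 days.
#'
#' @param overrides Optional named list of `archetype_spec` objects
#'   replacing individual defaults.
#' @return Named list of 17 [archetype_spec()] objects.
#' @export
default_archetypes <- function(overrides = NULL) {
  sp <- archetype_spec
  a <- list(
    # --- dairy group -------------------------------------------------------
    "D" = sp("D", c(40, 120), dairy_fraction = 0.90, cross_fraction = 0.05,
             calved_fraction = 0.45, calf_fraction = 0.25,
             yearling_fraction = 0.20, male_1to2_fraction = 0.05,
             calf_male_fraction = 0.32, adult_male_fraction = 0.02,
             out_rate = 0.5, in_rate = 0.05, slaughter_out_fraction = 0.05),
    "DnR-C" = sp("DnR-C", c(40, 100), dairy_fraction = 0.90,
                 cross_fraction = 0.05, calved_fraction = 0.80,
                 calf_fraction = 0.05, yearling_fraction = 0.05,
                 male_1to2_fraction = 0.05, calf_male_fraction = 0.41,
                 adult_male_fraction = 0.03,
                 out_rate = 0.5, in_rate = 0.35,
                 slaughter_out_fraction = 0.05,
                 birth_herd_in_fraction = 0.85),
    "DnR-nC" = sp("DnR-nC", c(40, 100), dairy_fraction = 0.90,
                  cross_fraction = 0.05, calved_fraction = 0.80,
                  calf_fraction = 0.05, yearling_fraction = 0.05,
                  male_1to2_fraction = 0.05, calf_male_fraction = 0.41,
                  adult_male_fraction = 0.03,
                  out_rate = 0.5, in_rate = 0.35,
                  slaughter_out_fraction = 0.05,
                  birth_herd_in_fraction = 0.02),
    "DRm" = sp("DRm", c(40, 100), dairy_fraction = 0.85,
               cross_fraction = 0.08, calved_fraction = 0.40,
               calf_fraction = 0.20, yearling_fraction = 0.30,
               male_1to2_fraction = 0.80, calf_male_fraction = 0.42,
               adult_male_fraction = 0.05,
               out_rate = 0.5, in_rate = 0.05,
               slaughter_out_fraction = 0.05),
    # --- beef group --------------------------------------------------------
    "BP" = sp("BP", c(40, 100), dairy_fraction = 0.02, cross_fraction = 0.03,
              calved_fraction = 0.45, calf_fraction = 0.25,
              yearling_fraction = 0.20, male_1to2_fraction = 0.30,
              calf_male_fraction = 0.55, adult_male_fraction = 0.08,
              out_rate = 0.4, in_rate = 0.05, slaughter_out_fraction = 0.10),
    "BSW" = sp("BSW", c(40, 120), dairy_fraction = 0.03,
               cross_fraction = 0.35, calved_fraction = 0.45,
               calf_fraction = 0.25, yearling_fraction = 0.20,
               male_1to2_fraction = 0.03, calf_male_fraction = 0.55,
               adult_male_fraction = 0.08,
               out_rate = 0.4, in_rate = 0.05, slaughter_out_fraction = 0.10),
    "BSY" = sp("BSY", c(40, 120), dairy_fraction = 0.03,
               cross_fraction = 0.35, calved_fraction = 0.40,
               calf_fraction = 0.25, yearling_fraction = 0.30,
               male_1to2_fraction = 0.50, calf_male_fraction = 0.50,
               adult_male_fraction = 0.10,
               out_rate = 0.4, in_rate = 0.05, slaughter_out_fraction = 0.10),
    "BSY-nR" = sp("BSY-nR", c(40, 120), dairy_fraction = 0.03,
                  cross_fraction = 0.35, calved_fraction = 0.40,
                  calf_fraction = 0.15, yearling_fraction = 0.40,
                  male_1to2_fraction = 0.90, calf_male_fraction = 0.50,
                  adult_male_fraction = 0.05,
                  out_rate = 0.4, in_rate = 0.10,
                  slaughter_out_fraction = 0.10),
    "BSB" = sp("BSB", c(40, 120), dairy_fraction = 0.03,
               cross_fraction = 0.35, calved_fraction = 0.40,
               calf_fraction = 0.25, yearling_fraction = 0.30,
               male_1to2_fraction = 0.50, calf_male_fraction = 0.50,
               adult_male_fraction = 0.08,
               out_rate = 0.6, in_rate = 0.05, slaughter_out_fraction = 0.80),
    # --- mixed -------------------------------------------------------------
    "M" = sp("M", c(40, 120), dairy_fraction = 0.50, cross_fraction = 0.45,
             calved_fraction = 0.45, calf_fraction = 0.25,
             yearling_fraction = 0.20, male_1to2_fraction = 0.30,
             calf_male_fraction = 0.40, adult_male_fraction = 0.05,
             out_rate = 0.5, in_rate = 0.05, slaughter_out_fraction = 0.10),
    # --- store / rearing ---------------------------------------------------
    "Sdm" = sp("Sdm", c(30, 80), dairy_fraction = 0.85, cross_fraction = 0.10,
               calved_fraction = 0, calf_fraction = 0.30,
               yearling_fraction = 0.60, male_1to2_fraction = 0.95,
               calf_male_fraction = 0.95, adult_male_fraction = 0.95,
               out_rate = 0.7, in_rate = 0.7, slaughter_out_fraction = 0.05),
    "Sbm" = sp("Sbm", c(30, 80), dairy_fraction = 0.03, cross_fraction = 0.30,
               calved_fraction = 0, calf_fraction = 0.20,
               yearling_fraction = 0.60, male_1to2_fraction = 0.95,
               calf_male_fraction = 0.95, adult_male_fraction = 0.95,
               out_rate = 0.7, in_rate = 0.7, slaughter_out_fraction = 0.05),
    "Sbf" = sp("Sbf", c(30, 80), dairy_fraction = 0.03, cross_fraction = 0.30,
               calved_fraction = 0, calf_fraction = 0.20,
               yearling_fraction = 0.60, male_1to2_fraction = 0.05,
               calf_male_fraction = 0.05, adult_male_fraction = 0.05,
               out_rate = 0.7, in_rate = 0.7, slaughter_out_fraction = 0.05),
    "Sbmx" = sp("Sbmx", c(30, 80), dairy_fraction = 0.03,
                cross_fraction = 0.30, calved_fraction = 0,
                calf_fraction = 0.20, yearling_fraction = 0.60,
                male_1to2_fraction = 0.50, calf_male_fraction = 0.50,
                adult_male_fraction = 0.50,
                out_rate = 0.7, in_rate = 0.7, slaughter_out_fraction = 0.05),
    "Rdf" = sp("Rdf", c(30, 80), dairy_fraction = 0.90, cross_fraction = 0.05,
               calved_fraction = 0, calf_fraction = 0.40,
               yearling_fraction = 0.55, male_1to2_fraction = 0.02,
               calf_male_fraction = 0.02, adult_male_fraction = 0.02,
               out_rate = 0.6, in_rate = 0.6, slaughter_out_fraction = 0.02,
               birth_herd_out_fraction = 0.75),
    # --- fattening / trading ----------------------------------------------
    "F" = sp("F", c(40, 100), dairy_fraction = 0.25, cross_fraction = 0.35,
             calved_fraction = 0, calf_fraction = 0.10,
             yearling_fraction = 0.50, male_1to2_fraction = 0.70,
             calf_male_fraction = 0.70, adult_male_fraction = 0.70,
             out_rate = 1.0, in_rate = 1.0, slaughter_out_fraction = 0.80),
    "T" = sp("T", c(30, 60), dairy_fraction = 0.30, cross_fraction = 0.30,
             calved_fraction = 0, calf_fraction = 0.20,
             yearling_fraction = 0.50, male_1to2_fraction = 0.50,
             calf_male_fraction = 0.50, adult_male_fraction = 0.50,
             out_rate = 2.0, in_rate = 2.0, slaughter_out_fraction = 0.03,
             short_stay_fraction = 0.75)
  )
  if (!is.null(overrides)) {
    stopifnot(all(names(overrides) %in% names(a)))
    a[names(overrides)] <- overrides
  }
  a
}

#' Nominal feature vector implied by an archetype
#'
#' Maps an archetype's generative parameters to the expected values of the
#' nine classification variables (large-herd limit), accounting for the
#' movement bookkeeping: contract-reared animals inflate snapshot sizes and
#' out-move counts, return in-moves inflate out-move counts.
#'
#' @param spec An [archetype_spec()].
#' @return Named numeric vector over [feature_variables()].
#' @export
expected_features <- function(spec) {
  s <- spec
  k_bo <- s$birth_herd_out_fraction * s$out_rate     # contract stays, per core animal
  k_bi <- s$birth_herd_in_fraction * s$in_rate       # returning heifers, per core animal
  out_total <- s$out_rate + k_bi                     # early moves of returnees add outs
  c(
    pFemaleAnimals = s$female_fraction,
    pDairyBreed = s$dairy_fraction,
    pCrossBreed = s$cross_fraction,
    pCalvedAnimals = s$calved_fraction / (1 + k_bo),
    pMalesBetween1and2Years = s$male_1to2_fraction,
    pAnimalsLess30Days = s$short_stay_fraction * s$out_rate / out_total,
    pOutMovesToSL = s$slaughter_out_fraction * s$out_rate / (1 + k_bo),
    pOutMovesToBirthHerd = k_bo / out_total,
    pInMovesToBirthHerd = s$birth_herd_in_fraction
  )
}
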