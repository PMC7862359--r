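# Synthetic register generator: turns archetype specs into labelled animal
# and movement tables with the within-year movement chains the nine
# classification variables are computed from.

# Evaluate `code` under a local RNG state, restoring the caller's stream.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

day_to_date <- function(day, year) as.Date(sprintf("%d-01-01", year)) + (day - 1)

# Draw demographic attributes for `k` animals from a spec's composition.
draw_demographics <- function(spec, k, may_date) {
  age_class <- sample(c("calf", "yearling", "adult"), k, replace = TRUE,
                      prob = c(spec$calf_fraction, spec$yearling_fraction,
                               spec$adult_fraction))
  p_male <- c(calf = spec$calf_male_fraction,
              yearling = spec$male_1to2_fraction,
              adult = spec$adult_male_fraction)[age_class]
  sex <- ifelse(rbinom(k, 1, p_male) == 1, "male", "female")
  age_days <- integer(k)
  age_days[age_class == "calf"] <- sample(30:364, sum(age_class == "calf"),
                                          replace = TRUE)
  age_days[age_class == "yearling"] <- sample(365:729,
                                              sum(age_class == "yearling"),
                                              replace = TRUE)
  age_days[age_class == "adult"] <- sample(730:3650,
                                           sum(age_class == "adult"),
                                           replace = TRUE)
  beef_frac <- 1 - spec$dairy_fraction - spec$cross_fraction
  btype <- sample(c("dairy", "cross", "beef"), k, replace = TRUE,
                  prob = c(spec$dairy_fraction, spec$cross_fraction,
                           beef_frac))
  dam <- character(k); sire <- character(k)
  nd <- sum(btype == "dairy")
  dam[btype == "dairy"] <- sample(DAIRY_BREEDS, nd, replace = TRUE)
  sire[btype == "dairy"] <- sample(DAIRY_BREEDS, nd, replace = TRUE)
  nb <- sum(btype == "beef")
  dam[btype == "beef"] <- sample(BEEF_BREEDS, nb, replace = TRUE)
  sire[btype == "beef"] <- sample(BEEF_BREEDS, nb, replace = TRUE)
  cx <- which(btype == "cross")
  if (length(cx) > 0) {
    dam_dairy <- rbinom(length(cx), 1, 0.5) == 1
    dam[cx] <- ifelse(dam_dairy, sample(DAIRY_BREEDS, length(cx), TRUE),
                      sample(BEEF_BREEDS, length(cx), TRUE))
    sire[cx] <- ifelse(dam_dairy, sample(BEEF_BREEDS, length(cx), TRUE),
                       sample(DAIRY_BREEDS, length(cx), TRUE))
  }
  tibble::tibble(
    sex = sex, age_class = age_class,
    birth_date = may_date - age_days,
    breed = dam, dam_breed = dam, sire_breed = sire
  )
}

#' Generate one synthetic herd
#'
#' Draws a resident (core) herd whose composition matches the archetype in
#' expectation, then layers the movement machinery on top: slaughter and
#' sale exits late in the year, short trading stays, contract-reared
#' animals that arrive from and return to their birth herds, returning
#' heifers with a paired early out-move and late return in-move, and
#' late-year purchases. Counterpart herds (birth herds, trading partners,
#' purchase sources) are emitted as ids only.
#'
#' @param spec An [archetype_spec()].
#' @param herd_id Identifier for the generated herd.
#' @param seed Integer seed; the same seed reproduces the herd exactly.
#' @param study_year Study year (movement window).
#' @return List with tibbles `animals` and `movements` (register schema)
#'   and the character vector `counterparts` of counterpart herd ids used.
#' @export
generate_herd <- function(spec, herd_id, seed, study_year = 2017L) {
  stopifnot(inherits(spec, "archetype_spec"))
  with_local_seed(seed, {
    may <- as.Date(sprintf("%d-05-01", study_year))
    n <- sample(seq(spec$herd_size_range[1], spec$herd_size_range[2]), 1)

    out_total <- round(spec$out_rate * n)
    k_ss <- round(spec$short_stay_fraction * out_total)
    k_bo <- round(spec$birth_herd_out_fraction * out_total)
    k_sl <- round(spec$slaughter_out_fraction * out_total)
    k_oo <- max(0L, out_total - k_ss - k_bo - k_sl)
    in_total <- round(spec$in_rate * n)
    k_bi <- round(spec$birth_herd_in_fraction * in_total)
    k_purch <- max(0L, in_total - k_bi - k_ss - k_bo)

    cp <- function(tag) paste0(herd_id, "_", tag)
    used_cp <- character(0)
    aid <- 0L
    next_ids <- function(k) {
      ids <- sprintf("%s_A%04d", herd_id, aid + seq_len(k))
      aid <<- aid + k
      ids
    }
    animals <- list()
    movements <- list()

    # core residents, born in the herd
    core <- draw_demographics(spec, n, may)
    calved <- rep(FALSE, n)
    adult_female <- core$age_class == "adult" & core$sex == "female"
    p_af <- spec$adult_fraction * (1 - spec$adult_male_fraction)
    q <- if (p_af > 0) min(1, spec$calved_fraction / p_af) else 0
    calved[adult_female] <- rbinom(sum(adult_female), 1, q) == 1
    core_ids <- next_ids(n)
    core_exit <- rep(as.Date(NA), n)

    # late-year exits from the core: slaughter first, then sales
    n_exit <- min(n, k_sl + k_oo)
    exiters <- sample.int(n, n_exit)
    exit_day <- sample(250:340, n_exit, replace = TRUE)
    core_exit[exiters] <- day_to_date(exit_day, study_year)
    sl_idx <- head(seq_len(n_exit), min(k_sl, n_exit))
    if (n_exit > 0) {
      dest_sale <- cp("OUT"); used_cp <- c(used_cp, dest_sale)
      is_sl <- seq_len(n_exit) %in% sl_idx
      movements[[length(movements) + 1]] <- tibble::tibble(
        animal_id = core_ids[exiters],
        date = core_exit[exiters],
        source_herd = herd_id,
        destination_id = ifelse(is_sl, TERMINAL_CODES[["slaughter"]], dest_sale),
        destination_kind = ifelse(is_sl, "slaughter", "herd")
      )
    }
    animals[[1]] <- dplyr::mutate(
      core,
      animal_id = core_ids, herd_id = herd_id,
      has_calved_by_sep1 = calved,
      herd_entry_date = .data$birth_date, herd_exit_date = core_exit
    )

    # short trading stays: in-move from one partner, out-move to another
    if (k_ss > 0) {
      src <- cp("M1"); dst <- cp("M2"); used_cp <- c(used_cp, src, dst)
      d <- draw_demographics(spec, k_ss, may)
      e_day <- sample(10:320, k_ss, replace = TRUE)
      x_day <- e_day + sample(5:25, k_ss, replace = TRUE)
      ids <- next_ids(k_ss)
      entry <- day_to_date(e_day, study_year)
      animals[[length(animals) + 1]] <- dplyr::mutate(
        d, birth_date = pmin(.data$birth_date, entry - 1),
        animal_id = ids, herd_id = herd_id, has_calved_by_sep1 = FALSE,
        herd_entry_date = entry,
        herd_exit_date = day_to_date(x_day, study_year)
      )
      movements[[length(movements) + 1]] <- tibble::tibble(
        animal_id = rep(ids, 2),
        date = day_to_date(c(e_day, x_day), study_year),
        source_herd = c(rep(src, k_ss), rep(herd_id, k_ss)),
        destination_id = c(rep(herd_id, k_ss), rep(dst, k_ss)),
        destination_kind = "herd"
      )
    }

    # contract-reared animals: arrive from and return to their birth herd
    if (k_bo > 0) {
      bhp <- cp("BH"); used_cp <- c(used_cp, bhp)
      d <- draw_demographics(spec, k_bo, may)
      e_day <- sample(30:80, k_bo, replace = TRUE)
      x_day <- sample(250:330, k_bo, replace = TRUE)
      ids <- next_ids(k_bo)
      entry <- day_to_date(e_day, study_year)
      animals[[length(animals) + 1]] <- dplyr::mutate(
        d, birth_date = pmin(.data$birth_date, entry - 1),
        animal_id = ids, herd_id = herd_id, has_calved_by_sep1 = FALSE,
        herd_entry_date = entry,
        herd_exit_date = day_to_date(x_day, study_year)
      )
      movements[[length(movements) + 1]] <- tibble::tibble(
        animal_id = rep(ids, 2),
        date = day_to_date(c(e_day, x_day), study_year),
        source_herd = c(rep(bhp, k_bo), rep(herd_id, k_bo)),
        destination_id = c(rep(herd_id, k_bo), rep(bhp, k_bo)),
        destination_kind = "herd"
      )
    }

    # returning heifers: early out-move to the rearer, late return in-move
    if (k_bi > 0) {
      rear <- cp("CR"); used_cp <- c(used_cp, rear)
      e_day <- sample(5:20, k_bi, replace = TRUE)
      r_day <- sample(250:300, k_bi, replace = TRUE)
      ids <- next_ids(k_bi)
      d <- draw_demographics(spec, k_bi, may)
      d$sex <- "female"
      d$birth_date <- may - sample(750:900, k_bi, replace = TRUE)
      animals[[length(animals) + 1]] <- dplyr::mutate(
        d, animal_id = ids, herd_id = herd_id, has_calved_by_sep1 = FALSE,
        herd_entry_date = day_to_date(r_day, study_year),
        herd_exit_date = as.Date(NA)
      )
      movements[[length(movements) + 1]] <- tibble::tibble(
        animal_id = rep(ids, 2),
        date = day_to_date(c(e_day, r_day), study_year),
        source_herd = c(rep(herd_id, k_bi), rep(rear, k_bi)),
        destination_id = c(rep(rear, k_bi), rep(herd_id, k_bi)),
        destination_kind = "herd"
      )
    }

    # late-year purchases
    if (k_purch > 0) {
      src <- cp("SRC"); used_cp <- c(used_cp, src)
      d <- draw_demographics(spec, k_purch, may)
      e_day <- sample(280:350, k_purch, replace = TRUE)
      ids <- next_ids(k_purch)
      entry <- day_to_date(e_day, study_year)
      animals[[length(animals) + 1]] <- dplyr::mutate(
        d, birth_date = pmin(.data$birth_date, entry - 1),
        animal_id = ids, herd_id = herd_id, has_calved_by_sep1 = FALSE,
        herd_entry_date = entry,
        herd_exit_date = as.Date(NA)
      )
      movements[[length(movements) + 1]] <- tibble::tibble(
        animal_id = ids,
        date = day_to_date(e_day, study_year),
        source_herd = src, destination_id = herd_id,
        destination_kind = "herd"
      )
    }

    animals <- dplyr::bind_rows(animals)[, ANIMAL_COLS]
    movements <- if (length(movements) > 0) {
      dplyr::arrange(dplyr::bind_rows(movements), .data$date, .data$animal_id)
    } else {
      tibble::tibble(animal_id = character(), date = as.Date(character()),
                     source_herd = character(), destination_id = character(),
                     destination_kind = character())
    }
    list(animals = animals, movements = movements,
         counterparts = unique(used_cp))
  })
}

#' Generate a labelled synthetic register
#'
#' Generates `herds_per_type` herds for each of the 17 archetypes (plus the
#' counterpart herds their movements reference) and assembles a validated
#' [herd_registry()]. Byte-identical output under a fixed seed.
#'
#' @param herds_per_type Number of primary herds per herd type.
#' @param seed Integer seed.
#' @param study_year Study year.
#' @param archetypes Named list of [archetype_spec()]s; defaults to
#'   [default_archetypes()].
#' @return List with elements `registry` (a `herd_registry`) and `truth`
#'   (tibble `herd_id`, `herd_type`, `role` = `"primary"`/`"counterpart"`).
#' @export
generate_registry <- function(herds_per_type = 20L, seed = 1L,
                              study_year = 2017L, archetypes = NULL) {
  if (is.null(archetypes)) archetypes <- default_archetypes()
  types <- names(archetypes)
  plan <- tidyr::expand_grid(herd_type = types, rep = seq_len(herds_per_type))
  sub_seeds <- with_local_seed(seed,
                               sample.int(.Machine$integer.max - 1L, nrow(plan)))
  herds <- lapply(seq_len(nrow(plan)), function(i) {
    ht <- plan$herd_type[i]
    hid <- sprintf("%s_%03d", gsub("[^A-Za-z]", "", ht), plan$rep[i])
    # disambiguate types sharing letters after sanitization
    hid <- sprintf("H%02d_%s", match(ht, types), hid)
    generate_herd(archetypes[[ht]], hid, seed = sub_seeds[i],
                  study_year = study_year)
  })
  animals <- dplyr::bind_rows(lapply(herds, `[[`, "animals"))
  movements <- dplyr::bind_rows(lapply(herds, `[[`, "movements"))
  primary <- tibble::tibble(
    herd_id = vapply(herds, function(h) h$animals$herd_id[1], character(1)),
    herd_type = plan$herd_type,
    role = "primary"
  )
  cps <- unique(unlist(lapply(herds, `[[`, "counterparts")))
  truth <- dplyr::bind_rows(
    primary,
    tibble::tibble(herd_id = cps, herd_type = "counterpart",
                   role = "counterpart")
  )
  registry <- herd_registry(animals, movements, study_year = study_year,
                            check = TRUE)
  list(registry = registry, truth = truth)
}
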