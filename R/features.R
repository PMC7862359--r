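# Herd-level aggregation: snapshot counts, the nine classification
# variables, and the initial ICBF-style breeding/dairy/beef/mixed split.

#' Herd members at a snapshot date
#'
#' Applies the half-open membership convention: an animal belongs to the
#' herd on `date` iff it entered on or before `date` and has not exited on
#' or before `date` (open exit = still present). An animal entering on the
#' snapshot date itself is a member; one exiting on the snapshot date is
#' not counted twice.
#'
#' @param registry A [herd_registry()].
#' @param herd_id Herd identifier; unknown herds give an empty set.
#' @param date A `Date` (normally one of the registry snapshot dates).
#' @return Character vector of animal ids.
#' @export
snapshot_members <- function(registry, herd_id, date) {
  a <- registry$animals
  date <- as.Date(date)
  keep <- a$herd_id == herd_id &
    !is.na(a$herd_entry_date) & a$herd_entry_date <= date &
    (is.na(a$herd_exit_date) | a$herd_exit_date > date)
  a$animal_id[keep]
}

#' Birth herd of each animal
#'
#' The birth herd is the animal's residency herd when it entered at birth
#' (`herd_entry_date == birth_date`), otherwise the source herd of the
#' animal's earliest movement within the study year — the earliest residence
#' the one-year register window can attest — and `NA` when neither applies.
#' Needed for the two birth-herd transport variables.
#'
#' @param registry A [herd_registry()].
#' @return Tibble with columns `animal_id`, `birth_herd`.
#' @export
birth_herds <- function(registry) {
  a <- registry$animals
  born_here <- !is.na(a$birth_date) & !is.na(a$herd_entry_date) &
    a$birth_date == a$herd_entry_date
  first_src <- registry$movements |>
    dplyr::arrange(.data$date) |>
    dplyr::distinct(.data$animal_id, .keep_all = TRUE) |>
    dplyr::select("animal_id", first_source = "source_herd")
  tibble::tibble(animal_id = a$animal_id,
                 resident = a$herd_id, born_here = born_here) |>
    dplyr::left_join(first_src, by = "animal_id") |>
    dplyr::mutate(
      birth_herd = dplyr::if_else(.data$born_here, .data$resident,
                                  .data$first_source)
    ) |>
    dplyr::select("animal_id", "birth_herd")
}

age_days_at <- function(birth_date, date) {
  as.integer(as.Date(date) - birth_date)
}

#' Compute the nine classification variables for every herd
#'
#' Aggregates the register to herd level. Demographic proportions are taken
#' on the May snapshot, except `pCalvedAnimals`, which uses the September
#' snapshot. `pOutMovesToSL` is the yearly count of moves to slaughter
#' relative to the *maximum* snapshot herd size (and may therefore exceed 1
#' for high-throughput herds; such herds are flagged). The birth-herd move
#' proportions are relative to yearly out- and in-move counts.
#' `pMalesBetween1and2Years` is relative to all animals aged 1 to < 2 years
#' ([365, 730) completed days) on the May snapshot.
#' `pAnimalsLess30Days` counts animals that entered by an inward movement
#' during the year and left by any outward movement strictly less than 30
#' days later, relative to all out-moves of the year.
#'
#' Any zero denominator yields a 0 proportion and a flag row, so downstream
#' map training and tree classification always receive complete vectors.
#'
#' @param registry A [herd_registry()].
#' @param herd_ids Herds to featurize; default: all herds appearing in the
#'   animal table.
#' @return Tibble, one row per herd: `herd_id`, the three snapshot sizes,
#'   `maximum_herd_size`, `n_out_moves`, `n_in_moves` and the nine
#'   proportions ([feature_variables()]). Flag rows (herd, flag name) are
#'   attached as attribute `"flags"`.
#' @export
compute_features <- function(registry, herd_ids = NULL) {
  a <- registry$animals
  m <- registry$movements
  snaps <- registry$snapshot_dates
  if (is.null(herd_ids)) herd_ids <- sort(unique(a$herd_id))

  a$breed_type <- classify_breed_type(a$dam_breed, a$sire_breed)
  bh <- birth_herds(registry)
  a <- dplyr::left_join(a, bh, by = "animal_id")

  member <- function(date) {
    !is.na(a$herd_entry_date) & a$herd_entry_date <= date &
      (is.na(a$herd_exit_date) | a$herd_exit_date > date)
  }
  in_jan <- member(snaps[1]); in_may <- member(snaps[2]); in_sep <- member(snaps[3])
  age_may <- age_days_at(a$birth_date, snaps[2])

  m <- dplyr::left_join(m, bh, by = "animal_id")
  out_by_herd <- split(seq_len(nrow(m)), m$source_herd)
  in_idx <- which(m$destination_kind == "herd")
  in_by_herd <- split(in_idx, m$destination_id[in_idx])
  animal_rows_by_herd <- split(seq_len(nrow(a)), a$herd_id)

  flags <- list()
  note <- function(herd, flag) {
    flags[[length(flags) + 1]] <<- tibble::tibble(herd_id = herd, flag = flag)
  }
  ratio <- function(num, den, herd, flag) {
    if (den == 0) { note(herd, flag); 0 } else num / den
  }

  rows <- lapply(herd_ids, function(h) {
    ai <- animal_rows_by_herd[[h]]
    if (is.null(ai)) ai <- integer(0)
    jan <- ai[in_jan[ai]]; may <- ai[in_may[ai]]; sep <- ai[in_sep[ai]]
    n_jan <- length(jan); n_may <- length(may); n_sep <- length(sep)
    max_size <- max(n_jan, n_may, n_sep)

    yearling <- may[!is.na(age_may[may]) & age_may[may] >= 365 &
                      age_may[may] < 730]

    oi <- out_by_herd[[h]]; if (is.null(oi)) oi <- integer(0)
    ii <- in_by_herd[[h]]; if (is.null(ii)) ii <- integer(0)
    n_out <- length(oi); n_in <- length(ii)
    n_sl <- sum(m$destination_kind[oi] == "slaughter")
    n_out_bh <- sum(m$destination_kind[oi] == "herd" &
                      !is.na(m$birth_herd[oi]) &
                      m$destination_id[oi] == m$birth_herd[oi])
    n_in_bh <- sum(!is.na(m$birth_herd[ii]) & m$birth_herd[ii] == h)

    # short-stay animals: inward move into h, any outward move < 30 days later
    n_short <- 0L
    if (length(ii) > 0 && length(oi) > 0) {
      ins <- tibble::tibble(animal_id = m$animal_id[ii], d_in = m$date[ii])
      outs <- tibble::tibble(animal_id = m$animal_id[oi], d_out = m$date[oi])
      pairs <- dplyr::inner_join(ins, outs, by = "animal_id",
                                 relationship = "many-to-many")
      stay <- as.integer(pairs$d_out - pairs$d_in)
      n_short <- dplyr::n_distinct(pairs$animal_id[stay >= 0 & stay < 30])
    }

    p_sl <- ratio(n_sl, max_size, h, "zero_maximum_herd_size")
    if (p_sl > 1) note(h, "pOutMovesToSL_above_1")

    tibble::tibble(
      herd_id = h,
      herd_size_jan = n_jan, herd_size_may = n_may, herd_size_sep = n_sep,
      maximum_herd_size = max_size,
      n_out_moves = n_out, n_in_moves = n_in,
      pFemaleAnimals = ratio(sum(a$sex[may] == "female"), n_may, h,
                             "zero_may_size"),
      pDairyBreed = ratio(sum(a$breed_type[may] == "dairy"), n_may, h,
                          "zero_may_size"),
      pCrossBreed = ratio(sum(a$breed_type[may] == "cross"), n_may, h,
                          "zero_may_size"),
      pCalvedAnimals = ratio(sum(a$has_calved_by_sep1[sep], na.rm = TRUE),
                             n_sep, h, "zero_sep_size"),
      pMalesBetween1and2Years = ratio(sum(a$sex[yearling] == "male"),
                                      length(yearling), h, "no_yearlings"),
      pAnimalsLess30Days = ratio(n_short, n_out, h, "no_out_moves"),
      pOutMovesToSL = p_sl,
      pOutMovesToBirthHerd = ratio(n_out_bh, n_out, h, "no_out_moves"),
      pInMovesToBirthHerd = ratio(n_in_bh, n_in, h, "no_in_moves")
    )
  })

  res <- dplyr::bind_rows(rows)
  attr(res, "flags") <- if (length(flags) > 0) {
    dplyr::distinct(dplyr::bind_rows(flags))
  } else {
    tibble::tibble(herd_id = character(), flag = character())
  }
  res
}

#' Initial breeding/dairy/beef/mixed herd classification
#'
#' The seed classification applied before map-based rule extraction: herds
#' are breeding enterprises iff the proportion of animals that had ever
#' calved by 1 September is at least 25%; breeding herds are dairy if at
#' least 70% of their animals are of dairy breed type, beef if that value is
#' below 30%, and mixed otherwise. Non-breeding herds remain `unknown`.
#'
#' @param features Feature table from [compute_features()] (or any data
#'   frame with `pCalvedAnimals` and `pDairyBreed` columns).
#' @return Factor with levels `dairy`, `beef`, `mixed`, `unknown`, one per
#'   row of `features`.
#' @export
initial_classification <- function(features) {
  calved <- features$pCalvedAnimals
  dairy <- features$pDairyBreed
  out <- dplyr::case_when(
    calved < 0.25 ~ "unknown",
    dairy >= 0.70 ~ "dairy",
    dairy < 0.30 ~ "beef",
    TRUE ~ "mixed"
  )
  factor(out, levels = c("dairy", "beef", "mixed", "unknown"))
}
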