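# Register container: an animal table and a movement table with snapshot
# semantics, emulating a one-year extract from a national cattle register.

ANIMAL_COLS <- c(
  "animal_id", "herd_id", "sex", "breed", "dam_breed", "sire_breed",
  "birth_date", "has_calved_by_sep1", "herd_entry_date", "herd_exit_date"
)
MOVEMENT_COLS <- c(
  "animal_id", "date", "source_herd", "destination_id", "destination_kind"
)

#' Construct a herd register
#'
#' Bundles an animal table, a movement table and the three demographic
#' snapshot dates of a study year into a validated register object. The
#' default snapshots are 1 January, 1 May and 1 September of the study year,
#' matching the seasonal calving pattern the snapshot design is built
#' around.
#'
#' Membership of a herd at a snapshot date follows a half-open convention:
#' an animal is a member iff `herd_entry_date <= date` and the exit date is
#' open or `herd_exit_date > date`, so an animal moving on a snapshot day is
#' counted exactly once, in the destination herd.
#'
#' @param animals Data frame with columns `animal_id`, `herd_id`, `sex`
#'   (`"female"`/`"male"`), `breed`, `dam_breed`, `sire_breed`,
#'   `birth_date`, `has_calved_by_sep1` (logical), `herd_entry_date`,
#'   `herd_exit_date` (`NA` = still in herd). Dates as `Date` or ISO-8601
#'   strings.
#' @param movements Data frame with columns `animal_id`, `date`,
#'   `source_herd`, `destination_id`, `destination_kind`
#'   (`"herd"`, `"slaughter"`, `"export"`).
#' @param study_year Integer year the movement window covers.
#' @param snapshot_dates Three strictly increasing `Date`s.
#' @param check If `TRUE` (default), stop when [validate_registry()] finds
#'   violations.
#' @return Object of class `herd_registry`.
#' @export
herd_registry <- function(animals, movements, study_year = 2017L,
                          snapshot_dates = NULL, check = TRUE) {
  if (is.null(snapshot_dates)) {
    snapshot_dates <- as.Date(sprintf("%d-%02d-01", study_year, c(1L, 5L, 9L)))
  }
  snapshot_dates <- as.Date(snapshot_dates)
  animals <- tibble::as_tibble(animals)
  movements <- tibble::as_tibble(movements)
  missing_a <- setdiff(ANIMAL_COLS, names(animals))
  if (length(missing_a) > 0) {
    stop("animal table is missing column(s): ", paste(missing_a, collapse = ", "))
  }
  missing_m <- setdiff(MOVEMENT_COLS, names(movements))
  if (length(missing_m) > 0) {
    stop("movement table is missing column(s): ", paste(missing_m, collapse = ", "))
  }
  for (col in c("birth_date", "herd_entry_date", "herd_exit_date")) {
    animals[[col]] <- parse_iso_date(animals[[col]], col)
  }
  movements$date <- parse_iso_date(movements$date, "date")
  animals$has_calved_by_sep1 <- as.logical(animals$has_calved_by_sep1)
  reg <- structure(
    list(
      animals = animals[ANIMAL_COLS],
      movements = movements[MOVEMENT_COLS],
      snapshot_dates = snapshot_dates,
      study_year = as.integer(study_year)
    ),
    class = "herd_registry"
  )
  if (check) {
    v <- validate_registry(reg)
    if (nrow(v) > 0) {
      stop(
        "registry has ", nrow(v), " validation violation(s), e.g. ",
        paste(utils::head(paste0(v$rule, " [", v$record_id, "]"), 5),
              collapse = "; ")
      )
    }
  }
  reg
}

parse_iso_date <- function(x, what) {
  if (inherits(x, "Date")) return(x)
  chr <- as.character(x)
  chr[!is.na(chr) & chr == ""] <- NA_character_
  out <- as.Date(chr, format = "%Y-%m-%d")
  bad <- which(!is.na(chr) & is.na(out))
  if (length(bad) > 0) {
    stop("unparseable ", what, " value(s) in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  out
}

#' @export
print.herd_registry <- function(x, ...) {
  cat("<herd_registry>\n")
  cat("  animals:   ", nrow(x$animals), " in ",
      dplyr::n_distinct(x$animals$herd_id), " herds\n", sep = "")
  cat("  movements: ", nrow(x$movements), "\n", sep = "")
  cat("  study year ", x$study_year, "; snapshots ",
      paste(format(x$snapshot_dates), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Validate a herd register
#'
#' Checks every register invariant and returns the violations, one row per
#' offending record: unique animal ids, valid sex codes, calving implies
#' female, date ordering (`birth <= entry <= exit`), movement dates inside
#' the study year, movement animal ids present in the animal table, terminal
#' destination codes used iff the destination kind is `slaughter`/`export`,
#' and exactly three strictly increasing snapshot dates.
#'
#' @param registry A `herd_registry` (constructed with `check = FALSE` if it
#'   may be dirty).
#' @return Tibble with columns `record_id`, `rule`, `detail`; zero rows iff
#'   the register is clean.
#' @export
validate_registry <- function(registry) {
  a <- registry$animals
  m <- registry$movements
  out <- list()
  add <- function(ids, rule, detail) {
    if (length(ids) > 0) {
      out[[length(out) + 1]] <<- tibble::tibble(
        record_id = as.character(ids), rule = rule, detail = detail
      )
    }
  }

  dup <- unique(a$animal_id[duplicated(a$animal_id)])
  add(dup, "unique_animal_id", "animal_id occurs more than once")
  add(a$animal_id[!a$sex %in% c("female", "male")],
      "sex_code", "sex must be 'female' or 'male'")
  add(a$animal_id[!is.na(a$has_calved_by_sep1) & a$has_calved_by_sep1 &
                    a$sex != "female"],
      "calved_implies_female", "has_calved_by_sep1 TRUE for a male")
  add(a$animal_id[!is.na(a$birth_date) & !is.na(a$herd_entry_date) &
                    a$birth_date > a$herd_entry_date],
      "birth_before_entry", "birth_date after herd_entry_date")
  add(a$animal_id[!is.na(a$herd_exit_date) & !is.na(a$herd_entry_date) &
                    a$herd_entry_date > a$herd_exit_date],
      "entry_before_exit", "herd_entry_date after herd_exit_date")

  if (nrow(m) > 0) {
    add(m$animal_id[!m$animal_id %in% a$animal_id],
        "movement_animal_known", "movement references unknown animal_id")
    yr <- as.integer(format(m$date, "%Y"))
    add(m$animal_id[!is.na(yr) & yr != registry$study_year],
        "movement_in_study_year", "movement date outside study year")
    add(m$animal_id[!m$destination_kind %in% c("herd", "slaughter", "export")],
        "destination_kind_code", "unknown destination_kind")
    terminal <- m$destination_kind %in% c("slaughter", "export")
    add(m$animal_id[terminal & !m$destination_id %in% TERMINAL_CODES],
        "terminal_destination", "slaughter/export move must use a terminal code")
    add(m$animal_id[!terminal & m$destination_id %in% TERMINAL_CODES],
        "herd_destination", "herd move uses a terminal code")
  }

  sd_ok <- length(registry$snapshot_dates) == 3 &&
    !anyNA(registry$snapshot_dates) &&
    all(diff(registry$snapshot_dates) > 0)
  if (!sd_ok) add("registry", "snapshot_dates",
                  "need exactly three strictly increasing snapshot dates")

  if (length(out) == 0) {
    tibble::tibble(record_id = character(), rule = character(),
                   detail = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Read a herd register from CSV files
#'
#' Reads `animals.csv` and `movements.csv` (comma-separated, UTF-8, ISO-8601
#' dates, header row mandatory; an empty `herd_exit_date` means the animal
#' is still in the herd) and returns a validated [herd_registry()]. Load
#' fails with an informative error naming the offending rows on missing
#' columns, unparseable dates, duplicated animal ids or referential
#' violations.
#'
#' @param animals_file,movements_file Paths to the two CSV files.
#' @inheritParams herd_registry
#' @return A `herd_registry`.
#' @export
read_registry <- function(animals_file, movements_file, study_year = 2017L,
                          snapshot_dates = NULL) {
  animals <- readr::read_csv(
    animals_file,
    col_types = readr::cols(
      .default = readr::col_character(),
      has_calved_by_sep1 = readr::col_logical()
    ),
    progress = FALSE
  )
  movements <- readr::read_csv(
    movements_file,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  herd_registry(animals, movements, study_year = study_year,
                snapshot_dates = snapshot_dates, check = TRUE)
}

#' Write a herd register to CSV files
#'
#' Writes `animals.csv` and `movements.csv` into `dir` using the same
#' dialect [read_registry()] expects, so `read_registry()` of the output is
#' identity on all documented fields.
#'
#' @param registry A `herd_registry`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_registry <- function(registry, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("animals.csv", "movements.csv"))
  readr::write_csv(registry$animals, paths[1], na = "", progress = FALSE)
  readr::write_csv(registry$movements, paths[2], na = "", progress = FALSE)
  invisible(paths)
}
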