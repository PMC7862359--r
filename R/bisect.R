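# Behavioural threshold recovery: controlled single-variable registries
# plus integer bisection locate each printed classification boundary as a
# count quotient.

#' Build a controlled single-herd register
#'
#' Constructs a register holding one herd (`"CTRL"`) of `n` resident adult
#' animals in which exactly one classification variable is dialled by
#' integer counts: `n_calved` ever-calved cows, `n_dairy` animals of dairy
#' parentage (the rest pure beef), `n_slaughter` late-year moves to
#' slaughter, and `n_trade` pass-through animals that enter by an inward
#' move and leave `stay_days` later. Used by [recover_threshold()] and the
#' test suite to probe decision boundaries behaviourally.
#'
#' @param n Resident herd size.
#' @param n_calved,n_dairy,n_slaughter,n_trade Integer counts as above.
#' @param stay_days Stay length of the trade animals, in days.
#' @param study_year Study year.
#' @return A `herd_registry`.
#' @export
controlled_herd_registry <- function(n = 200L, n_calved = 0L, n_dairy = 0L,
                                     n_slaughter = 0L, n_trade = 0L,
                                     stay_days = 10L, study_year = 2017L) {
  stopifnot(n_calved <= n, n_dairy <= n, n_slaughter <= n)
  herd <- "CTRL"
  jan1 <- as.Date(sprintf("%d-01-01", study_year))
  birth <- jan1 - 1500
  ids <- sprintf("C%04d", seq_len(n))
  exit <- rep(as.Date(NA), n)
  exit[seq_len(n_slaughter)] <- jan1 + 299
  breed <- ifelse(seq_len(n) <= n_dairy, "Holstein/Friesian", "Charolais")
  animals <- tibble::tibble(
    animal_id = ids, herd_id = herd, sex = "female",
    breed = breed, dam_breed = breed, sire_breed = breed,
    birth_date = birth,
    has_calved_by_sep1 = seq_len(n) <= n_calved,
    herd_entry_date = birth, herd_exit_date = exit
  )
  movements <- tibble::tibble(
    animal_id = ids[seq_len(n_slaughter)],
    date = jan1 + 299, source_herd = herd,
    destination_id = TERMINAL_CODES[["slaughter"]],
    destination_kind = "slaughter"
  )
  if (n_trade > 0) {
    tid <- sprintf("T%04d", seq_len(n_trade))
    enter <- jan1 + 99
    animals <- dplyr::bind_rows(animals, tibble::tibble(
      animal_id = tid, herd_id = herd, sex = "female",
      breed = "Charolais", dam_breed = "Charolais", sire_breed = "Charolais",
      birth_date = enter - 400, has_calved_by_sep1 = FALSE,
      herd_entry_date = enter, herd_exit_date = enter + stay_days
    ))
    movements <- dplyr::bind_rows(movements, tibble::tibble(
      animal_id = rep(tid, 2),
      date = c(rep(enter, n_trade), rep(enter + stay_days, n_trade)),
      source_herd = c(rep("EXT1", n_trade), rep(herd, n_trade)),
      destination_id = c(rep(herd, n_trade), rep("EXT2", n_trade)),
      destination_kind = "herd"
    ))
  }
  herd_registry(animals, movements, study_year = study_year)
}

classify_controlled <- function(tree, ...) {
  reg <- controlled_herd_registry(...)
  f <- compute_features(reg, "CTRL")
  classify_herd(tree, f[, the_nine_variables])
}

# smallest integer k in [lo, hi] with pred(k) TRUE, assuming monotone pred
bisect_smallest <- function(lo, hi, pred) {
  while (lo < hi) {
    mid <- (lo + hi) %/% 2
    if (pred(mid)) hi <- mid else lo <- mid + 1
  }
  lo
}

#' Recover a classification boundary behaviourally
#'
#' Bisects over a family of controlled registries in which a single count
#' varies, and returns the boundary at which the assigned class flips —
#' expressed on the variable's own scale (a proportion, or days for the
#' trading window). The boundary emerges from the classifier's behaviour on
#' whole registers, not from reading the tree's stored constants.
#'
#' @param which One of `"breeding"`, `"dairy"`, `"beef"`, `"slaughter"`,
#'   `"dealer_days"`.
#' @param n Herd size of the controlled registries (resolution is `1/n`).
#' @param tree Tree to probe; default [build_default_tree()].
#' @return A single number: the recovered boundary (e.g. 0.25, 0.70, 0.30,
#'   0.5, or 30 days).
#' @export
recover_threshold <- function(which = c("breeding", "dairy", "beef",
                                        "slaughter", "dealer_days"),
                              n = 200L, tree = build_default_tree()) {
  which <- match.arg(which)
  grp <- function(...) classify_controlled(tree, n = n, ...)$main_group
  switch(
    which,
    breeding = {
      # smallest calved count whose herd is a breeding (dairy) enterprise
      k <- bisect_smallest(0L, n, function(k) {
        grp(n_calved = k, n_dairy = n) == "dairy"
      })
      k / n
    },
    dairy = {
      k <- bisect_smallest(0L, n, function(k) {
        grp(n_calved = n %/% 2, n_dairy = k) == "dairy"
      })
      k / n
    },
    beef = {
      # smallest dairy share that is no longer a beef enterprise
      k <- bisect_smallest(0L, n, function(k) {
        grp(n_calved = n %/% 2, n_dairy = k) != "beef"
      })
      k / n
    },
    slaughter = {
      k <- bisect_smallest(0L, n, function(k) {
        grp(n_slaughter = k) == "fattening"
      })
      k / n
    },
    dealer_days = {
      # smallest stay length no longer counted as trading
      bisect_smallest(1L, 60L, function(d) {
        grp(n_trade = 60L, stay_days = d) != "trading"
      })
    }
  )
}
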