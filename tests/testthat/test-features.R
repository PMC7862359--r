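test_that("snapshot membership follows the half-open convention", {
  reg <- tiny_registry()
  may <- as.Date("2017-05-01")

  expect_setequal(snapshot_members(reg, "A", may), c("a1", "a2", "a3"))
  expect_length(snapshot_members(reg, "nope", may), 0)

  # exited April 30 -> gone on May 1; entering on the snapshot day -> member
  reg2 <- reg
  reg2$animals$herd_exit_date[1] <- as.Date("2017-04-30")
  reg2$animals$herd_entry_date[2] <- may
  reg2$animals$birth_date[2] <- may
  expect_setequal(snapshot_members(reg2, "A", may), c("a2", "a3"))

  # exit on the snapshot day itself: not a member (counted at destination)
  reg3 <- reg
  reg3$animals$herd_exit_date[1] <- may
  expect_false("a1" %in% snapshot_members(reg3, "A", may))

  # day-by-day residency oracle over a generated herd
  spec <- default_archetypes()[["T"]]
  h <- generate_herd(spec, "TT", seed = 5)
  regT <- herd_registry(h$animals, h$movements)
  for (d in regT$snapshot_dates) {
    d <- as.Date(d, origin = "1970-01-01")
    a <- regT$animals
    expected <- a$animal_id[
      vapply(seq_len(nrow(a)), function(i) {
        a$herd_entry_date[i] <= d &&
          (is.na(a$herd_exit_date[i]) || a$herd_exit_date[i] > d)
      }, logical(1))
    ]
    expect_setequal(snapshot_members(regT, "TT", d), expected)
  }
})

test_that("feature quotients are exact on a hand-built herd", {
  reg <- quotient_registry()
  f <- compute_features(reg, "Q")
  expect_equal(f$herd_size_jan, 8)
  expect_equal(f$herd_size_may, 10)
  expect_equal(f$herd_size_sep, 9)
  expect_equal(f$maximum_herd_size, 10)
  expect_equal(f$n_out_moves, 12)
  expect_equal(f$pFemaleAnimals, 0.6)     # 6 females of 10 in May
  expect_equal(f$pOutMovesToSL, 0.4)      # 4 slaughter moves / max size 10
  expect_equal(f$pOutMovesToBirthHerd, 0.25) # 3 of 12 out-moves
  expect_equal(f$pInMovesToBirthHerd, 0)
  expect_equal(f$pMalesBetween1and2Years, 0) # no yearlings -> flagged zero
  expect_true("no_yearlings" %in% attr(f, "flags")$flag)
})

test_that("features match a naive re-scan oracle on generated herds", {
  arch <- default_archetypes()
  for (ht in c("D", "DnR-C", "BSB", "Rdf", "T", "F")) {
    h <- generate_herd(arch[[ht]], paste0("X", ht), seed = 21)
    reg <- herd_registry(h$animals, h$movements)
    got <- compute_features(reg, paste0("X", ht))
    want <- oracle_features(reg, paste0("X", ht))
    for (nm in names(want)) {
      expect_equal(got[[nm]], want[[nm]],
                   info = paste(ht, nm), tolerance = 1e-12)
    }
  }
})

test_that("initial classification applies the 25/70/30 rules at the boundary", {
  f <- tibble::tibble(
    pCalvedAnimals = c(0.24, 0.25, 0.40, 0.40, 0.40, 0.40),
    pDairyBreed = c(0.90, 0.90, 0.70, 0.699, 0.50, 0.299)
  )
  expect_equal(
    as.character(initial_classification(f)),
    c("unknown", "dairy", "dairy", "mixed", "mixed", "beef")
  )

  # monotone in pDairyBreed: raising it never moves a breeding herd
  # towards beef
  rank <- c(beef = 1, mixed = 2, dairy = 3)
  dairy_seq <- seq(0, 1, by = 0.01)
  cls <- initial_classification(
    tibble::tibble(pCalvedAnimals = 0.5, pDairyBreed = dairy_seq)
  )
  expect_true(all(diff(rank[as.character(cls)]) >= 0))
})

test_that("zero denominators yield flagged zero proportions", {
  # a herd whose animals all leave before May: zero May size, no moves
  animals <- tibble::tibble(
    animal_id = "z1", herd_id = "Z", sex = "female", breed = "Jersey",
    dam_breed = "Jersey", sire_breed = "Jersey",
    birth_date = as.Date("2016-01-01"),
    has_calved_by_sep1 = FALSE,
    herd_entry_date = as.Date("2016-01-01"),
    herd_exit_date = as.Date("2017-02-01")
  )
  movements <- tibble::tibble(
    animal_id = character(), date = as.Date(character()),
    source_herd = character(), destination_id = character(),
    destination_kind = character())
  reg <- herd_registry(animals, movements)
  f <- compute_features(reg, "Z")
  expect_equal(f$pFemaleAnimals, 0)
  expect_equal(f$pAnimalsLess30Days, 0)
  flags <- attr(f, "flags")
  expect_true(all(c("zero_may_size", "no_out_moves", "no_in_moves") %in%
                    flags$flag))
})
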