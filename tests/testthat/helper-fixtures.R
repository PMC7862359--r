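# Shared fixtures: tiny hand-built registers and SOM training sets.

# A minimal clean register: three resident animals in herd A, one movement.
tiny_registry <- function() {
  animals <- tibble::tibble(
    animal_id = c("a1", "a2", "a3"),
    herd_id = "A",
    sex = c("female", "female", "male"),
    breed = c("Jersey", "Charolais", "Jersey"),
    dam_breed = c("Jersey", "Charolais", "Jersey"),
    sire_breed = c("Holstein/Friesian", "Limousin", "Charolais"),
    birth_date = as.Date(c("2013-02-01", "2014-03-01", "2016-04-01")),
    has_calved_by_sep1 = c(TRUE, FALSE, FALSE),
    herd_entry_date = as.Date(c("2013-02-01", "2014-03-01", "2016-04-01")),
    herd_exit_date = as.Date(c(NA, NA, "2017-10-01"))
  )
  movements <- tibble::tibble(
    animal_id = "a3", date = as.Date("2017-10-01"), source_herd = "A",
    destination_id = "SLAUGHTER", destination_kind = "slaughter"
  )
  herd_registry(animals, movements, study_year = 2017L)
}

# A hand-built herd with exactly known feature quotients:
# 10 May members (6 female), 4 slaughter out-moves with snapshot sizes
# 8/10/9, and 3 of 12 out-moves returning animals to their birth herd.
quotient_registry <- function() {
  n <- 10L
  ids <- sprintf("q%02d", 1:n)
  sex <- c(rep("female", 6), rep("male", 4))
  # animals q9, q10 enter after Jan 1 (so Jan size 8) and one, q10,
  # exits before Sep 1 (so Sep size 9)
  entry <- as.Date(rep("2016-01-01", n))
  entry[9:10] <- as.Date("2017-02-01")
  exit <- rep(as.Date(NA), n)
  exit[10] <- as.Date("2017-08-15")
  birth <- as.Date(rep("2014-06-01", n))
  birth[9:10] <- as.Date("2016-06-01")
  animals <- tibble::tibble(
    animal_id = ids, herd_id = "Q", sex = sex,
    breed = "Charolais", dam_breed = "Charolais", sire_breed = "Charolais",
    birth_date = birth, has_calved_by_sep1 = FALSE,
    herd_entry_date = entry, herd_exit_date = exit
  )
  # 12 out-moves in total: 4 slaughter (q1-q4, exits late year are not
  # needed for move counting), 3 back to the birth herd of q9/q10-style
  # entrants, 5 to an unrelated herd. Move animals q1..q8 stay members in
  # May (moves after Sep do not affect snapshots except q10's exit).
  mv <- function(aid, day, dest, kind) {
    tibble::tibble(animal_id = aid, date = as.Date(day), source_herd = "Q",
                   destination_id = dest, destination_kind = kind)
  }
  movements <- dplyr::bind_rows(
    mv(ids[1:4], "2017-10-01", "SLAUGHTER", "slaughter"),
    # q9, q10 entered from herd "B" (their earliest movement source), and
    # q10 plus two re-listed moves of q9 return to B
    tibble::tibble(animal_id = c("q09", "q10"),
                   date = as.Date("2017-02-01"), source_herd = "B",
                   destination_id = "Q", destination_kind = "herd"),
    mv(c("q09", "q10", "q09"), c("2017-09-20", "2017-08-15", "2017-11-05"),
       "B", "herd"),
    mv(ids[5:8], "2017-10-10", "X", "herd"),
    mv("q01", "2017-11-20", "X", "herd")
  )
  herd_registry(animals, movements, study_year = 2017L)
}

# Two well-separated Gaussian clusters in N dimensions (normalised scale).
two_cluster_data <- function(n_per = 15L, N = 3L, sep = 4, sd = 0.3,
                             seed = 99L) {
  set.seed(seed)
  rbind(
    matrix(rnorm(n_per * N, -sep / 2, sd), n_per, N),
    matrix(rnorm(n_per * N, +sep / 2, sd), n_per, N)
  )
}

# Exhaustive best-matching-unit search, written independently of find_bmu:
# scan nodes in index order with a strict < comparison.
oracle_bmu <- function(W, z) {
  best <- 1L
  best_d <- Inf
  for (i in seq_len(nrow(W))) {
    d <- sqrt(sum((W[i, ] - z)^2))
    if (d < best_d) {
      best_d <- d
      best <- i
    }
  }
  best
}
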