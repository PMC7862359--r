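# Naive re-implementation of the herd-level variables: explicit per-animal
# and per-movement loops, kept deliberately independent of compute_features.

oracle_features <- function(registry, herd) {
  a <- as.data.frame(registry$animals)
  m <- as.data.frame(registry$movements)
  snaps <- registry$snapshot_dates

  is_member <- function(i, d) {
    !is.na(a$herd_entry_date[i]) && a$herd_entry_date[i] <= d &&
      (is.na(a$herd_exit_date[i]) || a$herd_exit_date[i] > d)
  }
  members_on <- function(d) {
    out <- c()
    for (i in seq_len(nrow(a))) {
      if (a$herd_id[i] == herd && is_member(i, d)) out <- c(out, i)
    }
    out
  }
  jan <- members_on(snaps[1]); may <- members_on(snaps[2])
  sep <- members_on(snaps[3])
  max_size <- max(length(jan), length(may), length(sep))

  # birth herd per animal, by scanning movements chronologically
  birth_of <- function(id) {
    i <- which(a$animal_id == id)
    if (!is.na(a$birth_date[i]) && !is.na(a$herd_entry_date[i]) &&
        a$birth_date[i] == a$herd_entry_date[i]) {
      return(a$herd_id[i])
    }
    mine <- m[m$animal_id == id, ]
    if (nrow(mine) == 0) return(NA_character_)
    mine$source_herd[order(mine$date)][1]
  }

  n_out <- 0; n_in <- 0; n_sl <- 0; n_out_bh <- 0; n_in_bh <- 0
  for (j in seq_len(nrow(m))) {
    if (m$source_herd[j] == herd) {
      n_out <- n_out + 1
      if (m$destination_kind[j] == "slaughter") n_sl <- n_sl + 1
      bh <- birth_of(m$animal_id[j])
      if (m$destination_kind[j] == "herd" && !is.na(bh) &&
          m$destination_id[j] == bh) {
        n_out_bh <- n_out_bh + 1
      }
    }
    if (m$destination_kind[j] == "herd" && m$destination_id[j] == herd) {
      n_in <- n_in + 1
      bh <- birth_of(m$animal_id[j])
      if (!is.na(bh) && bh == herd) n_in_bh <- n_in_bh + 1
    }
  }

  # animals that came in by a movement and left again within 30 days
  short_ids <- c()
  ins <- m[m$destination_kind == "herd" & m$destination_id == herd, ]
  outs <- m[m$source_herd == herd, ]
  for (j in seq_len(nrow(ins))) {
    mine_out <- outs[outs$animal_id == ins$animal_id[j], ]
    for (l in seq_len(nrow(mine_out))) {
      stay <- as.integer(mine_out$date[l] - ins$date[j])
      if (stay >= 0 && stay < 30) short_ids <- c(short_ids, ins$animal_id[j])
    }
  }
  n_short <- length(unique(short_ids))

  btype <- as.character(classify_breed_type(a$dam_breed, a$sire_breed))
  n_yearling <- 0; n_yearling_male <- 0
  for (i in may) {
    age <- as.integer(snaps[2] - a$birth_date[i])
    if (!is.na(age) && age >= 365 && age < 730) {
      n_yearling <- n_yearling + 1
      if (a$sex[i] == "male") n_yearling_male <- n_yearling_male + 1
    }
  }
  frac <- function(num, den) if (den == 0) 0 else num / den

  list(
    herd_size_jan = length(jan), herd_size_may = length(may),
    herd_size_sep = length(sep), maximum_herd_size = max_size,
    n_out_moves = n_out, n_in_moves = n_in,
    pFemaleAnimals = frac(sum(a$sex[may] == "female"), length(may)),
    pDairyBreed = frac(sum(btype[may] == "dairy"), length(may)),
    pCrossBreed = frac(sum(btype[may] == "cross"), length(may)),
    pCalvedAnimals = frac(sum(a$has_calved_by_sep1[sep]), length(sep)),
    pMalesBetween1and2Years = frac(n_yearling_male, n_yearling),
    pAnimalsLess30Days = frac(n_short, n_out),
    pOutMovesToSL = frac(n_sl, max_size),
    pOutMovesToBirthHerd = frac(n_out_bh, n_out),
    pInMovesToBirthHerd = frac(n_in_bh, n_in)
  )
}
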