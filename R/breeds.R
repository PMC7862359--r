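# Breed lists used for per-animal breed typing. Six dairy breeds and 25 beef
# breeds, following the Irish Cattle Breeding Federation convention.

DAIRY_BREEDS <- c(
  "Ayrshire", "Brown Swiss", "Holstein/Friesian", "Jersey", "Normande",
  "Norwegian Red"
)

BEEF_BREEDS <- c(
  "Angus", "Aubrac", "Blonde d'Aquitaine", "Belgian Blue", "Belted Galloway",
  "Bazadais", "Charolais", "Dexter", "Galloway", "Hereford", "Highland",
  "Irish Maol/Droimeann", "Kerry", "Longhorn", "Limousin", "Marchigiana",
  "Montbeliarde", "MRI/MRY", "Piedmontese", "Partenaise", "Rotbunte",
  "Romagnola", "Salers", "Shorthorn", "Simmental"
)

#' Dairy and beef breed lists
#'
#' The built-in breed lists used by [classify_breed_type()]: 6 dairy breeds
#' and 25 beef breeds.
#'
#' @return Named list with elements `dairy` and `beef`.
#' @export
breed_lists <- function() list(dairy = DAIRY_BREEDS, beef = BEEF_BREEDS)

#' Classify an animal's breed type from its parents' breeds
#'
#' An animal is *dairy* if both dam and sire are dairy breeds (not
#' necessarily the same breed), *beef* if both are beef breeds, and *cross*
#' if bred by a beef sire and a dairy dam or vice versa. Any missing or
#' unlisted parent breed yields *other*; such animals count in herd-size
#' denominators but in no breed-proportion numerator.
#'
#' @param dam_breed,sire_breed Character vectors of breed codes; `NA` or
#'   `""` for unknown parentage. Recycled to a common length.
#' @return Factor with levels `dairy`, `beef`, `cross`, `other`.
#' @examples
#' classify_breed_type("Jersey", "Holstein/Friesian") # dairy
#' classify_breed_type("Jersey", "Charolais")         # cross
#' @export
classify_breed_type <- function(dam_breed, sire_breed) {
  n <- max(length(dam_breed), length(sire_breed))
  dam <- rep_len(as.character(dam_breed), n)
  sire <- rep_len(as.character(sire_breed), n)
  side <- function(x) {
    out <- rep("other", length(x))
    out[!is.na(x) & x %in% DAIRY_BREEDS] <- "dairy"
    out[!is.na(x) & x %in% BEEF_BREEDS] <- "beef"
    out
  }
  d <- side(dam)
  s <- side(sire)
  type <- rep("other", n)
  type[d == "dairy" & s == "dairy"] <- "dairy"
  type[d == "beef" & s == "beef"] <- "beef"
  type[(d == "dairy" & s == "beef") | (d == "beef" & s == "dairy")] <- "cross"
  factor(type, levels = c("dairy", "beef", "cross", "other"))
}
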