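# Feeding-composition tables per habitat and Morisita-Horn similarity.

#' Collapse feeding observations to one per hour and category
#'
#' To maximise data independence, observations of the same food
#' (species + food type) within the same calendar hour count once.
#'
#' @param obs data.frame with `time` (POSIXct), `species`, `food_type`
#'   (and any other columns, preserved from the first row kept).
#' @return Deduplicated data.frame.
#' @export
dedup_hourly <- function(obs) {
  if (nrow(obs) == 0) return(obs)
  key <- paste(format(obs$time, "%Y-%m-%d %H"), obs$species, obs$food_type)
  obs[!duplicated(key), , drop = FALSE]
}

#' Feeding percentages per food category within a habitat
#'
#' Percentage of (deduplicated) feeding observations falling on each
#' species/food-type category, out of all feeding observations in the
#' habitat. Non-plant food types (e.g. insects) can be excluded.
#'
#' @param obs Deduplicated feeding observations with `species`, `food_type`.
#' @param habitat Label stored on the output.
#' @param plants_only If `TRUE`, drop categories whose `food_type` is in
#'   `non_plant_types` before computing percentages.
#' @param non_plant_types Food types treated as non-plant.
#' @return data.frame of class `feeding_table`: `habitat`, `species`,
#'   `food_type`, `count`, `percentage` (sums to 100), with attribute
#'   `total` = number of observations used.
#' @export
feeding_percentages <- function(obs, habitat,
                                plants_only = FALSE,
                                non_plant_types = c("insects", "other")) {
  if (plants_only) obs <- obs[!(obs$food_type %in% non_plant_types), , drop = FALSE]
  if (nrow(obs) == 0) stop("no feeding observations for habitat ", habitat)
  key <- paste(obs$species, obs$food_type, sep = "|")
  tab <- table(key)
  parts <- strsplit(names(tab), "|", fixed = TRUE)
  out <- data.frame(habitat = habitat,
                    species = vapply(parts, `[`, "", 1),
                    food_type = vapply(parts, `[`, "", 2),
                    count = as.integer(tab),
                    percentage = 100 * as.numeric(tab) / sum(tab))
  out <- out[order(-out$count), ]
  rownames(out) <- NULL
  attr(out, "total") <- sum(tab)
  class(out) <- c("feeding_table", class(out))
  out
}

#' Morisita-Horn similarity between two proportion vectors
#'
#' `S = 2 sum(p q) / (sum(p^2) + sum(q^2))` over a shared category
#' universe: 1 for identical composition, 0 for disjoint support. The
#' complementary dissimilarity `1 - S` is available via `dissimilarity =
#' TRUE` for cross-checks against distance-based implementations.
#'
#' @param p,q Non-negative vectors over the same categories; normalised to
#'   sum to 1 internally.
#' @param dissimilarity Return `1 - S` instead of `S`.
#' @return Similarity (or dissimilarity) in `[0, 1]`.
#' @export
horn_morisita_similarity <- function(p, q, dissimilarity = FALSE) {
  stopifnot(length(p) == length(q))
  if (any(p < 0) || any(q < 0)) stop("proportions must be non-negative")
  if (sum(p) == 0 || sum(q) == 0) stop("all-zero composition vector")
  p <- p / sum(p); q <- q / sum(q)
  s <- 2 * sum(p * q) / (sum(p^2) + sum(q^2))
  if (dissimilarity) 1 - s else s
}

#' Morisita-Horn similarity between two feeding tables
#'
#' Aligns the category universes of two [feeding_percentages()] tables
#' (absent categories get 0) and applies [horn_morisita_similarity()].
#'
#' @param tab1,tab2 `feeding_table`s.
#' @return Similarity in `[0, 1]`.
#' @export
feeding_similarity <- function(tab1, tab2) {
  k1 <- paste(tab1$species, tab1$food_type, sep = "|")
  k2 <- paste(tab2$species, tab2$food_type, sep = "|")
  univ <- union(k1, k2)
  p <- q <- stats::setNames(numeric(length(univ)), univ)
  p[k1] <- tab1$percentage
  q[k2] <- tab2$percentage
  horn_morisita_similarity(p, q)
}
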