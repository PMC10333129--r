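#' Summarize example foods into a food-type nutrient profile
#'
#' For each food type, the per-nutrient concentration is the median across
#' example foods drawn from dietary databases; the item weight is the mean of
#' the example weights. Medians of even-sized samples are the mean of the two
#' middle order statistics.
#'
#' @param examples data.frame: one row per example food, one column per
#'   nutrient (numeric, `NA` allowed), plus a `weight` column in grams.
#' @param food_type name of the food type.
#' @return a list with `food_type`, `per_nutrient_amount` (named numeric),
#'   `item_weight`, `n_examples`.
#' @export
summarize_food_type <- function(examples, food_type = "food") {
  if (is.null(examples) || nrow(examples) == 0L)
    stop("no example foods for food type '", food_type, "'")
  if (!"weight" %in% names(examples)) stop("examples need a 'weight' column")
  nut_cols <- setdiff(names(examples), "weight")
  amounts <- vapply(nut_cols, function(j) {
    x <- examples[[j]]
    if (any(x < 0, na.rm = TRUE)) stop("negative nutrient amount in '", j, "'")
    stats::median(x, na.rm = TRUE)
  }, numeric(1))
  w <- mean(examples$weight)
  if (!is.finite(w) || w <= 0) stop("food type '", food_type, "': item weight must be > 0")
  list(food_type = food_type, per_nutrient_amount = amounts,
       item_weight = w, n_examples = nrow(examples))
}

#' Standardize a food-type profile to amount per gram
#'
#' Nutrient sources report per-item amounts on mixed bases; dividing by the
#' mean item weight puts all food types on an amount-per-gram scale.
#'
#' @param food output of [summarize_food_type()].
#' @return named numeric vector of per-gram amounts.
#' @export
standardize_per_gram <- function(food) {
  if (!is.finite(food$item_weight) || food$item_weight <= 0)
    stop("item_weight must be > 0")
  food$per_nutrient_amount / food$item_weight
}

stage_value <- function(foods, food_map, omnivore) {
  if (!length(foods)) return(NULL)
  miss <- setdiff(foods, rownames(food_map))
  if (length(miss)) stop("unknown food type(s): ", paste(miss, collapse = ", "))
  m <- food_map[foods, , drop = FALSE]
  f <- if (omnivore) function(x) mean(x, na.rm = TRUE) else function(x) stats::median(x, na.rm = TRUE)
  v <- apply(m, 2L, f)
  v[is.nan(v)] <- NA_real_
  v
}

#' Per-species nutrient profile from adult and juvenile diets
#'
#' Each life stage gets the median across its food types (omnivores instead
#' average across all foods, applied within each stage); the species value is
#' the median of the adult and juvenile values.
#'
#' @param adult_foods,juvenile_foods character vectors of food types (either
#'   may be empty).
#' @param food_map matrix of per-gram nutrient amounts, rownames = food type.
#' @param omnivore logical; use the mean across foods instead of the median.
#' @return named numeric vector, one value per nutrient (`NA` = missing).
#' @export
species_profile <- function(adult_foods, juvenile_foods, food_map, omnivore = FALSE) {
  if (!length(adult_foods) && !length(juvenile_foods))
    stop("species has no recorded foods")
  stages <- list(stage_value(adult_foods, food_map, omnivore),
                 stage_value(juvenile_foods, food_map, omnivore))
  stages <- stages[!vapply(stages, is.null, logical(1))]
  m <- do.call(rbind, stages)
  v <- apply(m, 2L, stats::median, na.rm = TRUE)
  v[is.nan(v)] <- NA_real_
  v
}

#' Family nutrient profile: median across member species
#'
#' @param profiles matrix, one row per species, one column per nutrient.
#' @return named numeric vector; a nutrient is `NA` when missing in all species.
#' @export
family_profile <- function(profiles) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1,
                                                 dimnames = list(NULL, names(profiles)))
  if (nrow(profiles) == 0L) stop("family has no species profiles")
  v <- apply(profiles, 2L, stats::median, na.rm = TRUE)
  v[is.nan(v)] <- NA_real_
  v
}

#' Drop nutrients with excessive family-level missingness
#'
#' Nutrients missing in more than `threshold` of families are removed from the
#' modelled set (strict `>`, so a nutrient at exactly the threshold is kept).
#'
#' @param nutrients matrix of family-level values (rows = families).
#' @param threshold missingness fraction in (0, 1); default 0.30.
#' @return the reduced matrix, with dropped nutrient names in
#'   `attr(, "dropped")`.
#' @export
mask_sparse_nutrients <- function(nutrients, threshold = 0.30) {
  stopifnot(threshold > 0, threshold < 1)
  miss <- colMeans(is.na(nutrients))
  drop <- names(miss)[miss > threshold]
  out <- nutrients[, setdiff(colnames(nutrients), drop), drop = FALSE]
  attr(out, "dropped") <- drop
  out
}

#' Z-transform a vector, preserving missing values
#'
#' Centres and scales to mean 0, sd 1 over the non-missing entries (sample sd,
#' n-1 denominator).
#'
#' @param x numeric vector with `NA` allowed.
#' @return transformed vector of the same length.
#' @export
z_transform <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values")
  s <- stats::sd(x[ok])
  if (s == 0) stop("zero variance: cannot z-transform a constant")
  (x - mean(x[ok])) / s
}

#' Binary codings of symbiosis and vitamin levels
#'
#' A family is coded obligate when strictly more than half of its sampled
#' species have obligate symbionts. Vitamin levels are coded low/high at the
#' 25% and 50% across-family quantiles (two parallel codings; values exactly
#' at a threshold are "low").
#'
#' @param n_obligate,n_sampled integer vectors per family.
#' @param vitamins matrix of family-level vitamin values (`NA` allowed).
#' @param quantile_type passed to [stats::quantile()]; default 7 (linear
#'   interpolation of order statistics).
#' @return list with `obligate` (logical), and `low25`, `low50` (logical
#'   matrices matching `vitamins`; `NA` preserved).
#' @export
discretize_traits <- function(n_obligate, n_sampled, vitamins = NULL, quantile_type = 7) {
  keep <- n_sampled > 0L
  if (any(!keep)) warning(sum(!keep), " families with no sampled species excluded")
  obligate <- ifelse(keep, n_obligate / n_sampled > 0.5, NA)
  out <- list(obligate = obligate)
  if (!is.null(vitamins)) {
    cutm <- function(p) {
      q <- apply(vitamins, 2L, stats::quantile, probs = p, na.rm = TRUE, type = quantile_type)
      sweep(vitamins, 2L, q, `<=`)
    }
    out$low25 <- cutm(0.25)
    out$low50 <- cutm(0.50)
  }
  out
}

#' Family feeding-niche assignment from species-level niches
#'
#' A family is omnivorous if any member species combines plant and
#' animal/detritus feeding; specialist niches (phloem, xylem, blood, predator,
#' wood, fungivore) require that most species (strictly more than
#' `specialist_frac`) feed exclusively there; families whose species span
#' multiple non-vascular plant tissues are generalist herbivores; anything
#' else is "other".
#'
#' @param species_niches character vector of per-species niche labels among
#'   `herbivore, omnivore, phloem, xylem, wood, blood, predator, fungivore, other`.
#' @param specialist_frac threshold fraction for specialist niches (default 0.5).
#' @return a single niche label for the family.
#' @export
classify_family_niche <- function(species_niches,
                                  specialist_frac = 0.5) {
  species_niches <- species_niches[!is.na(species_niches)]
  if (!length(species_niches)) return(NA_character_)
  if (any(species_niches == "omnivore")) return("omnivore")
  tab <- table(species_niches) / length(species_niches)
  for (sp in c("phloem", "xylem", "wood", "blood", "predator", "fungivore"))
    if (!is.na(tab[sp]) && tab[sp] > specialist_frac) return(sp)
  if (!is.na(tab["herbivore"]) && tab["herbivore"] > 0) return("herbivore")
  "other"
}

#' Build the family-level analysis table
#'
#' Runs the full construction: food-type medians, per-gram standardization,
#' species profiles (median across stages; omnivores average across foods),
#' family profiles (median across species), obligate-symbiosis counts
#' excluding unresolved records, niche assignment, and sparse-nutrient
#' masking.
#'
#' @param foods data.frame: `food_type`, `example`, `weight`, one column per
#'   nutrient.
#' @param species data.frame: `species`, `family`, `adult_foods`,
#'   `juvenile_foods` (`;`-separated food types), `niche`, `status` in
#'   `obligate`, `non_obligate`, `unresolved`.
#' @param families data.frame: `family`, `species_richness`, `family_age`,
#'   `metabolism`.
#' @param missing_threshold nutrient missingness cut (default 0.30).
#' @return list with `table` (one row per family), `nutrients` (matrix),
#'   `provenance` (thresholds, dropped nutrients).
#' @export
build_family_table <- function(foods, species, families, missing_threshold = 0.30) {
  nut_cols <- setdiff(names(foods), c("food_type", "example", "weight"))
  per_gram <- lapply(split(foods, foods$food_type), function(d) {
    ft <- summarize_food_type(d[, c(nut_cols, "weight")], d$food_type[1L])
    standardize_per_gram(ft)
  })
  food_map <- do.call(rbind, per_gram)
  rownames(food_map) <- names(per_gram)

  split_foods <- function(s) if (is.na(s) || s == "") character() else strsplit(s, ";", fixed = TRUE)[[1L]]
  sp_prof <- t(vapply(seq_len(nrow(species)), function(i) {
    species_profile(split_foods(species$adult_foods[i]),
                    split_foods(species$juvenile_foods[i]),
                    food_map, omnivore = identical(species$niche[i], "omnivore"))
  }, numeric(ncol(food_map))))
  rownames(sp_prof) <- species$species

  fams <- sort(unique(species$family))
  nut <- t(vapply(fams, function(f)
    family_profile(sp_prof[species$family == f, , drop = FALSE]),
    numeric(ncol(food_map))))
  rownames(nut) <- fams

  resolved <- species$status != "unresolved"
  n_sampled <- vapply(fams, function(f) sum(resolved & species$family == f), integer(1))
  n_obligate <- vapply(fams, function(f)
    sum(resolved & species$family == f & species$status == "obligate"), integer(1))
  niche <- vapply(fams, function(f)
    classify_family_niche(species$niche[species$family == f]), character(1))

  nut <- mask_sparse_nutrients(nut, missing_threshold)
  tab <- data.frame(family = fams, n_sampled = n_sampled, n_obligate = n_obligate,
                    feeding_niche = niche, stringsAsFactors = FALSE)
  m <- match(fams, families$family)
  tab$species_richness <- families$species_richness[m]
  tab$family_age <- families$family_age[m]
  tab$metabolism <- families$metabolism[m]
  rownames(tab) <- NULL
  list(table = tab, nutrients = nut,
       provenance = list(missing_threshold = missing_threshold,
                         quantile_type = 7,
                         dropped_nutrients = attr(nut, "dropped")))
}

#' Validate input table schemas
#'
#' Reports the row and column of every violation instead of stopping at the
#' first.
#'
#' @param foods,species,families input data.frames as for
#'   [build_family_table()].
#' @return data.frame of violations (`table`, `row`, `column`, `problem`);
#'   zero rows when all inputs validate.
#' @export
validate_schemas <- function(foods = NULL, species = NULL, families = NULL) {
  bad <- list()
  note <- function(tb, row, col, problem)
    bad[[length(bad) + 1L]] <<- data.frame(table = tb, row = row, column = col,
                                           problem = problem, stringsAsFactors = FALSE)
  if (!is.null(foods)) {
    for (col in c("food_type", "weight"))
      if (!col %in% names(foods)) note("foods", NA, col, "missing column")
    if ("weight" %in% names(foods))
      for (i in which(!is.na(foods$weight) & foods$weight <= 0))
        note("foods", i, "weight", "weight must be > 0")
    for (col in setdiff(names(foods), c("food_type", "example", "weight")))
      for (i in which(!is.na(foods[[col]]) & foods[[col]] < 0))
        note("foods", i, col, "negative nutrient amount")
  }
  if (!is.null(species)) {
    for (col in c("species", "family", "adult_foods", "juvenile_foods", "status"))
      if (!col %in% names(species)) note("species", NA, col, "missing column")
    if (all(c("adult_foods", "juvenile_foods") %in% names(species))) {
      empty <- (is.na(species$adult_foods) | species$adult_foods == "") &
        (is.na(species$juvenile_foods) | species$juvenile_foods == "")
      for (i in which(empty)) note("species", i, "adult_foods", "no foods recorded")
    }
    if ("status" %in% names(species))
      for (i in which(!species$status %in% c("obligate", "non_obligate", "unresolved")))
        note("species", i, "status", "unknown status")
  }
  if (!is.null(families)) {
    for (col in c("family", "species_richness", "family_age"))
      if (!col %in% names(families)) note("families", NA, col, "missing column")
    if ("species_richness" %in% names(families))
      for (i in which(!is.na(families$species_richness) & families$species_richness < 1))
        note("families", i, "species_richness", "richness must be >= 1")
    if ("family_age" %in% names(families))
      for (i in which(!is.na(families$family_age) & families$family_age <= 0))
        note("families", i, "family_age", "age must be > 0")
  }
  if (!length(bad))
    return(data.frame(table = character(), row = integer(), column = character(),
                      problem = character()))
  do.call(rbind, bad)
}
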