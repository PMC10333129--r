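test_that("food-type summaries take medians across examples and mean weights", {
  ex <- data.frame(nutA = c(2, 4), weight = c(4, 6))
  ft <- summarize_food_type(ex, "fruit")
  expect_equal(unname(ft$per_nutrient_amount["nutA"]), 3)
  expect_equal(ft$item_weight, 5)
  expect_equal(ft$n_examples, 2L)

  single <- summarize_food_type(data.frame(nutA = 5, weight = 2), "seed")
  expect_equal(unname(single$per_nutrient_amount["nutA"]), 5)

  robust <- summarize_food_type(data.frame(nutA = c(1, 2, 100), weight = rep(1, 3)), "leaf")
  expect_equal(unname(robust$per_nutrient_amount["nutA"]), 2)

  expect_error(summarize_food_type(data.frame(), "none"), "no example")
  expect_error(summarize_food_type(data.frame(nutA = -1, weight = 1), "bad"), "negative")
})

test_that("per-gram standardization divides by mean item weight", {
  ft <- list(per_nutrient_amount = c(a = 10, b = 4), item_weight = 2)
  expect_equal(standardize_per_gram(ft), c(a = 5, b = 2))
  ft$per_nutrient_amount <- c(a = 10, b = 0)
  ft$item_weight <- 5
  expect_equal(standardize_per_gram(ft), c(a = 2, b = 0))
  ft$item_weight <- 0
  expect_error(standardize_per_gram(ft), "> 0")
})

test_that("species profiles use per-stage medians, omnivores per-stage means", {
  fm <- matrix(c(2, 4, 1, 3, 6, 5), nrow = 6,
               dimnames = list(paste0("f", 1:6), "nutA"))
  expect_equal(unname(species_profile("f1", "f2", fm)), 3)
  # adult {1,3} -> 2, juvenile {3} -> 3, species = median(2, 3) = 2.5
  fm2 <- matrix(c(1, 3), 2, dimnames = list(c("fa", "fb"), "nutA"))
  fm3 <- rbind(fm2, fc = 3)
  expect_equal(unname(species_profile(c("fa", "fb"), "fc", fm3)), 2.5)
  # omnivore: mean across all foods {1, 2, 6} = 3
  fo <- matrix(c(1, 2, 6), 3, dimnames = list(c("x", "y", "z"), "nutA"))
  expect_equal(unname(species_profile(c("x", "y", "z"), character(), fo,
                                      omnivore = TRUE)), 3)
  expect_error(species_profile("nope", character(), fo), "unknown food")
  expect_error(species_profile(character(), character(), fo), "no recorded foods")
})

test_that("family profiles are medians over species, even counts interpolated", {
  m <- matrix(c(2, 4, 9), 3, dimnames = list(NULL, "nutA"))
  expect_equal(unname(family_profile(m)), 4)
  expect_equal(unname(family_profile(matrix(7, 1, dimnames = list(NULL, "nutA")))), 7)
  expect_equal(unname(family_profile(matrix(1:4, 4, dimnames = list(NULL, "nutA")))), 2.5)
  allna <- matrix(NA_real_, 2, 1, dimnames = list(NULL, "nutA"))
  expect_true(is.na(family_profile(allna)))
})

test_that("sparse nutrients are masked with a strict threshold", {
  m <- matrix(1, 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  m[1:7, "a"] <- NA  # 35% missing -> dropped
  m[1:6, "b"] <- NA  # exactly 30% -> retained
  out <- mask_sparse_nutrients(m, 0.30)
  expect_equal(attr(out, "dropped"), "a")
  expect_equal(colnames(out), c("b", "c"))
})

test_that("z-transform centres, scales and preserves missingness", {
  expect_equal(z_transform(c(1, 2, 3)), c(-1, 0, 1))
  z <- z_transform(c(1, NA, 3))
  expect_equal(z, c(-sqrt(2) / 2, NA, sqrt(2) / 2))
  expect_error(z_transform(c(2, 2, 2)), "zero variance")
  expect_error(z_transform(c(1, NA)), "at least 2")
})

test_that("discretization uses strict >0.5 for symbiosis and type-7 quantiles", {
  d <- discretize_traits(n_obligate = c(3, 2, 0), n_sampled = c(4, 4, 6),
                         vitamins = matrix(c(1, 2, 3), 3, 1,
                                           dimnames = list(NULL, "B5")))
  expect_equal(d$obligate, c(TRUE, FALSE, FALSE))  # 0.75 > .5; 0.5 is not
  v <- matrix(1:4, 4, 1, dimnames = list(NULL, "B5"))
  d2 <- discretize_traits(rep(1, 4), rep(2, 4), v)
  expect_equal(unname(d2$low50[, 1]), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(d2$low25[, 1]), c(TRUE, FALSE, FALSE, FALSE))
  expect_warning(discretize_traits(c(1, 0), c(2, 0)), "excluded")
})

test_that("family niche assignment follows the omnivore/specialist rules", {
  expect_equal(classify_family_niche(c("herbivore", "omnivore")), "omnivore")
  expect_equal(classify_family_niche(rep("phloem", 3)), "phloem")
  expect_equal(classify_family_niche(c("phloem", "herbivore", "phloem")), "phloem")
  expect_equal(classify_family_niche(c("phloem", "herbivore")), "herbivore")
  expect_equal(classify_family_niche(c("predator", "predator", "blood")), "predator")
})

test_that("table construction is deterministic and permutation invariant", {
  set.seed(31)
  d <- sim_food_tables()
  a <- build_family_table(d$foods, d$species, d$families)
  b <- build_family_table(d$foods, d$species, d$families)
  expect_identical(a, b)
  perm_f <- d$foods[sample(nrow(d$foods)), ]
  perm_s <- d$species[sample(nrow(d$species)), ]
  c2 <- build_family_table(perm_f, perm_s, d$families)
  expect_equal(c2$nutrients, a$nutrients)
  expect_equal(c2$table$n_obligate, a$table$n_obligate)
  # unresolved records are excluded from both counts
  expect_equal(a$table$n_sampled,
               as.vector(table(d$species$family[d$species$status != "unresolved"])[a$table$family]))
})

test_that("schema validation reports row and column of each violation", {
  foods <- data.frame(food_type = "f", example = "e", nutA = c(1, -2),
                      weight = c(0, 5))
  v <- validate_schemas(foods = foods)
  expect_true(any(v$column == "weight" & v$row == 1))
  expect_true(any(v$column == "nutA" & v$row == 2))
  sp <- data.frame(species = "s", family = "f", adult_foods = "",
                   juvenile_foods = "", status = "weird")
  v2 <- validate_schemas(species = sp)
  expect_true(any(v2$problem == "no foods recorded"))
  expect_true(any(v2$problem == "unknown status"))
  ok <- validate_schemas(families = data.frame(family = "f", species_richness = 10,
                                               family_age = 50))
  expect_equal(nrow(ok), 0L)
})
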