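#' Default synthetic study configuration
#'
#' Bundles the generator settings used across the synthetic analyses:
#' a 150-tip birth-death tree rescaled to a 400-Myr root (echoing the insect
#' family timescale), binary-trait CTMC rates, latent phylogenetic
#' correlations between the symbiosis liability and nutrient traits,
#' per-trait phylogenetic heritability, richness-model coefficients, and
#' host-symbiont association signal.
#'
#' @param n_tips,birth,death,root_age tree settings.
#' @param q01,q10 gain/loss rates of the binary trait (per Myr, on the
#'   rescaled tree).
#' @param r_liab_nutrient latent phylogenetic correlation between the
#'   symbiosis liability and the first nutrient.
#' @param h2 phylogenetic heritability of the continuous traits.
#' @param n_sampled species sampled per family for the binomial proportion.
#' @param missingness fraction of nutrient cells set missing.
#' @param richness_base,richness_age_effect,richness_trait_effect,clade_sd
#'   Poisson species-richness model (log scale).
#' @param assoc_signal co-phylogenetic signal in `[0, 1]`.
#' @param seed integer seed.
#' @return a named list.
#' @export
sim_config <- function(n_tips = 150, birth = 0.03, death = 0.01, root_age = 400,
                       q01 = 0.004, q10 = 0.002, r_liab_nutrient = -0.4,
                       h2 = 0.8, n_sampled = 10, missingness = 0.05,
                       richness_base = 4, richness_age_effect = 0.3,
                       richness_trait_effect = 0, clade_sd = 0.5,
                       assoc_signal = 1, seed = 1L) {
  as.list(environment())
}

#' Simulate an ultrametric birth-death tree
#'
#' Birth-death tree conditioned on the number of tips (via [ape::rphylo()]),
#' rescaled so the root age equals `root_age`.
#'
#' @param n_tips number of tips (>= 3).
#' @param birth,death per-lineage rates.
#' @param root_age depth of the root in Myr.
#' @return an ultrametric `phylo` with tips `t1..tn`.
#' @export
sim_tree <- function(n_tips = 150, birth = 0.03, death = 0.01, root_age = 400) {
  stopifnot(n_tips >= 3)
  tr <- ape::rphylo(n_tips, birth, death, fossils = FALSE)
  h <- max(node_depths(tr)[seq_len(n_tips)])
  tr$edge.length <- tr$edge.length * root_age / h
  tr
}

#' Simulate a discrete trait along a tree under a CTMC
#'
#' Root-to-tip simulation with exponential waiting times; the full branch
#' histories and true node states are retained so recovery tests can be
#' scored against known truth.
#'
#' @param tree a `phylo`.
#' @param Q generator (states in `colnames(Q)`).
#' @param root_state optional label; default drawn from the uniform root
#'   distribution.
#' @return list with `tip_states` (named), `node_states` (all Ntip+Nnode in
#'   ape numbering), `n_changes`, `histories` (per postorder edge), `truth`.
#' @export
sim_mk_trait <- function(tree, Q, root_state = NULL) {
  validate_Q(Q)
  states <- colnames(Q)
  k <- length(states)
  tr <- stats::reorder(tree, "postorder")
  ntot <- ape::Ntip(tr) + tr$Nnode
  root <- tr$edge[nrow(tr$edge), 1L]
  node_states <- integer(ntot)
  node_states[root] <- if (is.null(root_state)) sample.int(k, 1L) else
    match(root_state, states)
  histories <- vector("list", nrow(tr$edge))
  n_changes <- 0L
  for (i in rev(seq_len(nrow(tr$edge)))) {
    par <- tr$edge[i, 1L]; ch <- tr$edge[i, 2L]
    s <- node_states[par]
    t_left <- tr$edge.length[i]
    seg <- list()
    repeat {
      rate <- -Q[s, s]
      w <- if (rate > 0) stats::rexp(1, rate) else Inf
      if (w >= t_left) {
        seg[[length(seg) + 1L]] <- c(s, t_left)
        break
      }
      seg[[length(seg) + 1L]] <- c(s, w)
      t_left <- t_left - w
      pr <- Q[s, ]; pr[s] <- 0
      s <- sample.int(k, 1L, prob = pr)
      n_changes <- n_changes + 1L
    }
    m <- do.call(rbind, seg)
    histories[[i]] <- data.frame(state = m[, 1L], time = m[, 2L])
    node_states[ch] <- s
  }
  tips <- stats::setNames(states[node_states[seq_len(ape::Ntip(tr))]], tr$tip.label)
  list(tip_states = tips, node_states = states[node_states],
       n_changes = n_changes, histories = histories, tree = tr,
       truth = list(Q = Q, root_state = states[node_states[root]],
                    n_changes = n_changes))
}

#' Simulate correlated binary + continuous traits under the liability model
#'
#' Multivariate Brownian liabilities on the tree with a specified cross-trait
#' correlation matrix; per-trait phylogenetic heritability is imposed by
#' mixing in independent noise. The first liability drives the binary
#' symbiosis trait: each tip's probability is the inverse-logit of its
#' (scaled) liability and family counts are binomial draws. This is exactly
#' the generative structure the binomial-logit phylogenetic mixed model
#' assumes.
#'
#' @param tree a `phylo`.
#' @param r_matrix latent phylogenetic correlation matrix across (liability,
#'   nutrient 1, nutrient 2, ...); default 3 traits with r(liab, B5) from
#'   `r_liab`.
#' @param r_liab shortcut for the liability-first-nutrient correlation.
#' @param h2 per-trait phylogenetic heritability (recycled).
#' @param liab_sd total standard deviation of the liability on the logit
#'   scale.
#' @param n_sampled species sampled per family (scalar or per tip).
#' @param missingness fraction of nutrient cells masked to `NA`.
#' @return list with `liability`, `binary`, `n_obligate`, `n_sampled`,
#'   `nutrients` (matrix with `NA`s), `truth`.
#' @export
sim_correlated_traits <- function(tree, r_matrix = NULL, r_liab = -0.4,
                                  h2 = 0.8, liab_sd = 2, n_sampled = 10,
                                  missingness = 0.05) {
  n <- ape::Ntip(tree)
  if (is.null(r_matrix)) {
    r_matrix <- diag(3)
    r_matrix[1, 2] <- r_matrix[2, 1] <- r_liab
  }
  m <- nrow(r_matrix)
  h2 <- rep_len(h2, m)
  C <- stats::cov2cor(ape::vcv.phylo(tree))
  ch <- chol(C + diag(1e-10, n))
  Z <- matrix(stats::rnorm(n * m), n, m)
  phy <- t(ch) %*% Z %*% chol(r_matrix) # cov = C (x) r_matrix
  noise <- matrix(stats::rnorm(n * m), n, m)
  traits <- sweep(phy, 2L, sqrt(h2), `*`) + sweep(noise, 2L, sqrt(1 - h2), `*`)
  rownames(traits) <- tree$tip.label
  liab <- traits[, 1L] * liab_sd
  pr <- stats::plogis(liab)
  ns <- rep_len(n_sampled, n)
  n_ob <- stats::rbinom(n, ns, pr)
  nut <- traits[, -1L, drop = FALSE]
  colnames(nut) <- paste0("nutrient", seq_len(ncol(nut)))
  if (missingness > 0) {
    mask <- matrix(stats::runif(length(nut)) < missingness, nrow(nut))
    nut[mask] <- NA
  }
  list(liability = liab, binary = stats::setNames(liab > 0, tree$tip.label),
       n_obligate = stats::setNames(n_ob, tree$tip.label),
       n_sampled = stats::setNames(ns, tree$tip.label), nutrients = nut,
       truth = list(r_matrix = r_matrix, h2 = h2, liab_sd = liab_sd,
                    missingness = missingness))
}

#' Simulate a symbiont tree and host associations with tunable congruence
#'
#' With `signal = 1` the symbiont phylogeny mirrors the host phylogeny and
#' every symbiont keeps its co-diverging host; each symbiont instead switches
#' to a uniformly chosen host with probability `1 - signal`.
#'
#' @param host_tree a `phylo`.
#' @param signal co-phylogenetic signal in `[0, 1]`.
#' @param n_sampled species sampled per host family.
#' @param p_with probability a sampled species carries its family's symbiont.
#' @return list with `symbiont_tree`, `A` (binary host x symbiont matrix),
#'   `table` (combination counts for linked pairs), `truth`.
#' @export
sim_host_symbiont <- function(host_tree, signal = 1, n_sampled = 10, p_with = 0.8) {
  stopifnot(signal >= 0, signal <= 1)
  n <- ape::Ntip(host_tree)
  st <- host_tree
  st$tip.label <- paste0("S_", host_tree$tip.label)
  # mild branch-length noise so the mirrored tree is not byte-identical
  st$edge.length <- st$edge.length * stats::runif(length(st$edge.length), 0.9, 1.1)
  host_of <- seq_len(n)
  switch_i <- stats::runif(n) > signal
  host_of[switch_i] <- sample.int(n, sum(switch_i), replace = TRUE)
  A <- matrix(0L, n, n, dimnames = list(host_tree$tip.label, st$tip.label))
  A[cbind(host_of, seq_len(n))] <- 1L
  linked <- which(A == 1L, arr.ind = TRUE)
  tab <- data.frame(host_family = rownames(A)[linked[, 1L]],
                    symbiont_lineage = colnames(A)[linked[, 2L]],
                    stringsAsFactors = FALSE)
  tab$n_with <- stats::rbinom(nrow(tab), n_sampled, p_with)
  tab$n_without <- n_sampled - tab$n_with
  tab$intracellular <- stats::runif(nrow(tab)) < 0.5
  list(symbiont_tree = st, A = A, table = tab,
       truth = list(signal = signal, host_of = host_of))
}

#' Simulate species richness, family age and metabolism at the tips
#'
#' Richness is Poisson with log-rate `base + age_effect * z(age) +
#' trait_effect * trait + clade effect`, the clade effect being a Brownian
#' deviate on the tree with standard deviation `clade_sd`; zero counts are
#' truncated up to 1. Family age is the terminal branch length; metabolism is
#' a phylogenetically conserved binary label (thresholded independent
#' Brownian deviate).
#'
#' @param tree a `phylo`.
#' @param trait numeric/logical vector per tip (e.g. obligate symbiosis).
#' @param base,age_effect,trait_effect,clade_sd model coefficients (log
#'   scale).
#' @return data.frame with `family`, `species_richness`, `family_age`,
#'   `metabolism`, plus `truth` attribute.
#' @export
sim_richness <- function(tree, trait, base = 4, age_effect = 0.3,
                         trait_effect = 0, clade_sd = 0.5) {
  n <- ape::Ntip(tree)
  age <- tree$edge.length[match(seq_len(n), tree$edge[, 2L])]
  C <- stats::cov2cor(ape::vcv.phylo(tree))
  ch <- chol(C + diag(1e-10, n))
  clade <- as.vector(t(ch) %*% stats::rnorm(n)) * clade_sd
  metab <- ifelse(as.vector(t(ch) %*% stats::rnorm(n)) > 0, "holo", "hemi")
  eta <- base + age_effect * as.vector(scale(age)) +
    trait_effect * as.numeric(trait[tree$tip.label]) + clade
  rich <- stats::rpois(n, exp(eta))
  n_trunc <- sum(rich < 1L)
  rich <- pmax(rich, 1L)
  out <- data.frame(family = tree$tip.label, species_richness = rich,
                    family_age = age, metabolism = metab,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(base = base, age_effect = age_effect,
                             trait_effect = trait_effect, clade_sd = clade_sd,
                             n_truncated = n_trunc)
  out
}

#' Simulate food-example, species-diet and family input tables
#'
#' Small generator for the table-construction pipeline: food types with
#' within-type noise around known per-gram nutrient levels, species that eat
#' subsets of foods, and family metadata. The known food-type medians make
#' the whole construction checkable.
#'
#' @param n_food_types,n_species,n_families,n_nutrients table sizes.
#' @param examples_per_type examples per food type.
#' @param noise_sd within-food-type lognormal noise sd.
#' @return list with `foods`, `species`, `families` data.frames and `truth`.
#' @export
sim_food_tables <- function(n_food_types = 6, n_species = 40, n_families = 10,
                            n_nutrients = 4, examples_per_type = 5,
                            noise_sd = 0.2) {
  ft <- paste0("food", seq_len(n_food_types))
  nutr <- paste0("nut", seq_len(n_nutrients))
  true_level <- matrix(stats::rlnorm(n_food_types * n_nutrients, 1, 0.8),
                       n_food_types, n_nutrients, dimnames = list(ft, nutr))
  true_weight <- stats::runif(n_food_types, 1, 50)
  foods <- do.call(rbind, lapply(seq_len(n_food_types), function(i) {
    ex <- data.frame(food_type = ft[i],
                     example = paste0(ft[i], "_ex", seq_len(examples_per_type)))
    for (j in nutr)
      ex[[j]] <- true_level[i, j] * stats::rlnorm(examples_per_type, 0, noise_sd)
    ex$weight <- true_weight[i] * stats::rlnorm(examples_per_type, 0, noise_sd / 2)
    ex
  }))
  fams <- paste0("fam", seq_len(n_families))
  species <- data.frame(
    species = paste0("sp", seq_len(n_species)),
    family = sample(fams, n_species, replace = TRUE),
    stringsAsFactors = FALSE)
  species$adult_foods <- vapply(seq_len(n_species), function(i)
    paste(sample(ft, sample(1:3, 1)), collapse = ";"), character(1))
  species$juvenile_foods <- vapply(seq_len(n_species), function(i)
    if (stats::runif(1) < 0.8) paste(sample(ft, sample(1:2, 1)), collapse = ";")
    else "", character(1))
  species$niche <- sample(c("herbivore", "omnivore", "predator", "phloem"),
                          n_species, replace = TRUE, prob = c(0.5, 0.2, 0.2, 0.1))
  species$status <- sample(c("obligate", "non_obligate", "unresolved"),
                           n_species, replace = TRUE, prob = c(0.4, 0.5, 0.1))
  families <- data.frame(family = fams,
                         species_richness = stats::rpois(n_families, 200) + 1L,
                         family_age = stats::runif(n_families, 20, 350),
                         metabolism = sample(c("holo", "hemi"), n_families,
                                             replace = TRUE),
                         stringsAsFactors = FALSE)
  list(foods = foods, species = species, families = families,
       truth = list(true_level = true_level, true_weight = true_weight))
}

#' Write a ground-truth sidecar as JSON
#' @param truth a list (any generator's `truth` element).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
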