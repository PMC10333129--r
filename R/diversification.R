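#' Empirical logit of a percentage with a sample-size-aware epsilon
#'
#' `log((k + 0.5) / (n - k + 0.5))` where `k = pct/100 * n`; finite at 0%
#' and 100%.
#'
#' @param pct percentage in `[0, 100]`.
#' @param n number of species sampled per family.
#' @return numeric vector.
#' @export
empirical_logit <- function(pct, n) {
  k <- pct / 100 * n
  log((k + 0.5) / (n - k + 0.5))
}

#' Species richness and obligate symbiosis: multi-response model
#'
#' MR-BPMM with Poisson species richness (log link) and the binomial
#' proportion of species with obligate symbionts as responses; family age
#' (z-transformed) and metabolism (holo/hemi) as fixed effects; an
#' unstructured phylogenetic covariance as the random term. Grafted families
#' (see [graft_tip()]) are excluded by default because their ages are
#' unreliable.
#'
#' @param tab data.frame with `family`, `species_richness`, `family_age`,
#'   `metabolism`, `n_obligate`, `n_sampled`.
#' @param tree ultrametric `phylo` whose tips cover `tab$family`.
#' @param exclude_grafted drop tips flagged by grafting.
#' @param ... chain settings passed to [bpmm()].
#' @return list with `fit` (a `bpmm`), `summary`, and `correlation`
#'   (phylogenetic correlation draws between richness and symbiosis).
#' @export
richness_model <- function(tab, tree, exclude_grafted = TRUE, ...) {
  grafted <- attr(tree, "grafted")
  if (exclude_grafted && length(grafted)) {
    tab <- tab[!tab$family %in% grafted, , drop = FALSE]
    tree <- ape::drop.tip(tree, intersect(tree$tip.label, grafted))
  }
  tab <- tab[match(tree$tip.label, tab$family), , drop = FALSE]
  y <- cbind(richness = tab$species_richness, symbiosis = tab$n_obligate)
  trials <- cbind(1, tab$n_sampled)
  X <- cbind(`(Intercept)` = 1, age = as.vector(scale(tab$family_age)),
             holo = as.numeric(tab$metabolism == "holo"))
  C <- stats::cov2cor(ape::vcv.phylo(tree))
  fit <- bpmm(y = y, family = c("poisson", "binomial"), X = X, trials = trials,
              random = list(phylo = bpmm_term(C, map = tab$family,
                                              structure = "unstructured")),
              ...)
  corr <- phylo_correlation(fit, "phylo", "richness", "symbiosis")
  list(fit = fit, summary = summary(fit), correlation = corr)
}

#' Focal-versus-background contrasts of species richness
#'
#' For each focal niche-by-symbiosis cell, refits the richness model with a
#' two-level fixed factor (focal cell versus all other families) plus age and
#' metabolism, and reports the focal contrast.
#'
#' @param tab as in [richness_model()], plus `feeding_niche` and an
#'   `obligate` logical column.
#' @param tree ultrametric `phylo`.
#' @param cells data.frame with `niche`, `obligate` rows to test; default all
#'   observed combinations with at least `min_n` families.
#' @param min_n minimum focal-cell size (default 2).
#' @param ... chain settings passed to [bpmm()].
#' @return data.frame with one row per tested cell: contrast mode, CI,
#'   pMCMC, cell size; skipped cells are reported with `NA`s.
#' @export
niche_contrasts <- function(tab, tree, cells = NULL, min_n = 2, ...) {
  tab <- tab[match(tree$tip.label, tab$family), , drop = FALSE]
  if (is.null(cells)) {
    cells <- unique(data.frame(niche = tab$feeding_niche, obligate = tab$obligate))
    cells <- cells[stats::complete.cases(cells), , drop = FALSE]
  }
  C <- stats::cov2cor(ape::vcv.phylo(tree))
  out <- NULL
  for (i in seq_len(nrow(cells))) {
    focal <- tab$feeding_niche == cells$niche[i] & tab$obligate == cells$obligate[i]
    focal[is.na(focal)] <- FALSE
    if (sum(focal) < min_n) {
      out <- rbind(out, data.frame(niche = cells$niche[i],
                                   obligate = cells$obligate[i], n_focal = sum(focal),
                                   mode = NA, mean = NA, lower = NA, upper = NA,
                                   pMCMC = NA))
      next
    }
    X <- cbind(`(Intercept)` = 1, focal = as.numeric(focal),
               age = as.vector(scale(tab$family_age)),
               holo = as.numeric(tab$metabolism == "holo"))
    fit <- bpmm(y = tab$species_richness, family = "poisson", X = X,
                random = list(phylo = bpmm_term(C, map = tab$family,
                                                structure = "shared")),
                ...)
    s <- summarize_draws(fit$draws$beta[, "y:focal"])
    out <- rbind(out, data.frame(niche = cells$niche[i],
                                 obligate = cells$obligate[i], n_focal = sum(focal),
                                 t(s)))
  }
  rownames(out) <- NULL
  out
}

#' Assemble the sister-pair analysis table
#'
#' Joins the cherries of the tree with family-level data; each pair
#' contributes two rows sharing a pair id and the pair's node label.
#'
#' @param tree ultrametric `phylo`.
#' @param tab family table with `family`, `species_richness`, `n_obligate`,
#'   `n_sampled`, `feeding_niche`.
#' @return data.frame: `pair`, `node_label`, `family`, `species_richness`,
#'   `pct_obligate`, `n_sampled`, `feeding_niche`, `pair_age`.
#' @export
sister_pair_table <- function(tree, tab) {
  pairs <- extract_sister_pairs(tree)
  labs <- internal_node_labels(tree)
  ntip <- ape::Ntip(tree)
  if (is.null(tab$feeding_niche)) tab$feeding_niche <- NA_character_
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    fams <- c(pairs$tip_a[i], pairs$tip_b[i])
    m <- match(fams, tab$family)
    data.frame(pair = paste0("pair", i),
               node_label = labs[pairs$node[i] - ntip],
               family = fams,
               species_richness = tab$species_richness[m],
               pct_obligate = 100 * tab$n_obligate[m] / tab$n_sampled[m],
               n_sampled = tab$n_sampled[m],
               feeding_niche = tab$feeding_niche[m],
               pair_age = pairs$pair_age[i], stringsAsFactors = FALSE)
  }))
}

#' Sister-pair species richness model
#'
#' Poisson model of richness on the logit-transformed percentage of species
#' with obligate symbionts, pair age and feeding niche, with sister-pair
#' identity and pair nodes (linked to the phylogeny) as random effects.
#'
#' @param pairs table from [sister_pair_table()].
#' @param tree the `phylo` the pairs came from.
#' @param ... chain settings passed to [bpmm()].
#' @return list with `fit` and `summary`.
#' @export
sister_richness_model <- function(pairs, tree, ...) {
  stopifnot(nrow(pairs) >= 20)
  Cfull <- phylo_vcv(tree, include_internal = TRUE)
  nodes <- unique(pairs$node_label)
  Cn <- Cfull[nodes, nodes, drop = FALSE]
  Cn <- Cn / max(diag(Cn))
  niche <- factor(pairs$feeding_niche)
  X <- cbind(`(Intercept)` = 1,
             pct_logit = empirical_logit(pairs$pct_obligate, pairs$n_sampled),
             age = as.vector(scale(pairs$pair_age)))
  if (nlevels(niche) > 1L)
    X <- cbind(X, stats::model.matrix(~niche)[, -1L, drop = FALSE])
  Ip <- diag(length(unique(pairs$pair)))
  rownames(Ip) <- colnames(Ip) <- unique(pairs$pair)
  fit <- bpmm(y = pairs$species_richness, family = "poisson", X = X,
              random = list(pair = bpmm_term(Ip, map = pairs$pair,
                                             structure = "shared"),
                            node = bpmm_term(Cn, map = pairs$node_label,
                                             structure = "shared")),
              ...)
  list(fit = fit, summary = summary(fit))
}

#' Log2 richness-ratio analysis of sister pairs differing in symbiosis
#'
#' Restricts to pairs whose members differ in the percentage of species with
#' obligate symbionts, orients each pair so the higher-percentage family is
#' the numerator, and fits a Gaussian model of `log2(richness ratio)` on the
#' difference in percentage and pair age, with pair nodes linked to the
#' phylogeny as a random effect.
#'
#' @param pairs table from [sister_pair_table()].
#' @param tree the `phylo` the pairs came from.
#' @param ... chain settings passed to [bpmm()].
#' @return list with `fit`, `summary`, and `data` (the oriented per-pair
#'   table).
#' @export
sister_log2_analysis <- function(pairs, tree, ...) {
  sp <- split(pairs, pairs$pair)
  rows <- do.call(rbind, lapply(sp, function(d) {
    if (nrow(d) != 2L || anyNA(d$pct_obligate)) return(NULL)
    if (d$pct_obligate[1L] == d$pct_obligate[2L]) return(NULL)
    hi <- which.max(d$pct_obligate); lo <- 3L - hi
    data.frame(pair = d$pair[1L], node_label = d$node_label[1L],
               log2_ratio = log2(d$species_richness[hi] / d$species_richness[lo]),
               d_pct = d$pct_obligate[hi] - d$pct_obligate[lo],
               pair_age = d$pair_age[1L], stringsAsFactors = FALSE)
  }))
  stopifnot(!is.null(rows), nrow(rows) >= 5)
  Cfull <- phylo_vcv(tree, include_internal = TRUE)
  nodes <- unique(rows$node_label)
  Cn <- Cfull[nodes, nodes, drop = FALSE]
  Cn <- Cn / max(diag(Cn))
  X <- cbind(`(Intercept)` = 1, d_pct = as.vector(scale(rows$d_pct, scale = FALSE)) / 100,
             age = as.vector(scale(rows$pair_age)))
  fit <- bpmm(y = rows$log2_ratio, family = "gaussian", X = X,
              random = list(node = bpmm_term(Cn, map = rows$node_label,
                                             structure = "shared")),
              ...)
  list(fit = fit, summary = summary(fit), data = rows)
}
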