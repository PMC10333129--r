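#' Pipeline configuration
#'
#' Thresholds, chain settings and stage toggles for an end-to-end synthetic
#' run. The single `seed` fans out to per-stage child seeds as
#' `seed + 1009 * stage_index`, so stages can be re-run independently yet
#' reproducibly.
#'
#' @param seed integer master seed.
#' @param sim a [sim_config()].
#' @param obligate_threshold family proportion above which a family is coded
#'   obligate (default 0.5).
#' @param vitamin_quantiles quantile cut-offs for low/high vitamin codings.
#' @param missing_threshold nutrient missingness cut (default 0.30).
#' @param chain list of `n_iter`, `burnin`, `thin`, `n_chains` for BPMM
#'   stages (desk-scale defaults).
#' @param n_maps stochastic character maps per reconstruction.
#' @param stages character vector of stages to run, in order, among
#'   `"synth"`, `"scm"`, `"correlation"`, `"cophylogeny"`, `"diversification"`.
#' @return a config list.
#' @export
pipeline_config <- function(seed = 1L, sim = sim_config(seed = seed),
                            obligate_threshold = 0.5,
                            vitamin_quantiles = c(0.25, 0.5),
                            missing_threshold = 0.30,
                            chain = list(n_iter = 6000, burnin = 1000,
                                         thin = 10, n_chains = 2),
                            n_maps = 200,
                            stages = c("synth", "scm", "correlation",
                                       "cophylogeny", "diversification")) {
  as.list(environment())
}

stage_seed <- function(config, i) (config$seed + 1009L * i) %% .Machine$integer.max

#' Run the synthetic end-to-end pipeline
#'
#' Generates a synthetic dataset with known truth, then runs the requested
#' analysis stages: stochastic-character-map ancestral reconstruction with
#' origin/loss counts, the symbiosis-nutrient phylogenetic correlation,
#' co-phylogenetic ParaFit, and the richness/sister analyses. All artifacts
#' are written as plain-text files into `out_dir` together with a manifest
#' recording seeds, settings and MD5 content hashes.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  artifacts <- character()
  put <- function(obj, file, writer = utils::write.csv) {
    path <- file.path(out_dir, file)
    writer(obj, path)
    artifacts <<- c(artifacts, path)
    path
  }

  set.seed(stage_seed(config, 1L))
  sim <- config$sim
  tree <- sim_tree(sim$n_tips, sim$birth, sim$death, sim$root_age)
  traits <- sim_correlated_traits(tree, r_liab = sim$r_liab_nutrient,
                                  h2 = sim$h2, n_sampled = sim$n_sampled,
                                  missingness = sim$missingness)
  rich <- sim_richness(tree, traits$binary, base = sim$richness_base,
                       age_effect = sim$richness_age_effect,
                       trait_effect = sim$richness_trait_effect,
                       clade_sd = sim$clade_sd)
  hs <- sim_host_symbiont(tree, signal = sim$assoc_signal)
  fam_tab <- data.frame(family = tree$tip.label,
                        n_sampled = traits$n_sampled,
                        n_obligate = traits$n_obligate,
                        rich[match(tree$tip.label, rich$family),
                             c("species_richness", "family_age", "metabolism")],
                        stringsAsFactors = FALSE)
  fam_tab$obligate <- fam_tab$n_obligate / fam_tab$n_sampled > config$obligate_threshold
  fam_tab$feeding_niche <- sample(c("herbivore", "omnivore", "phloem", "predator"),
                                  nrow(fam_tab), replace = TRUE,
                                  prob = c(0.5, 0.2, 0.15, 0.15))
  results$synth <- list(tree = tree, traits = traits, richness = rich,
                        host_symbiont = hs, family_table = fam_tab)
  if ("synth" %in% config$stages) {
    put(fam_tab, "families_analysis.csv", function(x, p) utils::write.csv(x, p, row.names = FALSE))
    put(traits$nutrients, "nutrients.csv")
    writeLines(write_newick(tree), file.path(out_dir, "tree.nwk"))
    artifacts <- c(artifacts, file.path(out_dir, "tree.nwk"))
    write_truth(list(traits = traits$truth, richness = attr(rich, "truth"),
                     host_symbiont = hs$truth), file.path(out_dir, "truth.json"))
    artifacts <- c(artifacts, file.path(out_dir, "truth.json"))
  }

  if ("scm" %in% config$stages) {
    set.seed(stage_seed(config, 2L))
    st <- stats::setNames(ifelse(fam_tab$obligate, "ob", "non"), fam_tab$family)
    qfit <- sample_q_posterior(tree, st, constraint = "all_rates_different",
                               n_iter = 4000, burnin = 1000, thin = 30)
    Qs <- lapply(seq_len(nrow(qfit$draws)), function(i)
      rate_matrix(qfit$states, qfit$draws[i, ], "all_rates_different"))
    maps <- stochastic_maps(tree, st, Qs, n_maps = config$n_maps,
                            branch_histories = FALSE)
    summ <- summarize_node_states(maps)
    assigned <- summ$assigned
    assigned[seq_len(ape::Ntip(tree))] <- st[maps$tree$tip.label]
    trans <- count_state_transitions(maps$tree, assigned, focal = "ob")
    results$scm <- list(q_posterior = qfit, node_summary = summ,
                        origins = trans$origins, losses = trans$losses)
    put(data.frame(node = seq_along(assigned), state = assigned),
        "ancestral_states.csv", function(x, p) utils::write.csv(x, p, row.names = FALSE))
  }

  if ("correlation" %in% config$stages) {
    set.seed(stage_seed(config, 3L))
    nut1 <- traits$nutrients[, 1L]
    y <- cbind(symbiosis = fam_tab$n_obligate, nutrient = z_transform(nut1))
    fit <- bpmm(y = y, family = c("binomial", "gaussian"),
                trials = cbind(fam_tab$n_sampled, 1),
                random = list(phylo = bpmm_term(stats::cov2cor(ape::vcv.phylo(tree)),
                                                map = fam_tab$family,
                                                structure = "unstructured")),
                n_iter = config$chain$n_iter, burnin = config$chain$burnin,
                thin = config$chain$thin, n_chains = config$chain$n_chains)
    corr <- phylo_correlation(fit, "phylo", "symbiosis", "nutrient")
    results$correlation <- list(fit = fit,
                                r_summary = summarize_draws(corr$r_term))
    put(data.frame(t(results$correlation$r_summary)), "phylo_correlation.csv",
        function(x, p) utils::write.csv(x, p, row.names = FALSE))
  }

  if ("cophylogeny" %in% config$stages) {
    set.seed(stage_seed(config, 4L))
    pf <- parafit_global(tree, hs$symbiont_tree, hs$A, n_perm = 499)
    results$cophylogeny <- pf
    write_truth(pf[c("statistic", "p_value", "n_perm")],
                file.path(out_dir, "parafit.json"))
    artifacts <- c(artifacts, file.path(out_dir, "parafit.json"))
  }

  if ("diversification" %in% config$stages) {
    set.seed(stage_seed(config, 5L))
    pairs <- sister_pair_table(tree, fam_tab)
    results$diversification <- list(n_pairs = nrow(pairs) / 2L, pairs = pairs)
    put(pairs, "sisters.csv", function(x, p) utils::write.csv(x, p, row.names = FALSE))
  }

  manifest <- list(seed = config$seed, stages = config$stages,
                   settings = config[c("obligate_threshold", "vitamin_quantiles",
                                       "missing_threshold", "chain", "n_maps")],
                   files = lapply(stats::setNames(nm = basename(artifacts)),
                                  function(f) unname(tools::md5sum(file.path(out_dir, f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  results$out_dir <- out_dir
  invisible(results)
}

#' Sensitivity harness: re-run key analyses under data-subset variants
#'
#' Each variant filters the family table (and prunes the tree accordingly)
#' or switches the vitamin quantile threshold, re-runs the
#' symbiosis-nutrient correlation, and collects the key estimate so
#' robustness of the qualitative conclusion can be compared across variants.
#'
#' @param config a [pipeline_config()].
#' @param variants named list; each element is either a predicate
#'   `function(family_table) logical_rows` or the string `"quantile25"`.
#' @return data.frame: variant, families retained, posterior mode / CI /
#'   pMCMC of the phylogenetic correlation.
#' @export
sensitivity_harness <- function(config = pipeline_config(),
                                variants = list(all = function(tab) rep(TRUE, nrow(tab)))) {
  set.seed(stage_seed(config, 1L))
  sim <- config$sim
  tree <- sim_tree(sim$n_tips, sim$birth, sim$death, sim$root_age)
  traits <- sim_correlated_traits(tree, r_liab = sim$r_liab_nutrient,
                                  h2 = sim$h2, n_sampled = sim$n_sampled,
                                  missingness = sim$missingness)
  tab <- data.frame(family = tree$tip.label, n_sampled = traits$n_sampled,
                    n_obligate = traits$n_obligate,
                    nutrient = traits$nutrients[, 1L], stringsAsFactors = FALSE)
  out <- NULL
  for (vn in names(variants)) {
    v <- variants[[vn]]
    keep <- if (is.function(v)) v(tab) else rep(TRUE, nrow(tab))
    if (sum(keep) < 10L) {
      warning("variant '", vn, "' leaves fewer than 10 families; skipped")
      next
    }
    sub <- tab[keep, , drop = FALSE]
    tr <- ape::keep.tip(tree, sub$family)
    set.seed(stage_seed(config, 7L))
    fit <- bpmm(y = cbind(symbiosis = sub$n_obligate,
                          nutrient = z_transform(sub$nutrient)),
                family = c("binomial", "gaussian"),
                trials = cbind(sub$n_sampled, 1),
                random = list(phylo = bpmm_term(stats::cov2cor(ape::vcv.phylo(tr)),
                                                map = sub$family,
                                                structure = "unstructured")),
                n_iter = config$chain$n_iter, burnin = config$chain$burnin,
                thin = config$chain$thin, n_chains = config$chain$n_chains)
    s <- summarize_draws(phylo_correlation(fit, "phylo", 1, 2)$r_term)
    out <- rbind(out, data.frame(variant = vn, n_families = sum(keep), t(s)))
  }
  rownames(out) <- NULL
  out
}
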