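test_that("posterior summaries follow the pMCMC and HPD conventions", {
  expect_equal(pmcmc(rep(1, 1000)), 2 / 1001)
  expect_equal(pmcmc(c(-1, 1, -2, 2)), 1)
  s <- summarize_draws(c(1, 2, 3))
  expect_equal(unname(s["lower"]), 1)
  expect_equal(unname(s["upper"]), 3)
  expect_true(s["mode"] >= 1 && s["mode"] <= 3)
  expect_equal(hpd_interval(stats::qnorm(seq(0.0005, 0.9995, length.out = 2000))),
               c(-1.96, 1.96), tolerance = 0.05)
})

test_that("the Gaussian conjugate case matches the closed-form posterior", {
  set.seed(30)
  y <- stats::rnorm(40, 0, 1.5)
  fit <- bpmm(y = y, family = "gaussian", X = matrix(0, 40, 1),
              n_iter = 6000, burnin = 1000, thin = 1, n_chains = 1)
  nu <- 0.002; V <- 1
  Fx <- function(s2) 1 - stats::pgamma(1 / s2, (nu + 40) / 2, (nu * V + sum(y^2)) / 2)
  ks <- suppressWarnings(stats::ks.test(fit$draws$R[, 1], Fx)$statistic)
  expect_lt(unname(ks), 0.05)
})

test_that("binomial intercept-only model centres at the observed logit", {
  set.seed(31)
  # all families 5 of 10: latent intercept should sit near logit(0.5) = 0
  fit <- bpmm(y = rep(5, 60), family = "binomial", trials = 10,
              n_iter = 4000, burnin = 1000, thin = 3, n_chains = 1)
  s <- summarize_draws(fit$draws$beta[, 1])
  expect_lt(abs(s["mean"]), 0.25)
  expect_gt(s["pMCMC"], 0.05)
})

test_that("ICC and correlation draws obey their algebraic definitions", {
  p <- 2
  fake <- structure(list(
    draws = list(G = list(phylo = cbind(`a.a` = c(1, 3), `b.a` = c(0.5, 0),
                                        `a.b` = c(0.5, 0), `b.b` = c(1, 1))),
                 R = cbind(`a.a` = c(1, 1), `b.a` = 0, `a.b` = 0, `b.b` = c(1, 1))),
    term_names = "phylo", responses = c("a", "b"),
    family = c("binomial", "gaussian"), r_structure = "unstructured",
    terms = list(list(structure = "unstructured"))), class = "bpmm")
  icc_a <- variance_partition(fake, "phylo", 1)
  expect_equal(icc_a[1], 1 / (2 + pi^2 / 3))   # logit link variance added
  icc_b <- variance_partition(fake, "phylo", 2)
  expect_equal(icc_b[2], 1 / 2)               # gaussian: no link variance
  r <- phylo_correlation(fake, "phylo", 1, 2)
  expect_equal(r$r_term, c(0.5, 0))
  fake$terms[[1]]$structure <- "shared"
  expect_error(phylo_correlation(fake, "phylo"), "shared")
})

test_that("ICC and correlations stay in bounds for every draw of a real fit", {
  set.seed(32)
  tr <- sim_tree(40, 1, 0, 1)
  s <- sim_correlated_traits(tr, r_liab = -0.4, h2 = 0.8, missingness = 0)
  fit <- fit_bivariate_gauss(tr, cbind(a = s$liability, b = s$nutrients[, 1]),
                             n_iter = 1200, burnin = 200, thin = 2)
  icc <- variance_partition(fit, "phylo", 1)
  expect_true(all(icc >= 0 & icc <= 1))
  r <- phylo_correlation(fit, "phylo", 1, 2)$r_term
  expect_true(all(r >= -1 & r <= 1))
  # unstructured G draws are PSD (2x2: positive diagonal, det >= 0)
  g <- fit$draws$G$phylo
  expect_true(all(g[, "a.a"] > 0 & g[, "b.b"] > 0))
  expect_true(all(g[, "a.a"] * g[, "b.b"] - g[, "a.b"]^2 >= -1e-10))
})

test_that("masking a fifth of a Gaussian response barely moves fixed effects", {
  set.seed(33)
  tr <- sim_tree(80, 1, 0, 1)
  s <- sim_correlated_traits(tr, r_liab = -0.6, h2 = 0.8, missingness = 0)
  y_full <- cbind(a = s$liability, b = s$nutrients[, 1])
  y_mask <- y_full
  y_mask[sample(80, 16), "b"] <- NA
  f1 <- fit_bivariate_gauss(tr, y_full, n_iter = 2000, burnin = 500, thin = 2)
  f2 <- fit_bivariate_gauss(tr, y_mask, n_iter = 2000, burnin = 500, thin = 2)
  for (j in 1:2) {
    m1 <- mean(f1$draws$beta[, j]); m2 <- mean(f2$draws$beta[, j])
    expect_lt(abs(m1 - m2), 0.5 * stats::sd(f1$draws$beta[, j]) + 0.05)
  }
})

test_that("node predictions reduce to the intercept on a star tree and krige exactly", {
  set.seed(34)
  star <- ape::stree(6, "star")
  star$edge.length <- rep(1, 6)
  C <- ape::vcv.phylo(star)
  yb <- stats::rbinom(6, 10, 0.7)
  fit <- bpmm(y = yb, family = "binomial", trials = 10,
              random = list(phylo = bpmm_term(C, map = star$tip.label,
                                              structure = "shared")),
              n_iter = 1500, burnin = 500, thin = 5, n_chains = 1)
  pred <- predict_nodes(fit, star, "phylo", conditional_mean = TRUE)
  # the star root shares no path with any tip: prediction = plogis(intercept)
  expect_equal(unname(pred$draws[, 1, 1]),
               unname(stats::plogis(fit$draws$beta[, 1])), tolerance = 1e-10)
  # kriging identity on a structured tree
  tr <- sim_tree(5, 1, 0, 1)
  C5 <- ape::vcv.phylo(tr)
  fit5 <- bpmm(y = stats::rnorm(5), family = "gaussian",
               random = list(phylo = bpmm_term(C5, map = tr$tip.label,
                                               structure = "shared")),
               n_iter = 400, burnin = 100, thin = 10, n_chains = 1)
  pred5 <- predict_nodes(fit5, tr, "phylo", conditional_mean = TRUE)
  Cf <- phylo_vcv(tr, include_internal = TRUE)
  nodes <- setdiff(rownames(Cf), tr$tip.label)
  K <- Cf[nodes, tr$tip.label] %*% solve(Cf[tr$tip.label, tr$tip.label])
  k <- 2
  manual <- as.vector(K %*% fit5$draws$U$phylo[k, , 1]) + fit5$draws$beta[k, 1]
  expect_equal(unname(pred5$draws[k, , 1]), manual, tolerance = 1e-8)
  # monotonicity: all-obligate tips push the root above 0.5
  yb1 <- rep(10, 6)
  fit1 <- bpmm(y = yb1, family = "binomial", trials = 10,
               random = list(phylo = bpmm_term(C, map = star$tip.label,
                                               structure = "shared")),
               n_iter = 1500, burnin = 500, thin = 5, n_chains = 1)
  p1 <- predict_nodes(fit1, star, "phylo")
  expect_true(all(p1$mean > 0.5))
})

test_that("convergence diagnostics match coda and flag separated chains", {
  set.seed(35)
  x <- matrix(stats::rnorm(1000), dimnames = list(NULL, "p"))
  same <- gelman_rubin(list(x, x))
  expect_equal(unname(same$psrf), 1, tolerance = 2e-3)
  far <- gelman_rubin(list(x, x + 5))
  expect_gt(unname(far$psrf), 1.1)
  expect_false(far$converged)
  # white noise: ESS within 20% of the chain length
  ess <- gelman_rubin(list(x))$ess
  expect_gt(unname(ess), 800)
  expect_lt(unname(ess), 1200)
  # against coda
  ml <- coda::mcmc.list(coda::mcmc(x), coda::mcmc(x + 0.1))
  g <- coda::gelman.diag(ml)$psrf[1, 1]
  mine <- gelman_rubin(list(x, x + 0.1))$psrf
  expect_equal(unname(mine), unname(g), tolerance = 0.05)
  single <- gelman_rubin(list(x))
  expect_true(is.na(single$psrf))
})

test_that("multi-chain fits expose per-chain draws for diagnostics", {
  set.seed(36)
  tr <- sim_tree(25, 1, 0, 1)
  s <- sim_correlated_traits(tr, missingness = 0)
  C <- stats::cov2cor(ape::vcv.phylo(tr))
  fit <- bpmm(y = s$nutrients[, 1], family = "gaussian",
              random = list(phylo = bpmm_term(C, map = tr$tip.label,
                                              structure = "shared")),
              n_iter = 1000, burnin = 200, thin = 4, n_chains = 2)
  expect_equal(length(fit$chains), 2L)
  gr <- gelman_rubin(fit$chains)
  expect_true(all(is.finite(gr$psrf)))
  expect_equal(nrow(fit$draws$beta), 2 * 200)
  sm <- summary(fit)
  expect_true(all(c("fixed", "variance", "icc") %in% names(sm)))
})
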