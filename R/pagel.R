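PAGEL_STATES <- c("00", "01", "10", "11")

#' Names of the free rates of the paired-trait models
#' @param model `"independent"` (4 rates) or `"dependent"` (8 rates).
#' @return character vector of rate names.
#' @export
pagel_rate_names <- function(model = c("independent", "dependent")) {
  model <- match.arg(model)
  if (model == "independent")
    c("t1_01", "t1_10", "t2_01", "t2_10")
  else
    c("t1_01.t2=0", "t1_01.t2=1", "t1_10.t2=0", "t1_10.t2=1",
      "t2_01.t1=0", "t2_01.t1=1", "t2_10.t1=0", "t2_10.t1=1")
}

#' Generator of the 4-state chain for two binary traits
#'
#' Combined states are `00, 01, 10, 11` (trait1 then trait2). Only one trait
#' may change at a time: dual transitions have rate exactly 0. Under the
#' independent model each trait's gain/loss rate ignores the other trait's
#' state; the dependent model lets every rate depend on the background
#' state.
#'
#' @param rates named (or positionally ordered per [pagel_rate_names()])
#'   non-negative rates.
#' @param model `"independent"` or `"dependent"`.
#' @return 4 x 4 generator with zero row sums.
#' @export
pagel_generator <- function(rates, model = c("independent", "dependent")) {
  model <- match.arg(model)
  nm <- pagel_rate_names(model)
  stopifnot(length(rates) == length(nm), all(rates >= 0))
  r <- stats::setNames(as.numeric(rates), nm)
  g <- function(x) if (model == "independent") r[[substr(x, 1L, 5L)]] else r[[x]]
  Q <- matrix(0, 4, 4, dimnames = list(PAGEL_STATES, PAGEL_STATES))
  if (model == "independent") {
    Q["00", "10"] <- r[["t1_01"]]; Q["01", "11"] <- r[["t1_01"]]
    Q["10", "00"] <- r[["t1_10"]]; Q["11", "01"] <- r[["t1_10"]]
    Q["00", "01"] <- r[["t2_01"]]; Q["10", "11"] <- r[["t2_01"]]
    Q["01", "00"] <- r[["t2_10"]]; Q["11", "10"] <- r[["t2_10"]]
  } else {
    Q["00", "10"] <- r[["t1_01.t2=0"]]; Q["01", "11"] <- r[["t1_01.t2=1"]]
    Q["10", "00"] <- r[["t1_10.t2=0"]]; Q["11", "01"] <- r[["t1_10.t2=1"]]
    Q["00", "01"] <- r[["t2_01.t1=0"]]; Q["10", "11"] <- r[["t2_01.t1=1"]]
    Q["01", "00"] <- r[["t2_10.t1=0"]]; Q["11", "10"] <- r[["t2_10.t1=1"]]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Combine two binary tip vectors into 4-state labels
#' @param x1,x2 named 0/1 vectors over the same tips.
#' @return named character vector of combined states.
#' @export
pagel_tip_states <- function(x1, x2) {
  stopifnot(!is.null(names(x1)), setequal(names(x1), names(x2)))
  x2 <- x2[names(x1)]
  stats::setNames(paste0(as.integer(x1), as.integer(x2)), names(x1))
}

#' Log-likelihood of the paired-trait model
#'
#' @param tree a `phylo`.
#' @param x1,x2 named 0/1 tip vectors.
#' @param rates free rates (see [pagel_rate_names()]).
#' @param model `"independent"` or `"dependent"`.
#' @param root_prior root state prior over the 4 combined states.
#' @return log-likelihood.
#' @export
paired_loglik <- function(tree, x1, x2, rates, model = c("independent", "dependent"),
                          root_prior = "uniform") {
  Q <- pagel_generator(rates, model)
  mk_loglik(tree, pagel_tip_states(x1, x2), Q, root_prior)
}

# Joint hyper-prior density: rates ~ Exp(mean m), m ~ U(0, hyper_max).
pagel_logprior <- function(lr, lm, hyper_max) {
  m <- exp(lm)
  if (m <= 0 || m >= hyper_max) return(-Inf)
  # log-scale Jacobians for rates and for m
  sum(stats::dexp(exp(lr), 1 / m, log = TRUE) + lr) - log(hyper_max) + lm
}

#' MCMC over paired-trait transition rates under the exponential hyper-prior
#'
#' Rates get independent exponential priors whose mean is itself uniform on
#' (0, `hyper_max`); proposals are multiplicative log-normal random walks
#' adapted during burn-in. Three chains are run by default.
#'
#' @inheritParams paired_loglik
#' @param n_iter,burnin,thin per-chain settings (desk-scale defaults).
#' @param n_chains number of independent chains (default 3).
#' @param hyper_max upper bound of the uniform hyper-prior (default 10).
#' @param prior_only drop the likelihood (prior-predictive check).
#' @return list with `draws` (pooled matrix over chains: rates,
#'   `hyper_mean`, `loglik`), `chains` (list of per-chain matrices),
#'   `accept`, `model`.
#' @export
fit_paired_mcmc <- function(tree, x1, x2, model = c("independent", "dependent"),
                            n_iter = 50000, burnin = 10000, thin = 40,
                            n_chains = 3, hyper_max = 10, root_prior = "uniform",
                            prior_only = FALSE) {
  model <- match.arg(model)
  if (length(unique(x1)) < 2L || length(unique(x2)) < 2L)
    stop("both traits must vary across tips")
  nm <- pagel_rate_names(model)
  nr <- length(nm)
  prep <- mk_prep(tree, pagel_tip_states(x1, x2), PAGEL_STATES)
  rp <- root_prior_vec(root_prior, pagel_generator(rep(1, nr), model))
  ll_fun <- function(lr) {
    if (prior_only) return(0)
    mk_loglik_cpp(prep$edge, prep$elen, prep$ntip, prep$nnode, prep$tipL,
                  unname(pagel_generator(exp(lr), model)), rp)
  }
  run_chain <- function() {
    lr <- stats::rnorm(nr, log(0.5), 0.3)
    lm <- log(stats::runif(1, 0.2, hyper_max / 2))
    cur_ll <- ll_fun(lr)
    cur_lp <- pagel_logprior(lr, lm, hyper_max)
    step <- rep(0.6, nr + 1L)
    keep <- floor((n_iter - burnin) / thin)
    out <- matrix(NA_real_, keep, nr + 2L,
                  dimnames = list(NULL, c(nm, "hyper_mean", "loglik")))
    acc <- numeric(nr + 1L); tries <- numeric(nr + 1L); kept <- 0L
    for (it in seq_len(n_iter)) {
      j <- ((it - 1L) %% (nr + 1L)) + 1L
      plr <- lr; plm <- lm
      if (j <= nr) plr[j] <- plr[j] + stats::rnorm(1, 0, step[j])
      else plm <- plm + stats::rnorm(1, 0, step[j])
      new_lp <- pagel_logprior(plr, plm, hyper_max)
      tries[j] <- tries[j] + 1
      if (is.finite(new_lp)) {
        new_ll <- if (j <= nr) ll_fun(plr) else cur_ll
        if (is.finite(new_ll) &&
            log(stats::runif(1)) < (new_ll + new_lp) - (cur_ll + cur_lp)) {
          lr <- plr; lm <- plm; cur_ll <- new_ll; cur_lp <- new_lp
          acc[j] <- acc[j] + 1
        }
      }
      if (it <= burnin && it %% 200L == 0L) {
        r <- acc / pmax(tries, 1)
        step <- step * ifelse(r > 0.4, 1.25, ifelse(r < 0.2, 0.8, 1))
        acc[] <- 0; tries[] <- 0
      }
      if (it > burnin && (it - burnin) %% thin == 0L) {
        kept <- kept + 1L
        out[kept, ] <- c(exp(lr), exp(lm), cur_ll)
      }
    }
    list(draws = out, accept = sum(acc) / max(sum(tries), 1))
  }
  chains <- lapply(seq_len(n_chains), function(i) run_chain())
  list(draws = do.call(rbind, lapply(chains, `[[`, "draws")),
       chains = lapply(chains, `[[`, "draws"),
       accept = mean(vapply(chains, `[[`, numeric(1), "accept")),
       model = model)
}

#' Stepping-stone estimate of a log marginal likelihood
#'
#' Runs a random-walk Metropolis sampler through a path of power posteriors
#' `prior x likelihood^beta` with temperatures at quantiles of
#' Beta(`beta_shape`, 1), warm-starting each stone from the previous one, and
#' combines per-stone likelihood samples into the stepping-stone estimator.
#' Works for any model expressed through `loglik` and `logprior` over an
#' unconstrained parameter vector (supply log-scale Jacobians inside
#' `logprior`).
#'
#' @param loglik,logprior functions of the parameter vector.
#' @param init initial parameter vector.
#' @param n_stones number of stones (default 100).
#' @param iters iterations per stone (default 1000).
#' @param burnin_first extra burn-in before the first stone.
#' @param rw_sd random-walk proposal sd (scalar or per-parameter), adapted.
#' @param beta_shape shape of the Beta(.,1) temperature ladder (default 0.3).
#' @return list with `lnml`, `per_stone` (data.frame: beta, mean log-lik,
#'   contribution, acceptance, ess).
#' @export
stepping_stone_lnml <- function(loglik, logprior, init, n_stones = 100,
                                iters = 1000, burnin_first = 500, rw_sd = 0.5,
                                beta_shape = 0.3) {
  p <- length(init)
  betas <- (seq(0, n_stones) / n_stones)^(1 / beta_shape)
  theta <- init
  cur_ll <- loglik(theta); cur_lp <- logprior(theta)
  if (!is.finite(cur_lp)) stop("init has zero prior density")
  step <- rep_len(rw_sd, p)
  contrib <- numeric(n_stones)
  stone_stats <- vector("list", n_stones)
  for (s in seq_len(n_stones)) {
    b <- betas[s]; b_next <- betas[s + 1L]
    nit <- iters + if (s == 1L) burnin_first else 0L
    lls <- numeric(iters)
    acc <- 0L; tries <- 0L; kept <- 0L
    for (it in seq_len(nit)) {
      j <- ((it - 1L) %% p) + 1L
      prop <- theta
      prop[j] <- prop[j] + stats::rnorm(1, 0, step[j])
      new_lp <- logprior(prop)
      tries <- tries + 1L
      if (is.finite(new_lp)) {
        new_ll <- loglik(prop)
        if (is.finite(new_ll) &&
            log(stats::runif(1)) < (b * new_ll + new_lp) - (b * cur_ll + cur_lp)) {
          theta <- prop; cur_ll <- new_ll; cur_lp <- new_lp
          acc <- acc + 1L
        }
      }
      if (it %% 100L == 0L) {
        r <- acc / tries
        step <- step * if (r > 0.4) 1.25 else if (r < 0.2) 0.8 else 1
        acc <- 0L; tries <- 0L
      }
      if (it > nit - iters) {
        kept <- kept + 1L
        lls[kept] <- cur_ll
      }
    }
    if (any(!is.finite(lls))) stop("non-finite likelihood samples at stone ", s)
    d <- (b_next - b) * lls
    m <- max(d)
    contrib[s] <- m + log(mean(exp(d - m)))
    stone_stats[[s]] <- data.frame(beta = b, mean_ll = mean(lls),
                                   contribution = contrib[s],
                                   ess = gelman_rubin(matrix(lls))$ess)
  }
  list(lnml = sum(contrib), per_stone = do.call(rbind, stone_stats))
}

#' Stepping-stone log marginal likelihood of a paired-trait model
#'
#' @inheritParams fit_paired_mcmc
#' @param n_stones,iters stepping-stone settings (paper-scale default
#'   100 x 1000).
#' @return list as from [stepping_stone_lnml()] plus `model`.
#' @export
pagel_lnml <- function(tree, x1, x2, model = c("independent", "dependent"),
                       n_stones = 100, iters = 1000, hyper_max = 10,
                       root_prior = "uniform") {
  model <- match.arg(model)
  nm <- pagel_rate_names(model)
  nr <- length(nm)
  prep <- mk_prep(tree, pagel_tip_states(x1, x2), PAGEL_STATES)
  rp <- root_prior_vec(root_prior, pagel_generator(rep(1, nr), model))
  ll <- function(th) mk_loglik_cpp(prep$edge, prep$elen, prep$ntip, prep$nnode,
                                   prep$tipL,
                                   unname(pagel_generator(exp(th[seq_len(nr)]), model)),
                                   rp)
  lp <- function(th) pagel_logprior(th[seq_len(nr)], th[nr + 1L], hyper_max)
  res <- stepping_stone_lnml(ll, lp, init = c(rep(log(0.5), nr), log(1)),
                             n_stones = n_stones, iters = iters)
  res$model <- model
  res
}

#' Bayes factor and evidence category from two log marginal likelihoods
#'
#' `BF = 2 (lnML_complex - lnML_simple)`; over 2 counts as positive
#' evidence, over 5 strong, over 10 very strong.
#'
#' @param lnml_complex,lnml_simple log marginal likelihoods (nats).
#' @return list with `lnml_dependent`, `lnml_independent`, `bayes_factor`,
#'   `category`.
#' @export
bayes_factor <- function(lnml_complex, lnml_simple) {
  stopifnot(is.finite(lnml_complex), is.finite(lnml_simple))
  bf <- 2 * (lnml_complex - lnml_simple)
  cat <- if (bf > 10) "very strong" else if (bf > 5) "strong" else
    if (bf > 2) "positive" else "none"
  list(lnml_dependent = lnml_complex, lnml_independent = lnml_simple,
       bayes_factor = bf, category = cat)
}

#' Posterior contrast between two transition rates
#'
#' @param chain draws matrix from [fit_paired_mcmc()] (`$draws`).
#' @param rate_a,rate_b column names.
#' @return named numeric: mode, mean, lower, upper, pMCMC of `a - b`.
#' @export
rate_contrast <- function(chain, rate_a, rate_b) {
  stopifnot(rate_a %in% colnames(chain), rate_b %in% colnames(chain))
  summarize_draws(chain[, rate_a] - chain[, rate_b])
}
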