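#' Define a covariance-structured random term for [bpmm()]
#'
#' @param C covariance matrix over term levels (rownames = level labels);
#'   use an identity matrix for iid terms.
#' @param map character/factor of length n assigning data rows to levels;
#'   `NULL` means rows are the levels in `rownames(C)` order.
#' @param structure `"unstructured"` (full across-response covariance) or
#'   `"shared"` (independent per-response variances, no covariance).
#' @return a term definition list.
#' @export
bpmm_term <- function(C, map = NULL, structure = c("unstructured", "shared")) {
  structure <- match.arg(structure)
  if (is.null(rownames(C))) rownames(C) <- colnames(C) <- paste0("L", seq_len(nrow(C)))
  list(C = C, map = map, structure = structure)
}

#' Prior settings for [bpmm()]
#'
#' Variance matrices get inverse-Wishart priors in the (V, nu)
#' parameterization (scale `nu * V`, degrees of freedom `nu`); defaults are
#' `V = diag(p)`, `nu = p - 1 + 0.002`. Fixed effects get independent normal
#' priors with mean 0; binomial responses default to variance
#' `fixed residual + pi^2/3`, which is approximately flat on the probability
#' scale under a logit link, all others to 1e10.
#'
#' @param G_V,G_nu prior for random-term covariances (recycled over terms).
#' @param R_V,R_nu prior for the residual covariance.
#' @param beta_V fixed-effect prior variance; `NULL` = per-family default.
#' @return a prior definition list.
#' @export
bpmm_prior <- function(G_V = NULL, G_nu = NULL, R_V = NULL, R_nu = NULL,
                       beta_V = NULL) {
  list(G_V = G_V, G_nu = G_nu, R_V = R_V, R_nu = R_nu, beta_V = beta_V)
}

init_liability <- function(y, family, trials) {
  l <- y
  for (j in seq_along(family)) {
    if (family[j] == "binomial")
      l[, j] <- stats::qlogis((y[, j] + 0.5) / (trials[, j] + 1))
    else if (family[j] == "poisson")
      l[, j] <- log(y[, j] + 0.5)
  }
  l[is.na(l)] <- 0
  l
}

riwish <- function(nu, S) {
  # G^{-1} ~ Wishart(S^{-1}, nu)
  p <- nrow(S)
  W <- stats::rWishart(1L, nu, solve(S))[, , 1L]
  solve((W + t(W)) / 2)
}

#' Bayesian phylogenetic mixed model (single or multi-response)
#'
#' MCMC sampler for Gaussian, binomial (logit) and Poisson (log) responses
#' with covariance-structured random effects. All responses are represented
#' through latent liabilities: Gaussian observations are their own liability,
#' missing Gaussian cells are imputed by data augmentation, and binomial /
#' Poisson cells carry Metropolis-updated liabilities. Random effects and
#' (co)variance matrices get conjugate Gibbs updates; terms whose levels
#' balance the data (e.g. one row per tip) are updated in the eigenbasis of
#' their covariance, giving O(n) per-sweep cost.
#'
#' Each response receives its own coefficients for every column of `X`
#' (trait-specific intercepts; no global intercept).
#'
#' @param y numeric response matrix (n x p) or vector; `NA` allowed (Gaussian
#'   cells are imputed, non-Gaussian `NA` cells are treated as unobserved).
#' @param family character vector over responses: `"gaussian"`,
#'   `"binomial"`, `"poisson"`.
#' @param X fixed-effect design matrix (n x q); default intercept-only.
#' @param trials binomial trial counts (vector or n x p matrix).
#' @param random named list of [bpmm_term()] definitions.
#' @param r_structure residual structure: `"unstructured"` (full
#'   inverse-Wishart) or `"diagonal"`; defaults to unstructured for
#'   all-Gaussian models and diagonal otherwise.
#' @param fix_residual named numeric of residual variances to fix (diagonal
#'   structure only); binomial responses default to 1 (their residual is not
#'   identifiable on the latent scale).
#' @param prior a [bpmm_prior()].
#' @param n_iter,burnin,thin,n_chains chain settings (desk-scale defaults
#'   60,000 / 10,000 / 50 / 3).
#' @param verbose print progress.
#' @return an object of class `bpmm` with pooled `draws` (`beta`, `G` per
#'   term, `R`, `U` effect draws per term, `liab_mean`), per-chain parameter
#'   matrices in `chains`, and metadata.
#' @export
bpmm <- function(y, family = "gaussian", X = NULL, trials = NULL,
                 random = list(), r_structure = NULL, fix_residual = NULL,
                 prior = bpmm_prior(), n_iter = 60000, burnin = 10000,
                 thin = 50, n_chains = 3, verbose = FALSE) {
  if (is.null(dim(y))) y <- matrix(y, ncol = 1L,
                                   dimnames = list(names(y), "y"))
  y <- as.matrix(y)
  n <- nrow(y); p <- ncol(y)
  if (is.null(colnames(y))) colnames(y) <- paste0("trait", seq_len(p))
  resp <- colnames(y)
  family <- rep_len(family, p)
  stopifnot(all(family %in% c("gaussian", "binomial", "poisson")))
  if (is.null(X)) X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  q <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(q))
  if (is.null(trials)) trials <- matrix(1, n, p)
  if (is.null(dim(trials))) trials <- matrix(trials, n, p)
  if (nrow(trials) == 1L && n > 1L) trials <- matrix(trials, n, p, byrow = TRUE)

  if (is.null(r_structure))
    r_structure <- if (all(family == "gaussian") && p > 1L) "unstructured" else "diagonal"
  r_structure <- match.arg(r_structure, c("unstructured", "diagonal"))
  rfix <- rep(NA_real_, p); names(rfix) <- resp
  if (r_structure == "diagonal")
    rfix[family == "binomial"] <- 1
  if (!is.null(fix_residual)) {
    if (r_structure == "unstructured") stop("fix_residual requires diagonal residual structure")
    rfix[names(fix_residual)] <- fix_residual
  }

  # term preprocessing: eigendecomposition + level mapping
  terms <- lapply(random, function(tm) {
    C <- tm$C
    L <- nrow(C)
    map <- tm$map
    zi <- if (is.null(map)) seq_len(n) else match(as.character(map), rownames(C))
    if (is.null(map) && L != n) stop("term without map must have one level per row")
    if (anyNA(zi)) stop("term map has levels absent from C: ",
                        paste(unique(as.character(map)[is.na(zi)]), collapse = ", "))
    eg <- eigen((C + t(C)) / 2, symmetric = TRUE)
    d <- pmax(eg$values, 1e-10)
    cnt <- tabulate(zi, L)
    list(E = eg$vectors, d = d, zi = zi, L = L, cnt = cnt,
         fast = length(unique(cnt)) == 1L && cnt[1L] >= 1L,
         Cinv = if (length(unique(cnt)) > 1L || cnt[1L] < 1L)
           eg$vectors %*% (t(eg$vectors) / d) else NULL,
         structure = tm$structure, levels = rownames(C))
  })
  nt <- length(terms)

  # priors
  GV <- prior$G_V; Gnu <- prior$G_nu
  if (is.null(GV)) GV <- diag(p)
  if (is.null(Gnu)) Gnu <- p - 1 + 0.002
  RV <- if (is.null(prior$R_V)) diag(p) else prior$R_V
  Rnu <- if (is.null(prior$R_nu)) p - 1 + 0.002 else prior$R_nu
  bV <- prior$beta_V
  if (is.null(bV)) {
    bV <- ifelse(family == "binomial",
                 ifelse(is.na(rfix), 1, rfix) + pi^2 / 3, 1e10)
  }
  bV <- rep_len(bV, p) # per response, recycled over coefficients

  gauss_obs <- sweep(!is.na(y), 2L, family == "gaussian", `&`)
  latent_mask <- !gauss_obs # cells whose liability is sampled

  keep_per <- floor((n_iter - burnin) / thin)
  if (keep_per < 1L) stop("n_iter/burnin/thin leave no retained draws")

  run_chain <- function(chain_id) {
    l <- init_liability(y, family, trials)
    B <- matrix(0, q, p)
    U <- lapply(terms, function(tm) matrix(0, tm$L, p))
    G <- lapply(seq_len(nt), function(i) diag(p) * 0.5 + 0.01)
    R <- diag(p)
    if (r_structure == "diagonal") diag(R) <- ifelse(is.na(rfix), 1, rfix)
    mh_step <- matrix(0.8, n, p)
    draws <- list(
      beta = matrix(NA_real_, keep_per, q * p),
      G = lapply(seq_len(nt), function(i) matrix(NA_real_, keep_per, p * p)),
      R = matrix(NA_real_, keep_per, p * p),
      U = lapply(terms, function(tm) array(NA_real_, c(keep_per, tm$L, p)))
    )
    kept <- 0L
    for (it in seq_len(n_iter)) {
      Rinv <- solve(R)
      # --- fixed effects ---
      r2 <- l
      for (t in seq_len(nt)) r2 <- r2 - U[[t]][terms[[t]]$zi, , drop = FALSE]
      XtX <- crossprod(X)
      Om <- kronecker(XtX, Rinv) + diag(rep(1 / bV, q), q * p)
      b <- as.vector(t((crossprod(X, r2)) %*% Rinv))
      ch <- chol(Om)
      mu_b <- backsolve(ch, forwardsolve(t(ch), b))
      xb <- mu_b + backsolve(ch, stats::rnorm(q * p))
      B <- t(matrix(xb, p, q))
      # --- random effects ---
      for (t in seq_len(nt)) {
        tm <- terms[[t]]
        res <- l - X %*% B
        for (s in setdiff(seq_len(nt), t))
          res <- res - U[[s]][terms[[s]]$zi, , drop = FALSE]
        M <- rowsum(res, group = tm$zi, reorder = FALSE)
        # rowsum drops empty levels; rebuild full L x p
        Mi <- matrix(0, tm$L, p)
        Mi[as.integer(rownames(M)), ] <- M
        Ginv <- solve(G[[t]])
        if (tm$fast) {
          cc <- tm$cnt[1L]
          Mt <- crossprod(tm$E, Mi) # E' Z'res
          if (p == 1L) {
            v <- 1 / (1 / (tm$d * G[[t]][1L, 1L]) + cc * Rinv[1L, 1L])
            tt <- v * (Mt[, 1L] * Rinv[1L, 1L]) + sqrt(v) * stats::rnorm(tm$L)
            U[[t]] <- tm$E %*% cbind(tt)
          } else if (p == 2L) {
            a_ <- Ginv[1, 1] / tm$d + cc * Rinv[1, 1]
            b_ <- Ginv[1, 2] / tm$d + cc * Rinv[1, 2]
            c_ <- Ginv[2, 2] / tm$d + cc * Rinv[2, 2]
            b1 <- Rinv[1, 1] * Mt[, 1L] + Rinv[1, 2] * Mt[, 2L]
            b2 <- Rinv[1, 2] * Mt[, 1L] + Rinv[2, 2] * Mt[, 2L]
            det_ <- a_ * c_ - b_^2
            s11 <- c_ / det_; s22 <- a_ / det_; s12 <- -b_ / det_
            m1 <- s11 * b1 + s12 * b2
            m2 <- s12 * b1 + s22 * b2
            L11 <- sqrt(s11); L21 <- s12 / L11
            L22 <- sqrt(pmax(s22 - L21^2, 1e-12))
            z1 <- stats::rnorm(tm$L); z2 <- stats::rnorm(tm$L)
            U[[t]] <- tm$E %*% cbind(m1 + L11 * z1, m2 + L21 * z1 + L22 * z2)
          } else {
            Tm <- matrix(0, tm$L, p)
            for (i in seq_len(tm$L)) {
              Om_i <- Ginv / tm$d[i] + cc * Rinv
              ch_i <- chol(Om_i)
              b_i <- Rinv %*% Mt[i, ]
              m_i <- backsolve(ch_i, forwardsolve(t(ch_i), b_i))
              Tm[i, ] <- m_i + backsolve(ch_i, stats::rnorm(p))
            }
            U[[t]] <- tm$E %*% Tm
          }
        } else {
          Om <- kronecker(tm$Cinv, Ginv) + kronecker(diag(tm$cnt, tm$L), Rinv)
          b <- as.vector(t(Mi %*% Rinv))
          ch <- chol(Om)
          m_u <- backsolve(ch, forwardsolve(t(ch), b))
          xu <- m_u + backsolve(ch, stats::rnorm(tm$L * p))
          U[[t]] <- t(matrix(xu, p, tm$L))
        }
        # --- G update ---
        if (tm$fast || is.null(tm$Cinv)) {
          Tm2 <- crossprod(tm$E, U[[t]])
          S <- crossprod(Tm2 / sqrt(tm$d))
        } else {
          S <- t(U[[t]]) %*% tm$Cinv %*% U[[t]]
        }
        if (tm$structure == "unstructured" && p > 1L) {
          G[[t]] <- riwish(Gnu + tm$L, Gnu * GV + S)
        } else {
          for (j in seq_len(p)) {
            gj <- 1 / stats::rgamma(1, (Gnu + tm$L) / 2,
                                    (Gnu * GV[j, j] + S[j, j]) / 2)
            Gnew <- matrix(0, p, p); Gnew <- G[[t]]
            Gnew[j, ] <- 0; Gnew[, j] <- 0; Gnew[j, j] <- gj
            G[[t]] <- Gnew
          }
        }
      }
      # --- residual update ---
      mu <- X %*% B
      for (t in seq_len(nt)) mu <- mu + U[[t]][terms[[t]]$zi, , drop = FALSE]
      E <- l - mu
      if (r_structure == "unstructured") {
        R <- riwish(Rnu + n, Rnu * RV + crossprod(E))
      } else {
        for (j in seq_len(p)) {
          if (!is.na(rfix[j])) { R[j, j] <- rfix[j]; next }
          R[j, j] <- 1 / stats::rgamma(1, (Rnu + n) / 2,
                                       (Rnu * RV[j, j] + sum(E[, j]^2)) / 2)
        }
      }
      Rinv <- solve(R)
      # --- liability updates ---
      for (j in seq_len(p)) {
        idx <- which(latent_mask[, j])
        if (!length(idx)) next
        # conditional prior of e_ij given the row's other residuals
        if (p == 1L) {
          cm <- rep(0, length(idx)); cv <- R[1L, 1L]
        } else {
          Rjj <- R[j, j]; Rjm <- R[j, -j, drop = FALSE]
          Rmm_inv <- solve(R[-j, -j, drop = FALSE])
          w <- Rjm %*% Rmm_inv
          cv <- as.numeric(Rjj - w %*% t(Rjm))
          cm <- as.vector(E[idx, -j, drop = FALSE] %*% t(w))
        }
        prior_mean <- mu[idx, j] + cm
        if (family[j] == "gaussian") {
          l[idx, j] <- prior_mean + sqrt(cv) * stats::rnorm(length(idx))
          E[idx, j] <- l[idx, j] - mu[idx, j]
        } else {
          obs <- !is.na(y[idx, j])
          cur <- l[idx, j]
          propv <- cur + mh_step[idx, j] * stats::rnorm(length(idx))
          llik <- function(v) {
            out <- numeric(length(v))
            if (family[j] == "binomial") {
              # log-scale inverse links stay finite for any liability
              out[obs] <- y[idx, j][obs] * stats::plogis(v[obs], log.p = TRUE) +
                (trials[idx, j][obs] - y[idx, j][obs]) *
                stats::plogis(-v[obs], log.p = TRUE)
            } else {
              out[obs] <- y[idx, j][obs] * v[obs] - exp(v[obs])
            }
            out
          }
          lr <- llik(propv) - llik(cur) +
            stats::dnorm(propv, prior_mean, sqrt(cv), log = TRUE) -
            stats::dnorm(cur, prior_mean, sqrt(cv), log = TRUE)
          lr[is.na(lr)] <- -Inf
          accept <- log(stats::runif(length(idx))) < lr
          l[idx, j][accept] <- propv[accept]
          if (it <= burnin && it %% 25L == 0L) {
            ar <- mean(accept)
            mh_step[idx, j] <- mh_step[idx, j] *
              if (ar > 0.5) 1.2 else if (ar < 0.3) 0.85 else 1
          }
          E[idx, j] <- l[idx, j] - mu[idx, j]
        }
      }
      if (it > burnin && (it - burnin) %% thin == 0L) {
        kept <- kept + 1L
        draws$beta[kept, ] <- as.vector(B)
        for (t in seq_len(nt)) {
          draws$G[[t]][kept, ] <- as.vector(G[[t]])
          draws$U[[t]][kept, , ] <- U[[t]]
        }
        draws$R[kept, ] <- as.vector(R)
      }
    }
    draws
  }

  all_draws <- lapply(seq_len(n_chains), run_chain)
  # draws$beta columns follow as.vector(B) with B (q coefs) x (p responses)
  bn <- as.vector(outer(colnames(X), resp, function(c, r) paste(r, c, sep = ":")))
  pool <- list(
    beta = do.call(rbind, lapply(all_draws, `[[`, "beta")),
    G = lapply(seq_len(nt), function(t)
      do.call(rbind, lapply(all_draws, function(d) d$G[[t]]))),
    R = do.call(rbind, lapply(all_draws, `[[`, "R")),
    U = lapply(seq_len(nt), function(t) {
      arrs <- lapply(all_draws, function(d) d$U[[t]])
      out <- array(NA_real_, c(keep_per * n_chains, terms[[t]]$L, p))
      for (i in seq_along(arrs))
        out[(i - 1L) * keep_per + seq_len(keep_per), , ] <- arrs[[i]]
      out
    })
  )
  colnames(pool$beta) <- bn
  gn <- as.vector(outer(resp, resp, paste, sep = "."))
  for (t in seq_len(nt)) colnames(pool$G[[t]]) <- gn
  colnames(pool$R) <- gn
  names(pool$G) <- names(pool$U) <- names(random)
  chains_param <- lapply(all_draws, function(d) {
    m <- d$beta
    colnames(m) <- bn
    for (t in seq_len(nt)) {
      g <- d$G[[t]][, which(diag(p) == 1), drop = FALSE]
      colnames(g) <- paste0("G.", names(random)[t], ".", resp)
      m <- cbind(m, g)
    }
    rr <- d$R[, which(diag(p) == 1), drop = FALSE]
    colnames(rr) <- paste0("R.", resp)
    cbind(m, rr)
  })
  structure(list(draws = pool, chains = chains_param, family = family,
                 responses = resp, X = X, terms = terms,
                 term_names = names(random), r_structure = r_structure,
                 rfix = rfix, trials = trials, y = y,
                 settings = list(n_iter = n_iter, burnin = burnin, thin = thin,
                                 n_chains = n_chains)),
            class = "bpmm")
}

#' Summarize a fitted BPMM
#'
#' Posterior modes (Gaussian KDE), means, 95% highest-density intervals and
#' pMCMC for fixed effects and variance parameters, plus per-term ICCs and,
#' where unstructured covariances were fitted, phylogenetic/residual
#' correlations.
#'
#' @param object a `bpmm` fit.
#' @param ... unused.
#' @return list with `fixed` (data.frame), `variance` (data.frame), `icc`
#'   (data.frame), `correlations` (data.frame, possibly empty).
#' @export
summary.bpmm <- function(object, ...) {
  fx <- t(apply(object$draws$beta, 2L, summarize_draws))
  fixed <- data.frame(parameter = rownames(fx), fx, row.names = NULL)
  p <- length(object$responses)
  vr <- NULL
  for (t in seq_along(object$draws$G)) {
    dg <- object$draws$G[[t]][, which(diag(p) == 1), drop = FALSE]
    s <- t(apply(dg, 2L, summarize_draws))
    vr <- rbind(vr, data.frame(parameter = paste0("G.", object$term_names[t], ".",
                                                  object$responses),
                               s, row.names = NULL))
  }
  dr <- object$draws$R[, which(diag(p) == 1), drop = FALSE]
  s <- t(apply(dr, 2L, summarize_draws))
  vr <- rbind(vr, data.frame(parameter = paste0("R.", object$responses), s,
                             row.names = NULL))
  icc <- NULL
  for (t in seq_along(object$term_names))
    for (j in seq_len(p)) {
      d <- variance_partition(object, object$term_names[t], response = j)
      icc <- rbind(icc, data.frame(term = object$term_names[t],
                                   response = object$responses[j],
                                   t(summarize_draws(d)), row.names = NULL))
    }
  cors <- NULL
  if (p > 1L)
    for (t in seq_along(object$term_names)) {
      if (object$terms[[t]]$structure != "unstructured") next
      for (a in seq_len(p - 1L)) for (b in seq((a + 1L), p)) {
        d <- phylo_correlation(object, object$term_names[t], a, b)
        cors <- rbind(cors, data.frame(term = object$term_names[t],
                                       pair = paste(object$responses[a],
                                                    object$responses[b], sep = ":"),
                                       t(summarize_draws(d$r_term)), row.names = NULL))
      }
    }
  list(fixed = fixed, variance = vr, icc = icc, correlations = cors)
}

#' Intraclass correlation (variance partition) draws for one term
#'
#' `ICC = V_term / (sum of all random-term variances + residual + link
#' variance)`, with link variance `pi^2/3` for binomial (logit) responses and
#' 0 otherwise; computed per posterior draw.
#'
#' @param fit a `bpmm`.
#' @param term term name.
#' @param response response index or name.
#' @return numeric vector of ICC draws.
#' @export
variance_partition <- function(fit, term, response = 1L) {
  p <- length(fit$responses)
  j <- if (is.character(response)) match(response, fit$responses) else response
  dcol <- (j - 1L) * p + j
  vt <- fit$draws$G[[term]][, dcol]
  tot <- fit$draws$R[, dcol]
  for (nm in fit$term_names) tot <- tot + fit$draws$G[[nm]][, dcol]
  link <- if (fit$family[j] == "binomial") pi^2 / 3 else 0
  vt / (tot + link)
}

#' Between-response correlation draws from an unstructured term
#'
#' @param fit a `bpmm`.
#' @param term term name (must have been fitted unstructured).
#' @param a,b response indices or names.
#' @return list with `r_term` (correlation draws from the term covariance)
#'   and `r_residual` (from the residual covariance; `NULL` for diagonal
#'   residual structure).
#' @export
phylo_correlation <- function(fit, term, a = 1L, b = 2L) {
  p <- length(fit$responses)
  ti <- match(term, fit$term_names)
  if (fit$terms[[ti]]$structure != "unstructured")
    stop("term '", term, "' was fitted as shared (no covariance)")
  a <- if (is.character(a)) match(a, fit$responses) else a
  b <- if (is.character(b)) match(b, fit$responses) else b
  cidx <- function(i, j) (j - 1L) * p + i
  g <- fit$draws$G[[term]]
  r_term <- g[, cidx(a, b)] / sqrt(g[, cidx(a, a)] * g[, cidx(b, b)])
  r_res <- NULL
  if (fit$r_structure == "unstructured") {
    r <- fit$draws$R
    r_res <- r[, cidx(a, b)] / sqrt(r[, cidx(a, a)] * r[, cidx(b, b)])
  }
  list(r_term = r_term, r_residual = r_res)
}

#' Posterior predictions at internal nodes of the phylogeny
#'
#' Internal-node random effects are drawn from their conditional multivariate
#' normal given the tip effects (kriging against the tips+nodes covariance),
#' added to the node-level fixed predictor and inverse-linked. One node draw
#' is taken per retained posterior iteration (`conditional_mean = TRUE`
#' instead plugs in the conditional mean).
#'
#' @param fit a `bpmm` whose `term` was fitted over the tree's tips.
#' @param tree the `phylo` the term covariance came from.
#' @param term name of the phylogenetic term.
#' @param X_nodes node-level design matrix (defaults to all-ones columns
#'   matching the fit's design).
#' @param conditional_mean plug in conditional means instead of sampling.
#' @return list with `draws` (array: draws x nodes x responses, inverse-link
#'   scale), `mean` (nodes x responses), `classified` (nodes x responses
#'   logical, posterior mean > 0.5; meaningful for binomial), node labels as
#'   dimnames.
#' @export
predict_nodes <- function(fit, tree, term, X_nodes = NULL,
                          conditional_mean = FALSE) {
  ti <- match(term, fit$term_names)
  if (is.na(ti)) stop("no term named '", term, "'")
  tm <- fit$terms[[ti]]
  Cfull <- phylo_vcv(tree, include_internal = TRUE)
  tips <- tm$levels
  if (!all(tips %in% rownames(Cfull))) stop("tree does not match fitted covariance")
  nodes <- setdiff(rownames(Cfull), tips)
  Ctt <- Cfull[tips, tips, drop = FALSE]
  Cnt <- Cfull[nodes, tips, drop = FALSE]
  Cnn <- Cfull[nodes, nodes, drop = FALSE]
  K <- Cnt %*% solve(Ctt)
  Sc <- Cnn - K %*% t(Cnt)
  Sc <- (Sc + t(Sc)) / 2
  ch <- tryCatch(chol(Sc + diag(1e-8, nrow(Sc))), error = function(e) NULL)
  p <- length(fit$responses)
  q <- ncol(fit$X)
  if (is.null(X_nodes)) X_nodes <- matrix(1, length(nodes), q)
  nk <- nrow(fit$draws$beta)
  out <- array(NA_real_, c(nk, length(nodes), p),
               dimnames = list(NULL, nodes, fit$responses))
  for (k in seq_len(nk)) {
    Ut <- matrix(fit$draws$U[[ti]][k, , ], ncol = p)
    Gk <- matrix(fit$draws$G[[ti]][k, ], p, p)
    mu_n <- K %*% Ut
    if (!conditional_mean && !is.null(ch)) {
      Z <- matrix(stats::rnorm(length(nodes) * p), length(nodes), p)
      cg <- tryCatch(chol(Gk), error = function(e) diag(sqrt(diag(Gk)), p))
      mu_n <- mu_n + t(ch) %*% Z %*% cg
    }
    B <- matrix(fit$draws$beta[k, ], q, p)
    eta <- X_nodes %*% B + mu_n
    for (j in seq_len(p)) {
      out[k, , j] <- switch(fit$family[j],
                            gaussian = eta[, j],
                            binomial = stats::plogis(eta[, j]),
                            poisson = exp(eta[, j]))
    }
  }
  m <- apply(out, c(2L, 3L), mean)
  list(draws = out, mean = m, classified = m > 0.5)
}
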