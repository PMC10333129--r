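#' Build a CTMC rate matrix (Mk generator)
#'
#' @param states character vector of state labels (length k).
#' @param rates for `equal_rates` a single rate; for `all_rates_different` a
#'   vector of k(k-1) off-diagonal rates filled row-wise.
#' @param constraint rate constraint.
#' @return a k x k generator with zero row sums, dimnames = states, and the
#'   constraint stored as an attribute.
#' @export
rate_matrix <- function(states, rates, constraint = c("equal_rates", "all_rates_different")) {
  constraint <- match.arg(constraint)
  k <- length(states)
  stopifnot(k >= 2L, all(rates >= 0))
  Q <- matrix(0, k, k, dimnames = list(states, states))
  off <- which(row(Q) != col(Q))
  off <- off[order(row(Q)[off], col(Q)[off])]
  if (constraint == "equal_rates") {
    stopifnot(length(rates) == 1L)
    Q[off] <- rates
  } else {
    stopifnot(length(rates) == k * (k - 1L))
    Q[off] <- rates
  }
  diag(Q) <- -rowSums(Q)
  attr(Q, "constraint") <- constraint
  Q
}

validate_Q <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) stop("Q must be square")
  offs <- Q[row(Q) != col(Q)]
  if (any(offs < 0)) stop("Q off-diagonals must be >= 0")
  if (any(abs(rowSums(Q)) > 1e-12 * max(1, max(abs(Q))))) stop("Q rows must sum to 0")
  invisible(Q)
}

# Precompute postorder edge structures and tip partial likelihoods.
mk_prep <- function(tree, tip_states, states = NULL) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- ape::Ntip(tr)
  if (is.matrix(tip_states)) {
    tipL <- tip_states[tree$tip.label, , drop = FALSE]
    states <- colnames(tipL)
  } else {
    x <- tip_states[tree$tip.label]
    if (anyNA(x)) stop("tip states missing for: ",
                       paste(tree$tip.label[is.na(x)], collapse = ", "))
    if (is.null(states)) states <- sort(unique(as.character(x)))
    idx <- match(as.character(x), states)
    if (anyNA(idx)) stop("unknown state label(s): ",
                         paste(unique(as.character(x)[is.na(idx)]), collapse = ", "))
    tipL <- matrix(0, ntip, length(states))
    tipL[cbind(seq_len(ntip), idx)] <- 1
  }
  list(tree = tr, edge = tr$edge, elen = tr$edge.length, ntip = ntip,
       nnode = tr$Nnode, tipL = tipL, states = states)
}

root_prior_vec <- function(root_prior, Q) {
  k <- nrow(Q)
  if (is.numeric(root_prior) && length(root_prior) == k) return(root_prior / sum(root_prior))
  if (identical(root_prior, "uniform")) return(rep(1 / k, k))
  if (identical(root_prior, "stationary")) {
    ev <- eigen(t(Q))
    i <- which.min(abs(ev$values))
    p <- abs(Re(ev$vectors[, i]))
    return(p / sum(p))
  }
  stop("root_prior must be 'uniform', 'stationary' or a length-k vector")
}

#' Mk model log-likelihood by Felsenstein pruning
#'
#' Per-branch transition probabilities are matrix exponentials of the
#' generator (eigendecomposition with a scaling-and-squaring fallback); the
#' root state is integrated over `root_prior`.
#'
#' @param tree a `phylo` object.
#' @param tip_states named vector of state labels for every tip, or a tip x
#'   state likelihood matrix (rows in any tip order, `tree$tip.label` used to
#'   align) to encode ambiguity.
#' @param Q generator from [rate_matrix()] (or any valid generator with
#'   dimnames).
#' @param root_prior `"uniform"` (default), `"stationary"`, or a probability
#'   vector over states.
#' @return log-likelihood (a single number).
#' @export
mk_loglik <- function(tree, tip_states, Q, root_prior = "uniform") {
  validate_Q(Q)
  prep <- mk_prep(tree, tip_states, colnames(Q))
  mk_loglik_cpp(prep$edge, prep$elen, prep$ntip, prep$nnode, prep$tipL,
                unname(Q), root_prior_vec(root_prior, Q))
}

# Crude parsimony change count (Fitch) used to scale default rate priors.
fitch_changes <- function(prep) {
  ntot <- prep$ntip + prep$nnode
  sets <- vector("list", ntot)
  for (i in seq_len(prep$ntip)) sets[[i]] <- which(prep$tipL[i, ] > 0)
  changes <- 0L
  e <- prep$edge
  for (i in seq_len(nrow(e))) { # postorder: children resolved before parents
    par <- e[i, 1L]; ch <- e[i, 2L]
    if (is.null(sets[[par]])) sets[[par]] <- sets[[ch]]
    else {
      inter <- intersect(sets[[par]], sets[[ch]])
      if (length(inter)) sets[[par]] <- inter
      else {
        sets[[par]] <- union(sets[[par]], sets[[ch]])
        changes <- changes + 1L
      }
    }
  }
  changes
}

#' Posterior sampling of Mk transition rates
#'
#' Metropolis-Hastings on log-rates targeting `prior x likelihood`, with a
#' multiplicative log-normal random walk adapted during burn-in towards
#' 20-40% acceptance. The default rate prior is exponential with mean equal
#' to the parsimony change count divided by total tree length.
#'
#' @param tree,tip_states,root_prior as in [mk_loglik()].
#' @param constraint `"equal_rates"` or `"all_rates_different"`.
#' @param prior_mean mean of the exponential prior on each rate; default
#'   parsimony-based.
#' @param n_iter,burnin,thin chain settings.
#' @param states optional explicit state set.
#' @param prior_only drop the likelihood term (prior-predictive check).
#' @return list with `draws` (matrix, one column per free rate), `accept`,
#'   `states`, `constraint`, `prior_mean`, and a `loglik` vector.
#' @export
sample_q_posterior <- function(tree, tip_states,
                               constraint = c("equal_rates", "all_rates_different"),
                               prior_mean = NULL, n_iter = 11000, burnin = 1000,
                               thin = 10, root_prior = "uniform", states = NULL,
                               prior_only = FALSE) {
  constraint <- match.arg(constraint)
  prep <- mk_prep(tree, tip_states, states)
  k <- length(prep$states)
  obs <- colSums(prep$tipL) > 0
  if (sum(obs) < 2L) stop("need at least 2 observed states to estimate rates")
  nr <- if (constraint == "equal_rates") 1L else k * (k - 1L)
  if (is.null(prior_mean))
    prior_mean <- max(fitch_changes(prep), 1L) / sum(prep$elen)
  build <- function(lr) unname(rate_matrix(prep$states, exp(lr), constraint))
  ll_fun <- function(lr) {
    if (prior_only) return(0)
    Qm <- build(lr)
    mk_loglik_cpp(prep$edge, prep$elen, prep$ntip, prep$nnode,
                  prep$tipL, Qm, root_prior_vec(root_prior, Qm))
  }
  lp_fun <- function(lr) sum(stats::dexp(exp(lr), 1 / prior_mean, log = TRUE) + lr)
  lr <- rep(log(prior_mean), nr)
  cur_ll <- ll_fun(lr); cur_lp <- lp_fun(lr)
  step <- rep(0.5, nr)
  keep <- floor((n_iter - burnin) / thin)
  draws <- matrix(NA_real_, keep, nr)
  lls <- numeric(keep)
  acc <- numeric(nr); tries <- numeric(nr); kept <- 0L
  for (it in seq_len(n_iter)) {
    j <- ((it - 1L) %% nr) + 1L
    prop <- lr
    prop[j] <- prop[j] + stats::rnorm(1, 0, step[j])
    new_ll <- ll_fun(prop); new_lp <- lp_fun(prop)
    tries[j] <- tries[j] + 1
    if (is.finite(new_ll) && log(stats::runif(1)) < (new_ll + new_lp) - (cur_ll + cur_lp)) {
      lr <- prop; cur_ll <- new_ll; cur_lp <- new_lp
      acc[j] <- acc[j] + 1
    }
    if (it <= burnin && it %% 100L == 0L) {
      r <- acc / pmax(tries, 1)
      step <- step * ifelse(r > 0.4, 1.3, ifelse(r < 0.2, 0.75, 1))
      acc[] <- 0; tries[] <- 0
    }
    if (it > burnin && (it - burnin) %% thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- exp(lr)
      lls[kept] <- cur_ll
    }
  }
  colnames(draws) <- if (nr == 1L) "rate" else {
    lab <- expand.grid(to = prep$states, from = prep$states)[, 2:1]
    lab <- lab[lab$from != lab$to, ]
    paste0(lab$from, "->", lab$to)
  }
  list(draws = draws, accept = sum(acc) / max(sum(tries), 1), states = prep$states,
       constraint = constraint, prior_mean = prior_mean, loglik = lls)
}

# Joint sampling of node states given tip data and Q: root from
# root_prior * D_root, then children conditionally on parents (preorder).
sample_node_states <- function(prep, P, part, root, rp, n_draws) {
  ntot <- prep$ntip + prep$nnode
  k <- ncol(part)
  e <- prep$edge
  draws <- matrix(NA_integer_, n_draws, ntot)
  pr_root <- rp * part[root, ]
  pr_root <- pr_root / sum(pr_root)
  draws[, root] <- sample.int(k, n_draws, replace = TRUE, prob = pr_root)
  for (i in rev(seq_len(nrow(e)))) { # reverse postorder = preorder
    par <- e[i, 1L]; ch <- e[i, 2L]
    Pe <- P[, , i]
    w <- Pe * rep(part[ch, ], each = k) # w[sp, sc]
    w <- w / rowSums(w)
    ps <- draws[, par]
    u <- stats::runif(n_draws)
    cw <- w[ps, , drop = FALSE]
    cs <- cw %*% (upper.tri(diag(k), diag = TRUE) * 1)
    draws[, ch] <- max.col((cs >= u - 1e-15) * 1, ties.method = "first")
  }
  draws
}

# Conditional path sampling on one branch by uniformization.
sample_branch_path <- function(a, b, t, Q, Pab) {
  k <- nrow(Q)
  mu <- max(-diag(Q))
  if (mu <= 0 || t <= 0) return(data.frame(state = a, time = t))
  Rm <- diag(k) + Q / mu
  u <- stats::runif(1) * Pab
  n <- 0L
  Rpow <- list(diag(k))
  cum <- stats::dpois(0, mu * t) * (a == b)
  while (cum < u && n < 10000L) {
    n <- n + 1L
    Rpow[[n + 1L]] <- Rpow[[n]] %*% Rm
    cum <- cum + stats::dpois(n, mu * t) * Rpow[[n + 1L]][a, b]
  }
  if (n == 0L) return(data.frame(state = a, time = t))
  states <- integer(n + 2L)
  states[1L] <- a; states[n + 2L] <- b
  for (j in seq_len(n)) {
    w <- Rm[states[j], ] * Rpow[[n - j + 1L]][, b]
    states[j + 1L] <- sample.int(k, 1L, prob = w)
  }
  times <- c(0, sort(stats::runif(n)) * t, t)
  seg_state <- states[-length(states)]
  seg_len <- diff(times)
  keep <- c(TRUE, diff(seg_state) != 0)
  data.frame(state = seg_state[keep],
             time = as.numeric(tapply(seg_len, cumsum(keep), sum)))
}

#' Stochastic character maps
#'
#' Samples joint ancestral node states from their conditional distribution
#' given tips and `Q`, and (optionally) full piecewise-constant branch
#' histories conditioned on the sampled endpoint states by uniformization.
#' `Q` may be a single generator or a list of posterior draws, cycled across
#' maps to integrate over rate uncertainty.
#'
#' @inheritParams mk_loglik
#' @param Q generator matrix or list of generators.
#' @param n_maps number of maps.
#' @param branch_histories sample within-branch histories (set `FALSE` when
#'   only node states are needed; much faster).
#' @return object of class `scm_maps`: list with `node_states` (n_maps x
#'   (Ntip+Nnode) integer matrix, ape node numbering), `states`, `tree`
#'   (postorder), `histories` (list per map of per-edge data.frames, or
#'   `NULL`).
#' @export
stochastic_maps <- function(tree, tip_states, Q, n_maps = 1000,
                            branch_histories = TRUE, root_prior = "uniform") {
  Qs <- if (is.matrix(Q)) list(Q) else Q
  lapply(Qs, validate_Q)
  prep <- mk_prep(tree, tip_states, colnames(Qs[[1L]]))
  rp <- root_prior_vec(root_prior, Qs[[1L]])
  nQ <- length(Qs)
  per <- tabulate(rep_len(seq_len(nQ), n_maps), nQ)
  node_states <- NULL
  histories <- if (branch_histories) vector("list", n_maps) else NULL
  done <- 0L
  for (qi in seq_len(nQ)) {
    if (per[qi] == 0L) next
    r <- mk_partials_cpp(prep$edge, prep$elen, prep$ntip, prep$nnode, prep$tipL,
                         unname(Qs[[qi]]), rp, keep_P = TRUE)
    ns <- sample_node_states(prep, r$P, r$partials, r$root, rp, per[qi])
    node_states <- rbind(node_states, ns)
    if (branch_histories) {
      for (m in seq_len(per[qi])) {
        hist <- vector("list", nrow(prep$edge))
        for (e in seq_len(nrow(prep$edge))) {
          a <- ns[m, prep$edge[e, 1L]]; b <- ns[m, prep$edge[e, 2L]]
          hist[[e]] <- sample_branch_path(a, b, prep$elen[e], unname(Qs[[qi]]),
                                          r$P[a, b, e])
        }
        histories[[done + m]] <- hist
      }
    }
    done <- done + per[qi]
  }
  structure(list(node_states = node_states, states = prep$states,
                 tree = prep$tree, histories = histories),
            class = "scm_maps")
}

#' Analytic marginal ancestral state probabilities
#'
#' Exact per-node marginal posteriors under the Mk model (two-pass
#' rescaled pruning); the oracle the map-based frequencies converge to.
#'
#' @inheritParams mk_loglik
#' @return matrix (Ntip+Nnode) x k of marginal probabilities.
#' @export
mk_marginals <- function(tree, tip_states, Q, root_prior = "uniform") {
  validate_Q(Q)
  prep <- mk_prep(tree, tip_states, colnames(Q))
  rp <- root_prior_vec(root_prior, Q)
  r <- mk_partials_cpp(prep$edge, prep$elen, prep$ntip, prep$nnode, prep$tipL,
                       unname(Q), rp, keep_P = TRUE)
  ntot <- prep$ntip + prep$nnode
  k <- nrow(Q)
  up <- matrix(NA_real_, ntot, k)
  up[r$root, ] <- rp
  e <- prep$edge
  for (i in rev(seq_len(nrow(e)))) {
    par <- e[i, 1L]; ch <- e[i, 2L]
    Pe <- r$P[, , i]
    msg_ch <- as.vector(Pe %*% r$partials[ch, ]) # child's message into parent
    w <- up[par, ] * r$partials[par, ] / pmax(msg_ch, 1e-300)
    up[ch, ] <- as.vector(t(Pe) %*% w)
    up[ch, ] <- up[ch, ] / sum(up[ch, ])
  }
  m <- up * r$partials
  m <- m / rowSums(m)
  colnames(m) <- prep$states
  # rows are in ape node numbering already (partials indexed by node id)
  m
}

#' Summarize sampled node states into frequencies and assignments
#'
#' @param maps an `scm_maps` object (or an integer matrix of node-state
#'   draws).
#' @param rule `"majority"`: assign the modal state only when its frequency
#'   is strictly above 0.5, else `"uncertain"` (binary-trait convention);
#'   `"modal"`: always assign the most frequent state (multi-state niche
#'   convention).
#' @return list with `freq` (nodes x states matrix) and `assigned`
#'   (character vector, `"uncertain"` possible under `"majority"`).
#' @export
summarize_node_states <- function(maps, rule = c("majority", "modal")) {
  rule <- match.arg(rule)
  ns <- if (inherits(maps, "scm_maps")) maps$node_states else maps
  states <- if (inherits(maps, "scm_maps")) maps$states else
    as.character(sort(unique(as.vector(ns))))
  k <- length(states)
  freq <- t(apply(ns, 2L, function(col) tabulate(col, k) / length(col)))
  colnames(freq) <- states
  top <- max.col(freq, ties.method = "first")
  assigned <- states[top]
  if (rule == "majority") {
    fmax <- freq[cbind(seq_len(nrow(freq)), top)]
    assigned[fmax <= 0.5] <- "uncertain"
  }
  list(freq = freq, assigned = assigned)
}

#' Count origins and losses of a focal state over tree edges
#'
#' Origins are edges whose parent is outside the focal state set and whose
#' child is inside; losses the reverse. Edges touching `"uncertain"` nodes
#' are excluded and reported.
#'
#' @param tree a `phylo` object.
#' @param assignments character vector of state assignments for all
#'   `Ntip+Nnode` nodes (ape numbering); may contain `"uncertain"`.
#' @param focal character vector of focal state labels.
#' @return list with `origins`, `losses`, `edges` (per-edge data.frame with
#'   `parent`, `child`, `from`, `to`, `event`), `n_uncertain_edges`.
#' @export
count_state_transitions <- function(tree, assignments, focal) {
  e <- tree$edge
  from <- assignments[e[, 1L]]
  to <- assignments[e[, 2L]]
  unc <- from == "uncertain" | to == "uncertain"
  event <- rep("none", nrow(e))
  event[!unc & !(from %in% focal) & (to %in% focal)] <- "origin"
  event[!unc & (from %in% focal) & !(to %in% focal)] <- "loss"
  list(origins = sum(event == "origin"), losses = sum(event == "loss"),
       edges = data.frame(parent = e[, 1L], child = e[, 2L],
                          from = from, to = to, event = event),
       n_uncertain_edges = sum(unc))
}

#' Serialize one stochastic map as simmap-style annotated Newick
#'
#' @param maps an `scm_maps` object with branch histories.
#' @param i map index.
#' @return a Newick string with `{state,time:...}` branch annotations.
#' @export
write_simmap <- function(maps, i = 1L) {
  stopifnot(inherits(maps, "scm_maps"), !is.null(maps$histories))
  tr <- maps$tree
  hist <- maps$histories[[i]]
  ann <- vapply(seq_along(hist), function(e) {
    h <- hist[[e]]
    paste0("{", paste0(maps$states[h$state], ",",
                       format(h$time, digits = 10, trim = TRUE), collapse = ":"), "}")
  }, character(1))
  labs <- c(tr$tip.label, internal_node_labels(tr))
  parts <- character(nrow(tr$edge))
  build <- function(node) {
    kids <- tr$edge[tr$edge[, 1L] == node, 2L]
    if (!length(kids)) return(labs[node])
    inner <- vapply(kids, function(ch) {
      e <- which(tr$edge[, 2L] == ch)
      paste0(build(ch), ":", ann[e])
    }, character(1))
    paste0("(", paste(inner, collapse = ","), ")")
  }
  paste0(build(ape::Ntip(tr) + 1L), ";")
}
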