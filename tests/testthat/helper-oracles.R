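# Independent oracles used across tests: brute-force enumeration of the Mk
# likelihood and ancestral marginals, a plain eigen-based matrix exponential,
# and small simulation helpers. These never call the package's pruning path.

expm_eig <- function(M) {
  e <- eigen(M)
  Re(e$vectors %*% diag(exp(e$values), nrow(M)) %*% solve(e$vectors))
}

# Sum over all internal-node state assignments.
enum_mk <- function(tree, tips, Q, rp, marginals = FALSE) {
  tr <- stats::reorder(tree, "postorder")
  k <- nrow(Q)
  ntip <- ape::Ntip(tr)
  nn <- tr$Nnode
  P <- lapply(seq_len(nrow(tr$edge)), function(e) expm_eig(Q * tr$edge.length[e]))
  ts <- match(tips[tr$tip.label], colnames(Q))
  root <- tr$edge[nrow(tr$edge), 1L]
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
  w <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    st <- c(ts, grid[g, ])
    pr <- rp[st[root]]
    for (e in seq_len(nrow(tr$edge)))
      pr <- pr * P[[e]][st[tr$edge[e, 1L]], st[tr$edge[e, 2L]]]
    w[g] <- pr
  }
  if (!marginals) return(log(sum(w)))
  w <- w / sum(w)
  m <- matrix(0, nn, k)
  for (g in seq_len(nrow(grid)))
    for (j in seq_len(nn)) m[j, grid[g, j]] <- m[j, grid[g, j]] + w[g]
  m
}

# Two binary traits evolved on the combined 4-state chain.
sim_pagel_tips <- function(tree, dependent, strength = 4) {
  Q <- if (dependent)
    pagel_generator(c("t1_01.t2=0" = 1, "t1_01.t2=1" = 1,
                      "t1_10.t2=0" = 1, "t1_10.t2=1" = 1,
                      "t2_01.t1=0" = 1 / strength, "t2_01.t1=1" = strength,
                      "t2_10.t1=0" = strength, "t2_10.t1=1" = 1 / strength),
                    "dependent")
  else
    pagel_generator(c(t1_01 = 1, t1_10 = 1, t2_01 = 1, t2_10 = 1), "independent")
  s <- sim_mk_trait(tree, Q)
  x <- s$tip_states
  list(x1 = stats::setNames(as.integer(substr(x, 1, 1) == "1"), names(x)),
       x2 = stats::setNames(as.integer(substr(x, 2, 2) == "1"), names(x)))
}

# Bivariate Gaussian fit used by calibration tests (desk-scale settings).
fit_bivariate_gauss <- function(tree, y, n_iter = 2500, burnin = 500, thin = 2) {
  C <- stats::cov2cor(ape::vcv.phylo(tree))
  bpmm(y = y, family = "gaussian",
       random = list(phylo = bpmm_term(C, map = tree$tip.label,
                                       structure = "unstructured")),
       n_iter = n_iter, burnin = burnin, thin = thin, n_chains = 1)
}
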