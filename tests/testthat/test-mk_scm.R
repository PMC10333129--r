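test_that("rate matrices respect constraints and validation", {
  Q <- rate_matrix(c("0", "1"), 0.3)
  expect_equal(Q["0", "1"], 0.3)
  expect_equal(rowSums(Q), c("0" = 0, "1" = 0))
  Qa <- rate_matrix(c("a", "b", "c"), 1:6, "all_rates_different")
  expect_equal(Qa["a", "b"], 1)
  expect_equal(Qa["c", "b"], 6)
  expect_error(rate_matrix(c("0", "1"), -1), "rates")
  bad <- matrix(c(-1, 1, 0.5, -0.6), 2, 2, byrow = TRUE)
  expect_error(mk_loglik(parse_newick("(A:1,B:1);"), c(A = "0", B = "0"),
                         structure(bad, dimnames = list(c("0", "1"), c("0", "1")))),
               "sum to 0")
})

test_that("pruning likelihood matches enumeration and symmetry identities", {
  # no-change limit: two identical tips, zero rate, uniform root
  tr2 <- parse_newick("(A:1,B:1);")
  expect_equal(mk_loglik(tr2, c(A = "0", B = "0"), rate_matrix(c("0", "1"), 0)),
               log(0.5))
  set.seed(5)
  for (i in 1:20) {
    n <- sample(3:5, 1)
    tr <- sim_tree(n, 1, 0, 1)
    k <- sample(2:3, 1)
    st <- as.character(seq_len(k) - 1)
    Q <- rate_matrix(st, stats::runif(k * (k - 1), 0.1, 2), "all_rates_different")
    tips <- stats::setNames(sample(st, n, TRUE), tr$tip.label)
    a <- mk_loglik(tr, tips, Q)
    b <- enum_mk(tr, tips, Q, rep(1 / k, k))
    expect_lt(abs(a - b) / abs(b), 1e-10)
  }
  # ER likelihood invariant to state relabelling
  tr <- sim_tree(10, 1, 0, 1)
  Qe <- rate_matrix(c("0", "1"), 0.7)
  tips <- stats::setNames(sample(c("0", "1"), 10, TRUE), tr$tip.label)
  flipped <- stats::setNames(ifelse(tips == "0", "1", "0"), names(tips))
  expect_equal(mk_loglik(tr, tips, Qe), mk_loglik(tr, flipped, Qe))
})

test_that("likelihood is invariant to re-rooting for reversible Q", {
  skip_if_not_installed("phytools")
  set.seed(6)
  tr <- sim_tree(8, 1, 0, 1)
  Q <- rate_matrix(c("0", "1"), 0.6)
  tips <- stats::setNames(sample(c("0", "1"), 8, TRUE), tr$tip.label)
  ll0 <- mk_loglik(tr, tips, Q, "stationary")
  rr <- phytools::reroot(tr, node.number = 12, position = 0.3 * tr$edge.length[which(tr$edge[, 2] == 12)])
  ll1 <- mk_loglik(rr, tips, Q, "stationary")
  expect_equal(ll0, ll1, tolerance = 1e-8)
})

test_that("Q posterior sampling recovers simulated rates and obeys the prior", {
  set.seed(9)
  hits <- 0
  for (i in 1:8) {
    tr <- sim_tree(200, 1, 0, 1)
    s <- sim_mk_trait(tr, rate_matrix(c("0", "1"), 0.5))
    if (length(unique(s$tip_states)) < 2) next
    fit <- sample_q_posterior(tr, s$tip_states, "equal_rates",
                              n_iter = 3000, burnin = 800, thin = 5)
    med <- stats::median(fit$draws[, 1])
    hits <- hits + (abs(med - 0.5) / 0.5 < 0.25)
  }
  expect_gte(hits, 6)  # most replicates within 25% of truth
  # prior-predictive: with likelihood off the draws match the exponential prior
  tr <- sim_tree(20, 1, 0, 1)
  s <- sim_mk_trait(tr, rate_matrix(c("0", "1"), 0.5))
  pp <- sample_q_posterior(tr, s$tip_states, "equal_rates", prior_mean = 2,
                           n_iter = 22000, burnin = 2000, thin = 10,
                           prior_only = TRUE)
  expect_equal(mean(pp$draws[, 1]), 2, tolerance = 0.25)
  expect_error(sample_q_posterior(tr, stats::setNames(rep("0", 20), tr$tip.label)),
               "at least 2 observed states")
  # equal_rates on 2 states has one free parameter
  expect_equal(ncol(pp$draws), 1L)
})

test_that("stochastic maps condition on tips and calibrate to marginals", {
  set.seed(13)
  tr <- sim_tree(30, 1, 0, 1)
  Q <- rate_matrix(c("0", "1"), c(0.8, 1.1), "all_rates_different")
  s <- sim_mk_trait(tr, Q)
  maps <- stochastic_maps(tr, s$tip_states, Q, n_maps = 300, branch_histories = FALSE)
  obs <- match(s$tip_states[maps$tree$tip.label], maps$states)
  expect_true(all(t(maps$node_states[, 1:30]) == obs))
  # map frequencies approach exact marginals (5-tip enumeration oracle)
  tr5 <- sim_tree(5, 1, 0, 1)
  s5 <- sim_mk_trait(tr5, Q)
  em <- enum_mk(tr5, s5$tip_states, Q, c(0.5, 0.5), marginals = TRUE)
  mg <- mk_marginals(tr5, s5$tip_states, Q)
  expect_equal(unname(mg[6:9, ]), em, tolerance = 1e-10)
  mp <- stochastic_maps(tr5, s5$tip_states, Q, n_maps = 4000, branch_histories = FALSE)
  fr <- summarize_node_states(mp)$freq
  expect_lt(max(abs(fr[6:9, 1] - em[, 1])), 4 * sqrt(0.25 / 4000) + 1e-3)
})

test_that("branch histories are consistent and match the q*t change rate", {
  set.seed(14)
  tr <- parse_newick("(A:2,B:2);")
  Q <- rate_matrix(c("0", "1"), 0.5)
  # differing tips with a tiny rate: every map must contain a change
  maps <- stochastic_maps(tr, c(A = "0", B = "1"),
                          rate_matrix(c("0", "1"), 0.01), n_maps = 50)
  nseg <- vapply(maps$histories, function(h) sum(vapply(h, nrow, integer(1))),
                 integer(1))
  expect_true(all(nseg >= 3))  # 2 branches, at least one extra segment
  # dwell times on each branch sum to the branch length
  for (m in 1:10) {
    h <- maps$histories[[m]]
    lens <- vapply(h, function(d) sum(d$time), numeric(1))
    expect_equal(lens, maps$tree$edge.length, tolerance = 1e-9)
  }
  # unconditional expected change count per branch is ~ q * t for a
  # symmetric 2-state chain (ambiguous tips = prior process)
  amb <- matrix(1, 2, 2, dimnames = list(c("A", "B"), c("0", "1")))
  mu <- stochastic_maps(tr, amb, Q, n_maps = 2000)
  changes <- vapply(mu$histories, function(h)
    sum(vapply(h, nrow, integer(1)) - 1L), integer(1))
  expect_equal(mean(changes) / 2, 0.5 * 2, tolerance = 0.1)
})

test_that("node-state summaries follow the majority and modal rules", {
  ns <- rbind(c(1L, 1L, 1L), c(1L, 2L, 2L), c(2L, 1L, 2L), c(2L, 2L, 1L))
  colnames(ns) <- NULL
  m <- structure(list(node_states = ns, states = c("no", "yes")),
                 class = "scm_maps")
  s <- summarize_node_states(m)
  expect_equal(s$assigned, c("uncertain", "uncertain", "uncertain"))
  ns2 <- rbind(c(1L, 2L), c(1L, 2L), c(1L, 1L), c(2L, 2L))
  m2 <- structure(list(node_states = ns2, states = c("no", "yes")),
                  class = "scm_maps")
  expect_equal(summarize_node_states(m2)$assigned, c("no", "yes"))
  # modal rule assigns the plurality state even below 0.5
  ns3 <- matrix(c(1L, 1L, 2L, 3L, 3L), 5, 1)
  expect_equal(summarize_node_states(
    structure(list(node_states = ns3, states = c("a", "b", "c")),
              class = "scm_maps"), rule = "modal")$assigned, "a")
})

test_that("transition counting matches a brute-force edge scan", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  # root non-focal, cherry subtree focal: one origin, no loss
  asg <- c("x", "x", "x", "x", "ob")
  asg[1:2] <- "ob"
  ct <- count_state_transitions(tr, asg, focal = "ob")
  expect_equal(ct$origins, 1L)
  expect_equal(ct$losses, 0L)
  # random labelling vs direct scan
  set.seed(15)
  tr50 <- sim_tree(50, 1, 0, 1)
  asg50 <- sample(c("ob", "non"), 99, TRUE)
  ct50 <- count_state_transitions(tr50, asg50, focal = "ob")
  manual <- sum(asg50[tr50$edge[, 1]] == "non" & asg50[tr50$edge[, 2]] == "ob")
  expect_equal(ct50$origins, manual)
  # uncertain nodes excluded and reported
  asg50[3] <- "uncertain"
  ct_u <- count_state_transitions(tr50, asg50, focal = "ob")
  expect_equal(ct_u$n_uncertain_edges, sum(tr50$edge[, 2] == 3 | tr50$edge[, 1] == 3))
})

test_that("simmap serialization preserves states and dwell times", {
  set.seed(16)
  tr <- sim_tree(6, 1, 0, 1)
  Q <- rate_matrix(c("0", "1"), 0.8)
  s <- sim_mk_trait(tr, Q)
  maps <- stochastic_maps(tr, s$tip_states, Q, n_maps = 2)
  txt <- write_simmap(maps, 1)
  expect_match(txt, "\\{0|1,")
  expect_match(txt, ";$")
  # total dwell time in the string equals total tree length
  times <- as.numeric(unlist(regmatches(txt, gregexpr("(?<=,)[0-9.eE+-]+", txt, perl = TRUE))))
  expect_equal(sum(times), sum(tr$edge.length), tolerance = 1e-6)
})
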