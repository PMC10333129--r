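#' Build the host x symbiont combination table
#'
#' One row per pairwise combination of host family and symbiont lineage:
#' the number of species in the family sampled with that symbiont versus the
#' number sampled without it. Vertically transmitted lineages can be
#' excluded.
#'
#' @param species data.frame with `species`, `family`, `symbiont` (lineage
#'   name or `NA` when no obligate symbiont was found).
#' @param symbionts data.frame with `lineage`, `intracellular` (logical),
#'   `vertical` (logical).
#' @param symbiont_tree optional `phylo`; every retained lineage must be a
#'   tip.
#' @param exclude_vertical drop vertically transmitted lineages (default
#'   TRUE).
#' @return data.frame with `host_family`, `symbiont_lineage`, `n_with`,
#'   `n_without`, `intracellular`.
#' @export
build_association_table <- function(species, symbionts, symbiont_tree = NULL,
                                    exclude_vertical = TRUE) {
  if (exclude_vertical) symbionts <- symbionts[!symbionts$vertical, , drop = FALSE]
  lineages <- symbionts$lineage
  if (!is.null(symbiont_tree)) {
    miss <- setdiff(lineages, symbiont_tree$tip.label)
    if (length(miss)) stop("symbiont lineage(s) absent from symbiont tree: ",
                           paste(miss, collapse = ", "))
  }
  fams <- sort(unique(species$family))
  grid <- expand.grid(host_family = fams, symbiont_lineage = lineages,
                      stringsAsFactors = FALSE)
  n_with <- mapply(function(f, s)
    sum(species$family == f & !is.na(species$symbiont) & species$symbiont == s),
    grid$host_family, grid$symbiont_lineage)
  n_samp <- vapply(grid$host_family, function(f) sum(species$family == f), integer(1))
  out <- data.frame(grid, n_with = n_with, n_without = n_samp - n_with,
                    intracellular = symbionts$intracellular[
                      match(grid$symbiont_lineage, symbionts$lineage)],
                    stringsAsFactors = FALSE)
  drop <- out$n_with + out$n_without == 0L
  if (any(drop)) message(sum(drop), " combination rows with zero sampled species dropped")
  rownames(out) <- NULL
  out[!drop, , drop = FALSE]
}

#' Covariance structures over host x symbiont combination rows
#'
#' Builds the four structures used to partition variation in obligate
#' symbiosis: `h` (host identity, independent of phylogeny), `[h]` (host
#' phylogenetic covariance expanded to rows), `[s]` (symbiont phylogenetic
#' covariance expanded), and `[hs]` (elementwise product of `[h]` and `[s]`;
#' PSD by the Schur product theorem). Phylogenetic covariances are scaled to
#' unit diagonal before expansion.
#'
#' @param host_tree,symbiont_tree `phylo` objects covering the referenced
#'   taxa.
#' @param table combination table from [build_association_table()].
#' @return named list of four matrices over rows of `table`, each with a
#'   `map`-free one-level-per-row layout (rownames = combination id).
#' @export
interaction_covariances <- function(host_tree, symbiont_tree, table) {
  rid <- paste(table$host_family, table$symbiont_lineage, sep = "|")
  Ch <- stats::cov2cor(ape::vcv.phylo(host_tree))
  Cs <- stats::cov2cor(ape::vcv.phylo(symbiont_tree))
  hi <- match(table$host_family, rownames(Ch))
  si <- match(table$symbiont_lineage, rownames(Cs))
  if (anyNA(hi)) stop("host family absent from host tree")
  if (anyNA(si)) stop("symbiont lineage absent from symbiont tree")
  h <- outer(table$host_family, table$host_family, `==`) * 1
  Hph <- Ch[hi, hi]
  Sph <- Cs[si, si]
  HS <- Hph * Sph
  out <- list(h = h, `[h]` = Hph, `[s]` = Sph, `[hs]` = HS)
  out <- lapply(out, function(m) {
    dimnames(m) <- list(rid, rid)
    ev <- min(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8) {
      m <- m + diag(1e-8 - ev, nrow(m))
      ev2 <- min(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values)
      if (ev2 < -1e-8) stop("covariance structure not PSD after jitter")
    }
    m
  })
  out
}

pcoa_coords <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  B <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% B %*% J
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values))) {
    # Lingoes correction: add a constant to squared distances
    c1 <- -min(eg$values)
    D2 <- D^2 + 2 * c1
    diag(D2) <- 0
    G <- J %*% (-0.5 * D2) %*% J
    eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  }
  pos <- eg$values > 1e-8 * max(eg$values)
  eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(eg$values[pos]), sum(pos))
}

#' Global ParaFit test of host-symbiont co-phylogenetic congruence
#'
#' Correlates host- and symbiont-shared branch lengths through principal
#' coordinates of the two patristic distance matrices (Lingoes-corrected for
#' negative eigenvalues). The global statistic is the sum of squared elements
#' of the fourth-corner matrix; the null distribution permutes each
#' symbiont's host links.
#'
#' @param host_tree,symbiont_tree `phylo` objects.
#' @param A binary association matrix, hosts x symbionts (dimnames matching
#'   tip labels).
#' @param n_perm number of permutations (default 1000).
#' @return list with `statistic`, `p_value`, `n_perm`.
#' @export
parafit_global <- function(host_tree, symbiont_tree, A, n_perm = 1000) {
  A <- as.matrix(A)
  if (sum(A) < 2L) {
    warning("degenerate association matrix (fewer than 2 links); p = 1")
    return(list(statistic = NA_real_, p_value = 1, n_perm = n_perm))
  }
  hosts <- rownames(A); symbs <- colnames(A)
  Dh <- stats::cophenetic(host_tree)[hosts, hosts]
  Ds <- stats::cophenetic(symbiont_tree)[symbs, symbs]
  Vh <- pcoa_coords(Dh)
  Vs <- pcoa_coords(Ds)
  stat_fun <- function(Am) sum((t(Vh) %*% Am %*% Vs)^2)
  obs <- stat_fun(A)
  perm <- vapply(seq_len(n_perm), function(i)
    stat_fun(apply(A, 2L, sample)), numeric(1))
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  list(statistic = obs, p_value = p, n_perm = n_perm)
}

#' Variance partitioning of obligate symbiosis over co-phylogenetic
#' structures
#'
#' Fits a binomial BPMM to the combination table with the requested subset of
#' `h`, `[h]`, `[s]`, `[hs]` covariance structures as random effects and an
#' intracellular/extracellular fixed effect, and returns the ICC of each
#' structure.
#'
#' @param table combination table from [build_association_table()].
#' @param covs list from [interaction_covariances()].
#' @param structures which structures to fit (default all four).
#' @param ... chain settings passed to [bpmm()].
#' @return list with `fit` (a `bpmm`) and `icc` (data.frame of per-structure
#'   ICC summaries).
#' @export
cophylo_partition <- function(table, covs, structures = c("h", "[h]", "[s]", "[hs]"),
                              ...) {
  rid <- paste(table$host_family, table$symbiont_lineage, sep = "|")
  random <- lapply(covs[structures], function(C) bpmm_term(C, map = rid,
                                                          structure = "shared"))
  names(random) <- structures
  X <- stats::model.matrix(~intracellular, data.frame(intracellular = table$intracellular))
  fit <- bpmm(y = table$n_with, family = "binomial",
              trials = table$n_with + table$n_without, X = X,
              random = random, ...)
  icc <- do.call(rbind, lapply(structures, function(s)
    data.frame(structure = s, t(summarize_draws(variance_partition(fit, s))),
               row.names = NULL)))
  list(fit = fit, icc = icc)
}
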