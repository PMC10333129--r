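TRANSITION_CATEGORIES <- c("NonToNon", "NonToOb", "ObToOb", "ObToNon")

#' Classify internal nodes by symbiosis transition category
#'
#' Four-way classification from a node's own state and the states of its
#' immediate descendants: non-obligate nodes are `NonToNon` unless at least
#' one descendant is obligate (`NonToOb`); obligate nodes are `ObToOb` unless
#' at least one descendant is non-obligate (`ObToNon`).
#'
#' @param tree a `phylo`.
#' @param obligate logical vector of length `Ntip + Nnode` (ape numbering;
#'   `NA` = unassigned, such nodes are excluded with a warning).
#' @return data.frame with `node` (ape id), `label`, `category`.
#' @export
classify_nodes <- function(tree, obligate) {
  ntip <- ape::Ntip(tree)
  ids <- ntip + seq_len(tree$Nnode)
  labs <- internal_node_labels(tree)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  cat <- vapply(ids, function(nd) {
    s <- obligate[nd]
    ch <- obligate[kids[[as.character(nd)]]]
    if (is.na(s) || anyNA(ch)) return(NA_character_)
    if (!s) {
      if (any(ch)) "NonToOb" else "NonToNon"
    } else {
      if (any(!ch)) "ObToNon" else "ObToOb"
    }
  }, character(1))
  if (anyNA(cat)) warning(sum(is.na(cat)), " unassigned internal nodes excluded")
  data.frame(node = ids, label = labs, category = cat, stringsAsFactors = FALSE)
}

#' Resample node classifications from the posterior
#'
#' Propagates classification uncertainty: each resample takes one posterior
#' draw of the node probabilities, thresholds it at 0.5, and reclassifies
#' every internal node.
#'
#' @param pred output of [predict_nodes()] for the binomial symbiosis model
#'   (single response).
#' @param tree the `phylo` (with the same internal-node labels).
#' @param tip_obligate named logical over tips (observed family states).
#' @param n_resamples number of resamples (default 100).
#' @return list of classification data.frames (one per resample), with the
#'   posterior draw index in `attr(, "draw")`.
#' @export
resample_classifications <- function(pred, tree, tip_obligate, n_resamples = 100) {
  ntip <- ape::Ntip(tree)
  labs <- internal_node_labels(tree)
  nd <- dim(pred$draws)[1L]
  draw_idx <- if (n_resamples <= nd) round(seq(1, nd, length.out = n_resamples))
  else sample.int(nd, n_resamples, replace = TRUE)
  lapply(draw_idx, function(r) {
    ob <- rep(NA, ntip + tree$Nnode)
    ob[seq_len(ntip)] <- as.logical(tip_obligate[tree$tip.label])
    ob[ntip + seq_len(tree$Nnode)] <- pred$draws[r, labs, 1L] > 0.5
    out <- classify_nodes(tree, ob)
    attr(out, "draw") <- r
    out
  })
}

#' Ancestral B-vitamin levels across symbiosis transition categories
#'
#' For each resampled classification, fits a multi-response Gaussian BPMM of
#' node-level nutrient estimates on the four-level transition category
#' (category-specific intercepts, unstructured phylogenetic and residual
#' covariances, phylogenetic covariance linked to node labels), retains a few
#' draws per resample, and pools draws across resamples. Contrasts follow
#' the later-minus-earlier convention: origin = NonToOb - NonToNon,
#' maintenance = ObToOb - NonToNon, loss = ObToNon - ObToOb.
#'
#' @param tree a `phylo`.
#' @param classifications list from [resample_classifications()] (or a
#'   single classification data.frame).
#' @param node_nutrients matrix of node-level nutrient values, rownames =
#'   internal-node labels, one column per nutrient (e.g. B5, B9).
#' @param n_iter,burnin,thin per-resample chain settings; the desk-scale
#'   defaults retain 10 draws per resample.
#' @return list with `contrasts` (data.frame of pooled summaries per
#'   contrast x nutrient), `draws` (named list of pooled contrast draws),
#'   `n_pooled`, `skipped` (contrast/resample pairs lacking a category).
#' @export
ancestral_nutrient_model <- function(tree, classifications, node_nutrients,
                                     n_iter = 11000, burnin = 1000, thin = 1000) {
  if (is.data.frame(classifications)) classifications <- list(classifications)
  Cfull <- phylo_vcv(tree, include_internal = TRUE)
  labs <- internal_node_labels(tree)
  Cn <- Cfull[labs, labs]
  Cn <- Cn / max(diag(Cn))
  resp <- colnames(node_nutrients)
  contrast_def <- list(origin = c("NonToOb", "NonToNon"),
                       maintenance = c("ObToOb", "NonToNon"),
                       loss = c("ObToNon", "ObToOb"))
  pool <- list()
  skipped <- NULL
  for (ri in seq_along(classifications)) {
    cl <- classifications[[ri]]
    keep <- !is.na(cl$category) & cl$label %in% rownames(node_nutrients)
    cl <- cl[keep, , drop = FALSE]
    y <- node_nutrients[cl$label, , drop = FALSE]
    cats <- factor(cl$category, levels = TRANSITION_CATEGORIES)
    present <- levels(droplevels(cats))
    X <- stats::model.matrix(~0 + category,
                             data.frame(category = droplevels(cats)))
    colnames(X) <- present
    fit <- bpmm(y = y, family = "gaussian", X = X,
                random = list(phylo = bpmm_term(Cn[cl$label, cl$label],
                                                structure = "unstructured")),
                n_iter = n_iter, burnin = burnin, thin = thin, n_chains = 1)
    for (cn in names(contrast_def)) {
      ab <- contrast_def[[cn]]
      if (!all(ab %in% present)) {
        skipped <- rbind(skipped, data.frame(resample = ri, contrast = cn))
        next
      }
      for (j in resp) {
        d <- fit$draws$beta[, paste0(j, ":", ab[1L])] -
          fit$draws$beta[, paste0(j, ":", ab[2L])]
        key <- paste(cn, j, sep = ".")
        pool[[key]] <- c(pool[[key]], d)
      }
    }
  }
  summaries <- do.call(rbind, lapply(names(pool), function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1L]]
    data.frame(contrast = parts[1L], nutrient = parts[2L],
               t(summarize_draws(pool[[k]])), n_draws = length(pool[[k]]),
               row.names = NULL)
  }))
  list(contrasts = summaries, draws = pool,
       n_pooled = lengths(pool), skipped = skipped)
}
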