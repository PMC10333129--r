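#' @useDynLib symbiophy, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Parse a Newick string into a validated phylogeny
#'
#' Wraps [ape::read.tree()] and enforces the structural invariants the rest of
#' the package relies on: a single root, unique tip labels, and non-negative
#' branch lengths.
#'
#' @param text Newick string (single tree, terminated by `;`).
#' @return An object of class `phylo`.
#' @export
parse_newick <- function(text) {
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("newick parse error (unbalanced parentheses or malformed input): ",
         substr(text, 1L, 60L))
  validate_phylo(tree)
  tree
}

#' Read a validated phylogeny from a Newick file
#' @param file path to a Newick file.
#' @return A `phylo` object.
#' @export
read_phylo <- function(file) parse_newick(paste(readLines(file, warn = FALSE), collapse = ""))

#' Serialize a phylogeny to Newick
#'
#' Round-trips topology, labels and branch lengths to 10 significant digits.
#'
#' @param tree a `phylo` object.
#' @param file optional path; when `NULL` the string is returned.
#' @return Newick string (invisibly when writing to file).
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree, digits = 10)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

validate_phylo <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths")
  ntab <- tabulate(tree$edge[, 2L], nbins = ape::Ntip(tree) + tree$Nnode)
  if (any(ntab > 1L)) stop("node with multiple parents: not a tree")
  invisible(tree)
}

#' Root-to-node path lengths
#'
#' @param tree a `phylo` object.
#' @return numeric vector of length `Ntip + Nnode`, indexed by ape node number.
#' @export
node_depths <- function(tree) ape::node.depth.edgelength(tree)

#' Maximum relative spread of root-to-tip distances
#'
#' Zero for a perfectly ultrametric tree. Used as the post-graft
#' ultrametricity check (`< 1e-6` expected).
#'
#' @param tree a `phylo` object.
#' @return a single non-negative number.
#' @export
ultrametric_spread <- function(tree) {
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  (max(d) - min(d)) / max(d)
}

#' Labels for internal nodes, generating `N<number>` where absent
#' @param tree a `phylo` object.
#' @return character vector of length `Nnode`.
#' @export
internal_node_labels <- function(tree) {
  n <- ape::Ntip(tree)
  lab <- tree$node.label
  ids <- n + seq_len(tree$Nnode)
  if (is.null(lab) || !length(lab)) return(paste0("N", ids))
  lab[is.na(lab) | lab == ""] <- paste0("N", ids)[is.na(lab) | lab == ""]
  lab
}

#' Graft a new tip onto an ultrametric tree at a published sister taxon
#'
#' Families with trait data but absent from the reference phylogeny are
#' attached on the stem branch of their published sister taxon. The default
#' attaches at the midpoint of the sister's stem; `"stem_top"` attaches just
#' below the sister's parent node (offset 1e-8 Myr to avoid a zero-length
#' branch). The new tip's branch length is chosen so the tree remains
#' ultrametric. Grafted tips accumulate in `attr(tree, "grafted")` so that
#' age-sensitive analyses can exclude them.
#'
#' @param tree ultrametric `phylo`.
#' @param tip name of the new tip.
#' @param sister tip label or internal-node label of the sister clade.
#' @param position `"midpoint"` (default) or `"stem_top"`.
#' @return the enlarged `phylo`, still ultrametric.
#' @export
graft_tip <- function(tree, tip, sister, position = c("midpoint", "stem_top")) {
  position <- match.arg(position)
  if (tip %in% tree$tip.label) stop("tip already present: ", tip)
  ntip <- ape::Ntip(tree)
  sid <- match(sister, tree$tip.label)
  if (is.na(sid)) {
    nl <- internal_node_labels(tree)
    hit <- match(sister, nl)
    if (!is.na(hit)) sid <- ntip + hit
  }
  if (is.na(sid)) stop("sister taxon not found in tree: ", sister)
  root <- ntip + 1L
  if (sid == root) stop("cannot graft onto the root stem")
  ei <- which(tree$edge[, 2L] == sid)
  L <- tree$edge.length[ei]
  pos <- if (position == "midpoint") L / 2 else max(L - 1e-8, L * 1e-8)
  dep <- node_depths(tree)
  H <- max(dep[seq_len(ntip)])
  attach_depth <- dep[sid] - pos
  tiplen <- H - attach_depth
  if (tiplen <= 0) stop("attachment point above tree height; tree not ultrametric?")
  tt <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                       tip.label = tip, edge.length = tiplen, Nnode = 1L),
                  class = "phylo")
  grafted <- c(attr(tree, "grafted"), tip)
  out <- ape::bind.tree(tree, tt, where = sid, position = pos)
  validate_phylo(out)
  if (ultrametric_spread(out) > 1e-6)
    stop("graft broke ultrametricity (spread ", ultrametric_spread(out), ")")
  attr(out, "grafted") <- grafted
  out
}

#' Apply a grafting table
#'
#' @param tree ultrametric `phylo`.
#' @param table data.frame with columns `new_family`, `sister_taxon`.
#' @param position passed to [graft_tip()].
#' @return the enlarged tree with all new families attached.
#' @export
graft_tips <- function(tree, table, position = "midpoint") {
  stopifnot(all(c("new_family", "sister_taxon") %in% names(table)))
  for (i in seq_len(nrow(table)))
    tree <- graft_tip(tree, table$new_family[i], table$sister_taxon[i], position)
  tree
}

#' Phylogenetic variance-covariance matrix
#'
#' `C[i, j]` is the root-to-MRCA path length shared by elements `i` and `j`;
#' the diagonal holds root-to-element depths. With `include_internal = TRUE`
#' internal nodes are included under their (auto-generated) labels, as needed
#' when node-level responses are linked to the phylogeny.
#'
#' @param tree a `phylo` object.
#' @param include_internal include internal nodes as rows/columns.
#' @return a symmetric positive semi-definite matrix with dimnames.
#' @export
phylo_vcv <- function(tree, include_internal = FALSE) {
  if (!include_internal) return(ape::vcv.phylo(tree))
  dep <- node_depths(tree)
  m <- ape::mrca(tree, full = TRUE)
  C <- matrix(dep[m], nrow(m), ncol(m))
  labs <- c(tree$tip.label, internal_node_labels(tree))
  dimnames(C) <- list(labs, labs)
  C
}

#' Extract sister pairs (cherries) and their ages
#'
#' A cherry is an internal node whose two descendants are both tips. The pair
#' age is the time depth of the pair's common ancestor, in the tree's branch
#' length units (Myr here).
#'
#' @param tree ultrametric `phylo`.
#' @return data.frame with columns `tip_a`, `tip_b`, `pair_age`, `node`.
#' @export
extract_sister_pairs <- function(tree) {
  ntip <- ape::Ntip(tree)
  dep <- node_depths(tree)
  H <- max(dep[seq_len(ntip)])
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  out <- lapply(names(kids), function(nd) {
    ch <- kids[[nd]]
    if (length(ch) == 2L && all(ch <= ntip)) {
      nd <- as.integer(nd)
      data.frame(tip_a = tree$tip.label[ch[1L]], tip_b = tree$tip.label[ch[2L]],
                 pair_age = H - dep[nd], node = nd, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(tip_a = character(), tip_b = character(),
                      pair_age = numeric(), node = integer())
  rownames(out) <- NULL
  out
}
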