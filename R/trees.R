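# Tree construction, bootstrap and consensus.
#
# Trees are unrooted internally (ape "phylo" objects); bootstrap supports
# live in node.label as percentages. Newick output roots arbitrarily at the
# first label unless an outgroup is supplied.

#' BIO-NJ tree from a distance matrix
#'
#' Neighbor joining with variance-weighted branch estimation (the BIONJ
#' agglomeration). Negative estimated branch lengths are clamped to zero.
#'
#' @param d labelled symmetric distance matrix with at least 3 labels.
#' @return an unrooted \code{phylo} tree.
#' @export
bionj_tree <- function(d) {
  d <- as.matrix(d)
  .check(nrow(d) >= 3, "BIO-NJ needs at least 3 labels (got %d)", nrow(d))
  .check(isSymmetric(unname(d)), "distance matrix must be symmetric")
  tr <- ape::bionj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# ---- bipartition bookkeeping -------------------------------------------
# A split is stored canonically as the side that does NOT contain the
# reference label (first label of the full set), so compatibility of two
# splits reduces to the laminar condition (disjoint or nested).

.split_key <- function(labels) paste(sort(labels), collapse = "\r")

# non-trivial canonical splits of a tree, as a named list key -> label set
.tree_splits <- function(tree, ref) {
  labs <- tree$tip.label
  n <- length(labs)
  pp <- ape::prop.part(tree)
  out <- list()
  for (cl in pp) {
    side <- labs[cl]
    if (ref %in% side) side <- setdiff(labs, side)
    k <- length(side)
    if (k >= 2 && k <= n - 2) out[[.split_key(side)]] <- side
  }
  out
}

#' Majority-rule extended consensus with bootstrap supports
#'
#' Counts bipartitions across replicate trees, keeps every split present in
#' more than half of them, then greedily adds the remaining splits in order
#' of decreasing frequency while they stay compatible (the extended
#' majority rule used by standard consensus programs). Each internal node
#' of the returned tree is labelled with the percentage of replicates
#' containing its bipartition.
#'
#' @param trees list (or \code{multiPhylo}) of trees on identical label
#'   sets.
#' @return a \code{phylo} tree without branch lengths; \code{node.label}
#'   holds supports in [0, 100].
#' @export
consensus_tree <- function(trees) {
  .check(length(trees) >= 1, "need at least one tree")
  labs <- sort(trees[[1]]$tip.label)
  ref <- labs[1]
  counts <- new.env(parent = emptyenv())
  sets <- new.env(parent = emptyenv())
  for (tr in trees) {
    .check(setequal(tr$tip.label, labs), "trees must share one label set")
    for (s in .tree_splits(tr, ref)) {
      k <- .split_key(s)
      counts[[k]] <- (if (is.null(counts[[k]])) 0 else counts[[k]]) + 1
      sets[[k]] <- s
    }
  }
  keys <- ls(counts)
  freq <- vapply(keys, function(k) counts[[k]], numeric(1))
  sizes <- vapply(keys, function(k) length(sets[[k]]), integer(1))
  # deterministic order: frequency desc, then larger split, then key
  ord <- order(-freq, -sizes, keys)
  accepted <- list(); support <- numeric(0)
  compatible_all <- function(s) {
    for (a in accepted) {
      inter <- length(intersect(s, a))
      if (inter > 0 && inter < length(s) && inter < length(a)) return(FALSE)
    }
    TRUE
  }
  # majority splits are mutually compatible and enter first; the remaining
  # splits are added greedily while compatible (extended majority rule)
  b <- length(trees)
  for (i in ord) {
    s <- sets[[keys[i]]]
    if (compatible_all(s)) {
      accepted <- c(accepted, list(s))
      support <- c(support, 100 * freq[i] / b)
    }
  }
  .build_from_splits(labs, accepted, support)
}

# build a phylo from a laminar family of canonical splits; supports become
# internal node labels (the root, which carries no bipartition, stays
# unlabelled)
.build_from_splits <- function(labs, splits, support) {
  k <- length(splits)
  if (k == 0)
    return(ape::read.tree(text = paste0("(", paste(labs, collapse = ","), ");")))
  sizes <- lengths(splits)
  # parent of a split = the smallest strictly-containing split (0 = root)
  parent <- vapply(seq_len(k), function(i) {
    sup <- which(vapply(seq_len(k), function(j)
      j != i && sizes[j] > sizes[i] && all(splits[[i]] %in% splits[[j]]),
      logical(1)))
    if (length(sup)) sup[which.min(sizes[sup])] else 0L
  }, integer(1))
  tip_parent <- vapply(labs, function(tp) {
    cont <- which(vapply(splits, function(s) tp %in% s, logical(1)))
    if (length(cont)) cont[which.min(sizes[cont])] else 0L
  }, integer(1))
  render <- function(i) {
    inner <- c(vapply(which(parent == i), render, character(1)),
               labs[tip_parent == i])
    if (i == 0L) paste0("(", paste(inner, collapse = ","), ");")
    else paste0("(", paste(inner, collapse = ","), ")",
                format(support[i], trim = TRUE, digits = 4))
  }
  ape::read.tree(text = render(0L))
}

# shared bootstrap driver: resample columns, rebuild distance + tree
.bootstrap_trees <- function(m, n_replicates, seed, tree_of_cols) {
  with_seed(seed, {
    lapply(seq_len(n_replicates), function(r)
      tree_of_cols(sample.int(m, m, replace = TRUE)))
  })
}

#' Bootstrap consensus tree from a genotype matrix
#'
#' Resamples sites with replacement, recomputes the transversion-weighted
#' genotype distance and a BIO-NJ tree per replicate, and summarises the
#' replicates as a majority-rule extended consensus whose internal nodes
#' carry the percentage of replicates containing each bipartition.
#'
#' @param x complete-case biallelic \code{\link{genotype_matrix}}.
#' @param n_replicates bootstrap replicates (default 1000).
#' @param seed RNG seed for the resampling.
#' @param transversion_weight passed to \code{\link{vcfphylo_distance}}.
#' @return list: \code{consensus} (phylo with supports), \code{main}
#'   (BIO-NJ tree from the unresampled data), \code{n_replicates}.
#' @export
bootstrap_consensus <- function(x, n_replicates = 1000, seed = 1,
                                transversion_weight = 2) {
  .check(n_replicates >= 1, "need at least one replicate")
  tv <- site_is_transversion(x)
  w <- ifelse(tv, transversion_weight, 1)
  f <- sweep(x$geno / 2, 2, sqrt(w), `*`)
  tree_of <- function(cols) {
    d <- .euclid(f[, cols, drop = FALSE])
    dimnames(d) <- list(x$samples, x$samples)
    bionj_tree(d)
  }
  trees <- .bootstrap_trees(ncol(f), n_replicates, seed, tree_of)
  list(consensus = consensus_tree(trees),
       main = bionj_tree(vcfphylo_distance(x, transversion_weight)),
       n_replicates = n_replicates)
}

#' Bootstrap consensus tree from a marker alignment (K2P + BIO-NJ)
#'
#' Alignment-column bootstrap of the Kimura 2-parameter BIO-NJ tree,
#' summarised as in \code{\link{bootstrap_consensus}}.
#'
#' @param aln \code{DNAbin} matrix.
#' @param n_replicates bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return list: \code{consensus}, \code{main}, \code{n_replicates}.
#' @export
k2p_bootstrap_consensus <- function(aln, n_replicates = 1000, seed = 1) {
  mat <- as.matrix(aln)
  tree_of <- function(cols) bionj_tree(k2p_matrix(mat[, cols, drop = FALSE]))
  trees <- .bootstrap_trees(ncol(mat), n_replicates, seed, tree_of)
  list(consensus = consensus_tree(trees),
       main = bionj_tree(k2p_matrix(mat)),
       n_replicates = n_replicates)
}

#' Monophyly and bootstrap support of a label set
#'
#' On an unrooted tree a label set is monophyletic iff it forms one side of
#' some edge. The support returned is that edge's bootstrap percentage
#' (taken from \code{node.label}); 0 when the tree carries no support for
#' the edge. Singletons and the full label set are trivially monophyletic
#' with support 100.
#'
#' @param tree a \code{phylo}, optionally with supports in
#'   \code{node.label}.
#' @param labels character vector of leaf labels.
#' @return list: \code{is_monophyletic} (logical), \code{support}
#'   (percentage in [0, 100]).
#' @export
clade_support <- function(tree, labels) {
  tips <- tree$tip.label
  unknown <- setdiff(labels, tips)
  .check(length(unknown) == 0, "unknown label(s): %s",
         paste(unknown, collapse = ", "))
  labels <- unique(labels)
  n <- length(tips)
  if (length(labels) %in% c(1L, n, n - 1L))
    return(list(is_monophyletic = TRUE, support = 100))
  pp <- ape::prop.part(tree)
  node_support <- function(idx) {
    # idx-th entry of prop.part corresponds to internal node n + idx
    if (is.null(tree$node.label)) return(0)
    lab <- tree$node.label[idx]
    v <- suppressWarnings(as.numeric(lab))
    if (is.na(v)) 0 else v
  }
  want <- .split_key(labels)
  want_c <- .split_key(setdiff(tips, labels))
  for (i in seq_along(pp)) {
    side <- tips[pp[[i]]]
    k <- .split_key(side)
    if (identical(k, want) || identical(k, want_c))
      return(list(is_monophyletic = TRUE, support = node_support(i)))
  }
  list(is_monophyletic = FALSE, support = 0)
}

#' Write a tree as Newick, optionally rooted on an outgroup
#'
#' @param tree a \code{phylo}.
#' @param path output path.
#' @param outgroup optional tip label to root on; otherwise the arbitrary
#'   internal representation is written as is.
#' @export
write_newick <- function(tree, path, outgroup = NULL) {
  if (!is.null(outgroup)) {
    .check(outgroup %in% tree$tip.label, "outgroup '%s' absent from tree", outgroup)
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
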