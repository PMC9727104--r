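# Population structure: variance-standardised genotype PCA, k-means group
# assignment, and strain typing from the TPI and COX1 diagnostic markers.

#' Variance-standardised genotype PCA
#'
#' Each variant is centered by its mean dosage 2p and scaled by
#' sqrt(2 p (1 - p)) with p the sample allele frequency (the standard
#' genotype-PCA normalisation, under which each site contributes unit
#' drift variance). Missing dosages are mean-imputed; monomorphic sites
#' are dropped. The explained fraction of each component uses the full
#' eigenvalue sum (the trace of the sample covariance), i.e. whole-spectrum
#' normalisation.
#'
#' @param x a \code{\link{genotype_matrix}} with at least 2 samples and one
#'   polymorphic site.
#' @param n_components number of components to retain (default 10).
#' @return object of class \code{genotype_pca}: \code{scores} (samples x
#'   components, each column scaled by the square root of its eigenvalue),
#'   \code{eigenvalues} (full non-increasing spectrum),
#'   \code{explained_fraction} (per component, against the full spectrum),
#'   \code{n_components}.
#' @export
genotype_pca <- function(x, n_components = 10) {
  g <- x$geno
  .check(nrow(g) >= 2, "PCA needs at least 2 samples")
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  .check(any(poly), "all sites are monomorphic: PCA undefined")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  center <- 2 * p
  scale <- sqrt(2 * p * (1 - p))
  gs <- sweep(g, 2, center, `-`)
  gs[is.na(gs)] <- 0                       # mean imputation after centering
  gs <- sweep(gs, 2, scale, `/`)
  covar <- tcrossprod(gs) / ncol(gs)
  eig <- eigen(covar, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  k <- min(n_components, length(lambda))
  scores <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(lambda[seq_len(k)]), k)
  rownames(scores) <- x$samples
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, eigenvalues = lambda,
                 explained_fraction = lambda / sum(lambda),
                 n_components = k),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat(sprintf("genotype_pca: %d samples, %d components retained\n",
              nrow(x$scores), x$n_components))
  pct <- 100 * x$explained_fraction[seq_len(min(3, x$n_components))]
  cat(sprintf("  variance explained: %s\n",
              paste(sprintf("PC%d %.2f%%", seq_along(pct), pct), collapse = ", ")))
  invisible(x)
}

#' Assign samples to groups by k-means on the leading components
#'
#' The study design identifies its main groups from the two major
#' principal components; this makes that step algorithmic: k-means on the
#' top two score columns with 25 restarts under a fixed seed, so labels
#' are arbitrary integers but stable for a given seed.
#'
#' @param pca a \code{\link{genotype_pca}} result.
#' @param k number of groups.
#' @param seed RNG seed for the restarts.
#' @return named integer vector of group labels (1..k) per sample.
#' @export
assign_groups <- function(pca, k, seed = 1) {
  .check(k >= 1, "k must be at least 1")
  .check(k <= nrow(pca$scores), "k = %d exceeds the %d samples",
         k, nrow(pca$scores))
  sc <- pca$scores[, seq_len(min(2, ncol(pca$scores))), drop = FALSE]
  if (k == 1) return(setNames(rep(1L, nrow(sc)), rownames(sc)))
  km <- with_seed(seed, kmeans(sc, centers = k, nstart = 25))
  setNames(as.integer(km$cluster), rownames(sc))
}

#' Strain typing from the TPI marker locus
#'
#' PCA on the TPI-locus genotypes, 2-means clustering on the first
#' component, and anchor-based naming: each cluster takes the strain label
#' of the anchor samples it contains. If a cluster contains anchors of
#' both strains its samples are left unassigned with a warning; a cluster
#' without anchors is likewise unassigned.
#'
#' @param tpi a \code{\link{genotype_matrix}} of TPI-locus sites.
#' @param anchors named character vector: sample id -> known strain
#'   ("sfC"/"sfR"); must cover both strains.
#' @param seed RNG seed for the clustering restarts.
#' @return data.frame: \code{sample_id}, \code{tpi_strain} in
#'   \{sfC, sfR, unassigned\}.
#' @export
tpi_strain_call <- function(tpi, anchors, seed = 1) {
  .check(all(c("sfC", "sfR") %in% anchors),
         "anchors must cover both strains (sfC and sfR)")
  .check(all(names(anchors) %in% tpi$samples),
         "anchor sample(s) absent from the TPI matrix")
  pca <- genotype_pca(tpi, n_components = 1)
  km <- with_seed(seed, kmeans(pca$scores[, 1], centers = 2, nstart = 25))
  cl <- km$cluster
  call <- rep("unassigned", length(cl))
  for (cluster in 1:2) {
    in_cl <- names(cl)[cl == cluster]
    anch <- unique(anchors[names(anchors) %in% in_cl])
    if (length(anch) == 1) {
      call[cl == cluster] <- anch
    } else if (length(anch) > 1) {
      warning(sprintf(
        "TPI cluster %d contains anchors of both strains; its %d samples left unassigned",
        cluster, length(in_cl)), call. = FALSE)
    }
  }
  data.frame(sample_id = tpi$samples, tpi_strain = call,
             stringsAsFactors = FALSE)
}

#' Mitochondrial strain typing from the COX1 barcode tree
#'
#' Builds the Kimura 2-parameter BIO-NJ tree, roots it on the outgroup,
#' and labels every sample by the anchored clade containing it: the clade
#' of strain S is the largest clade that holds every S anchor and no
#' anchor of the other strain (found by walking rootward from the anchor
#' MRCA). Samples inside both anchored clades (unresolved trees) or
#' neither are unassigned.
#'
#' @param aln \code{DNAbin} alignment including the outgroup sequence.
#' @param anchors named character vector: sample id -> known strain;
#'   must cover both strains.
#' @param outgroup_label tip used to root the tree.
#' @return data.frame: \code{sample_id}, \code{cox1_strain} in
#'   \{sfC, sfR, unassigned\}, one row per non-outgroup sequence.
#' @export
cox1_strain_call <- function(aln, anchors, outgroup_label = "outgroup") {
  mat <- as.matrix(aln)
  ids <- rownames(mat)
  .check(outgroup_label %in% ids, "outgroup label '%s' absent from alignment",
         outgroup_label)
  .check(all(c("sfC", "sfR") %in% anchors),
         "anchors must cover both strains (sfC and sfR)")
  .check(all(names(anchors) %in% ids), "anchor sample(s) absent from alignment")
  samples <- setdiff(ids, outgroup_label)
  d <- k2p_matrix(mat)
  # zero within-sample divergence: no resolved clades exist
  if (all(d[samples, samples] == 0))
    return(data.frame(sample_id = samples,
                      cox1_strain = "unassigned", stringsAsFactors = FALSE))
  tree <- ape::root(bionj_tree(d), outgroup = outgroup_label,
                    resolve.root = TRUE)
  root_node <- length(tree$tip.label) + 1L
  parent_of <- function(node) tree$edge[tree$edge[, 2] == node, 1]
  clade_of <- function(strain) {
    tips <- names(anchors)[anchors == strain]
    others <- names(anchors)[anchors != strain]
    node <- if (length(tips) == 1) match(tips, tree$tip.label)
            else ape::getMRCA(tree, tips)
    members <- function(nd) {
      if (nd <= length(tree$tip.label)) tree$tip.label[nd]
      else ape::extract.clade(tree, nd)$tip.label
    }
    # expand rootward while the clade stays pure of opposite anchors and
    # of the outgroup
    repeat {
      up <- parent_of(node)
      if (length(up) == 0 || node == root_node) break
      m_up <- members(up)
      if (any(others %in% m_up) || outgroup_label %in% m_up) break
      node <- up
    }
    setdiff(members(node), outgroup_label)
  }
  in_c <- samples %in% clade_of("sfC")
  in_r <- samples %in% clade_of("sfR")
  call <- ifelse(in_c & !in_r, "sfC", ifelse(in_r & !in_c, "sfR", "unassigned"))
  data.frame(sample_id = samples, cox1_strain = call, stringsAsFactors = FALSE)
}

#' Anchor vector from a manifest column
#' @param manifest sample manifest data.frame.
#' @param column anchor column name (\code{"anchor_tpi"} or
#'   \code{"anchor_cox1"}).
#' @return named character vector sample id -> strain.
#' @export
manifest_anchors <- function(manifest, column) {
  keep <- !is.na(manifest[[column]])
  setNames(manifest[[column]][keep], manifest$sample_id[keep])
}
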