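# Pairwise distances: Kimura 2-parameter for marker alignments and the
# transversion-weighted Euclidean genotype distance used for the
# individual-level nuclear phylogeny.

#' Kimura 2-parameter distance between two aligned sequences
#'
#' d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q)), with P and Q the proportions of
#' transition- and transversion-differing positions among the pairwise
#' compared positions (gaps and ambiguity codes are skipped pairwise). A
#' uniform substitution rate across the alignment is assumed. When the
#' observed divergence saturates the model (1 - 2P - Q <= 0 or
#' 1 - 2Q <= 0) a condition of class \code{"k2p_saturation"} is raised.
#'
#' @param seq_a,seq_b equal-length character vectors of nucleotides (or
#'   single strings).
#' @return distance in substitutions per site.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  if (length(seq_a) == 1 && nchar(seq_a[1]) > 1) seq_a <- strsplit(seq_a, "")[[1]]
  if (length(seq_b) == 1 && nchar(seq_b[1]) > 1) seq_b <- strsplit(seq_b, "")[[1]]
  .check(length(seq_a) == length(seq_b), "sequences must be aligned (equal length)")
  a <- toupper(seq_a); b <- toupper(seq_b)
  acgt <- c("A", "C", "G", "T")
  use <- a %in% acgt & b %in% acgt
  .check(any(use), "no comparable positions")
  a <- a[use]; b <- b[use]
  diff <- a != b
  purine <- c("A", "G")
  ts <- diff & ((a %in% purine) == (b %in% purine))
  p <- sum(ts) / length(a)
  q <- sum(diff & !ts) / length(a)
  k2p_from_pq(p, q)
}

# closed form shared by the scalar and matrix paths
k2p_from_pq <- function(p, q) {
  t1 <- 1 - 2 * p - q
  t2 <- 1 - 2 * q
  if (any(t1 <= 0) || any(t2 <= 0))
    stop(errorCondition(
      "K2P distance undefined: observed divergence saturates the model",
      class = c("k2p_saturation", "error", "condition")))
  -0.5 * log(t1 * sqrt(t2))
}

#' Kimura 2-parameter distance matrix for an alignment
#'
#' Vectorised all-pairs version of \code{\link{k2p_distance}} (indicator
#' cross-products over the alignment columns); pairwise deletion of
#' non-ACGT positions.
#'
#' @param aln an \code{ape::DNAbin} matrix or character matrix
#'   (sequences x positions).
#' @return a labelled symmetric \code{distance_matrix} (base matrix).
#' @export
k2p_matrix <- function(aln) {
  mat <- toupper(as.character(as.matrix(aln)))
  labels <- rownames(mat)
  ind <- lapply(c("A", "C", "G", "T"), function(b) (mat == b) * 1)
  names(ind) <- c("A", "C", "G", "T")
  valid <- ind$A + ind$C + ind$G + ind$T
  n_cmp <- tcrossprod(valid)
  .check(all(n_cmp[upper.tri(n_cmp)] > 0), "some pair has no comparable positions")
  same <- Reduce(`+`, lapply(ind, tcrossprod))
  ts <- tcrossprod(ind$A, ind$G) + tcrossprod(ind$G, ind$A) +
    tcrossprod(ind$C, ind$T) + tcrossprod(ind$T, ind$C)
  p <- ts / n_cmp
  q <- (n_cmp - same - ts) / n_cmp
  d <- k2p_from_pq(p, q)
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  d
}

#' Transversion-weighted Euclidean genotype distance between individuals
#'
#' Per individual and site, the allele frequency f = dosage / 2 is 0, 0.5
#' or 1; the distance between individuals i and j is
#' sqrt(sum_s w_s (f_is - f_js)^2) over the complete-case biallelic sites,
#' with weight w_s = 2 at transversion sites and 1 at transition sites
#' (transversions are rarer and less prone to saturation, so they carry
#' double weight).
#'
#' @param x a \code{\link{genotype_matrix}} with no missing dosages
#'   (run \code{\link{select_biallelic_complete}} first).
#' @param transversion_weight weight applied to transversion sites
#'   (default 2).
#' @param weight_on how the weight enters: \code{"squared_difference"}
#'   (default, w_s multiplies the squared per-site difference) or
#'   \code{"difference"} (w_s scales the unsquared difference, i.e. w_s^2
#'   multiplies the squared term).
#' @return labelled symmetric distance matrix.
#' @export
vcfphylo_distance <- function(x, transversion_weight = 2,
                              weight_on = c("squared_difference", "difference")) {
  weight_on <- match.arg(weight_on)
  .check(!anyNA(x$geno), "missing dosages present: run select_biallelic_complete() first")
  tv <- site_is_transversion(x)
  .check(!anyNA(tv), "non-SNV sites present: run select_biallelic_complete() first")
  w <- ifelse(tv, transversion_weight, 1)
  colscale <- if (weight_on == "squared_difference") sqrt(w) else w
  f <- sweep(x$geno / 2, 2, colscale, `*`)
  d <- .euclid(f)
  dimnames(d) <- list(x$samples, x$samples)
  d
}

# all-pairs Euclidean distance via the Gram matrix (much faster than
# stats::dist at this shape); clamps tiny negative squares from rounding
.euclid <- function(f) {
  g <- tcrossprod(f)
  sq <- diag(g)
  d <- sqrt(pmax(outer(sq, sq, `+`) - 2 * g, 0))
  diag(d) <- 0
  d
}

#' Write / read a distance matrix in PHYLIP square format
#' @param d labelled symmetric matrix.
#' @param path file path.
#' @export
write_phylip_dist <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(c(sprintf("%-10s", rownames(d)[i]),
                       sprintf("%.6f", d[i, ])), collapse = " "), con)
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  toks <- strsplit(trimws(lines[-1][seq_len(n)]), "\\s+")
  labels <- vapply(toks, `[`, character(1), 1)
  d <- t(vapply(toks, function(x) as.numeric(x[-1]), numeric(n)))
  dimnames(d) <- list(labels, labels)
  d
}
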