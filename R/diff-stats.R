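# Population differentiation: Weir & Cockerham (1984) variance-components
# F_ST (per site, windowed, genome-wide weighted), a label-permutation
# significance test, and windowed absolute divergence D_XY.

# normalise a grouping argument into a list of row index vectors
.group_rows <- function(x, grouping) {
  if (is.list(grouping) && !is.data.frame(grouping)) {
    idx <- lapply(grouping, function(g)
      if (is.character(g)) match(g, x$samples) else g)
    .check(!anyNA(unlist(idx)), "grouping names unknown sample ids")
    if (is.null(names(idx))) names(idx) <- paste0("group", seq_along(idx))
    return(idx)
  }
  if (!is.null(names(grouping)))
    grouping <- grouping[match(x$samples, names(grouping))]
  .check(length(grouping) == length(x$samples),
         "grouping must cover every sample")
  split(seq_along(x$samples), as.character(grouping))
}

# per-site W&C (1984) variance components a, b, c for r >= 2 diploid groups
.fst_components <- function(geno, idx_list) {
  r <- length(idx_list)
  m <- ncol(geno)
  n_i <- matrix(0, r, m); p_i <- matrix(0, r, m); h_i <- matrix(0, r, m)
  for (g in seq_len(r)) {
    block <- geno[idx_list[[g]], , drop = FALSE]
    known <- !is.na(block)
    n_i[g, ] <- colSums(known)
    tot <- colSums(block, na.rm = TRUE)
    p_i[g, ] <- ifelse(n_i[g, ] > 0, tot / (2 * n_i[g, ]), NA)
    h_i[g, ] <- ifelse(n_i[g, ] > 0,
                       colSums(block == 1L, na.rm = TRUE) / n_i[g, ], NA)
  }
  nbar <- colSums(n_i) / r
  nc <- (r * nbar - colSums(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(n_i * p_i) / (r * nbar)
  s2 <- colSums(n_i * (p_i - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  list(a = a, b = b, c = c_)
}

# genome-wide weighted mean from components (sites with undefined or zero
# denominators contribute nothing)
.wc_weighted_mean <- function(comp) {
  denom <- comp$a + comp$b + comp$c
  ok <- is.finite(denom) & denom != 0
  sum(comp$a[ok]) / sum(denom[ok])
}

#' Weir-Cockerham F_ST
#'
#' Per-site variance components a (among populations), b (among
#' individuals within populations) and c (within individuals) of the
#' Weir & Cockerham (1984) estimator, computed from diploid genotype
#' counts, plus the genome-wide weighted mean sum(a) / sum(a + b + c) over
#' sites with a defined, non-zero denominator. Sites where components are
#' undefined (fewer than two genotyped groups, or singleton groups) are
#' flagged, not silently dropped.
#'
#' @param x a \code{\link{genotype_matrix}}.
#' @param grouping either a (named) vector of group labels per sample, or
#'   a list of sample-id vectors, with at least two groups.
#' @return list of class \code{wc_fst}: \code{components} (data.frame a,
#'   b, c, defined flag, per-site ratio), \code{weighted_mean},
#'   \code{groups}.
#' @export
wc_fst <- function(x, grouping) {
  idx <- .group_rows(x, grouping)
  .check(length(idx) >= 2, "F_ST needs at least two groups")
  .check(all(lengths(idx) > 0), "every group needs at least one sample")
  comp <- .fst_components(x$geno, idx)
  denom <- comp$a + comp$b + comp$c
  defined <- is.finite(denom)
  ratio <- ifelse(defined & denom != 0, comp$a / denom, NA_real_)
  structure(list(
    components = data.frame(a = comp$a, b = comp$b, c = comp$c,
                            defined = defined, ratio = ratio),
    weighted_mean = .wc_weighted_mean(comp),
    groups = names(idx)), class = "wc_fst")
}

#' @export
print.wc_fst <- function(x, ...) {
  cat(sprintf("Weir-Cockerham F_ST (%s): weighted mean %.5f over %d sites\n",
              paste(x$groups, collapse = " vs "),
              x$weighted_mean, nrow(x$components)))
  invisible(x)
}

# half-open [start, end) windows aligned at coordinate 1, never spanning
# scaffolds; lengths default to the last observed position per scaffold
.window_frame <- function(sites, window_bp, scaffold_lengths = NULL) {
  .check(window_bp > 0, "window_bp must be positive")
  scafs <- unique(sites$scaffold)
  if (is.null(scaffold_lengths))
    scaffold_lengths <- tapply(sites$pos, sites$scaffold, max)[scafs]
  out <- do.call(rbind, lapply(scafs, function(sc) {
    len <- scaffold_lengths[[sc]]
    starts <- seq(1, len, by = window_bp)
    data.frame(scaffold = sc, start = starts,
               end = pmin(starts + window_bp, len + 1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

.site_window <- function(sites, windows, window_bp) {
  key_w <- paste(windows$scaffold, windows$start)
  key_s <- paste(sites$scaffold, (sites$pos - 1) %/% window_bp * window_bp + 1)
  match(key_s, key_w)
}

#' Windowed Weir-Cockerham F_ST
#'
#' Weighted-mean F_ST per non-overlapping window (half-open [start, end)
#' intervals aligned at coordinate 1, never spanning scaffolds). Empty
#' windows are emitted with a missing value.
#'
#' @inheritParams wc_fst
#' @param window_bp window width in bp (default 100 kb).
#' @param scaffold_lengths optional named vector of scaffold lengths;
#'   defaults to the last observed position per scaffold.
#' @return data.frame: scaffold, start, end, value, n_sites.
#' @export
windowed_fst <- function(x, grouping, window_bp = 100000,
                         scaffold_lengths = NULL) {
  idx <- .group_rows(x, grouping)
  comp <- .fst_components(x$geno, idx)
  denom <- comp$a + comp$b + comp$c
  ok <- is.finite(denom) & denom != 0
  win <- .window_frame(x$sites, window_bp, scaffold_lengths)
  wi <- .site_window(x$sites, win, window_bp)
  num_w <- rowsum(ifelse(ok, comp$a, 0), wi, reorder = FALSE)
  den_w <- rowsum(ifelse(ok, denom, 0), wi, reorder = FALSE)
  cnt_w <- rowsum(as.numeric(ok), wi, reorder = FALSE)
  win$value <- NA_real_
  win$n_sites <- 0L
  rows <- as.integer(rownames(num_w))
  win$n_sites[rows] <- as.integer(cnt_w)
  win$value[rows] <- ifelse(den_w != 0, num_w / den_w, NA_real_)
  win$value[win$n_sites == 0] <- NA_real_
  win
}

#' Permutation test of genetic differentiation
#'
#' Group labels are permuted uniformly (preserving group sizes), the
#' genome-wide weighted-mean F_ST is recomputed per replicate, and the
#' proportion of random groupings with higher F_ST than the real grouping
#' is the p-value. The conservative estimate
#' (1 + #\{null >= observed\}) / (1 + R) is also reported.
#'
#' @inheritParams wc_fst
#' @param n_replicates number of label permutations R (default 100).
#' @param seed RNG seed.
#' @return list of class \code{fst_permutation}: \code{observed},
#'   \code{null} (length R), \code{p}, \code{p_conservative},
#'   \code{n_replicates}, \code{seed}.
#' @export
fst_permutation_test <- function(x, grouping, n_replicates = 100, seed = 1) {
  .check(n_replicates >= 1, "need at least one replicate")
  idx <- .group_rows(x, grouping)
  sizes <- lengths(idx)
  pool <- unlist(idx, use.names = FALSE)
  observed <- .wc_weighted_mean(.fst_components(x$geno, idx))
  null <- with_seed(seed, vapply(seq_len(n_replicates), function(r) {
    perm <- sample(pool)
    split_idx <- split(perm, rep(seq_along(sizes), sizes))
    .wc_weighted_mean(.fst_components(x$geno, split_idx))
  }, numeric(1)))
  structure(list(observed = observed, null = null,
                 p = mean(null > observed),
                 p_conservative = (1 + sum(null >= observed)) / (1 + n_replicates),
                 n_replicates = n_replicates, seed = seed),
            class = "fst_permutation")
}

#' @export
print.fst_permutation <- function(x, ...) {
  cat(sprintf("F_ST permutation test: observed %.5f, p = %.4g (conservative %.4g, R = %d)\n",
              x$observed, x$p, x$p_conservative, x$n_replicates))
  invisible(x)
}

#' Windowed absolute divergence D_XY
#'
#' Per site, d_xy = p_a (1 - p_b) + p_b (1 - p_a) with p_a, p_b the group
#' allele frequencies - the expected proportion of allele differences
#' between one allele drawn from each group. The window value is the mean
#' over the SNVs in the window (per-SNV average; no per-bp normalisation,
#' so absolute levels are comparable only within a run).
#'
#' @param x a \code{\link{genotype_matrix}}.
#' @param group_a,group_b sample-id vectors (or logical/integer indices).
#' @param window_bp window width in bp.
#' @param scaffold_lengths optional named scaffold lengths.
#' @return data.frame: scaffold, start, end, value, n_sites.
#' @export
windowed_dxy <- function(x, group_a, group_b, window_bp = 100000,
                         scaffold_lengths = NULL) {
  idx <- .group_rows(x, list(a = group_a, b = group_b))
  .check(all(lengths(idx) > 0), "both groups must be non-empty")
  pa <- colMeans(x$geno[idx[[1]], , drop = FALSE], na.rm = TRUE) / 2
  pb <- colMeans(x$geno[idx[[2]], , drop = FALSE], na.rm = TRUE) / 2
  dxy <- pa * (1 - pb) + pb * (1 - pa)
  win <- .window_frame(x$sites, window_bp, scaffold_lengths)
  wi <- .site_window(x$sites, win, window_bp)
  ok <- is.finite(dxy)
  sum_w <- rowsum(ifelse(ok, dxy, 0), wi, reorder = FALSE)
  cnt_w <- rowsum(as.numeric(ok), wi, reorder = FALSE)
  win$value <- NA_real_; win$n_sites <- 0L
  rows <- as.integer(rownames(sum_w))
  win$n_sites[rows] <- as.integer(cnt_w)
  win$value[rows] <- ifelse(cnt_w > 0, sum_w / cnt_w, NA_real_)
  win
}

#' Between-mitochondrial-strain D_XY, invasive versus native
#'
#' Computes windowed D_XY between the two COX1-strain groups separately
#' within the invasive and within the native samples. If invasive
#' populations experienced admixture between the strains, their
#' between-strain D_XY is expected to fall below the native value.
#'
#' @param x a \code{\link{genotype_matrix}}.
#' @param manifest sample manifest (needs \code{sample_id},
#'   \code{status}).
#' @param strain_calls data.frame with \code{sample_id} and
#'   \code{cox1_strain}.
#' @param window_bp window width in bp.
#' @param scaffold_lengths optional named scaffold lengths.
#' @return list: \code{invasive}, \code{native} (window data.frames) and
#'   \code{summary} (median per class over non-empty windows, and the
#'   proportion of windows where invasive < native, ties counting 1/2).
#' @export
compare_strain_dxy <- function(x, manifest, strain_calls,
                               window_bp = 100000, scaffold_lengths = NULL) {
  man <- merge(manifest, strain_calls, by = "sample_id")
  res <- lapply(c("invasive", "native"), function(cls) {
    sub <- man[man$status == cls & man$cox1_strain %in% c("sfC", "sfR"), ]
    .check(all(c("sfC", "sfR") %in% sub$cox1_strain),
           "%s samples lack one of the mitochondrial strains", cls)
    windowed_dxy(x,
                 sub$sample_id[sub$cox1_strain == "sfC"],
                 sub$sample_id[sub$cox1_strain == "sfR"],
                 window_bp, scaffold_lengths)
  })
  names(res) <- c("invasive", "native")
  both <- res$invasive$n_sites > 0 & res$native$n_sites > 0
  vi <- res$invasive$value[both]; vn <- res$native$value[both]
  prop_lower <- if (any(both)) mean((vi < vn) + 0.5 * (vi == vn)) else NA_real_
  res$summary <- list(
    median_invasive = median(res$invasive$value[res$invasive$n_sites > 0]),
    median_native = median(res$native$value[res$native$n_sites > 0]),
    prop_windows_invasive_lower = prop_lower,
    n_windows_compared = sum(both))
  res
}
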