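# Composite-likelihood selective-sweep scan from the site frequency
# spectrum.
#
# Background model: every segregating site draws its derived-allele count
# k from the genome-wide spectrum phi. Sweep model at distance d from a
# grid position, with intensity alpha per bp: each of the n sampled
# lineages independently escapes the sweep with probability
# P_e = 1 - exp(-alpha d); the escapees are a without-replacement draw
# from the pre-sweep sample configuration (hypergeometric), and all
# non-escaping lineages collapse onto one beneficial haplotype whose
# allelic state is derived with the pre-sweep sample frequency. At
# P_e = 1 the sweep model reduces exactly to the background, so the
# composite-likelihood ratio Lambda = 2 (max_alpha ln L1 - ln L0) is
# non-negative by construction (alpha = Inf, the quasi-neutral extreme,
# is always part of the maximisation).

#' Site frequency spectrum of a genotype matrix
#'
#' Derived-allele counts k = sum of dosages per site, with the REF allele
#' treated as ancestral (unfolded); the folded option maps k to
#' min(k, n - k). Monomorphic sites are excluded.
#'
#' @param x complete-case biallelic \code{\link{genotype_matrix}}.
#' @param polarization \code{"unfolded"} (default) or \code{"folded"}.
#' @return list of class \code{sfs}: \code{n} (haploid sample size),
#'   \code{counts} (named vector over k = 1..n-1, or 1..floor(n/2) when
#'   folded), \code{polarization}.
#' @export
compute_sfs <- function(x, polarization = c("unfolded", "folded")) {
  polarization <- match.arg(polarization)
  .check(!anyNA(x$geno), "missing dosages: run select_biallelic_complete() first")
  n <- 2L * nrow(x$geno)
  k <- colSums(x$geno)
  k <- k[k > 0 & k < n]
  if (polarization == "folded") {
    k <- pmin(k, n - k)
    classes <- seq_len(n %/% 2)
  } else classes <- seq_len(n - 1)
  counts <- tabulate(k, nbins = max(classes))[classes]
  names(counts) <- classes
  structure(list(n = n, counts = counts, polarization = polarization),
            class = "sfs")
}

# background class probabilities with add-one smoothing on empty classes
.sfs_probs <- function(sfs) {
  cnt <- sfs$counts
  cnt[cnt == 0] <- 1
  cnt / sum(cnt)
}

# Precomputed pieces of the sweep site distribution, shared across escape
# probabilities: for each escapee count e, the joint weight of observing b
# derived alleles among the escapees together with the beneficial-haplotype
# state (S1 derived, S0 ancestral), marginalised over the background
# spectrum. phi is defined over j = 1..n-1 (unfolded).
.psweep_tables <- function(phi, n) {
  j <- seq_len(n - 1)
  p_j <- j / n
  w0 <- phi * (1 - p_j)
  w1 <- phi * p_j
  s0 <- vector("list", n + 1)
  s1 <- vector("list", n + 1)
  for (e in 0:n) {
    b <- 0:e
    # dh[b+1, j] = P(b of the e escapees are derived | j of n derived)
    dh <- outer(b, j, function(bb, jj) dhyper(bb, jj, n - jj, e))
    s0[[e + 1]] <- as.vector(dh %*% w0)
    s1[[e + 1]] <- as.vector(dh %*% w1)
  }
  list(s0 = s0, s1 = s1, n = n)
}

# exact sweep distribution over k = 0..n for one escape probability
.psweep_given_pe <- function(tables, pe) {
  n <- tables$n
  out <- numeric(n + 1)
  we <- dbinom(0:n, n, pe)
  for (e in 0:n) {
    if (we[e + 1] == 0) next
    b <- 0:e
    # ancestral beneficial haplotype: k = b ; derived: k = b + (n - e)
    out[b + 1] <- out[b + 1] + we[e + 1] * tables$s0[[e + 1]]
    out[b + (n - e) + 1] <- out[b + (n - e) + 1] + we[e + 1] * tables$s1[[e + 1]]
  }
  out
}

#' Exact sweep-model site distribution
#'
#' Probability distribution of the post-sweep derived-allele count
#' k = 0..n at a site with escape probability \code{pe}, given a
#' background spectrum. Sums to one for every (pe, n); at pe = 1 it
#' equals the background spectrum (neutrality is nested).
#'
#' @param sfs an (unfolded) \code{\link{compute_sfs}} result, or a
#'   probability vector over k = 1..n-1.
#' @param pe escape probability in [0, 1].
#' @param n haploid sample size (required when \code{sfs} is a bare
#'   probability vector).
#' @return numeric vector of length n + 1 (k = 0..n).
#' @export
sweep_site_probability <- function(sfs, pe, n = NULL) {
  if (inherits(sfs, "sfs")) {
    .check(sfs$polarization == "unfolded", "sweep model needs the unfolded spectrum")
    n <- sfs$n
    phi <- .sfs_probs(sfs)
  } else {
    .check(!is.null(n), "n required when sfs is a probability vector")
    phi <- sfs / sum(sfs)
    .check(length(phi) == n - 1, "probability vector must cover k = 1..n-1")
  }
  .check(pe >= 0 && pe <= 1, "pe must lie in [0, 1]")
  .psweep_given_pe(.psweep_tables(phi, n), pe)
}

#' Composite-likelihood ratio sweep scan
#'
#' Grids are evenly spaced per scaffold. At each grid position the sweep
#' log-likelihood of all segregating sites on the scaffold is maximised
#' over a log-spaced alpha grid (alpha = Inf, i.e. the background itself,
#' is always included, so Lambda >= 0) and compared with the background
#' log-likelihood: Lambda = 2 (max_alpha ln L1 - ln L0).
#'
#' For speed the per-site sweep log-probability is tabulated on a log grid
#' of x = alpha * d (linear interpolation; sites with x above
#' \code{x_neutral} contribute exactly zero, and x below \code{x_min} is
#' clamped).
#'
#' @param x complete-case biallelic \code{\link{genotype_matrix}} of the
#'   scanned group (sites monomorphic within the group are ignored).
#' @param grids_per_scaffold number of grid positions per scaffold
#'   (default 1000).
#' @param alpha_grid sweep intensities (per bp) to maximise over; default
#'   16 log-spaced values spanning 1e-8 to 1e-2.
#' @param scaffold_lengths optional named scaffold lengths (bp); defaults
#'   to the last observed position per scaffold.
#' @param n_x_bins resolution of the x = alpha d interpolation table.
#' @param x_min,x_neutral clamping bounds of the table.
#' @return data.frame of class \code{clr_scan}: \code{scaffold},
#'   \code{grid} (index within scaffold), \code{pos}, \code{clr}
#'   (Lambda), \code{alpha_hat} (Inf when the background fits best);
#'   attributes \code{n} and \code{background} (spectrum probabilities).
#' @export
clr_scan <- function(x, grids_per_scaffold = 1000,
                     alpha_grid = 10^seq(-8, -2, length.out = 16),
                     scaffold_lengths = NULL,
                     n_x_bins = 64, x_min = 1e-4, x_neutral = 50) {
  .check(length(alpha_grid) >= 1, "alpha grid must be non-empty")
  .check(all(alpha_grid > 0), "alpha values must be positive")
  .check(!anyNA(x$geno), "missing dosages: run select_biallelic_complete() first")
  n <- 2L * nrow(x$geno)
  k_all <- colSums(x$geno)
  seg <- k_all > 0 & k_all < n
  .check(any(seg), "no segregating sites in the scanned group")
  sfs <- compute_sfs(gm_subset(x, sites = which(seg)))
  phi <- .sfs_probs(sfs)
  lnphi <- log(phi)

  # interpolation table: rows k = 1..n-1, columns log-spaced x values,
  # with an exact neutral endpoint at x >= x_neutral
  tables <- .psweep_tables(phi, n)
  xg <- exp(seq(log(x_min), log(x_neutral), length.out = n_x_bins))
  lnP <- vapply(xg, function(xx)
    log(pmax(.psweep_given_pe(tables, 1 - exp(-xx))[2:n], 1e-300)),
    numeric(n - 1))
  lnP[, n_x_bins] <- lnphi                 # exact nesting at the endpoint
  lxg <- log(xg)

  scafs <- unique(x$sites$scaffold)
  if (is.null(scaffold_lengths))
    scaffold_lengths <- tapply(x$sites$pos, x$sites$scaffold, max)[scafs]
  out <- list()
  for (sc in scafs) {
    on_sc <- seg & x$sites$scaffold == sc
    pos_s <- x$sites$pos[on_sc]
    k_s <- k_all[on_sc]
    l0 <- lnphi[k_s]
    gpos <- round(seq(1, scaffold_lengths[[sc]],
                      length.out = grids_per_scaffold))
    clr <- numeric(length(gpos)); ahat <- rep(Inf, length(gpos))
    for (g in seq_along(gpos)) {
      d <- abs(pos_s - gpos[g])
      best <- 0; besta <- Inf
      for (a in alpha_grid) {
        xx <- pmax(a * d, x_min)
        act <- xx < x_neutral
        if (!any(act)) next
        lx <- log(xx[act])
        idx <- pmin(pmax(findInterval(lx, lxg), 1L), n_x_bins - 1L)
        frac <- (lx - lxg[idx]) / (lxg[idx + 1L] - lxg[idx])
        rows <- k_s[act]
        v0 <- lnP[cbind(rows, idx)]
        v1 <- lnP[cbind(rows, idx + 1L)]
        ll <- sum(v0 + frac * (v1 - v0) - l0[act])
        if (ll > best) { best <- ll; besta <- a }
      }
      clr[g] <- 2 * best
      ahat[g] <- besta
    }
    out[[sc]] <- data.frame(scaffold = sc, grid = seq_along(gpos),
                            pos = gpos, clr = clr, alpha_hat = ahat,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n") <- n
  attr(res, "background") <- phi
  class(res) <- c("clr_scan", "data.frame")
  res
}

#' Flag outlier grids of a sweep scan
#'
#' Grids whose composite-likelihood ratio exceeds the threshold are
#' flagged. The summary reports the flagged count, the total number of
#' grids, the flagged percentage (rounded to 3 decimal places) and the
#' median composite likelihood.
#'
#' @param scan a \code{\link{clr_scan}} result.
#' @param threshold outlier threshold on Lambda (default 100; an
#'   explicitly arbitrary, scale-dependent choice - inspect the Lambda
#'   distribution reported in the summary before trusting it on a new
#'   dataset).
#' @return list: \code{flagged} (rows of the scan above threshold) and
#'   \code{summary} (count, total, percentage, median_clr, threshold).
#' @export
flag_outlier_grids <- function(scan, threshold = 100) {
  hit <- scan$clr > threshold
  list(flagged = scan[hit, , drop = FALSE],
       summary = list(count = sum(hit), total = nrow(scan),
                      percentage = round(100 * sum(hit) / nrow(scan), 3),
                      median_clr = median(scan$clr),
                      threshold = threshold))
}

#' Merge neighbouring flagged grids into sweep loci
#'
#' Runs of flagged grids on one scaffold with inter-grid index gaps of at
#' most \code{max_gap_grids} merge into a single locus spanning the first
#' to the last member grid position.
#'
#' @param flagged data.frame of flagged grids (from
#'   \code{\link{flag_outlier_grids}}; needs scaffold, grid, pos, clr).
#' @param max_gap_grids largest index gap still merged (default 0:
#'   strictly adjacent grids).
#' @return data.frame: scaffold, start, end (bp), n_grids, max_clr.
#' @export
merge_grids_to_loci <- function(flagged, max_gap_grids = 0) {
  if (nrow(flagged) == 0)
    return(data.frame(scaffold = character(0), start = numeric(0),
                      end = numeric(0), n_grids = integer(0),
                      max_clr = numeric(0)))
  flagged <- flagged[order(flagged$scaffold, flagged$grid), ]
  new_run <- c(TRUE, diff(flagged$grid) > max_gap_grids + 1 |
                 flagged$scaffold[-1] != flagged$scaffold[-nrow(flagged)])
  run <- cumsum(new_run)
  out <- do.call(rbind, lapply(split(flagged, run), function(b)
    data.frame(scaffold = b$scaffold[1], start = min(b$pos),
               end = max(b$pos), n_grids = nrow(b), max_clr = max(b$clr),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Filter sweep loci to those specific to the invasive scan
#'
#' A locus is invasive-specific iff no grid of the native scan within its
#' [start, end] span exceeds the threshold. Both scans must share grid
#' coordinates.
#'
#' @param loci locus table from \code{\link{merge_grids_to_loci}} (from
#'   the invasive scan).
#' @param invasive_scan,native_scan \code{\link{clr_scan}} results on
#'   identical grid coordinates.
#' @param threshold outlier threshold applied to the native scan.
#' @return \code{loci} with an added logical \code{invasive_specific}
#'   column.
#' @export
invasive_specific_loci <- function(loci, invasive_scan, native_scan,
                                   threshold = 100) {
  .check(identical(invasive_scan[c("scaffold", "grid", "pos")],
                   native_scan[c("scaffold", "grid", "pos")]),
         "scans have mismatched grid coordinates")
  loci$invasive_specific <- vapply(seq_len(nrow(loci)), function(i) {
    inside <- native_scan$scaffold == loci$scaffold[i] &
      native_scan$pos >= loci$start[i] & native_scan$pos <= loci$end[i]
    !any(native_scan$clr[inside] > threshold)
  }, logical(1))
  loci
}
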