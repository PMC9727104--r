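test_that("site frequency spectrum tallies derived counts by hand", {
  # 2 diploids -> n = 4 alleles; per-site derived counts 1, 1, 3, plus a
  # monomorphic site contributing nothing
  gm <- toy_gm(rbind(c(0L, 1L, 1L, 2L), c(1L, 0L, 2L, 2L)))
  sfs <- compute_sfs(gm)
  expect_equal(sfs$n, 4L)
  expect_equal(unname(sfs$counts), c(2L, 0L, 1L))
  expect_equal(sum(sfs$counts), 3L)       # number of segregating sites
  folded <- compute_sfs(gm, polarization = "folded")
  expect_equal(unname(folded$counts), c(3L, 0L))
})

test_that("the sweep site distribution is a probability distribution nesting neutrality", {
  phi <- c(6, 3, 2, 1, 1, 1, 1, 1, 1)
  phi <- phi / sum(phi)
  for (n_ in c(10L)) {
    for (pe in c(0, 0.05, 0.25, 0.5, 0.9, 0.999, 1)) {
      p <- sweep_site_probability(phi, pe, n = n_)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(p >= 0))
    }
  }
  # full escape reproduces the background exactly
  p1 <- sweep_site_probability(phi, 1, n = 10L)
  expect_equal(p1[2:10], phi, tolerance = 1e-12)
  # no escape collapses every site to monomorphism
  p0 <- sweep_site_probability(phi, 0, n = 10L)
  expect_equal(sum(p0[c(1, 11)]), 1, tolerance = 1e-12)
})

test_that("the scan is exactly zero in the quasi-neutral limit and never negative", {
  set.seed(40)
  gm <- toy_gm(matrix(rbinom(10 * 200, 2, runif(200, 0.05, 0.95)), 10),
               pos = sort(sample.int(1e5, 200)))
  # alpha 1 with positions >= 51 bp from any grid: every site neutral
  scan <- clr_scan(gm, grids_per_scaffold = 20, alpha_grid = 1,
                   scaffold_lengths = c(s1 = 1e5))
  expect_true(all(abs(scan$clr) <= 1e-6))
  scan2 <- clr_scan(gm, grids_per_scaffold = 50,
                    scaffold_lengths = c(s1 = 1e5))
  expect_true(all(scan2$clr >= 0))
  expect_equal(formals(clr_scan)$grids_per_scaffold, 1000)
  expect_error(clr_scan(gm, alpha_grid = numeric(0)), "non-empty")
})

test_that("outlier flagging and locus merging follow the grid bookkeeping rules", {
  scan <- data.frame(scaffold = "s1", grid = 1:4,
                     pos = c(100, 200, 300, 400),
                     clr = c(0, 50, 150, 101), alpha_hat = 1e-4)
  fl <- flag_outlier_grids(scan, threshold = 100)
  expect_identical(fl$flagged$grid, 3:4)
  expect_equal(fl$summary$count, 2L)
  expect_equal(fl$summary$median_clr, median(c(0, 50, 150, 101)))
  none <- flag_outlier_grids(transform(scan, clr = c(0, 1, 2, 3)))
  expect_equal(nrow(none$flagged), 0L)

  flagged <- data.frame(scaffold = "s1", grid = c(10L, 11L, 12L),
                        pos = c(1000, 1100, 1200), clr = c(120, 130, 110))
  expect_equal(nrow(merge_grids_to_loci(flagged)), 1L)
  expect_equal(merge_grids_to_loci(flagged)$n_grids, 3L)
  split2 <- data.frame(scaffold = "s1", grid = c(10L, 40L),
                       pos = c(1000, 4000), clr = c(120, 130))
  expect_equal(nrow(merge_grids_to_loci(split2)), 2L)
  expect_equal(nrow(merge_grids_to_loci(split2, max_gap_grids = 29)), 1L)
  twoscaf <- data.frame(scaffold = c("s1", "s2"), grid = c(10L, 11L),
                        pos = c(1000, 1100), clr = c(120, 130))
  expect_equal(nrow(merge_grids_to_loci(twoscaf)), 2L)
})

test_that("the invasive-specific filter excludes loci with native outliers", {
  grids <- data.frame(scaffold = "s1", grid = 1:10, pos = 1:10 * 100)
  inv <- cbind(grids, clr = c(0, 0, 120, 130, 0, 0, 150, 0, 0, 0),
               alpha_hat = 1e-4)
  nat0 <- cbind(grids, clr = 0, alpha_hat = Inf)
  nat_hit <- nat0; nat_hit$clr[3] <- 150
  loci <- merge_grids_to_loci(inv[inv$clr > 100, ])
  expect_equal(nrow(loci), 2L)
  all_kept <- invasive_specific_loci(loci, inv, nat0)
  expect_true(all(all_kept$invasive_specific))
  one_dropped <- invasive_specific_loci(loci, inv, nat_hit)
  expect_identical(one_dropped$invasive_specific, c(FALSE, TRUE))
  shifted <- nat0; shifted$pos <- shifted$pos + 1
  expect_error(invasive_specific_loci(loci, inv, shifted), "mismatched")
})
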