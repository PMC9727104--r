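test_that("Weir-Cockerham components match an independent per-site transcription", {
  set.seed(30)
  for (rep in 1:5) {
    r <- sample(2:4, 1)
    sizes <- sample(4:9, r, replace = TRUE)
    geno <- matrix(rbinom(sum(sizes) * 12, 2, runif(12, 0.1, 0.9)),
                   sum(sizes), byrow = FALSE)
    geno[sample(length(geno), 5)] <- NA_integer_
    gm <- toy_gm(geno)
    labels <- rep(seq_len(r), sizes)
    fit <- wc_fst(gm, setNames(labels, gm$samples))
    for (s in sample(12, 4)) {
      oracle <- wc_site_oracle(split(geno[, s], labels))
      expect_equal(fit$components$a[s], oracle[["a"]], tolerance = 1e-12)
      expect_equal(fit$components$b[s], oracle[["b"]], tolerance = 1e-12)
      expect_equal(fit$components$c[s], oracle[["c"]], tolerance = 1e-12)
    }
    # weighted mean is the ratio of summed components
    comp <- fit$components[fit$components$defined, ]
    expect_equal(fit$weighted_mean,
                 sum(comp$a) / sum(comp$a + comp$b + comp$c))
  }
})

test_that("F_ST hits 1 at fixed differences and stays at/below 0 without differentiation", {
  fixed <- toy_gm(rbind(matrix(0L, 8, 10), matrix(2L, 8, 10)))
  grouping <- rep(c("p1", "p2"), each = 8)
  expect_equal(wc_fst(fixed, setNames(grouping, fixed$samples))$weighted_mean, 1)

  same <- matrix(rep(c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 1L), 10), 8)
  ident <- toy_gm(rbind(same, same))
  f0 <- wc_fst(ident, setNames(grouping, ident$samples))$weighted_mean
  expect_lte(f0, 0)
  # per-site ratio never exceeds 1
  set.seed(31)
  gm <- toy_gm(matrix(rbinom(16 * 40, 2, 0.5), 16))
  fit <- wc_fst(gm, setNames(grouping, gm$samples))
  expect_true(all(fit$components$ratio <= 1, na.rm = TRUE))
  expect_error(wc_fst(gm, setNames(rep("p1", 16), gm$samples)), "two groups")
})

test_that("the single-site example matches the independent oracle", {
  gm <- toy_gm(matrix(c(0L, 1L, 1L, 2L), 4, 1))
  fit <- wc_fst(gm, setNames(c("p1", "p1", "p2", "p2"), gm$samples))
  oracle <- wc_site_oracle(list(c(0L, 1L), c(1L, 2L)))
  expect_equal(fit$weighted_mean,
               oracle[["a"]] / sum(oracle), tolerance = 1e-12)
})

test_that("windowed F_ST respects window and scaffold boundaries", {
  geno <- matrix(rbinom(8 * 6, 2, 0.5), 8)
  gm <- genotype_matrix(geno, data.frame(
    scaffold = rep(c("s1", "s2"), each = 3),
    pos = c(50L, 150000L, 450000L, 50L, 120000L, 260000L),
    ref = "A", alt = "G"), paste0("x", 1:8))
  grouping <- setNames(rep(c("a", "b"), each = 4), gm$samples)
  win <- windowed_fst(gm, grouping,
                      scaffold_lengths = c(s1 = 5e5, s2 = 3e5))
  expect_equal(nrow(win), 5 + 3)           # 100 kb default width
  expect_true(all(win$end > win$start))
  expect_true(all(win$scaffold[1:5] == "s1"))
  expect_true(all(is.na(win$value[win$n_sites == 0])))
  # a one-site window equals that site's a/(a+b+c)
  fit <- wc_fst(gm, grouping)
  one <- win[win$scaffold == "s1" & win$start == 1, ]
  expect_equal(one$n_sites, 1L)
  expect_equal(one$value, fit$components$ratio[1])
  expect_error(windowed_fst(gm, grouping, window_bp = 0), "positive")
})

test_that("permutation test reports both p-value conventions at the boundary", {
  # strong fixed differentiation: no permutation can beat the real split
  gm <- toy_gm(rbind(matrix(0L, 6, 20), matrix(2L, 6, 20)))
  grouping <- setNames(rep(c("a", "b"), each = 6), gm$samples)
  res <- fst_permutation_test(gm, grouping, n_replicates = 100, seed = 4)
  expect_equal(length(res$null), 100L)
  expect_equal(res$p, 0)
  expect_equal(res$p_conservative, 1 / 101)
  expect_equal(formals(fst_permutation_test)$n_replicates, 100)
})

test_that("d_xy matches enumeration over haplotype draws", {
  # fixed difference -> every cross-group allele pair differs
  fixed <- toy_gm(rbind(matrix(0L, 4, 1), matrix(2L, 4, 1)))
  win <- windowed_dxy(fixed, paste0("smp", 1:4), paste0("smp", 5:8))
  expect_equal(win$value, 1)
  # both groups monomorphic for the same allele
  mono <- toy_gm(matrix(2L, 8, 1))
  expect_equal(windowed_dxy(mono, paste0("smp", 1:4),
                            paste0("smp", 5:8))$value, 0)
  # p_a = p_b = 0.5: enumerate one allele from each group
  half <- toy_gm(matrix(1L, 8, 1))
  alleles_a <- c(0, 1); alleles_b <- c(0, 1)   # frequency 0.5 each
  enum <- mean(outer(alleles_a, alleles_b, `!=`))
  expect_equal(windowed_dxy(half, paste0("smp", 1:4),
                            paste0("smp", 5:8))$value, enum)
  # symmetry in group exchange, values within [0, 1]
  set.seed(33)
  gm <- toy_gm(matrix(rbinom(10 * 25, 2, 0.4), 10))
  ab <- windowed_dxy(gm, paste0("smp", 1:5), paste0("smp", 6:10))
  ba <- windowed_dxy(gm, paste0("smp", 6:10), paste0("smp", 1:5))
  expect_equal(ab$value, ba$value)
  expect_true(all(ab$value >= 0 & ab$value <= 1, na.rm = TRUE))
  expect_error(windowed_dxy(gm, character(0), paste0("smp", 1:5)))
})

test_that("strain D_XY comparison ties to exactly one half on mirrored classes", {
  set.seed(34)
  geno <- matrix(rbinom(8 * 30, 2, 0.5), 8)
  # invasive samples are exact genotype copies of the native ones
  gm <- toy_gm(rbind(geno, geno), samples = sprintf("t%02d", 1:16))
  manifest <- data.frame(sample_id = gm$samples,
                         status = rep(c("native", "invasive"), each = 8))
  calls <- data.frame(sample_id = gm$samples,
                      cox1_strain = rep(c("sfC", "sfC", "sfC", "sfC",
                                          "sfR", "sfR", "sfR", "sfR"), 2))
  cmp <- compare_strain_dxy(gm, manifest, calls, window_bp = 1000)
  expect_equal(cmp$summary$median_invasive, cmp$summary$median_native)
  expect_equal(cmp$summary$prop_windows_invasive_lower, 0.5)
  # a class missing one strain is a contract violation
  calls$cox1_strain[calls$sample_id == "t05"] <- "sfC"
  calls$cox1_strain[calls$sample_id %in% c("t06", "t07", "t08")] <- "sfC"
  expect_error(compare_strain_dxy(gm, manifest, calls, window_bp = 1000),
               "lack")
})

test_that("admixture confined to invasive samples lowers their between-strain D_XY", {
  scen <- default_scenario()
  nuc <- default_filtered()
  calls <- data.frame(sample_id = scen$truth$sample_id,
                      cox1_strain = scen$truth$cox1_strain)
  cmp <- compare_strain_dxy(nuc, scen$manifest, calls)
  expect_lt(cmp$summary$median_invasive, cmp$summary$median_native)
  expect_gt(cmp$summary$prop_windows_invasive_lower, 0.5)
})
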