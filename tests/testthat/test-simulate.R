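test_that("Balding-Nichols drift keeps the mean and respects its limits", {
  expect_identical(simulate_group_frequencies(0.3, 0), 0.3)
  expect_identical(simulate_group_frequencies(0, 0.1), 0)
  expect_identical(simulate_group_frequencies(1, 0.1), 1)
  expect_error(simulate_group_frequencies(0.3, 1), "F must lie")
  expect_error(simulate_group_frequencies(0.3, -0.1), "F must lie")
  set.seed(11)
  draws <- simulate_group_frequencies(rep(0.3, 10000), 0.05)
  expect_lt(abs(mean(draws) - 0.30), 0.01)
  # variance F p (1 - p)
  expect_lt(abs(var(draws) - 0.05 * 0.3 * 0.7) / (0.05 * 0.3 * 0.7), 0.15)
})

test_that("binomial genotype draws match their frequencies", {
  set.seed(2)
  g0 <- simulate_genotypes(c(0, 1), 5L)
  expect_true(all(g0[, 1] == 0))
  expect_true(all(g0[, 2] == 2))
  g <- simulate_genotypes(rep(0.4, 10), 5000L)
  expect_lt(abs(mean(g) - 0.80), 0.02)
})

test_that("sweep injection fixes the center, spares far sites, and restores diversity with distance", {
  set.seed(5)
  n <- 60; m <- 7
  pos <- c(0, 1e3, 5e3, 2e4, 5e4, 2e5, 1e7) + 1   # growing distance from center
  p <- rep(0.5, m)
  geno <- matrix(rbinom(n * m, 2L, 0.5), n)
  swept <- inject_sweep(geno, pos, center_bp = 1, alpha = 1e-5, p_pre = p)
  # d = 0: all lineages collapse onto the beneficial haplotype
  expect_true(all(swept[, 1] == swept[1, 1]))
  expect_true(swept[1, 1] %in% c(0L, 2L))
  # alpha * d > 50: escape probability is 1 up to 1e-22, nothing changes
  expect_identical(swept[, m], geno[, m])
  expect_error(inject_sweep(geno, pos, 1, alpha = 0, p_pre = p), "alpha")

  # expected heterozygosity rises monotonically with distance on average
  reps <- 300
  het <- matrix(0, reps, 5)
  for (r in seq_len(reps)) {
    g <- matrix(rbinom(n * 5, 2L, 0.5), n)
    s <- inject_sweep(g, c(1e3, 5e3, 2e4, 5e4, 2e5), center_bp = 0,
                      alpha = 1e-5, p_pre = rep(0.5, 5))
    pj <- colMeans(s) / 2
    het[r, ] <- 2 * pj * (1 - pj)
  }
  expect_true(all(diff(colMeans(het)) > 0))
})

test_that("mitochondrial haplotypes form two clades separated beyond within-clade variation", {
  ids <- sprintf("m%02d", 1:20)
  clade <- rep(c("sfC", "sfR"), each = 10)
  set.seed(8)
  aln <- simulate_mito_haplotypes(ids, clade)
  expect_equal(ncol(as.matrix(aln)), 1536)
  expect_equal(nrow(as.matrix(aln)), 21)   # samples + outgroup
  d <- k2p_matrix(aln)[ids, ids]
  within <- c(d[1:10, 1:10][upper.tri(diag(10))],
              d[11:20, 11:20][upper.tri(diag(10))])
  between <- d[1:10, 11:20]
  expect_gt(mean(between), mean(within))

  aln0 <- simulate_mito_haplotypes(ids, clade, within_rate = 0)
  mat0 <- as.character(as.matrix(aln0))
  expect_true(all(mat0[2:10, ] == rep(mat0[1, ], each = 9)))
  expect_error(simulate_mito_haplotypes(ids, clade, n_diagnostic = 0),
               "diagnostic")
})

test_that("scenario outputs are mutually consistent and seed-deterministic", {
  scen <- default_scenario()
  man <- scen$manifest
  expect_identical(man$sample_id, scen$nuclear$samples)
  expect_identical(man$sample_id, scen$tpi$samples)
  expect_identical(c(man$sample_id, "outgroup"),
                   rownames(as.matrix(scen$cox1)))

  cfg <- scenario_config(n_sites = 500, seed = 9)
  d1 <- file.path(tempdir(), "scen_a"); d2 <- file.path(tempdir(), "scen_b")
  write_scenario(simulate_scenario(cfg), d1)
  write_scenario(simulate_scenario(cfg), d2)
  for (f in c("nuclear.vcf", "tpi.vcf", "cox1.fasta", "manifest.tsv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})

test_that("truth serialization round-trips losslessly", {
  scen <- simulate_scenario(scenario_config(n_sites = 300, seed = 3))
  path <- tempfile(fileext = ".json")
  write_truth(scen$truth, path)
  back <- read_truth(path)
  expect_identical(back$sample_id, scen$truth$sample_id)
  expect_identical(back$cox1_strain, scen$truth$cox1_strain)
  expect_equal(back$p_anc, scen$truth$p_anc, tolerance = 0)
  expect_equal(unname(back$freqs), unname(scen$truth$freqs), tolerance = 0)
})

test_that("scenario groups are recoverable by PCA downstream", {
  scen <- simulate_scenario(scenario_config(n_sites = 2000, seed = 21))
  nuc <- select_biallelic_complete(scen$nuclear)
  pca <- genotype_pca(nuc, n_components = 2)
  native <- scen$truth$status == "native"
  groups <- assign_groups(pca, 3, seed = 1)
  expect_equal(adjusted_rand(groups[native], scen$truth$group[native]), 1)
})
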