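test_that("genotype PCA standardises sites and treats duplicates identically", {
  set.seed(20)
  geno <- matrix(rbinom(6 * 50, 2, 0.5), 6)
  geno[6, ] <- geno[5, ]                      # exact duplicate sample
  gm <- toy_gm(geno)
  pca <- genotype_pca(gm, n_components = 4)
  expect_equal(pca$scores[5, ], pca$scores[6, ])
  expect_true(all(diff(pca$eigenvalues) <= 1e-12))
  expect_true(all(pca$explained_fraction >= 0 & pca$explained_fraction <= 1))
  expect_lte(sum(pca$explained_fraction[seq_len(pca$n_components)]), 1)
  # retained components default to ten
  big <- toy_gm(matrix(rbinom(15 * 80, 2, 0.5), 15))
  expect_equal(genotype_pca(big)$n_components, 10L)
  mono <- toy_gm(matrix(2L, 4, 5))
  expect_error(genotype_pca(mono), "monomorphic")
})

test_that("explained fractions are invariant to sample and site order", {
  set.seed(21)
  gm <- toy_gm(matrix(rbinom(10 * 60, 2, 0.4), 10))
  base <- genotype_pca(gm, 5)
  perm_sites <- sample(60)
  perm_samples <- sample(10)
  gm2 <- gm_subset(gm, samples = perm_samples, sites = perm_sites)
  shuffled <- genotype_pca(gm2, 5)
  expect_equal(shuffled$explained_fraction, base$explained_fraction,
               tolerance = 1e-10)
  expect_equal(abs(shuffled$scores[gm$samples, 1]), abs(base$scores[, 1]),
               tolerance = 1e-8)
})

test_that("k-means grouping is deterministic and recovers separated groups", {
  scen <- default_scenario()
  nuc <- default_filtered()
  pca <- genotype_pca(nuc)
  g1 <- assign_groups(pca, 3, seed = 5)
  g2 <- assign_groups(pca, 3, seed = 5)
  expect_identical(g1, g2)
  native <- scen$truth$status == "native"
  expect_equal(adjusted_rand(g1[native], scen$truth$group[native]), 1)
  expect_identical(unname(assign_groups(pca, 1)), rep(1L, 177))
  expect_error(assign_groups(pca, 200), "exceeds")
})

test_that("invasive samples sit inside the Corn cluster on component 1", {
  scen <- default_scenario()
  pca <- genotype_pca(default_filtered())
  pc1 <- pca$scores[, 1]
  truth <- scen$truth
  centroid <- function(sel) mean(pc1[sel])
  inv <- truth$status == "invasive"
  d_corn <- abs(centroid(inv) - centroid(!inv & truth$group == "Corn"))
  d_rice <- abs(centroid(inv) - centroid(!inv & truth$group == "Rice"))
  d_mex <- abs(centroid(inv) - centroid(!inv & truth$group == "Corn.Mex"))
  expect_lt(d_corn, d_rice)
  expect_lt(d_corn, d_mex)
})

test_that("TPI strain calls match the generating strains and respect anchors", {
  scen <- default_scenario()
  anchors <- manifest_anchors(scen$manifest, "anchor_tpi")
  calls <- tpi_strain_call(scen$tpi, anchors, seed = 2)
  truth <- scen$truth$tpi_strain
  expect_gte(mean(calls$tpi_strain == truth), 0.95)
  # anchors receive their own label
  own <- calls$tpi_strain[match(names(anchors), calls$sample_id)]
  expect_true(all(own == anchors))
  # swapping the anchor naming swaps every call
  swapped <- anchors
  swapped[] <- ifelse(anchors == "sfC", "sfR", "sfC")
  calls2 <- tpi_strain_call(scen$tpi, swapped, seed = 2)
  expect_true(all(ifelse(calls$tpi_strain == "sfC", "sfR", "sfC") ==
                    calls2$tpi_strain))
  expect_error(tpi_strain_call(scen$tpi, anchors[anchors == "sfC"]),
               "both strains")
})

test_that("COX1 strain calls follow the anchored clades", {
  scen <- default_scenario()
  anchors <- manifest_anchors(scen$manifest, "anchor_cox1")
  calls <- cox1_strain_call(scen$cox1, anchors)
  expect_true(all(calls$cox1_strain == scen$truth$cox1_strain))
  own <- calls$cox1_strain[match(names(anchors), calls$sample_id)]
  expect_true(all(own == anchors))
  expect_error(cox1_strain_call(scen$cox1, anchors, outgroup_label = "nope"),
               "absent")
})

test_that("an unresolvable COX1 alignment leaves every sample unassigned", {
  ids <- sprintf("x%02d", 1:12)
  mat <- matrix("a", 13, 60)
  mat[13, 1:20] <- "g"                      # only the outgroup differs
  rownames(mat) <- c(ids, "outgroup")
  aln <- ape::as.DNAbin(mat)
  anchors <- setNames(rep(c("sfC", "sfR"), each = 2), ids[1:4])
  calls <- cox1_strain_call(aln, anchors)
  expect_true(all(calls$cox1_strain == "unassigned"))
})
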