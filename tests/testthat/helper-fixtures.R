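# Shared fixtures, generated in code.

# the default synthetic cohort is used by several files; build it once per
# test session
.fixture_cache <- new.env(parent = emptyenv())

default_scenario <- function(seed = 42) {
  key <- paste0("scen", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- simulate_scenario(scenario_config(seed = seed))
  .fixture_cache[[key]]
}

default_filtered <- function(seed = 42) {
  key <- paste0("filt", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <-
      select_biallelic_complete(apply_info_filters(default_scenario(seed)$nuclear))
  .fixture_cache[[key]]
}

# quick genotype matrix on one scaffold; ref/alt chosen so sites alternate
# transition / transversion unless given
toy_gm <- function(geno, pos = NULL, ref = NULL, alt = NULL,
                   scaffold = "s1", samples = NULL) {
  geno <- as.matrix(geno)
  m <- ncol(geno)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep(c("G", "T"), length.out = m)  # ts, tv, ts, ...
  if (is.null(samples)) samples <- paste0("smp", seq_len(nrow(geno)))
  genotype_matrix(geno, data.frame(scaffold = scaffold, pos = pos,
                                   ref = ref, alt = alt,
                                   stringsAsFactors = FALSE), samples)
}

# independent scalar transcription of the Weir & Cockerham (1984) variance
# components for one biallelic site, straight from the published formulas;
# genotypes is a list of integer dosage vectors, one per population
wc_site_oracle <- function(genotypes) {
  genotypes <- lapply(genotypes, function(g) g[!is.na(g)])
  r <- length(genotypes)
  n_i <- vapply(genotypes, length, numeric(1))
  p_i <- vapply(genotypes, function(g) sum(g) / (2 * length(g)), numeric(1))
  h_i <- vapply(genotypes, function(g) mean(g == 1), numeric(1))
  n_bar <- mean(n_i)
  n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n_i * p_i) / (r * n_bar)
  s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n_i * h_i) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - 1 / (n_bar - 1) *
       (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
       (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  c_ <- h_bar / 2
  c(a = a, b = b, c = c_)
}

# adjusted Rand index between two labelings
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  choose2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- choose2(as.vector(tab))
  sum_i <- choose2(rowSums(tab))
  sum_j <- choose2(colSums(tab))
  n2 <- choose2(sum(tab))
  expected <- sum_i * sum_j / n2
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}
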