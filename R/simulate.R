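# Synthetic cohort generator.
#
# Hierarchical Balding-Nichols model: every site has an ancestral allele
# frequency p_anc; each nuclear group g drifts to p_g ~ Beta with mean p_anc
# and variance F_g * p_anc * (1 - p_anc); the invasive gene pool drifts a
# second time from its source group with coefficient F_extra. Genotypes are
# then binomial draws, which gives closed-form control of expected F_ST
# between any two groups. A hard selective sweep is overlaid on chosen
# scaffolds with the star-like escape model also used by the scan.

#' Study-design defaults for the synthetic cohort
#'
#' Twelve geographic populations (99 native, 78 invasive samples, 177 in
#' total), three nuclear groups ("Rice", "Corn.Mex", "Corn") plus an
#' invasive gene pool derived from the Corn group, two mitochondrial COX1
#' clades crossing the nuclear groups, and a strain-diagnostic TPI locus.
#' Samples from Mississippi, Puerto Rico and Florida carry anchor strain
#' labels (previously typed individuals) used to name strain clusters.
#'
#' @return data.frame with one row per population: \code{population},
#'   \code{n}, \code{status}, \code{host_plant}, \code{group},
#'   \code{tpi_strain}, \code{cox1_frac_sfC} (fraction of samples on the
#'   sfC mitochondrial clade) and \code{anchor} (logical).
#' @export
default_populations <- function() {
  data.frame(
    population = c("Florida", "Guadeloupe", "FrenchGuiana", "PuertoRico",
                   "Mississippi", "Brazil", "Mexico",
                   "Benin", "India", "China", "Malawi", "Uganda"),
    n          = c(24L, 4L, 3L, 15L, 17L, 10L, 26L,
                   39L, 14L, 2L, 16L, 7L),
    status     = c(rep("native", 7), rep("invasive", 5)),
    host_plant = c("grass", "grass", "rice", "corn", "corn", "corn", "corn",
                   "corn", "corn", "corn", "corn", "corn"),
    group      = c("Rice", "Rice", "Rice", "Corn", "Corn", "Corn", "Corn.Mex",
                   rep("Corn", 5)),
    tpi_strain = c("sfR", "sfR", "sfR", "sfC", "sfC", "sfC", "sfC",
                   rep("sfC", 5)),
    cox1_frac_sfC = c(0, 0, 0, 0.6, 0.7, 0.8, 1,
                      0.6, 0.6, 0.5, 0.6, 0.6),
    anchor     = c(TRUE, FALSE, FALSE, TRUE, TRUE, rep(FALSE, 7)),
    stringsAsFactors = FALSE
  )
}

#' Build a simulation scenario configuration
#'
#' @param populations population table as in \code{\link{default_populations}}.
#' @param group_f named drift coefficients (one per nuclear group), each in
#'   [0, 1). Default 0.15 for the two outlying groups and 0.05 for Corn.
#' @param invasive_f_extra additional drift of the invasive gene pool from
#'   its source group. The default 0.08 puts expected Weir-Cockerham F_ST
#'   between invasive and native Corn samples near 0.04.
#' @param invasive_source nuclear group the invasive pool derives from.
#' @param n_sites total nuclear SNV count, spread evenly over scaffolds.
#' @param n_scaffolds,scaffold_length scaffold count and length (bp).
#' @param sweeps list of sweep specifications, each a list with
#'   \code{scaffold}, \code{center_bp}, \code{alpha} (escape intensity per
#'   bp) and \code{target} (\code{"invasive"} or \code{"both"}: invasive
#'   only, or invasive plus the native source group).
#' @param mito list: \code{seq_length} (bp), \code{n_diagnostic} clade
#'   diagnostic sites, \code{within_rate} per-bp within-clade mutation
#'   rate, \code{outgroup_divergence} per-bp divergence of the outgroup.
#' @param tpi list: \code{n_diagnostic} strain-diagnostic SNVs,
#'   \code{n_background} shared polymorphic SNVs, \code{noise} residual
#'   alternate-strain allele frequency at diagnostic sites.
#' @param missing_rate per-call probability of a missing genotype.
#' @param seed master seed; fully determines all outputs.
#'
#' @return object of class \code{scenario_config}
#' @export
scenario_config <- function(populations = default_populations(),
                            group_f = c(Rice = 0.15, Corn.Mex = 0.15, Corn = 0.05),
                            invasive_f_extra = 0.08,
                            invasive_source = "Corn",
                            n_sites = 20000L,
                            n_scaffolds = 5L,
                            scaffold_length = 1e6,
                            sweeps = list(list(scaffold = "scaffold_3",
                                               center_bp = 5e5,
                                               alpha = 1e-5,
                                               target = "invasive")),
                            mito = list(seq_length = 1536L, n_diagnostic = 30L,
                                        within_rate = 0.002,
                                        outgroup_divergence = 0.08),
                            tpi = list(n_diagnostic = 10L, n_background = 40L,
                                       noise = 0.03),
                            missing_rate = 0,
                            seed = 20200623L) {
  .check(all(populations$n > 0), "all population sizes must be positive")
  .check(all(populations$status %in% c("native", "invasive")),
         "status must be native or invasive")
  .check(all(populations$group %in% names(group_f)),
         "every population group needs a drift coefficient in group_f")
  .check(all(group_f >= 0 & group_f < 1), "group drift F must lie in [0, 1)")
  .check(invasive_f_extra >= 0 && invasive_f_extra < 1,
         "invasive_f_extra must lie in [0, 1)")
  .check(invasive_source %in% names(group_f), "unknown invasive source group")
  .check(n_sites >= n_scaffolds, "need at least one site per scaffold")
  scafs <- paste0("scaffold_", seq_len(n_scaffolds))
  for (sw in sweeps) {
    .check(sw$scaffold %in% scafs, "sweep on unknown scaffold '%s'", sw$scaffold)
    .check(sw$center_bp >= 1 && sw$center_bp <= scaffold_length,
           "sweep center must lie within the scaffold")
    .check(sw$alpha > 0, "sweep alpha must be positive")
    .check(sw$target %in% c("invasive", "both"),
           "sweep target must be 'invasive' or 'both'")
  }
  .check(mito$n_diagnostic >= 1, "need at least one clade-diagnostic mito site")
  .check(missing_rate >= 0 && missing_rate < 1, "missing_rate must be in [0, 1)")
  structure(list(populations = populations, group_f = group_f,
                 invasive_f_extra = invasive_f_extra,
                 invasive_source = invasive_source,
                 n_sites = as.integer(n_sites),
                 n_scaffolds = as.integer(n_scaffolds),
                 scaffold_length = scaffold_length,
                 sweeps = sweeps, mito = mito, tpi = tpi,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Balding-Nichols drift of allele frequencies
#'
#' Draws a subpopulation allele frequency from
#' Beta(p(1-F)/F, (1-p)(1-F)/F), which has mean p and variance
#' F p (1 - p). F = 0 (or a fixed ancestral allele) returns p unchanged.
#'
#' @param p_anc ancestral allele frequency (vectorised), in [0, 1].
#' @param f drift coefficient in [0, 1).
#' @return drifted allele frequencies, same length as \code{p_anc}.
#' @export
simulate_group_frequencies <- function(p_anc, f) {
  .check(f >= 0 && f < 1, "drift coefficient F must lie in [0, 1)")
  .check(all(p_anc >= 0 & p_anc <= 1), "allele frequencies must lie in [0, 1]")
  if (f == 0) return(p_anc)
  out <- p_anc
  mid <- p_anc > 0 & p_anc < 1
  if (any(mid)) {
    scale <- (1 - f) / f
    out[mid] <- rbeta(sum(mid), p_anc[mid] * scale, (1 - p_anc[mid]) * scale)
  }
  out
}

#' Binomial genotype draws from group allele frequencies
#'
#' @param freqs numeric matrix sites x groups (or a vector for one group)
#'   of allele frequencies.
#' @param n_per_group integer vector of diploid sample counts per group
#'   (same order as the columns of \code{freqs}).
#' @return integer dosage matrix, samples x sites, group blocks stacked in
#'   order.
#' @export
simulate_genotypes <- function(freqs, n_per_group) {
  if (is.vector(freqs)) freqs <- matrix(freqs, ncol = 1)
  .check(all(freqs >= 0 & freqs <= 1), "frequencies must lie in [0, 1]")
  .check(length(n_per_group) == ncol(freqs),
         "one sample count per group column required")
  m <- nrow(freqs)
  blocks <- lapply(seq_along(n_per_group), function(g) {
    n <- n_per_group[g]
    matrix(rbinom(n * m, 2L, rep(freqs[, g], each = n)), nrow = n)
  })
  do.call(rbind, blocks)
}

#' Overlay a hard selective sweep on a genotype block
#'
#' Star-like escape model: at a site at distance d from the sweep center,
#' each of the 2n lineages independently escapes the sweep with probability
#' 1 - exp(-alpha d); all non-escaping lineages inherit the allelic state of
#' one beneficial haplotype drawn per site from the pre-sweep frequency.
#' Far sites (alpha d large) are left unchanged in distribution; the site at
#' d = 0 becomes monomorphic.
#'
#' @param geno integer dosage matrix (samples x sites) of the swept group.
#' @param pos site positions (bp) on the swept scaffold.
#' @param center_bp sweep center (bp).
#' @param alpha escape intensity per bp, > 0.
#' @param p_pre pre-sweep allele frequencies of the swept group, one per
#'   site.
#' @return dosage matrix of the same shape with the sweep applied.
#' @export
inject_sweep <- function(geno, pos, center_bp, alpha, p_pre) {
  .check(alpha > 0, "sweep alpha must be positive")
  .check(length(pos) == ncol(geno) && length(p_pre) == ncol(geno),
         "pos and p_pre must have one entry per site")
  n <- nrow(geno)
  d <- abs(pos - center_bp)
  pe <- 1 - exp(-alpha * d)
  beneficial <- rbinom(length(pos), 1L, p_pre)          # one haplotype per site
  # decompose dosage into two exchangeable haploid lineages
  h1 <- (geno >= 1L) * 1L
  h2 <- (geno == 2L) * 1L
  esc1 <- matrix(runif(n * length(pos)) < rep(pe, each = n), nrow = n)
  esc2 <- matrix(runif(n * length(pos)) < rep(pe, each = n), nrow = n)
  ben <- matrix(rep(beneficial, each = n), nrow = n)
  h1 <- ifelse(esc1, h1, ben)
  h2 <- ifelse(esc2, h2, ben)
  out <- h1 + h2
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(geno)
  out
}

#' Simulate a mitochondrial marker alignment with two clades
#'
#' One sequence per sample. The two clades share a random backbone sequence
#' and differ at \code{n_diagnostic} fixed positions; each sample
#' additionally carries private mutations at rate \code{within_rate} per bp.
#' An outgroup sequence diverged at \code{outgroup_divergence} per bp is
#' appended (used to root the barcode tree).
#'
#' @param sample_ids character vector of sample names.
#' @param clade character vector ("sfC"/"sfR"), one per sample.
#' @param seq_length alignment length in bp (default 1536, the full-length
#'   COX1 barcode).
#' @param n_diagnostic number of clade-diagnostic substitutions.
#' @param within_rate per-bp within-clade mutation rate.
#' @param outgroup_divergence per-bp divergence of the outgroup sequence.
#' @param outgroup_label tip name for the outgroup.
#' @return an \code{ape::DNAbin} matrix with one row per sample plus the
#'   outgroup.
#' @export
simulate_mito_haplotypes <- function(sample_ids, clade, seq_length = 1536L,
                                     n_diagnostic = 30L, within_rate = 0.002,
                                     outgroup_divergence = 0.08,
                                     outgroup_label = "outgroup") {
  .check(n_diagnostic >= 1, "need at least one diagnostic site")
  .check(length(clade) == length(sample_ids), "one clade label per sample")
  bases <- c("a", "c", "g", "t")
  backbone <- sample(bases, seq_length, replace = TRUE)
  diag_pos <- sort(sample.int(seq_length, n_diagnostic))
  clade2 <- backbone
  for (i in diag_pos)
    clade2[i] <- sample(setdiff(bases, backbone[i]), 1)
  mutate <- function(seq, rate) {
    k <- rbinom(1, length(seq), rate)
    if (k > 0) {
      at <- sample.int(length(seq), k)
      for (i in at) seq[i] <- sample(setdiff(bases, seq[i]), 1)
    }
    seq
  }
  seqs <- lapply(seq_along(sample_ids), function(i) {
    base <- if (clade[i] == "sfR") clade2 else backbone
    mutate(base, within_rate)
  })
  # the outgroup descends from the clade ancestor: intermediate at the
  # diagnostic sites (half from each clade), so it roots the tree on the
  # branch between the clades rather than inside one of them
  anc <- backbone
  take2 <- diag_pos[seq_along(diag_pos) %% 2 == 0]
  anc[take2] <- clade2[take2]
  og <- mutate(anc, outgroup_divergence)
  mat <- do.call(rbind, c(seqs, list(og)))
  rownames(mat) <- c(sample_ids, outgroup_label)
  ape::as.DNAbin(mat)
}

# TPI-like marker genotypes: near-fixed differences between strains at the
# diagnostic sites plus shared background polymorphism.
simulate_tpi_matrix <- function(sample_ids, tpi_strain, spec) {
  n <- length(sample_ids)
  nd <- spec$n_diagnostic; nb <- spec$n_background
  p_diag <- ifelse(tpi_strain == "sfR", 1 - spec$noise, spec$noise)
  diag_block <- matrix(rbinom(n * nd, 2L, rep(p_diag, nd)), nrow = n)
  p_bg <- runif(nb, 0.1, 0.9)
  bg_block <- matrix(rbinom(n * nb, 2L, rep(p_bg, each = n)), nrow = n)
  geno <- cbind(diag_block, bg_block)
  m <- nd + nb
  pairs <- rbind(c("A", "G"), c("C", "T"), c("A", "C"), c("G", "T"))
  pick <- pairs[sample.int(4, m, replace = TRUE), , drop = FALSE]
  sites <- data.frame(scaffold = "tpi_locus", pos = seq_len(m) * 10L,
                      ref = pick[, 1], alt = pick[, 2],
                      stringsAsFactors = FALSE)
  genotype_matrix(geno, sites, sample_ids)
}

#' Simulate a full synthetic cohort
#'
#' Generates, under one master seed, the mutually consistent set of inputs
#' the analysis chain expects: a nuclear genotype matrix (with VCF-style
#' INFO annotations), a TPI marker genotype matrix, a COX1-like marker
#' alignment with an outgroup, a sample manifest and a truth record holding
#' every generating parameter. Identical configurations produce identical
#' outputs, byte for byte when written with \code{\link{write_scenario}}.
#'
#' @param config a \code{\link{scenario_config}}.
#' @return list with elements \code{nuclear} (genotype_matrix), \code{tpi}
#'   (genotype_matrix), \code{cox1} (DNAbin), \code{manifest} (data.frame)
#'   and \code{truth} (list).
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  pops <- config$populations
  sample_ids <- unlist(lapply(seq_len(nrow(pops)), function(i)
    sprintf("%s_%02d", pops$population[i], seq_len(pops$n[i]))))
  manifest <- data.frame(
    sample_id = sample_ids,
    population = rep(pops$population, pops$n),
    status = rep(pops$status, pops$n),
    host_plant = rep(pops$host_plant, pops$n),
    stringsAsFactors = FALSE)
  pop_of <- rep(seq_len(nrow(pops)), pops$n)
  # strain truths: TPI per population; COX1 clade split deterministically
  # (first round(frac * n) samples of each population are sfC)
  tpi_strain <- rep(pops$tpi_strain, pops$n)
  cox1_strain <- unlist(lapply(seq_len(nrow(pops)), function(i) {
    n <- pops$n[i]; k <- round(pops$cox1_frac_sfC[i] * n)
    c(rep("sfC", k), rep("sfR", n - k))
  }))
  is_anchor <- rep(pops$anchor, pops$n)
  manifest$anchor_tpi <- ifelse(is_anchor, tpi_strain, NA_character_)
  manifest$anchor_cox1 <- ifelse(is_anchor, cox1_strain, NA_character_)

  # effective gene pool of each sample: nuclear group, or the extra-drift
  # invasive pool for invasive samples
  group_names <- names(config$group_f)
  pool <- rep(pops$group, pops$n)
  pool[manifest$status == "invasive"] <- "invasive"
  pools <- c(group_names, "invasive")

  m <- config$n_sites
  truth <- list(config = config, sample_id = sample_ids,
                group = rep(pops$group, pops$n), pool = pool,
                status = manifest$status,
                tpi_strain = tpi_strain, cox1_strain = cox1_strain)

  with_seed(derive_seed(config$seed, "nuclear"), {
    p_anc <- pmin(pmax(rbeta(m, 0.5, 0.5), 0.02), 0.98)
    freqs <- sapply(group_names, function(g)
      simulate_group_frequencies(p_anc, config$group_f[[g]]))
    p_inv <- simulate_group_frequencies(freqs[, config$invasive_source],
                                        config$invasive_f_extra)
    freqs <- cbind(freqs, invasive = p_inv)
    colnames(freqs) <- pools

    # site map: even split over scaffolds, sorted unique positions
    per_scaf <- diff(round(seq(0, m, length.out = config$n_scaffolds + 1)))
    scaffold <- rep(paste0("scaffold_", seq_len(config$n_scaffolds)), per_scaf)
    pos <- unlist(lapply(per_scaf, function(k)
      sort(sample.int(config$scaffold_length, k))))
    is_ts <- runif(m) < 2 / 3   # transition:transversion ~ 2:1
    ts_pairs <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
    tv_pairs <- rbind(c("A", "C"), c("A", "T"), c("C", "A"), c("C", "G"),
                      c("G", "C"), c("G", "T"), c("T", "A"), c("T", "G"))
    ra <- matrix("", m, 2)
    ra[is_ts, ] <- ts_pairs[sample.int(4, sum(is_ts), TRUE), , drop = FALSE]
    ra[!is_ts, ] <- tv_pairs[sample.int(8, sum(!is_ts), TRUE), , drop = FALSE]

    # genotypes, sample by pool membership
    geno <- matrix(0L, length(sample_ids), m)
    for (pl in pools) {
      rows <- which(pool == pl)
      if (length(rows))
        geno[rows, ] <- matrix(
          rbinom(length(rows) * m, 2L, rep(freqs[, pl], each = length(rows))),
          nrow = length(rows))
    }

    # sweeps
    for (sw in config$sweeps) {
      on_scaf <- which(scaffold == sw$scaffold)
      targets <- if (sw$target == "invasive") "invasive"
                 else c("invasive", config$invasive_source)
      for (pl in targets) {
        rows <- which(pool == pl)
        geno[rows, on_scaf] <- inject_sweep(
          geno[rows, on_scaf, drop = FALSE], pos[on_scaf],
          sw$center_bp, sw$alpha, freqs[on_scaf, pl])
      }
    }

    # caller-style INFO annotations (all within the retention thresholds;
    # filter behaviour is exercised with dedicated fixtures)
    sites <- data.frame(scaffold = scaffold, pos = pos,
                        ref = ra[, 1], alt = ra[, 2],
                        qd = round(runif(m, 15, 35), 2),
                        fs = round(runif(m, 0, 10), 3),
                        mq = round(runif(m, 50, 60), 2),
                        mq_rank_sum = round(rnorm(m, 0, 1), 3),
                        read_pos_rank_sum = round(rnorm(m, 0, 1), 3),
                        stringsAsFactors = FALSE)
    if (config$missing_rate > 0)
      geno[runif(length(geno)) < config$missing_rate] <- NA_integer_
    nuclear <- genotype_matrix(geno, sites, sample_ids)
    truth$p_anc <- p_anc
    truth$freqs <- freqs
  })

  tpi <- with_seed(derive_seed(config$seed, "tpi"),
                   simulate_tpi_matrix(sample_ids, tpi_strain, config$tpi))
  cox1 <- with_seed(derive_seed(config$seed, "mito"),
                    simulate_mito_haplotypes(
                      sample_ids, cox1_strain,
                      seq_length = config$mito$seq_length,
                      n_diagnostic = config$mito$n_diagnostic,
                      within_rate = config$mito$within_rate,
                      outgroup_divergence = config$mito$outgroup_divergence))
  list(nuclear = nuclear, tpi = tpi, cox1 = cox1,
       manifest = manifest, truth = truth)
}

#' Write a simulated scenario to disk
#'
#' Emits the on-disk forms every pipeline stage can also start from:
#' nuclear and TPI VCF 4.2, a COX1 FASTA alignment, a tab-separated sample
#' manifest and a JSON truth file.
#'
#' @param scen result of \code{\link{simulate_scenario}}.
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of file paths.
#' @export
write_scenario <- function(scen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    nuclear_vcf = file.path(dir, "nuclear.vcf"),
    tpi_vcf = file.path(dir, "tpi.vcf"),
    cox1_fasta = file.path(dir, "cox1.fasta"),
    manifest = file.path(dir, "manifest.tsv"),
    truth = file.path(dir, "truth.json"))
  write_vcf(scen$nuclear, paths$nuclear_vcf)
  write_vcf(scen$tpi, paths$tpi_vcf)
  write_fasta(scen$cox1, paths$cox1_fasta)
  write_manifest(scen$manifest, paths$manifest)
  write_truth(scen$truth, paths$truth)
  invisible(paths)
}

#' Serialize / restore the generating truth of a scenario
#'
#' @param truth truth list from \code{\link{simulate_scenario}}.
#' @param path JSON file path.
#' @return \code{read_truth} returns the truth list (numeric values restored
#'   losslessly).
#' @export
write_truth <- function(truth, path) {
  out <- truth
  out$config <- unclass(out$config)
  out$freqs <- as.data.frame(out$freqs)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17),
                       pretty = FALSE, na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$freqs <- as.matrix(x$freqs)
  # keep sweeps as a list of specs (simplification turns it into a frame)
  if (is.data.frame(x$config$sweeps))
    x$config$sweeps <- lapply(seq_len(nrow(x$config$sweeps)),
                              function(i) as.list(x$config$sweeps[i, ]))
  x
}

#' Read / write the sample manifest
#'
#' Tab-separated table with columns \code{sample_id}, \code{population},
#' \code{status} (native/invasive), \code{host_plant} and the optional
#' anchor strain columns \code{anchor_tpi} / \code{anchor_cox1}.
#'
#' @param manifest data.frame as produced by \code{\link{simulate_scenario}}.
#' @param path TSV file path.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  man <- read.table(path, sep = "\t", header = TRUE, na.strings = "",
                    stringsAsFactors = FALSE)
  .check(!anyDuplicated(man$sample_id), "manifest sample ids must be unique")
  .check(all(man$status %in% c("native", "invasive")),
         "manifest status must be native or invasive")
  man
}

# plain sequential FASTA writer for DNAbin alignments
write_fasta <- function(aln, path) {
  mat <- as.character(as.matrix(aln))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(mat))) {
    writeLines(paste0(">", rownames(mat)[i]), con)
    writeLines(toupper(paste(mat[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' Read an aligned FASTA marker file
#' @param path FASTA file with equal-length sequences.
#' @return an \code{ape::DNAbin} matrix.
#' @export
read_fasta_alignment <- function(path) {
  aln <- ape::read.FASTA(path)
  len <- lengths(aln)
  .check(length(unique(len)) == 1, "sequences are not aligned (unequal lengths)")
  as.matrix(aln)
}
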