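# End-to-end orchestration: simulate (or load) -> filter -> strain typing
# -> population structure -> differentiation -> individual phylogeny ->
# sweep scan -> report. Every stage is also callable on its own; this
# driver wires them together under one seed and writes each intermediate
# to the output directory.

#' Pipeline configuration
#'
#' Exactly one of \code{scenario} (simulation mode) or \code{inputs}
#' (paths to an on-disk VCF, TPI VCF, COX1 FASTA and manifest TSV) must be
#' given. Stage parameters are validated here, before any stage runs.
#'
#' @param scenario a \code{\link{scenario_config}}, or NULL.
#' @param inputs named list with \code{nuclear_vcf}, \code{tpi_vcf},
#'   \code{cox1_fasta}, \code{manifest}, or NULL.
#' @param window_bp F_ST / D_XY window width (default 100 kb).
#' @param fst_replicates permutation replicates R (default 100).
#' @param bootstrap_replicates phylogeny bootstrap replicates
#'   (default 1000).
#' @param grids_per_scaffold sweep-scan grids per scaffold (default 1000).
#' @param clr_threshold sweep outlier threshold (default 100).
#' @param alpha_grid sweep intensity grid (per bp).
#' @param k_groups number of nuclear groups for k-means (default 3).
#' @param seed master seed.
#' @param out_dir output directory.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(scenario = NULL, inputs = NULL,
                            window_bp = 100000, fst_replicates = 100,
                            bootstrap_replicates = 1000,
                            grids_per_scaffold = 1000, clr_threshold = 100,
                            alpha_grid = 10^seq(-8, -2, length.out = 16),
                            k_groups = 3, seed = 1, out_dir = tempfile("run")) {
  .check(xor(is.null(scenario), is.null(inputs)),
         "exactly one of scenario / inputs must be given")
  if (!is.null(scenario)) stopifnot(inherits(scenario, "scenario_config"))
  if (!is.null(inputs))
    .check(all(c("nuclear_vcf", "tpi_vcf", "cox1_fasta", "manifest") %in%
                 names(inputs)), "inputs must name nuclear_vcf, tpi_vcf, cox1_fasta, manifest")
  .check(window_bp > 0, "window_bp must be positive")
  .check(fst_replicates >= 1, "fst_replicates must be at least 1")
  .check(bootstrap_replicates >= 1, "bootstrap_replicates must be at least 1")
  .check(grids_per_scaffold >= 2, "grids_per_scaffold must be at least 2")
  .check(k_groups >= 1, "k_groups must be at least 1")
  .check(all(alpha_grid > 0), "alpha grid must be positive")
  structure(list(scenario = scenario, inputs = inputs, window_bp = window_bp,
                 fst_replicates = fst_replicates,
                 bootstrap_replicates = bootstrap_replicates,
                 grids_per_scaffold = grids_per_scaffold,
                 clr_threshold = clr_threshold, alpha_grid = alpha_grid,
                 k_groups = k_groups, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Strain-by-host contingency table and marker agreement
#'
#' Counts samples by host plant and called strain, separately per marker,
#' and reports the rate at which the two markers agree (over samples
#' assigned by both).
#'
#' @param manifest sample manifest (sample_id, host_plant).
#' @param strain_calls data.frame with sample_id, tpi_strain, cox1_strain.
#' @return list: \code{table} (long data.frame marker x host x strain x
#'   count), \code{agreement_rate} (percentage, NA when no sample is
#'   assigned by both markers).
#' @export
strain_host_table <- function(manifest, strain_calls) {
  man <- merge(manifest, strain_calls, by = "sample_id")
  if (nrow(man) == 0)
    return(list(table = data.frame(marker = character(0),
                                   host_plant = character(0),
                                   strain = character(0), count = integer(0)),
                agreement_rate = NA_real_))
  long <- rbind(
    data.frame(marker = "TPI", host_plant = man$host_plant,
               strain = man$tpi_strain, stringsAsFactors = FALSE),
    data.frame(marker = "COX1", host_plant = man$host_plant,
               strain = man$cox1_strain, stringsAsFactors = FALSE))
  tab <- as.data.frame(table(marker = long$marker, host_plant = long$host_plant,
                             strain = long$strain), stringsAsFactors = FALSE)
  names(tab)[4] <- "count"
  both <- man$tpi_strain != "unassigned" & man$cox1_strain != "unassigned"
  agree <- if (any(both))
    100 * mean(man$tpi_strain[both] == man$cox1_strain[both]) else NA_real_
  list(table = tab[tab$count > 0, ], agreement_rate = agree)
}

# host concordance of one marker: % of calls matching the host-expected
# strain (corn -> sfC, rice/grass -> sfR), over assigned samples
.host_concordance <- function(host, strain) {
  expected <- ifelse(host == "corn", "sfC", "sfR")
  ok <- strain != "unassigned"
  if (!any(ok)) return(NA_real_)
  100 * mean(strain[ok] == expected[ok])
}

#' Run the full inference pipeline
#'
#' Executes every stage in dependency order, writes each intermediate
#' (VCF, TSV, Newick, JSON) under \code{config$out_dir}, logs stage
#' parameters and wall time to stderr, and returns the run report.
#' Identical configurations (including seed) reproduce identical numeric
#' content.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list of class \code{run_report}; also written as
#'   \code{report.json} and \code{report.txt} in the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    ts <- Sys.time()
    message(sprintf("[%s] stage %-12s ...", format(ts, "%H:%M:%S"), name))
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[%s] stage %-12s done (%.1f s)", format(Sys.time(), "%H:%M:%S"),
                    name, as.numeric(difftime(Sys.time(), ts, units = "secs"))))
    res
  }

  inp <- stage("inputs", {
    if (!is.null(config$scenario)) {
      scen <- simulate_scenario(config$scenario)
      write_scenario(scen, file.path(config$out_dir, "inputs"))
      scen
    } else {
      list(nuclear = read_vcf(config$inputs$nuclear_vcf),
           tpi = read_vcf(config$inputs$tpi_vcf),
           cox1 = read_fasta_alignment(config$inputs$cox1_fasta),
           manifest = read_manifest(config$inputs$manifest),
           truth = NULL)
    }
  })
  man <- inp$manifest

  nuc <- stage("filter", {
    out <- select_biallelic_complete(apply_info_filters(inp$nuclear))
    out
  })

  strains <- stage("strains", {
    tpi <- tpi_strain_call(inp$tpi, manifest_anchors(man, "anchor_tpi"),
                           seed = derive_seed(config$seed, "tpi_call"))
    cox1 <- cox1_strain_call(inp$cox1, manifest_anchors(man, "anchor_cox1"))
    calls <- merge(tpi, cox1, by = "sample_id")
    write.table(calls, file.path(config$out_dir, "strain_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    calls
  })
  hosts <- strain_host_table(man, strains)

  struct <- stage("structure", {
    pca <- genotype_pca(nuc, n_components = 10)
    groups <- assign_groups(pca, config$k_groups,
                            seed = derive_seed(config$seed, "kmeans"))
    write.table(data.frame(sample_id = rownames(pca$scores), pca$scores,
                           group = groups),
                file.path(config$out_dir, "pca_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(pca = pca, groups = groups)
  })

  # the "Corn group" of a run = the k-means cluster holding the majority
  # of invasive samples; its native members are the putative source
  invasive_ids <- man$sample_id[man$status == "invasive"]
  native_ids <- man$sample_id[man$status == "native"]
  corn_cluster <- as.integer(names(which.max(
    table(struct$groups[invasive_ids]))))
  native_corn_ids <- intersect(
    names(struct$groups)[struct$groups == corn_cluster], native_ids)

  diffs <- stage("diffstats", {
    grouping <- list(invasive = invasive_ids, native_corn = native_corn_ids)
    perm <- fst_permutation_test(gm_subset(nuc, samples = c(invasive_ids, native_corn_ids)),
                                 grouping, n_replicates = config$fst_replicates,
                                 seed = derive_seed(config$seed, "fst_perm"))
    wins <- windowed_fst(nuc, grouping, window_bp = config$window_bp)
    write.table(wins, file.path(config$out_dir, "fst_windows.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    dxy <- compare_strain_dxy(nuc, man, strains, window_bp = config$window_bp)
    jsonlite::write_json(
      list(observed = perm$observed, p = perm$p,
           p_conservative = perm$p_conservative, R = perm$n_replicates,
           seed = perm$seed),
      file.path(config$out_dir, "fst_permutation.json"),
      auto_unbox = TRUE, digits = NA)
    list(perm = perm, windows = wins, dxy = dxy)
  })

  phylo <- stage("vcfphylo", {
    bs <- bootstrap_consensus(nuc, n_replicates = config$bootstrap_replicates,
                              seed = derive_seed(config$seed, "bootstrap"))
    write_newick(bs$consensus, file.path(config$out_dir, "nuclear_consensus.nwk"))
    mono <- clade_support(bs$consensus, invasive_ids)
    list(bootstrap = bs, monophyly = mono)
  })

  sweep <- stage("sweep", {
    scan_inv <- clr_scan(select_biallelic_complete(gm_subset(inp$nuclear, samples = invasive_ids)),
                         grids_per_scaffold = config$grids_per_scaffold,
                         alpha_grid = config$alpha_grid,
                         scaffold_lengths = .scenario_lengths(config, inp))
    scan_nat <- clr_scan(select_biallelic_complete(gm_subset(inp$nuclear, samples = native_corn_ids)),
                         grids_per_scaffold = config$grids_per_scaffold,
                         alpha_grid = config$alpha_grid,
                         scaffold_lengths = .scenario_lengths(config, inp))
    fl <- flag_outlier_grids(scan_inv, config$clr_threshold)
    loci <- invasive_specific_loci(merge_grids_to_loci(fl$flagged),
                                   scan_inv, scan_nat, config$clr_threshold)
    write.table(as.data.frame(scan_inv),
                file.path(config$out_dir, "clr_invasive.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(loci, file.path(config$out_dir, "sweep_loci.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(scan_invasive = scan_inv, scan_native = scan_nat,
         flags = fl, loci = loci)
  })

  report <- list(
    version = as.character(utils::packageVersion("fawpopgen")),
    seed = config$seed,
    parameters = config[c("window_bp", "fst_replicates", "bootstrap_replicates",
                          "grids_per_scaffold", "clr_threshold", "k_groups")],
    samples = list(total = nrow(man),
                   native = sum(man$status == "native"),
                   invasive = sum(man$status == "invasive")),
    sites = list(input = n_sites(inp$nuclear), analysed = n_sites(nuc)),
    strains = list(host_table = hosts$table,
                   marker_agreement_pct = hosts$agreement_rate,
                   tpi_host_concordance_pct =
                     .host_concordance(man$host_plant, strains$tpi_strain),
                   cox1_host_concordance_pct =
                     .host_concordance(man$host_plant, strains$cox1_strain)),
    structure = list(
      explained_pct = 100 * struct$pca$explained_fraction[1:struct$pca$n_components],
      group_sizes = as.list(table(struct$groups)),
      corn_cluster = corn_cluster),
    fst = list(invasive_vs_native_corn = diffs$perm$observed,
               p = diffs$perm$p, p_conservative = diffs$perm$p_conservative),
    dxy = diffs$dxy$summary,
    monophyly = phylo$monophyly,
    sweep = list(summary = sweep$flags$summary,
                 n_loci = nrow(sweep$loci),
                 n_invasive_specific = sum(sweep$loci$invasive_specific)))
  class(report) <- "run_report"
  jsonlite::write_json(unclass(report), file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  writeLines(utils::capture.output(print(report)),
             file.path(config$out_dir, "report.txt"))
  message(sprintf("pipeline finished in %.1f s; outputs in %s",
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  config$out_dir))
  report
}

.scenario_lengths <- function(config, inp) {
  if (is.null(config$scenario)) return(NULL)
  len <- config$scenario$scaffold_length
  scafs <- paste0("scaffold_", seq_len(config$scenario$n_scaffolds))
  setNames(rep(len, length(scafs)), scafs)
}

#' @export
print.run_report <- function(x, ...) {
  cat("== fawpopgen run report ==\n")
  cat(sprintf("seed %d | %d samples (%d native, %d invasive) | %d/%d sites analysed\n",
              x$seed, x$samples$total, x$samples$native, x$samples$invasive,
              x$sites$analysed, x$sites$input))
  cat(sprintf("strain markers: agreement %.1f%%, TPI-host %.1f%%, COX1-host %.1f%%\n",
              x$strains$marker_agreement_pct,
              x$strains$tpi_host_concordance_pct,
              x$strains$cox1_host_concordance_pct))
  cat(sprintf("PCA: PC1 %.2f%%, PC2 %.2f%% of variance\n",
              x$structure$explained_pct[1], x$structure$explained_pct[2]))
  cat(sprintf("F_ST invasive vs native Corn: %.5f (p = %.4g, conservative %.4g)\n",
              x$fst$invasive_vs_native_corn, x$fst$p, x$fst$p_conservative))
  cat(sprintf("D_XY between strains: invasive median %.4f vs native %.4f (invasive lower in %.0f%% of windows)\n",
              x$dxy$median_invasive, x$dxy$median_native,
              100 * x$dxy$prop_windows_invasive_lower))
  cat(sprintf("invasive monophyly: %s, support %.1f%%\n",
              x$monophyly$is_monophyletic, x$monophyly$support))
  cat(sprintf("sweep: %d/%d grids above %.0f (%.3f%%), median CLR %.4f; %d loci, %d invasive-specific\n",
              x$sweep$summary$count, x$sweep$summary$total,
              x$sweep$summary$threshold, x$sweep$summary$percentage,
              x$sweep$summary$median_clr, x$sweep$n_loci,
              x$sweep$n_invasive_specific))
  invisible(x)
}
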