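#!/usr/bin/env Rscript
# Composite-likelihood sweep scan from the site frequency spectrum:
# 1,000 grids per scaffold, alpha maximised over a log-spaced grid,
# outliers above the conventional threshold of 100, neighbouring flagged
# grids merged into loci, and the native-Corn comparison scan used to
# keep only invasive-specific loci.

source("analysis/common.R")

raw <- read_vcf(file.path(DATA_DIR, "nuclear.vcf"))
man <- load_manifest()
scores <- read.table(file.path(OUT_DIR, "pca_scores.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)

inv <- man$sample_id[man$status == "invasive"]
corn_cluster <- as.integer(names(which.max(
  table(scores$group[scores$sample_id %in% inv]))))
native_corn <- scores$sample_id[scores$group == corn_cluster &
                                  scores$status == "native"]

scan_of <- function(ids) clr_scan(
  select_biallelic_complete(gm_subset(raw, samples = ids)),
  grids_per_scaffold = 1000, scaffold_lengths = scaffold_lengths())

scan_inv <- scan_of(inv)
scan_nat <- scan_of(native_corn)
write.table(as.data.frame(scan_inv), file.path(OUT_DIR, "clr_invasive.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(as.data.frame(scan_nat), file.path(OUT_DIR, "clr_native_corn.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

fl <- flag_outlier_grids(scan_inv, threshold = 100)
loci <- invasive_specific_loci(merge_grids_to_loci(fl$flagged),
                               scan_inv, scan_nat, threshold = 100)
write.table(loci, file.path(OUT_DIR, "sweep_loci.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

say("invasive scan: %d grids, median CLR %.4f; %d grids above %d (%.3f%%)",
    fl$summary$total, fl$summary$median_clr, fl$summary$count,
    fl$summary$threshold, fl$summary$percentage)
say("%d locus/loci after merging neighbouring grids; %d invasive-specific after the native comparison",
    nrow(loci), sum(loci$invasive_specific))
for (i in seq_len(nrow(loci)))
  say("  %s:%d-%d  max CLR %.1f  invasive_specific %s",
      loci$scaffold[i], as.integer(loci$start[i]), as.integer(loci$end[i]),
      loci$max_clr[i], loci$invasive_specific[i])
truth <- load_truth()
for (sw in truth$config$sweeps)
  say("injected truth: %s @ %d bp (target %s)",
      sw$scaffold, as.integer(sw$center_bp), sw$target)
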