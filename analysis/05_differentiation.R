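#!/usr/bin/env Rscript
# Weir-Cockerham F_ST in 100 kb windows, the genome-wide weighted mean
# with its label-permutation test (invasive vs native Corn), and the
# between-mitochondrial-strain D_XY contrast (invasive vs native).
# Expected: significant but mild invasive/native-Corn differentiation,
# and lower between-strain D_XY inside the invasive pool (admixture).

source("analysis/common.R")

nuc <- load_filtered()
man <- load_manifest()
scores <- read.table(file.path(OUT_DIR, "pca_scores.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
calls <- read.table(file.path(OUT_DIR, "strain_calls.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)

inv <- man$sample_id[man$status == "invasive"]
corn_cluster <- as.integer(names(which.max(
  table(scores$group[scores$sample_id %in% inv]))))
native_corn <- scores$sample_id[scores$group == corn_cluster &
                                  scores$status == "native"]
grouping <- list(invasive = inv, native_corn = native_corn)

wins <- windowed_fst(nuc, grouping, window_bp = 100000,
                     scaffold_lengths = scaffold_lengths())
write.table(wins, file.path(OUT_DIR, "fst_windows.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
perm <- fst_permutation_test(gm_subset(nuc, samples = c(inv, native_corn)),
                             grouping, n_replicates = 100, seed = SEED + 3L)
jsonlite::write_json(list(observed = perm$observed, p = perm$p,
                          p_conservative = perm$p_conservative,
                          R = perm$n_replicates, seed = perm$seed),
                     file.path(OUT_DIR, "fst_permutation.json"),
                     auto_unbox = TRUE, digits = NA)

say("invasive vs native Corn (n = %d + %d):", length(inv), length(native_corn))
say("  genome-wide weighted F_ST = %.4f, permutation p = %.3g (conservative %.3g, R = %d)",
    perm$observed, perm$p, perm$p_conservative, perm$n_replicates)
say("  windowed F_ST: median %.4f over %d non-empty 100 kb windows",
    median(wins$value, na.rm = TRUE), sum(wins$n_sites > 0))

dxy <- compare_strain_dxy(nuc, man, calls, window_bp = 100000,
                          scaffold_lengths = scaffold_lengths())
write.table(rbind(cbind(class = "invasive", dxy$invasive),
                  cbind(class = "native", dxy$native)),
            file.path(OUT_DIR, "dxy_windows.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
say("between-strain D_XY per SNV: invasive median %.4f vs native %.4f; invasive lower in %.0f%% of windows",
    dxy$summary$median_invasive, dxy$summary$median_native,
    100 * dxy$summary$prop_windows_invasive_lower)
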