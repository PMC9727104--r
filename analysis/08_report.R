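#!/usr/bin/env Rscript
# Collate the stage outputs into a single JSON + text summary of the
# inference chain's headline answers.

source("analysis/common.R")

man <- load_manifest()
calls <- read.table(file.path(OUT_DIR, "strain_calls.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
scores <- read.table(file.path(OUT_DIR, "pca_scores.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
perm <- jsonlite::read_json(file.path(OUT_DIR, "fst_permutation.json"),
                            simplifyVector = TRUE)
loci <- read.table(file.path(OUT_DIR, "sweep_loci.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
cons <- read_newick(file.path(OUT_DIR, "nuclear_consensus.nwk"))
inv <- man$sample_id[man$status == "invasive"]
mono <- clade_support(cons, inv)
hosts <- strain_host_table(man, calls)

summary <- list(
  samples = list(total = nrow(man),
                 native = sum(man$status == "native"),
                 invasive = sum(man$status == "invasive")),
  strain_marker_agreement_pct = hosts$agreement_rate,
  fst_invasive_vs_native_corn = perm$observed,
  fst_permutation_p = perm$p,
  invasive_monophyly = mono,
  sweep_loci = nrow(loci),
  invasive_specific_loci = sum(loci$invasive_specific))
jsonlite::write_json(summary, file.path(OUT_DIR, "summary.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

say("== inference chain summary ==")
say("cohort: %d samples (%d native / %d invasive)", summary$samples$total,
    summary$samples$native, summary$samples$invasive)
say("strain markers agree for %.1f%% of samples",
    summary$strain_marker_agreement_pct)
say("F_ST(invasive, native Corn) = %.4f, permutation p = %.3g",
    summary$fst_invasive_vs_native_corn, summary$fst_permutation_p)
say("invasive monophyly: %s (support %.1f%%)",
    mono$is_monophyletic, mono$support)
say("sweep loci: %d, of which %d invasive-specific",
    summary$sweep_loci, summary$invasive_specific_loci)
say("wrote %s", file.path(OUT_DIR, "summary.json"))
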