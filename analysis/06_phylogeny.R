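#!/usr/bin/env Rscript
# Individual-level nuclear phylogeny: transversion-weighted Euclidean
# genotype distances, BIO-NJ per bootstrap replicate (sites resampled,
# 200 replicates), majority-rule extended consensus. A monophyletic
# invasive clade supports a single invasive ancestry. The COX1 barcode
# tree is bootstrapped the same way; its two clades are the
# mitochondrial strains.

source("analysis/common.R")

nuc <- load_filtered()
man <- load_manifest()

boot <- bootstrap_consensus(nuc, n_replicates = 200, seed = SEED + 4L)
write_newick(boot$consensus, file.path(OUT_DIR, "nuclear_consensus.nwk"))
write_newick(boot$main, file.path(OUT_DIR, "nuclear_bionj.nwk"))

inv <- man$sample_id[man$status == "invasive"]
mono <- clade_support(boot$consensus, inv)
say("invasive monophyly: %s with %.1f%% bootstrap support (%d replicates)",
    mono$is_monophyletic, mono$support, boot$n_replicates)

cox1_aln <- read_fasta_alignment(file.path(DATA_DIR, "cox1.fasta"))
cb <- k2p_bootstrap_consensus(cox1_aln, n_replicates = 200, seed = SEED + 5L)
write_newick(cb$consensus, file.path(OUT_DIR, "cox1_consensus.nwk"),
             outgroup = "outgroup")
truth <- load_truth()
sfr <- truth$sample_id[truth$cox1_strain == "sfR"]
split <- clade_support(cb$consensus, sfr)
say("COX1 sfC/sfR split: monophyletic = %s, support %.1f%%",
    split$is_monophyletic, split$support)
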