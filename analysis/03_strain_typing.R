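#!/usr/bin/env Rscript
# Call host-plant strains (sfC / sfR) from the two diagnostic markers:
# PCA + 2-means on the TPI locus, and anchored clades on the COX1
# barcode tree (K2P distances, BIO-NJ, rooted on the outgroup). The two
# markers disagree by design for part of the corn-feeding samples -
# the mitochondrial strain crosses the nuclear groups.

source("analysis/common.R")

man <- load_manifest()
tpi_gm <- read_vcf(file.path(DATA_DIR, "tpi.vcf"))
cox1_aln <- read_fasta_alignment(file.path(DATA_DIR, "cox1.fasta"))

tpi <- tpi_strain_call(tpi_gm, manifest_anchors(man, "anchor_tpi"),
                       seed = SEED + 1L)
cox1 <- cox1_strain_call(cox1_aln, manifest_anchors(man, "anchor_cox1"))
calls <- merge(tpi, cox1, by = "sample_id")
write.table(calls, file.path(OUT_DIR, "strain_calls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

hosts <- strain_host_table(man, calls)
write.table(hosts$table, file.path(OUT_DIR, "strain_host_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

truth <- load_truth()
at <- match(calls$sample_id, truth$sample_id)
say("TPI calls:  %s", paste(names(table(calls$tpi_strain)),
                            table(calls$tpi_strain), collapse = ", "))
say("COX1 calls: %s", paste(names(table(calls$cox1_strain)),
                            table(calls$cox1_strain), collapse = ", "))
say("accuracy vs truth: TPI %.1f%%, COX1 %.1f%%",
    100 * mean(calls$tpi_strain == truth$tpi_strain[at]),
    100 * mean(calls$cox1_strain == truth$cox1_strain[at]))
say("marker agreement: %.1f%% - the corn-feeding sfR-mitochondria samples drive the discordance",
    hosts$agreement_rate)
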