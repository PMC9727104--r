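#!/usr/bin/env Rscript
# Apply the variant-caller hard filters (QD >= 2, FS <= 60, MQ >= 40,
# MQRankSum >= -12.5, ReadPosRankSum >= -8) and restrict to biallelic
# SNVs genotyped in every individual - the substrate of all nuclear
# statistics downstream.

source("analysis/common.R")

raw <- read_vcf(file.path(DATA_DIR, "nuclear.vcf"))
after_info <- apply_info_filters(raw)
complete <- select_biallelic_complete(after_info)

say("input sites: %d", n_sites(raw))
say("after INFO filters: %d (removed %d)",
    n_sites(after_info), n_sites(raw) - n_sites(after_info))
say("biallelic, complete-case: %d (removed %d)",
    n_sites(complete), n_sites(after_info) - n_sites(complete))
say("transversion fraction: %.3f", mean(site_is_transversion(complete)))

write_vcf(complete, file.path(DATA_DIR, "nuclear.filtered.vcf"))
say("wrote %s", file.path(DATA_DIR, "nuclear.filtered.vcf"))
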