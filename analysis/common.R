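# Shared setup for the numbered analysis drivers. Each driver is a thin
# narrative over the package functions; all computation lives in the
# package. Run the drivers in order from the repository root:
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_filter_variants.R
#   ...

suppressMessages(library(fawpopgen))

SEED <- 20200623L
DATA_DIR <- "results/data"
OUT_DIR <- "results"
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

cohort_config <- function() scenario_config(seed = SEED)

load_manifest <- function() read_manifest(file.path(DATA_DIR, "manifest.tsv"))
load_truth <- function() read_truth(file.path(DATA_DIR, "truth.json"))
load_filtered <- function() read_vcf(file.path(DATA_DIR, "nuclear.filtered.vcf"))

scaffold_lengths <- function() {
  cfg <- cohort_config()
  setNames(rep(cfg$scaffold_length, cfg$n_scaffolds),
           paste0("scaffold_", seq_len(cfg$n_scaffolds)))
}

say <- function(...) cat(sprintf(...), "\n")
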