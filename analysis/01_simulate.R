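#!/usr/bin/env Rscript
# Generate the synthetic study cohort: 177 individuals from 12
# populations (99 native, 78 invasive), three nuclear groups plus an
# invasive gene pool derived from the Corn group, two mitochondrial COX1
# clades crossing the nuclear groups, a strain-diagnostic TPI locus, and
# one invasive-specific selective sweep.

source("analysis/common.R")

scen <- simulate_scenario(cohort_config())
paths <- write_scenario(scen, DATA_DIR)

say("cohort: %d samples (%d native, %d invasive) in %d populations",
    nrow(scen$manifest), sum(scen$manifest$status == "native"),
    sum(scen$manifest$status == "invasive"),
    length(unique(scen$manifest$population)))
say("nuclear SNVs: %d on %d scaffolds; TPI SNVs: %d; COX1 alignment: %d x %d bp",
    n_sites(scen$nuclear), length(unique(scen$nuclear$sites$scaffold)),
    n_sites(scen$tpi), nrow(as.matrix(scen$cox1)), ncol(as.matrix(scen$cox1)))
for (sw in scen$truth$config$sweeps)
  say("injected sweep: %s @ %d bp, alpha %g, target %s",
      sw$scaffold, as.integer(sw$center_bp), sw$alpha, sw$target)
say("wrote %s", paste(unlist(paths), collapse = ", "))
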