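#!/usr/bin/env Rscript
# Long-running (hours-scale) self-assembly spot checks that exceed the
# default test suite's envelope.  Usage:
#   Rscript scripts/extended_spot_checks.R [--seed <int>] [--box <L>] [--steps <n>]
#
# Conditions covered:
#   1. aAS = 26, aCS = 45 (solvent favours the centre block): concentric
#      aggregate; hydrophobic B+C band thickness reported against the
#      ~2.7 rc reference scale.
#   2. aAS = 65, aCS = 26 (solvent favours the end blocks): watch for a
#      closed aggregate with non-empty encapsulated solvent.  Closure needs
#      enough chains to wrap a membrane around a cavity; boxes of 16^3 and
#      up with >= 2x10^5 steps are realistic starting points, and the run
#      reports the encapsulated count over time so partial progress is
#      visible.

suppressPackageStartupMessages(library(pentadpd))

args <- commandArgs(trailingOnly = TRUE)
flag <- function(name, default) {
  hit <- which(args == paste0("--", name))
  if (length(hit) == 1 && hit < length(args)) as.numeric(args[hit + 1])
  else default
}
seed <- as.integer(flag("seed", 1))
box <- flag("box", 18)
steps <- flag("steps", 3e5)

params <- dpd_params()
chain <- chain_topology(3, 3, 6)
report <- max(1, floor(steps / 20))

run_condition <- function(aAS, aCS, label) {
  message(sprintf("== %s: aAS=%g aCS=%g box=%g steps=%g seed=%d",
                  label, aAS, aCS, box, steps, seed))
  fr <- build_system(box, 0.10, chain, seed = seed, params = params)
  fr <- init_velocities(fr, 1, seed = seed + 1L)
  tr <- dpd_run(fr, interaction_matrix(aAS, aCS), params, steps,
                seed = seed + 2L, report_every = report)
  for (f in tr$frames) {
    enc <- encapsulated_solvent(f)
    ag <- find_aggregates(f)
    cat(sprintf("%s step %8g  %-20s largest %.2f  encapsulated %5d (%d pocket(s))\n",
                label, f$step, classify_morphology(f),
                ag$clusters[[1]]$size / ag$n_polymer, length(enc),
                attr(enc, "n_pockets")))
  }
  tr$final
}

f1 <- run_condition(26, 45, "A-philic")
ag <- find_aggregates(f1)
prof <- composition_profile(f1, ag$clusters[[1]])
th <- tryCatch(as.numeric(membrane_thickness(prof, c("B", "C"))),
               error = function(e) NA_real_)
cat(sprintf("A-philic hydrophobic (B+C) band thickness: %.3f rc (reference scale ~2.7)\n",
            th))

f2 <- run_condition(65, 26, "C-philic")
enc <- encapsulated_solvent(f2)
cat(sprintf("C-philic final encapsulated solvent: %d bead(s) in %d pocket(s)\n",
            length(enc), attr(enc, "n_pockets")))
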