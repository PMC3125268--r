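#!/usr/bin/env Rscript
# Stage 1 — build the synthetic two-tissue study.
#
# Simulates the genome, two annotation sources, the expression program and
# all planted nTARs under the default study conditions, then emits the
# aligned read sets for both protocols and tissues plus the poly-A tags.
# Everything downstream re-derives this state deterministically from SEED.

suppressMessages(library(ntarseq))
SEED <- 42L
out <- file.path("results", sprintf("run_seed%d", SEED))
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_genome(sim_config(), seed = SEED)
write_simulation(sim, out)
message(sprintf("simulated %d genes and %d planted nTARs on %d chromosomes",
                nrow(sim$genes), length(sim$ntars), length(sim$seqlengths)))

for (tis in sim$config$tissues) {
  scr <- simulate_reads(sim, "screening", tis, seed = SEED * 7L + match(tis, sim$config$tissues))
  val <- simulate_reads(sim, "validation", tis, seed = SEED * 11L + match(tis, sim$config$tissues))
  write_bed6(scr, file.path(out, sprintf("screening_%s.bed", tis)))
  write_bed6(val, file.path(out, sprintf("validation_%s.bed", tis)))
  message(sprintf("tissue %s: %d screening reads, %d validation reads",
                  tis, length(scr), length(val)))
}
tags <- simulate_reads(sim, "polyA", "A", seed = SEED * 13L)
write_bed6(tags, file.path(out, "polya_tags.bed"))
message(length(tags), " poly-A tags written; outputs under ", out)
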