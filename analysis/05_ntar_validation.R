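#!/usr/bin/env Rscript
# Stage 5 — strand-aware validation: confirmation with >=3 reads of the
# stranded protocol, sense/antisense orientation per class, detection
# ratios against related genes, gene-corrected differential calls across
# tissues, and 3'-anchored poly-A confirmation.

suppressMessages(library(ntarseq))
SEED <- 42L
out <- file.path("results", sprintf("run_seed%d", SEED))

sim <- simulate_genome(sim_config(), seed = SEED)
scr_a <- read_alignments(file.path(out, "screening_A.bed"), "bed6")
scr_b <- read_alignments(file.path(out, "screening_B.bed"), "bed6")
val_a <- read_alignments(file.path(out, "validation_A.bed"), "bed6",
                         protocol = "validation")
tags <- read_alignments(file.path(out, "polya_tags.bed"), "bed6",
                        protocol = "polyA_tag")
track_a <- coverage_track(scr_a, sim$seqlengths)
track_b <- coverage_track(scr_b, sim$seqlengths)

classified <- classify_ntars(detect_ntars(track_a, sim$mask), sim$condensed)
validated <- validate_ntars(classified, val_a, sim$condensed)
orient <- class_orientation_summary(validated)
write.table(orient, file.path(out, "orientation_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

gene_rel <- validated[validated$ntar_class != "NGA" & validated$confirmed]
ratios <- detection_ratio(gene_rel, sim$condensed, track_a)
write.table(ratios, file.path(out, "detection_ratios.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

expr_a <- gene_expression(sim$condensed, scr_a, tissue = "A")
expr_b <- gene_expression(sim$condensed, scr_b, tissue = "B")
diff <- differential_ntars(validated[validated$confirmed], track_a, track_b,
                           expr_a, expr_b)
write.table(diff, file.path(out, "differential_ntars.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
pol <- confirm_polya(validated, tags, sim$condensed)
write.table(pol, file.path(out, "polya_confirmation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("%d of %d candidates confirmed (%.2f%%)",
                sum(validated$confirmed), length(validated),
                percent(sum(validated$confirmed), length(validated), 2L)))
message("sense:antisense ratios by class (unambiguous only):")
print(orient[, c("ntar_class", "n_sense", "n_antisense", "ratio")])
message(sum(diff$differential), " differential nTARs after gene correction; ",
        sum(pol$polya_confirmed), " poly-A confirmed")
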