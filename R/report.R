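# Summary-report arithmetic and the end-to-end pipeline driver.

#' Percentage with half-up rounding at a fixed decimal count
#'
#' @param part,whole Counts; `whole` must be positive.
#' @param decimals Decimal places (half-up rounding).
#' @return `100 * part / whole`, rounded half-up.
#' @export
percent <- function(part, whole, decimals = 1L) {
  if (any(whole <= 0)) stop("whole must be > 0")
  s <- 10^decimals
  floor(100 * part / whole * s + 0.5 + 1e-9) / s
}

#' Cross-tissue presence partition
#'
#' @param records_a,records_b Expression tables from [gene_expression()]
#'   over the same unit universe.
#' @return List with `both`, `only_a`, `only_b`, `total_present` counts;
#'   `total_present = both + only_a + only_b` by construction.
#' @export
presence_partition <- function(records_a, records_b) {
  if (nrow(records_a) != nrow(records_b) ||
      !setequal(records_a$unit_id, records_b$unit_id))
    stop("presence partition requires the same unit universe in both tissues")
  b <- records_b[match(records_a$unit_id, records_b$unit_id), ]
  both <- sum(records_a$present & b$present)
  only_a <- sum(records_a$present & !b$present)
  only_b <- sum(!records_a$present & b$present)
  list(both = both, only_a = only_a, only_b = only_b,
       total_present = both + only_a + only_b)
}

#' Expression-magnitude histogram over decade classes
#'
#' Units are binned by FPKM decade — (0.01,0.1], (0.1,1], (1,10], (10,100],
#' (100,Inf) — with units failing the presence call collected in `absent`.
#'
#' @param records Expression table from [gene_expression()].
#' @return Named integer vector of class counts plus `absent`; sums to the
#'   universe size.
#' @export
expression_magnitude_histogram <- function(records) {
  edges <- c(0.01, 0.1, 1, 10, 100, Inf)
  labs <- c("(0.01,0.1]", "(0.1,1]", "(1,10]", "(10,100]", ">100")
  out <- stats::setNames(integer(length(labs) + 1L), c(labs, "absent"))
  pres <- records$present
  out["absent"] <- sum(!pres)
  if (any(pres)) {
    b <- cut(records$fpkm[pres], edges, labels = labs)
    out[labs] <- as.integer(table(b))
  }
  out
}

#' Run the full analysis pipeline on a synthetic transcriptome
#'
#' Simulates a genome and reads, then executes every stage in order:
#' annotation condensation, exon mask, coverage tracks, expression and
#' presence calls, enhancement, nTAR detection and classification,
#' strand-specific validation with orientation and detection ratios,
#' gene-corrected differential calls, poly-A confirmation, saturation
#' modelling, and the summary report with planted-truth recovery metrics.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed driving the simulation and the saturation draw.
#' @param thresholds Named list overriding the detection/validation
#'   thresholds (`min_length`, `min_avg_cov`, `min_reads`, `min_sp`,
#'   `confirm_reads`, `window`, `fold`, `penalty`, `present_fpkm`).
#' @param saturation Run the saturation stage (default TRUE).
#' @return A list with all stage outputs and a `report` list of counts,
#'   percentages and recovery metrics.
#' @export
run_pipeline <- function(config = sim_config(), seed = 1L,
                         thresholds = list(), saturation = TRUE) {
  th <- utils::modifyList(list(min_length = 50L, min_avg_cov = 3,
                               min_reads = 5L, min_sp = 2L,
                               confirm_reads = 3L, window = 10000L,
                               fold = 3, penalty = 1, present_fpkm = 0.01),
                          thresholds)
  sim <- simulate_genome(config, seed = seed)
  scr_a <- simulate_reads(sim, "screening", "A", seed = seed * 7L + 1L)
  scr_b <- simulate_reads(sim, "screening", "B", seed = seed * 7L + 2L)
  val_a <- simulate_reads(sim, "validation", "A", seed = seed * 7L + 3L)
  tags <- simulate_reads(sim, "polyA", "A", seed = seed * 7L + 4L)

  keep <- function(r) r[mcols(r)$unique]
  scr_a <- keep(scr_a); scr_b <- keep(scr_b); val_a <- keep(val_a)

  track_a <- coverage_track(scr_a, sim$seqlengths, stranded = FALSE)
  track_b <- coverage_track(scr_b, sim$seqlengths, stranded = FALSE)

  expr_a <- gene_expression(sim$condensed, scr_a, tissue = "A",
                            presence_threshold = th$present_fpkm,
                            min_sp = th$min_sp)
  expr_b <- gene_expression(sim$condensed, scr_b, tissue = "B",
                            presence_threshold = th$present_fpkm,
                            min_sp = th$min_sp)
  enh <- enhancement_call(expr_a$unit_id, expr_a$fpkm, expr_b$fpkm,
                          fold = th$fold, penalty = th$penalty)
  part <- presence_partition(expr_a, expr_b)

  cands <- detect_ntars(track_a, sim$mask, min_length = th$min_length,
                        min_avg_cov = th$min_avg_cov,
                        min_reads = th$min_reads, min_sp = th$min_sp)
  classified <- classify_ntars(cands, sim$condensed, window = th$window)
  validated <- validate_ntars(classified, val_a, sim$condensed,
                              min_reads = th$confirm_reads)
  orient <- class_orientation_summary(validated)
  gene_rel <- validated[validated$ntar_class != "NGA" & validated$confirmed]
  ratios <- detection_ratio(gene_rel, sim$condensed, track_a)
  diff <- differential_ntars(validated[validated$confirmed], track_a, track_b,
                             expr_a, expr_b, fold = th$fold,
                             penalty = th$penalty)
  polya <- confirm_polya(validated, tags, sim$condensed)
  recovery <- plant_recovery_report(classified, sim$ntars)

  sat <- NULL
  if (saturation) {
    curve <- detection_curve(scr_a, sim$condensed,
                             step = max(100L, floor(length(scr_a) / 40L)),
                             min_reads = th$min_reads, seed = seed * 7L + 5L)
    sat <- tryCatch(fit_saturation(curve),
                    error = function(e) structure(
                      list(error = conditionMessage(e)), class = "try-error"))
    sat <- list(curve = curve, fit = sat)
  }

  n_conf <- sum(validated$confirmed)
  report <- list(
    seed = seed,
    reads_used = c(A = length(scr_a), B = length(scr_b),
                   validation_A = length(val_a)),
    present_A = sum(expr_a$present), present_B = sum(expr_b$present),
    presence = part,
    pct_present = percent(part$total_present, nrow(expr_a), 1L),
    enhanced_A = sum(enh$enhanced_in == "A"),
    enhanced_B = sum(enh$enhanced_in == "B"),
    n_candidates = length(cands),
    n_confirmed = n_conf,
    pct_confirmed = if (length(cands) > 0)
      percent(n_conf, length(cands), 2L) else NA_real_,
    class_counts = table(factor(validated$ntar_class[validated$confirmed],
                                levels = .NTAR_CLASSES)),
    orientation = orient,
    detection_ratio_bins = table(ratios$bin),
    n_differential = sum(diff$differential),
    n_polya_confirmed = sum(polya$polya_confirmed),
    recovery = recovery$recall,
    saturation_asymptote = if (!is.null(sat) &&
                               inherits(sat$fit, "saturation_fit"))
      sat$fit$a else NA_real_
  )
  list(sim = sim, tracks = list(A = track_a, B = track_b),
       expression = list(A = expr_a, B = expr_b), enhancement = enh,
       candidates = cands, classified = classified, validated = validated,
       orientation = orient, ratios = ratios, differential = diff,
       polya = polya, recovery = recovery, saturation = sat,
       report = report)
}
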