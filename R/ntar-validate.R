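# Strand-specific validation of candidate nTARs: confirmation, orientation
# calls, per-class sense/antisense summaries, detection ratios against the
# related gene, gene-corrected tissue fold changes, and 3'-anchored poly-A
# tag confirmation.

#' Validate candidates with strand-specific reads
#'
#' Validation-protocol reads overlapping a candidate by at least one base are
#' counted per genomic strand. For gene-related candidates the counts are
#' expressed relative to the related gene's strand (sense = same strand). A
#' candidate is confirmed when the total is at least `min_reads`. Confirmed
#' candidates are oriented `sense` or `antisense` only when all reads agree;
#' mixed reads give `ambiguous`. Non-gene-associated (NGA) candidates have no
#' reference strand and stay `undetermined`.
#'
#' @param classified `GRanges` from [classify_ntars()].
#' @param validation_reads Stranded `GRanges` of validation-protocol reads.
#' @param condensed `GRangesList` of condensed gene models (for gene
#'   strands).
#' @param min_reads Reads required for confirmation (default 3).
#' @return The input `GRanges` with metadata columns `n_plus`, `n_minus`,
#'   `sense_reads`, `antisense_reads` (NA for NGA), `confirmed` and
#'   `orientation` (NA when unconfirmed).
#' @export
validate_ntars <- function(classified, validation_reads, condensed,
                           min_reads = 3L) {
  n <- length(classified)
  np <- integer(n); nm <- integer(n)
  ov <- findOverlaps(classified, validation_reads, ignore.strand = TRUE)
  if (length(ov) > 0L) {
    st <- as.character(strand(validation_reads))[subjectHits(ov)]
    tp <- table(factor(queryHits(ov)[st == "+"], levels = seq_len(n)))
    tm <- table(factor(queryHits(ov)[st == "-"], levels = seq_len(n)))
    np <- as.integer(tp); nm <- as.integer(tm)
  }
  spans <- gene_spans(condensed)
  gstrand <- as.character(strand(spans))[match(classified$related_gene,
                                               names(spans))]
  is_nga <- classified$ntar_class == "NGA" | is.na(gstrand)
  sense <- ifelse(is_nga, NA_integer_, ifelse(gstrand == "+", np, nm))
  anti  <- ifelse(is_nga, NA_integer_, ifelse(gstrand == "+", nm, np))
  confirmed <- (np + nm) >= min_reads
  orientation <- rep(NA_character_, n)
  orientation[confirmed & is_nga] <- "undetermined"
  idx <- confirmed & !is_nga
  orientation[idx & sense > 0 & anti == 0] <- "sense"
  orientation[idx & anti > 0 & sense == 0] <- "antisense"
  orientation[idx & sense > 0 & anti > 0] <- "ambiguous"
  mcols(classified)$n_plus <- np
  mcols(classified)$n_minus <- nm
  mcols(classified)$sense_reads <- sense
  mcols(classified)$antisense_reads <- anti
  mcols(classified)$confirmed <- confirmed
  mcols(classified)$orientation <- orientation
  classified
}

#' Per-class sense/antisense orientation summary
#'
#' Only confirmed candidates of unambiguous orientation enter the counts;
#' ambiguous and undetermined candidates are excluded.
#'
#' @param validated `GRanges` from [validate_ntars()].
#' @return data.frame with `ntar_class`, `n_sense`, `n_antisense`, `ratio`
#'   (`Inf`, flagged in `ratio_degenerate`, when no antisense exists).
#' @export
class_orientation_summary <- function(validated) {
  keep <- !is.na(validated$orientation) &
    validated$orientation %in% c("sense", "antisense")
  cl <- factor(validated$ntar_class[keep], levels = .NTAR_CLASSES)
  ns <- table(cl[validated$orientation[keep] == "sense"])
  na_ <- table(cl[validated$orientation[keep] == "antisense"])
  out <- data.frame(ntar_class = .NTAR_CLASSES,
                    n_sense = as.integer(ns),
                    n_antisense = as.integer(na_),
                    stringsAsFactors = FALSE)
  out$ratio <- ifelse(out$n_antisense == 0,
                      ifelse(out$n_sense == 0, NA_real_, Inf),
                      out$n_sense / out$n_antisense)
  out$ratio_degenerate <- out$n_antisense == 0
  out
}

# Mean per-base screening depth over a gene's condensed exons.
.gene_mean_depth <- function(condensed, track) {
  depth <- .total_depth(track)
  ex <- unlist(condensed, use.names = FALSE)
  sums <- .depth_sums(depth, ex)
  idx <- rep(seq_along(condensed), lengths(condensed))
  as.numeric(tapply(sums, idx, sum)) / sum(width(condensed))
}

#' Detection ratio of nTARs to their related genes
#'
#' Mean per-base depth over the candidate divided by mean per-base depth over
#' the related gene's condensed exons, both from the screening track, binned
#' at 0.25 boundaries. A related gene without any exonic coverage yields the
#' special category `"related gene not expressed"`.
#'
#' @param classified `GRanges` from [classify_ntars()]; must not contain NGA
#'   candidates (no related gene exists for them).
#' @param condensed `GRangesList` of condensed gene models.
#' @param track Screening-protocol `coverage_track`.
#' @return data.frame with `ntar_id`, `related_gene`, `ratio` (NA when the
#'   gene is not expressed) and `bin`.
#' @export
detection_ratio <- function(classified, condensed, track) {
  if (any(classified$ntar_class == "NGA"))
    stop("detection ratio is undefined for NGA candidates (no related gene)")
  nd <- .depth_sums(.total_depth(track), classified) / width(classified)
  gd_all <- .gene_mean_depth(condensed, track)
  gd <- gd_all[match(classified$related_gene, names(condensed))]
  ratio <- ifelse(gd > 0, nd / gd, NA_real_)
  bin <- ifelse(gd == 0, "related gene not expressed",
                as.character(cut(ratio, c(0, 0.25, 0.5, 0.75, 1, Inf),
                                 labels = c("(0,0.25]", "(0.25,0.5]",
                                            "(0.5,0.75]", "(0.75,1]", ">1"))))
  data.frame(ntar_id = classified$ntar_id,
             related_gene = classified$related_gene,
             ratio = ratio, bin = bin, stringsAsFactors = FALSE)
}

# Symmetric pseudocount fold: (a + p) / (b + p). Positive, reciprocal under
# swapping the tissues, and exactly 1 for equal values.
.pseudo_fold <- function(a, b, penalty) (a + penalty) / (b + penalty)

#' Gene-corrected differential nTAR calls across two tissues
#'
#' The candidate's tissue fold change (mean screening depth, symmetric
#' additive pseudocount) is divided by the related gene's FPKM fold change
#' computed the same way; NGA candidates are uncorrected. A candidate is
#' differential when the corrected fold is at least `fold` or at most
#' `1/fold`. A perfectly co-varying candidate/gene pair has corrected fold 1
#' for any tissue fold.
#'
#' @param classified `GRanges` from [classify_ntars()].
#' @param track_a,track_b Screening `coverage_track`s for the two tissues.
#' @param expr_a,expr_b Expression tables from [gene_expression()] for the
#'   two tissues.
#' @param fold Fold threshold (default 3).
#' @param penalty Additive pseudocount (default 1).
#' @return data.frame with `ntar_id`, `ntar_class`, `related_gene`, `cov_a`,
#'   `cov_b`, `ntar_fold`, `gene_fold` (1 for NGA), `corrected_fold`,
#'   `differential`.
#' @export
differential_ntars <- function(classified, track_a, track_b, expr_a, expr_b,
                               fold = 3, penalty = 1) {
  cov_a <- .depth_sums(.total_depth(track_a), classified) / width(classified)
  cov_b <- .depth_sums(.total_depth(track_b), classified) / width(classified)
  nf <- .pseudo_fold(cov_a, cov_b, penalty)
  fa <- expr_a$fpkm[match(classified$related_gene, expr_a$unit_id)]
  fb <- expr_b$fpkm[match(classified$related_gene, expr_b$unit_id)]
  gf <- ifelse(is.na(fa) | is.na(fb), 1, .pseudo_fold(fa, fb, penalty))
  gf[classified$ntar_class == "NGA"] <- 1
  cf <- nf / gf
  data.frame(ntar_id = classified$ntar_id,
             ntar_class = classified$ntar_class,
             related_gene = classified$related_gene,
             cov_a = cov_a, cov_b = cov_b,
             ntar_fold = nf, gene_fold = gf, corrected_fold = cf,
             differential = cf >= fold | cf <= 1 / fold,
             stringsAsFactors = FALSE)
}

#' Confirm nTARs with 3'-anchored poly-A tags
#'
#' A tag confirms a candidate when its 3'-anchored end (the rightmost base
#' for plus-strand tags, leftmost for minus-strand tags) falls inside the
#' candidate interval; a tag merely overlapping with its anchor outside does
#' not count.
#'
#' @param classified `GRanges` from [classify_ntars()] (or
#'   [validate_ntars()]).
#' @param polya_tags Stranded `GRanges` of 3'-anchored tag alignments.
#' @param condensed `GRangesList` of condensed gene models (for tag
#'   orientation relative to the related gene).
#' @param min_tags Tags required for confirmation (default 1).
#' @return data.frame with `ntar_id`, `n_tags`, `polya_confirmed` and
#'   `tag_orientation` (`sense`/`antisense`/`mixed` relative to the related
#'   gene, NA for NGA or untagged candidates).
#' @export
confirm_polya <- function(classified, polya_tags, condensed, min_tags = 1L) {
  anchor <- ifelse(as.character(strand(polya_tags)) == "-",
                   start(polya_tags), end(polya_tags))
  anchors <- GRanges(seqnames(polya_tags), IRanges(anchor, width = 1L),
                     strand = strand(polya_tags))
  n <- length(classified)
  ov <- findOverlaps(classified, anchors, ignore.strand = TRUE)
  ntags <- as.integer(table(factor(queryHits(ov), levels = seq_len(n))))
  spans <- gene_spans(condensed)
  gstrand <- as.character(strand(spans))[match(classified$related_gene,
                                               names(spans))]
  orient <- rep(NA_character_, n)
  if (length(ov) > 0L) {
    st <- as.character(strand(anchors))[subjectHits(ov)]
    gs <- gstrand[queryHits(ov)]
    rel <- ifelse(is.na(gs), NA_character_,
                  ifelse(st == gs, "sense", "antisense"))
    agg <- tapply(rel, queryHits(ov), function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0L) NA_character_
      else if (all(v == "sense")) "sense"
      else if (all(v == "antisense")) "antisense" else "mixed"
    })
    orient[as.integer(names(agg))] <- unlist(agg)
  }
  data.frame(ntar_id = classified$ntar_id, n_tags = ntags,
             polya_confirmed = ntags >= min_tags,
             tag_orientation = orient, stringsAsFactors = FALSE)
}
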