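# Nine-class positional classification of candidate novel transcribed
# regions relative to condensed gene models.
#
# Classes, with up/downstream taken on the related gene's strand:
#   ISE  intron-spanning: inside a gene span, covers a whole intron
#   ELU  exon-linked upstream: intronic, flush with an exon's 5' edge
#   ELD  exon-linked downstream: intronic, flush with an exon's 3' edge
#   UGI  upstream gene intersection: outside the span, flush with the 5' end
#   DGI  downstream gene intersection: flush with the 3' end
#   IGE  intragenic element: intronic, touching no exon
#   UGN  upstream gene neighbourhood: gap in (0, window] on the 5' side
#   DGN  downstream gene neighbourhood: same on the 3' side
#   NGA  non-gene associated: more than `window` bp from every gene
#
# A candidate satisfying several geometries is labelled once, by priority
# ISE > ELD/ELU > UGI/DGI > IGE > UGN/DGN > NGA; gene-internal labels bind to
# the enclosing gene, neighbourhood labels to the closest gene, remaining
# ties resolved by smaller distance, smaller gene start, then symbol.

.NTAR_CLASSES <- c("NGA", "UGN", "DGN", "UGI", "DGI", "ELU", "ELD", "IGE", "ISE")
.CLASS_RANK <- c(ISE = 1, ELD = 2, ELU = 2, UGI = 3, DGI = 3, IGE = 4,
                 UGN = 5, DGN = 5, NGA = 6)

#' Classify candidate nTARs into the nine positional classes
#'
#' @param candidates `GRanges` of candidates (must not overlap the exon
#'   mask the gene models contributed to).
#' @param condensed `GRangesList` of condensed gene models.
#' @param window Neighbourhood distance in bp separating gene-associated
#'   from non-gene-associated candidates (default 10000).
#' @param gap_tol Maximum gap in bp still counted as "flush" with an exon or
#'   gene boundary (default 0: direct contiguity).
#' @return The input `GRanges` with metadata columns `ntar_class`,
#'   `related_gene` (NA for NGA) and `distance` (bp; 0 for gene-internal and
#'   flush candidates).
#' @export
classify_ntars <- function(candidates, condensed, window = 10000L,
                           gap_tol = 0L) {
  spans <- gene_spans(condensed)
  ex_all <- unlist(condensed, use.names = FALSE)
  bad <- overlapsAny(candidates, ex_all, ignore.strand = TRUE)
  if (any(bad))
    stop("candidate overlaps an annotated exon (first: ",
         as.character(candidates[which(bad)[1L]]), ")")
  introns <- gene_introns(condensed)

  n <- length(candidates)
  cls <- rep("NGA", n)
  rel <- rep(NA_character_, n)
  dst <- rep(NA_real_, n)

  lab <- character(0); labq <- integer(0); labd <- numeric(0)
  labg <- character(0); labstart <- numeric(0)

  # gene-internal geometries: candidate inside an intron of the gene
  hi <- findOverlaps(candidates, introns, type = "within",
                     ignore.strand = TRUE)
  if (length(hi) > 0L) {
    q <- queryHits(hi); s <- subjectHits(hi)
    flush_l <- start(candidates)[q] - start(introns)[s] <= gap_tol
    flush_r <- end(introns)[s] - end(candidates)[q] <= gap_tol
    gplus <- as.character(strand(introns))[s] == "+"
    l <- ifelse(flush_l & flush_r, "ISE",
         ifelse(flush_l, ifelse(gplus, "ELD", "ELU"),
         ifelse(flush_r, ifelse(gplus, "ELU", "ELD"), "IGE")))
    lab <- c(lab, l); labq <- c(labq, q); labd <- c(labd, rep(0, length(q)))
    labg <- c(labg, introns$gene_symbol[s])
    sp_idx <- match(introns$gene_symbol[s], names(spans))
    labstart <- c(labstart, start(spans)[sp_idx])
  }

  # gene-external geometries: flush or within the neighbourhood window
  hs <- findOverlaps(candidates, spans, maxgap = window,
                     ignore.strand = TRUE)
  if (length(hs) > 0L) {
    q <- queryHits(hs); s <- subjectHits(hs)
    ov <- start(candidates)[q] <= end(spans)[s] &
          end(candidates)[q] >= start(spans)[s]
    q <- q[!ov]; s <- s[!ov]
    if (length(q) > 0L) {
      d <- GenomicRanges::distance(candidates[q], spans[s],
                                   ignore.strand = TRUE)
      left_of_gene <- end(candidates)[q] < start(spans)[s]
      gplus <- as.character(strand(spans))[s] == "+"
      at5 <- left_of_gene == gplus   # candidate at the gene's 5' end
      l <- ifelse(d <= gap_tol, ifelse(at5, "UGI", "DGI"),
                  ifelse(at5, "UGN", "DGN"))
      keep <- d <= gap_tol | d <= window
      lab <- c(lab, l[keep]); labq <- c(labq, q[keep])
      labd <- c(labd, as.numeric(d[keep]))
      labg <- c(labg, names(spans)[s[keep]])
      labstart <- c(labstart, start(spans)[s[keep]])
    }
  }

  if (length(lab) > 0L) {
    ord <- order(labq, .CLASS_RANK[lab], labd, labstart, labg)
    first <- !duplicated(labq[ord])
    pick <- ord[first]
    cls[labq[pick]] <- lab[pick]
    rel[labq[pick]] <- labg[pick]
    dst[labq[pick]] <- labd[pick]
  }

  # NGA distance: gap to the nearest gene anywhere on the chromosome (NA if
  # the chromosome holds no gene)
  nga <- which(cls == "NGA")
  if (length(nga) > 0L && length(spans) > 0L) {
    nr <- GenomicRanges::distanceToNearest(candidates[nga], spans,
                                           ignore.strand = TRUE)
    dst[nga[queryHits(nr)]] <- mcols(nr)$distance
  }

  mcols(candidates)$ntar_class <- cls
  mcols(candidates)$related_gene <- rel
  mcols(candidates)$distance <- dst
  candidates
}

#' Compare classified candidates with a planted truth table
#'
#' Candidates and planted regions are matched at >= 50% reciprocal overlap
#' (each planted region paired with the candidate maximizing the overlap).
#'
#' @param classified `GRanges` from [classify_ntars()].
#' @param truth `GRanges` of planted regions with metadata column
#'   `ntar_class` (and optionally `ntar_id`).
#' @param min_reciprocal Minimum reciprocal-overlap fraction (default 0.5).
#' @return List with `confusion` (true class x called class matrix, plus a
#'   `missed` column), `per_class` data.frame (n_true, n_called, recall,
#'   precision), `recall` and `precision` overall, and `matches`
#'   (truth index, candidate index).
#' @export
plant_recovery_report <- function(classified, truth, min_reciprocal = 0.5) {
  classes <- .NTAR_CLASSES
  ov <- findOverlaps(truth, classified, ignore.strand = TRUE)
  match_cand <- rep(NA_integer_, length(truth))
  if (length(ov) > 0L) {
    wo <- width(GenomicRanges::pintersect(truth[queryHits(ov)],
                                          classified[subjectHits(ov)]))
    frac_t <- wo / width(truth)[queryHits(ov)]
    frac_c <- wo / width(classified)[subjectHits(ov)]
    good <- frac_t >= min_reciprocal & frac_c >= min_reciprocal
    ovq <- queryHits(ov)[good]; ovs <- subjectHits(ov)[good]; w <- wo[good]
    if (length(ovq) > 0L) {
      ord <- order(ovq, -w)
      first <- !duplicated(ovq[ord])
      match_cand[ovq[ord][first]] <- ovs[ord][first]
    }
  }
  tc <- factor(truth$ntar_class, levels = classes)
  called <- rep("missed", length(truth))
  called[!is.na(match_cand)] <-
    classified$ntar_class[match_cand[!is.na(match_cand)]]
  confusion <- table(true = tc, called = factor(called,
                                                levels = c(classes, "missed")))
  correct <- !is.na(match_cand) & called == as.character(tc)
  per_class <- data.frame(
    ntar_class = classes,
    n_true = as.integer(table(tc)),
    n_called = as.integer(table(factor(classified$ntar_class,
                                       levels = classes))),
    recall = vapply(classes, function(k)
      if (sum(tc == k) == 0) NA_real_
      else sum(correct & tc == k) / sum(tc == k), numeric(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
  matched_cand_class <- classified$ntar_class[match_cand[!is.na(match_cand)]]
  per_class$precision <- vapply(classes, function(k) {
    nk <- sum(classified$ntar_class == k)
    if (nk == 0) NA_real_
    else sum(matched_cand_class == k &
               as.character(tc)[!is.na(match_cand)] == k) / nk
  }, numeric(1L))
  list(confusion = confusion, per_class = per_class,
       recall = mean(correct),
       precision = if (length(classified)) sum(correct) / length(classified)
                   else NA_real_,
       matches = data.frame(truth = which(!is.na(match_cand)),
                            candidate = match_cand[!is.na(match_cand)]))
}
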