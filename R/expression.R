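# Union-exon FPKM quantification, presence calls, penalized tissue-fold
# calls, and 5'-3' coverage-bias profiles.

#' FPKM from read count and exonic model length
#'
#' Fragments per kilobase of exonic model per million mapped fragments:
#' `n_reads / (exonic_bp/1000 * total_mapped/1e6)`.
#'
#' @param n_reads Reads assigned to the unit (overlap with any exon).
#' @param exonic_bp Total exonic length of the unit in bp.
#' @param total_mapped Total mapped fragments in the library.
#' @return Numeric FPKM (vectorized).
#' @export
fpkm <- function(n_reads, exonic_bp, total_mapped) {
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  if (any(exonic_bp < 1)) stop("exonic model length must be >= 1 bp")
  n_reads / ((exonic_bp / 1000) * (total_mapped / 1e6))
}

#' Quantify condensed genes in one library
#'
#' A read is assigned to a gene if it overlaps any condensed exon by at least
#' one base (reads spanning an exon/intron boundary are counted).
#'
#' @param condensed `GRangesList` from [condense_genes()].
#' @param reads `GRanges` of alignments.
#' @param total_mapped Total mapped fragments; defaults to `length(reads)`.
#' @param tissue Tissue tag recorded in the table.
#' @param presence_threshold,min_sp Presence-call parameters, see
#'   [call_present()].
#' @return data.frame: `unit_id`, `tissue`, `n_reads`, `n_start_points`,
#'   `fpkm`, `present`.
#' @export
gene_expression <- function(condensed, reads, total_mapped = NULL,
                            tissue = NA_character_,
                            presence_threshold = 0.01, min_sp = 2L) {
  if (is.null(total_mapped)) total_mapped <- length(reads)
  n <- countOverlaps(condensed, reads, ignore.strand = TRUE)
  # start points are counted over exon-assigned reads, not the whole span
  ov <- findOverlaps(condensed, reads, ignore.strand = TRUE)
  sp <- integer(length(condensed))
  if (length(ov) > 0L) {
    st <- .start_points(reads, strand_aware = TRUE)
    key <- paste(queryHits(ov), st[subjectHits(ov)])
    q <- queryHits(ov)[!duplicated(key)]
    tab <- table(q)
    sp[as.integer(names(tab))] <- as.integer(tab)
  }
  exonic_bp <- sum(width(condensed))
  f <- fpkm(n, exonic_bp, total_mapped)
  data.frame(unit_id = names(condensed), tissue = tissue,
             n_reads = as.integer(n), n_start_points = sp, fpkm = f,
             present = call_present(f, sp, presence_threshold, min_sp),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Presence call for an expression record
#'
#' A unit is present when its FPKM strictly exceeds the threshold and it is
#' supported by at least `min_sp` independent start points (guarding against
#' clonal amplification artifacts).
#'
#' @param fpkm Numeric FPKM values.
#' @param n_start_points Independent start-point counts.
#' @param threshold Strict FPKM threshold (default 0.01).
#' @param min_sp Minimum start points (default 2).
#' @return Logical vector.
#' @export
call_present <- function(fpkm, n_start_points, threshold = 0.01, min_sp = 2L) {
  fpkm > threshold & n_start_points >= min_sp
}

#' Penalized tissue-enhancement test
#'
#' Expression is enhanced in the first tissue when
#' `fpkm_a / (fpkm_b + penalty) >= fold`. The additive penalty damps fold
#' changes of barely-expressed units.
#'
#' @param fpkm_a,fpkm_b FPKM in the two tissues (vectorized).
#' @param fold Fold threshold (default 3).
#' @param penalty Additive penalty on the denominator (default 1).
#' @return Logical vector.
#' @export
tissue_enhanced <- function(fpkm_a, fpkm_b, fold = 3, penalty = 1) {
  stopifnot(all(fpkm_a >= 0), all(fpkm_b >= 0))
  fpkm_a / (fpkm_b + penalty) >= fold
}

#' Two-sided enhancement call
#'
#' @param unit_id Unit identifiers.
#' @param fpkm_a,fpkm_b FPKM in tissues A and B.
#' @inheritParams tissue_enhanced
#' @return data.frame with `unit_id`, `fpkm_a`, `fpkm_b`, `enhanced_in`
#'   (`"A"`, `"B"` or `"neither"`).
#' @export
enhancement_call <- function(unit_id, fpkm_a, fpkm_b, fold = 3, penalty = 1) {
  a <- tissue_enhanced(fpkm_a, fpkm_b, fold, penalty)
  b <- tissue_enhanced(fpkm_b, fpkm_a, fold, penalty)
  data.frame(unit_id = unit_id, fpkm_a = fpkm_a, fpkm_b = fpkm_b,
             enhanced_in = ifelse(a, "A", ifelse(b, "B", "neither")),
             stringsAsFactors = FALSE)
}

#' Length-stratified 5'-3' coverage-bias profile
#'
#' For each transcript the per-base exonic coverage is laid along the 5' to
#' 3' axis (reversed for minus-strand models), averaged into `n_bins`
#' equal-width bins, summed over all transcripts of a length class, and
#' scaled so that the class maximum equals 1.
#'
#' @param track A `coverage_track` (combined depth is used).
#' @param transcripts `GRangesList` of exon models (single-isoform
#'   transcripts or condensed genes).
#' @param length_class_edges Inner class edges in bp; default
#'   `c(1000, 2000, 5000)` gives classes (0,1], (1,2], (2,5], >5 kb.
#' @param n_bins Number of relative-position bins (>= 10).
#' @return data.frame with `length_class`, `bin` (1 = 5' end),
#'   `relative_coverage` in \[0, 1\]. Empty length classes are omitted with a
#'   warning.
#' @export
bias_profile <- function(track, transcripts,
                         length_class_edges = c(1000, 2000, 5000),
                         n_bins = 100L) {
  stopifnot(n_bins >= 10L)
  depth <- .total_depth(track)
  lens <- sum(width(transcripts))
  edges <- c(0, length_class_edges, Inf)
  labs <- paste0("(", edges[-length(edges)] / 1000, ",",
                 ifelse(is.finite(edges[-1]), paste0(edges[-1] / 1000, "]"),
                        "Inf) kb"))
  labs[length(labs)] <- paste0(">", edges[length(edges) - 1] / 1000, " kb")
  cls <- cut(lens, edges, labels = labs)
  sums <- matrix(0, nrow = length(labs), ncol = n_bins,
                 dimnames = list(labs, NULL))
  for (i in seq_along(transcripts)) {
    ex <- sort(transcripts[[i]])
    chr <- as.character(seqnames(ex))[1L]
    v <- unlist(lapply(seq_along(ex), function(j)
      as.numeric(depth[[chr]][start(ex)[j]:end(ex)[j]])), use.names = FALSE)
    if (as.character(strand(ex))[1L] == "-") v <- rev(v)
    sums[as.integer(cls[i]), ] <- sums[as.integer(cls[i]), ] + .bin_means(v, n_bins)
  }
  out <- NULL
  for (k in seq_along(labs)) {
    if (!any(cls == labs[k], na.rm = TRUE)) {
      warning("empty length class omitted: ", labs[k])
      next
    }
    prof <- sums[k, ]
    m <- max(prof)
    if (m > 0) prof <- prof / m
    out <- rbind(out, data.frame(length_class = labs[k],
                                 bin = seq_len(n_bins),
                                 relative_coverage = prof,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

# Average a per-base vector into n equal-width bins; vectors shorter than n
# bins are sampled at bin midpoints.
.bin_means <- function(v, n) {
  L <- length(v)
  if (L >= n) {
    idx <- ceiling(seq_along(v) * n / L)
    as.numeric(tapply(v, idx, mean))
  } else {
    v[pmax(1L, ceiling(seq_len(n) * L / n))]
  }
}
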