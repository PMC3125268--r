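# Detection of candidate novel transcribed regions: contiguous covered bases
# outside the annotated-exon mask, filtered on length, mean depth, read count
# and independent start points.

#' Detect candidate novel transcribed regions
#'
#' Covered bases of the screening track are intersected with the complement
#' of the annotated-exon mask; maximal runs of the remaining covered bases
#' form candidates (a run split by the mask yields separate candidates, each
#' filtered on its own). A run is kept when it is at least `min_length` bp
#' long, its mean per-base depth is at least `min_avg_cov`, and it is
#' supported by at least `min_reads` overlapping reads with at least
#' `min_sp` independent start points.
#'
#' @param track A `coverage_track` built from screening-protocol reads.
#' @param mask `GRanges` exon mask from [exon_mask()].
#' @param min_length Minimum candidate length in bp (default 50).
#' @param min_avg_cov Minimum mean per-base coverage (default 3).
#' @param min_reads Minimum overlapping reads (default 5).
#' @param min_sp Minimum independent start points (default 2).
#' @return `GRanges` of candidates with metadata columns `ntar_id`,
#'   `mean_depth`, `n_reads`, `n_start_points`.
#' @export
detect_ntars <- function(track, mask, min_length = 50L, min_avg_cov = 3,
                         min_reads = 5L, min_sp = 2L) {
  depth <- .total_depth(track)
  covered <- as(IRanges::slice(depth, lower = 1L, rangesOnly = TRUE),
                "GRanges")
  strand(covered) <- "*"
  runs <- GenomicRanges::setdiff(covered, mask, ignore.strand = TRUE)
  runs <- runs[width(runs) >= min_length]
  if (length(runs) == 0L) {
    mcols(runs) <- S4Vectors::DataFrame(ntar_id = character(0),
                                        mean_depth = numeric(0),
                                        n_reads = integer(0),
                                        n_start_points = integer(0))
    return(runs)
  }
  mcols(runs)$mean_depth <- .depth_sums(depth, runs) / width(runs)
  mcols(runs)$n_reads <- countOverlaps(runs, track$reads, ignore.strand = TRUE)
  mcols(runs)$n_start_points <- .sp_per_region(runs, track$reads, track$starts)
  keep <- mcols(runs)$mean_depth >= min_avg_cov &
    mcols(runs)$n_reads >= min_reads &
    mcols(runs)$n_start_points >= min_sp
  runs <- runs[keep]
  mcols(runs) <- cbind(S4Vectors::DataFrame(
    ntar_id = if (length(runs)) paste0("ntar_", seq_along(runs))
              else character(0)), mcols(runs))
  runs
}
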