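# Coverage tracks: per-base read depth plus the independent start-point set.
#
# A coverage_track is a plain list:
#   depth       - RleList (unstranded) or list(`+` = RleList, `-` = RleList)
#   reads       - the GRanges of alignments the track was built from
#   starts      - integer 5'-most coordinate per read (strand-aware when the
#                 track is stranded, leftmost otherwise)
#   stranded    - logical
#   seqlengths  - named integer vector
#   total_reads - number of alignments

#' Load uniquely-mapped alignments from BED6 or BAM
#'
#' BED6 input uses the score column as a uniqueness flag: `score >= 1` marks a
#' uniquely mapped read, `score == 0` a multi-mapper (the dialect written by
#' [write_bed6()] and the read simulator). BAM input drops unmapped and
#' secondary records and treats `NH > 1` as multi-mapping; spliced alignments
#' (`N` CIGAR operations) are split into their aligned blocks, all sharing one
#' start point, and soft-clipped bases are excluded.
#'
#' @param path Input file.
#' @param format `"bed6"` or `"bam"`.
#' @param protocol Tag recorded on every read (`"screening"`, `"validation"`,
#'   `"polyA_tag"`, ...).
#' @param unique_only Drop reads flagged as multi-mapping.
#' @return A `GRanges` with metadata columns `name`, `unique`, `protocol` and
#'   `primary` (FALSE for non-first blocks of a spliced alignment).
#' @export
read_alignments <- function(path, format = c("bed6", "bam"),
                            protocol = "screening", unique_only = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "bed6") {
    .check_bed_lines(path, min_fields = 6L)
    df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                            col.names = c("chrom", "start", "end", "name",
                                          "score", "strand"),
                            colClasses = c("character", "integer", "integer",
                                           "character", "numeric", "character"))
    if (nrow(df) == 0L) {
      warning("no alignments in ", path)
      return(GRanges())
    }
    st <- ifelse(df$strand == ".", "*", df$strand)
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end), strand = st)
    mcols(gr)$name <- df$name
    mcols(gr)$unique <- df$score >= 1
    mcols(gr)$primary <- TRUE
  } else {
    ga <- GenomicAlignments::readGAlignments(
      path, param = Rsamtools::ScanBamParam(
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                      isSecondaryAlignment = FALSE),
        tag = "NH", what = "qname"))
    if (length(ga) == 0L) {
      warning("no mapped alignments in ", path)
      return(GRanges())
    }
    blocks <- GenomicAlignments::grglist(ga, order.as.in.query = FALSE)
    nb <- lengths(blocks)
    gr <- unlist(blocks, use.names = FALSE)
    mcols(gr)$name <- rep(mcols(ga)$qname, nb)
    nh <- mcols(ga)$NH
    if (is.null(nh)) nh <- rep(1L, length(ga))
    nh[is.na(nh)] <- 1L
    mcols(gr)$unique <- rep(nh <= 1L, nb)
    # one start point per spliced read: flag its 5'-most block
    first_in_read <- unlist(lapply(nb, function(k) seq_len(k) == 1L))
    neg <- as.character(strand(gr)) == "-"
    last_in_read <- unlist(lapply(nb, function(k) seq_len(k) == k))
    mcols(gr)$primary <- ifelse(neg, last_in_read, first_in_read)
  }
  mcols(gr)$protocol <- protocol
  n0 <- sum(mcols(gr)$primary)
  if (unique_only) gr <- gr[mcols(gr)$unique]
  n1 <- sum(mcols(gr)$primary)
  message(sprintf("loaded %d reads from %s (%d kept, %d dropped as multi-mapping)",
                  n0, basename(path), n1, n0 - n1))
  gr
}

# 5'-most coordinate per alignment; leftmost when the read is unstranded or
# strand information is to be ignored.
.start_points <- function(reads, strand_aware = TRUE) {
  if (!strand_aware) return(start(reads))
  ifelse(as.character(strand(reads)) == "-", end(reads), start(reads))
}

#' Build a per-base coverage track
#'
#' Depth at a base is the number of alignments covering it. For stranded
#' tracks separate depth vectors are kept per strand, and a read's start
#' point is its 5'-most coordinate; unstranded tracks use the leftmost
#' coordinate.
#'
#' @param reads A `GRanges` of alignments (see [read_alignments()]).
#' @param seqlengths Named integer vector of chromosome lengths.
#' @param stranded Keep per-strand depth arrays.
#' @return A `coverage_track` object.
#' @export
coverage_track <- function(reads, seqlengths, stranded = FALSE) {
  if (length(reads) > 0L) {
    sl <- seqlengths[as.character(seqnames(reads))]
    bad <- which(is.na(sl) | end(reads) > sl | start(reads) < 1L)
    if (length(bad) > 0L)
      stop("read out of chromosome bounds: ",
           mcols(reads)$name[bad[1L]], " (", as.character(reads[bad[1L]]), ")")
  }
  seqlevels(reads) <- names(seqlengths)
  seqlengths(reads) <- seqlengths
  depth <- if (stranded) {
    list("+" = coverage(reads[strand(reads) == "+"]),
         "-" = coverage(reads[strand(reads) == "-"]))
  } else {
    coverage(reads)
  }
  # start points are 5'-most per read ('*' reads fall back to leftmost),
  # independent of whether the depth arrays are kept per strand
  track <- list(depth = depth, reads = reads,
                starts = .start_points(reads, strand_aware = TRUE),
                stranded = stranded, seqlengths = seqlengths,
                total_reads = if (length(reads)) sum(mcols(reads)$primary)
                              else 0L)
  class(track) <- "coverage_track"
  track
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", x$total_reads, "reads on",
      length(x$seqlengths), "chromosome(s);",
      if (x$stranded) "stranded" else "unstranded", "\n")
  invisible(x)
}

# Combined (strand-summed) depth of a track.
.total_depth <- function(track) {
  if (track$stranded) track$depth[["+"]] + track$depth[["-"]] else track$depth
}

# Sum of depth over each interval of a GRanges, from an RleList.
.depth_sums <- function(depth, gr) {
  out <- numeric(length(gr))
  for (chr in unique(as.character(seqnames(gr)))) {
    idx <- which(as.character(seqnames(gr)) == chr)
    v <- IRanges::Views(depth[[chr]], start(gr)[idx], end(gr)[idx])
    out[idx] <- IRanges::viewSums(v)
  }
  out
}

# Distinct 5'-start count per query interval, over reads overlapping each
# query with at least one base.
.sp_per_region <- function(regions, reads, starts) {
  ov <- findOverlaps(regions, reads, ignore.strand = TRUE)
  n <- integer(length(regions))
  if (length(ov) > 0L) {
    key <- paste(queryHits(ov),
                 as.character(seqnames(reads))[subjectHits(ov)],
                 starts[subjectHits(ov)])
    q <- queryHits(ov)[!duplicated(key)]
    tab <- table(q)
    n[as.integer(names(tab))] <- as.integer(tab)
  }
  n
}

#' Maximal contiguous covered segments of a track
#'
#' @param track A `coverage_track`.
#' @param min_depth Minimum depth for a base to count as covered.
#' @return A `GRanges` of maximal runs with depth `>= min_depth`, with
#'   metadata columns `mean_depth`, `n_reads` (alignments overlapping the
#'   run) and `n_start_points` (distinct 5' starts among them).
#' @export
covered_segments <- function(track, min_depth = 1L) {
  depth <- .total_depth(track)
  segs <- as(IRanges::slice(depth, lower = min_depth, rangesOnly = TRUE),
             "GRanges")
  if (length(segs) == 0L) return(segs)
  strand(segs) <- "*"
  mcols(segs)$mean_depth <- .depth_sums(depth, segs) / width(segs)
  mcols(segs)$n_reads <- countOverlaps(segs, track$reads, ignore.strand = TRUE)
  mcols(segs)$n_start_points <- .sp_per_region(segs, track$reads, track$starts)
  segs
}

#' Count independent start points in a region
#'
#' The number of distinct 5'-most alignment coordinates among reads
#' overlapping the region by at least one base. Clonal (identically starting)
#' reads collapse to one start point.
#'
#' @param reads A `GRanges` of alignments.
#' @param region A length-1 `GRanges`.
#' @param strand `"+"`, `"-"` or `"any"`; restricts reads to one strand.
#' @return Integer count.
#' @export
start_point_count <- function(reads, region, strand = "any") {
  stopifnot(length(region) == 1L)
  if (strand %in% c("+", "-"))
    reads <- reads[as.character(GenomicRanges::strand(reads)) == strand]
  pr <- mcols(reads)$primary
  if (!is.null(pr)) reads <- reads[pr]
  reads <- reads[overlapsAny(reads, region, ignore.strand = TRUE)]
  if (length(reads) == 0L) return(0L)
  # 5'-most coordinate per read; unstranded ('*') reads fall back to leftmost
  sp <- .start_points(reads, strand_aware = TRUE)
  length(unique(paste(as.character(seqnames(reads)), sp)))
}

#' Write a coverage track as bedGraph
#'
#' Four-column bedGraph, 0-based half-open, no track lines. Stranded tracks
#' produce two files (`<prefix>.plus.bedGraph`, `<prefix>.minus.bedGraph`);
#' minus-strand depths are written as given, not negated.
#'
#' @param track A `coverage_track`.
#' @param prefix Output path prefix.
#' @return Invisibly, the written file path(s).
#' @export
write_bedgraph <- function(track, prefix) {
  emit <- function(depth, path) {
    gr <- as(depth, "GRanges")
    gr <- gr[gr$score > 0]
    df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                     gr$score)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    path
  }
  if (track$stranded) {
    invisible(c(emit(track$depth[["+"]], paste0(prefix, ".plus.bedGraph")),
                emit(track$depth[["-"]], paste0(prefix, ".minus.bedGraph"))))
  } else {
    invisible(emit(track$depth, paste0(prefix, ".bedGraph")))
  }
}

#' Write alignments as BED6
#'
#' Score column encodes uniqueness: 1 for uniquely mapped reads, 0 for
#' multi-mappers. Unstranded reads are written with strand `"."`.
#'
#' @param reads A `GRanges` with metadata columns `name` and `unique`.
#' @param path Output file.
#' @export
write_bed6 <- function(reads, path) {
  st <- as.character(strand(reads))
  st[st == "*"] <- "."
  uniq <- mcols(reads)$unique
  if (is.null(uniq)) uniq <- rep(TRUE, length(reads))
  nm <- mcols(reads)$name
  if (is.null(nm)) nm <- paste0("r", seq_along(reads))
  df <- data.frame(as.character(seqnames(reads)), start(reads) - 1L,
                   end(reads), nm, as.integer(uniq), st)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
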