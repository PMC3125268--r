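# Independent brute-force oracles, written against plain base-R vectors and
# data.frames so they share no code path with the package implementation.
# All coordinates here are 1-based inclusive.

# Per-base depth vector over one chromosome.
o_coverage <- function(starts, ends, chrlen) {
  depth <- integer(chrlen)
  for (i in seq_along(starts)) {
    idx <- starts[i]:ends[i]
    depth[idx] <- depth[idx] + 1L
  }
  depth
}

# Maximal runs with depth >= min_depth: data.frame(start, end).
o_segments <- function(depth, min_depth = 1L) {
  on <- depth >= min_depth
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# Per-base union of a set of intervals as a boolean vector.
o_union_bases <- function(starts, ends, chrlen) {
  on <- logical(chrlen)
  for (i in seq_along(starts)) on[starts[i]:ends[i]] <- TRUE
  on
}

# Distinct 5' start coordinates of reads overlapping [qs, qe].
o_start_points <- function(starts, ends, strands, qs, qe) {
  hit <- ends >= qs & starts <= qe
  sp <- ifelse(strands == "-", ends, starts)[hit]
  length(unique(sp))
}

# Exhaustive nearest-gene scan over a plain gene table.
# genes: data.frame(symbol, chrom, strand, span_start, span_end)
o_nearest <- function(q_chrom, q_start, q_end, genes) {
  g <- genes[genes$chrom == q_chrom, , drop = FALSE]
  if (nrow(g) == 0L)
    return(list(symbol = NA_character_, distance = NA_real_,
                side = NA_character_))
  d <- numeric(nrow(g))
  for (i in seq_len(nrow(g))) {
    if (q_end < g$span_start[i]) d[i] <- g$span_start[i] - q_end - 1L
    else if (q_start > g$span_end[i]) d[i] <- q_start - g$span_end[i] - 1L
    else d[i] <- 0
  }
  ord <- order(d, g$span_start, g$symbol)
  i <- ord[1L]
  side <- if (q_end >= g$span_start[i] && q_start <= g$span_end[i]) {
    "overlapping"
  } else if (q_end < g$span_start[i]) {
    if (g$strand[i] == "+") "upstream" else "downstream"
  } else {
    if (g$strand[i] == "+") "downstream" else "upstream"
  }
  list(symbol = g$symbol[i], distance = d[i], side = side)
}

# Rule-table classifier for one candidate against a plain gene list.
# genes: list of list(symbol, chrom, strand, exons = 2-col matrix of
# start/end sorted by start). Returns list(label, symbol, distance).
o_classify <- function(chrom, cstart, cend, genes, window = 10000L) {
  rank <- c(ISE = 1, ELD = 2, ELU = 2, UGI = 3, DGI = 3, IGE = 4,
            UGN = 5, DGN = 5)
  best <- NULL
  for (g in genes) {
    if (g$chrom != chrom) next
    span <- c(min(g$exons[, 1L]), max(g$exons[, 2L]))
    label <- NULL; d <- NA_real_
    if (cstart >= span[1L] && cend <= span[2L]) {
      n <- nrow(g$exons)
      for (j in seq_len(max(0L, n - 1L))) {
        is_ <- g$exons[j, 2L] + 1L
        ie <- g$exons[j + 1L, 1L] - 1L
        if (cstart >= is_ && cend <= ie) {
          fl <- cstart == is_; fr <- cend == ie
          label <- if (fl && fr) "ISE"
                   else if (fl) { if (g$strand == "+") "ELD" else "ELU" }
                   else if (fr) { if (g$strand == "+") "ELU" else "ELD" }
                   else "IGE"
          d <- 0
          break
        }
      }
      if (is.null(label)) next      # touches exon space: invalid candidate
    } else if (cend < span[1L] || cstart > span[2L]) {
      left <- cend < span[1L]
      d <- if (left) span[1L] - cend - 1L else cstart - span[2L] - 1L
      at5 <- left == (g$strand == "+")
      if (d == 0) label <- if (at5) "UGI" else "DGI"
      else if (d <= window) label <- if (at5) "UGN" else "DGN"
      else next
    } else next                     # straddles a span edge: invalid
    cand <- list(rank = rank[[label]], d = d, gstart = span[1L],
                 symbol = g$symbol, label = label)
    if (is.null(best) ||
        cand$rank < best$rank ||
        (cand$rank == best$rank && (cand$d < best$d ||
          (cand$d == best$d && (cand$gstart < best$gstart ||
            (cand$gstart == best$gstart && cand$symbol < best$symbol))))))
      best <- cand
  }
  if (is.null(best)) list(label = "NGA", symbol = NA_character_,
                          distance = NA_real_)
  else list(label = best$label, symbol = best$symbol, distance = best$d)
}

# Convert a condensed GRangesList into the plain gene list o_classify eats.
o_gene_list <- function(condensed) {
  lapply(seq_along(condensed), function(i) {
    ex <- condensed[[i]]
    ord <- order(GenomicRanges::start(ex))
    list(symbol = names(condensed)[i],
         chrom = as.character(GenomicRanges::seqnames(ex))[1L],
         strand = as.character(GenomicRanges::strand(ex))[1L],
         exons = cbind(GenomicRanges::start(ex)[ord],
                       GenomicRanges::end(ex)[ord]))
  })
}
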