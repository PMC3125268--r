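# Small in-code fixture builders shared across test files.

library(GenomicRanges)

# GRangesList of transcripts from a list of list(id, sym, chrom, strand,
# exons = 2-col matrix of 1-based start/end).
make_transcripts <- function(spec) {
  grl <- GRangesList(lapply(spec, function(s)
    GRanges(s$chrom, IRanges::IRanges(s$exons[, 1L], s$exons[, 2L]),
            strand = s$strand)))
  names(grl) <- vapply(spec, `[[`, character(1L), "id")
  S4Vectors::mcols(grl)$tx_id <- names(grl)
  S4Vectors::mcols(grl)$gene_symbol <- vapply(spec, `[[`, character(1L), "sym")
  S4Vectors::mcols(grl)$source <- "test"
  grl
}

# Simple aligned-read GRanges.
make_reads <- function(chrom, start, width, strand = "*",
                       unique = TRUE, name = NULL) {
  gr <- GRanges(rep_len(chrom, length(start)),
                IRanges::IRanges(start, width = rep_len(width, length(start))),
                strand = rep_len(strand, length(start)))
  if (is.null(name)) name <- sprintf("r%d", seq_along(gr))
  S4Vectors::mcols(gr)$name <- name
  S4Vectors::mcols(gr)$unique <- rep_len(unique, length(gr))
  S4Vectors::mcols(gr)$primary <- rep_len(TRUE, length(gr))
  S4Vectors::mcols(gr)$protocol <- rep_len("test", length(gr))
  gr
}

# Random small genome for oracle-equivalence checks: a handful of genes with
# random exon structure on one chromosome, plus random reads everywhere.
rand_genome <- function(seed, chrlen = 100000L, n_genes = 5L,
                        n_reads = 1000L, read_len = 30L) {
  set.seed(seed)
  gene_spec <- list()
  cur <- sample(500:2000, 1L)
  for (i in seq_len(n_genes)) {
    n_ex <- sample(2:5, 1L)
    ew <- sample(80:400, n_ex, replace = TRUE)
    iw <- sample(150:900, n_ex - 1L, replace = TRUE)
    starts <- cumsum(c(cur, head(ew, -1L) + iw))
    gene_spec[[i]] <- list(id = sprintf("t%d", i), sym = sprintf("g%d", i),
                           chrom = "chrZ", strand = sample(c("+", "-"), 1L),
                           exons = cbind(starts, starts + ew - 1L))
    cur <- max(starts + ew - 1L) + sample(1000:4000, 1L)
  }
  if (cur > chrlen - 1000L) stop("random genome overflow")
  tx <- make_transcripts(gene_spec)
  reads <- make_reads("chrZ",
                      sample(seq_len(chrlen - read_len), n_reads,
                             replace = TRUE),
                      read_len,
                      strand = sample(c("+", "-"), n_reads, replace = TRUE))
  list(transcripts = tx, condensed = condense_genes(tx),
       reads = reads, seqlengths = c(chrZ = chrlen), read_len = read_len)
}

# Mirror a GRanges on a single chromosome of length L: coordinates are
# reflected; strands are flipped too when `flip_strand` (a true reverse
# complement of the layout) or kept as-is (pure coordinate reflection, which
# swaps every upstream/downstream relation).
mirror_gr <- function(gr, L, flip_strand = TRUE) {
  st <- as.character(strand(gr))
  if (flip_strand) st <- c("+" = "-", "-" = "+", "*" = "*")[st]
  out <- GRanges(seqnames(gr),
                 IRanges::IRanges(L - end(gr) + 1L, L - start(gr) + 1L),
                 strand = st)
  S4Vectors::mcols(out) <- S4Vectors::mcols(gr)
  out
}

mirror_condensed <- function(condensed, L, flip_strand = TRUE) {
  ex <- unlist(condensed, use.names = FALSE)
  m <- mirror_gr(ex, L, flip_strand)
  grl <- GenomicRanges::reduce(
    S4Vectors::split(m, S4Vectors::Rle(names(condensed),
                                       lengths(condensed))))
  grl[names(condensed)]
}

# Expected U<->D label swap under genome mirroring.
mirror_label <- function(lab) {
  map <- c(NGA = "NGA", IGE = "IGE", ISE = "ISE",
           UGN = "DGN", DGN = "UGN", UGI = "DGI", DGI = "UGI",
           ELU = "ELD", ELD = "ELU")
  unname(map[lab])
}
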