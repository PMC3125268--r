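#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width strand
#'   strand<- reduce findOverlaps countOverlaps distance coverage setdiff
#'   resize shift
#' @importFrom BiocGenerics sort lengths unlist table match paste
#' @importFrom IRanges IRanges ranges subsetByOverlaps overlapsAny
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits Rle runValue
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<-
NULL

# Transcript sets are GRangesList objects: one element per transcript, each a
# sorted, disjoint set of exon ranges on a single chromosome and strand.
# List-level metadata columns: tx_id, gene_symbol, source.

#' Load transcript models from a GTF or BED12 file
#'
#' Reads gene annotation into a set of transcript models. GTF input must carry
#' `gene_id` and `transcript_id` attributes on its `exon` features (1-based
#' inclusive coordinates, converted on read). BED12 input uses the block
#' columns for exon structure; the name field is either a transcript id or
#' `"<gene_symbol>|<transcript_id>"` (the dialect written by
#' [write_bed12()]). Overlapping exons within one transcript are merged.
#'
#' @param path Path to the annotation file.
#' @param format Either `"gtf"` or `"bed12"`.
#' @param source Free-text tag recorded on every transcript (e.g.
#'   `"refseq-like"`, `"ensembl-like"`).
#' @return A [GenomicRanges::GRangesList] of exons, one element per
#'   transcript, with metadata columns `tx_id`, `gene_symbol`, `source`.
#' @export
read_transcripts <- function(path, format = c("gtf", "bed12"),
                             source = "annotation") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "exon"]
    if (length(gr) == 0L) stop("no exon records in GTF file: ", path)
    bad <- which(!as.character(strand(gr)) %in% c("+", "-"))
    if (length(bad) > 0L)
      stop("unknown strand on GTF exon record ", bad[1L],
           " (transcript ", gr$transcript_id[bad[1L]], ")")
    exons <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                     strand = strand(gr))
    grl <- GenomicRanges::reduce(S4Vectors::split(exons, gr$transcript_id))
    idx <- match(names(grl), gr$transcript_id)
    sym <- gr$gene_id[idx]
    if (!is.null(gr$gene_name)) {
      has <- !is.na(gr$gene_name[idx])
      sym[has] <- gr$gene_name[idx][has]
    }
  } else {
    .check_bed_lines(path, min_fields = 12L)
    gr <- rtracklayer::import(path, format = "bed")
    bad <- which(!as.character(strand(gr)) %in% c("+", "-"))
    if (length(bad) > 0L)
      stop("unknown strand in BED12 record ", bad[1L])
    grl <- GenomicRanges::reduce(rtracklayer::blocks(gr))
    nm <- if (is.null(gr$name)) paste0("tx", seq_along(gr)) else gr$name
    parts <- strsplit(nm, "|", fixed = TRUE)
    sym <- vapply(parts, `[`, character(1L), 1L)
    txid <- make.unique(vapply(parts, function(p) p[length(p)], character(1L)))
    # blocks() does not always propagate strand; restore it from the record
    ex <- unlist(grl, use.names = FALSE)
    strand(ex) <- Rle(as.character(strand(gr)), lengths(grl))
    grl <- S4Vectors::split(ex, Rle(factor(txid, levels = txid), lengths(grl)))
  }
  mcols(grl)$tx_id <- names(grl)
  mcols(grl)$gene_symbol <- sym
  mcols(grl)$source <- source
  grl
}

# Pre-scan a BED file so malformed records fail with a line number.
.check_bed_lines <- function(path, min_fields = 6L) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < min_fields)
      stop("malformed BED record at line ", i, ": expected >= ", min_fields,
           " fields, found ", length(f))
    if (is.na(suppressWarnings(as.integer(f[2L]))) ||
        is.na(suppressWarnings(as.integer(f[3L]))))
      stop("malformed BED record at line ", i, ": non-numeric coordinates")
    if (min_fields >= 6L && !f[6L] %in% c("+", "-", "."))
      stop("unknown strand character '", f[6L], "' at line ", i)
  }
  invisible(TRUE)
}

#' Condense isoforms into single union-exon gene models
#'
#' All transcripts sharing a gene symbol are fused into one model whose exons
#' are the union of all isoform exons, overlaps merged. A symbol whose
#' isoforms sit on more than one chromosome or strand is an error by default;
#' with `multi_locus = "suffix"` each locus is kept under a disambiguated
#' symbol (`SYM@chrom:strand`).
#'
#' @param transcripts A `GRangesList` from [read_transcripts()].
#' @param multi_locus `"error"` or `"suffix"`.
#' @return A `GRangesList` of merged, disjoint exons, one element per gene
#'   symbol, with metadata columns `gene_symbol` and `n_isoforms`.
#' @export
condense_genes <- function(transcripts, multi_locus = c("error", "suffix")) {
  multi_locus <- match.arg(multi_locus)
  sym <- mcols(transcripts)$gene_symbol
  if (is.null(sym)) stop("transcripts carry no gene_symbol metadata")
  ex <- unlist(transcripts, use.names = FALSE)
  gene_of_exon <- Rle(sym, lengths = lengths(transcripts))
  locus <- paste(as.character(gene_of_exon),
                 as.character(seqnames(ex)),
                 as.character(strand(ex)), sep = "\r")
  per_sym <- unique(data.frame(sym = as.character(gene_of_exon),
                               locus = locus, stringsAsFactors = FALSE))
  multi <- names(which(table(per_sym$sym) > 1L))
  if (length(multi) > 0L) {
    if (multi_locus == "error")
      stop("gene symbol(s) on multiple chromosomes/strands: ",
           paste(sort(multi), collapse = ", "))
    use <- as.character(gene_of_exon)
    flag <- use %in% multi
    use[flag] <- paste0(use[flag], "@", as.character(seqnames(ex))[flag],
                        ":", as.character(strand(ex))[flag])
    gene_of_exon <- Rle(use)
  }
  condensed <- GenomicRanges::reduce(S4Vectors::split(ex, gene_of_exon))
  n_iso <- table(if (length(multi) > 0L && multi_locus == "suffix")
    mcols(transcripts)$gene_symbol else sym)
  mcols(condensed)$gene_symbol <- names(condensed)
  base_sym <- sub("@.*$", "", names(condensed))
  mcols(condensed)$n_isoforms <- as.integer(n_iso[base_sym])
  condensed
}

#' Gene spans of condensed models
#'
#' @param condensed A `GRangesList` from [condense_genes()].
#' @return A `GRanges`, one range per gene covering min exon start to max exon
#'   end, named by symbol and carrying the gene strand.
#' @export
gene_spans <- function(condensed) {
  sp <- unlist(range(condensed), use.names = TRUE)
  mcols(sp)$gene_symbol <- names(sp)
  sp
}

#' Intron set of condensed models
#'
#' @param condensed A `GRangesList` from [condense_genes()].
#' @return A `GRanges` of introns (gaps between consecutive condensed exons)
#'   with metadata column `gene_symbol`.
#' @export
gene_introns <- function(condensed) {
  sp <- gene_spans(condensed)
  out <- vector("list", length(condensed))
  for (i in seq_along(condensed)) {
    ir <- IRanges::gaps(ranges(condensed[[i]]),
                        start = start(sp)[i], end = end(sp)[i])
    out[[i]] <- GRanges(seqnames(sp)[i], ir, strand = strand(sp)[i])
  }
  introns <- do.call(c, out)
  mcols(introns)$gene_symbol <- rep(names(condensed),
                                    vapply(out, length, integer(1L)))
  introns
}

#' Build the annotated-exon mask
#'
#' Unions the exon space of one or more annotation sources into a disjoint,
#' strand-ignored interval set. Any covered base inside the mask is considered
#' annotated and excluded from novel-region detection.
#'
#' @param ... One or more `GRangesList` (transcript or condensed models) or
#'   `GRanges` of exons.
#' @param seqlengths Optional named vector of chromosome lengths; exons beyond
#'   a chromosome bound raise an error.
#' @return A reduced, unstranded `GRanges`.
#' @export
exon_mask <- function(..., seqlengths = NULL) {
  parts <- list(...)
  if (length(parts) == 0L) stop("at least one annotation source is required")
  grs <- lapply(parts, function(p) {
    g <- if (is(p, "GRangesList")) unlist(p, use.names = FALSE) else p
    strand(g) <- "*"
    g
  })
  all_ex <- do.call(c, grs)
  if (!is.null(seqlengths)) {
    sl <- seqlengths[as.character(seqnames(all_ex))]
    over <- which(!is.na(sl) & end(all_ex) > sl)
    miss <- which(is.na(sl))
    if (length(c(over, miss)) > 0L)
      stop("exon beyond chromosome bound or on unknown chromosome (first: ",
           as.character(all_ex)[c(over, miss)][1L], ")")
  }
  GenomicRanges::reduce(all_ex, ignore.strand = TRUE)
}

# Deterministic choice among candidate genes: smallest distance, then smaller
# span start, then lexicographically smallest symbol.
.pick_gene <- function(dist, span_start, symbol) {
  order(dist, span_start, symbol)[1L]
}

#' Nearest condensed gene for query intervals
#'
#' Distance is the gap in bases between the query and the closest condensed
#' gene span (0 for overlap or direct adjacency). `side` is taken relative to
#' the gene's strand: a query toward the gene's 5' end is `upstream`.
#' Equidistant genes are resolved by smaller span start, then symbol.
#'
#' @param query A `GRanges` of query intervals.
#' @param condensed A `GRangesList` from [condense_genes()].
#' @return A data.frame with one row per query: `gene_symbol` (NA if the
#'   query's chromosome holds no gene), `distance` (bp gap), and `side`
#'   (`"overlapping"`, `"upstream"` or `"downstream"`).
#' @export
nearest_gene <- function(query, condensed) {
  spans <- gene_spans(condensed)
  n <- length(query)
  out <- data.frame(gene_symbol = rep(NA_character_, n),
                    distance = rep(NA_real_, n),
                    side = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    q <- query[i]
    sp <- spans[as.character(seqnames(spans)) == as.character(seqnames(q))]
    if (length(sp) == 0L) next
    d <- GenomicRanges::distance(rep(q, length(sp)), sp, ignore.strand = TRUE)
    j <- .pick_gene(d, start(sp), names(sp))
    g <- sp[j]
    side <-
      if (d[j] == 0L && start(q) <= end(g) && end(q) >= start(g)) {
        "overlapping"
      } else if (end(q) < start(g)) {
        if (as.character(strand(g)) == "+") "upstream" else "downstream"
      } else {
        if (as.character(strand(g)) == "+") "downstream" else "upstream"
      }
    out$gene_symbol[i] <- names(g)
    out$distance[i] <- d[j]
    out$side[i] <- side
  }
  out
}

#' Write transcript or condensed models as BED12
#'
#' Names are written as `"<gene_symbol>|<id>"` so that gene symbols survive a
#' round trip through [read_transcripts()].
#'
#' @param models A `GRangesList` of exon sets.
#' @param path Output file.
#' @export
write_bed12 <- function(models, path) {
  bed <- rtracklayer::asBED(models)
  sym <- mcols(models)$gene_symbol
  if (is.null(sym)) sym <- names(models)
  bed$name <- paste0(sym, "|", names(models))
  rtracklayer::export(bed, path, format = "bed")
  invisible(path)
}

#' Write an interval set as BED3
#'
#' @param gr A `GRanges` (e.g. an exon mask).
#' @param path Output file.
#' @export
write_bed3 <- function(gr, path) {
  df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
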