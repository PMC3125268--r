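test_that("BED12 block arithmetic and GTF coordinate conversion are exact", {
  # BED12: chromStart 1000, two blocks [0,100) and [200,300) relative
  bed <- file.path(tempfile(fileext = ".bed"))
  writeLines(paste(c("chr1", 1000L, 1300L, "G|G.1", 0L, "+", 1000L, 1300L,
                     "0", 2L, "100,100,", "0,200,"), collapse = "\t"), bed)
  tx <- read_transcripts(bed, "bed12", source = "s")
  expect_equal(length(tx), 1L)
  expect_equal(start(tx[[1]]), c(1001L, 1201L))  # 0-based 1000, 1200
  expect_equal(end(tx[[1]]), c(1100L, 1300L))    # half-open 1100, 1300
  expect_equal(S4Vectors::mcols(tx)$gene_symbol, "G")

  # GTF exon start=101 end=200 (1-based inclusive) covers bases 101..200,
  # i.e. the 0-based half-open interval [100, 200)
  gtf <- tempfile(fileext = ".gtf")
  writeLines(paste(c("chr1", "src", "exon", 101L, 200L, ".", "+", ".",
                     'gene_id "G"; transcript_id "G.1";'),
                   collapse = "\t"), gtf)
  tx2 <- read_transcripts(gtf, "gtf", source = "s")
  expect_equal(start(tx2[[1]]), 101L)
  expect_equal(end(tx2[[1]]), 200L)
})

test_that("two isoforms of one symbol survive a BED12 round trip", {
  tx <- make_transcripts(list(
    list(id = "G.1", sym = "G", chrom = "chr1", strand = "+",
         exons = cbind(c(101L, 501L), c(200L, 700L))),
    list(id = "G.2", sym = "G", chrom = "chr1", strand = "+",
         exons = cbind(c(101L, 901L), c(300L, 1000L)))))
  path <- tempfile(fileext = ".bed")
  write_bed12(tx, path)
  back <- read_transcripts(path, "bed12", source = "s")
  expect_equal(length(back), 2L)
  expect_equal(sort(unique(S4Vectors::mcols(back)$gene_symbol)), "G")
  for (i in 1:2) {
    expect_equal(start(back[[i]]), start(tx[[i]]))
    expect_equal(end(back[[i]]), end(tx[[i]]))
  }
})

test_that("malformed annotation records fail with a line number", {
  bed12 <- function(...) paste(c(...), collapse = "\t")
  bad <- tempfile(fileext = ".bed")
  writeLines(c(bed12("chr1", 0L, 100L, "a", 0L, "+", 0L, 100L, "0", 1L,
                     "100,", "0,"),
               bed12("chr1", "x", 100L, "b", 0L, "+", 0L, 100L, "0", 1L,
                     "100,", "0,")),
             bad)
  expect_error(read_transcripts(bad, "bed12"), "line 2")
  bad2 <- tempfile(fileext = ".bed")
  writeLines(paste(c("chr1", 0L, 100L, "a", 0L, "%", 0L, 100L, "0", 1L,
                     "100,", "0,"), collapse = "\t"), bad2)
  expect_error(read_transcripts(bad2, "bed12"), "strand.*line 1")
})

test_that("condensation merges isoform exons into a disjoint union", {
  # 1-based version of exons {[0,100),[200,300)} + {[50,150),[200,400)}
  tx <- make_transcripts(list(
    list(id = "A.1", sym = "A", chrom = "chr1", strand = "+",
         exons = cbind(c(1L, 201L), c(100L, 300L))),
    list(id = "A.2", sym = "A", chrom = "chr1", strand = "+",
         exons = cbind(c(51L, 201L), c(150L, 400L)))))
  cg <- condense_genes(tx)
  expect_equal(length(cg), 1L)
  expect_equal(start(cg[["A"]]), c(1L, 201L))
  expect_equal(end(cg[["A"]]), c(150L, 400L))

  # single isoform: condensed model identical
  solo <- make_transcripts(list(
    list(id = "B.1", sym = "B", chrom = "chr2", strand = "-",
         exons = cbind(c(10L, 500L), c(90L, 600L)))))
  cb <- condense_genes(solo)
  expect_identical(start(cb[["B"]]), start(solo[[1]]))
  expect_identical(end(cb[["B"]]), end(solo[[1]]))
})

test_that("condensation conserves exonic base coverage (per-base oracle)", {
  set.seed(42)
  for (rep in 1:3) {
    sim <- simulate_genome(sim_config(n_genes = 12L), seed = rep * 13L)
    cg <- condense_genes(sim$transcripts)
    expect_setequal(names(cg), S4Vectors::mcols(sim$transcripts)$gene_symbol)
    for (sym in names(cg)) {
      iso <- sim$transcripts[
        S4Vectors::mcols(sim$transcripts)$gene_symbol == sym]
      ex <- unlist(iso, use.names = FALSE)
      chrlen <- sim$seqlengths[[as.character(seqnames(ex))[1]]]
      truth <- o_union_bases(start(ex), end(ex), chrlen)
      got <- o_union_bases(start(cg[[sym]]), end(cg[[sym]]), chrlen)
      expect_identical(got, truth)
      # disjoint and sorted
      expect_true(all(diff(start(cg[[sym]])) > 0))
      expect_true(all(start(cg[[sym]])[-1] > head(end(cg[[sym]]), -1) + 0))
    }
  }
})

test_that("a symbol on two chromosomes errors unless disambiguated", {
  tx <- make_transcripts(list(
    list(id = "X.1", sym = "X", chrom = "chr1", strand = "+",
         exons = cbind(1L, 100L)),
    list(id = "X.2", sym = "X", chrom = "chr2", strand = "+",
         exons = cbind(1L, 100L))))
  expect_error(condense_genes(tx), "X")
  cg <- condense_genes(tx, multi_locus = "suffix")
  expect_equal(length(cg), 2L)
  expect_true(all(grepl("^X@chr[12]", names(cg))))
})

test_that("exon mask is the strand-ignored union of all sources", {
  a <- GRanges("chr1", IRanges::IRanges(11L, 20L), strand = "+")
  b <- GRanges("chr1", IRanges::IRanges(16L, 30L), strand = "-")
  m <- exon_mask(a, b)
  expect_equal(start(m), 11L)
  expect_equal(end(m), 30L)
  expect_equal(as.character(strand(m)), "*")

  # empty source set is an error; an empty GRanges gives an empty mask
  expect_error(exon_mask(), "at least one")
  expect_equal(length(exon_mask(GRanges())), 0L)

  # idempotence: masking the mask changes nothing
  sim <- simulate_genome(sim_config(n_genes = 8L), seed = 7L)
  expect_identical(IRanges::ranges(exon_mask(sim$mask)),
                   IRanges::ranges(sim$mask))

  # two-source union equals the per-base oracle
  m2 <- exon_mask(sim$transcripts, sim$transcripts2,
                  seqlengths = sim$seqlengths)
  for (chr in names(sim$seqlengths)) {
    ex <- unlist(sim$transcripts, use.names = FALSE)
    ex2 <- unlist(sim$transcripts2, use.names = FALSE)
    keep1 <- as.character(seqnames(ex)) == chr
    keep2 <- as.character(seqnames(ex2)) == chr
    truth <- o_union_bases(c(start(ex)[keep1], start(ex2)[keep2]),
                           c(end(ex)[keep1], end(ex2)[keep2]),
                           sim$seqlengths[[chr]])
    sub <- m2[as.character(seqnames(m2)) == chr]
    got <- o_union_bases(start(sub), end(sub), sim$seqlengths[[chr]])
    expect_identical(got, truth)
  }
  expect_error(exon_mask(a, seqlengths = c(chr1 = 15L)), "bound")
})

test_that("nearest_gene matches gap arithmetic and the exhaustive oracle", {
  cg <- condense_genes(make_transcripts(list(
    list(id = "g.1", sym = "g", chrom = "chr1", strand = "+",
         exons = cbind(c(6001L, 8001L), c(6500L, 9000L))))))
  # query [5000,5100) in 0-based terms -> 1-based 5001..5100; gap 900
  res <- nearest_gene(GRanges("chr1", IRanges::IRanges(5001L, 5100L)), cg)
  expect_equal(res$gene_symbol, "g")
  expect_equal(res$distance, 900)
  expect_equal(res$side, "upstream")

  inside <- nearest_gene(GRanges("chr1", IRanges::IRanges(7000L, 7050L)), cg)
  expect_equal(inside$distance, 0)
  expect_equal(inside$side, "overlapping")

  empty <- nearest_gene(GRanges("chr9", IRanges::IRanges(1L, 10L)), cg)
  expect_true(is.na(empty$gene_symbol))

  # random queries vs exhaustive min-distance scan over ~50 genes
  set.seed(99)
  sim <- simulate_genome(sim_config(n_genes = 24L), seed = 31L)
  spans <- gene_spans(sim$condensed)
  gene_tab <- data.frame(symbol = names(spans),
                         chrom = as.character(seqnames(spans)),
                         strand = as.character(strand(spans)),
                         span_start = start(spans), span_end = end(spans),
                         stringsAsFactors = FALSE)
  qs <- sample(seq_len(sim$seqlengths[[1]] - 200L), 60L)
  q <- GRanges(sample(names(sim$seqlengths), 60L, replace = TRUE),
               IRanges::IRanges(qs, width = sample(50:500, 60L,
                                                   replace = TRUE)))
  got <- nearest_gene(q, sim$condensed)
  for (i in seq_along(q)) {
    o <- o_nearest(as.character(seqnames(q))[i], start(q)[i], end(q)[i],
                   gene_tab)
    expect_equal(got$gene_symbol[i], o$symbol)
    expect_equal(got$distance[i], o$distance)
    expect_equal(got$side[i], o$side)
  }
})

test_that("nearest_gene is symmetric under coordinate mirroring", {
  set.seed(5)
  rg <- rand_genome(11L)
  L <- rg$seqlengths[["chrZ"]]
  q <- GRanges("chrZ", IRanges::IRanges(sample(seq_len(L - 300L), 40L),
                                        width = 120L))
  fwd <- nearest_gene(q, rg$condensed)
  mir <- nearest_gene(mirror_gr(q, L), mirror_condensed(rg$condensed, L))
  expect_equal(fwd$gene_symbol, mir$gene_symbol)
  expect_equal(fwd$distance, mir$distance)
  expect_equal(fwd$side, mir$side)  # strand flip preserves 5'/3' relations
})
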