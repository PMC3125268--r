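# A compact locus for validation tests: one '+' gene with a candidate in
# its intron (IGE geometry) and one NGA candidate far away.
val_fixture <- function() {
  cg <- condense_genes(make_transcripts(list(
    list(id = "v.1", sym = "v", chrom = "chr1", strand = "+",
         exons = cbind(c(5001L, 6001L), c(5400L, 6400L))))))
  cand <- GRanges("chr1", IRanges::IRanges(c(5501L, 30001L),
                                           c(5700L, 30150L)))
  cl <- classify_ntars(cand, cg)
  cl$ntar_id <- c("ige1", "nga1")
  list(cg = cg, cl = cl)
}

test_that("validation counts, confirmation and orientation follow the rules", {
  fx <- val_fixture()
  # 5 reads on the gene strand over the intronic candidate: confirmed sense
  v <- validate_ntars(fx$cl[1], make_reads("chr1", seq(5510L, 5590L, 20L),
                                           40L, strand = "+"), fx$cg)
  expect_true(v$confirmed)
  expect_equal(v$orientation, "sense")
  expect_equal(v$sense_reads, 5L)
  expect_equal(v$antisense_reads, 0L)

  # 2 reads: below the confirmation threshold
  v2 <- validate_ntars(fx$cl[1], make_reads("chr1", c(5510L, 5550L), 40L,
                                            strand = "+"), fx$cg)
  expect_false(v2$confirmed)
  expect_true(is.na(v2$orientation))

  # 4 sense + 2 antisense: confirmed but ambiguous
  v3 <- validate_ntars(fx$cl[1],
                       make_reads("chr1", seq(5510L, 5610L, 20L), 40L,
                                  strand = c(rep("+", 4L), rep("-", 2L))),
                       fx$cg)
  expect_true(v3$confirmed)
  expect_equal(v3$orientation, "ambiguous")

  # NGA: no reference strand, orientation undetermined, genomic counts kept
  v4 <- validate_ntars(fx$cl[2], make_reads("chr1", c(30010L, 30050L,
                                                      30090L), 40L,
                                            strand = c("+", "+", "-")),
                       fx$cg)
  expect_true(v4$confirmed)
  expect_equal(v4$orientation, "undetermined")
  expect_equal(v4$n_plus, 2L)
  expect_equal(v4$n_minus, 1L)
  expect_true(is.na(v4$sense_reads))

  # orientation partition: labels of confirmed candidates sum to confirmed
  both <- validate_ntars(fx$cl, make_reads("chr1", c(seq(5510L, 5590L, 20L),
                                                     30010L, 30050L, 30090L),
                                           40L, strand = "+"), fx$cg)
  expect_equal(sum(!is.na(both$orientation)), sum(both$confirmed))
})

test_that("class orientation summaries use only unambiguous calls", {
  fake <- GRanges("chr1", IRanges::IRanges(seq(1L, by = 1000L,
                                               length.out = 14L),
                                           width = 100L))
  fake$ntar_class <- c(rep("IGE", 12L), "ELU", "ELU")
  fake$confirmed <- TRUE
  fake$orientation <- c(rep("sense", 10L), "antisense", "antisense",
                        "sense", "ambiguous")
  s <- class_orientation_summary(fake)
  ige <- s[s$ntar_class == "IGE", ]
  expect_equal(ige$n_sense, 10L)
  expect_equal(ige$n_antisense, 2L)
  expect_equal(ige$ratio, 5.0)
  elu <- s[s$ntar_class == "ELU", ]
  expect_equal(elu$n_sense, 1L)          # the ambiguous one is excluded
  expect_equal(elu$ratio, Inf)
  expect_true(elu$ratio_degenerate)
})

test_that("planted sense fractions are recovered within binomial error", {
  # 9:1 sense:antisense planted in IGE over 20 seeds
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 30L
    fake <- GRanges("chr1", IRanges::IRanges(seq(1L, by = 500L,
                                                 length.out = n),
                                             width = 100L))
    fake$ntar_class <- "IGE"
    fake$confirmed <- TRUE
    fake$orientation <- ifelse(runif(n) < 0.9, "sense", "antisense")
    s <- class_orientation_summary(fake)
    s$n_sense[s$ntar_class == "IGE"]
  }, integer(1L))
  p_hat <- sum(hits) / (20L * 30L)
  se <- sqrt(0.9 * 0.1 / (20L * 30L))
  expect_lt(abs(p_hat - 0.9), 3 * se)
})

test_that("detection ratios compare mean depths and bin at 0.25 boundaries", {
  fx <- val_fixture()
  # candidate depth 2 (two full-length reads), gene exonic depth 8
  gene_pos <- c(5001:5400, 6001:6400)
  reads <- c(make_reads("chr1", rep(5501L, 2L), 200L),
             make_reads("chr1", rep(gene_pos, 8L), 1L))
  tr <- coverage_track(reads, c(chr1 = 50000L))
  dr <- detection_ratio(fx$cl[1], fx$cg, tr)
  expect_equal(dr$ratio, 0.25)
  expect_equal(dr$bin, "(0,0.25]")

  # scale invariance: tripling every read leaves the ratio unchanged
  tr3 <- coverage_track(rep(reads, 3L), c(chr1 = 50000L))
  expect_equal(detection_ratio(fx$cl[1], fx$cg, tr3)$ratio, 0.25)

  # unexpressed related gene falls into the special category
  tr0 <- coverage_track(make_reads("chr1", rep(5501L, 2L), 200L),
                        c(chr1 = 50000L))
  dr0 <- detection_ratio(fx$cl[1], fx$cg, tr0)
  expect_true(is.na(dr0$ratio))
  expect_equal(dr0$bin, "related gene not expressed")

  # NGA candidates are rejected
  expect_error(detection_ratio(fx$cl, fx$cg, tr), "NGA")

  # random tracks against the brute-force mean-depth oracle
  set.seed(15)
  for (rep_i in 1:3) {
    rr <- make_reads("chr1", sample(4500:7000, 300L, replace = TRUE), 50L)
    trr <- coverage_track(rr, c(chr1 = 50000L))
    d <- o_coverage(start(rr), end(rr), 50000L)
    got <- detection_ratio(fx$cl[1], fx$cg, trr)
    expect_equal(got$ratio,
                 mean(d[5501:5700]) / mean(d[gene_pos]))
  }
})

test_that("gene-corrected differential calls behave as specified", {
  fx <- val_fixture()
  gene_pos <- c(5001:5400, 6001:6400)
  mk_track <- function(cand_depth, gene_depth)
    coverage_track(c(make_reads("chr1", rep(5501L, cand_depth), 200L),
                     make_reads("chr1", rep(gene_pos, gene_depth), 1L)),
                   c(chr1 = 50000L))
  expr_of <- function(f) data.frame(unit_id = "v", fpkm = f,
                                    stringsAsFactors = FALSE)

  # nTAR 6x up and gene 6x up: corrected fold 1, not differential
  d <- differential_ntars(fx$cl[1], mk_track(6L, 6L), mk_track(1L, 1L),
                          expr_of(6), expr_of(1))
  expect_equal(d$corrected_fold, 1, tolerance = 1e-9)
  expect_false(d$differential)

  # NGA 4x up: no gene correction, differential
  nga_a <- coverage_track(make_reads("chr1", rep(30001L, 8L), 150L),
                          c(chr1 = 50000L))
  nga_b <- coverage_track(make_reads("chr1", rep(30001L, 1L), 150L),
                          c(chr1 = 50000L))
  dn <- differential_ntars(fx$cl[2], nga_a, nga_b, expr_of(0), expr_of(0))
  expect_equal(dn$gene_fold, 1)
  expect_true(dn$differential)

  # reciprocal symmetry: swapping tissues inverts the corrected fold
  d_ab <- differential_ntars(fx$cl[1], mk_track(10L, 2L), mk_track(2L, 2L),
                             expr_of(2), expr_of(2))
  d_ba <- differential_ntars(fx$cl[1], mk_track(2L, 2L), mk_track(10L, 2L),
                             expr_of(2), expr_of(2))
  expect_equal(d_ab$corrected_fold, 1 / d_ba$corrected_fold)

  # a planted 5x excess (mean depth 25 vs 5 from 35 bp reads over the
  # 200 bp candidate) over a flat gene is flagged in >= 90% of 20 draws
  depth_track <- function(target) {
    n <- rpois(1L, target * 200 / 35)
    coverage_track(c(make_reads("chr1", sample(5501:5666, max(n, 1L),
                                               replace = TRUE), 35L),
                     make_reads("chr1", rep(gene_pos, 5L), 1L)),
                   c(chr1 = 50000L))
  }
  flags <- vapply(1:20, function(s) {
    set.seed(s)
    differential_ntars(fx$cl[1], depth_track(25), depth_track(5),
                       expr_of(5), expr_of(5))$differential
  }, logical(1L))
  expect_gte(mean(flags), 0.9)
})

test_that("poly-A confirmation requires the 3'-anchored end inside the nTAR", {
  fx <- val_fixture()
  # '+' tag ending inside the candidate
  tag_in <- make_reads("chr1", 5620L, 30L, strand = "+")       # ends 5649
  # '+' tag overlapping but anchored outside (ends beyond the candidate)
  tag_out <- make_reads("chr1", 5690L, 30L, strand = "+")      # ends 5719
  got <- confirm_polya(fx$cl[1], tag_in, fx$cg)
  expect_true(got$polya_confirmed)
  expect_equal(got$tag_orientation, "sense")
  expect_false(confirm_polya(fx$cl[1], tag_out, fx$cg)$polya_confirmed)

  # '-' tags anchor at their leftmost base
  tag_minus <- make_reads("chr1", 5690L, 30L, strand = "-")    # anchor 5690
  gm <- confirm_polya(fx$cl[1], tag_minus, fx$cg)
  expect_true(gm$polya_confirmed)
  expect_equal(gm$tag_orientation, "antisense")

  # planted truth: polyadenylated planted nTARs are confirmed, others not
  sim <- simulate_genome(sim_config(), seed = 17L)
  tags <- simulate_reads(sim, "polyA", "A", seed = 18L)
  cl <- sim$ntars
  cl$ntar_id <- cl$ntar_id
  pol <- confirm_polya(cl, tags, sim$condensed)
  expect_true(all(pol$polya_confirmed[sim$ntars$polya]))
  expect_false(any(pol$polya_confirmed[!sim$ntars$polya]))
})
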