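# Synthetic transcriptome with planted ground truth: a small multi-gene
# genome on two chromosomes, two annotation sources, a two-tissue expression
# program spanning four orders of magnitude, planted nTARs of all nine
# positional classes with known orientation, and seeded read simulation for
# the unstranded screening protocol (with 3' coverage bias), the stranded
# validation protocol, and 3'-anchored poly-A tags.

#' Simulation configuration
#'
#' Returns the default study conditions for the synthetic transcriptome,
#' optionally overridden by name. See the methods vignette for the rationale
#' behind every default.
#'
#' @param ... Named overrides of the defaults.
#' @return A `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_chromosomes = 2L,
    chrom_length = 300000L,
    n_genes = 24L,
    isoforms_range = c(1L, 3L),
    n_exons_range = c(3L, 7L),
    exon_meanlog = log(200), exon_sdlog = 0.45,
    exon_min = 80L, exon_max = 2000L,
    intron_meanlog = log(700), intron_sdlog = 0.5,
    intron_min = 200L, intron_max = 2500L,
    tissues = c("A", "B"),
    log10_fpkm_range = c(-1, 3),     # 0.1 - 1000 FPKM, four decades
    frac_absent = 0.05,
    frac_enhanced = 0.10,
    gene_fold = 5,
    ntars_per_class = 3L,
    ntar_length_range = c(60L, 150L),
    ntar_depth = 12,                 # mean planted coverage, tissue A
    sense_frac = c(NGA = NA_real_, UGN = 0.5, DGN = 0.85, UGI = 0.9,
                   DGI = 0.9, ELU = 0.9, ELD = 0.9, IGE = 0.8, ISE = 0.85),
    frac_differential = 0.3,
    ntar_fold = 5,
    polya_frac = 0.5,
    bias_tau = 5500,                 # 3'-retention half-distance, bp
    bias_min_length = 0L,
    read_length_screening = 35L,
    read_length_validation = 50L,
    polya_tag_length = 30L,
    nominal_depth = 2e7,             # nominal mapped fragments for FPKM->count
    noise_rate = 0.002,
    frac_multi = 0.02,
    second_source_drop = 0.15,
    neighbour_gap_range = c(300L, 7000L),
    ntar_margin = 150L,
    base_gap_range = c(1500L, 4000L),
    nga_clearance = 10500L
  )
  over <- list(...)
  if (length(over) > 0L) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown) > 0L)
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  class(cfg) <- "sim_config"
  cfg
}

.rlnorm_clamped <- function(n, meanlog, sdlog, lo, hi) {
  pmin(pmax(round(stats::rlnorm(n, meanlog, sdlog)), lo), hi)
}

#' Simulate a genome, annotation and planted truth
#'
#' Genes are laid out without overlap along each chromosome, separated by
#' randomized intergenic gaps. Planted nTARs respect their class geometry
#' exactly: intron-internal classes sit in dedicated introns (one per
#' region), flush classes are placed with zero gap to the relevant exon or
#' gene boundary, neighbourhood classes at a random gap within the 10 kb
#' window, and non-gene-associated regions with clearance beyond it. Two
#' annotation sources are emitted; the second omits a configurable fraction
#' of transcripts.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the full output is a deterministic function of
#'   `(config, seed)`.
#' @return An `ntar_sim` list: `transcripts` (source 1), `transcripts2`
#'   (source 2), `condensed`, `spans`, `mask`, `seqlengths`, `genes` (truth
#'   data.frame), `ntars` (truth `GRanges`), `config`, `seed`.
#' @export
simulate_genome <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  cfg <- config
  npc <- cfg$ntars_per_class

  ## gene structures in gene-relative coordinates
  genes <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    n_ex <- sample(seq(cfg$n_exons_range[1], cfg$n_exons_range[2]), 1L)
    ew <- .rlnorm_clamped(n_ex, cfg$exon_meanlog, cfg$exon_sdlog,
                          cfg$exon_min, cfg$exon_max)
    iw <- .rlnorm_clamped(n_ex - 1L, cfg$intron_meanlog, cfg$intron_sdlog,
                          cfg$intron_min, cfg$intron_max)
    starts <- cumsum(c(1L, head(ew, -1L) + iw))
    genes[[i]] <- list(
      symbol = sprintf("G%03d", i),
      strand = sample(c("+", "-"), 1L),
      ex_start = starts, ex_end = starts + ew - 1L,
      glen = starts[n_ex] + ew[n_ex] - 1L, n_ex = n_ex)
  }
  symbols <- vapply(genes, `[[`, character(1L), "symbol")

  ## plant assignments ------------------------------------------------------
  internal_classes <- c("ISE", "ELU", "ELD", "IGE")
  intron_pool <- do.call(rbind, lapply(seq_len(cfg$n_genes), function(i) {
    g <- genes[[i]]
    if (g$n_ex < 2L) return(NULL)
    data.frame(gene = i, intron = seq_len(g$n_ex - 1L),
               is_ = g$ex_end[-g$n_ex] + 1L, ie = g$ex_start[-1L] - 1L)
  }))
  intron_pool$width <- intron_pool$ie - intron_pool$is_ + 1L
  intron_pool$used <- FALSE

  plant <- list()
  for (klass in internal_classes) {
    for (j in seq_len(npc)) {
      len <- sample(seq(cfg$ntar_length_range[1], cfg$ntar_length_range[2]), 1L)
      need <- switch(klass, ISE = 0L,
                     IGE = len + 2L * cfg$ntar_margin,
                     len + cfg$ntar_margin)
      ok <- which(!intron_pool$used & intron_pool$width >= max(need, 50L))
      if (length(ok) == 0L)
        stop("infeasible planting: no free intron for class ", klass)
      row <- if (length(ok) == 1L) ok else sample(ok, 1L)
      intron_pool$used[row] <- TRUE
      gi <- intron_pool$gene[row]
      g <- genes[[gi]]
      is_ <- intron_pool$is_[row]; ie <- intron_pool$ie[row]
      flush_left_label <- if (g$strand == "+") "ELD" else "ELU"
      rel <- switch(klass,
        ISE = c(is_, ie),
        IGE = c(is_ + cfg$ntar_margin, is_ + cfg$ntar_margin + len - 1L),
        if (klass == flush_left_label) c(is_, is_ + len - 1L)
        else c(ie - len + 1L, ie))
      plant[[length(plant) + 1L]] <- list(class = klass, gene = gi,
                                          rel_start = rel[1L],
                                          rel_end = rel[2L])
    }
  }

  external_classes <- c("UGI", "DGI", "UGN", "DGN")
  flank_used <- matrix(FALSE, nrow = cfg$n_genes, ncol = 2L)  # left, right
  for (klass in external_classes) {
    for (j in seq_len(npc)) {
      len <- sample(seq(cfg$ntar_length_range[1], cfg$ntar_length_range[2]), 1L)
      gap <- if (klass %in% c("UGI", "DGI")) 0L
             else sample(seq(cfg$neighbour_gap_range[1],
                             cfg$neighbour_gap_range[2]), 1L)
      repeat {
        gi <- sample(cfg$n_genes, 1L)
        at5 <- klass %in% c("UGI", "UGN")
        side <- if (at5 == (genes[[gi]]$strand == "+")) 1L else 2L
        if (!flank_used[gi, side]) { flank_used[gi, side] <- TRUE; break }
      }
      plant[[length(plant) + 1L]] <- list(class = klass, gene = gi,
                                          side = side, len = len, gap = gap)
    }
  }
  for (j in seq_len(npc)) {
    len <- sample(seq(cfg$ntar_length_range[1], cfg$ntar_length_range[2]), 1L)
    plant[[length(plant) + 1L]] <- list(class = "NGA", gene = NA_integer_,
                                        len = len)
  }

  ## chromosome layout ------------------------------------------------------
  seqlengths <- stats::setNames(rep(cfg$chrom_length, cfg$n_chromosomes),
                                paste0("chr", seq_len(cfg$n_chromosomes)))
  order_genes <- sample(cfg$n_genes)
  chrom_of_gene <- integer(cfg$n_genes)
  gene_offset <- integer(cfg$n_genes)
  nga_idx <- which(vapply(plant, function(p) p$class == "NGA", logical(1L)))
  # interleave genes and NGA elements round-robin across chromosomes
  elements <- c(lapply(order_genes, function(g) list(type = "gene", gene = g)),
                lapply(nga_idx, function(k) list(type = "nga", plant = k)))
  elements <- elements[sample(length(elements))]
  chrom_assign <- rep(seq_len(cfg$n_chromosomes), length.out = length(elements))

  flank_of_gene <- lapply(seq_len(cfg$n_genes), function(g) {
    idx <- which(vapply(plant, function(p)
      !is.null(p$side) && !is.na(p$gene) && p$gene == g, logical(1L)))
    stats::setNames(idx, vapply(plant[idx], function(p)
      c("left", "right")[p$side], character(1L)))
  })

  # `pending_clear` keeps a planted flank feature strictly closest to its own
  # gene: after a right-flank feature with gap g, the next element must stay
  # more than g bp away from it.
  nga_coord <- list()
  for (ci in seq_len(cfg$n_chromosomes)) {
    cur <- 1000L
    pending_clear <- 0L
    for (k in which(chrom_assign == ci)) {
      el <- elements[[k]]
      if (el$type == "nga") {
        p <- plant[[el$plant]]
        cur <- cur + max(cfg$nga_clearance, pending_clear)
        nga_coord[[as.character(el$plant)]] <-
          c(ci, cur + 1L, cur + p$len)
        cur <- cur + p$len + cfg$nga_clearance
        pending_clear <- 0L
      } else {
        g <- el$gene
        base_gap <- sample(seq(cfg$base_gap_range[1], cfg$base_gap_range[2]), 1L)
        fl <- flank_of_gene[[g]]
        left_res <- 0L
        eff_gap <- max(base_gap, pending_clear)
        if ("left" %in% names(fl)) {
          p <- plant[[fl[["left"]]]]
          left_res <- p$len + p$gap
          eff_gap <- max(eff_gap, p$gap + 500L)
        }
        gstart <- cur + eff_gap + left_res + 1L
        chrom_of_gene[g] <- ci
        gene_offset[g] <- gstart - 1L
        if ("left" %in% names(fl)) {
          p <- plant[[fl[["left"]]]]
          plant[[fl[["left"]]]]$coord <-
            c(ci, gstart - p$gap - p$len, gstart - p$gap - 1L)
        }
        gend <- gene_offset[g] + genes[[g]]$glen
        cur <- gend
        pending_clear <- 0L
        if ("right" %in% names(fl)) {
          p <- plant[[fl[["right"]]]]
          plant[[fl[["right"]]]]$coord <-
            c(ci, gend + p$gap + 1L, gend + p$gap + p$len)
          cur <- gend + p$gap + p$len
          pending_clear <- p$gap + 500L
        }
      }
      if (cur > cfg$chrom_length - 1000L)
        stop("infeasible packing: chromosome ", ci, " too short for the ",
             "configured gene and nTAR counts")
    }
  }

  ## assemble annotation ----------------------------------------------------
  tx_list <- list(); tx_sym <- character(0); tx_id <- character(0)
  for (g in seq_len(cfg$n_genes)) {
    gi <- genes[[g]]
    chr <- names(seqlengths)[chrom_of_gene[g]]
    abs_start <- gene_offset[g] + gi$ex_start
    abs_end <- gene_offset[g] + gi$ex_end
    k_iso <- sample(seq(cfg$isoforms_range[1], cfg$isoforms_range[2]), 1L)
    for (iso in seq_len(k_iso)) {
      if (iso == 1L) idx <- seq_len(gi$n_ex)
      else {
        a <- sample(seq_len(gi$n_ex - 1L), 1L)
        b <- sample(seq(a + 1L, gi$n_ex), 1L)
        idx <- seq(a, b)
      }
      tx_list[[length(tx_list) + 1L]] <-
        GRanges(chr, IRanges(abs_start[idx], abs_end[idx]),
                strand = gi$strand)
      tx_sym <- c(tx_sym, gi$symbol)
      tx_id <- c(tx_id, paste0(gi$symbol, ".", iso))
    }
  }
  transcripts <- GRangesList(tx_list)
  names(transcripts) <- tx_id
  mcols(transcripts)$tx_id <- tx_id
  mcols(transcripts)$gene_symbol <- tx_sym
  mcols(transcripts)$source <- "refseq-like"

  keep2 <- stats::runif(length(transcripts)) >= cfg$second_source_drop
  if (!any(keep2)) keep2[1L] <- TRUE
  transcripts2 <- transcripts[keep2]
  mcols(transcripts2)$source <- "ensembl-like"

  condensed <- condense_genes(transcripts)
  spans <- gene_spans(condensed)
  mask <- exon_mask(transcripts, transcripts2, seqlengths = seqlengths)

  ## expression program -----------------------------------------------------
  ng <- cfg$n_genes
  fpkm_a <- 10^stats::runif(ng, cfg$log10_fpkm_range[1], cfg$log10_fpkm_range[2])
  fpkm_b <- fpkm_a * 10^stats::rnorm(ng, 0, 0.05)
  absent_a <- stats::runif(ng) < cfg$frac_absent
  absent_b <- stats::runif(ng) < cfg$frac_absent
  enhanced <- rep("none", ng)
  cand <- which(!absent_a & !absent_b)
  n_enh <- round(cfg$frac_enhanced * length(cand))
  if (n_enh > 0L) {
    pick <- sample(cand, n_enh)
    dir_a <- stats::runif(n_enh) < 0.5
    enhanced[pick] <- ifelse(dir_a, "A", "B")
    fpkm_b[pick[dir_a]] <- fpkm_a[pick[dir_a]] / cfg$gene_fold
    fpkm_a[pick[!dir_a]] <- fpkm_b[pick[!dir_a]] / cfg$gene_fold
  }
  fpkm_a[absent_a] <- 0
  fpkm_b[absent_b] <- 0
  genes_df <- data.frame(
    gene_symbol = symbols,
    chrom = names(seqlengths)[chrom_of_gene],
    strand = vapply(genes, `[[`, character(1L), "strand"),
    exonic_bp = as.integer(sum(width(condensed))[symbols]),
    fpkm_A = fpkm_a, fpkm_B = fpkm_b,
    present_A = fpkm_a > 0, present_B = fpkm_b > 0,
    enhanced = enhanced, stringsAsFactors = FALSE)

  ## planted nTAR truth -----------------------------------------------------
  np <- length(plant)
  p_chr <- character(np); p_start <- integer(np); p_end <- integer(np)
  p_class <- character(np); p_gene <- character(np)
  for (k in seq_len(np)) {
    p <- plant[[k]]
    p_class[k] <- p$class
    if (p$class == "NGA") {
      co <- nga_coord[[as.character(k)]]
      p_chr[k] <- names(seqlengths)[co[1L]]
      p_start[k] <- co[2L]; p_end[k] <- co[3L]
      p_gene[k] <- NA_character_
    } else if (!is.null(p$coord)) {          # external flank classes
      p_chr[k] <- names(seqlengths)[p$coord[1L]]
      p_start[k] <- p$coord[2L]; p_end[k] <- p$coord[3L]
      p_gene[k] <- symbols[p$gene]
    } else {                                  # internal classes
      p_chr[k] <- names(seqlengths)[chrom_of_gene[p$gene]]
      p_start[k] <- gene_offset[p$gene] + p$rel_start
      p_end[k] <- gene_offset[p$gene] + p$rel_end
      p_gene[k] <- symbols[p$gene]
    }
  }
  gene_strand <- stats::setNames(genes_df$strand, genes_df$gene_symbol)
  orientation <- rep(NA_character_, np)
  true_strand <- character(np)
  for (k in seq_len(np)) {
    if (p_class[k] == "NGA") {
      true_strand[k] <- sample(c("+", "-"), 1L)
    } else {
      s_frac <- cfg$sense_frac[[p_class[k]]]
      orientation[k] <- if (stats::runif(1) < s_frac) "sense" else "antisense"
      gs <- gene_strand[[p_gene[k]]]
      true_strand[k] <- if (orientation[k] == "sense") gs
                        else setdiff(c("+", "-"), gs)
    }
  }
  differential <- stats::runif(np) < cfg$frac_differential
  depth_a <- rep(cfg$ntar_depth, np)
  depth_b <- ifelse(differential, cfg$ntar_depth / cfg$ntar_fold,
                    cfg$ntar_depth)
  polya <- stats::runif(np) < cfg$polya_frac

  ntars <- GRanges(p_chr, IRanges(p_start, p_end), strand = true_strand)
  mcols(ntars) <- S4Vectors::DataFrame(
    ntar_id = sprintf("planted_%s_%02d", p_class, seq_len(np)),
    ntar_class = p_class, related_gene = p_gene,
    orientation = orientation, depth_A = depth_a, depth_B = depth_b,
    differential = differential, polya = polya)
  seqlevels(ntars) <- names(seqlengths)
  seqlengths(ntars) <- seqlengths

  sim <- list(transcripts = transcripts, transcripts2 = transcripts2,
              condensed = condensed, spans = spans, mask = mask,
              seqlengths = seqlengths, genes = genes_df, ntars = ntars,
              config = cfg, seed = seed)
  class(sim) <- "ntar_sim"
  sim
}

#' @export
print.ntar_sim <- function(x, ...) {
  cat("ntar_sim:", length(x$condensed), "genes,", length(x$ntars),
      "planted nTARs on", length(x$seqlengths), "chromosome(s), seed",
      x$seed, "\n")
  invisible(x)
}

# Valid genomic read starts within a gene's exons plus the 3'-retention
# weight of each (screening protocol bias).
.gene_read_starts <- function(exons, strand, read_len, tau, bias_min_length,
                              biased) {
  ex <- sort(exons)
  ew <- width(ex)
  L <- sum(ew)
  offs <- cumsum(c(0L, head(ew, -1L)))   # left-to-right transcript offsets
  starts <- integer(0); pluspos <- integer(0)
  for (j in seq_along(ex)) {
    if (ew[j] < read_len) next
    s <- start(ex)[j]:(end(ex)[j] - read_len + 1L)
    starts <- c(starts, s)
    pluspos <- c(pluspos, offs[j] + (s - start(ex)[j]) + 1L)
  }
  if (length(starts) == 0L) return(NULL)
  w <- rep(1, length(starts))
  if (biased && L > bias_min_length) {
    d3 <- if (strand == "+") L - (pluspos + read_len - 1L) else pluspos - 1L
    w <- exp(-d3 / tau)
  }
  list(starts = starts, weights = w)
}

#' Simulate aligned reads for one protocol and tissue
#'
#' The screening protocol emits unstranded fragments along mature gene models
#' with a 3'-retention bias (`exp(-d/tau)` in the distance `d` of the
#' fragment 3' end from the transcript 3' end); the validation protocol emits
#' stranded, positionally uniform fragments; the polyA protocol emits
#' 3'-anchored tags at gene ends and at planted poly-A-positive nTARs.
#' Fragment counts are Poisson with FPKM-implied means; planted nTARs
#' additionally receive a deterministic tiling pass so that their covered run
#' reproduces the planted interval exactly. A configurable fraction of
#' multi-mapping-flagged reads and of non-exonic background noise is added.
#'
#' @param sim An `ntar_sim` from [simulate_genome()].
#' @param protocol `"screening"`, `"validation"` or `"polyA"`.
#' @param tissue One of `sim$config$tissues`.
#' @param seed Integer seed.
#' @return A `GRanges` of aligned reads with metadata columns `name`,
#'   `unique`, `primary`, `protocol`.
#' @export
simulate_reads <- function(sim, protocol = c("screening", "validation",
                                             "polyA"),
                           tissue = "A", seed = 1L) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(sim, "ntar_sim"), tissue %in% sim$config$tissues)
  set.seed(seed)
  cfg <- sim$config
  fcol <- paste0("fpkm_", tissue)
  dcol <- paste0("depth_", tissue)

  if (protocol == "polyA") {
    TL <- cfg$polya_tag_length
    chr <- character(0); st <- integer(0); en <- integer(0); sd_ <- character(0)
    for (i in seq_len(nrow(sim$genes))) {
      if (sim$genes[[fcol]][i] <= 0) next
      sp <- sim$spans[sim$genes$gene_symbol[i]]
      n <- 1L + stats::rpois(1L, 1)
      p3 <- if (as.character(strand(sp)) == "+") end(sp) else start(sp)
      for (j in seq_len(n)) {
        chr <- c(chr, as.character(seqnames(sp)))
        if (as.character(strand(sp)) == "+") {
          st <- c(st, p3 - TL + 1L); en <- c(en, p3)
        } else {
          st <- c(st, p3); en <- c(en, p3 + TL - 1L)
        }
        sd_ <- c(sd_, as.character(strand(sp)))
      }
    }
    nt <- sim$ntars
    for (k in seq_along(nt)) {
      if (!nt$polya[k] || mcols(nt)[[dcol]][k] <= 0) next
      n <- 1L + stats::rpois(1L, 2)
      tl <- min(TL, width(nt)[k])
      for (j in seq_len(n)) {
        chr <- c(chr, as.character(seqnames(nt))[k])
        if (as.character(strand(nt))[k] == "+") {
          st <- c(st, end(nt)[k] - tl + 1L); en <- c(en, end(nt)[k])
        } else {
          st <- c(st, start(nt)[k]); en <- c(en, start(nt)[k] + tl - 1L)
        }
        sd_ <- c(sd_, as.character(strand(nt))[k])
      }
    }
    gr <- GRanges(chr, IRanges(st, en), strand = sd_)
    mcols(gr)$name <- paste0("tag_", tissue, "_", seq_along(gr))
    mcols(gr)$unique <- TRUE
    mcols(gr)$primary <- TRUE
    mcols(gr)$protocol <- "polyA_tag"
    return(gr)
  }

  R <- if (protocol == "screening") cfg$read_length_screening
       else cfg$read_length_validation
  biased <- protocol == "screening"
  chr <- character(0); st <- integer(0); sd_ <- character(0)

  ## gene fragments
  for (i in seq_len(nrow(sim$genes))) {
    f <- sim$genes[[fcol]][i]
    if (f <= 0) next
    sym <- sim$genes$gene_symbol[i]
    lam <- f * (sim$genes$exonic_bp[i] / 1000) * (cfg$nominal_depth / 1e6)
    n <- stats::rpois(1L, lam)
    if (n == 0L) next
    vp <- .gene_read_starts(sim$condensed[[sym]], sim$genes$strand[i], R,
                            cfg$bias_tau, cfg$bias_min_length, biased)
    if (is.null(vp)) next
    s <- vp$starts[sample.int(length(vp$starts), n, replace = TRUE,
                              prob = vp$weights)]
    chr <- c(chr, rep(sim$genes$chrom[i], n))
    st <- c(st, s)
    sd_ <- c(sd_, if (protocol == "validation")
      rep(sim$genes$strand[i], n) else sample(c("+", "-"), n, replace = TRUE))
  }

  ## planted nTAR fragments: deterministic tiling + Poisson extras
  nt <- sim$ntars
  for (k in seq_along(nt)) {
    d <- mcols(nt)[[dcol]][k]
    if (d <= 0) next
    a <- start(nt)[k]; b <- end(nt)[k]
    last <- b - R + 1L
    if (last < a) next
    tiles <- unique(c(seq(a, last, by = max(1L, R - 10L)), last))
    if (protocol == "validation")
      tiles <- unique(c(a, a + (last - a) %/% 2L, last))
    extra <- stats::rpois(1L, max(0, d * width(nt)[k] / R - length(tiles)))
    s <- c(tiles, if (extra > 0L) sample(a:last, extra, replace = TRUE))
    chr <- c(chr, rep(as.character(seqnames(nt))[k], length(s)))
    st <- c(st, s)
    sd_ <- c(sd_, if (protocol == "validation")
      rep(as.character(strand(nt))[k], length(s))
      else sample(c("+", "-"), length(s), replace = TRUE))
  }

  n_main <- length(st)

  ## non-exonic background noise
  n_noise <- stats::rpois(1L, cfg$noise_rate * n_main)
  if (n_noise > 0L) {
    got <- 0L; tries <- 0L
    while (got < n_noise && tries < 20L) {
      m <- (n_noise - got) * 3L
      nc <- sample(names(sim$seqlengths), m, replace = TRUE)
      ns <- floor(stats::runif(m, 1, sim$seqlengths[nc] - R)) + 1L
      cand <- GRanges(nc, IRanges(ns, width = R))
      ok <- !overlapsAny(cand, sim$mask, ignore.strand = TRUE)
      take <- min(sum(ok), n_noise - got)
      if (take > 0L) {
        sel <- which(ok)[seq_len(take)]
        chr <- c(chr, nc[sel]); st <- c(st, ns[sel])
        sd_ <- c(sd_, sample(c("+", "-"), take, replace = TRUE))
        got <- got + take
      }
      tries <- tries + 1L
    }
  }

  gr <- GRanges(chr, IRanges(st, width = R), strand = sd_)
  mcols(gr)$name <- paste0(substr(protocol, 1, 3), "_", tissue, "_",
                           seq_along(gr))
  mcols(gr)$unique <- TRUE

  ## multi-mapping-flagged reads (exercise the unique-only filter)
  n_multi <- stats::rpois(1L, cfg$frac_multi * n_main)
  if (n_multi > 0L) {
    mc <- sample(names(sim$seqlengths), n_multi, replace = TRUE)
    ms <- floor(stats::runif(n_multi, 1, sim$seqlengths[mc] - R)) + 1L
    mg <- GRanges(mc, IRanges(ms, width = R),
                  strand = sample(c("+", "-"), n_multi, replace = TRUE))
    mcols(mg)$name <- paste0("multi_", tissue, "_", seq_len(n_multi))
    mcols(mg)$unique <- FALSE
    gr <- c(gr, mg)
  }
  mcols(gr)$primary <- TRUE
  mcols(gr)$protocol <- protocol
  sort(gr, ignore.strand = TRUE)
}

#' Write a simulation to disk
#'
#' Emits the first annotation source as GTF, the second as BED12, the
#' condensed models as BED12, the exon mask as BED3, both truth tables as
#' TSV, and the configuration as JSON.
#'
#' @param sim An `ntar_sim`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ex <- unlist(sim$transcripts, use.names = FALSE)
  nb <- lengths(sim$transcripts)
  gtf <- ex
  mcols(gtf)$source <- "sim"
  mcols(gtf)$type <- "exon"
  mcols(gtf)$gene_id <- rep(mcols(sim$transcripts)$gene_symbol, nb)
  mcols(gtf)$transcript_id <- rep(mcols(sim$transcripts)$tx_id, nb)
  rtracklayer::export(gtf, file.path(dir, "annotation_source1.gtf"),
                      format = "gtf")
  write_bed12(sim$transcripts2, file.path(dir, "annotation_source2.bed"))
  write_bed12(sim$condensed, file.path(dir, "condensed.bed"))
  write_bed3(sim$mask, file.path(dir, "exon_mask.bed"))
  nt <- sim$ntars
  ntdf <- data.frame(chrom = as.character(seqnames(nt)),
                     start = start(nt) - 1L, end = end(nt),
                     as.data.frame(mcols(nt)),
                     true_strand = as.character(strand(nt)),
                     stringsAsFactors = FALSE)
  utils::write.table(ntdf, file.path(dir, "truth_ntars.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$genes, file.path(dir, "truth_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  class(cfg) <- NULL
  jsonlite::write_json(c(cfg, list(seed = sim$seed)),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
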