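---
title: "Methods: novel transcribed region discovery, classification and validation"
author: "ntarseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: novel transcribed region discovery, classification and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntarseq)
```

## The problem

Deep RNA-seq of a mammalian tissue recovers far more transcription than the
curated gene catalogues describe. After alignment, a substantial share of
uniquely mapped reads falls outside every annotated exon — in introns, at
gene boundaries, and in intergenic space. `ntarseq` implements a two-protocol
analysis of such *novel transcriptionally active regions* (nTARs): an
unstranded, 3'-biased oligo-dT library is used as the discovery (screening)
pass, and a strand-specific RNA-fragmentation library as the confirmation
(validation) pass that additionally supplies the orientation of each region
relative to its neighbouring gene. The package targets the post-alignment
part of the workflow only: its inputs are uniquely mapped alignments (BED6
or BAM) and gene annotation (GTF or BED12); read mapping itself is out of
scope.

## Gene models and the exon mask

Transcript isoforms sharing a gene symbol are condensed into a single
union-exon model (a "supertranscript"): the exons of all isoforms are
unioned and overlaps merged, so that evidence for any isoform counts toward
one gene. Condensation requires a symbol to live on one chromosome and
strand; violations are an error by default or are suffix-disambiguated on
request.

Novelty is defined against an *exon mask*: the strand-ignored union of the
exon space of **all** loaded annotation sources (two in the default design,
emulating a RefSeq-like and an Ensembl-like catalogue that do not fully
agree). The mask is strand-ignored because the screening protocol is
unstranded. Internally all intervals live in `GenomicRanges` containers
(1-based, closed); BED input and output keep their native 0-based half-open
convention, with conversion confined to the I/O layer.

## Detection

Per-base depth is accumulated over the screening alignments (an `Rle` per
chromosome). Maximal runs of covered bases are intersected with the
complement of the mask — a run split by the mask yields independent
fragments — and each surviving run becomes a candidate if it satisfies all
of:

| parameter | default | meaning |
|---|---|---|
| `min_length` | 50 bp | minimum run length |
| `min_avg_cov` | 3 | minimum mean per-base depth over the run |
| `min_reads` | 5 | minimum overlapping reads |
| `min_sp` | 2 | minimum independent start points |

An *independent start point* is a distinct 5'-most alignment coordinate
among the reads overlapping a region ('+' reads start at their leftmost
base, '−' reads at their rightmost, unstranded reads fall back to
leftmost). Requiring two start points discards clonal amplification stacks
that would otherwise pass the depth filters.

## The nine positional classes

Each candidate is placed relative to the condensed gene models, with
upstream/downstream always taken on the related gene's strand:

* **ISE** — inside a gene span, covering a whole intron;
* **ELU / ELD** — intronic, flush (zero gap) with an exon's 5' / 3' edge;
* **UGI / DGI** — outside the span, flush with the gene's 5' / 3' boundary;
* **IGE** — intronic, touching no exon;
* **UGN / DGN** — outside all spans, nearest-gene gap in (0, 10 kb], on the
  5' / 3' side;
* **NGA** — more than 10 kb from every gene.

A candidate satisfying several geometries receives exactly one label by the
priority ISE > ELD/ELU > UGI/DGI > IGE > UGN/DGN > NGA. Gene-internal
labels bind to the enclosing gene; neighbourhood labels to the closest
gene; residual ties resolve deterministically (smaller distance, smaller
gene start, lexicographic symbol). "Flush" means a zero-base gap — the
covered run would merge with the exon if the mask were lifted; a
`gap_tol` parameter (default 0) exposes this choice. Since condensed span
boundaries coincide with outermost exon edges and candidates never overlap
exons, every candidate inside a span lies within exactly one intron, which
makes the rule set total and single-valued.

## Validation, orientation and downstream statistics

A candidate is **confirmed** when at least 3 strand-specific validation
reads overlap it. Reads are counted sense/antisense relative to the related
gene's strand; only candidates whose reads all agree are assigned an
orientation, mixed ones are `ambiguous`, and NGA candidates (no reference
strand) stay `undetermined`. Per-class sense:antisense ratios use
unambiguous calls only.

The **detection ratio** compares mean per-base screening depth over the
candidate with that over the related gene's condensed exons, binned at 0.25
boundaries; mean depth (not FPKM) keeps both sides on one scale without a
length normalization. Genes with zero exonic coverage form the separate
"related gene not expressed" category.

**Differential calls** across two tissues divide the candidate's depth fold
by the related gene's FPKM fold (no correction for NGA) and flag folds
≥ 3 or ≤ 1/3. Both folds use the symmetric pseudocount form
`(a + 1)/(b + 1)`: it is strictly positive, reciprocal under swapping
tissues, and exactly 1 for a perfectly co-varying candidate/gene pair —
properties the corrected quotient needs. The gene-level
*tissue-enhancement* call keeps the asymmetric rule
`fpkm_a / (fpkm_b + 1) ≥ 3`, which is the stated gene-expression filter;
the penalty damps fold changes of barely expressed units, and the two
directions of the rule are mutually exclusive for any penalty > 0.

**Poly-A confirmation** accepts a candidate when at least one 3'-anchored
tag has its anchored end (rightmost base of a '+' tag, leftmost of a '−'
tag) inside the candidate; a tag that merely overlaps with its anchor
outside does not count.

## Quantification and presence

Gene FPKM is computed directly from the union-exon model:
`n / (exonic_kb × total_mapped / 10^6)`, where a read is assigned if it
overlaps any exon by at least one base. No isoform deconvolution is
attempted — the presence and fold-change logic downstream only consumes
gene-level values. A gene is **present** when FPKM strictly exceeds 0.01
and at least two independent start points support it. Presence is monotone
in FPKM at fixed start-point count.

## Saturation modelling

Reads are drawn uniformly without replacement; after every `step` draws the
number of condensed genes with ≥ 5 accumulated reads is recorded. The curve
is fitted with a saturating model — hyperbolic `a·x/(b+x)` by default,
exponential `a·(1−e^(−x/b))` as an alternative, both exposing the asymptote
as the parameter `a`. The source procedure's exact functional form is not
recoverable, so the family is configurable and the refit procedure is
model-agnostic. If the Pearson correlation between observed and fitted
values is below 0.99, the *second* crossing of the fitted curve with the
observed sequence (second sign change of the residuals) is located and the
fit is repeated on the points from that crossing rightward, until the
correlation target is met, no second crossing or fewer than 4 points
remain, improvement drops below 10⁻⁴, or 20 rounds pass. Initialization
uses the linearized double-reciprocal form with heuristic fallbacks; a
refit window that has gone completely flat (saturated tail) ends the
iteration with the previous round's fit and honest diagnostics
(`converged = FALSE`). The asymptote estimates the number of genes
detectable with unbounded sequencing from the same library, so it sits
*above* the count detected at full depth — tests therefore compare it with
the planted number of expressed genes, not with the full-pool count.

## 5'–3' coverage bias

For each transcript the exonic per-base coverage is laid along the 5'→3'
axis (reversed for minus-strand models), averaged into equal-width bins,
summed within length classes ((0,1], (1,2], (2,5], >5 kb by default) and
scaled to a class maximum of 1. Oligo-dT priming with template switch
under-represents 5' ends of long transcripts; the simulator reproduces this
with an exponential retention weight `exp(−d₃'/τ)` in the distance of the
fragment's 3' end from the transcript 3' end. The default τ = 5500 bp puts
the relative 5' coverage of a 5 kb transcript near `e^(−5000/5500) ≈ 0.40`,
the magnitude this protocol family shows, and makes the bias grow with
transcript length without a hard length switch.

## The synthetic study and what it does (not) show

`simulate_genome()` + `simulate_reads()` define the study conditions; all
defaults are fixed once in `sim_config()`:

* 2 chromosomes × 300 kb, 24 genes, 1–3 isoforms, 3–7 exons, log-normal
  exon/intron lengths (medians 200 / 700 bp);
* two annotation sources, the second omitting 15% of transcripts;
* per-tissue log-uniform expression over 0.1–1000 FPKM (four decades), 5%
  of genes absent per tissue, 10% enhanced 5-fold;
* 3 planted nTARs per class with exact class geometry (flush classes at
  zero gap, neighbourhood gaps in 0.3–7 kb, NGA clearance 10.5 kb) and
  margins that keep every planted region strictly closest to its own gene;
* per-class sense fractions (0.5 for UGN, 0.8–0.9 elsewhere), 30%
  differential at 5-fold, 50% poly-adenylated;
* planted mean depth 12× in tissue A; a deterministic tiling pass
  guarantees that the covered run reproduces each planted interval exactly,
  with Poisson extras on top;
* a nominal library of 2×10⁷ mapped fragments converts FPKM to expected
  counts (≈ 35–90 k emitted reads per library at this gene panel — sizes
  chosen so a full pipeline run takes seconds);
* 0.2% background noise reads placed outside annotated exons, and 2%
  multi-mapping-flagged reads to exercise the unique-only filter.

Everything is a deterministic function of `(config, seed)`, down to
byte-identical files.

The generator emulates the *geometry and bookkeeping* of the two-protocol
design, not sequence-level reality: reads are emitted pre-aligned (no
sequencing errors, no mappability structure), spliced reads never cross
exon junctions, background noise avoids exon space so that planted-absent
genes stay silent, and planted regions are expressed well above the
detection thresholds. Passing the recovery suite therefore demonstrates
that the pipeline's interval logic, filters, class rules and orientation
accounting are correct — it does not certify performance on real libraries,
where mappability artifacts, unannotated isoforms and borderline-expressed
regions dominate the error budget. Desk-scale library sizes also make FPKM
values scale-inflated relative to a 10⁸-read experiment (the presence
threshold of 0.01 FPKM is then easy to clear), and leave presence calls for
genes planted below ~1 FPKM stochastic, which is why recovery claims are
restricted to planted-absent genes.

## Numerical choices and degenerate inputs

* Percentages round half-up at the printed decimal count.
* Presence uses a strict inequality at the 0.01 FPKM threshold.
* Equidistant-gene ties resolve by (distance, gene start, symbol); the
  deterministic tie-break is positional, so it is not invariant under
  coordinate reflection (labels are; tests assert exactly that).
* A detection step larger than the read pool yields the single exhaustive
  curve point; flat all-zero curves and fits on fewer than 4 points are
  errors; degenerate refit windows terminate the iteration rather than
  fabricate a fit.
* Empty orientation denominators report an infinite ratio with a
  degeneracy flag rather than NaN.
* Sub-bin-length transcripts in the bias profile are sampled at bin
  midpoints instead of averaging empty bins.

## Known limitations

Spliced discovery is out of scope: candidate regions are contiguous, and a
spliced novel transcript appears as several independent candidates. The
FPKM implementation deliberately skips isoform-level deconvolution. The
differential rule is a fold filter, not a statistical test — no replicates,
no FDR. Orientation calls require perfect strand agreement; a single stray
antisense read demotes a region to `ambiguous`, which is conservative at
high validation depth.
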