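# ntarseq

Post-alignment discovery, classification and strand-aware validation of
novel transcriptionally active regions (nTARs) from bulk RNA-seq coverage,
with union-exon FPKM quantification, gene-detection saturation modelling
and 5'–3' coverage-bias profiling.

Deep RNA-seq of complex tissues shows substantial transcription outside
annotated exons. `ntarseq` implements a two-protocol analysis of that
signal: an unstranded *screening* library provides the discovery pass, and
a strand-specific *validation* library confirms each region and supplies
its orientation relative to the neighbouring gene. The package is aimed at
analysts working downstream of an aligner: inputs are uniquely mapped
alignments (BED6/BAM) and gene annotation (GTF/BED12); everything is
exercised end-to-end on a seeded synthetic transcriptome with planted
ground truth, so no external data are needed.

## The method in brief

* **Condensed gene models.** Isoforms sharing a symbol are fused into a
  union-exon "supertranscript"; an exon **mask** (strand-ignored union over
  all annotation sources) defines novelty.
* **Detection.** Maximal covered runs outside the mask become candidates
  when length ≥ 50 bp, mean depth ≥ 3, supported by ≥ 5 reads with ≥ 2
  independent start points (distinct 5' alignment coordinates — an
  anti-clonality guard).
* **Nine positional classes**, prioritized ISE > ELD/ELU > UGI/DGI > IGE >
  UGN/DGN > NGA, with upstream/downstream taken on the related gene's
  strand and a 10 kb neighbourhood window.
* **Validation.** Confirmation requires ≥ 3 stranded reads; orientation is
  called sense/antisense only when all reads agree. Per-class
  sense:antisense ratios, detection ratios versus the related gene,
  gene-corrected differential calls at 3-fold (`(a+1)/(b+1)` pseudocount
  folds), and 3'-anchored poly-A tag confirmation follow.
* **Expression.** Gene FPKM `n/(exonic_kb × total_mapped/10⁶)`; presence
  requires FPKM > 0.01 and ≥ 2 start points; tissue enhancement uses the
  penalized fold `fpkm_a/(fpkm_b + 1) ≥ 3`.
* **Saturation.** Random read drawing gives a detection curve (genes with
  ≥ 5 reads); a hyperbolic `a·x/(b+x)` fit, iteratively re-windowed at the
  second residual sign change until r ≥ 0.99, estimates the detectable-gene
  asymptote `a`.

See `vignettes/ntar-discovery-methods.Rmd` for the full model description,
parameter table and design rationale.

## Worked example

The numbered scripts under `analysis/` run the whole study on the default
synthetic transcriptome (seed 42); each stage writes its tables under
`results/run_seed42/`. Running them in order prints, among others:

```
$ Rscript analysis/01_simulate.R
simulated 24 genes and 27 planted nTARs on 2 chromosomes
tissue A: 37776 screening reads, 37210 validation reads

$ Rscript analysis/04_ntar_discovery.R
27 candidate nTARs; class counts:
DGI DGN ELD ELU IGE ISE NGA UGI UGN
  3   3   3   3   3   3   3   3   3
planted-truth recovery: 100.0% correctly classified

$ Rscript analysis/06_report.R
genes: 24/24 present (100.0%); 19 shared across tissues
nTARs: 27 candidates, 27 confirmed (100.00%), 13 differential
planted-truth recovery: 100.0%; saturation asymptote 20.3 genes
```

Read as: all 27 planted regions (3 per class) were re-detected from raw
coverage, classified into the correct positional class, and confirmed by
the stranded protocol; 13 carried a ≥ 3-fold tissue difference after
correcting for their related gene's fold change. The saturation asymptote
(≈ 20 genes) estimates how many condensed genes this library could ever
detect with ≥ 5 reads — slightly above the 19 detected at full depth, as a
rarefaction extrapolation should be.

The same machinery is available programmatically:

```r
library(ntarseq)
res <- run_pipeline(sim_config(), seed = 42)
res$report$class_counts
res$orientation          # per-class sense:antisense ratios
```

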