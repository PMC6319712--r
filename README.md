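# vesiclemiR

Analysis of small RNA-seq miRNA counts from cell lysates (CL) and their
secreted extracellular vesicles — shed microvesicles (sMVs) and exosomes
(Exos). Cells sort specific miRNAs into the vesicles they secrete, and
because those vesicles circulate in blood, EV miRNA signatures are studied
as non-invasive tumour markers. `vesiclemiR` implements the complete
inference chain from a raw count matrix to classifier metrics, for
bioinformaticians who want the analysis reproducible, testable and free of
external downloads: a synthetic-data generator with recorded ground truth
stands in for sequencing and clinical panels wherever needed.

## What it computes

Starting from integer counts `c[f, l]` (miRNA `f`, library `l`) annotated
by cell line, compartment (CL / sMV / Exo) and replicate:

1. **Quantification** — TPM on total miRNA-mapped reads,
   `TPM = c / colSums(c) * 1e6` (no length term), replicate averaging, and
   detection: TPM > 5 in at least one replicate.
2. **Differential expression** — a from-scratch two-group
   negative-binomial exact test: TMM normalization factors, qCML common (or
   tagwise) dispersion `phi` (variance `mu + phi mu^2`), conditional exact
   p-values, Benjamini–Hochberg FDR, and calls at |log2FC| > 1, p < 0.05,
   FDR < 0.05.
3. **EV distribution logic** — exact Venn partitions of detected sets,
   EV-enrichment labels (up in sMV-vs-CL and/or Exo-vs-CL), the four-way
   cross-cell-line EV overlap, and the screen for *cell-silent* miRNAs:
   undetectable in the lysate (< 5 TPM) yet enriched in the vesicles
   (> 1000 TPM levels).
4. **Correlation classifier** — Pearson correlation of an expression
   signature with tumour/normal panel samples; a sample is predicted
   tumour when `r` exceeds the largest coefficient among calibration
   normals; sensitivity/specificity reported to one decimal.
5. **Motif scan** — fraction of pre-miRNA sequences carrying literal
   candidate sorting motifs (`CUGU`, `GGAG`), with 0-based hit positions.

The central container is `MiRNAExperiment`, a `SummarizedExperiment`
subclass; sequences are `Biostrings::RNAStringSet`. See the methods
vignette (`vignettes/vesiclemiR-methods.Rmd`) for the statistical details
and design decisions.

## Worked example

```r
library(vesiclemiR)

cfg <- pipelineConfig(simulation = simulationConfig(nMirnas = 300, seed = 1),
                      seed = 1)
out <- runPipeline(cfg, outDir = tempfile(), verbose = FALSE)

out$deLysate
#> DifferentialResult: lineA-CL-R1+lineA-CL-R2 (A) vs lineB-CL-R1+lineB-CL-R2 (B), 278 features
#> dispersion: 0.0993 | thresholds: |log2FC| > 1, p < 0.05, FDR < 0.05
#> calls: 29 up, 29 down, 220 ns

out$distribution$cl
#> DistributionReport: 2 sets (lineA-CL, lineB-CL), union 278 features
#>          lineA-CL          lineB-CL lineA-CL&lineB-CL
#>                10                 1               267

out$cellSilent$lineA$counts
#> sMV_only Exo_only     both
#>        0        2       15

out$classification$report
#> ClassificationReport: 605 samples, rule 'max-normal', threshold r > -0.0326, 46 signature features
#>   label   n         min         max       mean
#>  normal  11 -0.04274744 -0.03264502 -0.0376225
#>       I 103  0.87217677  0.99379033  0.9592380
#>      II 223  0.84229812  0.99218229  0.9601995
#>     III 179  0.75612208  0.99063885  0.9563276
#>      IV  89  0.84420766  0.99467657  0.9576471

out$motif
#> MotifReport: motif CUGU found in 176 / 334 sequences (52.7%)
```

Reading the output: of 278 miRNAs detected in either lysate, 58 are called
dysregulated between the lines (the generator planted 20% of 300, some of
which fall below detection); 267 are detected in both lysates. Seventeen
lineA miRNAs are cell-silent yet EV-enriched. The 46-feature EV-enrichment
signature separates simulated tumours (mean r ≈ 0.96) from normals
(r ≈ −0.04), predicting every tumour above the calibration threshold, and
the motif scan reports the planted precursor fraction exactly.

The same stages run on real data via `readCounts()` (TSV plus a JSON
metadata sidecar), `readPanel()` and a FASTA path in `pipelineConfig()`.

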