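# ribostall

Detection of transcript-selective, compound-induced ribosome stalling from
ribosome profiling (ribo-seq) and matched mRNA-seq data.

Small molecules can arrest the eukaryotic ribosome during elongation on
specific transcripts. In ribosome profiling such an arrest appears as a
footprint pile-up at the stall codon, depleted footprint density 3′ of it,
and unchanged mRNA-seq coverage. `ribostall` is for computational biologists
analyzing that signature genome-wide: it converts transcriptome-coordinate
alignments into P-site-resolved read maps, runs metagene QC, and identifies
sensitive transcripts with the D_max divergence statistic, downstream
differential expression, and center-of-density analysis, plus translational
efficiency decomposition and uORF scanning.

## The core statistic

For each gene, the cumulative fractional read curve gives at codon *c* the
fraction of the transcript's footprints aligning at or 5′ of *c*, from
replicate-pooled counts. The divergence between treatment and vehicle,

    D_max = max_c [ CFR_treat(c) − CFR_veh(c) ],

is maximal just 3′ of the last stall (a Kolmogorov–Smirnov-style position).
D_max values are standardized against genes of similar read depth —
expression bins of 300 genes, leave-one-out mean/SD — to absorb the higher
chance divergence of sparse transcripts. Genes with D_max Z ≥ 2 have their
footprints 3′ of the D_max position extracted (codon 50 for all others) for
a negative-binomial differential test (DESeq2); a gene is called sensitive
when D_max Z > 2, FDR < 0.1, and downstream reads decrease. A
center-of-density shift analysis (count-weighted mean read position, same
Z-transformation, |Z| ≥ 3) provides a complementary detection path, and
repeating it while omitting the first 50/100/150 codons localizes stalls to
the early CDS.

## Worked example

Simulate 500 genes, implant stalls at codon 34 with 25% readthrough in ten
of them, and run detection:

```r
library(ribostall)

sim   <- simulate_transcriptome(500, seed = 7, with_sequence = FALSE)
specs <- implant_stalls(sim$specs, sim$specs$gene_id[1:10],
                        stall_codon = 34, readthrough = 0.25)
des   <- sim_design(3, assays = "ribo")
ex    <- simulate_experiment(specs, sim$transcripts, des,
                             depth = 5e5, seed = 8, level = "codon")
res   <- detect_stalls(ex$maps, des, sim$transcripts,
                       params = list(bin_size = 100))
subset(res$stalls, sensitive,
       select = c(gene_id, dmax, dmax_codon, zscore, log2fc, fdr))
#>  gene_id   dmax dmax_codon zscore log2fc      fdr
#>   g00001 0.3073         45   5.50 -2.019 1.03e-14
#>   g00002 0.2598         34   5.46 -2.069 2.23e-47
#>   g00003 0.3101         36   7.23 -2.033 3.64e-34
#>   g00004 0.1588         48  18.02 -2.047 5.02e-54
#>   g00005 0.3800         38   7.85 -2.283 4.14e-31
#>   g00006 0.2278         34   3.54 -1.809 1.10e-16
#>   g00007 0.1829         81   2.59 -1.919 1.42e-09
#>   g00008 0.2449         35   5.01 -2.130 5.94e-48
#>   g00009 0.3565         34  55.78 -1.883 1.92e-66
#>   g00010 0.2060         34   3.93 -1.785 7.91e-34
#>   g00278 0.0426        415   2.07 -0.782 3.39e-03
```

All ten implanted genes are recovered. Their `dmax_codon` sits at or 3′ of
the implanted stall (it bounds the stall region from the 3′ side; the peak
caller in `res$stalls$stall_codons` reports the stall codon itself), the
downstream log2 fold changes cluster near log2(0.25) = −2 — the implanted
readthrough — and the FDRs are vanishingly small. `g00278` is a borderline
false positive sitting exactly at the Z = 2 gate with a weak decrease; the
gate is deliberately permissive because it only selects a counting boundary.

The same stages run over files (FASTA/TSV in, TSV/JSON out) as

```r
ribostall_run("all", list(outdir = "run1", seed = 1, n_genes = 500))
```

or from a shell via `inst/cli/ribostall.R`.

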