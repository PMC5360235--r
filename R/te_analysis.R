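# Translational efficiency (TE = ribosome-footprint density over mRNA
# abundance) and the decomposition of expression changes into
# transcriptional vs translational components.

#' Median-of-ratios size factors and normalized counts
#'
#' Thin wrapper over DESeq2's size-factor estimator, applied within one
#' assay.
#' @param counts genes x samples integer matrix.
#' @return matrix of normalized counts.
#' @export
normalize_counts <- function(counts) {
  sf <- DESeq2::estimateSizeFactorsForMatrix(counts)
  sweep(counts, 2, sf, "/")
}

#' Translational efficiency per gene and condition
#'
#' TE = (mean normalized CDS footprint count) / (mean normalized CDS mRNA
#' count), computed per condition after median-of-ratios normalization
#' within each assay. Genes with a zero mRNA (or ribo) mean in either
#' condition are excluded and tallied, as are genes flagged as lacking a
#' poly-A tail (\code{polyA} = FALSE), which poly-A-selected mRNA-seq
#' underrepresents — histone transcripts being the canonical case.
#'
#' @param ribo_counts,mrna_counts genes x samples matrices (CDS-restricted
#'   counts), same gene order.
#' @param ribo_condition,mrna_condition per-sample condition vectors
#'   ("vehicle"/"treatment") for each matrix.
#' @param polyA optional named logical (gene -> has poly-A); FALSE genes
#'   are excluded.
#' @return data.frame(gene_id, te_vehicle, te_treatment, log2_dte,
#'   expression) with attribute \code{excluded}.
#' @export
translational_efficiency <- function(ribo_counts, mrna_counts,
                                     ribo_condition, mrna_condition,
                                     polyA = NULL) {
  stopifnot(identical(rownames(ribo_counts), rownames(mrna_counts)))
  rn <- normalize_counts(ribo_counts)
  mn <- normalize_counts(mrna_counts)
  rv <- rowMeans(rn[, ribo_condition == "vehicle", drop = FALSE])
  rt <- rowMeans(rn[, ribo_condition == "treatment", drop = FALSE])
  mv <- rowMeans(mn[, mrna_condition == "vehicle", drop = FALSE])
  mt <- rowMeans(mn[, mrna_condition == "treatment", drop = FALSE])

  ok <- rv > 0 & rt > 0 & mv > 0 & mt > 0
  n_zero <- sum(!ok)
  n_polya <- 0L
  if (!is.null(polyA)) {
    flag <- polyA[rownames(ribo_counts)]
    flag[is.na(flag)] <- TRUE
    n_polya <- sum(!flag & ok)
    ok <- ok & flag
  }
  out <- data.frame(gene_id = rownames(ribo_counts)[ok],
                    te_vehicle = (rv / mv)[ok],
                    te_treatment = (rt / mt)[ok],
                    log2_dte = log2((rt / mt)[ok] / (rv / mv)[ok]),
                    expression = rowSums(ribo_counts)[ok],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- c(zero_counts = n_zero, no_polyA = n_polya)
  out
}

#' Local Z-scores for TE changes
#'
#' Expression-binned Z-score of log2 TE change; |Z| > \code{z_out} genes
#' are flagged as outliers.
#'
#' @param te data.frame from \code{\link{translational_efficiency}}.
#' @param bin_size genes per expression bin.
#' @param z_out outlier threshold (default 3).
#' @export
dte_zscores <- function(te, bin_size = 300L, z_out = 3.0) {
  z <- local_zscore(stats::setNames(te$log2_dte, te$gene_id),
                    stats::setNames(te$expression, te$gene_id), bin_size)
  te$z_dte <- as.numeric(z)
  te$outlier <- abs(te$z_dte) > z_out
  te
}

#' Decompose expression changes into ribo-seq and mRNA-seq axes
#'
#' Per gene, the log2 change (treatment over vehicle) in normalized read
#' counts is computed separately for each assay and Z-score-transformed
#' against its own expression bins. Translation-only outliers — the
#' signature of an induced stall with unchanged mRNA — satisfy
#' |z_ribo| >= \code{z_out} and |z_mrna| < \code{z_out}; transcriptional
#' changes move both axes together.
#'
#' @inheritParams translational_efficiency
#' @param bin_size,z_out local Z-score parameters.
#' @return data.frame(gene_id, log2_ribo_change, log2_mrna_change, z_ribo,
#'   z_mrna, translation_only, both_axes).
#' @export
assay_change_decomposition <- function(ribo_counts, mrna_counts,
                                       ribo_condition, mrna_condition,
                                       bin_size = 300L, z_out = 3.0) {
  stopifnot(identical(rownames(ribo_counts), rownames(mrna_counts)))
  ch <- function(counts, condition) {
    n <- normalize_counts(counts)
    v <- rowMeans(n[, condition == "vehicle", drop = FALSE])
    t <- rowMeans(n[, condition == "treatment", drop = FALSE])
    list(change = log2(t / v), expr = rowSums(counts))
  }
  rc <- ch(ribo_counts, ribo_condition)
  mc <- ch(mrna_counts, mrna_condition)
  ok <- is.finite(rc$change) & is.finite(mc$change)
  g <- rownames(ribo_counts)[ok]
  z_ribo <- local_zscore(stats::setNames(rc$change[ok], g),
                         stats::setNames(rc$expr[ok], g), bin_size)
  z_mrna <- local_zscore(stats::setNames(mc$change[ok], g),
                         stats::setNames(mc$expr[ok], g), bin_size)
  out <- data.frame(gene_id = g,
                    log2_ribo_change = rc$change[ok],
                    log2_mrna_change = mc$change[ok],
                    z_ribo = as.numeric(z_ribo), z_mrna = as.numeric(z_mrna),
                    stringsAsFactors = FALSE)
  out$translation_only <- abs(out$z_ribo) >= z_out & abs(out$z_mrna) < z_out
  out$both_axes <- abs(out$z_ribo) >= z_out & abs(out$z_mrna) >= z_out
  rownames(out) <- NULL
  out
}

#' CDS read count matrix from codon maps
#'
#' Convenience: genes x samples matrix of whole-CDS counts, rows named by
#' gene.
#' @param maps named list of \code{codonmap} objects.
#' @param tx transcripts data.frame.
#' @export
cds_count_matrix <- function(maps, tx) {
  one <- function(cm) {
    if (inherits(cm, "codonmap")) {
      vapply(tx$transcript_id, function(id) sum(cm$counts[[id]]), numeric(1))
    } else {
      vapply(seq_len(nrow(tx)), function(i) {
        v <- cm$counts[[tx$transcript_id[i]]]
        sum(v[(tx$utr5_len[i] + 1L):(tx$utr5_len[i] + tx$cds_len[i])])
      }, numeric(1))
    }
  }
  m <- vapply(maps, one, numeric(nrow(tx)))
  matrix(as.integer(round(m)), nrow = nrow(tx),
         dimnames = list(tx$gene_id, names(maps)))
}
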