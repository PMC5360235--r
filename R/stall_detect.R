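# Stall detection: cumulative fractional read (CFR) curves, the D_max
# divergence statistic and its position, expression-binned Z-scores,
# D_max-gated downstream differential expression, sensitive-gene calls,
# and center-of-density shift analysis.
#
# A CFR curve gives, at each codon, the fraction of a transcript's
# footprints aligning at or 5' of that codon. A drug-induced stall makes
# the treatment CFR rise fast 5' of the stall and level off 3' of it;
# D_max is the maximum treatment-minus-vehicle CFR difference and its
# codon (the D_max position) bounds the stall region from the 3' side.

#' Cumulative fractional read curve
#'
#' @param counts per-codon counts for one transcript (total must be > 0;
#'   transcripts without reads are excluded upstream).
#' @return numeric vector in [0,1], nondecreasing, ending at 1.
#' @export
cfr_curve <- function(counts) {
  tot <- sum(counts)
  if (tot <= 0) stop("cfr_curve requires a positive read total")
  cumsum(counts) / tot
}

#' D_max: maximum CFR divergence and its position
#'
#' The statistic is signed — \code{max(cfr_treatment - cfr_vehicle)} — so
#' stalls (treatment reads shifted 5') give positive values. When several
#' codons attain the maximum, the 3'-most is reported: the position's role
#' is to bound the stall region from the 3' side, and for genes with one
#' or more stalls it falls 3' of the last stall.
#'
#' @param cfr_treatment,cfr_vehicle CFR curves over the same codon span.
#' @return list(dmax, dmax_codon) with dmax_codon 1-based.
#' @export
dmax <- function(cfr_treatment, cfr_vehicle) {
  stopifnot(length(cfr_treatment) == length(cfr_vehicle))
  d <- cfr_treatment - cfr_vehicle
  m <- max(d)
  list(dmax = m, dmax_codon = max(which(d >= m - 1e-12)))
}

#' Per-gene D_max table from replicate-pooled codon maps
#'
#' Counts are pooled (summed) across the replicates of each condition
#' before CFR construction. Genes need at least \code{min_reads} pooled
#' CDS reads in each condition; sparser genes are excluded and tallied in
#' the \code{excluded} attribute. \code{expression} is the pooled raw read
#' count across all compared samples, the axis used for local Z-score
#' binning.
#'
#' @param treatment_maps,vehicle_maps lists of \code{codonmap} objects.
#' @param min_reads minimum pooled CDS reads per condition (default 64).
#' @return data.frame(gene_id, transcript_id, dmax, dmax_codon, expression,
#'   n_codons) with attribute \code{excluded}.
#' @export
dmax_table <- function(treatment_maps, vehicle_maps, tx, min_reads = 64L) {
  ct <- pool_codon_maps(treatment_maps)
  cv <- pool_codon_maps(vehicle_maps)
  ids <- intersect(names(ct), names(cv))
  gene_of <- stats::setNames(tx$gene_id, tx$transcript_id)

  res <- vector("list", length(ids)); n_excl <- 0L
  for (i in seq_along(ids)) {
    id <- ids[i]
    a <- ct[[id]]; b <- cv[[id]]
    if (is.null(a) || is.null(b) || sum(a) < min_reads || sum(b) < min_reads) {
      n_excl <- n_excl + 1L
      next
    }
    dm <- dmax(cfr_curve(a), cfr_curve(b))
    res[[i]] <- data.frame(gene_id = gene_of[[id]], transcript_id = id,
                           dmax = dm$dmax, dmax_codon = dm$dmax_codon,
                           expression = sum(a) + sum(b),
                           n_codons = length(a), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(gene_id = character(), transcript_id = character(),
                      dmax = numeric(), dmax_codon = integer(),
                      expression = numeric(), n_codons = integer())
  rownames(out) <- NULL
  attr(out, "excluded") <- c(low_reads = n_excl)
  out
}

#' Null D_max distribution from two vehicle sample sets
#'
#' Computes per-gene D_max between two disjoint vehicle replicate sets.
#' Under the null (no treatment effect) this distribution matches the
#' treatment-vs-vehicle one, which is the basis for choosing the minimum
#' D_max Z-score gate.
#'
#' @inheritParams dmax_table
#' @param vehicle_a,vehicle_b lists of \code{codonmap} objects (disjoint).
#' @export
null_dmax <- function(vehicle_a, vehicle_b, tx, min_reads = 64L) {
  dmax_table(vehicle_a, vehicle_b, tx, min_reads = min_reads)
}

#' 5' boundary codon for downstream differential expression
#'
#' Genes with a D_max Z-score of \code{z_gate} (default 2) or higher use
#' their D_max position; all other genes use codon \code{default_codon}
#' (default 50). "3' of" is strict: the boundary codon itself is excluded
#' from downstream counting.
#'
#' @param dmax_z D_max Z-score(s).
#' @param dmax_codon D_max position(s).
#' @param default_codon fallback boundary (default 50).
#' @param z_gate Z threshold for using the D_max position (default 2,
#'   inclusive).
#' @export
downstream_boundary <- function(dmax_z, dmax_codon, default_codon = 50L,
                                z_gate = 2.0) {
  ifelse(dmax_z >= z_gate, dmax_codon, default_codon)
}

#' Reads mapping strictly 3' of a boundary codon
#' @param counts per-codon counts.
#' @param boundary boundary codon (excluded).
#' @export
downstream_counts <- function(counts, boundary) {
  L <- length(counts)
  if (boundary >= L) return(0L)
  sum(counts[(boundary + 1L):L])
}

#' Differential expression of downstream read counts
#'
#' Negative-binomial test per gene with median-of-ratios library-size
#' normalization, gene-wise dispersions shrunk toward a fitted
#' mean-dispersion trend, and Benjamini-Hochberg FDR across all tested
#' genes in one family (no independent filtering), via DESeq2. Genes with
#' all-zero counts are excluded and tallied.
#'
#' @param counts integer matrix, genes x samples.
#' @param condition factor/character per sample, levels "vehicle" and
#'   "treatment" ("vehicle" is the reference: log2FC is treatment over
#'   vehicle).
#' @return data.frame(gene_id, log2fc, p, fdr) with attribute
#'   \code{excluded}.
#' @export
differential_downstream <- function(counts, condition) {
  stopifnot(ncol(counts) == length(condition))
  condition <- stats::relevel(factor(condition), ref = "vehicle")
  if (any(table(condition) < 2)) stop("need >= 2 replicates per condition")
  nz <- rowSums(counts) > 0
  m <- counts[nz, , drop = FALSE]
  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = m,
    colData = S4Vectors::DataFrame(condition = condition),
    design = ~condition)
  dds <- tryCatch(
    DESeq2::DESeq(dds, quiet = TRUE),
    error = function(e) DESeq2::DESeq(dds, fitType = "local", quiet = TRUE))
  r <- DESeq2::results(dds, contrast = c("condition", "treatment", "vehicle"),
                       independentFiltering = FALSE, cooksCutoff = FALSE)
  out <- data.frame(gene_id = rownames(m), log2fc = r$log2FoldChange,
                    p = r$pvalue, fdr = r$padj, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- c(all_zero = sum(!nz))
  out
}

#' Call stall peaks from a treatment-minus-vehicle codon RPM difference
#'
#' Automatic stand-in for visual inspection of read-density plots: the
#' codon with the highest positive difference 5' of (and including) the
#' boundary is the primary stall; codons reaching at least
#' \code{shoulder_frac} of that peak are reported with it, supporting
#' multi-codon stalls.
#'
#' @param diff_rpm treatment minus vehicle per-codon RPM.
#' @param boundary 3' search limit (codon).
#' @param shoulder_frac fraction of the peak height for secondary calls
#'   (default 0.5).
#' @param min_peak_rpm minimum peak height to report anything (default 0).
#' @return integer vector of stall codons (primary first, then ascending).
#' @export
call_stall_peaks <- function(diff_rpm, boundary, shoulder_frac = 0.5,
                             min_peak_rpm = 0) {
  span <- seq_len(min(boundary, length(diff_rpm)))
  d <- diff_rpm[span]
  pk <- which.max(d)
  if (d[pk] <= min_peak_rpm) return(integer(0))
  others <- setdiff(which(d >= shoulder_frac * d[pk]), pk)
  c(pk, others)
}

#' Count-weighted mean read position (center of density)
#'
#' Mean codon index weighted by read counts, over codons strictly after
#' \code{omit_first}. A 5' shift of the treatment mean relative to vehicle
#' indicates early stalling; repeating the analysis omitting the first 50,
#' 100 and 150 codons localizes stalls to the early CDS.
#'
#' @param counts per-codon counts.
#' @param omit_first codons excluded from the 5' end (default 0).
#' @return mean position in codon units, or NA if no reads in the span.
#' @export
center_of_density <- function(counts, omit_first = 0L) {
  L <- length(counts)
  if (omit_first >= L) return(NA_real_)
  idx <- (omit_first + 1L):L
  w <- counts[idx]
  s <- sum(w)
  if (s == 0) return(NA_real_)
  sum(idx * w) / s
}

#' Center-of-density change between conditions with local Z-scores
#'
#' Per gene: pooled treatment and vehicle mean read positions, their
#' difference (delta = treatment - vehicle; negative for 5' shifts), and
#' the expression-binned Z-score of delta. Genes with |Z| >= \code{z_out}
#' are flagged as outliers.
#'
#' @inheritParams dmax_table
#' @param omit_first codons omitted from the 5' end (0, 50, 100, 150 ...).
#' @param bin_size local Z-score bin size.
#' @param z_out outlier threshold on |Z| (default 3).
#' @return data.frame(gene_id, transcript_id, mean_pos_treatment,
#'   mean_pos_vehicle, delta, expression, zscore, outlier, omit_first).
#' @export
cod_change_zscores <- function(treatment_maps, vehicle_maps, tx,
                               omit_first = 0L, min_reads = 64L,
                               bin_size = 300L, z_out = 3.0) {
  ct <- pool_codon_maps(treatment_maps)
  cv <- pool_codon_maps(vehicle_maps)
  ids <- intersect(names(ct), names(cv))
  gene_of <- stats::setNames(tx$gene_id, tx$transcript_id)

  rows <- lapply(ids, function(id) {
    a <- ct[[id]]; b <- cv[[id]]
    if (is.null(a) || is.null(b)) return(NULL)
    sa <- if (omit_first < length(a)) sum(a[(omit_first + 1L):length(a)]) else 0
    sb <- if (omit_first < length(b)) sum(b[(omit_first + 1L):length(b)]) else 0
    if (sa < min_reads || sb < min_reads) return(NULL)
    mt <- center_of_density(a, omit_first)
    mv <- center_of_density(b, omit_first)
    data.frame(gene_id = gene_of[[id]], transcript_id = id,
               mean_pos_treatment = mt, mean_pos_vehicle = mv,
               delta = mt - mv, expression = sum(a) + sum(b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out) || nrow(out) == 0)
    return(data.frame(gene_id = character(), transcript_id = character(),
                      mean_pos_treatment = numeric(), mean_pos_vehicle = numeric(),
                      delta = numeric(), expression = numeric(), zscore = numeric(),
                      outlier = logical(), omit_first = integer()))
  z <- local_zscore(stats::setNames(out$delta, out$gene_id),
                    stats::setNames(out$expression, out$gene_id), bin_size)
  out$zscore <- as.numeric(z)
  out$outlier <- abs(out$zscore) >= z_out
  out$omit_first <- omit_first
  rownames(out) <- NULL
  out
}

#' Combine D_max, Z-score and differential results into sensitive calls
#'
#' A gene is called sensitive when its D_max Z-score exceeds \code{z_min},
#' its downstream differential FDR is below \code{fdr_max}, and the
#' downstream change is a decrease (log2FC < 0). Stall codons come from
#' \code{\link{call_stall_peaks}} on the treatment-minus-vehicle RPM codon
#' profile 5' of the boundary.
#'
#' @param dm data.frame from \code{\link{dmax_table}} with a \code{zscore}
#'   column added.
#' @param de data.frame from \code{\link{differential_downstream}}.
#' @param boundary named integer vector (gene -> boundary codon).
#' @param diff_rpm named list (transcript -> treatment-minus-vehicle RPM
#'   per codon), or NULL to skip peak calling.
#' @param z_min,fdr_max call thresholds (defaults 2.0 and 0.1).
#' @return StallResult data.frame.
#' @export
call_sensitive <- function(dm, de, boundary, diff_rpm = NULL,
                           z_min = 2.0, fdr_max = 0.1) {
  m <- merge(dm, de, by = "gene_id", all.x = TRUE)
  m$boundary <- as.integer(boundary[m$gene_id])
  m$sensitive <- !is.na(m$fdr) & m$zscore > z_min & m$fdr < fdr_max &
    m$log2fc < 0
  m$stall_codons <- vector("list", nrow(m))
  if (!is.null(diff_rpm)) {
    for (i in which(m$sensitive)) {
      d <- diff_rpm[[m$transcript_id[i]]]
      if (!is.null(d))
        m$stall_codons[[i]] <- call_stall_peaks(d, m$boundary[i])
    }
  }
  m[order(m$gene_id), ]
}

#' Full stall-detection analysis on codon maps
#'
#' Runs the complete per-timepoint analysis: replicate-pooled CFR and
#' D_max per gene, expression-binned D_max Z-scores, boundary selection
#' (D_max position for Z >= \code{z_gate}, codon \code{default_codon}
#' otherwise), per-replicate downstream counts, negative-binomial
#' differential expression, sensitive-gene calls with stall-peak
#' positions, and center-of-density changes at each \code{omit_first}
#' value.
#'
#' Genes whose CDS has no codon 3' of their boundary (CDS shorter than the
#' default boundary with a sub-threshold Z) are excluded from the
#' differential step and tallied.
#'
#' @param maps named list of \code{codonmap} objects (ribo assay).
#' @param design data.frame(sample_id, condition) with condition in
#'   {"vehicle","treatment"}; sample_id must match \code{names(maps)}.
#' @param tx transcripts data.frame.
#' @param params list of tuning parameters; see
#'   \code{\link{default_params}}.
#' @return list(stalls = StallResult data.frame, dmax = D_max table,
#'   cod = center-of-density results by omit_first, excluded = tallies).
#' @export
detect_stalls <- function(maps, design, tx, params = default_params()) {
  p <- utils::modifyList(default_params(), params)
  stopifnot(all(design$sample_id %in% names(maps)))
  tmaps <- maps[design$sample_id[design$condition == "treatment"]]
  vmaps <- maps[design$sample_id[design$condition == "vehicle"]]

  dm <- dmax_table(tmaps, vmaps, tx, min_reads = p$min_reads)
  z <- local_zscore(stats::setNames(dm$dmax, dm$gene_id),
                    stats::setNames(dm$expression, dm$gene_id), p$bin_size)
  dm$zscore <- as.numeric(z)

  bnd <- downstream_boundary(dm$zscore, dm$dmax_codon,
                             default_codon = p$default_codon, z_gate = p$z_min)
  names(bnd) <- dm$gene_id
  testable <- bnd < dm$n_codons
  n_short <- sum(!testable)

  dmt <- dm[testable, ]
  bnd_t <- bnd[testable]
  cnt <- sapply(design$sample_id, function(s) {
    vapply(seq_len(nrow(dmt)), function(i)
      downstream_counts(maps[[s]]$counts[[dmt$transcript_id[i]]], bnd_t[i]),
      numeric(1))
  })
  cnt <- matrix(as.integer(round(cnt)), nrow = nrow(dmt),
                dimnames = list(dmt$gene_id, design$sample_id))
  de <- differential_downstream(cnt, design$condition)

  diff_rpm <- .condition_diff_rpm(tmaps, vmaps, dmt$transcript_id)
  stalls <- call_sensitive(dmt, de, bnd_t, diff_rpm,
                           z_min = p$z_min, fdr_max = p$fdr_max)

  cod <- lapply(p$omit_first, function(k)
    cod_change_zscores(tmaps, vmaps, tx, omit_first = k,
                       min_reads = p$min_reads, bin_size = p$bin_size,
                       z_out = p$cod_z_min))
  names(cod) <- as.character(p$omit_first)

  list(stalls = stalls, dmax = dm, cod = cod,
       excluded = c(attr(dm, "excluded"), boundary_beyond_cds = n_short,
                    attr(de, "excluded")))
}

# Treatment-minus-vehicle mean replicate RPM per codon for the given
# transcripts.
.condition_diff_rpm <- function(tmaps, vmaps, transcript_ids) {
  out <- vector("list", length(transcript_ids))
  names(out) <- transcript_ids
  for (id in transcript_ids) {
    rt <- rowMeans(vapply(tmaps, function(m)
      normalize_rpm(m$counts[[id]], m$total_cds_reads),
      numeric(length(tmaps[[1]]$counts[[id]]))))
    rv <- rowMeans(vapply(vmaps, function(m)
      normalize_rpm(m$counts[[id]], m$total_cds_reads),
      numeric(length(vmaps[[1]]$counts[[id]]))))
    out[[id]] <- rt - rv
  }
  out
}

#' Default stall-detection parameters
#'
#' \itemize{
#'   \item \code{min_reads} 64: minimum pooled CDS reads per condition for
#'     CFR/D_max and center-of-density inclusion.
#'   \item \code{bin_size} 300: genes per expression bin for local Z.
#'   \item \code{z_min} 2.0: D_max Z gate (boundary choice uses >=, the
#'     sensitive call uses >).
#'   \item \code{fdr_max} 0.1: BH FDR threshold on the downstream decrease.
#'   \item \code{default_codon} 50: boundary for genes below the Z gate.
#'   \item \code{cod_z_min} 3.0: center-of-density outlier |Z| threshold.
#'   \item \code{omit_first} c(0,50,100,150): 5' spans omitted in the
#'     center-of-density variants.
#' }
#' @export
default_params <- function() {
  list(min_reads = 64L, bin_size = 300L, z_min = 2.0, fdr_max = 0.1,
       default_codon = 50L, cod_z_min = 3.0, omit_first = c(0L, 50L, 100L, 150L))
}
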