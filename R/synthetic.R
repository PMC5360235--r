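# Synthetic ribosome-profiling experiment generator with known stall
# ground truth. The generator emulates the observable signature of
# compound-induced elongation stalling: a footprint pile-up at a known
# codon, attenuated footprint density 3' of it (the readthrough fraction),
# 3-nt periodicity within codons, negative-binomial count noise across
# biological replicates, and mRNA-seq coverage that is unchanged by
# treatment. It does NOT model sequence-dependent stall propensity, rRNA
# contamination, or footprint-length heterogeneity at stalls.

.SENSE_CODONS <- setdiff(
  as.vector(outer(as.vector(outer(c("A","C","G","T"), c("A","C","G","T"), paste0)),
                  c("A","C","G","T"), paste0)),
  c("TAA", "TAG", "TGA"))

.random_seq <- function(n) {
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.scrub_atg <- function(s) {
  while (grepl("ATG", s, fixed = TRUE)) s <- sub("ATG", "ACG", s, fixed = TRUE)
  s
}

#' Simulate a reference transcriptome with per-gene simulation specs
#'
#' Generates random transcripts (5'UTR + CDS + 3'UTR) with a valid start
#' and stop codon and no in-frame internal stop in the main ORF. A
#' fraction \code{uorf_rate} of transcripts carry a planted AUG in the
#' 5'UTR; the remaining 5'UTRs are scrubbed of AUGs, so \code{uorf_rate =
#' 0} yields no 5'UTR AUG anywhere. A fraction \code{paralog_rate} of
#' genes get a near-identical paralog (1\% diverged) for multi-mapping
#' tests. Baseline expression is log-normal (median 100 expected CDS
#' footprints before depth scaling, ~10-fold spread), with NB dispersion
#' 0.01 — typical biological-replicate overdispersion for count data of
#' this kind.
#'
#' @param n_genes number of genes.
#' @param seed RNG seed (mandatory; same seed gives identical output).
#' @param utr5_range,cds_codon_range,utr3_range uniform length ranges; CDS
#'   range is in codons (incl. start and stop).
#' @param uorf_rate fraction of transcripts with a planted 5'UTR AUG.
#' @param paralog_rate fraction of genes with a near-identical paralog.
#' @param with_sequence set FALSE to skip sequence generation (lengths
#'   only) for large count-level simulations.
#' @return list(transcripts, specs): the transcript table and the per-gene
#'   GeneSpec table (no stalls implanted yet; see
#'   \code{\link{implant_stalls}}).
#' @export
simulate_transcriptome <- function(n_genes, seed,
                                   utr5_range = c(30L, 300L),
                                   cds_codon_range = c(150L, 700L),
                                   utr3_range = c(50L, 400L),
                                   uorf_rate = 0.3, paralog_rate = 0,
                                   with_sequence = TRUE) {
  set.seed(seed)
  gid <- sprintf("g%05d", seq_len(n_genes))
  tid <- sprintf("t%05d", seq_len(n_genes))
  u5 <- sample(utr5_range[1]:utr5_range[2], n_genes, replace = TRUE)
  nc <- sample(cds_codon_range[1]:cds_codon_range[2], n_genes, replace = TRUE)
  u3 <- sample(utr3_range[1]:utr3_range[2], n_genes, replace = TRUE)

  seqs <- character(n_genes)
  if (with_sequence) {
    carries <- stats::runif(n_genes) < uorf_rate
    for (i in seq_len(n_genes)) {
      utr5 <- .scrub_atg(.random_seq(u5[i]))
      if (carries[i] && u5[i] >= 6) {
        p <- sample.int(u5[i] - 5L, 1L)  # room for ATG + stop downstream
        substr(utr5, p, p + 2L) <- "ATG"
      }
      cds <- paste0("ATG",
                    paste(sample(.SENSE_CODONS, nc[i] - 2L, replace = TRUE),
                          collapse = ""),
                    sample(c("TAA", "TAG", "TGA"), 1L))
      seqs[i] <- paste0(utr5, cds, .random_seq(u3[i]))
    }
  }
  tx <- data.frame(transcript_id = tid, gene_id = gid,
                   utr5_len = u5, cds_len = 3L * nc, utr3_len = u3,
                   sequence = seqs, stringsAsFactors = FALSE)
  specs <- data.frame(
    gene_id = gid, transcript_id = tid, n_codons = nc,
    base_expression = stats::rlnorm(n_genes, log(100), 1),
    dispersion = 0.01,
    stall_codon = NA_integer_, stall_amplitude = 0, readthrough = 1,
    p_frame0 = 0.70, p_frame1 = 0.15, p_frame2 = 0.15,
    peak_width = 1L, queue_shoulders = FALSE,
    has_polyA = TRUE, transcription_fold = 1, n_paralog_copies = 1L,
    stringsAsFactors = FALSE)

  if (paralog_rate > 0) {
    par_of <- which(stats::runif(n_genes) < paralog_rate)
    for (i in par_of) {
      s <- seqs[i]
      if (with_sequence && nchar(s) > 0) {
        mut <- sample.int(nchar(s), max(1L, nchar(s) %/% 100L))
        for (p in mut) substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1L)
      }
      tx <- rbind(tx, data.frame(
        transcript_id = paste0(tid[i], "p"), gene_id = paste0(gid[i], "p"),
        utr5_len = u5[i], cds_len = 3L * nc[i], utr3_len = u3[i],
        sequence = s, stringsAsFactors = FALSE))
      sp <- specs[i, ]
      sp$gene_id <- paste0(gid[i], "p"); sp$transcript_id <- paste0(tid[i], "p")
      specs <- rbind(specs, sp)
      specs$n_paralog_copies[i] <- 2L
      specs$n_paralog_copies[nrow(specs)] <- 2L
    }
    rownames(tx) <- rownames(specs) <- NULL
  }
  list(transcripts = tx, specs = specs)
}

#' Implant treatment-specific stalls into gene specs
#'
#' A stall is a multiplicative footprint peak of height
#' \code{1 + stall_amplitude} at the stall codon (optionally spread over
#' \code{peak_width} codons) with density 3' of it attenuated to
#' \code{readthrough} times the vehicle level. \code{readthrough = 1} with
#' \code{stall_amplitude = 0} means no stall. The defaults echo the
#' canonical target-transcript case: an early-CDS stall (codon 34) with
#' strong downstream attenuation.
#'
#' @param specs GeneSpec table.
#' @param gene_ids genes to modify.
#' @param stall_codon stall codon(s), recycled.
#' @param stall_amplitude peak height above baseline (default 8).
#' @param readthrough fraction of ribosome flux continuing 3' of the stall
#'   under treatment (default 0.25).
#' @param peak_width codons the stall peak spans, ending at the stall codon
#'   (default 1; toeprinting shows stalls can cover several codons).
#' @param queue_shoulders add secondary peaks (one third of the stall
#'   amplitude) 10 and 20 codons 5' of the stall, emulating queued
#'   ribosomes behind the arrest site (off by default).
#' @export
implant_stalls <- function(specs, gene_ids, stall_codon = 34L,
                           stall_amplitude = 8, readthrough = 0.25,
                           peak_width = 1L, queue_shoulders = FALSE) {
  i <- match(gene_ids, specs$gene_id)
  stopifnot(!anyNA(i))
  sc <- rep_len(stall_codon, length(i))
  stopifnot(all(sc >= 1L & sc <= specs$n_codons[i]),
            peak_width >= 1L, peak_width <= 5L)
  specs$stall_codon[i] <- sc
  specs$stall_amplitude[i] <- rep_len(stall_amplitude, length(i))
  specs$readthrough[i] <- rep_len(readthrough, length(i))
  specs$peak_width[i] <- as.integer(peak_width)
  specs$queue_shoulders[i] <- queue_shoulders
  specs
}

.is_stalled <- function(spec) {
  !is.na(spec$stall_codon) &&
    (spec$stall_amplitude > 0 || spec$readthrough < 1)
}

# Relative per-codon footprint weights under treatment (vehicle = all 1).
.treatment_shape <- function(spec) {
  L <- spec$n_codons
  sh <- rep(1, L)
  if (!.is_stalled(spec)) return(sh)
  s <- spec$stall_codon
  w <- if (is.null(spec$peak_width) || is.na(spec$peak_width)) 1L
       else spec$peak_width
  peak <- max(1L, s - w + 1L):s
  sh[peak] <- 1 + spec$stall_amplitude
  if (isTRUE(spec$queue_shoulders)) {
    for (q in c(s - 10L, s - 20L))
      if (q >= 1L) sh[q] <- 1 + spec$stall_amplitude / 3
  }
  if (s < L) sh[(s + 1):L] <- spec$readthrough
  sh
}

#' Expected per-codon footprint density for one gene
#'
#' Vehicle density is flat: \code{base_expression / n_codons} per codon.
#' Under treatment a stalled gene keeps the vehicle density 5' of the
#' stall, has \code{(1 + stall_amplitude)} times it at the stall codon,
#' and \code{readthrough} times it 3' of the stall — so the
#' downstream/upstream density ratio is exactly \code{readthrough}, and
#' the expected downstream log2 change is \code{log2(readthrough)}.
#'
#' @param spec one row of the GeneSpec table.
#' @param condition "vehicle" or "treatment".
#' @return numeric vector of expected reads per codon (vehicle total =
#'   base_expression).
#' @export
expected_density <- function(spec, condition = c("vehicle", "treatment")) {
  condition <- match.arg(condition)
  base <- spec$base_expression / spec$n_codons
  if (condition == "treatment") base * .treatment_shape(spec)
  else rep(base, spec$n_codons)
}

#' Closed-form expected D_max for a stalled gene spec
#'
#' For a single stall at codon s with amplitude A and readthrough r in a
#' CDS of L codons, the treatment CFR exceeds the vehicle CFR maximally at
#' the stall codon: \code{(s + A)/T - s/L} with
#' \code{T = s + A + (L - s) r}. Returns 0 for unstalled specs.
#' @param spec one GeneSpec row.
#' @export
expected_dmax <- function(spec) {
  if (!.is_stalled(spec)) return(0)
  L <- spec$n_codons; s <- spec$stall_codon
  A <- spec$stall_amplitude; r <- spec$readthrough
  T_ <- s + A + (L - s) * r
  (s + A) / T_ - s / L
}

#' Simulate a full profiling experiment from gene specs
#'
#' Per sample, per-gene totals are negative binomial with mean
#' (gene allocation) x depth — the allocation being the gene's share of
#' baseline expression times its condition/assay flux multiplier — and
#' positions are multinomial under \code{\link{expected_density}}.
#' Footprint P-sites are spread over the three codon positions with the
#' gene's frame weights (3-nt periodicity). mRNA-seq fragments ignore all
#' stall parameters (coverage uniform over the whole transcript,
#' treatment-invariant) except that genes lacking a poly-A tail are
#' downweighted by \code{polyA_factor} in both conditions, emulating
#' poly-A selection. A \code{transcription_fold} other than 1 scales both
#' assays under treatment (a transcriptional, not translational, change).
#'
#' @param specs GeneSpec table (see \code{\link{simulate_transcriptome}},
#'   \code{\link{implant_stalls}}).
#' @param tx transcripts data.frame (coordinate frame; sequences not
#'   required).
#' @param design data.frame(sample_id, condition, replicate, assay); see
#'   \code{\link{sim_design}}.
#' @param depth expected reads per sample (default 2e6).
#' @param seed RNG seed (mandatory).
#' @param level "codon" for \code{codonmap} output (ribo only; compact) or
#'   "nt" for full-resolution \code{readmap}s. mRNA maps are always
#'   nucleotide-resolution.
#' @param polyA_factor mRNA-seq recovery of non-poly-A genes (default 0.1).
#' @return list(maps = named list keyed by sample_id, truth = SimTruth
#'   data.frame).
#' @export
simulate_experiment <- function(specs, tx, design, depth = 2e6, seed,
                                level = c("codon", "nt"), polyA_factor = 0.1) {
  level <- match.arg(level)
  set.seed(seed)
  n <- nrow(specs)
  share <- specs$base_expression / sum(specs$base_expression)
  u5 <- stats::setNames(tx$utr5_len, tx$transcript_id)[specs$transcript_id]
  tx_len <- stats::setNames(tx$utr5_len + tx$cds_len + tx$utr3_len,
                            tx$transcript_id)[specs$transcript_id]

  shapes_v <- lapply(seq_len(n), function(i) rep(1, specs$n_codons[i]))
  shapes_t <- lapply(seq_len(n), function(i) .treatment_shape(specs[i, ]))
  flux_t <- vapply(seq_len(n), function(i)
    sum(shapes_t[[i]]) / specs$n_codons[i], numeric(1))

  maps <- vector("list", nrow(design))
  names(maps) <- design$sample_id
  for (j in seq_len(nrow(design))) {
    cond <- design$condition[j]; assay <- design$assay[j]
    mult <- rep(1, n)
    if (cond == "treatment") {
      mult <- specs$transcription_fold
      if (assay == "ribo") mult <- mult * flux_t
    }
    if (assay == "mrna") mult <- mult * ifelse(specs$has_polyA, 1, polyA_factor)
    mu <- share * mult * depth
    tot <- integer(n)
    od <- specs$dispersion > 0
    if (any(od))
      tot[od] <- stats::rnbinom(sum(od), mu = mu[od],
                                size = 1 / specs$dispersion[od])
    if (any(!od)) tot[!od] <- stats::rpois(sum(!od), mu[!od])

    counts <- vector("list", n)
    names(counts) <- specs$transcript_id
    if (assay == "ribo") {
      for (i in seq_len(n)) {
        sh <- if (cond == "treatment") shapes_t[[i]] else shapes_v[[i]]
        cc <- as.integer(stats::rmultinom(1, tot[i], sh))
        if (level == "codon") {
          counts[[i]] <- cc
        } else {
          f0 <- stats::rbinom(length(cc), cc, specs$p_frame0[i])
          rest <- cc - f0
          f1 <- stats::rbinom(length(cc), rest,
                              specs$p_frame1[i] /
                                (specs$p_frame1[i] + specs$p_frame2[i]))
          f2 <- rest - f1
          v <- integer(tx_len[i])
          base_nt <- u5[i] + 3L * (seq_along(cc) - 1L)
          v[base_nt + 1L] <- f0
          v[base_nt + 2L] <- f1
          v[base_nt + 3L] <- f2
          counts[[i]] <- v
        }
      }
      total_cds <- sum(vapply(counts, sum, numeric(1)))
      maps[[j]] <- structure(
        list(sample_id = design$sample_id[j], assay = assay, counts = counts,
             total_cds_reads = total_cds,
             dropped = c(off_reference = 0L, psite_out_of_bounds = 0L)),
        class = if (level == "codon") "codonmap" else "readmap")
    } else {
      for (i in seq_len(n))
        counts[[i]] <- tabulate(sample.int(tx_len[i], tot[i], replace = TRUE),
                                nbins = tx_len[i])
      total_cds <- 0
      for (i in seq_len(n))
        total_cds <- total_cds +
          sum(counts[[i]][(u5[i] + 1L):(u5[i] + 3L * specs$n_codons[i])])
      maps[[j]] <- structure(
        list(sample_id = design$sample_id[j], assay = assay, counts = counts,
             total_cds_reads = total_cds,
             dropped = c(off_reference = 0L, psite_out_of_bounds = 0L)),
        class = "readmap")
    }
  }

  truth <- data.frame(
    gene_id = specs$gene_id,
    stalled = vapply(seq_len(n), function(i) .is_stalled(specs[i, ]), logical(1)),
    stall_codon = specs$stall_codon,
    readthrough = specs$readthrough,
    expected_cds_log2fc = log2(flux_t * specs$transcription_fold),
    expected_downstream_log2fc = log2(specs$readthrough),
    stringsAsFactors = FALSE)
  list(maps = maps, truth = truth)
}

#' Standard two-condition replicate design
#'
#' @param n_rep replicates per condition (default 3).
#' @param assays assays to include (default ribo and mrna).
#' @return data.frame(sample_id, condition, replicate, assay).
#' @export
sim_design <- function(n_rep = 3L, assays = c("ribo", "mrna")) {
  g <- expand.grid(replicate = seq_len(n_rep),
                   condition = c("vehicle", "treatment"),
                   assay = assays, stringsAsFactors = FALSE)
  g$sample_id <- paste(g$assay, g$condition, g$replicate, sep = "_")
  g[, c("sample_id", "condition", "replicate", "assay")]
}

#' Convert a nucleotide read map to alignment records
#'
#' Inverts P-site assignment: each counted P-site becomes one alignment
#' with \code{pos5 = psite - offset} and a random footprint length in
#' 26-34 nt. P-sites closer than \code{offset} to the transcript 5' end
#' cannot be represented and are skipped. Used to exercise the ingestion
#' path end-to-end against maps of known content.
#'
#' @param rm_ a \code{readmap}.
#' @param offset P-site offset the ingest step will re-apply.
#' @return alignment data.frame (read_id, transcript_id, pos5, read_len).
#' @export
readmap_to_alignments <- function(rm_, offset = 14L) {
  rows <- lapply(names(rm_$counts), function(id) {
    v <- rm_$counts[[id]]
    nz <- which(v > 0)
    nz <- nz[nz - 1L >= offset]
    if (!length(nz)) return(NULL)
    pos <- rep(nz - 1L - offset, v[nz])
    data.frame(transcript_id = id, pos5 = pos, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    return(data.frame(read_id = character(), transcript_id = character(),
                      pos5 = integer(), read_len = integer()))
  out$read_id <- sprintf("r%07d", seq_len(nrow(out)))
  out$read_len <- sample(26:34, nrow(out), replace = TRUE)
  out[, c("read_id", "transcript_id", "pos5", "read_len")]
}
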