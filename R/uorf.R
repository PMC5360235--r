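# Upstream ORF enumeration and quantification. A uORF initiates at an AUG
# whose first nucleotide lies within the 5'UTR and runs to the first
# in-frame stop codon anywhere downstream in the transcript (the stop may
# fall inside the CDS; such uORFs overlap the main ORF and are flagged).

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Enumerate candidate uORFs in one transcript
#'
#' Every AUG starting in the 5'UTR is paired with the first downstream
#' in-frame stop codon; AUGs without one are excluded. Nested and
#' overlapping uORFs are all reported.
#'
#' @param sequence transcript sequence (5'UTR + CDS + 3'UTR).
#' @param utr5_len 5'UTR length (nt).
#' @return data.frame(start_nt, stop_nt, n_codons, overlaps_cds) with
#'   0-based start_nt (the A of AUG) and stop_nt (first nt of the stop
#'   codon); n_codons includes the stop codon.
#' @export
enumerate_uorfs <- function(sequence, utr5_len) {
  empty <- data.frame(start_nt = integer(), stop_nt = integer(),
                      n_codons = integer(), overlaps_cds = logical())
  if (is.na(sequence) || nchar(sequence) == 0 || utr5_len == 0) return(empty)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  starts <- gregexpr("ATG", substr(sequence, 1L, utr5_len + 2L), fixed = TRUE)[[1]]
  starts <- starts[starts > 0] - 1L            # to 0-based
  starts <- starts[starts < utr5_len]          # A of AUG in the 5'UTR
  if (!length(starts)) return(empty)

  rows <- lapply(starts, function(s) {
    p <- s + 3L
    while (p + 3L <= L) {
      codon <- substr(sequence, p + 1L, p + 3L)
      if (codon %in% .STOP_CODONS)
        return(data.frame(start_nt = s, stop_nt = p,
                          n_codons = (p - s) %/% 3L + 1L,
                          overlaps_cds = (p + 2L) >= utr5_len))
      p <- p + 3L
    }
    NULL
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) empty else out
}

#' Enumerate uORFs across a transcript set
#'
#' Transcripts without sequence are skipped and tallied in the
#' \code{skipped} attribute.
#' @param tx transcripts data.frame with a \code{sequence} column.
#' @export
enumerate_uorfs_all <- function(tx) {
  rows <- lapply(seq_len(nrow(tx)), function(i) {
    if (is.na(tx$sequence[i]) || tx$sequence[i] == "") return(NULL)
    u <- enumerate_uorfs(tx$sequence[i], tx$utr5_len[i])
    if (nrow(u) == 0) return(NULL)
    cbind(data.frame(transcript_id = tx$transcript_id[i],
                     stringsAsFactors = FALSE), u)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(transcript_id = character(), start_nt = integer(),
                      stop_nt = integer(), n_codons = integer(),
                      overlaps_cds = logical())
  n_noseq <- sum(is.na(tx$sequence) | tx$sequence == "")
  attr(out, "skipped") <- c(no_sequence = n_noseq)
  out
}

#' Quantify footprint occupancy of one uORF
#'
#' Counts P-site positions within [start_nt, stop_nt + 3) and the fraction
#' of those reads in each reading frame relative to the uORF start (a
#' translated uORF shows frame-0 dominance, i.e. 3-nt periodicity in its
#' own frame).
#'
#' @param nt_counts per-nucleotide counts for the transcript.
#' @param start_nt,stop_nt uORF coordinates (0-based).
#' @return list(count, frame_fractions); frame_fractions is NA (flagged)
#'   when the span holds no reads.
#' @export
quantify_uorf <- function(nt_counts, start_nt, stop_nt) {
  span <- (start_nt + 1L):(stop_nt + 3L)
  v <- nt_counts[span]
  total <- sum(v)
  if (total == 0)
    return(list(count = 0L, frame_fractions = rep(NA_real_, 3)))
  frame <- (seq_along(v) - 1L) %% 3L
  ff <- vapply(0:2, function(f) sum(v[frame == f]), numeric(1)) / total
  list(count = total, frame_fractions = ff)
}

#' Replicate-consistency test for treatment-induced uORF changes
#'
#' A uORF is flagged iff every treatment replicate's normalized count
#' strictly exceeds every vehicle replicate's (complete rank separation) —
#' a reading of "an increase consistent across replicates". Normalization
#' is reads-per-million CDS-aligned reads per sample. Under the null with
#' 3 vs 3 replicates the flag rate is 1/C(6,3) = 1/20.
#'
#' @param counts uORFs x samples matrix of raw uORF read counts.
#' @param totals named per-sample total CDS-aligned reads.
#' @param condition per-sample "vehicle"/"treatment".
#' @return data.frame(flagged, log2fc) row-aligned to \code{counts}.
#' @export
uorf_consistency_test <- function(counts, totals, condition) {
  stopifnot(ncol(counts) == length(condition))
  rpm <- sweep(counts, 2, totals[colnames(counts)], "/") * 1e6
  tr <- rpm[, condition == "treatment", drop = FALSE]
  ve <- rpm[, condition == "vehicle", drop = FALSE]
  flagged <- apply(tr, 1, min) > apply(ve, 1, max)
  log2fc <- log2(rowMeans(tr) / rowMeans(ve))
  data.frame(flagged = flagged, log2fc = log2fc, row.names = rownames(counts))
}

#' Quantify all uORFs across samples and test replicate consistency
#'
#' @param uorfs data.frame from \code{\link{enumerate_uorfs_all}}.
#' @param maps named list of \code{readmap} objects (nt resolution).
#' @param design data.frame(sample_id, condition).
#' @return uORF table with per-sample counts, frame fractions from pooled
#'   counts, flag and log2fc.
#' @export
uorf_scan <- function(uorfs, maps, design) {
  if (nrow(uorfs) == 0) return(uorfs)
  cnt <- vapply(design$sample_id, function(s) {
    m <- maps[[s]]
    vapply(seq_len(nrow(uorfs)), function(i)
      quantify_uorf(m$counts[[uorfs$transcript_id[i]]],
                    uorfs$start_nt[i], uorfs$stop_nt[i])$count, numeric(1))
  }, numeric(nrow(uorfs)))
  cnt <- matrix(cnt, nrow = nrow(uorfs),
                dimnames = list(NULL, design$sample_id))
  totals <- vapply(maps[design$sample_id], function(m)
    as.numeric(m$total_cds_reads), numeric(1))
  ct <- uorf_consistency_test(cnt, totals, design$condition)

  ff <- t(vapply(seq_len(nrow(uorfs)), function(i) {
    v <- Reduce(`+`, lapply(maps[design$sample_id], function(m)
      m$counts[[uorfs$transcript_id[i]]]))
    quantify_uorf(v, uorfs$start_nt[i], uorfs$stop_nt[i])$frame_fractions
  }, numeric(3)))
  colnames(ff) <- paste0("frame", 0:2)
  cbind(uorfs, as.data.frame(cnt), ff,
        data.frame(flagged = ct$flagged, log2fc = ct$log2fc))
}
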