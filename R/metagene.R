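# Metagene (normalized mean read, NMR) profiles around start and stop
# codons. The NMR at an offset is the across-transcript mean of
# count(offset) / (CDS total / CDS length), i.e. position density over mean
# CDS density, so a uniform library gives NMR = 1 everywhere.

#' Normalized mean read profile around the start or stop codon
#'
#' Offset 0 is the first nucleotide of the start codon (anchor "start") or
#' the first nucleotide of the stop codon (anchor "stop"). Per gene, only
#' the annotated transcript with the longest CDS is considered. A
#' transcript contributes only if its CDS is at least \code{min_cds_len}
#' nt, the whole window lies within the transcript, and it has nonzero CDS
#' reads (the mean-density denominator must be positive; empty transcripts
#' are excluded rather than contributing 0/0).
#'
#' @param rm_ a \code{readmap} (nucleotide resolution).
#' @param tx transcripts data.frame.
#' @param anchor "start" or "stop".
#' @param window integer c(lo, hi), offsets in nt relative to the anchor;
#'   defaults -50..300 for start, -300..50 for stop.
#' @param min_cds_len minimum CDS length (nt) for inclusion.
#' @return data.frame(anchor, offset, nmr, n_transcripts).
#' @export
normalized_mean_profile <- function(rm_, tx, anchor = c("start", "stop"),
                                    window = NULL, min_cds_len = 600L) {
  anchor <- match.arg(anchor)
  if (is.null(window)) window <- if (anchor == "start") c(-50L, 300L) else c(-300L, 50L)
  stopifnot(window[1] <= window[2])
  offsets <- window[1]:window[2]

  # longest CDS per gene
  o <- order(tx$gene_id, -tx$cds_len, tx$transcript_id)
  txl <- tx[o, ][!duplicated(tx$gene_id[o]), ]

  anchor_nt <- if (anchor == "start") txl$utr5_len else txl$utr5_len + txl$cds_len - 3L
  tx_len <- txl$utr5_len + txl$cds_len + txl$utr3_len
  fits <- txl$cds_len >= min_cds_len &
    anchor_nt + window[1] >= 0L & anchor_nt + window[2] < tx_len
  txl <- txl[fits, ]; anchor_nt <- anchor_nt[fits]
  if (nrow(txl) == 0) stop("no transcript accommodates the requested window")

  acc <- numeric(length(offsets)); n_used <- 0L
  for (i in seq_len(nrow(txl))) {
    v <- rm_$counts[[txl$transcript_id[i]]]
    cds <- v[(txl$utr5_len[i] + 1L):(txl$utr5_len[i] + txl$cds_len[i])]
    tot <- sum(cds)
    if (tot == 0) next
    dens <- tot / txl$cds_len[i]
    acc <- acc + v[anchor_nt[i] + offsets + 1L] / dens
    n_used <- n_used + 1L
  }
  if (n_used == 0) stop("no transcript with nonzero CDS reads in the window set")
  data.frame(anchor = anchor, offset = offsets, nmr = acc / n_used,
             n_transcripts = n_used, stringsAsFactors = FALSE)
}

#' Smooth a metagene profile with a centered moving average
#'
#' @param profile data.frame from \code{\link{normalized_mean_profile}}.
#' @param k odd window width in nt (default 3); edges are truncated to the
#'   available span rather than padded.
#' @export
smooth_profile <- function(profile, k = 3L) {
  stopifnot(k >= 1L, k %% 2L == 1L)
  if (k == 1L) return(profile)
  h <- (k - 1L) %/% 2L
  v <- profile$nmr
  n <- length(v)
  sm <- vapply(seq_len(n), function(i)
    mean(v[max(1L, i - h):min(n, i + h)]), numeric(1))
  profile$nmr <- sm
  profile
}
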