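# Reference transcriptome assembly and isoform selection.
#
# Transcript coordinates throughout the package are 0-based, half-open and
# transcript-local. The CDS occupies [utr5_len, utr5_len + cds_len); codon k
# (1-based, codon 1 = start codon) occupies nucleotides
# [utr5_len + 3*(k-1), utr5_len + 3*k).

#' Assemble transcript records from per-region sequences
#'
#' Concatenates 5'UTR, CDS and 3'UTR sequences (in that order) into single
#' transcript records and builds the region-length table that serves as the
#' coordinate frame for all downstream analyses. UTR records are optional;
#' an absent region has length zero. Transcripts whose CDS length is not a
#' multiple of 3, or is shorter than 6 nt (start codon plus at least one
#' more codon), are quarantined to a rejects table rather than repaired or
#' silently dropped.
#'
#' @param cds_records named character vector (or \code{DNAStringSet}) of CDS
#'   sequences; every transcript must have one.
#' @param utr5_records,utr3_records optional named character vectors of UTR
#'   sequences; transcripts absent from them get a zero-length region.
#' @param id_to_gene named character vector mapping transcript_id to
#'   gene_id. If \code{NULL}, ids of the form \code{"transcript|gene"}
#'   (Ensembl BioMart header dialect) are split; otherwise gene_id is set to
#'   the transcript_id.
#' @return list with \code{transcripts} (data.frame: transcript_id, gene_id,
#'   utr5_len, cds_len, utr3_len, sequence) and \code{rejects} (data.frame:
#'   transcript_id, reason).
#' @export
assemble_transcripts <- function(cds_records, utr5_records = NULL,
                                 utr3_records = NULL, id_to_gene = NULL) {
  cds_records  <- .as_seq_vector(cds_records)
  utr5_records <- .as_seq_vector(utr5_records)
  utr3_records <- .as_seq_vector(utr3_records)
  for (v in list(cds_records, utr5_records, utr3_records)) {
    if (length(v) && anyDuplicated(names(v)))
      stop("duplicate transcript id in region records: ",
           paste(unique(names(v)[duplicated(names(v))]), collapse = ", "))
  }

  raw_ids <- names(cds_records)
  if (is.null(id_to_gene) && any(grepl("|", raw_ids, fixed = TRUE))) {
    parts <- strsplit(raw_ids, "|", fixed = TRUE)
    tid <- vapply(parts, `[`, "", 1L)
    gid <- vapply(parts, function(p) if (length(p) >= 2) p[2] else p[1], "")
    names(cds_records) <- tid
    if (length(utr5_records))
      names(utr5_records) <- vapply(strsplit(names(utr5_records), "|", fixed = TRUE), `[`, "", 1L)
    if (length(utr3_records))
      names(utr3_records) <- vapply(strsplit(names(utr3_records), "|", fixed = TRUE), `[`, "", 1L)
    id_to_gene <- stats::setNames(gid, tid)
    if (anyDuplicated(tid)) stop("duplicate transcript id after header parsing")
  }
  ids <- names(cds_records)
  genes <- if (is.null(id_to_gene)) ids else unname(id_to_gene[ids])
  genes[is.na(genes)] <- ids[is.na(genes)]

  u5 <- ifelse(ids %in% names(utr5_records), utr5_records[ids], "")
  u3 <- ifelse(ids %in% names(utr3_records), utr3_records[ids], "")
  u5[is.na(u5)] <- ""; u3[is.na(u3)] <- ""
  cds_len <- nchar(cds_records)

  bad <- cds_len %% 3L != 0L | cds_len < 6L
  reason <- ifelse(cds_len %% 3L != 0L, "CDS not multiple of 3", "CDS shorter than 6 nt")
  rejects <- data.frame(transcript_id = ids[bad], reason = reason[bad],
                        stringsAsFactors = FALSE)

  keep <- !bad
  tx <- data.frame(
    transcript_id = ids[keep],
    gene_id = genes[keep],
    utr5_len = nchar(u5)[keep],
    cds_len = cds_len[keep],
    utr3_len = nchar(u3)[keep],
    sequence = paste0(u5, cds_records, u3)[keep],
    stringsAsFactors = FALSE)
  rownames(tx) <- NULL
  list(transcripts = tx, rejects = rejects)
}

.as_seq_vector <- function(x) {
  if (is.null(x)) return(character(0))
  if (methods::is(x, "XStringSet")) {
    stats::setNames(as.character(x), names(x))
  } else {
    stopifnot(is.character(x), !is.null(names(x)))
    x
  }
}

#' Select one representative isoform per gene by abundance
#'
#' In \code{"best"} mode (the default reference used for stall detection)
#' the most abundant splice isoform of each gene is kept, provided its TPM
#' is at least \code{min_tpm} (inclusive). In \code{"fraction"} mode all
#' isoforms contributing at least \code{min_fraction} of their gene's total
#' TPM are kept, for genes whose total TPM passes \code{min_tpm}; this
#' supports the broader alternative reference used to check that no targets
#' are missed by single-isoform collapsing.
#'
#' TPM ties between isoforms are broken by lexicographically smaller
#' transcript_id so that the output is deterministic. Output is sorted by
#' gene_id.
#'
#' @param abundance data.frame with columns transcript_id, gene_id, tpm.
#' @param min_tpm inclusive TPM threshold (default 1.0).
#' @param mode "best" or "fraction".
#' @param min_fraction minimum isoform share of gene TPM in fraction mode.
#' @return character vector of transcript ids.
#' @export
select_representative_isoforms <- function(abundance, min_tpm = 1.0,
                                           mode = c("best", "fraction"),
                                           min_fraction = 0.1) {
  mode <- match.arg(mode)
  stopifnot(nrow(abundance) > 0, all(abundance$tpm >= 0),
            !anyDuplicated(abundance$transcript_id))
  ab <- abundance[order(abundance$gene_id, -abundance$tpm, abundance$transcript_id), ]
  if (mode == "best") {
    best <- ab[!duplicated(ab$gene_id), ]
    best$transcript_id[best$tpm >= min_tpm]
  } else {
    tot <- tapply(ab$tpm, ab$gene_id, sum)
    ab$gene_total <- as.numeric(tot[ab$gene_id])
    keep <- ab$gene_total >= min_tpm & ab$gene_total > 0 &
      ab$tpm / ab$gene_total >= min_fraction
    ab$transcript_id[keep]
  }
}

#' Subset a multi-FASTA by an id list
#'
#' Records are written in the order of the id list. Ids absent from the
#' input are omitted and returned in \code{missing} (with a warning).
#'
#' @param seqs named character vector or \code{DNAStringSet}.
#' @param ids character vector of ids to keep.
#' @return list(records, missing).
#' @export
filter_fasta_by_ids <- function(seqs, ids) {
  nm <- names(seqs)
  missing <- setdiff(ids, nm)
  if (length(missing))
    warning(length(missing), " id(s) absent from reference: ",
            paste(utils::head(missing, 5), collapse = ", "))
  list(records = seqs[ids[ids %in% nm]], missing = missing)
}

#' Write a transcript set to FASTA plus a region-length table
#' @param tx transcripts data.frame from \code{\link{assemble_transcripts}}.
#' @param fasta_path,lengths_path output paths (FASTA may be NULL to skip).
#' @export
write_transcriptome <- function(tx, fasta_path = NULL, lengths_path = NULL) {
  if (!is.null(fasta_path)) {
    ss <- Biostrings::DNAStringSet(stats::setNames(tx$sequence, tx$transcript_id))
    Biostrings::writeXStringSet(ss, fasta_path)
  }
  if (!is.null(lengths_path)) {
    utils::write.table(tx[, c("transcript_id", "gene_id", "utr5_len",
                              "cds_len", "utr3_len")],
                       lengths_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(tx)
}

#' Read a transcript set back from FASTA plus a region-length table
#' @param fasta_path combined transcript FASTA (optional; lengths-only sets
#'   have an empty sequence column).
#' @param lengths_path TSV with transcript_id, gene_id, utr5_len, cds_len,
#'   utr3_len.
#' @export
read_transcriptome <- function(lengths_path, fasta_path = NULL) {
  tx <- utils::read.table(lengths_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!is.null(fasta_path)) {
    ss <- Biostrings::readDNAStringSet(fasta_path)
    nm <- sub("\\s.*$", "", names(ss))
    tx$sequence <- as.character(ss)[match(tx$transcript_id, nm)]
  } else {
    tx$sequence <- ""
  }
  ok <- tx$sequence == "" |
    nchar(tx$sequence) == tx$utr5_len + tx$cds_len + tx$utr3_len
  if (!all(ok)) stop("sequence length disagrees with region lengths for: ",
                     paste(utils::head(tx$transcript_id[!ok], 5), collapse = ", "))
  tx
}

# Number of codons (incl. stop) in each transcript's CDS.
cds_codons <- function(tx) tx$cds_len %/% 3L
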