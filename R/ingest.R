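# Alignment ingestion: read-length filtering, multi-map resolution, P-site
# assignment, and nucleotide/codon read maps with RPM normalization.
#
# Alignments are represented as a data.frame with columns read_id,
# transcript_id, pos5 (0-based 5' end on the transcript), read_len, and
# optionally n_best_sites (count of equal-best alignment sites for the
# read; computed from the emitted best-stratum records when absent).

#' Read transcriptome-coordinate alignments
#'
#' Accepts either a 4-column TSV (read_id, transcript_id, pos5, read_len;
#' with header) or SAM/BAM in transcript coordinates. SAM/BAM ingestion
#' takes the leftmost aligned position as pos5; reverse-strand and unmapped
#' records are discarded and tallied in the \code{dropped} attribute, since
#' transcriptome alignments of footprints are forward-strand.
#'
#' @param path input file.
#' @param format "auto" (by extension), "tsv", "sam" or "bam".
#' @return alignment data.frame with a \code{dropped} attribute (named
#'   integer tallies).
#' @export
read_alignments <- function(path, format = c("auto", "tsv", "sam", "bam")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sam", "bam")) ext else "tsv"
  }
  if (format == "tsv") {
    aln <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    stopifnot(all(c("read_id", "transcript_id", "pos5", "read_len") %in% names(aln)))
    attr(aln, "dropped") <- c(unmapped = 0L, reverse_strand = 0L)
    return(aln)
  }
  bam <- if (format == "sam") {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else path
  p <- Rsamtools::ScanBamParam(what = c("qname", "rname", "pos", "qwidth", "flag"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  unmapped <- bitwAnd(b$flag, 4L) != 0L
  reverse <- bitwAnd(b$flag, 16L) != 0L & !unmapped
  keep <- !unmapped & !reverse
  aln <- data.frame(read_id = b$qname[keep],
                    transcript_id = as.character(b$rname[keep]),
                    pos5 = b$pos[keep] - 1L,   # SAM POS is 1-based
                    read_len = b$qwidth[keep],
                    stringsAsFactors = FALSE)
  attr(aln, "dropped") <- c(unmapped = sum(unmapped), reverse_strand = sum(reverse))
  aln
}

#' Filter alignments by footprint length
#'
#' Retains alignments with read length in \code{[min_len, max_len]}, both
#' bounds inclusive — the conventional 26-34 nt ribosome-protected fragment
#' range by default.
#'
#' @param aln alignment data.frame.
#' @param min_len,max_len inclusive bounds (nt).
#' @export
filter_read_lengths <- function(aln, min_len = 26L, max_len = 34L) {
  if (min_len > max_len) stop("min_len > max_len")
  aln[aln$read_len >= min_len & aln$read_len <= max_len, , drop = FALSE]
}

#' Resolve multi-mapping reads
#'
#' Each read's records are its equal-best alignment sites (the aligner's
#' best stratum). Reads with more than \code{max_sites} equal-best sites
#' are discarded entirely; for surviving reads exactly one record is kept,
#' chosen deterministically as the first by (transcript_id, pos5). If an
#' \code{n_best_sites} column is present it is trusted; otherwise it is the
#' number of records per read_id.
#'
#' @param aln alignment data.frame (best-stratum records).
#' @param max_sites maximum tolerated equal-best sites (default 5).
#' @return one-record-per-read data.frame with a \code{dropped} attribute
#'   counting multimap-discarded reads.
#' @export
apply_multimap_policy <- function(aln, max_sites = 5L) {
  if (nrow(aln) == 0) {
    attr(aln, "dropped") <- c(multimap = 0L)
    return(aln)
  }
  o <- order(aln$read_id, aln$transcript_id, aln$pos5)
  a <- aln[o, , drop = FALSE]
  if (is.null(a$n_best_sites)) {
    sizes <- table(a$read_id)
    a$n_best_sites <- as.integer(sizes[a$read_id])
  }
  first <- !duplicated(a$read_id)
  kept <- a[first & a$n_best_sites <= max_sites, , drop = FALSE]
  n_reads <- sum(first)
  rownames(kept) <- NULL
  attr(kept, "dropped") <- c(multimap = n_reads - nrow(kept))
  kept
}

#' Infer the P-site position from a footprint 5' end
#'
#' The ribosomal P-site is assigned a fixed offset 3' of the footprint's 5'
#' end; the default of 14 nt places the first major footprint peak at
#' nucleotide +2 relative to the start codon. Out-of-bounds positions are
#' handled (dropped and tallied) by \code{\link{build_readmap}}.
#'
#' @param pos5 0-based 5'-end positions (vectorized).
#' @param offset P-site offset in nt (default 14).
#' @export
assign_psite <- function(pos5, offset = 14L) pos5 + offset

#' Build a P-site-assigned nucleotide read map
#'
#' Places each alignment's inferred P-site on its transcript and counts
#' occupancy per nucleotide. mRNA-seq fragments are not ribosome footprints
#' and get no offset: when \code{assay = "mrna"} and \code{offset} is left
#' \code{NULL}, the fragment 5' end is counted directly.
#'
#' Read accounting is conserved: reads in = reads placed + reads dropped
#' (off-reference + P-site out of bounds), recorded in \code{dropped}.
#'
#' @param aln length-filtered, multimap-resolved alignments.
#' @param tx transcripts data.frame (coordinate frame).
#' @param sample_id,assay sample annotation; assay is "ribo" or "mrna".
#' @param offset P-site offset; \code{NULL} means 14 for ribo, 0 for mrna.
#' @return object of class \code{readmap}: list(sample_id, assay, counts =
#'   named list of per-transcript integer vectors, total_cds_reads,
#'   dropped).
#' @export
build_readmap <- function(aln, tx, sample_id = "sample", assay = c("ribo", "mrna"),
                          offset = NULL) {
  assay <- match.arg(assay)
  if (is.null(offset)) offset <- if (assay == "ribo") 14L else 0L
  tx_len <- stats::setNames(tx$utr5_len + tx$cds_len + tx$utr3_len, tx$transcript_id)

  known <- aln$transcript_id %in% names(tx_len)
  psite <- assign_psite(aln$pos5, offset)
  inb <- known & psite >= 0L & psite < tx_len[aln$transcript_id]
  inb[is.na(inb)] <- FALSE

  counts <- lapply(stats::setNames(tx$transcript_id, tx$transcript_id), function(id)
    integer(tx_len[[id]]))
  placed <- split(psite[inb], aln$transcript_id[inb])
  for (id in names(placed))
    counts[[id]] <- tabulate(placed[[id]] + 1L, nbins = tx_len[[id]])

  cds_total <- 0L
  for (i in seq_len(nrow(tx))) {
    id <- tx$transcript_id[i]
    if (tx$cds_len[i] > 0)
      cds_total <- cds_total +
        sum(counts[[id]][(tx$utr5_len[i] + 1L):(tx$utr5_len[i] + tx$cds_len[i])])
  }
  structure(list(sample_id = sample_id, assay = assay, counts = counts,
                 total_cds_reads = cds_total,
                 dropped = c(off_reference = sum(!known),
                             psite_out_of_bounds = sum(known & !inb))),
            class = "readmap")
}

#' @export
print.readmap <- function(x, ...) {
  cat("readmap:", x$sample_id, sprintf("(%s)", x$assay),
      length(x$counts), "transcripts,",
      x$total_cds_reads, "CDS reads;",
      "dropped:", paste(names(x$dropped), x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Collapse a nucleotide read map to CDS codon resolution
#'
#' Codon k (1-based) sums the three nucleotides at
#' \code{[utr5_len + 3(k-1), utr5_len + 3k)}; reads outside the CDS are
#' excluded, so codon totals never exceed the source map totals.
#'
#' @param rm_ a \code{readmap}.
#' @param tx transcripts data.frame.
#' @return object of class \code{codonmap}: list(sample_id, assay, counts =
#'   named list of per-codon integer vectors, total_cds_reads).
#' @export
collapse_to_codons <- function(rm_, tx) {
  stopifnot(inherits(rm_, "readmap"))
  counts <- vector("list", nrow(tx))
  names(counts) <- tx$transcript_id
  for (i in seq_len(nrow(tx))) {
    id <- tx$transcript_id[i]
    v <- rm_$counts[[id]]
    if (is.null(v)) next
    cds <- v[(tx$utr5_len[i] + 1L):(tx$utr5_len[i] + tx$cds_len[i])]
    counts[[id]] <- as.integer(.colSums(cds, 3L, tx$cds_len[i] %/% 3L))
  }
  structure(list(sample_id = rm_$sample_id, assay = rm_$assay, counts = counts,
                 total_cds_reads = rm_$total_cds_reads),
            class = "codonmap")
}

#' Reads-per-million normalization
#'
#' Divides counts by the total number of reads aligning to protein-coding
#' regions and scales by 1e6.
#'
#' @param x numeric vector, or a list of per-transcript vectors.
#' @param total_cds_reads library-size denominator; must be positive.
#' @export
normalize_rpm <- function(x, total_cds_reads) {
  if (total_cds_reads <= 0) stop("total_cds_reads must be positive")
  if (is.list(x)) lapply(x, function(v) v / total_cds_reads * 1e6)
  else x / total_cds_reads * 1e6
}

#' Pool codon maps by summing counts per transcript
#'
#' Used to combine biological replicates before CFR/D_max computation.
#'
#' @param maps list of \code{codonmap} objects over the same reference.
#' @return named list of summed per-codon numeric vectors.
#' @export
pool_codon_maps <- function(maps) {
  stopifnot(length(maps) > 0)
  out <- maps[[1]]$counts
  for (m in maps[-1]) {
    for (id in names(out)) {
      v <- m$counts[[id]]
      if (!is.null(v)) out[[id]] <- out[[id]] + v
    }
  }
  out
}

# Mean of per-replicate RPM maps for one transcript (readplot-style density).
#' Average replicate RPM density for a transcript
#' @param maps list of \code{readmap} or \code{codonmap} objects.
#' @param transcript_id transcript to extract.
#' @export
mean_rpm_profile <- function(maps, transcript_id) {
  mats <- vapply(maps,
                 function(m) normalize_rpm(m$counts[[transcript_id]], m$total_cds_reads),
                 numeric(length(maps[[1]]$counts[[transcript_id]])))
  rowMeans(mats)
}

#' Write read/codon maps as sparse TSV
#'
#' One row per nonzero position: sample_id, transcript_id, position, count.
#' Positions are 0-based nucleotides for read maps and 1-based codons for
#' codon maps.
#' @param maps list of \code{readmap}/\code{codonmap} objects.
#' @param path output TSV.
#' @export
write_sparse_maps <- function(maps, path) {
  rows <- lapply(maps, function(m) {
    per_tx <- lapply(names(m$counts), function(id) {
      v <- m$counts[[id]]
      nz <- which(v != 0)
      if (!length(nz)) return(NULL)
      pos <- if (inherits(m, "codonmap")) nz else nz - 1L
      data.frame(sample_id = m$sample_id, transcript_id = id,
                 position = pos, count = v[nz], stringsAsFactors = FALSE)
    })
    do.call(rbind, per_tx)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample_id = character(), transcript_id = character(),
                      position = integer(), count = integer())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sparse TSV maps back into codonmap/readmap objects
#' @param path sparse TSV from \code{\link{write_sparse_maps}}.
#' @param tx transcripts data.frame.
#' @param level "codon" or "nt".
#' @param assay assay label to attach.
#' @export
read_sparse_maps <- function(path, tx, level = c("codon", "nt"), assay = "ribo") {
  level <- match.arg(level)
  d <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  n_at <- if (level == "codon") stats::setNames(cds_codons(tx), tx$transcript_id)
          else stats::setNames(tx$utr5_len + tx$cds_len + tx$utr3_len, tx$transcript_id)
  lapply(split(d, d$sample_id), function(ds) {
    counts <- lapply(stats::setNames(names(n_at), names(n_at)),
                     function(id) integer(n_at[[id]]))
    for (id in unique(ds$transcript_id)) {
      di <- ds[ds$transcript_id == id, ]
      idx <- if (level == "codon") di$position else di$position + 1L
      v <- integer(n_at[[id]]); v[idx] <- di$count
      counts[[id]] <- v
    }
    total <- if (level == "codon") sum(unlist(lapply(counts, sum))) else {
      s <- 0L
      for (i in seq_len(nrow(tx))) {
        id <- tx$transcript_id[i]
        s <- s + sum(counts[[id]][(tx$utr5_len[i] + 1L):(tx$utr5_len[i] + tx$cds_len[i])])
      }
      s
    }
    structure(list(sample_id = ds$sample_id[1], assay = assay, counts = counts,
                   total_cds_reads = total),
              class = if (level == "codon") "codonmap" else "readmap")
  })
}
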