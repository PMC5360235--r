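# Independent brute-force oracles, deliberately written as plain loops so
# they share no code with the package implementations they check.

bf_cfr <- function(counts) {
  out <- numeric(length(counts))
  tot <- sum(counts)
  run <- 0
  for (i in seq_along(counts)) {
    run <- run + counts[i]
    out[i] <- run / tot
  }
  out
}

bf_dmax <- function(cfr_t, cfr_v) {
  best <- -Inf
  pos <- NA_integer_
  for (i in seq_along(cfr_t)) {
    d <- cfr_t[i] - cfr_v[i]
    if (d >= best - 1e-12) {
      if (d > best) best <- d
      pos <- i
    }
  }
  list(dmax = best, dmax_codon = pos)
}

bf_downstream <- function(counts, boundary) {
  s <- 0
  for (i in seq_along(counts)) if (i > boundary) s <- s + counts[i]
  s
}

bf_center <- function(counts, omit_first = 0) {
  num <- 0; den <- 0
  for (i in seq_along(counts)) {
    if (i > omit_first) { num <- num + i * counts[i]; den <- den + counts[i] }
  }
  if (den == 0) NA_real_ else num / den
}

bf_collapse <- function(nt_counts, utr5_len, n_codons) {
  out <- integer(n_codons)
  for (k in seq_len(n_codons)) {
    for (j in 0:2) out[k] <- out[k] + nt_counts[utr5_len + 3 * (k - 1) + j + 1]
  }
  out
}

bf_uorfs <- function(sequence, utr5_len) {
  stops <- c("TAA", "TAG", "TGA")
  L <- nchar(sequence)
  res <- list()
  for (s in 0:(utr5_len - 1)) {
    if (substr(sequence, s + 1, s + 3) != "ATG") next
    p <- s + 3
    found <- NA_integer_
    while (p + 3 <= L) {
      if (substr(sequence, p + 1, p + 3) %in% stops) { found <- p; break }
      p <- p + 3
    }
    if (!is.na(found))
      res[[length(res) + 1]] <- data.frame(
        start_nt = s, stop_nt = found,
        n_codons = (found - s) / 3 + 1,
        overlaps_cds = (found + 2) >= utr5_len)
  }
  if (!length(res))
    return(data.frame(start_nt = integer(), stop_nt = integer(),
                      n_codons = integer(), overlaps_cds = logical()))
  do.call(rbind, res)
}

# Small random fixtures ------------------------------------------------------

random_codon_counts <- function(n_codons, lambda = 2) {
  rpois(n_codons, lambda)
}

# A tiny transcript table for unit tests.
tiny_tx <- function() {
  data.frame(
    transcript_id = c("tA", "tB"),
    gene_id = c("gA", "gB"),
    utr5_len = c(12L, 6L),
    cds_len = c(30L, 18L),
    utr3_len = c(8L, 0L),
    sequence = "",
    stringsAsFactors = FALSE)
}

# Build a codonmap object directly from a named list of count vectors.
make_codonmap <- function(counts, sample_id = "s", assay = "ribo") {
  structure(list(sample_id = sample_id, assay = assay, counts = counts,
                 total_cds_reads = sum(unlist(counts))),
            class = "codonmap")
}

make_readmap <- function(counts, tx, sample_id = "s", assay = "ribo") {
  cds_total <- 0
  for (i in seq_len(nrow(tx))) {
    v <- counts[[tx$transcript_id[i]]]
    cds_total <- cds_total +
      sum(v[(tx$utr5_len[i] + 1):(tx$utr5_len[i] + tx$cds_len[i])])
  }
  structure(list(sample_id = sample_id, assay = assay, counts = counts,
                 total_cds_reads = cds_total,
                 dropped = c(off_reference = 0L, psite_out_of_bounds = 0L)),
            class = "readmap")
}
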