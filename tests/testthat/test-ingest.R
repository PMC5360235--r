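make_aln <- function(...) {
  d <- data.frame(..., stringsAsFactors = FALSE)
  names(d) <- c("read_id", "transcript_id", "pos5", "read_len")[seq_along(d)]
  d
}

test_that("footprint length filter is inclusive on both bounds", {
  aln <- make_aln(sprintf("r%d", 1:4), "tA", c(0L, 1L, 2L, 3L),
                  c(25L, 26L, 34L, 35L))
  kept <- filter_read_lengths(aln)
  expect_equal(kept$read_len, c(26L, 34L))
  expect_equal(nrow(filter_read_lengths(aln, 1L, 1000L)), 4L)
  expect_error(filter_read_lengths(aln, 30L, 20L), "min_len")
})

test_that("multimap policy discards >5-site reads and breaks ties deterministically", {
  six <- make_aln(rep("rx", 6), sprintf("t%d", 1:6), rep(0L, 6), rep(28L, 6))
  unique_read <- make_aln("ru", "tQ", 7L, 30L)
  two <- make_aln(rep("r2", 2), c("B", "A"), c(10L, 50L), rep(29L, 2))
  res <- apply_multimap_policy(rbind(six, unique_read, two))
  expect_false("rx" %in% res$read_id)
  expect_equal(attr(res, "dropped")[["multimap"]], 1L)
  expect_equal(res$transcript_id[res$read_id == "ru"], "tQ")
  # tie-break: first by (transcript_id, pos5)
  expect_equal(res$transcript_id[res$read_id == "r2"], "A")
  expect_equal(res$pos5[res$read_id == "r2"], 50L)
  # a provided n_best_sites column is trusted over the record count
  tagged <- make_aln("rt", "tZ", 0L, 28L)
  tagged$n_best_sites <- 9L
  expect_equal(nrow(apply_multimap_policy(tagged)), 0L)
})

test_that("P-site offset lands the first footprint peak at CDS position +2", {
  # transcript with utr5_len 12: read 5' end at 0 -> P-site nt 14 -> +2 in CDS
  expect_equal(assign_psite(0L), 14L)
  expect_equal(assign_psite(14L, offset = 0L), 14L)
  expect_equal(assign_psite(0L, 14L) - 12L, 2L)
})

test_that("readmap placement, CDS totals, and read conservation", {
  tx <- tiny_tx()  # tA: utr5 12, cds 30, utr3 8 -> length 50
  aln <- make_aln(sprintf("r%d", 1:5),
                  c("tA", "tA", "tA", "unknown", "tA"),
                  c(0L, 0L, 20L, 0L, 45L), rep(28L, 5))
  rm_ <- build_readmap(aln, tx, sample_id = "s1", assay = "ribo")
  expect_equal(rm_$counts$tA[15], 2L)        # two P-sites at nt 14 (0-based)
  expect_equal(rm_$counts$tA[35], 1L)
  expect_equal(rm_$dropped[["off_reference"]], 1L)
  expect_equal(rm_$dropped[["psite_out_of_bounds"]], 1L)  # pos5 45 + 14 >= 50
  placed <- sum(unlist(rm_$counts))
  expect_equal(placed + sum(rm_$dropped), nrow(aln))
  expect_equal(rm_$total_cds_reads, 3L)      # nts 14 and 34 are CDS, 14 in [12,42)
  # mRNA assay: no offset
  rm_m <- build_readmap(aln[1:2, ], tx, assay = "mrna")
  expect_equal(rm_m$counts$tA[1], 2L)
})

test_that("per-transcript readmap sums equal per-transcript input reads", {
  set.seed(7)
  tx <- tiny_tx()
  n <- 200
  ids <- sample(tx$transcript_id, n, replace = TRUE)
  len <- ifelse(ids == "tA", 50L, 24L)
  aln <- make_aln(sprintf("r%04d", 1:n), ids,
                  vapply(len, function(l) sample.int(l, 1) - 1L, integer(1)),
                  rep(30L, n))
  rm_ <- build_readmap(aln, tx, offset = 0L)
  tallied <- table(aln$transcript_id)
  for (id in names(tallied))
    expect_equal(sum(rm_$counts[[id]]), as.integer(tallied[[id]]))
})

test_that("codon collapse matches the brute-force oracle on random maps", {
  set.seed(11)
  for (rep in 1:50) {
    u5 <- sample(0:20, 1)
    nc <- sample(3:40, 1)
    u3 <- sample(0:15, 1)
    tx <- data.frame(transcript_id = "t", gene_id = "g", utr5_len = u5,
                     cds_len = 3L * nc, utr3_len = u3, sequence = "")
    v <- rpois(u5 + 3 * nc + u3, 1)
    rm_ <- make_readmap(list(t = v), tx)
    cm <- collapse_to_codons(rm_, tx)
    expect_equal(cm$counts$t, bf_collapse(v, u5, nc))
    expect_lte(sum(cm$counts$t), sum(v))
  }
})

test_that("codon counts within one codon sum and UTR reads are excluded", {
  tx <- tiny_tx()
  v <- integer(50)
  v[12 + 3 * 4 + 1:3] <- c(1L, 2L, 3L)   # codon 5 of tA
  v[3] <- 7L                             # 5'UTR read
  cm <- collapse_to_codons(make_readmap(list(tA = v, tB = integer(24)), tx), tx)
  expect_equal(cm$counts$tA[5], 6L)
  expect_equal(sum(cm$counts$tA), 6L)
})

test_that("RPM normalization scales by CDS total x 1e6 and conserves mass", {
  expect_equal(normalize_rpm(4, 2e6), 2.0)
  expect_equal(normalize_rpm(numeric(5), 100), numeric(5))
  expect_error(normalize_rpm(1, 0), "positive")
  v <- rpois(300, 3)
  expect_equal(sum(normalize_rpm(v, sum(v))), 1e6)
})

test_that("averaged replicate density equals the mean of per-replicate RPM", {
  set.seed(3)
  tx <- tiny_tx()
  maps <- lapply(1:3, function(i)
    make_readmap(list(tA = rpois(50, 2), tB = rpois(24, 2)), tx,
                 sample_id = paste0("s", i)))
  avg <- mean_rpm_profile(maps, "tA")
  manual <- rowMeans(sapply(maps, function(m)
    m$counts$tA / m$total_cds_reads * 1e6))
  expect_equal(avg, manual)
})

test_that("SAM ingestion takes leftmost position and drops reverse/unmapped", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:tA\tLN:50",
    paste0("r1\t0\ttA\t1\t42\t28M\t*\t0\t0\t", strrep("A", 28), "\t*"),
    paste0("r2\t16\ttA\t5\t42\t28M\t*\t0\t0\t", strrep("A", 28), "\t*"),
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\tAAAA\t*"), sam)
  aln <- read_alignments(sam)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$pos5, 0L)          # SAM POS 1 -> 0-based
  expect_equal(aln$read_len, 28L)
  expect_equal(attr(aln, "dropped")[["reverse_strand"]], 1L)
  expect_equal(attr(aln, "dropped")[["unmapped"]], 1L)
})

test_that("sparse map TSV round trip preserves codon and nt maps", {
  set.seed(5)
  tx <- tiny_tx()
  cm <- make_codonmap(list(tA = rpois(10, 1), tB = rpois(6, 1)), "s1")
  f <- tempfile(fileext = ".tsv")
  write_sparse_maps(list(cm), f)
  back <- read_sparse_maps(f, tx, level = "codon")
  expect_equal(back$s1$counts$tA, cm$counts$tA)
  expect_equal(back$s1$counts$tB, cm$counts$tB)
})
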