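test_that("CFR arithmetic, monotonicity, and terminal value", {
  expect_equal(cfr_curve(c(2, 0, 3, 5)), c(0.2, 0.2, 0.5, 1.0))
  expect_equal(cfr_curve(c(7, 0, 0)), c(1, 1, 1))
  L <- 20
  expect_equal(cfr_curve(rep(1, L)), (1:L) / L)
  expect_error(cfr_curve(integer(5)), "positive")
  set.seed(41)
  for (i in 1:20) {
    cc <- random_codon_counts(sample(5:80, 1))
    cc[1] <- cc[1] + 1
    f <- cfr_curve(cc)
    expect_false(is.unsorted(f))
    expect_equal(f[length(f)], 1)
  }
})

test_that("D_max: identity, 3'-most tie-break, antisymmetry", {
  a <- cfr_curve(c(1, 2, 3))
  expect_equal(dmax(a, a)$dmax, 0)
  r <- dmax(c(0.5, 0.75, 1.0), c(0.25, 0.5, 1.0))
  expect_equal(r$dmax, 0.25)
  expect_equal(r$dmax_codon, 2L)      # codons 1 and 2 tie; 3'-most wins
  b <- cfr_curve(c(3, 1, 1))
  expect_equal(dmax(a, b)$dmax, max(a - b))
  expect_equal(dmax(b, a)$dmax, max(b - a))
  expect_equal(dmax(a, b)$dmax, -min(b - a))  # antisymmetry under swap
})

test_that("D_max equals the brute-force oracle on 600 random curve pairs", {
  set.seed(43)
  for (i in 1:600) {
    L <- sample(4:120, 1)
    ct <- random_codon_counts(L); ct[sample(L, 1)] <- ct[sample(L, 1)] + 5
    cv <- random_codon_counts(L)
    ct[1] <- ct[1] + 1; cv[1] <- cv[1] + 1
    ft <- cfr_curve(ct); fv <- cfr_curve(cv)
    got <- dmax(ft, fv)
    want <- bf_dmax(ft, fv)
    expect_equal(got$dmax, want$dmax)
    expect_equal(got$dmax_codon, want$dmax_codon)
  }
})

test_that("downstream boundary follows the Z gate and counting is strictly 3'", {
  expect_equal(downstream_boundary(2.5, 34L), 34L)
  expect_equal(downstream_boundary(1.0, 34L), 50L)
  expect_equal(downstream_boundary(2.0, 10L), 10L)   # gate is inclusive
  expect_equal(downstream_counts(c(1, 2, 3, 4), 2L), 7)
  expect_equal(downstream_counts(c(1, 2, 3, 4), 4L), 0L)
  expect_equal(downstream_counts(c(1, 2, 3, 4), 9L), 0L)
  set.seed(47)
  for (i in 1:600) {
    cc <- random_codon_counts(sample(3:100, 1))
    b <- sample(0:(length(cc) + 2), 1)
    expect_equal(downstream_counts(cc, b), bf_downstream(cc, b))
  }
})

test_that("center of density: symmetry, point mass, and oracle equivalence", {
  L <- 11
  expect_equal(center_of_density(rep(2, L)), (L + 1) / 2)
  v <- integer(30); v[7] <- 5L
  expect_equal(center_of_density(v), 7)
  expect_true(is.na(center_of_density(integer(10))))
  expect_true(is.na(center_of_density(rep(1, 5), omit_first = 5L)))
  set.seed(53)
  for (i in 1:600) {
    cc <- random_codon_counts(sample(3:100, 1))
    k <- sample(0:3, 1) * 10L
    expect_equal(center_of_density(cc, k), bf_center(cc, k))
  }
})

test_that("dmax_table pools replicates, gates sparse genes, and reports expression", {
  set.seed(59)
  tx <- data.frame(transcript_id = c("t1", "t2"), gene_id = c("g1", "g2"),
                   utr5_len = 0L, cds_len = c(300L, 300L), utr3_len = 0L,
                   sequence = "")
  rich <- lapply(1:2, function(i)
    make_codonmap(list(t1 = rpois(100, 3), t2 = rpois(100, 0.1)),
                  sample_id = paste0("v", i)))
  treat <- lapply(1:2, function(i)
    make_codonmap(list(t1 = rpois(100, 3), t2 = rpois(100, 0.1)),
                  sample_id = paste0("t", i)))
  dm <- dmax_table(treat, rich, tx, min_reads = 64L)
  expect_equal(dm$gene_id, "g1")       # t2 falls below min_reads
  expect_equal(attr(dm, "excluded")[["low_reads"]], 1L)
  pooled_t <- treat[[1]]$counts$t1 + treat[[2]]$counts$t1
  pooled_v <- rich[[1]]$counts$t1 + rich[[2]]$counts$t1
  want <- bf_dmax(bf_cfr(pooled_t), bf_cfr(pooled_v))
  expect_equal(dm$dmax, want$dmax)
  expect_equal(dm$dmax_codon, want$dmax_codon)
  expect_equal(dm$expression, sum(pooled_t) + sum(pooled_v))
})

test_that("identical replicate sets give an all-zero null D_max", {
  m <- make_codonmap(list(t1 = rpois(50, 2) + 1L))
  tx <- data.frame(transcript_id = "t1", gene_id = "g1", utr5_len = 0L,
                   cds_len = 150L, utr3_len = 0L, sequence = "")
  nd <- null_dmax(list(m), list(m), tx, min_reads = 1L)
  expect_equal(nd$dmax, 0)
})

test_that("differential test recovers a known two-fold downstream decrease", {
  set.seed(61)
  n <- 400
  mu <- exp(runif(n, log(50), log(2000)))
  veh <- sapply(1:3, function(i) rnbinom(n, mu = mu, size = 50))
  tre <- sapply(1:3, function(i) rnbinom(n, mu = mu, size = 50))
  halved <- 1:40
  tre[halved, ] <- sapply(1:3, function(i)
    rnbinom(length(halved), mu = mu[halved] / 2, size = 50))
  counts <- cbind(veh, tre)
  rownames(counts) <- sprintf("g%03d", 1:n)
  de <- differential_downstream(counts, rep(c("vehicle", "treatment"), each = 3))
  expect_equal(mean(de$log2fc[halved]), -1, tolerance = 0.1)
  expect_lt(abs(median(de$log2fc[-halved])), 0.1)
  expect_gt(mean(de$fdr[halved] < 0.1), 0.9)
})

test_that("all-zero genes are excluded and identical columns give ~zero log2FC", {
  cnt <- matrix(rpois(60, 20), nrow = 10)
  cnt <- cbind(cnt[, 1:3], cnt[, 1:3])   # treatment duplicates vehicle
  cnt[3, ] <- 0L
  rownames(cnt) <- sprintf("g%02d", 1:10)
  # dispersion-trend fitting grumbles on a 9-gene toy matrix; irrelevant here
  de <- suppressWarnings(
    differential_downstream(cnt, rep(c("vehicle", "treatment"), each = 3)))
  expect_equal(attr(de, "excluded")[["all_zero"]], 1L)
  expect_false("g03" %in% de$gene_id)
  expect_equal(de$log2fc, rep(0, 9), tolerance = 1e-6)
})

test_that("stall peak caller finds the primary codon and 50% shoulders", {
  d <- c(rep(0, 20), 2.1, 4.0, 2.2, rep(0, 30))
  pk <- call_stall_peaks(d, boundary = 40L)
  expect_equal(pk[1], 22L)
  expect_setequal(pk, c(21L, 22L, 23L))
  expect_equal(call_stall_peaks(rep(0, 50), 40L, min_peak_rpm = 0), integer(0))
  # search is restricted 5' of the boundary
  expect_equal(call_stall_peaks(d, boundary = 10L), integer(0))
})

test_that("stalls without downstream attenuation are not called sensitive", {
  # stall peak present but readthrough 1: no downstream decrease -> no call
  set.seed(67)
  sim <- simulate_transcriptome(400, seed = 71, with_sequence = FALSE)
  specs <- sim$specs
  specs <- implant_stalls(specs, specs$gene_id[1:4], stall_codon = 30L,
                          stall_amplitude = 10, readthrough = 1)
  specs <- implant_stalls(specs, specs$gene_id[5:8], stall_codon = 30L,
                          stall_amplitude = 10, readthrough = 0.25)
  des <- sim_design(3, assays = "ribo")
  ex <- simulate_experiment(specs, sim$transcripts, des, depth = 3e5,
                            seed = 73, level = "codon")
  res <- detect_stalls(ex$maps, des, sim$transcripts,
                       params = list(bin_size = 100L))
  s <- res$stalls
  expect_false(any(s$sensitive[s$gene_id %in% specs$gene_id[1:4]]))
  expect_true(all(s$sensitive[s$gene_id %in% specs$gene_id[5:8]]))
  # no-stall genes stay uncalled apart from (rare) noise
  expect_lte(sum(s$sensitive[!s$gene_id %in% specs$gene_id[1:8]]), 1)
})

test_that("an implanted early stall shifts the center of density 5' and omit_first erases it", {
  set.seed(79)
  L <- 400
  tx <- data.frame(transcript_id = "t1", gene_id = "g1", utr5_len = 0L,
                   cds_len = 3L * L, utr3_len = 0L, sequence = "")
  veh <- make_codonmap(list(t1 = rpois(L, 20)))
  shape <- c(rep(20, 29), 200, rep(20 * 0.3, L - 30))
  tre <- make_codonmap(list(t1 = rpois(L, shape)))
  deltas <- vapply(c(0L, 50L, 100L, 150L), function(k)
    center_of_density(tre$counts$t1, k) - center_of_density(veh$counts$t1, k),
    numeric(1))
  expect_lt(deltas[1], 0)
  expect_lt(abs(deltas[4]), abs(deltas[1]))
  expect_true(all(diff(abs(deltas)) <= 0) || abs(deltas[2]) < 5)
})
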