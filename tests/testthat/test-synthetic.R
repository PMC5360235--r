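test_that("same seed reproduces the transcriptome and experiment exactly", {
  a <- simulate_transcriptome(40, seed = 149)
  b <- simulate_transcriptome(40, seed = 149)
  expect_identical(a, b)
  des <- sim_design(2)
  ea <- simulate_experiment(a$specs, a$transcripts, des, depth = 5e4, seed = 151)
  eb <- simulate_experiment(b$specs, b$transcripts, des, depth = 5e4, seed = 151)
  expect_identical(ea, eb)
  ec <- simulate_experiment(a$specs, a$transcripts, des, depth = 5e4, seed = 152)
  expect_false(identical(ea$maps, ec$maps))
})

test_that("uorf_rate 0 leaves no AUG in any 5'UTR", {
  sim <- simulate_transcriptome(60, seed = 157, uorf_rate = 0)
  for (i in seq_len(60)) {
    utr <- substr(sim$transcripts$sequence[i], 1, sim$transcripts$utr5_len[i] + 2)
    expect_false(grepl("ATG", utr, fixed = TRUE))
  }
})

test_that("generated CDSs begin with AUG, end with a stop, and lengths agree", {
  sim <- simulate_transcriptome(50, seed = 163, paralog_rate = 0.2)
  tx <- sim$transcripts
  expect_gt(nrow(tx), 50)     # paralog copies appended
  for (i in seq_len(nrow(tx))) {
    expect_equal(nchar(tx$sequence[i]),
                 tx$utr5_len[i] + tx$cds_len[i] + tx$utr3_len[i])
    cds <- substr(tx$sequence[i], tx$utr5_len[i] + 1,
                  tx$utr5_len[i] + tx$cds_len[i])
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in%
                  c("TAA", "TAG", "TGA"))
  }
  expect_true(any(sim$specs$n_paralog_copies == 2L))
})

test_that("expected density: no-stall identity and exact readthrough step", {
  spec <- data.frame(gene_id = "g", transcript_id = "t", n_codons = 200L,
                     base_expression = 100, dispersion = 0.01,
                     stall_codon = NA_integer_, stall_amplitude = 0,
                     readthrough = 1, p_frame0 = 0.7, p_frame1 = 0.15,
                     p_frame2 = 0.15, has_polyA = TRUE,
                     transcription_fold = 1, n_paralog_copies = 1L)
  expect_equal(expected_density(spec, "treatment"),
               expected_density(spec, "vehicle"))
  spec$stall_codon <- 20L; spec$stall_amplitude <- 6; spec$readthrough <- 0.5
  dv <- expected_density(spec, "vehicle")
  dt <- expected_density(spec, "treatment")
  expect_equal(dt[1:19], dv[1:19])
  expect_equal(dt[20], dv[20] * 7)
  expect_equal(mean(dt[21:200]) / mean(dv[21:200]), 0.5)
  # closed-form D_max equals the numeric CFR scan on the expected curves
  expect_equal(expected_dmax(spec),
               bf_dmax(bf_cfr(dt), bf_cfr(dv))$dmax)
})

test_that("closed-form D_max matches numeric CFR divergence across random specs", {
  set.seed(167)
  for (i in 1:100) {
    spec <- data.frame(gene_id = "g", transcript_id = "t",
                       n_codons = sample(100:600, 1), base_expression = 50,
                       dispersion = 0, stall_codon = NA_integer_,
                       stall_amplitude = 0, readthrough = 1,
                       p_frame0 = 0.7, p_frame1 = 0.15, p_frame2 = 0.15,
                       has_polyA = TRUE, transcription_fold = 1,
                       n_paralog_copies = 1L)
    spec$stall_codon <- sample(10:90, 1)
    spec$stall_amplitude <- runif(1, 0, 20)
    spec$readthrough <- runif(1, 0.05, 1)
    nu <- bf_dmax(bf_cfr(expected_density(spec, "treatment")),
                  bf_cfr(expected_density(spec, "vehicle")))$dmax
    expect_equal(expected_dmax(spec), nu, tolerance = 1e-10)
  }
})

test_that("observed/expected codon ratios approach 1 at high depth without dispersion", {
  sim <- simulate_transcriptome(20, seed = 173, cds_codon_range = c(100L, 150L),
                                with_sequence = FALSE)
  specs <- sim$specs
  specs$dispersion <- 0
  specs <- implant_stalls(specs, specs$gene_id[1:3], stall_codon = 34L)
  des <- data.frame(sample_id = c("v1", "t1"),
                    condition = c("vehicle", "treatment"),
                    replicate = 1L, assay = "ribo")
  ex <- simulate_experiment(specs, sim$transcripts, des, depth = 2e6,
                            seed = 179, level = "codon")
  share <- specs$base_expression / sum(specs$base_expression)
  for (i in c(1, 5)) {
    exp_v <- expected_density(specs[i, ], "vehicle") /
      specs$base_expression[i] * share[i] * 2e6
    obs <- ex$maps$v1$counts[[specs$transcript_id[i]]]
    expect_equal(sum(obs) / sum(exp_v), 1, tolerance = 3 / sqrt(sum(exp_v)))
    expect_lt(max(abs(obs - exp_v) / pmax(sqrt(exp_v), 1)), 6)
  }
})

test_that("SimTruth invariants: downstream change is log2(readthrough) by construction", {
  sim <- simulate_transcriptome(30, seed = 181, with_sequence = FALSE)
  specs <- implant_stalls(sim$specs, sim$specs$gene_id[1:5],
                          stall_codon = 40L, readthrough = 0.3)
  des <- sim_design(2, assays = "ribo")
  ex <- simulate_experiment(specs, sim$transcripts, des, depth = 1e4, seed = 191)
  tr <- ex$truth
  stalled <- tr$stalled
  expect_equal(sum(stalled), 5L)
  expect_equal(tr$expected_downstream_log2fc[stalled], rep(log2(0.3), 5))
  expect_true(all(tr$expected_downstream_log2fc[!stalled] == 0))
  expect_true(all(tr$expected_cds_log2fc[!stalled] == 0))
})

test_that("mRNA coverage is treatment-invariant and poly-A selection downweights flagged genes", {
  sim <- simulate_transcriptome(200, seed = 193, with_sequence = FALSE)
  specs <- implant_stalls(sim$specs, sim$specs$gene_id[1:20],
                          stall_codon = 30L, readthrough = 0.2)
  specs$has_polyA[21:30] <- FALSE
  des <- sim_design(3, assays = "mrna")
  ex <- simulate_experiment(specs, sim$transcripts, des, depth = 5e5,
                            seed = 197)
  mat <- cds_count_matrix(ex$maps, sim$transcripts)
  cond <- des$condition
  # stalls leave mRNA unchanged: no gene flagged beyond the FDR level
  de <- differential_downstream(mat, cond)
  expect_lte(sum(de$fdr[match(specs$gene_id[1:20], de$gene_id)] < 0.1,
                 na.rm = TRUE), 1)
  lfc <- log2(rowMeans(mat[, cond == "treatment"]) /
                rowMeans(mat[, cond == "vehicle"]))
  expect_lt(abs(mean(lfc[1:20])), 0.15)
  # poly-A selection: whole-transcript recovery of flagged genes ~ polyA_factor
  tot <- vapply(specs$transcript_id[21:30], function(id)
    sum(vapply(ex$maps, function(m) sum(m$counts[[id]]), numeric(1))),
    numeric(1))
  ratio <- tot / (specs$base_expression[21:30] /
                    sum(specs$base_expression) * 6 * 5e5)
  expect_equal(mean(ratio), 0.1, tolerance = 0.03)
})

test_that("readmap -> alignment -> ingest round trip reproduces P-site maps", {
  sim <- simulate_transcriptome(15, seed = 199, utr5_range = c(20L, 60L),
                                with_sequence = FALSE)
  des <- data.frame(sample_id = "s1", condition = "vehicle", replicate = 1L,
                    assay = "ribo")
  ex <- simulate_experiment(sim$specs, sim$transcripts, des, depth = 2e4,
                            seed = 211, level = "nt")
  rm0 <- ex$maps$s1
  aln <- readmap_to_alignments(rm0, offset = 14L)
  rm1 <- build_readmap(aln, sim$transcripts, sample_id = "s1", assay = "ribo",
                       offset = 14L)
  for (id in names(rm0$counts)) {
    v0 <- rm0$counts[[id]]
    v0[seq_len(min(14L, length(v0)))] <- 0L   # P-sites < offset not representable
    expect_equal(rm1$counts[[id]], v0)
  }
})
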