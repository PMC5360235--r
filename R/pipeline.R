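# Pipeline orchestration: YAML run configuration, stage subcommands, and
# a JSON run manifest recording parameters, input checksums and read
# accounting so that results are reproducible and traceable.

.CONFIG_KEYS <- c(
  "reference_fasta", "lengths_tsv", "utr5_fasta", "cds_fasta", "utr3_fasta",
  "abundance_tsv", "alignments", "design_tsv", "outdir", "seed",
  "psite_offset", "min_len", "max_len", "max_sites", "min_tpm",
  "isoform_mode", "min_fraction", "bin_size", "z_min", "fdr_max",
  "default_codon", "cod_z_min", "omit_first", "min_reads", "min_cds_len",
  "n_genes", "depth", "n_rep", "uorf_rate")

.CONFIG_DEFAULTS <- list(
  psite_offset = 14L, min_len = 26L, max_len = 34L, max_sites = 5L,
  min_tpm = 1.0, isoform_mode = "best", min_fraction = 0.1,
  bin_size = 300L, z_min = 2.0, fdr_max = 0.1, default_codon = 50L,
  cod_z_min = 3.0, omit_first = c(0L, 50L, 100L, 150L), min_reads = 64L,
  min_cds_len = 600L, n_genes = 500L, depth = 2e5, n_rep = 3L,
  uorf_rate = 0.3, outdir = "ribostall_out", seed = 1L)

#' Read and validate a run configuration
#'
#' Unknown keys are rejected; all validation errors are reported in one
#' batch. Defaults are filled for absent keys.
#' @param path YAML file, or a named list used as-is.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  errs <- character(0)
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown))
    errs <- c(errs, paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  num_keys <- c("psite_offset", "min_len", "max_len", "max_sites", "min_tpm",
                "bin_size", "z_min", "fdr_max", "default_codon", "cod_z_min",
                "min_reads", "n_genes", "depth", "n_rep", "seed")
  for (k in intersect(num_keys, names(cfg)))
    if (!is.numeric(cfg[[k]])) errs <- c(errs, paste0(k, " must be numeric"))
  if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)
  utils::modifyList(.CONFIG_DEFAULTS, cfg)
}

.manifest <- function(cfg, inputs = character(0), tallies = NULL) {
  files <- inputs[file.exists(inputs)]
  list(package = "ribostall",
       version = as.character(utils::packageVersion("ribostall")),
       parameters = cfg[order(names(cfg))],
       input_md5 = as.list(tools::md5sum(files)),
       read_accounting = as.list(tallies))
}

.write_manifest <- function(manifest, outdir) {
  path <- file.path(outdir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

.write_tsv <- function(d, path) {
  num <- vapply(d, is.double, logical(1))
  d[num] <- lapply(d[num], function(x) formatC(x, digits = 6, format = "g"))
  lst <- vapply(d, is.list, logical(1))
  d[lst] <- lapply(d[lst], function(x)
    vapply(x, function(e) paste(e, collapse = ","), character(1)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run a pipeline stage
#'
#' Subcommands: \code{simulate} (synthetic experiment with truth),
#' \code{build-reference} (assemble regions + isoform selection),
#' \code{ingest} (alignments to read/codon maps), \code{metagene},
#' \code{detect-stalls}, \code{te}, \code{uorf-scan}, \code{report}, and
#' \code{all} (simulate then every analysis stage). Outputs are TSV/JSON
#' under \code{cfg$outdir}; every stage writes the run manifest.
#'
#' @param subcommand stage name.
#' @param config YAML path or config list (see
#'   \code{\link{read_run_config}}).
#' @return invisibly, a list of produced artifact paths.
#' @export
ribostall_run <- function(subcommand = c("all", "simulate", "build-reference",
                                         "ingest", "metagene", "detect-stalls",
                                         "te", "uorf-scan", "report"),
                          config = list()) {
  subcommand <- match.arg(subcommand)
  cfg <- read_run_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(subcommand,
    "simulate" = .stage_simulate(cfg),
    "build-reference" = .stage_reference(cfg),
    "ingest" = .stage_ingest(cfg),
    "metagene" = .stage_metagene(cfg),
    "detect-stalls" = .stage_detect(cfg),
    "te" = .stage_te(cfg),
    "uorf-scan" = .stage_uorf(cfg),
    "report" = .stage_report(cfg),
    "all" = {
      a <- .stage_simulate(cfg)
      c(a, .stage_metagene(cfg), .stage_detect(cfg), .stage_te(cfg),
        .stage_uorf(cfg), .stage_report(cfg))
    })
  invisible(out)
}

.require_inputs <- function(paths) {
  miss <- paths[!file.exists(paths)]
  if (length(miss))
    stop("missing input file(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
}

.stage_simulate <- function(cfg) {
  sim <- simulate_transcriptome(cfg$n_genes, seed = cfg$seed,
                                uorf_rate = cfg$uorf_rate)
  des <- sim_design(cfg$n_rep)
  ex <- simulate_experiment(sim$specs, sim$transcripts, des,
                            depth = cfg$depth, seed = cfg$seed + 1L,
                            level = "nt")
  o <- cfg$outdir
  write_transcriptome(sim$transcripts, file.path(o, "transcripts.fa"),
                      file.path(o, "transcript_lengths.tsv"))
  .write_tsv(des, file.path(o, "design.tsv"))
  .write_tsv(ex$truth, file.path(o, "truth.tsv"))
  write_sparse_maps(ex$maps[des$sample_id[des$assay == "ribo"]],
                    file.path(o, "ribo_maps.tsv"))
  write_sparse_maps(ex$maps[des$sample_id[des$assay == "mrna"]],
                    file.path(o, "mrna_maps.tsv"))
  .write_manifest(.manifest(cfg), o)
  file.path(o, c("transcripts.fa", "transcript_lengths.tsv", "design.tsv",
                 "truth.tsv", "ribo_maps.tsv", "mrna_maps.tsv",
                 "run_manifest.json"))
}

.stage_reference <- function(cfg) {
  .require_inputs(c(cfg$cds_fasta, cfg$abundance_tsv))
  cds <- Biostrings::readDNAStringSet(cfg$cds_fasta)
  u5 <- if (!is.null(cfg$utr5_fasta)) Biostrings::readDNAStringSet(cfg$utr5_fasta)
  u3 <- if (!is.null(cfg$utr3_fasta)) Biostrings::readDNAStringSet(cfg$utr3_fasta)
  asm <- assemble_transcripts(cds, u5, u3)
  ab <- utils::read.table(cfg$abundance_tsv, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  keep <- select_representative_isoforms(ab, min_tpm = cfg$min_tpm,
                                         mode = cfg$isoform_mode,
                                         min_fraction = cfg$min_fraction)
  tx <- asm$transcripts[asm$transcripts$transcript_id %in% keep, ]
  o <- cfg$outdir
  write_transcriptome(tx, file.path(o, "reference.fa"),
                      file.path(o, "transcript_lengths.tsv"))
  .write_tsv(asm$rejects, file.path(o, "rejects.tsv"))
  .write_manifest(.manifest(cfg, c(cfg$cds_fasta, cfg$abundance_tsv)), o)
  file.path(o, c("reference.fa", "transcript_lengths.tsv", "rejects.tsv"))
}

.stage_ingest <- function(cfg) {
  o <- cfg$outdir
  .require_inputs(c(file.path(o, "transcript_lengths.tsv"), cfg$alignments,
                    cfg$design_tsv))
  tx <- read_transcriptome(file.path(o, "transcript_lengths.tsv"))
  des <- utils::read.table(cfg$design_tsv, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(nrow(des) == length(cfg$alignments))
  maps <- lapply(seq_len(nrow(des)), function(i) {
    aln <- read_alignments(cfg$alignments[i])
    if (des$assay[i] == "ribo")
      aln <- filter_read_lengths(aln, cfg$min_len, cfg$max_len)
    aln <- apply_multimap_policy(aln, cfg$max_sites)
    build_readmap(aln, tx, sample_id = des$sample_id[i], assay = des$assay[i],
                  offset = if (des$assay[i] == "ribo") cfg$psite_offset else 0L)
  })
  names(maps) <- des$sample_id
  write_sparse_maps(maps[des$sample_id[des$assay == "ribo"]],
                    file.path(o, "ribo_maps.tsv"))
  if (any(des$assay == "mrna"))
    write_sparse_maps(maps[des$sample_id[des$assay == "mrna"]],
                      file.path(o, "mrna_maps.tsv"))
  tallies <- lapply(maps, function(m)
    c(m$dropped, placed_cds = m$total_cds_reads))
  .write_manifest(.manifest(cfg, c(cfg$alignments, cfg$design_tsv), tallies), o)
  file.path(o, "ribo_maps.tsv")
}

.load_run <- function(cfg, level = "codon") {
  o <- cfg$outdir
  .require_inputs(file.path(o, c("transcript_lengths.tsv", "design.tsv",
                                 "ribo_maps.tsv")))
  tx <- read_transcriptome(file.path(o, "transcript_lengths.tsv"))
  des <- utils::read.table(file.path(o, "design.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  nt_maps <- read_sparse_maps(file.path(o, "ribo_maps.tsv"), tx, "nt", "ribo")
  ribo <- if (level == "codon") lapply(nt_maps, collapse_to_codons, tx = tx)
          else nt_maps
  mrna <- if (file.exists(file.path(o, "mrna_maps.tsv")))
    read_sparse_maps(file.path(o, "mrna_maps.tsv"), tx, "nt", "mrna")
  list(tx = tx, design = des, ribo = ribo, mrna = mrna)
}

.stage_metagene <- function(cfg) {
  run <- .load_run(cfg, level = "nt")
  ribo_des <- run$design[run$design$assay == "ribo", ]
  prof <- do.call(rbind, lapply(ribo_des$sample_id, function(s) {
    p <- rbind(
      normalized_mean_profile(run$ribo[[s]], run$tx, "start",
                              min_cds_len = cfg$min_cds_len),
      normalized_mean_profile(run$ribo[[s]], run$tx, "stop",
                              min_cds_len = cfg$min_cds_len))
    p$sample_id <- s
    p
  }))
  path <- file.path(cfg$outdir, "metagene.tsv")
  .write_tsv(prof, path)
  path
}

.stage_detect <- function(cfg) {
  run <- .load_run(cfg, level = "codon")
  des <- run$design[run$design$assay == "ribo", ]
  res <- detect_stalls(run$ribo, des, run$tx,
                       params = cfg[c("min_reads", "bin_size", "z_min",
                                      "fdr_max", "default_codon", "cod_z_min",
                                      "omit_first")])
  o <- cfg$outdir
  .write_tsv(res$stalls, file.path(o, "stall_results.tsv"))
  .write_tsv(do.call(rbind, res$cod), file.path(o, "center_of_density.tsv"))
  .write_manifest(.manifest(cfg, tallies = as.list(res$excluded)), o)
  file.path(o, c("stall_results.tsv", "center_of_density.tsv"))
}

.stage_te <- function(cfg) {
  run <- .load_run(cfg, level = "codon")
  if (is.null(run$mrna)) stop("missing input file(s): mrna_maps.tsv", call. = FALSE)
  rdes <- run$design[run$design$assay == "ribo", ]
  mdes <- run$design[run$design$assay == "mrna", ]
  rmat <- cds_count_matrix(run$ribo[rdes$sample_id], run$tx)
  mmat <- cds_count_matrix(run$mrna[mdes$sample_id], run$tx)
  te <- dte_zscores(translational_efficiency(rmat, mmat, rdes$condition,
                                             mdes$condition),
                    bin_size = cfg$bin_size)
  dec <- assay_change_decomposition(rmat, mmat, rdes$condition, mdes$condition,
                                    bin_size = cfg$bin_size)
  o <- cfg$outdir
  .write_tsv(merge(te, dec, by = "gene_id", all = TRUE),
             file.path(o, "te_results.tsv"))
  file.path(o, "te_results.tsv")
}

.stage_uorf <- function(cfg) {
  run <- .load_run(cfg, level = "nt")
  tx <- read_transcriptome(file.path(cfg$outdir, "transcript_lengths.tsv"),
                           file.path(cfg$outdir, "transcripts.fa"))
  des <- run$design[run$design$assay == "ribo", ]
  u <- enumerate_uorfs_all(tx)
  res <- uorf_scan(u, run$ribo, des)
  path <- file.path(cfg$outdir, "uorf_results.tsv")
  .write_tsv(res, path)
  path
}

.stage_report <- function(cfg) {
  o <- cfg$outdir
  .require_inputs(file.path(o, "stall_results.tsv"))
  s <- utils::read.table(file.path(o, "stall_results.tsv"), sep = "\t",
                         header = TRUE, stringsAsFactors = FALSE)
  lines <- c(
    "# ribostall run report", "",
    sprintf("- genes analyzed (CFR/D_max): %d", nrow(s)),
    sprintf("- sensitive genes (D_max Z > threshold, downstream decrease, FDR gate): %d",
            sum(s$sensitive)),
    sprintf("- median D_max: %.4f", stats::median(s$dmax)))
  if (file.exists(file.path(o, "te_results.tsv"))) {
    te <- utils::read.table(file.path(o, "te_results.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
    lines <- c(lines, sprintf("- TE genes quantified: %d", nrow(te)))
  }
  path <- file.path(o, "report.md")
  writeLines(lines, path)
  path
}
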