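# End-to-end orchestration: simulate (or read) -> trim -> merge -> split ->
# place -> junctions -> dedup -> matrices/density, with a machine-readable
# run manifest and deterministic outputs for a fixed seed.

#' Build a validated pipeline run configuration
#'
#' All stage parameters default to the module defaults. Unknown keys are
#' rejected (they raise the usual unused-argument error). Input data come
#' either from `sim` (a [sim_config()]; a genome, panel and library are
#' simulated) or from `fastq_r1`/`fastq_r2`/`genome_fasta`/`regions_bed`.
#'
#' @param seed Integer seed for every stochastic stage (mandatory).
#' @param out_dir Output directory (created if missing).
#' @param sample Sample/condition label.
#' @param sim Optional [sim_config()] for simulated input.
#' @param genome_length,masked_fraction,region_margin Simulated-genome
#'   parameters (`region_margin` is the fraction of the genome left outside
#'   the single target region on each side).
#' @param fastq_r1,fastq_r2,genome_fasta,regions_bed Input paths (file
#'   mode).
#' @param binsizes Matrix resolutions in bp.
#' @param min_distance_matrix,min_distance_density Minimum junction
#'   distances for matrices (default 0) and density export (default 10).
#' @param oligo_len,overlap,repeat_threshold,homopolymer_max Panel-design
#'   parameters.
#' @param k,min_identity Alignment parameters.
#' @param design Whether to design and write a capture panel.
#' @return A `run_config` list.
#' @export
run_config <- function(seed, out_dir, sample = "sample1",
                       sim = NULL,
                       genome_length = 50000L, masked_fraction = 0.05,
                       region_margin = 0.2,
                       fastq_r1 = NULL, fastq_r2 = NULL,
                       genome_fasta = NULL, regions_bed = NULL,
                       binsizes = c(500L, 20L),
                       min_distance_matrix = 0,
                       min_distance_density = 10,
                       oligo_len = 70L, overlap = 35L,
                       repeat_threshold = 0.3, homopolymer_max = 10L,
                       k = 20L, min_identity = 0.9,
                       design = TRUE) {
  if (missing(seed)) abort("`seed` is mandatory")
  if (missing(out_dir)) abort("`out_dir` is mandatory")
  cfg <- as.list(environment())
  file_mode <- !is.null(cfg$fastq_r1)
  if (file_mode) {
    paths <- c(fastq_r1 = cfg$fastq_r1, fastq_r2 = cfg$fastq_r2,
               genome_fasta = cfg$genome_fasta, regions_bed = cfg$regions_bed)
    if (length(paths) < 4) abort("file mode needs fastq_r1, fastq_r2, genome_fasta and regions_bed")
    missing_files <- paths[!file.exists(paths)]
    if (length(missing_files)) {
      abort(sprintf("missing input file(s): %s",
                    paste(sprintf("%s (%s)", missing_files, names(missing_files)),
                          collapse = ", ")))
    }
  } else if (is.null(cfg$sim)) {
    cfg$sim <- sim_config(seed = as.integer(seed))
  }
  if (!is.null(cfg$sim)) cfg$sim$seed <- as.integer(seed)
  structure(cfg, class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order, writes all stage outputs and a JSON run
#' manifest (`manifest.json`) with per-stage read/junction counts under
#' `config$out_dir`. Rerunning with an identical configuration reproduces
#' byte-identical junction tables and matrices.
#'
#' @param config A [run_config()].
#' @return List with `junctions` (deduplicated tibble), `matrices` (one
#'   balanced `contact_matrix` per binsize), `density` (density-point
#'   tibble), `manifest` (the stage-count list), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  manifest <- list(sample = config$sample, seed = config$seed)

  ## --- inputs -----------------------------------------------------------
  if (is.null(config$fastq_r1)) {
    genome <- with_stage("simulate genome",
      simulate_genome(config$genome_length, config$masked_fraction,
                      seed = derive_seed(config$seed, 1L)))
    m <- round(config$region_margin * config$genome_length)
    regions <- target_regions(names(genome), m, config$genome_length - m,
                              name = "regionA")
    sim <- with_stage("simulate library",
                      simulate_library(regions, genome, config$sim))
    write_fasta(genome, out("genome.fa"))
    write_bed(regions, out("regions.bed"))
    write_library(sim, out(config$sample))
    r1 <- tibble(id = sim$reads$id, seq = sim$reads$r1_seq, qual = sim$reads$r1_qual)
    r2 <- tibble(id = sim$reads$id, seq = sim$reads$r2_seq, qual = sim$reads$r2_qual)
  } else {
    genome <- with_stage("read reference", read_fasta(config$genome_fasta))
    regions <- with_stage("read regions", read_bed(config$regions_bed))
    r1 <- with_stage("read FASTQ R1", read_fastq(config$fastq_r1))
    r2 <- with_stage("read FASTQ R2", read_fastq(config$fastq_r2))
    if (nrow(r1) != nrow(r2)) abort("stage 'read FASTQ' failed: mates out of sync")
  }
  regions <- add_region_seq(regions, genome)
  manifest$reads_in <- nrow(r1)

  ## --- capture panel ----------------------------------------------------
  if (isTRUE(config$design)) {
    panel <- with_stage("design panel",
      design_panel(regions, oligo_len = config$oligo_len, overlap = config$overlap,
                   repeat_threshold = config$repeat_threshold,
                   homopolymer_max = config$homopolymer_max))
    write_panel(panel, regions, out("panel"))
    manifest$panel <- list(n_oligos = nrow(panel), n_accepted = sum(panel$accepted))
  }

  ## --- read processing --------------------------------------------------
  trimmed <- with_stage("trim adapters", trim_adapters(r1, r2))
  manifest$trim <- trimmed$stats
  merged <- with_stage("merge pairs", merge_pairs(trimmed$r1, trimmed$r2))
  manifest$merge <- list(n_reads = nrow(merged), n_merged = sum(merged$merged))
  segments <- with_stage("split chimeric reads",
    split_chimeric(merged, regions, k = config$k, min_identity = config$min_identity))
  manifest$split <- attr(segments, "stats")
  segments <- with_stage("place segments",
                         place_segments(segments, merged, genome, k = config$k))
  manifest$place <- attr(segments, "stats")
  readr::write_tsv(segments, out("segments.tsv"), progress = FALSE)

  ## --- junctions --------------------------------------------------------
  junctions <- with_stage("call junctions", call_junctions(segments))
  dedup <- with_stage("deduplicate junctions", dedup_junctions(junctions))
  manifest$junctions <- attr(dedup, "stats")
  jx_matrix <- filter_junctions(dedup, config$min_distance_matrix)
  write_pairs(dedup, out("junctions.pairs.tsv"))

  ## --- matrices & density ----------------------------------------------
  reg1 <- regions[1, ]
  matrices <- list()
  for (bs in config$binsizes) {
    grid <- bin_grid(reg1$chrom, reg1$start, reg1$end, bs)
    cm <- with_stage(sprintf("matrix %d bp", bs),
                     ice_balance(bin_junctions(jx_matrix, grid)))
    cm$scale <- if (bs >= 100) "linear" else "log"
    write_contact_matrix(cm, out(sprintf("matrix_%dbp", bs)))
    matrices[[as.character(bs)]] <- cm
    manifest$matrices[[as.character(bs)]] <-
      list(total_counts = sum(cm$counts), n_masked = sum(cm$mask),
           converged = cm$converged, n_skipped = cm$n_skipped)
  }
  dens <- with_stage("density points",
                     density_points(dedup, min_distance = config$min_distance_density))
  readr::write_tsv(dens, out("density_points.tsv"), progress = FALSE)
  manifest$density <- list(n_points = nrow(dens))

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(list(junctions = dedup, matrices = matrices, density = dens,
                 manifest = manifest))
}
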