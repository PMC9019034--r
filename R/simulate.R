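# Synthetic tiled-capture MCC library simulator.
#
# Emulates the library structure the analysis pipeline expects: MNase
# digestion to mono-nucleosome-sized fragments (~180 bp), pairwise proximity
# ligation with a distance-decaying contact probability plus optional
# enriched anchor pairs, sonication of the ligated molecule to ~200 bp,
# paired-end 150 bp sequencing from both molecule ends (second mate
# reverse-complemented), PCR duplication and per-base substitution errors.
# Every simulated molecule is recorded in a ground-truth junction table.
#
# Junction coordinates in the truth table are canonicalised: when bases
# immediately downstream of the junction coincide with the genomic
# continuation of the first fragment, several junction placements explain
# the same read sequence, so the recorded junction is shifted maximally
# along the first fragment's continuation (the same convention the junction
# caller applies, analogous to indel left-alignment in VCF).

#' Simulation configuration
#'
#' Defaults reflect the library conditions the pipeline is designed for:
#' ~180 bp MNase fragments, sonication to ~200 bp, 150 bp paired-end reads,
#' and ~80% of ligation events on target.
#'
#' @param seed Integer seed; all randomness in [simulate_library()] derives
#'   from it.
#' @param n_ligation_events Number of unique ligation events to simulate.
#' @param fragment_len_mean,fragment_len_sd MNase fragment length (bp),
#'   Normal, truncated at 50 bp.
#' @param sonication_mean,sonication_sd Sonicated molecule length (bp),
#'   Normal, truncated to `[read_len, molecule length]`.
#' @param read_len Read length (bp) for both mates.
#' @param pcr_duplicate_rate Fraction of emitted truth records that are PCR
#'   duplicates of another record.
#' @param error_rate Per-base substitution probability applied to reads.
#' @param anchor_pairs `NULL` or a data frame with columns `chrom`, `posA`,
#'   `posB`, `enrichment`: loop-like contacts enriched `enrichment`-fold over
#'   the same-distance background within a `anchor_width` window.
#' @param anchor_width Width (bp) of the anchor windows (default 500).
#' @param decay_exponent Exponent `alpha > 0` of the contact-probability
#'   power law `p(d) ~ d^-alpha`.
#' @param distance_min,distance_max Support of the distance decay (bp).
#' @param off_target_fraction Fraction of ligation events whose first
#'   fragment falls uniformly in the genome rather than in a target region.
#' @param min_mappable Minimum alignable flank (bp) on each side of a
#'   junction for it to be flagged `junction_in_read` in the truth table;
#'   matches the aligner's minimum segment length.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_ligation_events = 10000L,
                       fragment_len_mean = 180, fragment_len_sd = 25,
                       sonication_mean = 200, sonication_sd = 30,
                       read_len = 150L,
                       pcr_duplicate_rate = 0.1,
                       error_rate = 0.001,
                       anchor_pairs = NULL,
                       anchor_width = 500,
                       decay_exponent = 1,
                       distance_min = 50, distance_max = 20000,
                       off_target_fraction = 0.2,
                       min_mappable = 20L) {
  cfg <- list(seed = as.integer(seed),
              n_ligation_events = as.integer(n_ligation_events),
              fragment_len_mean = fragment_len_mean, fragment_len_sd = fragment_len_sd,
              sonication_mean = sonication_mean, sonication_sd = sonication_sd,
              read_len = as.integer(read_len),
              pcr_duplicate_rate = pcr_duplicate_rate,
              error_rate = error_rate,
              anchor_pairs = anchor_pairs,
              anchor_width = anchor_width,
              decay_exponent = decay_exponent,
              distance_min = distance_min, distance_max = distance_max,
              off_target_fraction = off_target_fraction,
              min_mappable = as.integer(min_mappable))
  rates <- c(cfg$pcr_duplicate_rate, cfg$error_rate, cfg$off_target_fraction)
  if (any(rates < 0 | rates > 1)) abort("rates must be in [0, 1]")
  if (cfg$fragment_len_mean <= 0) abort("fragment_len_mean must be positive")
  if (cfg$decay_exponent <= 0) abort("decay_exponent must be positive")
  if (cfg$distance_min <= 0 || cfg$distance_min >= cfg$distance_max) {
    abort("need 0 < distance_min < distance_max")
  }
  if (!is.null(anchor_pairs)) {
    stopifnot(all(c("chrom", "posA", "posB", "enrichment") %in% names(anchor_pairs)))
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a random genome with soft-masked stretches
#'
#' @param genome_length Length in bp (>= 10 kb recommended).
#' @param masked_fraction Fraction of bases to soft-mask (lowercase), placed
#'   as random stretches of ~300 bp.
#' @param seed Integer seed (deterministic output for a fixed seed).
#' @param chrom Chromosome name.
#' @return Named character vector of length 1 (the chromosome sequence).
#' @export
simulate_genome <- function(genome_length, masked_fraction = 0, seed = 1L,
                            chrom = "chrS") {
  if (masked_fraction < 0 || masked_fraction > 1) {
    abort("masked_fraction must be in [0, 1]")
  }
  withr::with_seed(as.integer(seed), {
    g <- random_dna(genome_length)
    if (masked_fraction > 0) {
      chars <- strsplit(g, "", fixed = TRUE)[[1]]
      masked <- logical(genome_length)
      while (sum(masked) < masked_fraction * genome_length) {
        len <- max(50L, round(rnorm(1, 300, 100)))
        s <- sample.int(genome_length - len, 1)
        masked[s:(s + len - 1L)] <- TRUE
      }
      chars[masked] <- tolower(chars[masked])
      g <- paste(chars, collapse = "")
    }
    setNames(g, chrom)
  })
}

# CDF of the truncated power-law contact-decay distribution
powerlaw_cdf <- function(d, dmin, dmax, alpha) {
  d <- pmin(pmax(d, dmin), dmax)
  if (abs(alpha - 1) < 1e-12) {
    log(d / dmin) / log(dmax / dmin)
  } else {
    (d^(1 - alpha) - dmin^(1 - alpha)) / (dmax^(1 - alpha) - dmin^(1 - alpha))
  }
}

# inverse-CDF sampler for the same distribution
powerlaw_sample <- function(n, dmin, dmax, alpha) {
  u <- runif(n)
  if (abs(alpha - 1) < 1e-12) {
    d <- dmin * (dmax / dmin)^u
  } else {
    d <- (u * (dmax^(1 - alpha) - dmin^(1 - alpha)) + dmin^(1 - alpha))^(1 / (1 - alpha))
  }
  round(d)
}

# character lookup in a vector of long strings, 0-based positions
chr_at <- function(strings, pos0) substring(strings, pos0 + 1, pos0 + 1)

# sample n positions uniformly from the complement of the target regions
sample_outside_regions <- function(n, regions, glen) {
  gaps <- dplyr::bind_rows(lapply(names(glen), function(ch) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    bounds <- c(0, as.vector(rbind(r$start, r$end)), unname(glen[[ch]]))
    gs <- bounds[seq(1, length(bounds), by = 2)]
    ge <- bounds[seq(2, length(bounds), by = 2)]
    tibble(chrom = ch, start = gs, end = ge)[ge > gs, ]
  }))
  if (nrow(gaps) == 0 || sum(gaps$end - gaps$start) == 0) {
    abort("off_target_fraction > 0 but the target regions cover the whole genome")
  }
  gi <- sample.int(nrow(gaps), n, replace = TRUE, prob = gaps$end - gaps$start)
  list(chrom = gaps$chrom[gi],
       pos = floor(runif(n, gaps$start[gi], gaps$end[gi])))
}

#' Simulate a tiled-capture MCC library
#'
#' Generates paired-end reads and a ground-truth junction table for
#' `config$n_ligation_events` two-fragment proximity-ligation molecules.
#' Deterministic (byte-identical output) for a fixed `config$seed`.
#'
#' @param regions Regions tibble (`chrom`, `start`, `end`, `name`); the
#'   capture-enriched target regions.
#' @param genome Named character vector of chromosome sequences.
#' @param config A [sim_config()].
#' @return List with elements
#'   `reads` (tibble: `id`, `r1_seq`, `r1_qual`, `r2_seq`, `r2_qual`) and
#'   `truth` (tibble: `read_id`, `chrom1`, `pos1`, `strand1`, `chrom2`,
#'   `pos2`, `strand2`, `sonication_left`, `sonication_right`, `distance`,
#'   `d_drawn`, `is_pcr_duplicate`, `dup_of`, `junction_in_read`,
#'   `off_target`, `anchor`). Junction coordinates are canonical (see
#'   package vignette).
#' @export
simulate_library <- function(regions, genome, config = sim_config()) {
  regions <- check_regions(regions)
  stopifnot(inherits(config, "sim_config"))
  missing <- setdiff(unique(regions$chrom), names(genome))
  if (length(missing)) abort(sprintf("regions reference unknown chromosome(s): %s",
                                     paste(missing, collapse = ", ")))
  withr::with_seed(config$seed, simulate_library_impl(regions, genome, config))
}

simulate_library_impl <- function(regions, genome, cfg) {
  n <- cfg$n_ligation_events
  glen <- nchar(genome)
  region_len <- regions$end - regions$start
  total_region <- sum(region_len)

  ## --- event types: anchor / off-target / background -------------------
  anchors <- cfg$anchor_pairs
  p_anchor <- numeric(0)
  if (!is.null(anchors) && nrow(anchors) > 0) {
    w <- cfg$anchor_width
    d_ab <- abs(anchors$posB - anchors$posA)
    band <- powerlaw_cdf(d_ab + w / 2, cfg$distance_min, cfg$distance_max, cfg$decay_exponent) -
      powerlaw_cdf(pmax(d_ab - w / 2, cfg$distance_min), cfg$distance_min,
                   cfg$distance_max, cfg$decay_exponent)
    p_bg <- (w / total_region) * 0.5 * band
    p_anchor <- pmax(anchors$enrichment - 1, 0) * p_bg
    if (sum(p_anchor) > 0.5) abort("anchor enrichment implies > 50% anchor events; reduce enrichment")
  }

  u_type <- runif(n)
  anchor_id <- rep(0L, n)
  if (length(p_anchor)) {
    cum <- cumsum(p_anchor)
    anchor_id <- findInterval(u_type, c(0, cum), rightmost.closed = FALSE)
    anchor_id[u_type >= cum[length(cum)]] <- 0L
  }
  is_anchor <- anchor_id > 0L
  off_target <- !is_anchor & runif(n) < cfg$off_target_fraction

  ## --- fragment geometry ----------------------------------------------
  len1 <- pmax(50, round(rnorm(n, cfg$fragment_len_mean, cfg$fragment_len_sd)))
  len2 <- pmax(50, round(rnorm(n, cfg$fragment_len_mean, cfg$fragment_len_sd)))
  strand1 <- sample(c("+", "-"), n, replace = TRUE)
  strand2 <- sample(c("+", "-"), n, replace = TRUE)

  ridx <- sample.int(nrow(regions), n, replace = TRUE, prob = region_len)
  chrom <- regions$chrom[ridx]
  L <- unname(glen[chrom])

  # first fragment start: uniform within the region; off-target events fall
  # uniformly in the complement of the target regions
  start1 <- floor(runif(n, regions$start[ridx], pmax(regions$start[ridx] + 1,
                                                     regions$end[ridx] - len1)))
  if (any(off_target)) {
    ot <- sample_outside_regions(sum(off_target), regions, glen)
    chrom[off_target] <- ot$chrom
    L[off_target] <- unname(glen[ot$chrom])
    start1[off_target] <- pmin(ot$pos, L[off_target] - len1[off_target])
  }
  pos1 <- ifelse(strand1 == "+", start1 + len1, start1)

  # partner position: junction-proximal ends exactly d apart (decay law),
  # or both ends uniform in the anchor windows
  d_drawn <- powerlaw_sample(n, cfg$distance_min, cfg$distance_max, cfg$decay_exponent)
  sign <- sample(c(-1, 1), n, replace = TRUE)
  pos2 <- pos1 + sign * d_drawn
  flip <- pos2 < len2 + 1 | pos2 > L - len2 - 1
  pos2[flip] <- pos1[flip] - sign[flip] * d_drawn[flip]
  if (any(is_anchor)) {
    ai <- anchor_id[is_anchor]
    w <- cfg$anchor_width
    chrom[is_anchor] <- anchors$chrom[ai]
    L[is_anchor] <- unname(glen[anchors$chrom[ai]])
    pos1[is_anchor] <- round(runif(sum(is_anchor), anchors$posA[ai] - w / 2,
                                   anchors$posA[ai] + w / 2))
    pos2[is_anchor] <- round(runif(sum(is_anchor), anchors$posB[ai] - w / 2,
                                   anchors$posB[ai] + w / 2))
    start1[is_anchor] <- ifelse(strand1[is_anchor] == "+",
                                pos1[is_anchor] - len1[is_anchor], pos1[is_anchor])
    d_drawn[is_anchor] <- abs(pos2[is_anchor] - pos1[is_anchor])
  }
  # clamp both fragments inside the chromosome
  start1 <- pmin(pmax(start1, 0), L - len1)
  pos1 <- ifelse(strand1 == "+", start1 + len1, start1)
  pos2 <- pmin(pmax(pos2, len2), L - len2)
  start2 <- ifelse(strand2 == "+", pos2, pos2 - len2)

  ## --- molecule assembly ----------------------------------------------
  gseq <- unname(genome[chrom])
  part1 <- toupper(substring(gseq, start1 + 1, start1 + len1))
  part1 <- ifelse(strand1 == "-", revcomp(part1), part1)
  part2 <- toupper(substring(gseq, start2 + 1, start2 + len2))
  part2 <- ifelse(strand2 == "-", revcomp(part2), part2)
  molecule <- paste0(part1, part2)
  mol_len <- len1 + len2

  ## --- canonical junction shift ----------------------------------------
  # shift the junction right while the next read base coincides with the
  # genomic continuation of fragment 1
  a <- integer(n)
  cap <- pmin(len2 - 1L,
              ifelse(strand1 == "+", L - pos1 - 1, pos1 - 1))
  active <- which(cap > 0)
  while (length(active)) {
    i <- active
    cont_pos <- ifelse(strand1[i] == "+", pos1[i] + a[i], pos1[i] - 1 - a[i])
    ext <- toupper(chr_at(gseq[i], cont_pos))
    ext <- ifelse(strand1[i] == "-", chartr("ACGT", "TGCA", ext), ext)
    nxt <- chr_at(molecule[i], len1[i] + a[i])
    ok <- ext == nxt
    a[i[ok]] <- a[i[ok]] + 1L
    active <- i[ok][a[i[ok]] < cap[i[ok]]]
  }
  pos1c <- ifelse(strand1 == "+", pos1 + a, pos1 - a)
  pos2c <- ifelse(strand2 == "+", pos2 + a, pos2 - a)
  jmol <- len1 + a

  ## --- sonication window ----------------------------------------------
  wlen <- round(rnorm(n, cfg$sonication_mean, cfg$sonication_sd))
  wlen <- pmin(pmax(wlen, cfg$read_len), mol_len)
  wstart <- floor(runif(n, 0, mol_len - wlen + 1))
  wend <- wstart + wlen
  window <- substring(molecule, wstart + 1, wend)
  junction_in_read <- (jmol - wstart >= cfg$min_mappable) &
    (wend - jmol >= cfg$min_mappable)

  # genomic coordinate of a molecule offset (raw fragment mapping)
  mol2genome <- function(t) {
    in1 <- t < len1
    ifelse(in1,
           ifelse(strand1 == "+", start1 + t, start1 + len1 - 1 - t),
           ifelse(strand2 == "+", start2 + (t - len1), start2 + len2 - 1 - (t - len1)))
  }
  strand_at <- function(t) ifelse(t < len1, strand1, strand2)
  son_first <- ifelse(strand_at(wstart) == "+", mol2genome(wstart), mol2genome(wstart) + 1)
  son_last_t <- wend - 1
  son_last <- ifelse(strand_at(son_last_t) == "+", mol2genome(son_last_t) + 1,
                     mol2genome(son_last_t))
  son_left <- pmin(son_first, son_last)
  son_right <- pmax(son_first, son_last)

  ## --- PCR duplication --------------------------------------------------
  ids <- sprintf("sim%07d", seq_len(n))
  r <- cfg$pcr_duplicate_rate
  n_dup <- if (r > 0) round(n * r / (1 - r)) else 0L
  dup_src <- if (n_dup > 0) sort(sample.int(n, n_dup, replace = TRUE)) else integer(0)
  all_idx <- c(seq_len(n), dup_src)
  dup_flag <- c(rep(FALSE, n), rep(TRUE, n_dup))
  dup_rank <- c(rep(0L, n), stats::ave(dup_src, dup_src, FUN = seq_along))
  read_id <- ifelse(dup_flag, sprintf("%s_dup%d", ids[all_idx], dup_rank), ids[all_idx])

  ## --- reads ------------------------------------------------------------
  win <- window[all_idx]
  wl <- wlen[all_idx]
  rl <- pmin(cfg$read_len, wl)
  r1 <- substring(win, 1, rl)
  r2 <- revcomp(substring(win, wl - rl + 1, wl))
  if (cfg$error_rate > 0) {
    r1 <- mutate_reads(r1, cfg$error_rate)
    r2 <- mutate_reads(r2, cfg$error_rate)
  }
  reads <- tibble(id = read_id, r1_seq = r1, r1_qual = strrep("F", nchar(r1)),
                  r2_seq = r2, r2_qual = strrep("F", nchar(r2)))

  truth <- tibble(
    read_id = read_id,
    chrom1 = chrom[all_idx], pos1 = pos1c[all_idx], strand1 = strand1[all_idx],
    chrom2 = chrom[all_idx], pos2 = pos2c[all_idx], strand2 = strand2[all_idx],
    sonication_left = son_left[all_idx], sonication_right = son_right[all_idx],
    distance = abs(pos2c - pos1c)[all_idx],
    d_drawn = d_drawn[all_idx],
    is_pcr_duplicate = dup_flag,
    dup_of = ifelse(dup_flag, ids[all_idx], NA_character_),
    junction_in_read = junction_in_read[all_idx],
    off_target = off_target[all_idx],
    anchor = anchor_id[all_idx]
  )
  list(reads = reads, truth = truth, config = cfg)
}

# apply i.i.d. substitution errors to reads
mutate_reads <- function(seqs, rate) {
  nerr <- stats::rbinom(length(seqs), nchar(seqs), rate)
  hit <- which(nerr > 0)
  for (i in hit) {
    pos <- sample.int(nchar(seqs[i]), nerr[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Write a simulated library to disk
#'
#' Writes `<prefix>_R1.fastq`, `<prefix>_R2.fastq` and `<prefix>_truth.tsv`.
#'
#' @param sim Result of [simulate_library()].
#' @param prefix Output path prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_library <- function(sim, prefix) {
  paths <- c(r1 = paste0(prefix, "_R1.fastq"), r2 = paste0(prefix, "_R2.fastq"),
             truth = paste0(prefix, "_truth.tsv"))
  write_fastq(tibble(id = sim$reads$id, seq = sim$reads$r1_seq, qual = sim$reads$r1_qual),
              paths[["r1"]])
  write_fastq(tibble(id = sim$reads$id, seq = sim$reads$r2_seq, qual = sim$reads$r2_qual),
              paths[["r2"]])
  readr::write_tsv(sim$truth, paths[["truth"]], progress = FALSE)
  invisible(paths)
}
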