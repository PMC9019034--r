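# Shared fixtures and independent oracles, all built in code.

# deterministic small genome + single enriched region
toy_world <- function(seed = 7, genome_length = 50000, masked_fraction = 0.05,
                      region = c(10000, 40000)) {
  genome <- simulate_genome(genome_length, masked_fraction, seed = seed)
  regions <- target_regions(names(genome), region[1], region[2], name = "regionA")
  list(genome = genome, regions = regions,
       regions_seq = add_region_seq(regions, genome))
}

# run the processing chain from simulated reads to called junctions
process_sim <- function(sim, world) {
  r1 <- tibble::tibble(id = sim$reads$id, seq = sim$reads$r1_seq, qual = sim$reads$r1_qual)
  r2 <- tibble::tibble(id = sim$reads$id, seq = sim$reads$r2_seq, qual = sim$reads$r2_qual)
  tr <- trim_adapters(r1, r2)
  merged <- merge_pairs(tr$r1, tr$r2)
  seg <- split_chimeric(merged, world$regions_seq)
  seg <- place_segments(seg, merged, world$genome)
  list(merged = merged, segments = seg, junctions = call_junctions(seg))
}

# orientation-free junction identity key
junction_key <- function(d) {
  paste(d$chrom1, pmin(d$pos1, d$pos2), pmax(d$pos1, d$pos2))
}

# brute-force O(n^2) single-linkage wobble dedup oracle
oracle_dedup <- function(jx, wobble = 2) {
  n <- nrow(jx)
  near <- function(u, v) abs(outer(u, v, "-")) <= wobble
  adj <- near(jx$pos1, jx$pos1) & near(jx$pos2, jx$pos2) &
    near(jx$sonication_left, jx$sonication_left) &
    near(jx$sonication_right, jx$sonication_right) &
    outer(jx$chrom1, jx$chrom1, "==") & outer(jx$chrom2, jx$chrom2, "==")
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  rep_ord <- order(jx$read_id, jx$pos1, jx$pos2, jx$sonication_left, jx$sonication_right)
  keep <- rep_ord[!duplicated(comp[rep_ord])]
  sort(keep)
}

# random junction fixture dense enough to force wobble clusters
random_junctions <- function(n, span = 400, seed = 42) {
  withr::with_seed(seed, {
    tibble::tibble(
      read_id = sprintf("r%04d", sample(n)),
      chrom1 = "chrS",
      pos1 = sample.int(span, n, replace = TRUE),
      strand1 = sample(c("+", "-"), n, replace = TRUE),
      chrom2 = "chrS",
      pos2 = sample.int(span, n, replace = TRUE) + span,
      strand2 = sample(c("+", "-"), n, replace = TRUE),
      sonication_left = sample.int(span, n, replace = TRUE),
      sonication_right = sample.int(span, n, replace = TRUE) + 2 * span,
      distance = NA_real_
    ) |>
      dplyr::mutate(distance = abs(pos2 - pos1))
  })
}

# random symmetric non-negative matrix with positive entries
random_symmetric_counts <- function(n, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(n * n, 5) + stats::runif(n * n), n, n)
    m <- m + t(m)
    m
  })
}
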