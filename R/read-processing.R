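# From raw FASTQ pairs to genomically placed read segments:
# 3' adapter trimming, overlap-merging of mates into single molecules,
# local-alignment splitting of chimeric reads against the target-region
# sequences (first pass) and placement confirmation against the full
# reference (second pass).

# standard Illumina TruSeq 3' adapters
DEFAULT_ADAPTER_R1 <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"
DEFAULT_ADAPTER_R2 <- "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT"

# trim the 3' adapter from one vector of reads.
# Longest suffix of the read matching a prefix of the adapter wins; matches
# of >= 10 bp tolerate 10% mismatches, shorter matches (down to min_match)
# must be exact. Returns the new read lengths (NA = untrimmed).
trim_one <- function(seqs, adapter, min_match = 3L, max_mismatch_frac = 0.1) {
  len <- nchar(seqs)
  alen <- nchar(adapter)
  new_len <- rep(NA_integer_, length(seqs))
  # reads carrying an adapter seed somewhere: per-read descending scan.
  # Three staggered 6-mer seeds so that matches with up to two mismatches
  # (the 10% tolerance at typical match lengths) are still screened in.
  seeds <- unique(substring(adapter, c(1L, 7L, 13L), c(6L, 12L, 18L)))
  seeds <- seeds[nchar(seeds) == 6L]
  araw <- charToRaw(adapter)
  cand <- Reduce(`|`, lapply(seeds, function(s) stringi::stri_detect_fixed(seqs, s)))
  cand <- which(cand)
  for (i in cand) {
    li <- len[i]
    rraw <- charToRaw(seqs[i])
    for (o in seq(min(alen, li), 10L, by = -1L)) {
      mism <- sum(rraw[(li - o + 1L):li] != araw[1:o])
      if (mism <= floor(o * max_mismatch_frac)) {
        new_len[i] <- li - o
        break
      }
    }
  }
  # short exact suffix matches for everything still untrimmed
  for (o in seq(min(9L, alen), min_match, by = -1L)) {
    todo <- which(is.na(new_len) & len >= o)
    if (!length(todo)) next
    hit <- substring(seqs[todo], len[todo] - o + 1L, len[todo]) == substr(adapter, 1L, o)
    new_len[todo[hit]] <- len[todo[hit]] - o
  }
  new_len
}

#' Trim 3' adapters from a read pair
#'
#' Adapter-matching suffixes are removed (minimum match 3 bp; matches of 10
#' bp or more tolerate 10% mismatches). Pairs in which either mate drops
#' below `min_len` after trimming are discarded.
#'
#' @param r1,r2 Read tibbles (`id`, `seq`, `qual`) as from [read_fastq()];
#'   mates must be in sync.
#' @param adapter1,adapter2 Adapter sequences (defaults: standard Illumina
#'   TruSeq).
#' @param min_len Minimum post-trim read length to keep a pair (default 20).
#' @return List with trimmed `r1`, `r2` and a `stats` list
#'   (`n_in`, `n_trimmed`, `n_dropped`).
#' @export
trim_adapters <- function(r1, r2,
                          adapter1 = DEFAULT_ADAPTER_R1,
                          adapter2 = DEFAULT_ADAPTER_R2,
                          min_len = 20L) {
  if (nrow(r1) != nrow(r2)) abort("mates out of sync: R1 and R2 differ in length")
  t1 <- trim_one(r1$seq, adapter1)
  t2 <- trim_one(r2$seq, adapter2)
  n_trimmed <- sum(!is.na(t1) | !is.na(t2))
  l1 <- ifelse(is.na(t1), nchar(r1$seq), t1)
  l2 <- ifelse(is.na(t2), nchar(r2$seq), t2)
  keep <- l1 >= min_len & l2 >= min_len
  out1 <- tibble(id = r1$id[keep], seq = substr(r1$seq[keep], 1L, l1[keep]),
                 qual = substr(r1$qual[keep], 1L, l1[keep]))
  out2 <- tibble(id = r2$id[keep], seq = substr(r2$seq[keep], 1L, l2[keep]),
                 qual = substr(r2$qual[keep], 1L, l2[keep]))
  list(r1 = out1, r2 = out2,
       stats = list(n_in = nrow(r1), n_trimmed = n_trimmed,
                    n_dropped = sum(!keep)))
}

#' Merge overlapping mates into single molecules
#'
#' If the 3' end of R1 and the reverse complement of R2 share an overlap of
#' at least `min_overlap` bp with mismatch density at most
#' `max_mismatch_density`, the pair is spliced into one consensus read (the
#' higher-quality base wins at mismatches). Non-overlapping pairs are passed
#' through as two unmerged reads tagged with the mate rank (`/1`, `/2`).
#'
#' @param r1,r2 Read tibbles (`id`, `seq`, `qual`), mates in sync.
#' @param min_overlap Minimum overlap in bp (default 10).
#' @param max_mismatch_density Maximum fraction of mismatches tolerated in
#'   the overlap (default 0.25).
#' @return Tibble of merged reads: `id`, `seq`, `qual`, `length`, `merged`,
#'   `mate_overlap`.
#' @export
merge_pairs <- function(r1, r2, min_overlap = 10L, max_mismatch_density = 0.25) {
  if (nrow(r1) != nrow(r2)) abort("mates out of sync: R1 and R2 differ in length")
  n <- nrow(r1)
  if (n == 0) {
    return(tibble(id = character(), seq = character(), qual = character(),
                  length = integer(), merged = logical(), mate_overlap = integer()))
  }
  s1 <- r1$seq
  s2r <- revcomp(r2$seq)
  q2r <- stringi::stri_reverse(r2$qual)
  l1 <- nchar(s1)
  l2 <- nchar(s2r)
  ov <- rep(NA_integer_, n)
  # exact overlap scan, largest first (vectorised over reads)
  maxo <- pmin(l1, l2)
  for (o in seq(max(maxo), min_overlap, by = -1L)) {
    todo <- which(is.na(ov) & maxo >= o)
    if (!length(todo)) next
    hit <- substring(s1[todo], l1[todo] - o + 1L, l1[todo]) == substring(s2r[todo], 1L, o)
    ov[todo[hit]] <- o
  }
  # mismatch-tolerant fallback for pairs without an exact overlap
  mism_at <- vector("list", n)
  todo <- which(is.na(ov))
  for (i in todo) {
    a <- charToRaw(s1[i])
    b <- charToRaw(s2r[i])
    for (o in seq(maxo[i], min_overlap, by = -1L)) {
      d <- which(a[(l1[i] - o + 1L):l1[i]] != b[1:o])
      if (length(d) <= max_mismatch_density * o) {
        ov[i] <- o
        mism_at[[i]] <- d
        break
      }
    }
  }
  merged <- !is.na(ov)
  out <- vector("list", 2L)
  if (any(merged)) {
    mo <- ov[merged]
    ms1 <- s1[merged]
    ms2 <- s2r[merged]
    mseq <- paste0(ms1, substring(ms2, mo + 1L, l2[merged]))
    mqual <- paste0(r1$qual[merged], substring(q2r[merged], mo + 1L, l2[merged]))
    # consensus at mismatching overlap positions: higher-quality base wins
    mi <- which(lengths(mism_at[merged]) > 0)
    for (j in mi) {
      o <- mo[j]
      li <- nchar(ms1[j])
      for (d in mism_at[merged][[j]]) {
        p1 <- li - o + d           # position in R1/consensus
        qa <- utf8ToInt(substr(r1$qual[merged][j], p1, p1))
        qb <- utf8ToInt(substr(q2r[merged][j], d, d))
        if (qb > qa) {
          substr(mseq[j], p1, p1) <- substr(ms2[j], d, d)
          substr(mqual[j], p1, p1) <- substr(q2r[merged][j], d, d)
        }
      }
    }
    out[[1L]] <- tibble(id = r1$id[merged], seq = mseq, qual = mqual,
                        length = nchar(mseq), merged = TRUE,
                        mate_overlap = mo)
  }
  if (any(!merged)) {
    um <- which(!merged)
    out[[2L]] <- tibble(
      id = c(paste0(r1$id[um], "/1"), paste0(r2$id[um], "/2")),
      seq = c(s1[um], r2$seq[um]),
      qual = c(r1$qual[um], r2$qual[um]),
      length = c(l1[um], nchar(r2$seq[um])),
      merged = FALSE,
      mate_overlap = 0L
    )
  }
  bind_rows(out)
}

#' Split chimeric reads against the target-region sequences
#'
#' First-pass mapping: finds gap-free local alignments of each read to the
#' capture-enriched region sequences (both strands) above the minimum
#' length/identity, then greedily selects a set of segments that tile the
#' read with query overlaps below 5 bp. Reads without any segment are
#' uninformative (off-target) and absent from the output.
#'
#' @param reads Tibble with `id` and `seq` columns (e.g. from
#'   [merge_pairs()]).
#' @param regions Regions tibble carrying sequence.
#' @param k Seed k-mer length (also the minimum detectable segment length).
#' @param min_len Minimum segment length in bp (default 20).
#' @param min_identity Minimum segment identity (default 0.9).
#' @param max_overlap Maximum tolerated query overlap between selected
#'   segments (default 5, matching the junction-adjacency rule).
#' @param max_seed_gap Maximum query gap bridged within one seed chain
#'   (default 35; bridges isolated substitutions).
#' @return Segment tibble ordered by read and query position: `read_id`,
#'   `q_start`, `q_end`, `region`, `chrom`, `g_start`, `g_end`, `strand`,
#'   `score`, `identity`. Genomic coordinates are absolute (region offset
#'   applied). Attribute `stats` carries `n_reads`, `n_on_target`,
#'   `on_target_fraction`.
#' @export
split_chimeric <- function(reads, regions, k = 20L, min_len = 20L,
                           min_identity = 0.9, max_overlap = 5L,
                           max_seed_gap = 35L) {
  regions <- check_regions(regions, need_seq = TRUE)
  stopifnot(all(c("id", "seq") %in% names(reads)))
  targets <- setNames(toupper(regions$seq), regions$name)
  index <- kmer_index(targets, k)
  hits <- seed_hits(reads$seq, index, k)
  chains <- chain_seeds(hits, k, max_seed_gap)
  chains <- score_chains(chains, reads$seq, targets, k)
  chains <- chains[q_end - q_start >= min_len & identity >= min_identity]
  if (nrow(chains) > 0) {
    chains[, keep := greedy_select(q_start, q_end, score, max_overlap), by = ridx]
    chains <- chains[keep == TRUE][, keep := NULL]
  }
  setorder(chains, ridx, q_start)
  seg <- tibble(
    read_id = reads$id[chains$ridx],
    q_start = chains$q_start, q_end = chains$q_end,
    region = chains$target,
    chrom = regions$chrom[match(chains$target, regions$name)],
    g_start = chains$g_start + regions$start[match(chains$target, regions$name)],
    g_end = chains$g_end + regions$start[match(chains$target, regions$name)],
    strand = chains$strand,
    score = chains$score, identity = chains$identity
  )
  n_on <- dplyr::n_distinct(seg$read_id)
  attr(seg, "stats") <- list(n_reads = nrow(reads), n_on_target = n_on,
                             on_target_fraction = n_on / max(nrow(reads), 1L))
  seg
}

#' Confirm segment placement against the full reference
#'
#' Second-pass mapping: each split sub-read is re-aligned against the whole
#' reference genome. Segments whose best second-pass placement disagrees
#' with the first-pass locus by more than `max_shift` bp, or which map
#' equally well to two distinct loci, are flagged ambiguous and dropped
#' (kept with flags when `keep_all = TRUE`).
#'
#' @param segments Segment tibble from [split_chimeric()].
#' @param reads The read tibble the segments were called from.
#' @param genome Named character vector of chromosome sequences.
#' @param max_shift Maximum tolerated disagreement between passes (default
#'   1000 bp).
#' @param k Seed k-mer length (default 20).
#' @return Segment tibble with confirmed genomic coordinates; attribute
#'   `stats` carries `n_in`, `n_ambiguous`, `n_discordant`.
#' @export
place_segments <- function(segments, reads, genome, max_shift = 1000L,
                           k = 20L, keep_all = FALSE) {
  if (nrow(segments) == 0) return(segments)
  missing <- setdiff(unique(segments$chrom), names(genome))
  if (length(missing)) {
    abort(sprintf("reference is missing chromosome(s): %s", paste(missing, collapse = ", ")))
  }
  seqs <- substring(reads$seq[match(segments$read_id, reads$id)],
                    segments$q_start + 1L, segments$q_end)
  index <- kmer_index(genome, k)
  hits <- seed_hits(seqs, index, k)
  placements <- chain_seeds(hits, k, max_seed_gap = 35L)
  # best placement(s) per segment by seed support
  best <- placements[order(ridx, -nseed, target, g_start)][, .SD[nseed == max(nseed)], by = ridx]
  top <- best[, .(chrom2 = target[1L], g_start2 = g_start[1L], g_end2 = g_end[1L],
                  strand2 = strand[1L],
                  ambiguous = .N > 1L &&
                    (length(unique(target)) > 1L || diff(range(g_start)) > 5)),
              by = ridx]
  m <- match(seq_len(nrow(segments)), top$ridx)
  found <- !is.na(m)
  ambiguous <- rep(FALSE, nrow(segments))
  discordant <- rep(TRUE, nrow(segments))  # unplaced counts as discordant
  g2s <- segments$g_start
  g2e <- segments$g_end
  ambiguous[found] <- top$ambiguous[m[found]]
  same_chrom <- found & top$chrom2[m] == segments$chrom
  shift <- abs(top$g_start2[m] - segments$g_start)
  discordant[same_chrom] <- shift[same_chrom] > max_shift
  ok <- found & !ambiguous & !discordant
  g2s[ok] <- top$g_start2[m[ok]]
  g2e[ok] <- top$g_end2[m[ok]]
  out <- segments
  out$g_start <- g2s
  out$g_end <- g2e
  out$ambiguous <- ambiguous
  out$concordant <- !discordant & !ambiguous
  stats <- list(n_in = nrow(segments), n_ambiguous = sum(ambiguous),
                n_discordant = sum(discordant & !ambiguous))
  if (!keep_all) {
    out <- out[out$concordant, !(names(out) %in% c("ambiguous", "concordant"))]
  }
  attr(out, "stats") <- stats
  out
}
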