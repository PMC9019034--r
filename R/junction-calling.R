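# Reconstruction of exact ligation junctions from adjacent read segments,
# PCR-duplicate removal with +/-2 bp coordinate wobble, and distance
# filtering.

#' Call ligation junctions from read segments
#'
#' For each pair of consecutive segments of one read whose read-coordinate
#' gap or overlap is below `max_gap` bp, one junction is emitted. The
#' junction coordinate of a segment is its junction-proximal end
#' (`g_end` for `+` strand, `g_start` for `-`). Query overlaps between the
#' two segments (ambiguous junction placement: the overlapping bases match
#' both fragments' genomes) are resolved canonically by assigning the
#' overlap to the first segment, i.e. the junction is shifted maximally
#' along the first fragment — the same normalisation the simulator applies
#' to its ground truth. Reads with three or more segments yield all
#' consecutive-pair junctions. Sonication ends are the outer genomic
#' coordinates of the read's first and last segments.
#'
#' Partners are canonically ordered so that `(chrom1, pos1) <=
#' (chrom2, pos2)`.
#'
#' @param segments Segment tibble ([split_chimeric()] or
#'   [place_segments()]), read-coordinate sorted within reads.
#' @param max_gap Maximum read-space gap/overlap for two fragment ends to be
#'   called as one junction (default 5 bp, exclusive: a 5 bp gap does not
#'   qualify).
#' @return Junction tibble: `read_id`, `chrom1`, `pos1`, `strand1`,
#'   `chrom2`, `pos2`, `strand2`, `sonication_left`, `sonication_right`,
#'   `distance` (bp, `NA` for inter-chromosomal pairs).
#' @export
call_junctions <- function(segments, max_gap = 5L) {
  empty <- tibble(read_id = character(), chrom1 = character(), pos1 = numeric(),
                  strand1 = character(), chrom2 = character(), pos2 = numeric(),
                  strand2 = character(), sonication_left = numeric(),
                  sonication_right = numeric(), distance = numeric())
  if (nrow(segments) == 0) return(empty)
  seg <- segments %>%
    group_by(.data$read_id) %>%
    arrange(.data$q_start, .by_group = TRUE) %>%
    mutate(
      outer_first = if_else(.data$strand[1L] == "+", .data$g_start[1L], .data$g_end[1L]),
      outer_last = if_else(.data$strand[n()] == "+", .data$g_end[n()], .data$g_start[n()]),
      nxt_q_start = lead(.data$q_start), nxt_chrom = lead(.data$chrom),
      nxt_g_start = lead(.data$g_start), nxt_g_end = lead(.data$g_end),
      nxt_strand = lead(.data$strand)
    ) %>%
    ungroup() %>%
    filter(!is.na(.data$nxt_q_start), abs(.data$nxt_q_start - .data$q_end) < max_gap)
  if (nrow(seg) == 0) return(empty)
  # overlap resolved canonically: trim the next segment's start
  trim <- pmax(seg$q_end - seg$nxt_q_start, 0)
  p1 <- if_else(seg$strand == "+", seg$g_end, seg$g_start)
  p2 <- if_else(seg$nxt_strand == "+", seg$nxt_g_start + trim, seg$nxt_g_end - trim)
  jx <- tibble(
    read_id = seg$read_id,
    chrom1 = seg$chrom, pos1 = p1, strand1 = seg$strand,
    chrom2 = seg$nxt_chrom, pos2 = p2, strand2 = seg$nxt_strand,
    sonication_left = pmin(seg$outer_first, seg$outer_last),
    sonication_right = pmax(seg$outer_first, seg$outer_last)
  )
  # canonical partner ordering
  swap <- jx$chrom2 < jx$chrom1 | (jx$chrom1 == jx$chrom2 & jx$pos2 < jx$pos1)
  jx[swap, c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")] <-
    jx[swap, c("chrom2", "pos2", "strand2", "chrom1", "pos1", "strand1")]
  jx$distance <- ifelse(jx$chrom1 == jx$chrom2, abs(jx$pos2 - jx$pos1), NA_real_)
  jx
}

#' Remove PCR duplicates with coordinate wobble
#'
#' Two junctions are duplicates iff they share the chromosome pair and all
#' four of `sonication_left`, `sonication_right`, `pos1`, `pos2` differ by
#' at most `wobble` bp. Duplicates are clustered by single linkage on this
#' relation and one representative per cluster is kept (lowest `read_id`,
#' lexicographically), which makes the output independent of input order.
#'
#' @param junctions Junction tibble from [call_junctions()].
#' @param wobble Per-coordinate tolerance in bp (default 2).
#' @return Deduplicated junction tibble; attribute `stats` carries `n_raw`
#'   and `n_unique`.
#' @export
dedup_junctions <- function(junctions, wobble = 2L) {
  n <- nrow(junctions)
  if (n == 0) {
    attr(junctions, "stats") <- list(n_raw = 0L, n_unique = 0L)
    return(junctions)
  }
  ord <- order(junctions$sonication_left)
  sl <- junctions$sonication_left[ord]
  # candidate pairs: sonication_left within wobble (two-pointer window)
  hi <- findInterval(sl + wobble, sl)
  i <- rep.int(seq_len(n), pmax(hi - seq_len(n), 0L))
  j <- sequence(pmax(hi - seq_len(n), 0L)) + i
  if (length(i)) {
    a <- ord[i]
    b <- ord[j]
    same <- junctions$chrom1[a] == junctions$chrom1[b] &
      junctions$chrom2[a] == junctions$chrom2[b] &
      abs(junctions$pos1[a] - junctions$pos1[b]) <= wobble &
      abs(junctions$pos2[a] - junctions$pos2[b]) <= wobble &
      abs(junctions$sonication_right[a] - junctions$sonication_right[b]) <= wobble
    a <- a[same]
    b <- b[same]
  } else {
    a <- b <- integer(0)
  }
  comp <- union_find(n, a, b)
  rep_ord <- order(junctions$read_id, junctions$pos1, junctions$pos2,
                   junctions$sonication_left, junctions$sonication_right)
  keep <- rep_ord[!duplicated(comp[rep_ord])]
  out <- junctions[sort(keep), , drop = FALSE]
  attr(out, "stats") <- list(n_raw = n, n_unique = nrow(out))
  out
}

# union-find with path halving; returns component labels 1..n
union_find <- function(n, a, b) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(a)) {
    ra <- find(a[k])
    rb <- find(b[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  vapply(seq_len(n), find, integer(1))
}

#' Filter junctions by minimum intra-chromosomal distance
#'
#' Removes intra-chromosomal junctions with `distance < min_distance`
#' (so `distance == min_distance` is retained). Inter-chromosomal junctions
#' are kept. The density-plot export uses 10 bp; matrices use an
#' independently configurable threshold (default 0).
#'
#' @param junctions Junction tibble.
#' @param min_distance Minimum distance in bp (default 10).
#' @return Filtered junction tibble.
#' @export
filter_junctions <- function(junctions, min_distance = 10) {
  if (min_distance < 0) abort("`min_distance` must be >= 0")
  if (min_distance == 0) return(junctions)
  keep <- is.na(junctions$distance) | junctions$distance >= min_distance
  junctions[keep, , drop = FALSE]
}
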