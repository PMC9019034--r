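# Capture panel design: fixed-length oligos tiled across each target region
# with a constant step (oligo_len - overlap), a right-anchored terminal oligo
# so the region end is always covered, and repeat/homopolymer/N filtering
# based on the soft-masking carried by the input FASTA.

#' Tile target regions with candidate capture oligos
#'
#' Candidate oligos start at `region_start + k * step` with
#' `step = oligo_len - overlap`; if the final regular tile does not reach the
#' region end, one extra oligo ending exactly at the region end is appended,
#' so every base of the region is coverable. All oligos have length
#' `oligo_len`.
#'
#' @param regions Regions tibble carrying sequence (see [add_region_seq()]).
#' @param oligo_len Oligo length in nt (default 70).
#' @param overlap Overlap between consecutive oligos in nt (default 35).
#' @return Oligo tibble: `region`, `chrom`, `start`, `end`, `seq`,
#'   `repeat_fraction`, `max_homopolymer`, `accepted` (all `TRUE` before
#'   filtering), `rejection_reason`.
#' @export
#' @examples
#' r <- target_regions("chrS", 0, 105, name = "toy",
#'                     seq = paste(rep("ACGTA", 21), collapse = ""))
#' tile_region(r)  # two tiles: [0,70) and [35,105)
tile_region <- function(regions, oligo_len = 70L, overlap = 35L) {
  regions <- check_regions(regions, need_seq = TRUE)
  if (overlap <= 0 || overlap >= oligo_len) abort("need 0 < overlap < oligo_len")
  step <- oligo_len - overlap
  short <- regions$end - regions$start < oligo_len
  if (any(short)) {
    abort(sprintf("region(s) shorter than oligo_len (%d nt): %s", oligo_len,
                  paste(regions$name[short], collapse = ", ")))
  }
  oligos <- purrr::pmap_dfr(regions, function(chrom, start, end, name, seq, ...) {
    L <- end - start
    starts <- start + step * (0:floor((L - oligo_len) / step))
    if (max(starts) + oligo_len < end) starts <- c(starts, end - oligo_len)
    off <- starts - start
    oseq <- substring(seq, off + 1, off + oligo_len)
    tibble(region = name, chrom = chrom, start = starts, end = starts + oligo_len,
           seq = oseq)
  })
  oligos$repeat_fraction <- stringi::stri_count_charclass(oligos$seq, "[a-zN]") / oligo_len
  oligos$max_homopolymer <- max_homopolymer_run(oligos$seq)
  oligos$accepted <- TRUE
  oligos$rejection_reason <- NA_character_
  attr(oligos, "design") <- list(oligo_len = as.integer(oligo_len),
                                 overlap = as.integer(overlap),
                                 step = as.integer(step))
  oligos
}

# longest single-base run per sequence, case-insensitive
max_homopolymer_run <- function(seqs) {
  vapply(toupper(seqs), function(s) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    max(r$lengths)
  }, integer(1), USE.NAMES = FALSE)
}

#' Filter tiled oligos for repeats, homopolymers and Ns
#'
#' Rejection rules, in order of precedence: any `N` base (`N_content`),
#' soft-masked/`N` fraction above `repeat_threshold` (`repeat`), or a
#' homopolymer run longer than `homopolymer_max` (`homopolymer`). The
#' accepted set is the panel; an empty accepted set is valid but warned
#' about.
#'
#' @param oligos Oligo tibble from [tile_region()].
#' @param repeat_threshold Maximum tolerated repeat (soft-masked) fraction
#'   (default 0.3).
#' @param homopolymer_max Maximum tolerated homopolymer run (default 10).
#' @return The oligo tibble with `accepted`/`rejection_reason` filled in.
#' @export
filter_repeats <- function(oligos, repeat_threshold = 0.3, homopolymer_max = 10L) {
  stopifnot(all(c("seq", "repeat_fraction", "max_homopolymer") %in% names(oligos)))
  has_n <- grepl("[Nn]", oligos$seq)
  rep_bad <- oligos$repeat_fraction > repeat_threshold
  hp_bad <- oligos$max_homopolymer > homopolymer_max
  reason <- rep(NA_character_, nrow(oligos))
  reason[hp_bad] <- "homopolymer"
  reason[rep_bad] <- "repeat"
  reason[has_n] <- "N_content"
  oligos$accepted <- is.na(reason)
  oligos$rejection_reason <- reason
  if (!any(oligos$accepted)) warn("all oligos rejected; panel is empty")
  oligos
}

#' Design a capture panel in one call
#'
#' Convenience wrapper: [tile_region()] followed by [filter_repeats()].
#'
#' @inheritParams tile_region
#' @inheritParams filter_repeats
#' @return Filtered oligo tibble.
#' @export
design_panel <- function(regions, oligo_len = 70L, overlap = 35L,
                         repeat_threshold = 0.3, homopolymer_max = 10L) {
  des <- tile_region(regions, oligo_len = oligo_len, overlap = overlap)
  out <- filter_repeats(des, repeat_threshold = repeat_threshold,
                        homopolymer_max = homopolymer_max)
  attr(out, "design") <- attr(des, "design")
  out
}

#' Per-region panel coverage report
#'
#' @param oligos Oligo tibble (filtered or not; unfiltered oligos count as
#'   accepted).
#' @param regions Regions tibble used for the design.
#' @return Tibble with one row per region: oligo counts, bases covered at
#'   least once and at least twice, fraction covered, and the largest
#'   uncovered gap left by rejections.
#' @export
panel_report <- function(oligos, regions) {
  regions <- check_regions(regions)
  purrr::pmap_dfr(regions[c("chrom", "start", "end", "name")],
                  function(chrom, start, end, name) {
    o <- oligos[oligos$region == name & oligos$accepted, , drop = FALSE]
    L <- end - start
    cov <- integer(L)
    for (i in seq_len(nrow(o))) {
      idx <- (o$start[i] - start + 1):(o$end[i] - start)
      cov[idx] <- cov[idx] + 1L
    }
    gaps <- rle(cov == 0L)
    largest_gap <- if (any(gaps$values)) max(gaps$lengths[gaps$values]) else 0L
    tibble(region = name, length = L,
           n_oligos = sum(oligos$region == name),
           n_accepted = nrow(o),
           covered_1x = sum(cov >= 1L), covered_2x = sum(cov >= 2L),
           frac_covered = sum(cov >= 1L) / L,
           largest_gap = largest_gap)
  })
}

#' Write a designed panel to FASTA, BED and a TSV report
#'
#' Oligo FASTA names encode coordinates as `chrom:start-end`; the BED carries
#' the accept/reject status in column 5.
#'
#' @param oligos Oligo tibble.
#' @param regions Regions tibble used for the design.
#' @param prefix Output path prefix; writes `<prefix>.fa`, `<prefix>.bed`,
#'   `<prefix>_report.tsv`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_panel <- function(oligos, regions, prefix) {
  acc <- oligos[oligos$accepted, , drop = FALSE]
  fa <- setNames(acc$seq, sprintf("%s:%d-%d", acc$chrom, acc$start, acc$end))
  paths <- c(fasta = paste0(prefix, ".fa"), bed = paste0(prefix, ".bed"),
             report = paste0(prefix, "_report.tsv"))
  write_fasta(fa, paths[["fasta"]])
  bed <- oligos[c("chrom", "start", "end")]
  bed$name <- sprintf("%s_oligo%d", oligos$region, seq_len(nrow(oligos)))
  bed$score <- ifelse(oligos$accepted, "accepted", oligos$rejection_reason)
  readr::write_tsv(bed, paths[["bed"]], col_names = FALSE, progress = FALSE)
  readr::write_tsv(panel_report(oligos, regions), paths[["report"]], progress = FALSE)
  invisible(paths)
}
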