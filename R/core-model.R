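# Coordinate conventions, binning arithmetic and the theoretical-resolution
# utility shared by every other module.
#
# All genomic intervals are 0-based, half-open [start, end). A "regions"
# tibble has columns chrom/start/end/name and, once sequence is attached,
# seq (uppercase plus soft-masked lowercase, N allowed).

#' Construct a target-region tibble
#'
#' A thin validated constructor for the tabular region representation used
#' throughout the package: one row per capture-enriched region of interest.
#'
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open interval bounds (bp).
#' @param name Optional region labels; defaults to `region1`, `region2`, ...
#' @param seq Optional DNA sequences of length `end - start` (soft-masked
#'   lowercase preserved).
#' @return A tibble with columns `chrom`, `start`, `end`, `name` and,
#'   if supplied, `seq`.
#' @export
#' @examples
#' target_regions("chrS", 0, 1000, name = "toy")
target_regions <- function(chrom, start, end, name = NULL, seq = NULL) {
  out <- tibble(chrom = as.character(chrom), start = as.numeric(start),
                end = as.numeric(end))
  if (!is.null(name)) out$name <- as.character(name)
  if (!is.null(seq)) out$seq <- as.character(seq)
  check_regions(out, need_seq = !is.null(seq))
}

#' Attach region sequence from a genome
#'
#' @param regions Regions tibble (`chrom`, `start`, `end`, ...).
#' @param genome Named character vector of chromosome sequences, as returned
#'   by [read_fasta()].
#' @return `regions` with a `seq` column (case preserved from the genome).
#' @export
add_region_seq <- function(regions, genome) {
  regions <- check_regions(regions)
  missing <- setdiff(unique(regions$chrom), names(genome))
  if (length(missing)) {
    abort(sprintf("genome is missing chromosome(s): %s", paste(missing, collapse = ", ")))
  }
  too_long <- regions$end > nchar(genome[regions$chrom])
  if (any(too_long)) abort("region end beyond chromosome length")
  regions$seq <- unname(substring(genome[regions$chrom], regions$start + 1, regions$end))
  regions
}

#' Define a binning grid over one region
#'
#' Bins are half-open, left-anchored at `start`; the last bin may be short
#' when the region length is not a multiple of `binsize` and is a
#' full-status bin.
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open region bounds.
#' @param binsize Bin width in bp (e.g. 20, 50, 500).
#' @return An object of class `bin_grid`.
#' @export
#' @examples
#' g <- bin_grid("chrS", 0, 999, binsize = 500)
#' g$n_bins  # 2, last bin is 499 bp
bin_grid <- function(chrom, start, end, binsize) {
  if (length(chrom) != 1 || !nzchar(chrom)) abort("`chrom` must be a single non-empty string")
  if (start < 0 || start >= end) abort("need 0 <= start < end")
  if (binsize <= 0) abort("`binsize` must be positive")
  structure(
    list(chrom = chrom, start = as.numeric(start), end = as.numeric(end),
         binsize = as.numeric(binsize),
         n_bins = as.integer(ceiling((end - start) / binsize))),
    class = "bin_grid"
  )
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> %s:%d-%d, binsize %d bp, %d bins\n",
              x$chrom, x$start, x$end, x$binsize, x$n_bins))
  invisible(x)
}

#' Map genomic positions to bin ordinals
#'
#' @param pos Genomic position(s), 0-based, inside the grid's region.
#' @param grid A [bin_grid()].
#' @return Integer bin ordinal(s) in `0:(n_bins - 1)`.
#' @export
#' @examples
#' g <- bin_grid("chrS", 100, 1100, 500)
#' bin_index(c(100, 120, 1099), g)
bin_index <- function(pos, grid) {
  stopifnot(inherits(grid, "bin_grid"))
  if (any(pos < grid$start | pos >= grid$end)) {
    abort(sprintf("position(s) outside region %s:%d-%d", grid$chrom, grid$start, grid$end))
  }
  as.integer(floor((pos - grid$start) / grid$binsize))
}

# left coordinate of bin i (0-based ordinal)
bin_start <- function(grid, i) grid$start + i * grid$binsize

#' Expected restriction-fragment length for a recognition-motif length
#'
#' Under a uniform i.i.d. base composition a restriction enzyme with a
#' `motif_len`-bp recognition site cuts on average every `4^motif_len` bp,
#' which bounds the resolution attainable with restriction-enzyme-based 3C:
#' 256 bp for a 4-cutter, 4096 bp for a 6-cutter. MNase digestion is largely
#' sequence-independent, so MNase-based libraries are not subject to this
#' bound — ligation junctions can form (and be resolved) at any position.
#'
#' @param motif_len Non-negative integer motif length(s).
#' @return Expected fragment length(s) in bp (`4^motif_len`).
#' @export
#' @examples
#' expected_fragment_length(c(4, 6))
expected_fragment_length <- function(motif_len) {
  if (any(motif_len < 0)) abort("`motif_len` must be >= 0")
  if (any(motif_len != floor(motif_len))) abort("`motif_len` must be integer-valued")
  4^motif_len
}
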