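# File-format boundaries: FASTA (soft-masking preserved), BED (3+ columns,
# native 0-based half-open), FASTQ (plain or gzipped), pairs-style junction
# TSV (1-based on disk, 0-based in memory).

#' Read a FASTA file, preserving soft-masking
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences; lowercase (repeat-masked)
#'   bases are preserved as-is.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  # keep only the first whitespace-delimited token of each header
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = width)
  invisible(path)
}

#' Read a BED file of regions
#'
#' BED is 0-based half-open, matching the package's internal convention, so
#' coordinates pass through unchanged.
#'
#' @param path Path to a BED (3+ column) file.
#' @return Regions tibble with columns `chrom`, `start`, `end`, `name` and
#'   any extra BED columns as `X5`, `X6`, ...
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       show_col_types = FALSE, progress = FALSE)
  if (ncol(x) < 3) abort(sprintf("BED file %s has fewer than 3 columns", path))
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 4) names(x)[4] <- "name"
  check_regions(x)
}

#' Write regions to BED
#'
#' @param regions Regions tibble; `chrom`, `start`, `end` and, if present,
#'   `name` plus any additional columns are written.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  regions <- check_regions(regions)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(regions))
  readr::write_tsv(regions[cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path Path to a FASTQ or FASTQ.gz file.
#' @return Tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  if (length(lines) %% 4 != 0) {
    abort(sprintf("malformed FASTQ %s: %d lines is not a multiple of 4 (truncated record %d)",
                  path, length(lines), length(lines) %/% 4 + 1))
  }
  n <- length(lines) %/% 4
  hd <- lines[seq(1, length(lines), by = 4)]
  sq <- lines[seq(2, length(lines), by = 4)]
  pl <- lines[seq(3, length(lines), by = 4)]
  ql <- lines[seq(4, length(lines), by = 4)]
  bad <- which(!startsWith(hd, "@") | !startsWith(pl, "+") | nchar(sq) != nchar(ql))
  if (length(bad)) {
    abort(sprintf("malformed FASTQ %s: bad record %d", path, bad[1]))
  }
  tibble(id = sub("\\s.*$", "", sub("^@", "", hd)), seq = sq, qual = ql)
}

#' Write a FASTQ file
#'
#' @param reads Tibble with columns `id`, `seq`, `qual`.
#' @param path Output path (gzipped if it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write a junction table in pairs-style TSV
#'
#' Positions are written 1-based for compatibility with pairs-format
#' consumers; [read_pairs()] converts back to the internal 0-based
#' convention.
#'
#' @param junctions Junction tibble (see [call_junctions()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(junctions, path) {
  cols <- c("read_id", "chrom1", "pos1", "chrom2", "pos2", "strand1", "strand2",
            "sonication_left", "sonication_right")
  stopifnot(all(cols %in% names(junctions)))
  out <- junctions[cols]
  out$pos1 <- out$pos1 + 1
  out$pos2 <- out$pos2 + 1
  out$sonication_left <- out$sonication_left + 1
  out$sonication_right <- out$sonication_right + 1
  names(out) <- c("readID", "chr1", "pos1", "chr2", "pos2", "strand1", "strand2",
                  "sonication_left", "sonication_right")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a pairs-style junction TSV written by [write_pairs()]
#'
#' @param path Path to the TSV.
#' @return Junction tibble with 0-based coordinates.
#' @export
read_pairs <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[names(x) == "readID"] <- "read_id"
  names(x)[names(x) == "chr1"] <- "chrom1"
  names(x)[names(x) == "chr2"] <- "chrom2"
  x$pos1 <- x$pos1 - 1
  x$pos2 <- x$pos2 - 1
  x$sonication_left <- x$sonication_left - 1
  x$sonication_right <- x$sonication_right - 1
  x$distance <- ifelse(x$chrom1 == x$chrom2, abs(x$pos2 - x$pos1), NA_real_)
  tibble::as_tibble(x)
}
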