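# Small shared helpers. All coordinates in the package are 0-based, half-open;
# conversion to 1-based happens only at I/O boundaries that require it.

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement. Case is preserved (soft-masked lowercase
#' stays lowercase), `N`/`n` are self-complementary.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "aacgTN"))
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", x))
}

# number of mismatching positions between equal-length strings (vectorised)
str_mismatches <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) return(integer(0))
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b, USE.NAMES = FALSE)
}

# uniform random DNA string of length n (uppercase)
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# validate a regions tibble (chrom/start/end[/name[/seq]])
check_regions <- function(regions, need_seq = FALSE) {
  req <- c("chrom", "start", "end")
  if (!is.data.frame(regions) || !all(req %in% names(regions))) {
    abort("`regions` must be a data frame with columns chrom, start, end")
  }
  if (nrow(regions) == 0L) abort("`regions` is empty")
  bad <- regions$start < 0 | regions$start >= regions$end | !nzchar(regions$chrom)
  if (any(bad)) {
    abort(sprintf("invalid interval(s) at row(s) %s: need 0 <= start < end and non-empty chrom",
                  paste(which(bad), collapse = ", ")))
  }
  if (!"name" %in% names(regions)) regions$name <- sprintf("region%d", seq_len(nrow(regions)))
  if (need_seq) {
    if (!"seq" %in% names(regions)) abort("`regions` must carry a `seq` column; see add_region_seq()")
    if (any(nchar(regions$seq) != regions$end - regions$start)) {
      abort("region sequence length must equal end - start")
    }
  }
  tibble::as_tibble(regions)
}

# derive a substream seed from a base seed (kept below 2^31)
derive_seed <- function(seed, offset) {
  (abs(as.integer(seed)) + 1013L * as.integer(offset)) %% 2147483587L
}
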