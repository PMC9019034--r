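# Internal gap-free seed-and-extend local aligner used for chimeric-read
# splitting (first pass, against target-region sequences) and placement
# confirmation (second pass, against the full reference).
#
# Strategy: exact k-mer seeds on both strands, chained per
# (read, target, strand, diagonal); seed chains separated by a query gap
# small enough to be bridged by substitutions are merged into one gap-free
# segment whose identity is computed by direct string comparison. This is a
# deliberately simple aligner: the library's fragments are short (>= 20 bp
# after sonication splitting) and the contract only requires gap-free local
# alignments above a minimum score/identity.

#' @import data.table
NULL

.datatable.aware <- TRUE

# k-mer index of a set of sequences, both strands.
# Returns data.table(kmer, target, pos, strand), keyed by kmer; pos is the
# 0-based position of the k-mer on the forward strand.
kmer_index <- function(seqs, k) {
  stopifnot(length(seqs) > 0, !is.null(names(seqs)))
  parts <- lapply(names(seqs), function(nm) {
    s <- toupper(seqs[[nm]])
    L <- nchar(s)
    if (L < k) return(NULL)
    n <- L - k + 1L
    km <- substring(s, 1:n, k:L)
    data.table(kmer = c(km, revcomp(km)),
               target = nm,
               pos = rep(0:(n - 1L), 2L),
               strand = rep(c("+", "-"), each = n))
  })
  dt <- rbindlist(parts)
  setkey(dt, kmer)
  dt
}

# all k-mer seed hits of reads against an index.
# seqs: character vector; returns data.table(ridx, q, target, pos, strand).
seed_hits <- function(seqs, index, k, chunk_size = 4000L) {
  n <- length(seqs)
  out <- vector("list", ceiling(n / chunk_size))
  for (ci in seq_along(out)) {
    idx <- ((ci - 1L) * chunk_size + 1L):min(ci * chunk_size, n)
    lens <- nchar(seqs[idx])
    nk <- pmax(lens - k + 1L, 0L)
    if (sum(nk) == 0) next
    ridx <- rep(idx, nk)
    q <- sequence(nk) - 1L
    kmers <- substring(rep(toupper(seqs[idx]), nk), q + 1L, q + k)
    reads_dt <- data.table(kmer = kmers, ridx = ridx, q = q)
    out[[ci]] <- index[reads_dt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  }
  rbindlist(out)
}

# chain seeds into gap-free segments.
# Returns data.table(ridx, target, strand, q_start, q_end, g_start, g_end, nseed).
chain_seeds <- function(hits, k, max_seed_gap = 35L) {
  if (nrow(hits) == 0) {
    return(data.table(ridx = integer(), target = character(), strand = character(),
                      q_start = integer(), q_end = integer(),
                      g_start = numeric(), g_end = numeric(), nseed = integer()))
  }
  hits <- copy(hits)
  hits[, diag := fifelse(strand == "+", pos - q, pos + q)]
  setorder(hits, ridx, target, strand, diag, q)
  hits[, grp := rleid(ridx, target, strand, diag)]
  hits[, newc := c(TRUE, diff(q) > max_seed_gap), by = grp]
  hits[, chain := cumsum(newc)]
  chains <- hits[, .(ridx = ridx[1L], target = target[1L], strand = strand[1L],
                     diag = diag[1L], q_start = q[1L], q_end = q[.N] + k,
                     nseed = .N), by = chain]
  chains[, g_start := fifelse(strand == "+", diag + q_start, diag - q_end + k)]
  chains[, g_end := fifelse(strand == "+", diag + q_end, diag - q_start + k)]
  chains[, c("chain", "diag") := NULL]
  chains[]
}

# score chains against read and target sequences; adds identity and score.
# read_seqs indexed by ridx; targets: named character vector (local coords).
score_chains <- function(chains, read_seqs, targets, k) {
  if (nrow(chains) == 0) {
    chains[, `:=`(identity = numeric(), score = numeric())]
    return(chains)
  }
  len <- chains$q_end - chains$q_start
  dense <- chains$nseed == len - k + 1L
  mism <- integer(nrow(chains))
  need <- which(!dense)
  if (length(need)) {
    rs <- substring(toupper(read_seqs[chains$ridx[need]]),
                    chains$q_start[need] + 1L, chains$q_end[need])
    ts <- substring(toupper(targets[chains$target[need]]),
                    chains$g_start[need] + 1L, chains$g_end[need])
    minus <- chains$strand[need] == "-"
    ts[minus] <- revcomp(ts[minus])
    mism[need] <- str_mismatches(rs, ts)
  }
  chains[, identity := (len - mism) / len]
  chains[, score := len - 2L * mism]
  chains[]
}

# greedy selection of segments tiling the read with query overlaps < max_overlap
greedy_select <- function(q_start, q_end, score, max_overlap = 5L) {
  o <- order(-score, q_start, q_end)
  keep <- logical(length(score))
  aqs <- numeric(0)
  aqe <- numeric(0)
  for (i in o) {
    if (length(aqs)) {
      ov <- pmin(aqe, q_end[i]) - pmax(aqs, q_start[i])
      if (any(ov >= max_overlap)) next
    }
    keep[i] <- TRUE
    aqs <- c(aqs, q_start[i])
    aqe <- c(aqe, q_end[i])
  }
  keep
}
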