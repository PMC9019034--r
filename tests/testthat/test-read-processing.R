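adapter <- tiledmcc:::DEFAULT_ADAPTER_R1
adapter2 <- tiledmcc:::DEFAULT_ADAPTER_R2

mk_reads <- function(seqs, ids = sprintf("r%d", seq_along(seqs))) {
  tibble::tibble(id = ids, seq = seqs, qual = strrep("F", nchar(seqs)))
}

test_that("adapter trimming removes 3' adapter suffixes and drops short pairs", {
  insert <- withr::with_seed(1, tiledmcc:::random_dna(80))
  # ensure the fixture read does not end in an accidental adapter prefix
  stopifnot(substr(insert, 78, 80) != substr(adapter, 1, 3))
  full <- paste0(insert, adapter)                   # full adapter read-through
  partial <- paste0(insert, substr(adapter, 1, 6))  # short exact suffix
  r1 <- mk_reads(c(full, insert, partial))
  r2 <- mk_reads(c(insert, insert, insert))
  out <- trim_adapters(r1, r2)
  expect_identical(out$r1$seq, c(insert, insert, insert))
  expect_identical(out$r2$seq, rep(insert, 3))
  expect_equal(out$stats$n_trimmed, 2)
  expect_equal(out$stats$n_dropped, 0)
  expect_identical(nchar(out$r1$qual), nchar(out$r1$seq))
})

test_that("adapter matches of >= 10 bp tolerate 10% mismatches", {
  insert <- withr::with_seed(2, tiledmcc:::random_dna(60))
  stopifnot(substr(insert, 58, 60) != substr(adapter, 1, 3))
  ad20 <- substr(adapter, 1, 20)
  substr(ad20, 10, 10) <- if (substr(ad20, 10, 10) == "A") "C" else "A"
  r1 <- mk_reads(paste0(insert, ad20))
  out <- trim_adapters(r1, mk_reads(insert))
  expect_identical(out$r1$seq, insert)
})

test_that("pairs reduced below 20 bp after trimming are dropped and counted", {
  small <- withr::with_seed(3, tiledmcc:::random_dna(5))
  r1 <- mk_reads(c(paste0(small, adapter),
                   withr::with_seed(4, tiledmcc:::random_dna(100))))
  r2 <- mk_reads(c(withr::with_seed(5, tiledmcc:::random_dna(100)),
                   withr::with_seed(6, tiledmcc:::random_dna(100))))
  out <- trim_adapters(r1, r2)
  expect_equal(out$stats$n_dropped, 1)
  expect_equal(nrow(out$r1), 1)
  expect_identical(out$r1$id, "r2")
})

test_that("overlapping mates merge into the spliced consensus", {
  mol <- withr::with_seed(7, tiledmcc:::random_dna(270))
  r1 <- mk_reads(substr(mol, 1, 150))
  r2 <- mk_reads(revcomp(substr(mol, 121, 270)))
  out <- merge_pairs(r1, r2)
  expect_equal(nrow(out), 1)
  expect_true(out$merged)
  expect_equal(out$length, 270)          # 150 + 150 - 30
  expect_equal(out$mate_overlap, 30)
  expect_identical(out$seq, mol)
})

test_that("disjoint mates pass through as two unmerged reads", {
  a <- withr::with_seed(8, tiledmcc:::random_dna(150))
  b <- withr::with_seed(9, tiledmcc:::random_dna(150))
  out <- merge_pairs(mk_reads(a, "x"), mk_reads(b, "x"))
  expect_equal(nrow(out), 2)
  expect_false(any(out$merged))
  expect_identical(out$id, c("x/1", "x/2"))
  expect_identical(out$seq[1], a)
})

test_that("the higher-quality base wins at overlap mismatches", {
  s <- withr::with_seed(10, tiledmcc:::random_dna(40))
  s_alt <- s
  substr(s_alt, 20, 20) <- if (substr(s, 20, 20) == "G") "T" else "G"
  # fully-overlapping mates disagreeing at one base
  r1 <- tibble::tibble(id = "m", seq = s, qual = strrep("F", 40))        # Q37
  r2_seq <- revcomp(s_alt)
  q2 <- strrep("#", 40)                                                  # Q2
  out <- merge_pairs(r1, tibble::tibble(id = "m", seq = r2_seq, qual = q2))
  expect_true(out$merged)
  expect_identical(out$seq, s)           # R1 base kept
  # now make R2 the high-quality mate
  out2 <- merge_pairs(tibble::tibble(id = "m", seq = s, qual = strrep("#", 40)),
                      tibble::tibble(id = "m", seq = r2_seq, qual = strrep("F", 40)))
  expect_identical(out2$seq, s_alt)      # R2 base kept
})

# deterministic chimeric fixture: two loci whose junction is unambiguous
chimera_world <- function(seed = 11, p = 500, frag = 75) {
  g <- withr::with_seed(seed, tiledmcc:::random_dna(3000))
  q <- 2000
  repeat {
    fwd_ok <- substr(g, q + 1, q + 1) != substr(g, p + frag + 1, p + frag + 1)
    bwd_ok <- substr(g, p + frag, p + frag) != substr(g, q, q)
    if (fwd_ok && bwd_ok) break
    q <- q + 1
  }
  region <- target_regions("chrS", 0, 3000, name = "regionA", seq = g)
  list(genome = setNames(g, "chrS"), region = region, p = p, q = q, frag = frag)
}

test_that("chimeric reads split into segments at the exact junction", {
  w <- chimera_world()
  read <- paste0(substr(w$genome, w$p + 1, w$p + w$frag),
                 substr(w$genome, w$q + 1, w$q + w$frag))
  seg <- split_chimeric(mk_reads(read, "chim"), w$region)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$q_start, c(0, 75))
  expect_equal(seg$q_end, c(75, 150))
  expect_equal(seg$g_start, c(w$p, w$q))
  expect_equal(seg$g_end, c(w$p + 75, w$q + 75))
  expect_identical(seg$strand, c("+", "+"))
  expect_equal(seg$identity, c(1, 1))
})

test_that("non-chimeric and off-target reads are handled as such", {
  w <- chimera_world()
  whole <- substr(w$genome, 101, 260)
  seg <- split_chimeric(mk_reads(whole, "plain"), w$region)
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$q_start, seg$q_end), c(0, 160))

  foreign <- withr::with_seed(99, tiledmcc:::random_dna(160))
  both <- split_chimeric(mk_reads(c(whole, foreign)), w$region)
  expect_equal(nrow(both), 1)           # foreign read yields no segment
  st <- attr(both, "stats")
  expect_equal(st$n_reads, 2)
  expect_equal(st$n_on_target, 1)
  expect_equal(st$on_target_fraction, 0.5)
  expect_error(split_chimeric(mk_reads(whole), w$region[0, ]), "empty")
})

test_that("a substitution inside a segment is bridged and lowers identity", {
  w <- chimera_world()
  p1 <- substr(w$genome, w$p + 1, w$p + 75)
  substr(p1, 37, 37) <- if (substr(p1, 37, 37) == "A") "G" else "A"
  read <- paste0(p1, substr(w$genome, w$q + 1, w$q + 75))
  seg <- split_chimeric(mk_reads(read, "sub"), w$region)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$q_end[1] - seg$q_start[1], 75)
  expect_equal(seg$identity[1], 74 / 75)
  expect_equal(seg$g_start[1], w$p)
})

test_that("selected segments never overlap by 5 bp or more in the query", {
  world <- toy_world(seed = 37)
  sim <- simulate_library(world$regions, world$genome,
                          sim_config(seed = 12, n_ligation_events = 600,
                                     error_rate = 0, pcr_duplicate_rate = 0))
  r1 <- tibble::tibble(id = sim$reads$id, seq = sim$reads$r1_seq, qual = sim$reads$r1_qual)
  r2 <- tibble::tibble(id = sim$reads$id, seq = sim$reads$r2_seq, qual = sim$reads$r2_qual)
  merged <- merge_pairs(r1, r2)
  seg <- split_chimeric(merged, world$regions_seq)
  bad <- seg |>
    dplyr::group_by(read_id) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::summarise(viol = {
      any(vapply(seq_along(q_start), function(i) {
        any(pmin(q_end[-i], q_end[i]) - pmax(q_start[-i], q_start[i]) >= 5)
      }, logical(1)))
    })
  expect_false(any(bad$viol))
})

test_that("second-pass placement confirms concordant segments and flags ambiguity", {
  w <- chimera_world()
  read <- paste0(substr(w$genome, w$p + 1, w$p + w$frag),
                 substr(w$genome, w$q + 1, w$q + w$frag))
  rd <- mk_reads(read, "chim")
  seg <- split_chimeric(rd, w$region)
  placed <- place_segments(seg, rd, w$genome)
  expect_equal(placed$g_start, seg$g_start)   # concordant: unchanged
  expect_equal(nrow(placed), 2)

  # duplicated 80 bp block > 1 kb apart: equally good second-pass placements
  block <- withr::with_seed(15, tiledmcc:::random_dna(80))
  gdup <- setNames(paste0(block, withr::with_seed(16, tiledmcc:::random_dna(1500)),
                          block, withr::with_seed(17, tiledmcc:::random_dna(500))),
                   "chrS")
  rdup <- target_regions("chrS", 0, nchar(gdup), name = "regionA", seq = gdup[[1]])
  rd2 <- mk_reads(substr(block, 1, 75), "dup")
  seg2 <- split_chimeric(rd2, rdup)
  placed2 <- place_segments(seg2, rd2, gdup, keep_all = TRUE)
  expect_true(all(placed2$ambiguous))
  placed2_drop <- place_segments(seg2, rd2, gdup)
  expect_equal(nrow(placed2_drop), 0)
  expect_equal(attr(placed2_drop, "stats")$n_ambiguous, nrow(seg2))

  expect_error(place_segments(seg, rd, c(other = "ACGT")), "missing chromosome")
})
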