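jx_at <- function(pos1, pos2, chrom = "chrS", read_id = NULL) {
  n <- length(pos1)
  tibble::tibble(read_id = read_id %||% sprintf("r%d", seq_len(n)),
                 chrom1 = chrom, pos1 = pos1, strand1 = "+",
                 chrom2 = chrom, pos2 = pos2, strand2 = "+",
                 sonication_left = pmin(pos1, pos2) - 50,
                 sonication_right = pmax(pos1, pos2) + 50,
                 distance = abs(pos2 - pos1))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("binning is symmetric and conserves junction mass", {
  grid <- bin_grid("chrS", 0, 5000, 500)
  m1 <- bin_junctions(jx_at(100, 1100), grid)
  expect_equal(sum(m1$counts), 2)                  # off-diagonal counted twice
  expect_equal(m1$counts[1, 3], 1)
  expect_equal(m1$counts[3, 1], 1)
  m2 <- bin_junctions(jx_at(600, 900), grid)       # both ends in bin 1
  expect_equal(m2$counts[2, 2], 1)
  expect_equal(sum(m2$counts), 1)
  m3 <- bin_junctions(jx_at(c(10, 600, 2600), c(1100, 3200, 4700)), grid)
  expect_equal(sum(m3$counts), 6)                  # three distinct off-diagonal pairs
  # out-of-region junctions are skipped and counted
  m4 <- bin_junctions(jx_at(c(100, 100), c(1100, 9000)), grid)
  expect_equal(m4$n_skipped, 1)
  expect_equal(sum(m4$counts), 2)
})

test_that("mass conservation holds for random junction sets", {
  grid <- bin_grid("chrS", 0, 2000, 100)
  jx <- withr::with_seed(11, jx_at(sample.int(2000, 300, TRUE) - 1,
                                   sample.int(2000, 300, TRUE) - 1))
  m <- bin_junctions(jx, grid)
  b1 <- bin_index(jx$pos1, grid)
  b2 <- bin_index(jx$pos2, grid)
  expect_equal(sum(m$counts), 2 * sum(b1 != b2) + sum(b1 == b2))
  expect_identical(m$counts, t(m$counts))
})

test_that("ICE balancing equalises row sums and is idempotent", {
  # already balanced 2x2: unchanged up to global scale
  g2 <- bin_grid("chrS", 0, 1000, 500)
  cm <- tiledmcc:::new_contact_matrix(matrix(c(0, 4, 4, 0), 2), g2)
  bal <- ice_balance(cm)
  expect_true(bal$converged)
  expect_equal(bal$balanced, cm$counts)
  expect_equal(bal$bias, c(1, 1))

  # random symmetric positive 10x10
  g10 <- bin_grid("chrS", 0, 1000, 100)
  m <- random_symmetric_counts(10, seed = 2)
  bal10 <- ice_balance(tiledmcc:::new_contact_matrix(m, g10))
  rs <- rowSums(bal10$balanced)
  expect_lt(max(rs) - min(rs), 1e-4 * mean(rs))
  expect_equal(sum(bal10$balanced), sum(m))  # mass preserved

  # idempotence: re-balancing a balanced matrix moves nothing beyond tol
  again <- ice_balance(tiledmcc:::new_contact_matrix(bal10$balanced, g10))
  expect_lt(max(abs(again$balanced - bal10$balanced)), 1e-5 * mean(bal10$balanced))
})

test_that("zero-marginal bins are masked; empty matrices refuse to balance", {
  g <- bin_grid("chrS", 0, 400, 100)
  m <- random_symmetric_counts(4, seed = 3)
  m[2, ] <- 0
  m[, 2] <- 0
  bal <- ice_balance(tiledmcc:::new_contact_matrix(m, g))
  expect_identical(bal$mask, c(FALSE, TRUE, FALSE, FALSE))
  expect_true(is.na(bal$bias[2]))
  expect_true(all(bal$balanced[2, ] == 0))
  rs <- rowSums(bal$balanced)[!bal$mask]
  expect_lt(max(rs) - min(rs), 1e-4 * mean(rs))
  empty <- tiledmcc:::new_contact_matrix(matrix(0, 3, 3), bin_grid("chrS", 0, 300, 100))
  expect_error(ice_balance(empty), "all bins are masked")
})

test_that("downsampling equalises table sizes deterministically", {
  ta <- jx_at(seq(0, 990, 10), seq(0, 990, 10) + 3000)   # 100 junctions
  tb <- ta[1:80, ]
  ds <- downsample_junctions(list(a = ta, b = tb), seed = 4)
  expect_equal(vapply(ds, nrow, integer(1)), c(a = 80L, b = 80L))
  expect_identical(ds$b, tb)                              # already at min size
  ds2 <- downsample_junctions(list(a = ta, b = tb), seed = 4)
  expect_identical(ds, ds2)                               # same seed, same subset
  ds3 <- downsample_junctions(list(a = ta, b = tb), seed = 5)
  expect_false(identical(ds$a, ds3$a))
  expect_error(downsample_junctions(list(a = ta)), ">= 2")
  expect_error(downsample_junctions(list(a = ta, b = tb[0, ])), "empty")
})

test_that("differential matrices subtract balanced signal with union masking", {
  g <- bin_grid("chrS", 0, 3000, 500)
  ja <- withr::with_seed(6, jx_at(sample.int(3000, 400, TRUE) - 1,
                                  sample.int(3000, 400, TRUE) - 1))
  ma <- ice_balance(bin_junctions(ja, g))
  d0 <- differential_matrix(ma, ma)
  expect_true(all(d0$balanced == 0))

  # anchor-pair enrichment present in A only shows up positive
  extra <- jx_at(rep(250, 60) + withr::with_seed(8, sample.int(100, 60, TRUE)),
                 rep(2250, 60) + withr::with_seed(9, sample.int(100, 60, TRUE)))
  mb <- ice_balance(bin_junctions(dplyr::bind_rows(ja, extra), g))
  d <- differential_matrix(mb, ma)
  expect_gt(d$balanced[1, 5], 0)
  top <- which(d$balanced == max(d$balanced), arr.ind = TRUE)[1, ]
  expect_setequal(unname(top), c(1, 5))  # symmetric matrix: either orientation

  # union masking
  ja2 <- ja[bin_index(ja$pos1, g) != 2 & bin_index(ja$pos2, g) != 2, ]
  mz <- ice_balance(bin_junctions(ja2, g))
  dz <- differential_matrix(mz, ma)
  expect_true(dz$mask[3])
  expect_true(all(dz$balanced[3, ] == 0))
  # grid mismatch is an error
  other <- ice_balance(bin_junctions(ja, bin_grid("chrS", 0, 3000, 100)))
  expect_error(differential_matrix(ma, other), "grid mismatch")
})

test_that("density points honour the distance filter and scale linearly", {
  lone <- density_points(jx_at(1000, 5000))
  expect_equal(nrow(lone), 1)
  lone2 <- density_points(jx_at(21000, 38000))
  expect_equal(lone$density, lone2$density)  # kernel self-weight is constant
  expect_gt(lone$density, 0)

  twin <- density_points(jx_at(c(1000, 1000), c(5000, 5000)))
  expect_equal(twin$density, rep(2 * lone$density, 2))

  # junctions closer than 10 bp are excluded
  close <- density_points(jx_at(c(1000, 2000), c(1005, 2500)))
  expect_equal(nrow(close), 1)
  expect_equal(close$x, 2000)
  expect_equal(nrow(density_points(jx_at(1000, 1005))), 0)

  # ascending density ordering so dense points draw last
  mix <- density_points(jx_at(c(1000, 1000, 4000), c(5000, 5000, 9000)))
  expect_true(!is.unsorted(mix$density))
})

test_that("tidy, glance and matrix export expose consistent views", {
  g <- bin_grid("chrS", 0, 2000, 500)
  jx <- jx_at(c(100, 600, 600, 150, 1300, 200),
              c(1600, 1100, 1100, 800, 1700, 900))
  cm <- ice_balance(bin_junctions(jx, g))
  td <- tidy(cm)
  expect_equal(nrow(td), 4 * 5 / 2)
  expect_equal(sum(td$count[td$bin1 != td$bin2]) * 2 + sum(td$count[td$bin1 == td$bin2]),
               sum(cm$counts))
  gl <- glance(cm)
  expect_equal(gl$n_bins, 4L)
  expect_true(gl$balanced)
  expect_true(gl$converged)

  tmp <- withr::local_tempdir()
  paths <- write_contact_matrix(cm, file.path(tmp, "m"))
  expect_true(all(file.exists(paths)))
  dense <- as.matrix(readr::read_tsv(paths[["dense"]], col_names = FALSE,
                                     show_col_types = FALSE))
  expect_equal(unname(dense), unname(cm$counts))
  meta <- jsonlite::read_json(paths[["json"]])
  expect_equal(meta$binsize, 500)
  expect_equal(meta$n_bins, 4)

  p <- ggplot2::autoplot(cm)
  expect_s3_class(p, "ggplot")
  dp <- plot_density_points(density_points(jx))
  expect_s3_class(dp, "ggplot")
})
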