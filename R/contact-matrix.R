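# Binned contact matrices from junction tables: raw binning, ICE balancing,
# condition-matched downsampling, differential matrices and density-plot
# export.

new_contact_matrix <- function(counts, grid, balanced = NULL, bias = NULL,
                               mask = NULL, scale = "linear",
                               converged = NA, n_iter = NA_integer_,
                               n_skipped = 0L) {
  structure(list(counts = counts, grid = grid, balanced = balanced,
                 bias = bias, mask = mask, scale = scale,
                 converged = converged, n_iter = n_iter,
                 n_skipped = n_skipped),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s:%d-%d, %d bp bins (%d x %d), total counts %g%s\n",
              x$grid$chrom, x$grid$start, x$grid$end, x$grid$binsize,
              x$grid$n_bins, x$grid$n_bins, sum(x$counts),
              if (!is.null(x$balanced)) ", ICE-balanced" else ""))
  invisible(x)
}

#' Bin junctions into a raw contact matrix
#'
#' Each junction with both ends inside the grid's region increments
#' `counts[b1, b2]` and `counts[b2, b1]` (the diagonal once when
#' `b1 == b2`), so the total off-diagonal mass equals twice the number of
#' off-diagonal junctions. Junctions outside the region are skipped and
#' counted.
#'
#' @param junctions Junction tibble.
#' @param grid A [bin_grid()].
#' @return A `contact_matrix` (raw counts; `n_skipped` records out-of-region
#'   junctions).
#' @export
bin_junctions <- function(junctions, grid) {
  stopifnot(inherits(grid, "bin_grid"))
  inside <- junctions$chrom1 == grid$chrom & junctions$chrom2 == grid$chrom &
    junctions$pos1 >= grid$start & junctions$pos1 < grid$end &
    junctions$pos2 >= grid$start & junctions$pos2 < grid$end
  jx <- junctions[inside, , drop = FALSE]
  n <- grid$n_bins
  counts <- matrix(0, n, n)
  if (nrow(jx) > 0) {
    bb1 <- bin_index(jx$pos1, grid) + 1L
    bb2 <- bin_index(jx$pos2, grid) + 1L
    b1 <- pmin(bb1, bb2)
    b2 <- pmax(bb1, bb2)
    tab <- table((b1 - 1L) * n + b2)
    idx <- as.integer(names(tab))
    counts[cbind((idx - 1L) %/% n + 1L, (idx - 1L) %% n + 1L)] <- as.integer(tab)
    lower <- t(counts)
    diag(lower) <- 0
    counts <- counts + lower
  }
  new_contact_matrix(counts, grid, n_skipped = sum(!inside))
}

#' ICE-balance a contact matrix
#'
#' Iterative correction: bins with zero marginal are masked, then row sums
#' over unmasked bins are repeatedly normalised by their mean and divided
#' out (`W <- W / (s_i * s_j)`, `bias <- bias * s`) until the maximum
#' deviation of the normalised row sums from 1 drops below `tol` or
#' `max_iter` is reached. The balanced matrix is rescaled so its unmasked
#' mass equals the raw unmasked mass.
#'
#' @param x A `contact_matrix` with raw counts.
#' @param max_iter Maximum iterations (default 200).
#' @param tol Convergence tolerance on row sums (default 1e-5).
#' @return The `contact_matrix` with `balanced`, `bias`, `mask`,
#'   `converged` and `n_iter` filled in. Masked bins have `NA` bias and
#'   zeroed balanced rows/columns.
#' @export
ice_balance <- function(x, max_iter = 200L, tol = 1e-5) {
  stopifnot(inherits(x, "contact_matrix"))
  counts <- x$counts
  n <- nrow(counts)
  mask <- rowSums(counts) == 0
  if (all(mask)) abort("all bins are masked (empty matrix); cannot balance")
  W <- counts
  W[mask, ] <- 0
  W[, mask] <- 0
  bias <- rep(1, n)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    s <- rowSums(W)
    snorm <- s / mean(s[!mask])
    if (max(abs(snorm[!mask] - 1)) < tol) {
      converged <- TRUE
      break
    }
    snorm[mask | snorm == 0] <- 1
    bias <- bias * snorm
    W <- W / outer(snorm, snorm)
  }
  raw_mass <- sum(counts[!mask, !mask])
  bal_mass <- sum(W[!mask, !mask])
  if (bal_mass > 0) W <- W * (raw_mass / bal_mass)
  bias[mask] <- NA_real_
  x$balanced <- W
  x$bias <- bias
  x$mask <- mask
  x$converged <- converged
  x$n_iter <- iter
  x
}

#' Downsample junction tables to a common size
#'
#' Every table is sampled uniformly without replacement down to the lowest
#' unique-junction count across tables, so matrices built from them are
#' directly comparable. Deterministic for a fixed seed; tables are processed
#' in list order.
#'
#' @param tables Named list of (deduplicated, filtered) junction tibbles,
#'   one per condition or replicate.
#' @param seed Integer seed.
#' @return List of junction tibbles, all with the same number of rows.
#' @export
downsample_junctions <- function(tables, seed = 1L) {
  if (!is.list(tables) || length(tables) < 2) abort("need a list of >= 2 junction tables")
  sizes <- vapply(tables, nrow, integer(1))
  if (any(sizes == 0)) {
    nm <- names(tables)[sizes == 0]
    abort(sprintf("empty junction table(s): %s",
                  paste(if (is.null(nm)) which(sizes == 0) else nm, collapse = ", ")))
  }
  min_n <- min(sizes)
  withr::with_seed(as.integer(seed), {
    lapply(tables, function(tb) {
      if (nrow(tb) == min_n) return(tb)
      tb[sort(sample.int(nrow(tb), min_n)), , drop = FALSE]
    })
  })
}

#' Differential contact matrix
#'
#' Per-bin difference of two ICE-balanced matrices built from equally
#' downsampled junction tables on the same grid
#' (`balanced_A - balanced_B`). Bins masked in either input are masked in
#' the output.
#'
#' @param a,b Balanced `contact_matrix` objects on identical grids.
#' @return A `contact_matrix` whose `balanced` slot holds the signed
#'   difference (`scale = "difference"`; `counts` holds the raw count
#'   difference for reference).
#' @export
differential_matrix <- function(a, b) {
  stopifnot(inherits(a, "contact_matrix"), inherits(b, "contact_matrix"))
  ga <- a$grid
  gb <- b$grid
  if (!identical(ga[c("chrom", "start", "end", "binsize")],
                 gb[c("chrom", "start", "end", "binsize")])) {
    abort("grid mismatch between the two matrices")
  }
  if (is.null(a$balanced) || is.null(b$balanced)) {
    abort("both matrices must be ICE-balanced (see ice_balance())")
  }
  mask <- a$mask | b$mask
  d <- a$balanced - b$balanced
  d[mask, ] <- 0
  d[, mask] <- 0
  out <- new_contact_matrix(a$counts - b$counts, ga, balanced = d,
                            bias = NULL, mask = mask, scale = "difference")
  out
}

#' Junction density-plot points
#'
#' Junctions (intra-chromosomal, at least `min_distance` bp apart) are
#' binned on a 2-D grid of `cell_size` bp cells; the cell counts are
#' smoothed with a Gaussian kernel of `bandwidth` cells, and each junction
#' is annotated with the smoothed local density of its cell. Points are
#' returned sorted by ascending density so that dense points draw last.
#'
#' @param junctions Junction tibble.
#' @param cell_size Cell width in bp (default 20).
#' @param bandwidth Gaussian kernel sigma in cells (default 3).
#' @param min_distance Minimum junction distance in bp (default 10).
#' @return Tibble `x`, `y`, `density` (one row per retained junction).
#' @export
density_points <- function(junctions, cell_size = 20, bandwidth = 3,
                           min_distance = 10) {
  jx <- filter_junctions(junctions, min_distance)
  jx <- jx[!is.na(jx$distance), , drop = FALSE]
  if (nrow(jx) == 0) return(tibble(x = numeric(), y = numeric(), density = numeric()))
  cx <- floor(jx$pos1 / cell_size)
  cy <- floor(jx$pos2 / cell_size)
  r <- ceiling(3 * bandwidth)
  g <- stats::dnorm(-r:r, sd = bandwidth)
  g <- g / sum(g)
  ix <- cx - min(cx) + 1L
  iy <- cy - min(cy) + 1L
  H <- matrix(0, max(ix) + 2L * r, max(iy) + 2L * r)
  cnt <- dplyr::count(tibble(ix = ix + r, iy = iy + r), .data$ix, .data$iy)
  H[cbind(cnt$ix, cnt$iy)] <- cnt$n
  # separable Gaussian smoothing (rows then columns)
  H <- apply(H, 2, function(v) stats::filter(v, g, sides = 2))
  H <- t(apply(H, 1, function(v) stats::filter(v, g, sides = 2)))
  H[is.na(H)] <- 0
  tibble(x = jx$pos1, y = jx$pos2,
         density = H[cbind(ix + r, iy + r)]) %>%
    arrange(.data$density)
}

#' Write a contact matrix to disk
#'
#' Writes a dense TSV (`<prefix>_dense.tsv`), a COO triplet TSV
#' (`<prefix>_coo.tsv`: bin1, bin2, count and, when present, balanced) and a
#' sidecar JSON (`<prefix>.json`) describing region, binsize, mask and bias.
#'
#' @param x A `contact_matrix`.
#' @param prefix Output path prefix.
#' @param which Which matrix to write densely: "counts" or "balanced".
#' @return Named character vector of the written paths, invisibly.
#' @export
write_contact_matrix <- function(x, prefix, which = c("counts", "balanced")) {
  which <- match.arg(which)
  m <- if (which == "balanced") x$balanced else x$counts
  if (is.null(m)) abort(sprintf("matrix has no '%s' component", which))
  paths <- c(dense = paste0(prefix, "_dense.tsv"), coo = paste0(prefix, "_coo.tsv"),
             json = paste0(prefix, ".json"))
  utils::write.table(m, paths[["dense"]], sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  ut <- which(upper.tri(x$counts, diag = TRUE) & (x$counts != 0), arr.ind = TRUE)
  coo <- tibble(bin1 = ut[, 1] - 1L, bin2 = ut[, 2] - 1L,
                count = x$counts[ut])
  if (!is.null(x$balanced)) coo$balanced <- x$balanced[ut]
  readr::write_tsv(coo, paths[["coo"]], progress = FALSE)
  jsonlite::write_json(
    list(chrom = x$grid$chrom, start = x$grid$start, end = x$grid$end,
         binsize = x$grid$binsize, n_bins = x$grid$n_bins, scale = x$scale,
         mask = if (is.null(x$mask)) logical(0) else x$mask,
         bias = if (is.null(x$bias)) numeric(0) else x$bias,
         converged = x$converged, n_iter = x$n_iter),
    paths[["json"]], auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}

#' Tidy a contact matrix into a long tibble
#'
#' @param x A `contact_matrix`.
#' @param ... Unused.
#' @return Tibble with one row per upper-triangle bin pair: `bin1`, `bin2`,
#'   `start1`, `start2`, `count`, and `balanced`/`masked` when available.
#' @export
tidy.contact_matrix <- function(x, ...) {
  n <- x$grid$n_bins
  ut <- which(upper.tri(x$counts, diag = TRUE), arr.ind = TRUE)
  out <- tibble(bin1 = ut[, 1] - 1L, bin2 = ut[, 2] - 1L,
                start1 = bin_start(x$grid, ut[, 1] - 1L),
                start2 = bin_start(x$grid, ut[, 2] - 1L),
                count = x$counts[ut])
  if (!is.null(x$balanced)) out$balanced <- x$balanced[ut]
  if (!is.null(x$mask)) out$masked <- x$mask[ut[, 1]] | x$mask[ut[, 2]]
  out
}

#' One-row summary of a contact matrix
#'
#' @param x A `contact_matrix`.
#' @param ... Unused.
#' @return One-row tibble: bins, binsize, total counts, masked bins, ICE
#'   convergence state.
#' @export
glance.contact_matrix <- function(x, ...) {
  tibble(n_bins = x$grid$n_bins, binsize = x$grid$binsize,
         total_counts = sum(x$counts),
         n_masked = if (is.null(x$mask)) NA_integer_ else sum(x$mask),
         balanced = !is.null(x$balanced),
         converged = x$converged, n_iter = x$n_iter,
         n_skipped = x$n_skipped)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
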