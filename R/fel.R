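# Two-dimensional free-energy landscape over (RMSD, Rg) reaction
# coordinates by Boltzmann inversion of the occupancy histogram.

#' Free-energy landscape over (RMSD, Rg)
#'
#' Bins the paired per-frame series on a regular 2-D grid spanning the
#' observed data range (upper boundary of the last bin inclusive) and
#' converts counts to Gibbs energies by
#' `G_i = -kB T ln(N_i / N_max)` with `kB = 0.0083145 kJ/(mol K)`. The
#' modal bin has `G = 0`; empty bins are set to the unnatural-barrier
#' energy `max(finite G) + 2 kB T`.
#'
#' @param rmsd,rg `scalar_series` (or numeric vectors) of equal length.
#' @param n_bins integer vector of length 2: bins per axis (default
#'   `c(50, 50)`, each >= 2).
#' @param temperature Kelvin (default 300).
#' @return object of class `"landscape_grid"`: list with `rmsd_edges`,
#'   `rg_edges`, `counts` (RMSD bins x Rg bins), `G` (kJ/mol),
#'   `temperature`, `empty_bin_energy` and `bin_of_frame` (two-column
#'   matrix of per-frame bin indices).
#' @export
compute_fel <- function(rmsd, rg, n_bins = c(50, 50), temperature = 300) {
  xv <- if (inherits(rmsd, "scalar_series")) rmsd$values else as.numeric(rmsd)
  yv <- if (inherits(rg, "scalar_series")) rg$values else as.numeric(rg)
  if (length(xv) != length(yv))
    stop("series error: RMSD and Rg series differ in length")
  if (length(xv) < 1) stop("series error: empty series")
  n_bins <- rep(as.integer(n_bins), length.out = 2)
  if (any(n_bins < 2)) stop("n_bins must be >= 2 per axis")
  edges <- function(v, k) {
    r <- range(v)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)   # degenerate axis
    seq(r[1], r[2], length.out = k + 1)
  }
  ex <- edges(xv, n_bins[1]); ey <- edges(yv, n_bins[2])
  bin_of <- function(v, e) pmin(pmax(findInterval(v, e, all.inside = TRUE),
                                     1L), length(e) - 1L)
  bx <- bin_of(xv, ex); by <- bin_of(yv, ey)
  counts <- matrix(0L, n_bins[1], n_bins[2])
  for (f in seq_along(bx)) counts[bx[f], by[f]] <- counts[bx[f], by[f]] + 1L
  kBT <- .kB * temperature
  G <- matrix(NA_real_, n_bins[1], n_bins[2])
  pop <- counts > 0
  G[pop] <- -kBT * log(counts[pop] / max(counts))
  barrier <- max(G[pop]) + 2 * kBT
  G[!pop] <- barrier
  structure(list(rmsd_edges = ex, rg_edges = ey, counts = counts, G = G,
                 temperature = temperature, empty_bin_energy = barrier,
                 bin_of_frame = cbind(rmsd_bin = bx, rg_bin = by)),
            class = "landscape_grid")
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf(paste0("free-energy landscape: %d x %d bins, %d frames, ",
                     "T = %g K, barrier %.2f kJ/mol\n"),
              nrow(x$G), ncol(x$G), sum(x$counts), x$temperature,
              x$empty_bin_energy))
  invisible(x)
}

# connected component (8-neighborhood) of `open` cells containing `start`
.flood_fill <- function(open, start) {
  nx <- nrow(open); ny <- ncol(open)
  comp <- matrix(FALSE, nx, ny)
  stack <- list(start)
  comp[start[1], start[2]] <- TRUE
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (di in -1:1) for (dj in -1:1) {
      i <- cur[1] + di; j <- cur[2] + dj
      if (i < 1 || j < 1 || i > nx || j > ny) next
      if (open[i, j] && !comp[i, j]) {
        comp[i, j] <- TRUE
        stack[[length(stack) + 1]] <- c(i, j)
      }
    }
  }
  comp
}

#' Extract energy basins and representative frames
#'
#' Finds local minima of G over the populated bins (a bin is a minimum
#' when no 8-neighbor has lower G), merges minima that are not separated
#' by a real barrier -- a shallower minimum connected to a deeper one
#' through bins all within `merge_barrier` of its own G belongs to the
#' same basin, which keeps histogram noise inside one well from splitting
#' it -- then ranks basins by G and by count and keeps at most
#' `max_basins`. Each basin records its member frames (frames falling in
#' the minimum bin) and the representative frame whose (RMSD, Rg) lies
#' closest to the bin center.
#'
#' @param grid a [compute_fel()] result.
#' @param rmsd,rg the series the grid was built from (used to pick the
#'   representative frame).
#' @param max_basins maximum number of basins to report (default 2).
#' @param merge_barrier minimum barrier height (kJ/mol) for two minima to
#'   count as distinct basins; default `kB * temperature` (thermal
#'   energy).
#' @param min_occupancy smallest fraction of all frames a bin must hold
#'   to qualify as a basin minimum (default 0.01); screens out isolated
#'   outlier frames.
#' @return list of basins; each has `bin` (indices), `G` (kJ/mol),
#'   `count`, `member_frames`, `representative_frame`,
#'   `rmsd_range`/`rg_range` (the bin rectangle).
#' @export
extract_basins <- function(grid, rmsd, rg, max_basins = 2,
                           merge_barrier = 0.0083145 * grid$temperature,
                           min_occupancy = 0.01) {
  xv <- if (inherits(rmsd, "scalar_series")) rmsd$values else as.numeric(rmsd)
  yv <- if (inherits(rg, "scalar_series")) rg$values else as.numeric(rg)
  pop <- grid$counts > 0
  if (!any(pop)) stop("landscape error: no populated bins")
  nx <- nrow(grid$G); ny <- ncol(grid$G)
  min_count <- max(1, ceiling(min_occupancy * sum(grid$counts)))
  mins <- list()
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (!pop[i, j] || grid$counts[i, j] < min_count) next
    nb_i <- max(1, i - 1):min(nx, i + 1)
    nb_j <- max(1, j - 1):min(ny, j + 1)
    nbG <- grid$G[nb_i, nb_j]
    if (grid$G[i, j] <= min(nbG))
      mins[[length(mins) + 1]] <- c(i, j)
  }
  ord <- order(vapply(mins, function(b) grid$G[b[1], b[2]], numeric(1)),
               -vapply(mins, function(b) grid$counts[b[1], b[2]], numeric(1)))
  mins <- mins[ord]
  # drop minima reachable from a deeper one without climbing more than
  # merge_barrier above their own level (no real barrier between them)
  if (length(mins) > 1) {
    keep <- rep(TRUE, length(mins))
    for (k in seq_along(mins)[-1]) {
      lvl <- grid$G[mins[[k]][1], mins[[k]][2]] + merge_barrier
      comp <- .flood_fill(grid$G <= lvl, mins[[k]])
      for (m in seq_len(k - 1)) {
        if (keep[m] && comp[mins[[m]][1], mins[[m]][2]]) {
          keep[k] <- FALSE
          break
        }
      }
    }
    mins <- mins[keep]
  }
  mins <- mins[seq_len(min(max_basins, length(mins)))]
  lapply(mins, function(b) {
    i <- b[1]; j <- b[2]
    members <- which(grid$bin_of_frame[, 1] == i & grid$bin_of_frame[, 2] == j)
    cx <- mean(grid$rmsd_edges[i + 0:1]); cy <- mean(grid$rg_edges[j + 0:1])
    # distance in bin-width units so the two axes weigh equally
    wx <- diff(grid$rmsd_edges[i + 0:1]); wy <- diff(grid$rg_edges[j + 0:1])
    rep_frame <- members[which.min(((xv[members] - cx) / wx)^2 +
                                   ((yv[members] - cy) / wy)^2)]
    list(bin = c(i, j), G = grid$G[i, j], count = grid$counts[i, j],
         member_frames = members, representative_frame = rep_frame,
         rmsd_range = grid$rmsd_edges[i + 0:1],
         rg_range = grid$rg_edges[j + 0:1])
  })
}
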