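#' Neighbourhood fate composition
#'
#' For each receiver, the fraction of its `k` nearest receivers sharing its
#' fate is computed; cells are then binned as "homogeneous tissue" (more
#' than 75% same-fate neighbours), "borders" (25-75%, inclusive) or
#' "isolated cells" (less than 25%), and the three percentages of all
#' receivers are returned. The neighbourhood size is 5 in the reference
#' analysis.
#'
#' @param cells Cells data frame with fates assigned to all receivers.
#' @param lattice A `cp_lattice`.
#' @param k Neighbourhood size (default 5).
#' @return A `neighborhood_composition` object: list with `frac_homog`,
#'   `frac_border`, `frac_isolated` (percent, summing to 100), `k`, `n`.
#' @export
neighborhood_composition <- function(cells, lattice, k = 5) {
  rec <- cells[!cells$producer, ]
  if (nrow(rec) < k + 1)
    cp_stop(sprintf("need more than k = %d receivers", k),
            "cp_config_error")
  if (anyNA(rec$fate))
    cp_stop("all receiver fates must be assigned", "cp_config_error")
  v <- vectors_from_cells(lattice, cells)
  recv_mask <- v$occupied & !v$producer
  frac <- vapply(seq_len(nrow(rec)), function(i) {
    nb <- nearest_neighbors(lattice, rec$site[i], k = k,
                            occupied = recv_mask)
    mean(v$fate[nb] == fate_to_int(rec$fate[i]))
  }, numeric(1))
  structure(
    list(frac_homog = 100 * mean(frac > 0.75),
         frac_border = 100 * mean(frac >= 0.25 & frac <= 0.75),
         frac_isolated = 100 * mean(frac < 0.25),
         k = k, n = nrow(rec)),
    class = "neighborhood_composition"
  )
}

#' @export
print.neighborhood_composition <- function(x, ...) {
  cat(sprintf(
    "Neighbourhood composition (k = %d, n = %d):\n  homogeneous >75%%: %.1f%%\n  borders 25-75%%:  %.1f%%\n  isolated <25%%:   %.1f%%\n",
    x$k, x$n, x$frac_homog, x$frac_border, x$frac_isolated))
  invisible(x)
}

#' Binned 1D morphogen gradient across replicate runs
#'
#' Receiver contents are binned by distance from the producing margin; per
#' bin the replicate means are averaged and their standard deviation taken,
#' then (optionally) everything is normalized to the maximum of the mean
#' profile at the reference time. Bins containing no cells are reported as
#' missing.
#'
#' @param trajs A `tissue_sim` or list of them (replicates).
#' @param times Snapshot times (s) to profile.
#' @param bin_width Bin width in um (default 25).
#' @param reference_time Time whose maximum mean normalizes the profiles
#'   (default the latest of `times`).
#' @param normalize Normalize to the reference maximum (default TRUE).
#' @return Data frame: `time`, `bin_center`, `mean`, `sd`, `n_replicates`.
#' @export
gradient_profile <- function(trajs, times, bin_width = 25,
                             reference_time = max(times), normalize = TRUE) {
  if (inherits(trajs, "tissue_sim")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1)
  edge <- trajs[[1]]$producer_edge
  max_x <- max(vapply(trajs, function(tr)
    max(tr$lattice$centers$x), numeric(1))) - edge
  breaks <- seq(0, max_x + bin_width, by = bin_width)
  centers <- breaks[-length(breaks)] + bin_width / 2
  per_time <- lapply(times, function(tm) {
    bm <- vapply(trajs, function(tr) {
      cells <- cells_at(tr, tm)
      rec <- cells[!cells$producer, ]
      xb <- findInterval(rec$x - edge, breaks, rightmost.closed = TRUE)
      out <- rep(NA_real_, length(centers))
      agg <- tapply(rec$content, factor(xb, levels = seq_along(centers)),
                    mean)
      out[as.integer(names(agg))] <- as.numeric(agg)
      out
    }, numeric(length(centers)))
    bm <- matrix(bm, nrow = length(centers))
    data.frame(time = tm, bin_center = centers,
               mean = rowMeans(bm, na.rm = TRUE),
               sd = apply(bm, 1, stats::sd, na.rm = TRUE),
               n_replicates = rowSums(!is.na(bm)))
  })
  out <- do.call(rbind, per_time)
  out <- out[out$n_replicates > 0, ]
  if (normalize) {
    ref <- out[abs(out$time - reference_time) < 1e-9, ]
    norm <- max(ref$mean, na.rm = TRUE)
    if (is.finite(norm) && norm > 0) {
      out$mean <- out$mean / norm
      out$sd <- out$sd / norm
    }
  }
  rownames(out) <- NULL
  out
}

#' Threshold time-course across replicates
#'
#' Applies [compute_thresholds()] to the receiver contents of every
#' snapshot of every replicate and returns the replicate mean and standard
#' deviation of the lower threshold, the upper threshold and their
#' difference (the distinctness of the fate decision). Degenerate snapshots
#' (all contents equal) yield both thresholds at the common value and
#' difference 0.
#'
#' @param trajs A `tissue_sim` or list of them.
#' @param times Snapshot times (default: all common snapshot times).
#' @return Data frame: `time`, `theta_low_mean`, `theta_low_sd`,
#'   `theta_high_mean`, `theta_high_sd`, `diff_mean`, `diff_sd`.
#' @export
threshold_timecourse <- function(trajs, times = NULL) {
  if (inherits(trajs, "tissue_sim")) trajs <- list(trajs)
  if (is.null(times)) times <- trajs[[1]]$times
  rows <- lapply(times, function(tm) {
    th <- vapply(trajs, function(tr) {
      cells <- cells_at(tr, tm)
      contents <- cells$content[!cells$producer]
      res <- tryCatch(compute_thresholds(contents, tm),
                      cp_degenerate_error = function(e)
                        list(theta_low = contents[1],
                             theta_high = contents[1]))
      c(res$theta_low, res$theta_high)
    }, numeric(2))
    th <- matrix(th, nrow = 2)
    d <- th[2, ] - th[1, ]
    data.frame(time = tm,
               theta_low_mean = mean(th[1, ]), theta_low_sd = stats::sd(th[1, ]),
               theta_high_mean = mean(th[2, ]), theta_high_sd = stats::sd(th[2, ]),
               diff_mean = mean(d), diff_sd = stats::sd(d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pattern boundary positions over time
#'
#' With fates derived from a fixed set of thresholds, scans a sliding
#' 20 um majority window along the distance-from-margin axis in each
#' snapshot and reports where the window majority switches from hindbrain
#' to midbrain and from midbrain to forebrain. An absent interface (no
#' cells of a fate) yields a missing value.
#'
#' @param traj A `tissue_sim` trajectory.
#' @param thr A `thresholds` object (fixed, e.g. set at t_TRS).
#' @param times Snapshot times (default all).
#' @param window Window width in um (default 20).
#' @return Data frame: `time`, `x_hind_mid`, `x_mid_fore` (um from the
#'   producing margin).
#' @export
boundary_positions <- function(traj, thr, times = NULL, window = 20) {
  if (is.null(times)) times <- traj$times
  edge <- traj$producer_edge
  rows <- lapply(times, function(tm) {
    cells <- cells_at(traj, tm)
    rec <- cells[!cells$producer, ]
    code <- classify_content(rec$content, thr)
    xm <- rec$x - edge
    centers <- seq(0, max(xm), by = window / 10)
    maj <- vapply(centers, function(cc) {
      sel <- abs(xm - cc) <= window / 2
      if (!any(sel)) return(NA_integer_)
      tab <- tabulate(code[sel], nbins = 3)
      as.integer(which.max(rev(tab)))  # prefer higher code on ties
    }, integer(1))
    maj <- 4L - maj  # undo rev()
    ok <- !is.na(maj)
    cen <- centers[ok]; mj <- maj[ok]
    hm <- NA_real_; mf <- NA_real_
    if (length(mj) > 1) {
      ch <- which(mj[-length(mj)] == 3L & mj[-1] != 3L)
      if (length(ch)) hm <- (cen[ch[1]] + cen[ch[1] + 1]) / 2
      ch2 <- which(mj[-length(mj)] == 2L & mj[-1] == 1L)
      ch2 <- ch2[is.na(hm) | cen[ch2] >= hm]
      if (length(ch2)) mf <- (cen[ch2[1]] + cen[ch2[1] + 1]) / 2
    }
    if (!any(code == 3L)) hm <- NA_real_
    if (!any(code == 1L) || !any(code == 2L)) mf <- NA_real_
    data.frame(time = tm, x_hind_mid = hm, x_mid_fore = mf)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lifetimes of nearest-neighbour relationships
#'
#' Identifies the `k` nearest receivers of every receiver in every snapshot
#' and measures, per (cell, neighbour) pair, the contiguous intervals over
#' which the neighbour stays among the cell's `k` nearest. A pair present
#' in `m` consecutive snapshots at cadence `s` seconds contributes a
#' lifetime of `m * s` seconds (capped at the observation span), so a pair
#' that never changes scores the full duration.
#'
#' @param traj A `tissue_sim` trajectory.
#' @param k Neighbourhood size (default 5).
#' @param bin_width_min Histogram bin width in minutes (default 2).
#' @return List with `durations_min` (numeric vector) and `histogram`
#'   (data frame `bin_mid_min`, `count`).
#' @export
neighbor_lifetimes <- function(traj, k = 5, bin_width_min = 2) {
  times <- traj$times
  ns <- length(times)
  interval <- if (ns > 1) diff(times)[1] else traj$config$duration
  pair_tabs <- lapply(seq_len(ns), function(j) {
    s <- traj$snapshots[[j]]
    keep <- !s$producer
    sites <- s$site[keep]
    ids <- s$cell_id[keep]
    v <- list(occupied = logical(n_sites(traj$lattice)))
    v$occupied[sites] <- TRUE
    id_of_site <- integer(n_sites(traj$lattice))
    id_of_site[sites] <- ids
    keys <- unlist(lapply(seq_along(sites), function(i) {
      nb <- nearest_neighbors(traj$lattice, sites[i], k = k,
                              occupied = v$occupied)
      ids[i] * 1e7 + id_of_site[nb]
    }))
    cbind(key = keys, snap = j)
  })
  tab <- do.call(rbind, pair_tabs)
  tab <- tab[order(tab[, "key"], tab[, "snap"]), , drop = FALSE]
  new_run <- c(TRUE, diff(tab[, "key"]) != 0 | diff(tab[, "snap"]) != 1)
  run_id <- cumsum(new_run)
  run_len <- as.numeric(table(run_id))
  first_idx <- which(new_run)
  first_time <- times[tab[first_idx, "snap"]]
  span <- max(times) - first_time
  durations <- pmin(run_len * interval, pmax(span, interval))
  durations_min <- durations / 60
  breaks <- seq(0, max(durations_min) + bin_width_min, by = bin_width_min)
  h <- graphics::hist(durations_min, breaks = breaks, plot = FALSE)
  list(durations_min = durations_min,
       histogram = data.frame(bin_mid_min = h$mids, count = h$counts))
}
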