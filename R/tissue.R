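#' Tissue dynamics configuration
#'
#' Event probabilities and settings for tissue expansion (cell insertion by
#' division/intercalation, one joint rate), nearest-neighbour migration with
#' optional gradient-directed sorting, and morphogen-discrepancy apoptosis.
#'
#' @param p_ins Per-cell per-step insertion probability. The default equals
#'   `kappa * dt` with the measured expansion rate and a 1 s step, so a
#'   constant probability reproduces the observed exponential tissue growth.
#' @param p_mig Per-cell per-step migration (neighbour-swap) probability.
#' @param p_dirmig Directed-sorting gain factor: 0 disables sorting, 0.02 is
#'   "weak" and 0.2 "strong" sorting. The probability of a proposed swap
#'   becomes `clamp(p_mig + p_dirmig * s * |dC| / (|dC| + dirmig_scale),
#'   0, 1)`, where `s = +1` when the swap moves the higher-content cell
#'   toward the producing margin (gradient-reinforcing) and `-1` otherwise.
#' @param dirmig_scale Half-saturation scale (content units, default 20) of
#'   the sorting gain: content differences well below it barely bias the
#'   swap, differences well above it exert the full gain. This keeps
#'   sorting inactive while contents are still small and noisy and focuses
#'   it on genuine outliers once the gradient is established.
#' @param apoptosis_enabled Enable the apoptosis sweep (active only in the
#'   last `apoptosis_window` fraction of the run).
#' @param apoptosis_budget Maximum apoptotic cells per run (default 130,
#'   with 100-130 the empirically matched range).
#' @param apoptosis_window Active fraction of the run, counted from the end
#'   (default 1/3).
#' @param apoptosis_interval Steps between apoptosis sweeps (default 60).
#'   Each sweep removes the cells with the largest content discrepancy to
#'   their five nearest neighbours, with the per-sweep kill count chosen so
#'   the budget spreads uniformly over the active window.
#' @param donor_band Half-width (um) of the x band from which replacement
#'   donors are drawn (default 6).
#' @param discrepancy How the content discrepancy to the five nearest
#'   neighbours is measured: `"relative"` (default),
#'   `|c - m| / (c + m + 1)` with `m` the neighbour mean, or `"absolute"`,
#'   `|c - m|`. The relative measure compares contents on the scale of the
#'   local fate decision, so outlier cells are found wherever they sit on
#'   the gradient; the absolute measure concentrates on the region of
#'   highest content where differences are numerically largest.
#' @param discrepancy_floor Minimum neighbour discrepancy for a cell to be
#'   eligible for apoptosis (default 0), on the scale of `discrepancy`.
#' @return A `dynamics_config` object.
#' @export
dynamics_config <- function(p_ins = growth_constant(60, 1000, 9000),
                            p_mig = 0.01, p_dirmig = 0, dirmig_scale = 20,
                            apoptosis_enabled = FALSE,
                            apoptosis_budget = 130,
                            apoptosis_window = 1 / 3,
                            apoptosis_interval = 60,
                            donor_band = 6,
                            discrepancy = c("relative", "absolute"),
                            discrepancy_floor = 0) {
  discrepancy <- match.arg(discrepancy)
  check_probability(p_ins, "p_ins")
  check_probability(p_mig, "p_mig")
  if (!is.numeric(p_dirmig) || p_dirmig < 0 || p_dirmig > 1)
    cp_stop("p_dirmig must be in [0, 1]", "cp_config_error")
  if (apoptosis_budget < 0 || apoptosis_window <= 0 || apoptosis_window > 1 ||
      apoptosis_interval < 1 || donor_band < 0 || dirmig_scale <= 0)
    cp_stop("invalid dynamics parameter", "cp_config_error")
  structure(
    list(p_ins = p_ins, p_mig = p_mig, p_dirmig = p_dirmig,
         dirmig_scale = dirmig_scale,
         apoptosis_enabled = isTRUE(apoptosis_enabled),
         apoptosis_budget = as.integer(apoptosis_budget),
         apoptosis_window = apoptosis_window,
         apoptosis_interval = as.integer(apoptosis_interval),
         donor_band = donor_band, discrepancy = discrepancy,
         discrepancy_floor = discrepancy_floor),
    class = "dynamics_config"
  )
}

dyn_params <- function(cfg) unclass(cfg)

next_cell_id <- function(cells) {
  if (nrow(cells) == 0) 1L else max(cells$cell_id) + 1L
}

#' Insert a new cell at a site, shifting cells toward the nearest empty site
#'
#' Implements tissue expansion by division/intercalation: the cells on the
#' path from `at_site` to the nearest empty site are shifted one position
#' outward (carrying content and fate), and the vacated `at_site` is filled
#' with a new cell whose content and fate are copied from a uniformly chosen
#' receiver within `donor_band` um of the same distance from the producing
#' margin (the band widens to the nearest donor if empty). On a saturated
#' lattice the insertion is skipped and flagged (attribute `"skipped"`).
#'
#' @param lattice A `cp_lattice`.
#' @param cells Cells data frame.
#' @param at_site Site id of the receiver cell where insertion occurs.
#' @param dyn A [dynamics_config()].
#' @return Updated cells data frame; attribute `"new_cell_id"` carries the
#'   id of the inserted cell (or `NA` when skipped).
#' @export
insertion_event <- function(lattice, cells, at_site, dyn = dynamics_config()) {
  at_site <- check_site(lattice, at_site)
  row <- which(cells$site == at_site)
  if (length(row) != 1 || cells$producer[row])
    cp_stop("at_site must hold a receiver cell", "cp_site_error")
  v <- vectors_from_cells(lattice, cells)
  if (all(v$occupied)) {
    attr(cells, "skipped") <- TRUE
    attr(cells, "new_cell_id") <- NA_integer_
    return(cells)
  }
  path <- path_to_nearest_empty(lattice, at_site, v$occupied)
  # shift records outward along the path
  for (m in rev(seq_along(path))[-length(path)]) {
    to <- path[m]; from <- path[m - 1]
    v$occupied[to] <- TRUE
    v$content[to] <- v$content[from]
    v$fate[to] <- v$fate[from]
    v$cell_id[to] <- v$cell_id[from]
    v$producer[to] <- FALSE
  }
  xy <- as.matrix(lattice$centers[, c("x", "y")])
  occ_tmp <- v$occupied
  occ_tmp[at_site] <- FALSE
  donor <- cpp_pick_donor(xy, occ_tmp, v$producer,
                          lattice$centers$x[at_site], dyn$donor_band,
                          at_site - 1L) + 1L
  new_id <- next_cell_id(cells)
  v$occupied[at_site] <- TRUE
  v$producer[at_site] <- FALSE
  if (donor >= 1) {
    v$content[at_site] <- v$content[donor]
    v$fate[at_site] <- v$fate[donor]
  } else {
    v$content[at_site] <- 0
    v$fate[at_site] <- 0L
  }
  v$cell_id[at_site] <- new_id
  out <- cells_from_vectors(lattice, v$occupied, v$producer, v$content,
                            v$fate, v$cell_id)
  attr(out, "skipped") <- FALSE
  attr(out, "new_cell_id") <- new_id
  out
}

#' Attempt a (possibly gradient-directed) migration swap for one cell
#'
#' Draws one of the cell's five nearest occupied receivers uniformly and
#' executes the swap with probability
#' `clamp(p_mig + p_dirmig * s * |dC| / (|dC| + dirmig_scale), 0, 1)`,
#' where `s = +1` when the swap moves the higher-content cell toward the
#' producing margin (reinforcing the gradient) and `-1` otherwise. With
#' `p_dirmig = 0` this is the undirected swap at rate `p_mig`. Accepted
#' swaps exchange the full cell records (content, fate, identity) between
#' the two sites.
#'
#' @param cells Cells data frame.
#' @param lattice A `cp_lattice`.
#' @param site Site id of the migrating receiver cell.
#' @param dyn A [dynamics_config()].
#' @return Updated cells data frame; attribute `"swapped_with"` holds the
#'   partner site id or `NA` if no swap happened.
#' @export
migration_event <- function(cells, lattice, site, dyn = dynamics_config()) {
  site <- check_site(lattice, site)
  row <- which(cells$site == site)
  if (length(row) != 1 || cells$producer[row])
    cp_stop("site must hold a receiver cell", "cp_site_error")
  v <- vectors_from_cells(lattice, cells)
  recv <- v$occupied & !v$producer
  nb <- nearest_neighbors(lattice, site, k = 5, occupied = recv)
  attr(cells, "swapped_with") <- NA_integer_
  if (length(nb) == 0) return(cells)
  j <- nb[sample.int(length(nb), 1)]
  ci <- v$content[site]; cj <- v$content[j]
  xi <- lattice$centers$x[site]; xj <- lattice$centers$x[j]
  dc <- ci - cj
  sg <- 0
  if (dc > 0) sg <- if (xj < xi) 1 else -1
  if (dc < 0) sg <- if (xj > xi) 1 else -1
  p <- min(1, max(0, dyn$p_mig + dyn$p_dirmig * sg * abs(dc) / (abs(dc) + dyn$dirmig_scale)))
  if (stats::runif(1) < p) {
    rj <- which(cells$site == j)
    swap_cols <- c("content", "fate", "cell_id")
    tmp <- cells[row, swap_cols]
    cells[row, swap_cols] <- cells[rj, swap_cols]
    cells[rj, swap_cols] <- tmp
    attr(cells, "swapped_with") <- j
  }
  cells
}

#' Apoptosis sweep: remove and replace the strongest morphogen outliers
#'
#' Computes, for every receiver, the discrepancy `|content - mean(content of
#' its 5 nearest receivers)|` and removes the cells with the largest
#' discrepancy (above `discrepancy_floor`), never exceeding the remaining
#' run budget. The per-sweep kill count spreads the budget uniformly over
#' the active window (the last `apoptosis_window` of the run). Each removed
#' cell is replaced in place by copying content and fate from a random
#' donor in the same x band, exactly as for insertions, so the occupied
#' count never decreases.
#'
#' @param cells Cells data frame.
#' @param lattice A `cp_lattice`.
#' @param step Current step index (1-based, absolute).
#' @param duration Total number of steps in the run.
#' @param dyn A [dynamics_config()] with `apoptosis_enabled = TRUE`.
#' @param budget_state List with element `killed` (deaths so far this run).
#' @return List with `cells`, updated `budget_state`, and `killed_sites`
#'   (site ids replaced in this sweep).
#' @export
apoptosis_sweep <- function(cells, lattice, step, duration,
                            dyn = dynamics_config(apoptosis_enabled = TRUE),
                            budget_state = list(killed = 0L)) {
  killed_sites <- integer(0)
  win_start <- duration - floor(duration * dyn$apoptosis_window) + 1
  sweeps <- seq.int(win_start, duration)
  sweeps <- sweeps[sweeps %% dyn$apoptosis_interval == 0]
  if (!dyn$apoptosis_enabled || !(step %in% sweeps) || length(sweeps) == 0)
    return(list(cells = cells, budget_state = budget_state,
                killed_sites = killed_sites))
  sweep_idx <- sum(sweeps <= step)
  target_cum <- min(dyn$apoptosis_budget,
                    round(dyn$apoptosis_budget * sweep_idx / length(sweeps)))
  k <- target_cum - budget_state$killed
  if (k <= 0)
    return(list(cells = cells, budget_state = budget_state,
                killed_sites = killed_sites))
  v <- vectors_from_cells(lattice, cells)
  recv <- v$occupied & !v$producer
  sites <- which(recv)
  disc <- vapply(sites, function(s) {
    nb <- nearest_neighbors(lattice, s, k = 5, occupied = recv)
    if (length(nb) == 0) return(-Inf)
    m <- mean(v$content[nb])
    d <- abs(v$content[s] - m)
    if (dyn$discrepancy == "relative") d / (v$content[s] + m + 1) else d
  }, numeric(1))
  eligible <- disc > dyn$discrepancy_floor
  ord <- order(-disc[eligible], sites[eligible])
  victims <- head(sites[eligible][ord], k)
  xy <- as.matrix(lattice$centers[, c("x", "y")])
  for (s in victims) {
    occ_tmp <- v$occupied
    occ_tmp[s] <- FALSE
    donor <- cpp_pick_donor(xy, occ_tmp, v$producer, lattice$centers$x[s],
                            dyn$donor_band, s - 1L) + 1L
    if (donor >= 1) {
      v$content[s] <- v$content[donor]
      v$fate[s] <- v$fate[donor]
    } else {
      v$content[s] <- 0
      v$fate[s] <- 0L
    }
    v$cell_id[s] <- max(v$cell_id) + 1L
    killed_sites <- c(killed_sites, s)
  }
  budget_state$killed <- budget_state$killed + length(victims)
  list(cells = cells_from_vectors(lattice, v$occupied, v$producer, v$content,
                                  v$fate, v$cell_id),
       budget_state = budget_state, killed_sites = killed_sites)
}
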