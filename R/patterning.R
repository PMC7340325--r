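#' Thirds-splitting fate thresholds
#'
#' French-flag thresholds chosen so the three fate classes (forebrain,
#' midbrain, hindbrain) have equal cell numbers at the time they are set:
#' the lower threshold sits at the boundary of the first third of the
#' sorted contents, the upper at the second, each placed halfway between
#' the bounding order statistics (so the thresholds are content-scale
#' free). With distinct contents the class sizes differ by at most one
#' cell. When tied values straddle a boundary the threshold is placed
#' halfway to the next distinct value, keeping ties in one class.
#'
#' @param contents Numeric vector of receiver morphogen contents (length at
#'   least 3).
#' @param t Time (s) at which the thresholds are set (`t_TRS`).
#' @return A `thresholds` object: list with `theta_low`, `theta_high`,
#'   `set_time`, `n`.
#' @examples
#' compute_thresholds(1:9, t = 5400)
#' @export
compute_thresholds <- function(contents, t = NA_real_) {
  contents <- as.numeric(contents)
  n <- length(contents)
  if (n < 3)
    cp_stop("need at least 3 receiver cells", "cp_config_error")
  s <- sort(contents)
  if (s[1] == s[n])
    cp_stop("all contents identical: thresholds are degenerate",
            "cp_degenerate_error")
  boundary <- function(m) {
    if (s[m] < s[m + 1]) return((s[m] + s[m + 1]) / 2)
    above <- which(s > s[m])
    if (length(above)) return((s[m] + s[above[1]]) / 2)
    below <- which(s < s[m])
    (s[below[length(below)]] + s[m]) / 2
  }
  m1 <- ceiling(n / 3)
  m2 <- ceiling(2 * n / 3)
  structure(list(theta_low = boundary(m1), theta_high = boundary(m2),
                 set_time = t, n = n),
            class = "thresholds")
}

#' @export
print.thresholds <- function(x, ...) {
  cat(sprintf(
    "Fate thresholds (set at t = %s s, n = %d): theta_low = %.4g, theta_high = %.4g\n",
    format(x$set_time), x$n, x$theta_low, x$theta_high))
  invisible(x)
}

classify_content <- function(content, thr) {
  ifelse(content < thr$theta_low, 1L,
         ifelse(content < thr$theta_high, 2L, 3L))
}

#' Assign fates from contents and thresholds
#'
#' Half-open bands: content below `theta_low` is forebrain, at least
#' `theta_low` but below `theta_high` midbrain, at least `theta_high`
#' hindbrain (a content exactly on a threshold belongs to the higher band).
#' Producers stay unassigned.
#'
#' @param cells Cells data frame.
#' @param thr A `thresholds` object.
#' @return `cells` with the `fate` column set.
#' @export
assign_fates <- function(cells, thr) {
  if (!inherits(thr, "thresholds"))
    cp_stop("thr must come from compute_thresholds()", "cp_config_error")
  code <- classify_content(cells$content, thr)
  fate <- int_to_fate(code)
  fate[cells$producer] <- NA_character_
  cells$fate <- fate
  cells
}

#' Fate-adoption times by back-tracing a trajectory
#'
#' Fixes each cell's final fate from its content at `thr$set_time`, then
#' traces the cell backward through the snapshots and reports the earliest
#' time from which its content classifies to that final fate at every later
#' snapshot (the last entry into the final band). Cells in-band from the
#' start adopt at 0.
#'
#' Cells created during the run (insertions, apoptosis replacements) copy
#' their morphogen content from a donor cell. With `inherit = TRUE` (the
#' default) the back-trace therefore continues through the donor lineage:
#' before its birth a cell's content history is its donor's, recursively.
#' This reflects that the inherited content - not the cell object - carries
#' the fate information, and is what makes adoption timing comparable
#' across transport modes in a tissue where most final cells are born late.
#' With `inherit = FALSE` a late-born cell can adopt no earlier than its
#' first appearance.
#'
#' @param traj A `tissue_sim` trajectory with snapshots up to
#'   `thr$set_time`.
#' @param thr A `thresholds` object (typically computed from the receiver
#'   contents at `set_time`).
#' @param inherit Follow the donor lineage before a cell's birth (default
#'   TRUE).
#' @return Data frame with `cell_id`, `fate`, `adoption_time` (s).
#' @export
fate_adoption_times <- function(traj, thr, inherit = TRUE) {
  t_set <- thr$set_time
  it <- which(abs(traj$times - t_set) < 1e-9)
  if (length(it) != 1)
    cp_stop("trajectory has no snapshot at thr$set_time",
            "cp_snapshot_error")
  use <- which(traj$times <= t_set + 1e-9)
  times <- traj$times[use]
  final <- traj$snapshots[[it]]
  keep <- !final$producer
  ids <- final$cell_id[keep]
  final_code <- classify_content(final$content[keep], thr)
  parent <- integer(0)
  if (inherit && !is.null(traj$lineage) && nrow(traj$lineage)) {
    parent <- traj$lineage$parent
    names(parent) <- as.character(traj$lineage$child)
  }
  # contents matrix: rows = cells alive at set_time, cols = snapshots;
  # absent cells fall back to their donor lineage when inheriting
  cmat <- matrix(NA_real_, nrow = length(ids), ncol = length(use))
  for (j in seq_along(use)) {
    s <- traj$snapshots[[use[j]]]
    trace_ids <- ids
    m <- match(trace_ids, s$cell_id)
    if (length(parent)) {
      repeat {
        miss <- which(is.na(m))
        if (!length(miss)) break
        anc <- parent[as.character(trace_ids[miss])]
        if (all(is.na(anc))) break
        has <- !is.na(anc)
        trace_ids[miss[has]] <- anc[has]
        m2 <- match(trace_ids[miss[has]], s$cell_id)
        m[miss[has]] <- m2
        if (!any(has)) break
      }
    }
    cmat[, j] <- s$content[m]
  }
  in_band <- !is.na(cmat) &
    matrix(classify_content(as.vector(cmat), thr) ==
             rep(final_code, ncol(cmat)),
           nrow = length(ids))
  present <- !is.na(cmat)
  adoption <- vapply(seq_along(ids), function(i) {
    mism <- which(present[i, ] & !in_band[i, ])
    if (length(mism)) {
      j <- max(mism) + 1L
      if (j > length(times)) return(times[length(times)])
      return(times[j])
    }
    times[which(present[i, ])[1]]
  }, numeric(1))
  data.frame(cell_id = ids, fate = int_to_fate(final_code),
             adoption_time = adoption, stringsAsFactors = FALSE)
}

#' Fraction of cells having adopted their final fate over time
#'
#' @param adoption Result of [fate_adoption_times()].
#' @param times Evaluation times (s).
#' @return Data frame with `time` and `fraction` (of all traced cells whose
#'   adoption time is at or before `time`).
#' @export
adoption_timecourse <- function(adoption, times) {
  data.frame(time = times,
             fraction = vapply(times, function(t)
               mean(adoption$adoption_time <= t + 1e-9), numeric(1)))
}

#' Time at which a given fraction of cells has adopted its final fate
#'
#' @param adoption Result of [fate_adoption_times()].
#' @param q Target fraction (default 0.75).
#' @param times Candidate times; default the sorted unique adoption times.
#' @return The earliest time at which the adopted fraction reaches `q`.
#' @export
adoption_quantile <- function(adoption, q = 0.75, times = NULL) {
  if (is.null(times)) times <- sort(unique(adoption$adoption_time))
  tc <- adoption_timecourse(adoption, times)
  hit <- which(tc$fraction >= q)
  if (!length(hit)) return(NA_real_)
  tc$time[hit[1]]
}

#' Community fate-decision configuration (optional variant)
#'
#' Settings for the neighbour-influenced fate-update variant in which,
#' every `update_interval` sweeps, a cell re-adopts a fate with probability
#' `beta * p_wnt` toward its content-implied fate and `gamma * p_nei`
#' toward the majority fate of its five nearest neighbours. The variant is
#' off by default: it produces fate patches rather than contiguous stripes,
#' which is why it is not part of the standard model.
#'
#' @param update_interval Sweeps between updates (default 20).
#' @param beta,gamma Non-negative weights.
#' @param p_wnt,p_nei Per-update adoption probabilities.
#' @return A `community_config` object.
#' @export
community_config <- function(update_interval = 20, beta = 1, gamma = 1,
                             p_wnt = 0.5, p_nei = 0.5) {
  if (beta < 0 || gamma < 0)
    cp_stop("weights must be non-negative", "cp_config_error")
  check_probability(p_wnt, "p_wnt")
  check_probability(p_nei, "p_nei")
  structure(list(update_interval = as.integer(update_interval),
                 beta = beta, gamma = gamma, p_wnt = p_wnt, p_nei = p_nei),
            class = "community_config")
}

#' One community fate-decision update
#'
#' Each receiver draws once: with probability `beta * p_wnt` it adopts the
#' fate implied by its own content and the thresholds; otherwise, with
#' probability `gamma * p_nei`, it adopts the majority fate among its five
#' nearest receivers (ties keep the current fate); otherwise it is
#' unchanged.
#'
#' @param cells Cells data frame with initialized fates.
#' @param lattice A `cp_lattice`.
#' @param thr A `thresholds` object.
#' @param cfg A [community_config()].
#' @return Updated cells data frame.
#' @export
community_fate_update <- function(cells, lattice, thr,
                                  cfg = community_config()) {
  v <- vectors_from_cells(lattice, cells)
  recv_mask <- v$occupied & !v$producer
  rows <- which(!cells$producer)
  u <- stats::runif(length(rows))
  w <- cfg$beta * cfg$p_wnt
  g <- cfg$gamma * cfg$p_nei
  new_fate <- cells$fate
  for (k in seq_along(rows)) {
    i <- rows[k]
    if (u[k] < w) {
      new_fate[i] <- int_to_fate(classify_content(cells$content[i], thr))
    } else if (u[k] < w + g) {
      nb <- nearest_neighbors(lattice, cells$site[i], k = 5,
                              occupied = recv_mask)
      if (!length(nb)) next
      nf <- v$fate[nb]
      nf <- nf[nf > 0]
      if (!length(nf)) next
      tab <- tabulate(nf, nbins = 3)
      top <- which(tab == max(tab))
      if (length(top) == 1) new_fate[i] <- int_to_fate(top)
    }
  }
  cells$fate <- new_fate
  cells
}
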