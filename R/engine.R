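#' Full simulation configuration
#'
#' Collects geometry, timing, transport and tissue-dynamics settings for one
#' Monte-Carlo run. Defaults reproduce the reference setup: a 1000 x 1000 um
#' lattice of 8 um cells, two layers of static morphogen-producing cells at
#' the x = 0 margin, a receiving tissue of initial length 60 um that expands
#' exponentially toward the full domain, 1 s time steps for 10800 s
#' (180 min), and fate thresholds set at `t_trs` (default 90 min).
#'
#' @param width,height Lattice size (um).
#' @param cell_radius Cell radius (um).
#' @param dt Time step (s, default 1).
#' @param duration Simulated time (s, default 10800 = 180 min).
#' @param t_trs Threshold-setting time (s, default 5400 = 90 min); must not
#'   exceed `duration`.
#' @param producer_layers Number of producing cell layers at the margin
#'   (default 2); the producer band spans `producer_layers * 2 *
#'   cell_radius` um from x = 0.
#' @param initial_length Initial length of the receiving tissue (um,
#'   default 60).
#' @param snapshot_every Snapshot cadence (s, default 60); snapshots at
#'   `t_trs` and at the end are always taken.
#' @param seed Integer RNG seed; one seeded stream drives packing and every
#'   stochastic event, making runs bit-reproducible.
#' @param transport A [transport_config()].
#' @param dynamics A [dynamics_config()].
#' @param max_failures Packing saturation parameter (see
#'   [build_lattice()]).
#' @return A `sim_config` object.
#' @export
sim_config <- function(width = 1000, height = 1000, cell_radius = 8,
                       dt = 1, duration = 10800, t_trs = 5400,
                       producer_layers = 2, initial_length = 60,
                       snapshot_every = 60, seed = 1,
                       transport = transport_config(),
                       dynamics = dynamics_config(),
                       max_failures = 50000) {
  if (!inherits(transport, "transport_config"))
    cp_stop("transport must be a transport_config", "cp_config_error")
  if (!inherits(dynamics, "dynamics_config"))
    cp_stop("dynamics must be a dynamics_config", "cp_config_error")
  if (t_trs > duration)
    cp_stop("t_trs must not exceed duration", "cp_config_error")
  if (producer_layers < 1)
    cp_stop("need at least one producer layer", "cp_config_error")
  if (dt <= 0 || duration <= 0 || snapshot_every <= 0)
    cp_stop("dt, duration and snapshot_every must be positive",
            "cp_config_error")
  structure(
    list(width = width, height = height, cell_radius = cell_radius,
         dt = dt, duration = duration, t_trs = t_trs,
         producer_layers = producer_layers, initial_length = initial_length,
         snapshot_every = snapshot_every, seed = as.integer(seed),
         transport = transport, dynamics = dynamics,
         max_failures = max_failures),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("Simulation config: %g x %g um, r = %g um, %s transport\n",
           "  dt = %g s, duration = %g s, t_trs = %g s, seed = %d\n",
           "  p_ins = %.3g, p_mig = %.3g, p_dirmig = %.3g, apoptosis = %s\n"),
    x$width, x$height, x$cell_radius, x$transport$mode,
    x$dt, x$duration, x$t_trs, x$seed,
    x$dynamics$p_ins, x$dynamics$p_mig, x$dynamics$p_dirmig,
    if (x$dynamics$apoptosis_enabled) "on" else "off"))
  invisible(x)
}

producer_edge_of <- function(config) {
  config$producer_layers * 2 * config$cell_radius
}

snapshot_schedule <- function(config) {
  nsteps <- round(config$duration / config$dt)
  every <- max(1L, round(config$snapshot_every / config$dt))
  steps <- sort(unique(c(seq.int(every, nsteps, by = every),
                         round(config$t_trs / config$dt), nsteps)))
  steps[steps >= 1 & steps <= nsteps]
}

state_snapshot <- function(state, time) {
  idx <- which(state$occupied)
  snap <- list(time = time, site = idx, cell_id = state$cell_id[idx],
               producer = state$producer[idx],
               content = state$content[idx], fate = state$fate[idx])
  if (!is.null(state$field)) {
    snap$field <- state$field
    snap$L <- state$L
  }
  snap
}

#' Initialize a simulation state
#'
#' Seeds the RNG, packs the lattice, fills the `producer_layers` site layers
#' nearest x = 0 with static producing cells, and occupies the sites within
#' `initial_length` um of the producer band with receiving cells of zero
#' morphogen content and unset fate. In diffusion mode the extracellular
#' field is created with `L(0) = initial_length`. Producers use the tissue's
#' frame of reference: they stay fixed and all other cells move relative to
#' them.
#'
#' @param config A [sim_config()].
#' @return A `tissue_state` list (lattice, per-site state vectors, field,
#'   counters) ready for [step_simulation()].
#' @export
initialize_simulation <- function(config) {
  set.seed(config$seed)
  lattice <- build_lattice(config$width, config$height, config$cell_radius,
                           seed = NULL, max_failures = config$max_failures)
  edge <- producer_edge_of(config)
  x <- lattice$centers$x
  producer <- x <= edge
  receiver0 <- x > edge & x <= edge + config$initial_length
  if (!any(producer) || !any(receiver0))
    cp_stop("lattice too small for the producer layers and initial tissue",
            "cp_geometry_error")
  n <- n_sites(lattice)
  occupied <- producer | receiver0
  content <- numeric(n)
  fate <- integer(n)
  cell_id <- integer(n)
  cell_id[occupied] <- seq_len(sum(occupied))
  field <- NULL
  L <- config$initial_length
  if (config$transport$mode == "diffusion") {
    f <- morphogen_field(length = config$width - edge,
                         L0 = config$initial_length, cfg = config$transport)
    field <- f$C
    L <- f$L
  }
  state <- list(
    config = config, lattice = lattice, producer_edge = edge,
    occupied = occupied, producer = producer, content = content,
    fate = fate, cell_id = cell_id, next_id = sum(occupied) + 1L,
    t = 0L, field = field, L = L, apop_killed = 0L,
    counts = NULL, totals = numeric(0), apop_steps = integer(0),
    lineage = data.frame(child = integer(0), parent = integer(0)),
    snapshots = list()
  )
  state$snapshots <- list(state_snapshot(state, 0))
  class(state) <- "tissue_state"
  state
}

#' Advance a simulation state by one or more Monte-Carlo steps
#'
#' Each step applies, in fixed order and sweeping cells in ascending site
#' order: production (cytoneme deposition attempts by producers, or one
#' field step plus absorption by every receiver), insertion, migration,
#' decay, and - inside its active window - apoptosis. Event acceptance
#' compares a uniform draw against the event probability. Producers never
#' move, divide, die or receive morphogen.
#'
#' @param state A `tissue_state` from [initialize_simulation()].
#' @param nsteps Number of steps to advance (default 1).
#' @return The advanced `tissue_state`.
#' @export
step_simulation <- function(state, nsteps = 1) {
  config <- state$config
  nsteps <- as.integer(nsteps)
  total_steps <- round(config$duration / config$dt)
  xy <- as.matrix(state$lattice$centers[, c("x", "y")])
  dx <- (config$width - state$producer_edge) / (config$transport$nx - 1)
  snap_steps <- snapshot_schedule(config)
  res <- cpp_advance(
    xy, state$lattice$nbor, state$producer,
    state$occupied, state$content, state$fate, state$cell_id, state$next_id,
    tp_params(config$transport, dx), dyn_params(config$dynamics),
    config$dt, nsteps, state$t, total_steps,
    as.integer(snap_steps),
    if (is.null(state$field)) numeric(0) else state$field, state$L,
    state$producer_edge, config$cell_radius, state$apop_killed)
  state$occupied <- res$occupied
  state$content <- res$content
  state$fate <- res$fate
  state$cell_id <- res$cell_id
  state$next_id <- res$next_id
  if (!is.null(state$field)) {
    state$field <- res$field
    state$L <- res$L
  }
  state$t <- state$t + nsteps
  state$counts <- rbind(state$counts, res$counts)
  state$totals <- if (length(state$totals))
    state$totals + res$totals else res$totals
  state$apop_steps <- c(state$apop_steps, res$apoptosis_steps)
  state$apop_killed <- res$apoptosis_killed
  state$lineage <- rbind(state$lineage,
                         data.frame(child = res$lineage_child,
                                    parent = res$lineage_parent))
  state$snapshots <- c(state$snapshots, res$snapshots)
  state
}

#' Run a full patterning simulation
#'
#' Runs the Monte-Carlo event loop for the configured duration and captures
#' a trajectory: per-snapshot cell tables (with persistent cell identities
#' for back-tracing), per-step event counts, morphogen bookkeeping totals
#' and the apoptosis log. Runs are bit-reproducible given the same
#' configuration and seed.
#'
#' @param config A [sim_config()].
#' @return A `tissue_sim` trajectory object; see [cells_at()],
#'   [event_counts()], [fate_adoption_times()] and the metrics functions
#'   for what can be computed from it.
#' @examples
#' cfg <- sim_config(width = 250, height = 250, duration = 300,
#'                   t_trs = 300, seed = 42)
#' traj <- run_simulation(cfg)
#' traj
#' @export
run_simulation <- function(config) {
  state <- initialize_simulation(config)
  nsteps <- round(config$duration / config$dt)
  state <- step_simulation(state, nsteps)
  times <- vapply(state$snapshots, function(s) s$time, numeric(1))
  structure(
    list(config = config, lattice = state$lattice,
         producer_edge = state$producer_edge,
         seed = config$seed, times = times,
         snapshots = state$snapshots, counts = state$counts,
         totals = state$totals,
         apoptosis_times = state$apop_steps * config$dt,
         lineage = state$lineage,
         final = state),
    class = "tissue_sim"
  )
}

#' Cell table at a snapshot time
#'
#' @param traj A `tissue_sim` trajectory.
#' @param time Snapshot time in seconds (must be one of `traj$times`).
#' @return Cells data frame (`site`, `x`, `y`, `producer`, `content`,
#'   `fate`, `cell_id`).
#' @export
cells_at <- function(traj, time) {
  i <- which(abs(traj$times - time) < 1e-9)
  if (length(i) != 1)
    cp_stop(sprintf("no snapshot at t = %g s", time), "cp_snapshot_error")
  s <- traj$snapshots[[i]]
  data.frame(site = s$site, x = traj$lattice$centers$x[s$site],
             y = traj$lattice$centers$y[s$site], producer = s$producer,
             content = s$content, fate = int_to_fate(s$fate),
             cell_id = s$cell_id, stringsAsFactors = FALSE)
}

#' Per-step event counts of a trajectory
#'
#' @param traj A `tissue_sim` trajectory.
#' @return Data frame with one row per step: occupied/receiver counts and
#'   accepted event counts per process.
#' @export
event_counts <- function(traj) {
  df <- as.data.frame(traj$counts)
  df$step <- seq_len(nrow(df))
  df$time <- df$step * traj$config$dt
  df
}

#' @export
print.tissue_sim <- function(x, ...) {
  nrec <- sum(!x$snapshots[[length(x$snapshots)]]$producer)
  cat(sprintf(
    paste0("Tissue patterning trajectory (%s transport)\n",
           "  %d sites, %d final cells (%d receivers), %g s simulated, ",
           "%d snapshots, seed %d\n"),
    x$config$transport$mode, n_sites(x$lattice),
    length(x$snapshots[[length(x$snapshots)]]$site), nrec,
    x$config$duration, length(x$snapshots), x$seed))
  invisible(x)
}

#' @export
summary.tissue_sim <- function(object, ...) {
  cells <- cells_at(object, max(object$times))
  rec <- cells[!cells$producer, ]
  tot <- object$totals
  cat(sprintf("Final tissue: %d receivers + %d producers\n",
              nrow(rec), sum(cells$producer)))
  cat(sprintf("  x extent beyond producers: %.0f um\n",
              max(rec$x) - object$producer_edge))
  cat(sprintf("  content: mean %.2f, max %.2f\n",
              mean(rec$content), max(rec$content)))
  cat(sprintf(
    "  events: %d insertions, %d migrations, %d apoptoses\n",
    sum(object$counts[, "insertions"]), sum(object$counts[, "migrations"]),
    sum(object$counts[, "apoptosis"])))
  if (object$config$transport$mode == "cytoneme")
    cat(sprintf("  cytonemes: %d formed, %d deposits (%g units)\n",
                sum(object$counts[, "filopodia"]),
                sum(object$counts[, "deposits"]), tot[["deposited"]]))
  invisible(object)
}

#' Plot a trajectory
#'
#' `which = "fates"` draws the 2D cell-fate map at a snapshot (producers
#' green, forebrain red, midbrain white, hindbrain blue, unset grey);
#' `"gradient"` the content-vs-distance profile; `"growth"` the occupied
#' cell count over time on a log scale.
#'
#' @param x A `tissue_sim` trajectory.
#' @param which One of `"fates"`, `"gradient"`, `"growth"`.
#' @param time Snapshot time (default: final).
#' @param thresholds Optional [compute_thresholds()] result; when given and
#'   fates are unset, fates are derived from it for plotting.
#' @param ... Unused.
#' @export
plot.tissue_sim <- function(x, which = c("fates", "gradient", "growth"),
                            time = max(x$times), thresholds = NULL, ...) {
  which <- match.arg(which)
  cells <- cells_at(x, time)
  if (which == "growth") {
    ec <- event_counts(x)
    plot(ec$time / 60, ec$n_occupied, log = "y", type = "l",
         xlab = "time (min)", ylab = "occupied cells (log)",
         main = "Tissue growth")
    return(invisible(x))
  }
  if (which == "gradient") {
    rec <- cells[!cells$producer, ]
    plot(rec$x - x$producer_edge, rec$content, pch = 16, cex = 0.4,
         col = adjustcolor("steelblue", 0.5),
         xlab = "distance from producing margin (um)",
         ylab = "cell morphogen content",
         main = sprintf("t = %g min", time / 60))
    return(invisible(x))
  }
  if (!is.null(thresholds) && all(is.na(cells$fate[!cells$producer])))
    cells <- assign_fates(cells, thresholds)
  cols <- rep("grey80", nrow(cells))
  cols[cells$producer] <- "forestgreen"
  cols[!is.na(cells$fate) & cells$fate == "forebrain"] <- "firebrick"
  cols[!is.na(cells$fate) & cells$fate == "midbrain"] <- "white"
  cols[!is.na(cells$fate) & cells$fate == "hindbrain"] <- "royalblue"
  plot(cells$x, cells$y, asp = 1, pch = 21, bg = cols, col = "grey40",
       cex = 0.7, xlab = "x (um)", ylab = "y (um)",
       main = sprintf("Cell fates, t = %g min", time / 60))
  invisible(x)
}
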