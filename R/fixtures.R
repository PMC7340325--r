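#' Deterministic miniature fixtures for testing and examples
#'
#' Builds small, fully seeded objects exercising every module without any
#' external data: miniature lattices with scripted content fields, stand-in
#' filopodium length/angle histograms (mean length 17 um), and scripted
#' trajectories for the metrics functions. Every fixture is completely
#' determined by `(spec, seed)`.
#'
#' Specs:
#' \describe{
#'   \item{`tiny-ramp`, `tiny-step`, `tiny-uniform`}{about 20-site lattice
#'     (90 x 90 um) fully occupied by receivers with content strictly
#'     decreasing in x, a two-level step in x, or constant.}
#'   \item{`small-random`, `small-ramp`}{about 200-site lattice
#'     (300 x 300 um) with seeded uniform or ramp contents.}
#'   \item{`histograms`}{list of `cp_dist` histogram stand-ins for
#'     filopodium length (um, mean 17) and angle (degrees).}
#'   \item{`frozen-trajectory`}{a `tissue_sim`-shaped object whose cells
#'     never move (11 snapshots, 60 s cadence).}
#'   \item{`single-swap-trajectory`}{as frozen, but one chosen cell pair
#'     exchanges positions at t = 300 s.}
#' }
#'
#' @param spec Fixture name (see Details).
#' @param seed Integer seed.
#' @return Fixture object; lattice fixtures return
#'   `list(lattice, cells)`.
#' @export
make_fixture <- function(spec = c("tiny-ramp", "tiny-step", "tiny-uniform",
                                  "small-random", "small-ramp",
                                  "histograms", "frozen-trajectory",
                                  "single-swap-trajectory"),
                         seed = 1) {
  spec <- match.arg(spec)
  set.seed(seed)
  if (spec == "histograms") {
    len_centers <- seq(3, 45, by = 2)
    len_w <- stats::dgamma(len_centers, shape = 1 / 0.35^2,
                           scale = 17 * 0.35^2)
    ang_centers <- seq(-85, 85, by = 10)
    ang_w <- stats::dnorm(ang_centers, 0, 35)
    return(list(length = dist_histogram(len_centers, len_w),
                angle = dist_histogram(ang_centers, ang_w)))
  }
  if (spec %in% c("frozen-trajectory", "single-swap-trajectory")) {
    return(fixture_trajectory(swap = spec == "single-swap-trajectory",
                              seed = seed))
  }
  side <- if (startsWith(spec, "tiny")) 90 else 300
  lattice <- build_lattice(side, side, 8, seed = NULL)
  x <- lattice$centers$x
  n <- n_sites(lattice)
  content <- switch(sub("^(tiny|small)-", "", spec),
    ramp = (side - x) * 2,
    step = ifelse(x < stats::median(x), 10, 0),
    uniform = rep(5, n),
    random = stats::runif(n, 0, 100))
  cells <- data.frame(site = seq_len(n), x = x, y = lattice$centers$y,
                      producer = FALSE, content = content,
                      fate = NA_character_, cell_id = seq_len(n),
                      stringsAsFactors = FALSE)
  list(lattice = lattice, cells = cells)
}

# A hand-scripted trajectory: static cells, optionally one pair swap at
# t = 300 s. Shaped like a tissue_sim so the metrics functions accept it.
fixture_trajectory <- function(swap, seed) {
  fx <- make_fixture("small-random", seed = seed)
  lattice <- fx$lattice
  cells <- fx$cells
  times <- seq(0, 600, by = 60)
  n <- nrow(cells)
  make_snap <- function(tm, cells) {
    list(time = tm, site = cells$site, cell_id = cells$cell_id,
         producer = cells$producer, content = cells$content,
         fate = fate_to_int(cells$fate))
  }
  a <- 1L  # swapped with the farthest site so all neighbour pairs break
  b <- which.max((cells$x - cells$x[a])^2 + (cells$y - cells$y[a])^2)
  snaps <- lapply(times, function(tm) {
    cc <- cells
    if (swap && tm >= 300) {
      cc[c(a, b), c("content", "cell_id")] <- cc[c(b, a),
                                                 c("content", "cell_id")]
    }
    make_snap(tm, cc)
  })
  structure(
    list(config = list(dt = 1, duration = 600, snapshot_every = 60,
                       transport = list(mode = "none")),
         lattice = lattice, producer_edge = 0, seed = seed,
         times = times, snapshots = snaps, counts = NULL,
         totals = numeric(0), apoptosis_times = numeric(0)),
    class = "tissue_sim"
  )
}

#' Write a histogram distribution to a two-column text file
#'
#' Companion of [read_histogram_dist()]; used to emit the stand-in
#' filopodium length/angle histograms as plain-text fixtures.
#'
#' @param dist A `cp_dist` histogram distribution.
#' @param path Output path.
#' @param header Column names (default `c("bin_center", "weight")`).
#' @export
write_histogram_fixture <- function(dist, path,
                                    header = c("bin_center", "weight")) {
  if (dist$type != 3L)
    cp_stop("only histogram distributions can be written",
            "cp_config_error")
  df <- stats::setNames(data.frame(dist$vals, dist$wts), header)
  utils::write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
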