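#' Build a fixed irregular lattice of possible cell positions
#'
#' Generates a dense random packing of non-overlapping circles of radius
#' `cell_radius` inside a `width` x `height` rectangle by sequential random
#' dart-throwing: candidate centres are drawn uniformly and rejected if they
#' overlap an accepted circle, until `max_failures` consecutive rejections,
#' which operationally defines saturation ("no further circle fits under the
#' sampler"). The resulting centres are the fixed possible cell positions for
#' the whole simulation; they never move. The x axis measures distance from
#' the morphogen-producing margin at x = 0, y is the lateral coordinate, and
#' all lengths are in micrometres.
#'
#' @param width,height Domain size in micrometres (each at least
#'   `2 * cell_radius`).
#' @param cell_radius Cell radius in micrometres (default 8).
#' @param seed Optional integer seed; if supplied, `set.seed()` is called
#'   before sampling. When `NULL` the current RNG stream is used, which is
#'   how [run_simulation()] folds packing into a single reproducible stream.
#' @param max_failures Consecutive rejections that end the packing (default
#'   50000).
#' @return An object of class `cp_lattice`: a list with `width`, `height`,
#'   `cell_radius`, a `centers` data frame (`site`, `x`, `y`) and a
#'   precomputed per-site sorted neighbour table used by the fast queries.
#' @examples
#' lat <- build_lattice(200, 200, 8, seed = 1)
#' nrow(lat$centers)
#' @export
build_lattice <- function(width, height, cell_radius = 8, seed = NULL,
                          max_failures = 50000) {
  if (!is.numeric(width) || !is.numeric(height) || !is.numeric(cell_radius) ||
      width <= 0 || height <= 0 || cell_radius <= 0 ||
      width < 2 * cell_radius || height < 2 * cell_radius)
    cp_stop("invalid geometry: need width, height >= 2 * cell_radius > 0",
            "cp_geometry_error")
  if (!is.null(seed)) set.seed(seed)
  centers <- cpp_pack_circles(width, height, cell_radius,
                              as.integer(max_failures))
  new_lattice(centers, width, height, cell_radius)
}

#' Construct a lattice from explicit centre coordinates
#'
#' Mainly for tests and miniature fixtures where an exact geometry is wanted.
#' The non-overlap and in-bounds invariants are enforced.
#'
#' @param centers Two-column matrix or data frame of centre coordinates (um).
#' @inheritParams build_lattice
#' @return A `cp_lattice` object.
#' @export
manual_lattice <- function(centers, width, height, cell_radius = 8) {
  centers <- as.matrix(centers)[, 1:2, drop = FALSE]
  if (nrow(centers) >= 2) {
    d <- as.matrix(stats::dist(centers))
    diag(d) <- Inf
    if (min(d) < 2 * cell_radius - 1e-9)
      cp_stop("centres closer than one cell diameter", "cp_geometry_error")
  }
  if (any(centers[, 1] < cell_radius - 1e-9) ||
      any(centers[, 1] > width - cell_radius + 1e-9) ||
      any(centers[, 2] < cell_radius - 1e-9) ||
      any(centers[, 2] > height - cell_radius + 1e-9))
    cp_stop("centres out of bounds", "cp_geometry_error")
  new_lattice(centers, width, height, cell_radius)
}

new_lattice <- function(centers, width, height, cell_radius) {
  centers <- matrix(as.numeric(centers), ncol = 2)
  n <- nrow(centers)
  nbor <- cpp_neighbor_lists(centers, min(30L, max(1L, n - 1L)))
  structure(
    list(
      width = width, height = height, cell_radius = cell_radius,
      centers = data.frame(site = seq_len(n), x = centers[, 1],
                           y = centers[, 2]),
      nbor = nbor  # 0-based, internal
    ),
    class = "cp_lattice"
  )
}

#' @export
print.cp_lattice <- function(x, ...) {
  cat(sprintf(
    "Irregular circle-packing lattice: %d sites, %g x %g um, cell radius %g um\n",
    nrow(x$centers), x$width, x$height, x$cell_radius))
  invisible(x)
}

#' Number of sites in a lattice
#' @param lattice A `cp_lattice`.
#' @return Integer site count.
#' @export
n_sites <- function(lattice) nrow(lattice$centers)

#' k nearest occupied sites
#'
#' Returns the `k` occupied sites closest (Euclidean centre distance) to a
#' query site, excluding the query site itself, ties broken by ascending
#' site index. If fewer than `k` occupied sites exist they are all returned.
#'
#' @param lattice A `cp_lattice`.
#' @param site Query site id.
#' @param k Number of neighbours (default 5, the neighbourhood size used
#'   throughout the model).
#' @param occupied Logical vector over sites; defaults to all occupied.
#' @return Integer vector of site ids ordered by distance.
#' @export
nearest_neighbors <- function(lattice, site, k = 5, occupied = NULL) {
  site <- check_site(lattice, site)
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    cp_stop("`k` must be a positive integer", "cp_config_error")
  if (is.null(occupied)) occupied <- rep(TRUE, n_sites(lattice))
  xy <- as.matrix(lattice$centers[, c("x", "y")])
  res <- cpp_knn(xy, lattice$nbor, occupied, site - 1L, as.integer(k))
  res + 1L
}

#' Path from an occupied site to the nearest empty site
#'
#' Finds the globally nearest empty site and returns a site sequence from
#' `start` to it, stepping through successive occupied nearest-neighbour
#' sites (greedy descent on the 8-nearest-site graph with a breadth-first
#' fallback). During a cell insertion the cells on this path are shifted one
#' position outward, morphogen content and all.
#'
#' @param lattice A `cp_lattice`.
#' @param start Occupied start site id.
#' @param occupied Logical occupancy vector over sites.
#' @return Integer vector of site ids; the last is empty, all others
#'   occupied.
#' @export
path_to_nearest_empty <- function(lattice, start, occupied) {
  start <- check_site(lattice, start)
  if (all(occupied))
    cp_stop("lattice is saturated: no empty site", "cp_saturation_error")
  xy <- as.matrix(lattice$centers[, c("x", "y")])
  res <- cpp_path_to_empty(xy, lattice$nbor, occupied, start - 1L)
  res + 1L
}

#' Write lattice centres to a CSV file
#'
#' Plain tabular serialization (`site_id`, `x_um`, `y_um`) for
#' reproducibility and external tooling.
#'
#' @param lattice A `cp_lattice`.
#' @param path Output file path.
#' @export
write_lattice <- function(lattice, path) {
  df <- data.frame(site_id = lattice$centers$site,
                   x_um = lattice$centers$x, y_um = lattice$centers$y)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a lattice from a CSV written by [write_lattice()]
#'
#' @param path CSV file with columns `site_id`, `x_um`, `y_um`.
#' @param width,height,cell_radius Geometry of the original lattice.
#' @return A `cp_lattice`.
#' @export
read_lattice <- function(path, width, height, cell_radius = 8) {
  df <- utils::read.csv(path)
  manual_lattice(cbind(df$x_um, df$y_um), width, height, cell_radius)
}
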