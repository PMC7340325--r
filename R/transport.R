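#' Exponential growth-rate constant of an expanding tissue
#'
#' For a tissue growing exponentially from length `L0` to `L_T` over time
#' `T`, returns the rate constant `kappa = log(L_T / L0) / T` (1/s). With
#' the measured neural-plate expansion (60 um to 1000 um over 9000 s) this
#' is 3.13e-4 per second, and the advective growth field of the diffusion
#' equation equals this constant.
#'
#' @param L0 Initial length (um), positive.
#' @param L_T Final length (um), positive.
#' @param T Elapsed time (s), positive.
#' @return Growth rate constant in 1/s.
#' @examples
#' growth_constant(60, 1000, 9000)
#' @export
growth_constant <- function(L0, L_T, T) {
  if (!is.numeric(L0) || !is.numeric(L_T) || !is.numeric(T) ||
      any(c(L0, L_T, T) <= 0))
    cp_stop("L0, L_T and T must all be positive", "cp_domain_error")
  log(L_T / L0) / T
}

# ---- samplable distributions ----------------------------------------------

new_dist <- function(type, a = 0, b = 0, lo = 0, hi = 0,
                     vals = numeric(0), wts = numeric(0)) {
  structure(list(type = as.integer(type), a = a, b = b, lo = lo, hi = hi,
                 vals = as.numeric(vals), wts = as.numeric(wts)),
            class = "cp_dist")
}

#' Samplable distributions for filopodium length and angle
#'
#' Small constructors for the distributions a [transport_config()] can carry:
#' a degenerate point mass, a Gamma (parametrised by mean and coefficient of
#' variation), a truncated centred Normal, and a discrete empirical histogram
#' (bin centre, weight). The Gamma/truncated-Normal pair is the built-in
#' stand-in for the measured filopodium length/angle distributions: mean
#' length 17 um (about two cell diameters) with CV 0.35, and angles relative
#' to the tissue-ward axis truncated to (-90, 90) degrees with SD 35.
#'
#' @param value Point mass value (`dist_fixed`), or histogram bin centres
#'   (`dist_histogram`).
#' @param mean,cv Mean and coefficient of variation of the Gamma.
#' @param sd,lo,hi Standard deviation and truncation bounds of the Normal.
#' @param weight Non-negative histogram weights.
#' @return A `cp_dist` object.
#' @name distributions
#' @examples
#' mean(draw_dist(dist_gamma(17, 0.35), 1e4))
NULL

#' @rdname distributions
#' @export
dist_fixed <- function(value) new_dist(0L, a = value)

#' @rdname distributions
#' @export
dist_gamma <- function(mean = 17, cv = 0.35) {
  if (mean <= 0 || cv <= 0)
    cp_stop("gamma mean and cv must be positive", "cp_config_error")
  shape <- 1 / cv^2
  new_dist(1L, a = shape, b = mean / shape)
}

#' @rdname distributions
#' @export
dist_truncnorm <- function(sd = 35, lo = -90, hi = 90) {
  if (sd <= 0 || lo >= hi)
    cp_stop("need sd > 0 and lo < hi", "cp_config_error")
  new_dist(2L, a = sd, lo = lo, hi = hi)
}

#' @rdname distributions
#' @export
dist_histogram <- function(value, weight) {
  if (length(value) != length(weight) || length(value) == 0 ||
      any(weight < 0) || sum(weight) <= 0)
    cp_stop("histogram needs matching bin centres and non-negative weights",
            "cp_config_error")
  new_dist(3L, vals = value, wts = weight)
}

#' Draw from a `cp_dist`
#' @param dist A `cp_dist` object.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_dist <- function(dist, n = 1) {
  if (!inherits(dist, "cp_dist"))
    cp_stop("distribution not configured", "cp_config_error")
  cpp_sample_dist(dist, as.integer(n))
}

#' Read an empirical histogram distribution from a two-column text file
#'
#' The file format is two delimited columns (bin centre, weight) with an
#' optional header, one file each for filopodium length (um) and angle
#' (degrees).
#'
#' @param path File path.
#' @return A `cp_dist` histogram distribution.
#' @export
read_histogram_dist <- function(path) {
  first_token <- strsplit(trimws(readLines(path, n = 1)), "[,; \t]+")[[1]][1]
  has_header <- is.na(suppressWarnings(as.numeric(first_token)))
  df <- utils::read.table(path, header = has_header, sep = "",
                          comment.char = "#")
  dist_histogram(df[[1]], df[[2]])
}

# ---- transport configuration ----------------------------------------------

#' Morphogen transport configuration
#'
#' Bundles everything the morphogen-dynamics step needs. Exactly one
#' transport mode is active per run: `"cytoneme"` (stochastic deposition by
#' signalling filopodia grown from producer cells) or `"diffusion"`
#' (extracellular concentration field on the exponentially growing domain,
#' absorbed by each receiving cell every time step). Decay applies in both
#' modes: with probability `p_decay` per cell per step the cumulative
#' content drops by one unit (clamped at zero).
#'
#' @param mode `"cytoneme"` or `"diffusion"`.
#' @param p_fil Per-producer per-step filopodium formation probability.
#' @param deposit_amount Morphogen units per successful contact (default 1,
#'   the same quantum the decay process removes).
#' @param contact_tolerance Distance (um) from a cell surface within which a
#'   filopodium tip deposits (default 2).
#' @param p_decay Per-cell per-step decay probability.
#' @param length_dist,angle_dist `cp_dist` objects for filopodium length
#'   (um) and angle (degrees, relative to the tissue-ward +x axis).
#' @param D Diffusion constant (um^2/s, default 0.1).
#' @param C0 Fixed concentration at the producing boundary (default 0.1).
#' @param kappa Domain growth rate (1/s); default from the measured
#'   expansion, [growth_constant()](60, 1000, 9000).
#' @param nx Number of field grid nodes (default 501, i.e. 2 um spacing on
#'   the full-grown 1000 um domain).
#' @param scheme `"lagrangian"` (material coordinate on the growing domain;
#'   default) or `"eulerian"` (fixed grid, literal constant advection
#'   velocity `u`, for comparison).
#' @param u Advection velocity for the Eulerian scheme; defaults to `kappa`.
#' @return A `transport_config` object.
#' @export
transport_config <- function(mode = c("cytoneme", "diffusion"),
                             p_fil = 0.05, deposit_amount = 1,
                             contact_tolerance = 2, p_decay = 5e-4,
                             length_dist = dist_gamma(17, 0.35),
                             angle_dist = dist_truncnorm(35, -90, 90),
                             D = 0.1, C0 = 0.1,
                             kappa = growth_constant(60, 1000, 9000),
                             nx = 501, scheme = c("lagrangian", "eulerian"),
                             u = NULL) {
  mode <- match.arg(mode)
  scheme <- match.arg(scheme)
  check_probability(p_fil, "p_fil")
  check_probability(p_decay, "p_decay")
  if (deposit_amount <= 0 || contact_tolerance < 0 || D < 0 || C0 < 0 ||
      nx < 3)
    cp_stop("invalid transport parameter", "cp_config_error")
  if (mode == "cytoneme" &&
      (!inherits(length_dist, "cp_dist") || !inherits(angle_dist, "cp_dist")))
    cp_stop("length_dist and angle_dist must be cp_dist objects",
            "cp_config_error")
  structure(
    list(mode = mode, p_fil = p_fil, deposit_amount = deposit_amount,
         contact_tolerance = contact_tolerance, p_decay = p_decay,
         length_dist = length_dist, angle_dist = angle_dist,
         D = D, C0 = C0, kappa = kappa, nx = as.integer(nx),
         scheme = scheme, u = if (is.null(u)) kappa else u),
    class = "transport_config"
  )
}

# transport_config -> list the C++ kernel understands
tp_params <- function(cfg, dx) {
  list(mode = if (cfg$mode == "cytoneme") 0L else 1L,
       p_fil = cfg$p_fil, deposit_amount = cfg$deposit_amount,
       contact_tolerance = cfg$contact_tolerance, p_decay = cfg$p_decay,
       length_dist = unclass(cfg$length_dist),
       angle_dist = unclass(cfg$angle_dist),
       D = cfg$D, kappa = cfg$kappa, C0 = cfg$C0,
       scheme = if (cfg$scheme == "lagrangian") 0L else 1L,
       u = cfg$u, dx = dx)
}

# ---- filopodia -------------------------------------------------------------

#' Sample a filopodium from a producing cell
#'
#' Length and angle are independent draws from the configured distributions;
#' the tip lies at `origin + length * (cos(angle), sin(angle))` with the
#' angle measured from the +x axis pointing into the receiving tissue. Each
#' filopodium makes a single deposition attempt and is then discarded.
#'
#' @param origin Numeric length-2 centre of the producing cell (um).
#' @param cfg A [transport_config()] in cytoneme mode.
#' @return A `filopodium`: list with `origin`, `length` (um), `angle`
#'   (degrees) and `tip` (um).
#' @export
sample_filopodium <- function(origin, cfg) {
  if (!inherits(cfg$length_dist, "cp_dist") ||
      !inherits(cfg$angle_dist, "cp_dist"))
    cp_stop("filopodium distributions not configured", "cp_config_error")
  len <- draw_dist(cfg$length_dist, 1)
  ang <- draw_dist(cfg$angle_dist, 1)
  structure(
    list(origin = as.numeric(origin), length = len, angle = ang,
         tip = as.numeric(origin) +
           len * c(cos(ang * pi / 180), sin(ang * pi / 180))),
    class = "filopodium"
  )
}

#' Attempt a morphogen deposition at a filopodium tip
#'
#' If the tip lies within `contact_tolerance` of the surface of an occupied
#' receiving cell (centre distance at most `cell_radius +
#' contact_tolerance`; a tip inside the cell also counts), the nearest such
#' cell receives `deposit_amount` units. Producing cells never receive
#' morphogen. No contact is a valid outcome and leaves every cell unchanged.
#'
#' @param fil A `filopodium` from [sample_filopodium()].
#' @param lattice A `cp_lattice`.
#' @param cells Cells data frame (`site`, `producer`, `content`, ...).
#' @param cfg A [transport_config()].
#' @return List with `cells` (possibly updated) and `site` (the receiving
#'   site id, or `NA` if the filopodium retracted without contact).
#' @export
attempt_deposition <- function(fil, lattice, cells, cfg) {
  v <- vectors_from_cells(lattice, cells)
  xy <- as.matrix(lattice$centers[, c("x", "y")])
  tgt <- cpp_deposit_target(xy, v$occupied, v$producer,
                            fil$tip[1], fil$tip[2],
                            lattice$cell_radius, cfg$contact_tolerance)
  if (tgt < 0) return(list(cells = cells, site = NA_integer_))
  site <- tgt + 1L
  row <- which(cells$site == site)
  cells$content[row] <- cells$content[row] + cfg$deposit_amount
  list(cells = cells, site = site)
}

# ---- the 1D extracellular field -------------------------------------------

#' Create the 1D extracellular morphogen field
#'
#' The concentration profile for diffusion-mode transport, defined over the
#' receiving tissue with the producing boundary at distance 0. Internally
#' the default solver works in the material (Lagrangian) coordinate
#' `xi = x / L(t)` of the uniformly growing domain `L(t) = L0 * exp(kappa t)`,
#' in which the growing-domain transport equation reduces to
#' `dC/dt = (D / L(t)^2) d2C/dxi2 - kappa C`; the advection and dilution of
#' the expanding tissue are thereby honoured exactly. Boundary conditions
#' are `C = C0` at the origin and `C = 0` at the far end.
#'
#' @param length Physical domain length scale (um); the far boundary.
#' @param L0 Initial tissue length (um, default 60).
#' @param cfg A [transport_config()] supplying `D`, `kappa`, `C0`, `nx`,
#'   `scheme` and `u`.
#' @return A `morphogen_field`: list with the nodal concentrations `C`,
#'   current domain length `L`, elapsed time `t` and the solver settings.
#' @export
morphogen_field <- function(length = 1000, L0 = 60,
                            cfg = transport_config("diffusion")) {
  nx <- cfg$nx
  C <- numeric(nx)
  C[1] <- cfg$C0
  structure(
    list(C = C, nx = nx, D = cfg$D, kappa = cfg$kappa, C0 = cfg$C0,
         L = L0, t = 0, scheme = cfg$scheme, u = cfg$u,
         length = length, dx = length / (nx - 1)),
    class = "morphogen_field"
  )
}

#' Advance the morphogen field by `dt` seconds
#'
#' Explicit second-order central differences with automatic substepping to
#' satisfy the stability bound of the scheme; concentrations stay
#' non-negative and the boundary values are reimposed every substep.
#'
#' @param field A `morphogen_field`.
#' @param dt Time increment in seconds (> 0).
#' @return The advanced `morphogen_field`.
#' @export
diffusion_step <- function(field, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    cp_stop("dt must be a positive number", "cp_config_error")
  res <- cpp_diffusion_advance(field$C, field$L, field$D, field$kappa,
                               field$C0, dt,
                               if (field$scheme == "lagrangian") 0L else 1L,
                               field$u, field$dx)
  field$C <- res$C
  field$L <- res$L
  field$t <- field$t + dt
  field
}

#' Concentration at physical distance(s) from the producing boundary
#'
#' Linear interpolation between grid nodes. Positions beyond the current
#' domain return 0; negative positions are an error.
#'
#' @param field A `morphogen_field`.
#' @param x Distances from the producing boundary (um).
#' @return Numeric vector of concentrations.
#' @export
field_at <- function(field, x) {
  if (any(x < 0) || any(x > field$length))
    cp_stop("position outside the field domain", "cp_interpolation_error")
  scheme <- if (field$scheme == "lagrangian") 0L else 1L
  vapply(x, function(xi)
    cpp_field_value(field$C, field$L, scheme, field$dx, xi), numeric(1))
}

#' Absorb the local field concentration into a cell
#'
#' In diffusion mode each receiving cell increases its cumulative morphogen
#' content by the local concentration `C(x, t)` every time step; absorption
#' does not deplete the field.
#'
#' @param cell One-row cells data frame; its `x` is the distance from the
#'   producing boundary.
#' @param field A `morphogen_field`.
#' @return The cell with updated `content`.
#' @export
absorb_field <- function(cell, field) {
  cell$content <- cell$content + field_at(field, cell$x)
  cell
}

#' Stochastic decay of cellular morphogen content
#'
#' With probability `p_decay` per cell per step, the cumulative content is
#' reduced by one unit, clamped at zero. Vectorised over the rows of
#' `cells`; each row draws independently.
#'
#' @param cells Cells data frame (or any data frame with a `content`
#'   column).
#' @param p_decay Decay probability per step.
#' @return `cells` with updated `content`.
#' @export
decay_step <- function(cells, p_decay) {
  check_probability(p_decay, "p_decay")
  hit <- stats::runif(nrow(cells)) < p_decay
  cells$content[hit] <- pmax(cells$content[hit] - 1, 0)
  cells
}
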