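test_that("neighbourhood composition handles pure and mixed fields", {
  fx <- make_fixture("small-random", seed = 1)
  cells <- fx$cells
  cells$fate <- "midbrain"
  nc <- neighborhood_composition(cells, fx$lattice)
  expect_equal(nc$frac_homog, 100)
  expect_equal(nc$frac_border, 0)
  expect_equal(nc$frac_isolated, 0)
  # one deeply embedded dissenter contributes 1/n to the isolated bin
  cells2 <- cells
  cells2$fate[10] <- "forebrain"
  nc2 <- neighborhood_composition(cells2, fx$lattice)
  expect_equal(nc2$frac_isolated, 100 / nrow(cells2), tolerance = 1e-9)
  expect_error(neighborhood_composition(cells[1:4, ], fx$lattice),
               class = "cp_config_error")
})

test_that("composition bins match a per-cell brute-force count", {
  fx <- make_fixture("small-random", seed = 2)
  cells <- fx$cells
  set.seed(3)
  cells$fate <- sample(c("forebrain", "midbrain", "hindbrain"),
                       nrow(cells), replace = TRUE)
  nc <- neighborhood_composition(cells, fx$lattice)
  occ <- rep(TRUE, n_sites(fx$lattice))
  frac <- vapply(seq_len(nrow(cells)), function(i) {
    nb <- oracle_knn(fx$lattice, cells$site[i], 5, occ)
    mean(cells$fate[match(nb, cells$site)] == cells$fate[i])
  }, numeric(1))
  expect_equal(nc$frac_homog, 100 * mean(frac > 0.75), tolerance = 1e-9)
  expect_equal(nc$frac_border, 100 * mean(frac >= 0.25 & frac <= 0.75),
               tolerance = 1e-9)
  expect_equal(nc$frac_isolated, 100 * mean(frac < 0.25), tolerance = 1e-9)
  expect_equal(nc$frac_homog + nc$frac_border + nc$frac_isolated, 100,
               tolerance = 1e-9)
})

test_that("composition is invariant under rigid translation", {
  fx <- make_fixture("small-random", seed = 4)
  cells <- fx$cells
  set.seed(5)
  cells$fate <- sample(c("forebrain", "hindbrain"), nrow(cells),
                       replace = TRUE)
  nc1 <- neighborhood_composition(cells, fx$lattice)
  shifted <- manual_lattice(cbind(fx$lattice$centers$x + 40,
                                  fx$lattice$centers$y + 40),
                            380, 380, 8)
  cells2 <- cells
  cells2$x <- cells$x + 40
  cells2$y <- cells$y + 40
  nc2 <- neighborhood_composition(cells2, shifted)
  expect_equal(nc1$frac_homog, nc2$frac_homog)
  expect_equal(nc1$frac_isolated, nc2$frac_isolated)
})

test_that("gradient profiles reproduce hand-computed bin means", {
  t1 <- make_fixture("frozen-trajectory", seed = 6)
  gp <- gradient_profile(t1, times = 0, bin_width = 50, normalize = FALSE)
  cells <- cells_at(t1, 0)
  want <- mean(cells$content[cells$x >= 0 & cells$x < 50])
  expect_equal(gp$mean[gp$bin_center == 25], want, tolerance = 1e-9)
  # a single replicate has zero SD
  expect_true(all(gp$sd == 0 | is.na(gp$sd)))
  # uniform contents normalize to a flat unit profile
  t2 <- make_fixture("frozen-trajectory", seed = 6)
  t2$snapshots <- lapply(t2$snapshots, function(s) {
    s$content <- rep(3, length(s$site)); s
  })
  gp2 <- gradient_profile(t2, times = 0, bin_width = 50)
  expect_true(all(abs(gp2$mean - 1) < 1e-9))
})

test_that("two known replicates average correctly per bin", {
  ta <- make_fixture("frozen-trajectory", seed = 7)
  tb <- make_fixture("frozen-trajectory", seed = 7)
  tb$snapshots <- lapply(tb$snapshots, function(s) {
    s$content <- s$content + 10; s
  })
  gp <- gradient_profile(list(ta, tb), times = 0, bin_width = 50,
                         normalize = FALSE)
  ca <- cells_at(ta, 0); cb <- cells_at(tb, 0)
  sel <- ca$x >= 50 & ca$x < 100
  expect_equal(gp$mean[gp$bin_center == 75],
               mean(c(mean(ca$content[sel]), mean(cb$content[sel]))),
               tolerance = 1e-9)
  expect_equal(gp$sd[gp$bin_center == 75],
               sd(c(mean(ca$content[sel]), mean(cb$content[sel]))),
               tolerance = 1e-9)
})

test_that("threshold time-courses degrade gracefully and match sorts", {
  tr <- make_fixture("frozen-trajectory", seed = 8)
  # all equal at one time -> difference 0
  tr$snapshots[[1]]$content <- rep(4, length(tr$snapshots[[1]]$site))
  tt <- threshold_timecourse(tr, times = c(0, 60))
  expect_equal(tt$diff_mean[tt$time == 0], 0)
  # contents 1..9 -> difference within (2, 4)
  tr$snapshots[[2]]$content <- c(1:9, rep(5, length(tr$snapshots[[2]]$site) - 9))
  cells9 <- 1:9
  thr9 <- compute_thresholds(cells9)
  expect_gt(thr9$theta_high - thr9$theta_low, 2)
  expect_lt(thr9$theta_high - thr9$theta_low, 4)
  # replicate mean/sd against direct computation
  t2 <- make_fixture("frozen-trajectory", seed = 9)
  tt2 <- threshold_timecourse(list(t2, t2), times = 60)
  one <- compute_thresholds(cells_at(t2, 60)$content, 60)
  expect_equal(tt2$theta_low_mean, one$theta_low, tolerance = 1e-9)
  expect_equal(tt2$theta_low_sd, 0)
})

test_that("boundary positions sit between the fate stripes", {
  # perfectly sorted synthetic field: content decreasing in x over ~300 um
  fx <- make_fixture("small-ramp", seed = 10)
  tr <- make_fixture("frozen-trajectory", seed = 10)
  tr$snapshots <- lapply(tr$snapshots, function(s) {
    s$content <- fx$cells$content[s$site]; s
  })
  tr$lattice <- fx$lattice
  contents <- fx$cells$content
  thr <- compute_thresholds(contents, 0)
  bp <- boundary_positions(tr, thr, times = 0)
  x_sorted <- sort(fx$cells$x)
  n <- length(x_sorted)
  expect_equal(bp$x_hind_mid, x_sorted[ceiling(n / 3)], tolerance = 25)
  expect_equal(bp$x_mid_fore, x_sorted[ceiling(2 * n / 3)], tolerance = 25)
  # single-fate tissue has no boundaries
  tr1 <- tr
  tr1$snapshots <- lapply(tr1$snapshots, function(s) {
    s$content <- rep(1, length(s$site)); s
  })
  thr1 <- structure(list(theta_low = 10, theta_high = 20, set_time = 0,
                         n = 5), class = "thresholds")
  bp1 <- boundary_positions(tr1, thr1, times = 0)
  expect_true(is.na(bp1$x_hind_mid))
  expect_true(is.na(bp1$x_mid_fore))
})

test_that("neighbour lifetimes: frozen tissue scores the full duration", {
  tr <- make_fixture("frozen-trajectory", seed = 11)
  nl <- neighbor_lifetimes(tr)
  expect_true(all(abs(nl$durations_min - 10) < 1e-9))  # 600 s span
  expect_identical(sum(nl$histogram$count), length(nl$durations_min))
})

test_that("a forced swap at t = 300 s cuts those lifetimes to 300 s", {
  tr <- make_fixture("single-swap-trajectory", seed = 11)
  nl <- neighbor_lifetimes(tr)
  expect_setequal(unique(round(nl$durations_min * 60)), c(300, 600))
  expect_gt(sum(abs(nl$durations_min * 60 - 300) < 1e-6), 0)
})

test_that("lifetimes match a pairwise interval-scan oracle on a moving run", {
  traj <- run_simulation(small_sim_config(
    seed = 12, duration = 300,
    dynamics_args = list(p_ins = 0, p_mig = 0.05)))
  nl <- neighbor_lifetimes(traj, k = 5)
  # oracle: enumerate pair presence per snapshot, scan runs
  keysets <- lapply(seq_along(traj$times), function(j) {
    s <- traj$snapshots[[j]]
    keep <- !s$producer
    sites <- s$site[keep]
    occ <- rep(FALSE, n_sites(traj$lattice))
    occ[sites] <- TRUE
    id_of <- integer(n_sites(traj$lattice))
    id_of[s$site] <- s$cell_id
    unlist(lapply(sites, function(st) {
      nb <- oracle_knn(traj$lattice, st, 5, occ)
      paste(id_of[st], id_of[nb])
    }))
  })
  all_keys <- unique(unlist(keysets))
  pres <- vapply(keysets, function(ks) all_keys %in% ks,
                 logical(length(all_keys)))
  interval <- diff(traj$times)[1]
  span <- max(traj$times)
  oracle <- unlist(apply(pres, 1, function(row) {
    r <- rle(row)
    lens <- r$lengths[r$values]
    starts <- cumsum(c(1, r$lengths))[-(length(r$lengths) + 1)][r$values]
    pmin(lens * interval, pmax(span - traj$times[starts], interval))
  }))
  expect_equal(sort(nl$durations_min * 60), sort(oracle))
})
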