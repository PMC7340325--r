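test_that("insertion shifts one chain, duplicates one donor, adds one cell", {
  fx <- make_fixture("small-ramp", seed = 1)
  lat <- fx$lattice
  cells <- fx$cells[-(1:20), ]  # free some sites
  at <- cells$site[which(!cells$producer)[5]]
  set.seed(2)
  out <- insertion_event(lat, cells, at)
  expect_false(attr(out, "skipped"))
  expect_identical(nrow(out), nrow(cells) + 1L)
  # multiset of previous contents preserved, one donor value duplicated
  extra <- out$content
  for (v in cells$content) extra <- extra[-match(v, extra)]
  expect_length(extra, 1)
  expect_true(extra %in% cells$content)
  new_row <- out[out$cell_id == attr(out, "new_cell_id"), ]
  expect_identical(new_row$site, at)
  # donor comes from the same x band (ramp contents encode x)
  donor_x <- cells$x[match(new_row$content, cells$content)]
  expect_lte(abs(donor_x - new_row$x), 6 + 1e-9)
})

test_that("insertion on a saturated lattice is skipped, not fatal", {
  fx <- make_fixture("tiny-uniform", seed = 1)
  out <- insertion_event(fx$lattice, fx$cells, fx$cells$site[1])
  expect_true(attr(out, "skipped"))
  expect_identical(nrow(out), nrow(fx$cells))
})

test_that("constant p_ins produces exponential growth of the cell count", {
  # sized so the lattice stays well below saturation throughout
  cfg <- small_sim_config(seed = 3, duration = 3000, width = 500,
                          height = 500,
                          transport_args = list(p_fil = 0),
                          dynamics_args = list(p_ins = 5e-4, p_mig = 0))
  traj <- run_simulation(cfg)
  ec <- event_counts(traj)
  n0 <- ec$n_receivers[1]
  nT <- ec$n_receivers[nrow(ec)]
  expect_equal(log(nT / n0), 5e-4 * 3000, tolerance = 0.10)
  fit <- summary(lm(log(ec$n_receivers) ~ ec$time))
  expect_gt(fit$r.squared, 0.95)
})

test_that("migration does nothing at p_mig = 0 and is binomial undirected", {
  lat <- manual_lattice(rbind(c(8, 8), c(24, 8)), 32, 16, 8)
  cells <- data.frame(site = 1:2, x = lat$centers$x, y = lat$centers$y,
                      producer = FALSE, content = c(0, 10),
                      fate = NA_character_, cell_id = 1:2,
                      stringsAsFactors = FALSE)
  out <- migration_event(cells, lat, 1, dynamics_config(p_mig = 0))
  expect_true(is.na(attr(out, "swapped_with")))
  expect_identical(out$cell_id, cells$cell_id)

  set.seed(4)
  n <- 3000
  p <- 0.3
  swaps <- sum(replicate(n, !is.na(attr(
    migration_event(cells, lat, 1, dynamics_config(p_mig = p, p_dirmig = 0)),
    "swapped_with"))))
  expect_lt(abs(swaps - n * p), 3 * sqrt(n * p * (1 - p)))
})

test_that("directed migration strictly favours gradient-reinforcing swaps", {
  lat <- manual_lattice(rbind(c(8, 8), c(24, 8)), 32, 16, 8)
  # high-content cell sits anteriorly (larger x): swapping moves it toward
  # the producing margin, which reinforces the gradient
  cells <- data.frame(site = 1:2, x = lat$centers$x, y = lat$centers$y,
                      producer = FALSE, content = c(0, 10),
                      fate = NA_character_, cell_id = 1:2,
                      stringsAsFactors = FALSE)
  n <- 4000
  rate <- function(p_dirmig, seed) {
    set.seed(seed)
    dyn <- dynamics_config(p_mig = 0.1, p_dirmig = p_dirmig,
                           dirmig_scale = 20)
    mean(replicate(n, !is.na(attr(migration_event(cells, lat, 2, dyn),
                                  "swapped_with"))))
  }
  undirected <- rate(0, 5)
  directed <- rate(0.2, 5)
  expect_gt(directed, undirected)
  # and the anti-sorting direction is suppressed below the undirected rate
  cells_rev <- cells
  cells_rev$content <- c(10, 0)
  set.seed(6)
  dyn <- dynamics_config(p_mig = 0.1, p_dirmig = 0.2, dirmig_scale = 20)
  anti <- mean(replicate(n, !is.na(attr(
    migration_event(cells_rev, lat, 2, dyn), "swapped_with"))))
  expect_lt(anti, undirected)
})

test_that("directed sorting monotonically increases the content-position rank correlation", {
  rho_gain <- vapply(1:5, function(seed) {
    cfg <- small_sim_config(seed = seed, duration = 400,
                            transport_args = list(p_fil = 0, p_decay = 0),
                            dynamics_args = list(p_ins = 0, p_mig = 0.05,
                                                 p_dirmig = 0.5,
                                                 dirmig_scale = 5))
    state <- initialize_simulation(cfg)
    state$content[state$occupied & !state$producer] <-
      runif(sum(state$occupied & !state$producer), 0, 100)
    rho0 <- cor(state$content[state$occupied & !state$producer],
                -state$lattice$centers$x[state$occupied & !state$producer],
                method = "spearman")
    state <- step_simulation(state, 400)
    rho1 <- cor(state$content[state$occupied & !state$producer],
                -state$lattice$centers$x[state$occupied & !state$producer],
                method = "spearman")
    rho1 - rho0
  }, numeric(1))
  expect_true(all(rho_gain > 0))
})

test_that("apoptosis ignores homogeneous tissue and removes the worst outlier", {
  fx <- make_fixture("small-random", seed = 9)
  lat <- fx$lattice
  cells <- fx$cells
  dyn <- dynamics_config(apoptosis_enabled = TRUE, apoptosis_budget = 10,
                         apoptosis_interval = 10)
  # all equal -> no discrepancy -> nothing happens
  cells_eq <- cells
  cells_eq$content <- 5
  res <- apoptosis_sweep(cells_eq, lat, step = 100, duration = 120,
                         dyn = dyn)
  expect_length(res$killed_sites, 0)
  # a single extreme outlier is removed first
  cells_out <- cells_eq
  cells_out$content[10] <- 100
  set.seed(10)
  res2 <- apoptosis_sweep(cells_out, lat, step = 100, duration = 120,
                          dyn = dyn)
  expect_true(cells_out$site[10] %in% res2$killed_sites)
  expect_false(res2$cells$content[10] == 100)
})

test_that("donor choice is uniform over the frozen x band", {
  fx <- make_fixture("small-ramp", seed = 1)
  lat <- fx$lattice
  cells <- fx$cells
  v <- cytopattern:::vectors_from_cells(lat, cells)
  xy <- as.matrix(lat$centers[, c("x", "y")])
  at <- 40L
  x_at <- lat$centers$x[at]
  band <- setdiff(which(abs(lat$centers$x - x_at) <= 6), at)
  set.seed(11)
  draws <- replicate(200 * length(band),
    cytopattern:::cpp_pick_donor(xy, v$occupied, v$producer, x_at, 6,
                                 at - 1L) + 1L)
  expect_true(all(draws %in% band))
  obs <- table(factor(draws, levels = band))
  expect_gt(chisq.test(obs)$p.value, 1e-4)
  # empty band widens to the nearest-in-x donor
  occ2 <- v$occupied
  occ2[band] <- FALSE
  far <- cytopattern:::cpp_pick_donor(xy, occ2, v$producer, x_at, 6,
                                      at - 1L) + 1L
  cand <- which(occ2)
  cand <- cand[cand != at]
  expect_equal(abs(lat$centers$x[far] - x_at),
               min(abs(lat$centers$x[cand] - x_at)))
})

test_that("producers are never moved, killed, or given content", {
  cfg <- small_sim_config(seed = 12, duration = 400,
                          dynamics_args = list(
                            p_mig = 0.05, p_dirmig = 0.1,
                            apoptosis_enabled = TRUE,
                            apoptosis_interval = 20))
  state0 <- initialize_simulation(cfg)
  traj <- run_simulation(cfg)
  final <- cells_at(traj, 400)
  prods <- final[final$producer, ]
  expect_identical(sort(prods$site), which(state0$producer))
  expect_true(all(prods$content == 0))
  ec <- event_counts(traj)
  expect_true(all(ec$n_occupied - ec$n_receivers ==
                  sum(state0$producer)))
})
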