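test_that("thresholds split 1..9 into exact thirds between order statistics", {
  thr <- compute_thresholds(1:9, t = 100)
  expect_gt(thr$theta_low, 3); expect_lt(thr$theta_low, 4)
  expect_gt(thr$theta_high, 6); expect_lt(thr$theta_high, 7)
  cells <- data.frame(producer = FALSE, content = 1:9)
  fates <- assign_fates(cells, thr)$fate
  expect_identical(fates, rep(c("forebrain", "midbrain", "hindbrain"),
                              each = 3))
})

test_that("identical contents give a degenerate-threshold error", {
  expect_error(compute_thresholds(rep(5, 10)),
               class = "cp_degenerate_error")
  expect_error(compute_thresholds(1:2), class = "cp_config_error")
})

test_that("class sizes differ by at most one for distinct contents", {
  set.seed(1)
  for (i in 1:200) {
    n <- sample(3:500, 1)
    contents <- runif(n, 0, 100)
    thr <- compute_thresholds(contents)
    code <- findInterval(contents, c(thr$theta_low, thr$theta_high)) + 1L
    sizes <- tabulate(code, 3)
    expect_lte(max(sizes) - min(sizes), 1)
  }
})

test_that("thresholds are equivariant under constant content shifts", {
  set.seed(2)
  contents <- rnorm(100)
  thr <- compute_thresholds(contents)
  thr2 <- compute_thresholds(contents + 7.5)
  expect_equal(thr2$theta_low, thr$theta_low + 7.5, tolerance = 1e-12)
  expect_equal(thr2$theta_high, thr$theta_high + 7.5, tolerance = 1e-12)
})

test_that("fate assignment uses half-open bands and skips producers", {
  thr <- structure(list(theta_low = 2, theta_high = 5, set_time = 0, n = 3),
                   class = "thresholds")
  cells <- data.frame(producer = c(FALSE, FALSE, FALSE, FALSE, TRUE),
                      content = c(0, 2, 5, 10, 100))
  fates <- assign_fates(cells, thr)$fate
  expect_identical(fates, c("forebrain", "midbrain", "hindbrain",
                            "hindbrain", NA))
  # exact match against a direct comparison oracle
  set.seed(3)
  cc <- data.frame(producer = FALSE, content = runif(500, 0, 8))
  got <- assign_fates(cc, thr)$fate
  want <- ifelse(cc$content < 2, "forebrain",
                 ifelse(cc$content < 5, "midbrain", "hindbrain"))
  expect_identical(got, want)
})

test_that("adoption times recover scripted crossing histories", {
  # hand-built trajectory: 4 cells with known content time courses
  times <- seq(0, 100, by = 10)
  hist <- rbind(
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),        # forebrain from t = 0
    c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10),       # crosses into midbrain band
    c(0, 0, 20, 20, 20, 20, 20, 20, 20, 20, 20), # hindbrain from t = 20
    c(0, 20, 20, 0, 0, 20, 20, 20, 20, 20, 20))  # dips out, re-enters at 50
  lat <- manual_lattice(cbind(seq(8, 8 + 3 * 16, 16), 8), 70, 16, 8)
  snaps <- lapply(seq_along(times), function(j)
    list(time = times[j], site = 1:4, cell_id = 1:4,
         producer = rep(FALSE, 4), content = hist[, j],
         fate = rep(0L, 4)))
  traj <- structure(list(config = list(dt = 1), lattice = lat,
                         producer_edge = 0, times = times,
                         snapshots = snaps,
                         lineage = data.frame(child = integer(0),
                                              parent = integer(0))),
                    class = "tissue_sim")
  thr <- structure(list(theta_low = 5.5, theta_high = 15, set_time = 100,
                        n = 4), class = "thresholds")
  ad <- fate_adoption_times(traj, thr)
  expect_identical(ad$adoption_time[ad$cell_id == 1], 0)
  expect_identical(ad$adoption_time[ad$cell_id == 2], 60)  # content 6 >= 5.5
  expect_identical(ad$adoption_time[ad$cell_id == 3], 20)
  expect_identical(ad$adoption_time[ad$cell_id == 4], 50)
  # backward linear-scan oracle over all snapshots
  oracle <- vapply(1:4, function(i) {
    final <- findInterval(hist[i, 11], c(5.5, 15)) + 1
    codes <- findInterval(hist[i, ], c(5.5, 15)) + 1
    bad <- which(codes != final)
    if (length(bad)) times[max(bad) + 1] else 0
  }, numeric(1))
  expect_identical(ad$adoption_time[match(1:4, ad$cell_id)], oracle)
  expect_true(all(ad$adoption_time <= 100))
})

test_that("adoption fraction is non-decreasing and quantiles behave", {
  traj <- run_simulation(small_sim_config(seed = 13, duration = 900,
                                          t_trs = 900))
  cells <- cells_at(traj, 900)
  thr <- compute_thresholds(cells$content[!cells$producer], 900)
  ad <- fate_adoption_times(traj, thr)
  expect_true(all(ad$adoption_time <= 900))
  tc <- adoption_timecourse(ad, seq(0, 900, 60))
  expect_true(all(diff(tc$fraction) >= 0))
  t50 <- adoption_quantile(ad, 0.5)
  expect_gte(mean(ad$adoption_time <= t50), 0.5)
})

test_that("late-born cells without inheritance adopt no earlier than birth", {
  traj <- run_simulation(small_sim_config(
    seed = 14, duration = 1500, t_trs = 1500,
    dynamics_args = list(p_ins = 2e-3)))
  cells <- cells_at(traj, 1500)
  thr <- compute_thresholds(cells$content[!cells$producer], 1500)
  ad_no <- fate_adoption_times(traj, thr, inherit = FALSE)
  ad_in <- fate_adoption_times(traj, thr, inherit = TRUE)
  first_seen <- rep(Inf, max(ad_no$cell_id))
  for (j in seq_along(traj$times)) {
    ids <- traj$snapshots[[j]]$cell_id
    new <- ids[is.finite(ids) & first_seen[ids] == Inf]
    first_seen[new] <- traj$times[j]
  }
  born_late <- ad_no$cell_id[first_seen[ad_no$cell_id] > 0]
  expect_true(all(ad_no$adoption_time[match(born_late, ad_no$cell_id)] >=
                  pmin(first_seen[born_late], 1500) - 60))
  # inheritance can only move adoption earlier
  m <- match(ad_no$cell_id, ad_in$cell_id)
  expect_true(all(ad_in$adoption_time[m] <= ad_no$adoption_time + 1e-9))
})

test_that("community fate updates reduce to thresholding when gamma = 0", {
  fx <- make_fixture("small-random", seed = 15)
  thr <- compute_thresholds(fx$cells$content)
  cells <- assign_fates(fx$cells, thr)
  cells$fate <- sample(c("forebrain", "midbrain", "hindbrain"),
                       nrow(cells), replace = TRUE)
  cfg <- community_config(beta = 1, gamma = 0, p_wnt = 1)
  out <- community_fate_update(cells, fx$lattice, thr, cfg)
  expect_identical(out$fate, assign_fates(fx$cells, thr)$fate)
})

test_that("community updates adopt the neighbourhood fate when beta = 0", {
  fx <- make_fixture("small-random", seed = 16)
  thr <- compute_thresholds(fx$cells$content)
  cells <- fx$cells
  cells$fate <- "midbrain"
  cells$fate[1] <- "hindbrain"
  cfg <- community_config(beta = 0, gamma = 1, p_nei = 1)
  set.seed(17)
  out <- community_fate_update(cells, fx$lattice, thr, cfg)
  expect_identical(out$fate[1], "midbrain")
})

test_that("strong neighbour coupling increases fate clustering", {
  fx <- make_fixture("small-random", seed = 18)
  thr <- compute_thresholds(fx$cells$content)
  cells <- fx$cells
  set.seed(19)
  cells$fate <- sample(c("forebrain", "midbrain", "hindbrain"),
                       nrow(cells), replace = TRUE)
  same_frac <- function(cc) {
    nc <- neighborhood_composition(cc, fx$lattice)
    nc$frac_homog + nc$frac_border
  }
  before <- same_frac(cells)
  cfg <- community_config(beta = 0, gamma = 1, p_nei = 0.9)
  for (i in 1:10) cells <- community_fate_update(cells, fx$lattice, thr, cfg)
  expect_gt(same_frac(cells), before)
})
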