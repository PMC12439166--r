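# Weighted-ensemble engine: distance function, variation-maximising
# resampler contracts, conservation, lineage bookkeeping and profiles.

test_that("rgyr distance is a symmetric pseudo-metric on states", {
  expect_equal(rgyr_distance(1.2, 0.9), 0.3)
  expect_equal(rgyr_distance(0.7, 0.7), 0)
  set.seed(3)
  for (i in 1:10) {
    a <- matrix(rnorm(30), 10, 3); b <- matrix(rnorm(30), 10, 3)
    expect_equal(rgyr_distance(a, b), rgyr_distance(b, a), tolerance = 1e-14)
    expect_gte(rgyr_distance(a, b), 0)
    expect_equal(rgyr_distance(a, a), 0)
  }
})

test_that("degenerate ensembles are returned unchanged", {
  pp <- revo_params(n_walkers = 10, n_cycles = 1)
  # all walkers identical: every distance 0, no proposal can raise V
  set.seed(1)
  rs <- resample_revo(rep(1.5, 10), rep(0.1, 10), pp)
  expect_identical(rs$parent, 1:10)
  expect_equal(rs$weights, rep(0.1, 10))
  expect_length(rs$record$clones, 0L)
  # two walkers farther apart than merge_dist: no merge possible
  pp2 <- revo_params(n_walkers = 2, merge_dist = 0.25)
  rs2 <- resample_revo(c(0, 1), c(0.5, 0.5), pp2)
  expect_identical(rs2$parent, 1:2)
  # near-zero distance exponent: variation is flat, nothing accepted
  pp3 <- revo_params(n_walkers = 10, dist_exp = 1e-12)
  set.seed(2)
  rs3 <- resample_revo(runif(10), rep(0.1, 10), pp3)
  expect_identical(rs3$parent, 1:10)
})

test_that("resampling conserves weight and respects the weight bounds", {
  pp <- revo_params(n_walkers = 30)
  set.seed(9)
  for (i in 1:20) {
    vals <- runif(30, 0.5, 1.6)
    w <- runif(30); w <- w / sum(w)
    rs <- resample_revo(vals, w, pp)
    expect_lt(abs(sum(rs$weights) - sum(w)), 1e-12)
    expect_true(all(rs$weights >= pp$pmin & rs$weights <= pp$pmax))
    expect_length(rs$weights, 30L)
    expect_length(rs$record$clones, nrow(rs$record$merges))
  }
  expect_error(resample_revo(c(0, 1), c(0.9, 0.3), pp), class = "fa_validation_error")
})

test_that("a long double-well run conserves probability at every cycle", {
  prop <- make_double_well_propagator(double_well_spec(barrier = 3))
  pp <- revo_params(n_walkers = 20, n_cycles = 200, steps_per_cycle = 10)
  res <- run_weighted_ensemble(prop, rep(1, 20), pp, seed = 5)
  expect_lt(max(abs(rowSums(res$post_weights) - 1)), 1e-12)
  expect_true(all(res$post_weights >= pp$pmin & res$post_weights <= pp$pmax))
})

test_that("runs are reproducible and n_cycles = 0 returns the initial ensemble", {
  prop <- make_double_well_propagator(double_well_spec())
  pp <- revo_params(n_walkers = 10, n_cycles = 30)
  r1 <- run_weighted_ensemble(prop, rep(-1, 10), pp, seed = 42)
  r2 <- run_weighted_ensemble(prop, rep(-1, 10), pp, seed = 42)
  expect_identical(r1$values, r2$values)
  expect_identical(r1$parent, r2$parent)
  pp0 <- revo_params(n_walkers = 10, n_cycles = 0)
  r0 <- run_weighted_ensemble(prop, seq(-1, 1, length.out = 10), pp0, seed = 1)
  expect_equal(r0$values[1, ], seq(-1, 1, length.out = 10))
  expect_equal(r0$final_weights, rep(0.1, 10))
})

test_that("every final walker traces back to an initial walker", {
  prop <- make_double_well_propagator(double_well_spec(barrier = 1))
  pp <- revo_params(n_walkers = 15, n_cycles = 40)
  res <- run_weighted_ensemble(prop, rep(0.5, 15), pp, seed = 3)
  for (wk in 1:15) {
    lin <- trace_lineage(res, wk)
    expect_equal(nrow(lin), 41L)
    expect_true(all(is.finite(lin$value)))
    expect_true(all(lin$weight > 0))
  }
  # a lineage is a contiguous path: consecutive values differ by one cycle
  # of diffusion, not by teleports between wells
  pp0 <- revo_params(n_walkers = 5, n_cycles = 0)
  r0 <- run_weighted_ensemble(prop, rep(0, 5), pp0, seed = 2)
  expect_equal(nrow(trace_lineage(r0, 1)), 1L)
  expect_error(trace_lineage(res, 99), class = "fa_validation_error")
})

test_that("both children of a clone trace to the cloned parent", {
  pp <- revo_params(n_walkers = 4, merge_dist = 10, char_dist = 0.1,
                    n_cycles = 1, steps_per_cycle = 0)
  still <- structure(function(x, n_steps) x, class = c("fa_propagator", "function"))
  res <- run_weighted_ensemble(still, c(0, 0, 0, 1), pp, seed = 1)
  rec <- res$records[[1]]
  skip_if(length(rec$clones) == 0)
  parent <- rec$clones[1]
  children <- which(res$parent[1, ] == parent)
  expect_gte(length(children), 2L)
  for (ch in children)
    expect_equal(trace_lineage(res, ch)$value[2], res$values[2, parent])
})

test_that("free-energy profiles are normalised, flat for uniform samples, and scale-invariant", {
  vals <- seq(0.05, 0.95, by = 0.1)
  fe <- free_energy_profile(vals, bins = seq(0, 1, by = 0.1))
  expect_equal(nrow(fe), 10L)
  expect_equal(sum(fe$p), 1, tolerance = 1e-12)
  expect_equal(diff(range(fe$F)), 0, tolerance = 1e-12)
  w <- runif(10) + 0.5
  f1 <- free_energy_profile(vals, w, bins = seq(0, 1, by = 0.1))
  f2 <- free_energy_profile(vals, 2 * w, bins = seq(0, 1, by = 0.1))
  expect_equal(f1$F, f2$F, tolerance = 1e-14)
  expect_error(free_energy_profile(vals, bins = seq(5, 6, by = 0.1), range = c(5, 6)),
               class = "fa_validation_error")
})

test_that("equilibrated harmonic-well walkers recover the Boltzmann profile", {
  k <- 4; kT <- 1
  prop <- make_langevin_propagator(function(x) k * x, diffusion = 1, dt = 1e-3,
                                   kT = kT)
  set.seed(17)
  init <- rnorm(50, 0, sqrt(kT / k))
  pp <- revo_params(n_walkers = 50, steps_per_cycle = 50, n_cycles = 600)
  res <- run_weighted_ensemble(prop, init, pp, seed = 18)
  fe <- free_energy_profile(res, bins = 30)
  # analytic reference: Gaussian bin masses renormalised over occupied bins
  pref <- stats::pnorm(fe$bin_upper, 0, sqrt(kT / k)) -
    stats::pnorm(fe$bin_lower, 0, sqrt(kT / k))
  pref <- pref / sum(pref)
  cum <- cumsum(fe$p)
  central <- cum >= 0.10 & (cum - fe$p) <= 0.90   # central 80% of the mass
  expect_lt(max(abs(fe$F[central] + log(pref[central]))), 0.3)
})

test_that("weighted-well occupancy agrees with long brute-force simulation", {
  # tilted double well: the WE weighted occupancy of the favoured well must
  # match a much longer plain simulation (and the Boltzmann value) within the
  # sampling allowance of 40 correlated walkers
  barrier <- 1.5; tilt <- 0.8
  grad <- function(x) 4 * barrier * x * (x^2 - 1) + tilt
  prop <- make_langevin_propagator(grad, diffusion = 1, dt = 2e-3)
  pp <- revo_params(n_walkers = 40, steps_per_cycle = 25, n_cycles = 1500)
  set.seed(23)
  res <- run_weighted_ensemble(prop, runif(40, -1.2, 1.2), pp, seed = 24)
  rows <- (floor(0.5 * pp$n_cycles) + 1):(pp$n_cycles) + 1
  v <- as.vector(res$values[rows, ]); w <- as.vector(res$weights[rows, ])
  p_left_we <- sum(w[v < 0]) / sum(w)
  set.seed(25)
  x <- prop(runif(2000, -1.2, 1.2), 20000)   # ~50x the per-walker WE time
  p_left_bf <- mean(x < 0)
  expect_lt(abs(p_left_we - p_left_bf), 0.05)
})
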