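# Synthetic-data generators: exactness of the zero-noise limits, seeded
# determinism, and the statistical structure each generator promises.

test_that("zero-noise panel equals the generating logistic exactly", {
  tru <- matrix(c(1e-6, NA), 1, 2, dimnames = list("A", c("E1", "E2")))
  spec <- panel_spec(tru, hill = 1, noise_sd = 0, n_replicates = 1)
  tbl <- gen_inhibition_panel(spec)
  e1 <- tbl[tbl$enzyme_id == "E1", ]
  expect_equal(e1$percent_inhibition,
               logistic4(log10(e1$concentration), 0, 100, 1, -6))
  # absent truth reads out at exactly 0%
  expect_identical(tbl$percent_inhibition[tbl$enzyme_id == "E2"], rep(0, 10))
})

test_that("panel generation is deterministic given the seed", {
  spec <- default_panel_spec(seed = 9)
  expect_identical(gen_inhibition_panel(spec), gen_inhibition_panel(spec))
  alt <- gen_inhibition_panel(default_panel_spec(seed = 10))
  expect_false(identical(gen_inhibition_panel(spec)$percent_inhibition,
                         alt$percent_inhibition))
})

test_that("panel spec validation names the offending field", {
  tru <- matrix(1e-6, 1, 1, dimnames = list("A", "E"))
  expect_error(panel_spec(tru, noise_sd = -1), "noise_sd", class = "fa_validation_error")
  expect_error(panel_spec(tru, concentrations = c(2e-6, 1e-6)), "concentrations",
               class = "fa_validation_error")
  expect_error(panel_spec(tru, n_replicates = 0), "n_replicates",
               class = "fa_validation_error")
})

test_that("default study panel has the screen's design and composition", {
  spec <- default_panel_spec(seed = 4)
  tbl <- gen_inhibition_panel(spec)
  expect_equal(dim(spec$true_ic50), c(58L, 7L))
  expect_equal(length(spec$concentrations), 10L)
  expect_equal(range(spec$concentrations), c(5e-9, 1e-4))
  expect_equal(nrow(tbl), 58 * 7 * 10 * 2)
  tru <- spec$true_ic50
  expect_equal(sum(is.na(tru)), 251L)
  expect_equal(sum(!is.na(tru) & tru <= 1e-4), 106L)
  expect_equal(sum(!is.na(tru) & tru > 1e-4), 49L)
})

test_that("collapse trajectory contracts for positive rates and not for zero", {
  # rate 0: mean OLS slope of the rgyr series over seeds is indistinguishable from 0
  slopes <- vapply(1:50, function(s) {
    tr <- gen_collapse_trajectory(collapse_traj_spec(collapse_rate = 0, n_frames = 60,
                                                     seed = s))
    rg <- radius_of_gyration(tr)
    unname(stats::coef(stats::lm(rgyr_nm ~ time_ns, rg))[2])
  }, numeric(1))
  ci <- stats::t.test(slopes)$conf.int
  expect_true(ci[1] < 0 && ci[2] > 0)
  # positive rate: every seed ends more compact than it starts
  for (s in 1:20) {
    rg <- radius_of_gyration(gen_collapse_trajectory(collapse_traj_spec(seed = s)))
    expect_lt(rg$rgyr_nm[nrow(rg)], rg$rgyr_nm[1])
  }
})

test_that("collapse trajectories stay finite and bounded, and a single rigid molecule keeps its internal rgyr", {
  spec <- collapse_traj_spec(seed = 3)
  tr <- gen_collapse_trajectory(spec)
  expect_true(all(is.finite(tr$coords)))
  expect_lt(max(abs(tr$coords)), 2 * sqrt(3) * spec$box_edge + spec$box_edge)
  expect_identical(gen_collapse_trajectory(spec)$coords, tr$coords)
  one <- gen_collapse_trajectory(collapse_traj_spec(n_molecules = 1, seed = 2))
  rg <- radius_of_gyration(one)$rgyr_nm
  expect_equal(rg, rep(rg[1], length(rg)), tolerance = 1e-12)
})

test_that("overcrowded placement fails with a placement error", {
  expect_error(gen_collapse_trajectory(
    collapse_traj_spec(n_molecules = 50, box_edge = 0.3, min_separation = 0.2)),
    class = "fa_placement_error")
})

test_that("ring fiber construction has the stated geometry", {
  fb <- gen_ring_fiber(fiber_spec(5, rise = 3.5, twist = 30))
  expect_length(fb$rings, 5L)
  cent <- t(vapply(fb$rings, function(r) colMeans(fb$coords[r$atom_idx, ]), numeric(3)))
  gaps <- sqrt(rowSums(diff(cent)^2))
  expect_equal(gaps, rep(3.5, 4), tolerance = 1e-10)
  # single unit: one ring, no contacts
  solo <- gen_ring_fiber(fiber_spec(1))
  expect_length(solo$rings, 1L)
  expect_equal(nrow(detect_stacking_contacts(solo)), 0L)
  # branch point adds rings and a degree-3 anchor
  br <- gen_ring_fiber(fiber_spec(5, branch_points = list(c(3, 2))))
  expect_length(br$rings, 7L)
  ct <- detect_stacking_contacts(br)
  deg3 <- sum(ct$ring_i == 3 | ct$ring_j == 3)
  expect_equal(deg3, 3L)
  # glycoside decoration does not change ring contacts
  gl <- gen_ring_fiber(fiber_spec(5, branch_points = list(c(3, 2)), with_glycoside = TRUE))
  expect_equal(nrow(detect_stacking_contacts(gl)), nrow(ct))
  expect_true(any(gl$atoms$group == "glycoside"))
})

test_that("double-well propagator has Brownian statistics at zero barrier", {
  spec <- double_well_spec(barrier = 0, diffusion = 0.8, dt = 2e-3, seed = 1)
  prop <- make_double_well_propagator(spec)
  n_steps <- 100
  set.seed(21)
  x <- prop(rep(0, 1e4), n_steps)
  expect_equal(stats::var(x), 2 * spec$diffusion * n_steps * spec$dt, tolerance = 0.05)
})

test_that("a 20 kT barrier prevents well crossings on short runs", {
  prop <- make_double_well_propagator(double_well_spec(barrier = 20, dt = 1e-3))
  set.seed(8)
  x <- prop(rep(1, 100), 1000)   # 100 independent walkers, started at +well
  expect_true(all(x > 0))
})

test_that("zero propagation steps leave the state untouched", {
  prop <- make_double_well_propagator(double_well_spec())
  expect_identical(prop(c(-1, 0.5, 2), 0), c(-1, 0.5, 2))
})

test_that("long brute-force double-well runs converge to the Boltzmann density", {
  spec <- double_well_spec(barrier = 2, dt = 2e-3, seed = 1)
  prop <- make_double_well_propagator(spec)
  edges <- seq(-2, 2, length.out = 41)
  mids <- (edges[-1] + edges[-41]) / 2
  ref <- exp(-double_well_potential(mids, spec) / spec$kT)
  ref <- ref / sum(ref)
  kl_for <- function(n_steps) {
    set.seed(30)
    x <- prop(stats::runif(1000, -1.5, 1.5), n_steps)
    h <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), 40)
    p <- (h + 0.5) / sum(h + 0.5)          # smoothed empirical
    sum(p * log(p / ref))
  }
  kls <- c(kl_for(50), kl_for(500), kl_for(5000))
  expect_lt(kls[3], kls[1])                 # KL shrinks with run length
  expect_lt(kls[3], 0.06)                   # near the finite-sample floor
})
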