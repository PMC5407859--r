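# Forward projection model and inverse height solvers.

test_that("full-length projection follows h * |sin tau|", {
  b <- toy_bundle()
  v90 <- image_view(100, "medial", parallel_angle_deg = 10)  # tau = 90
  expect_equal(render_projection("a1", b, v90, "full_length"), 2.4)
  v0 <- image_view(10, "medial", parallel_angle_deg = 10)    # tau = 0
  expect_equal(render_projection("a1", b, v0, "full_length"), 0)
  v30 <- image_view(40, "medial", parallel_angle_deg = 10)   # tau = 30
  expect_equal(render_projection("a1", b, v30, "full_length"), 1.2)
})

test_that("full-length projection is strictly increasing in tau and h", {
  taus <- seq(1, 89, by = 1)
  p <- 2.4 * abs(sin(deg(taus)))
  expect_true(all(diff(p) > 0))
  hs <- seq(0.3, 3, by = 0.1)
  expect_true(all(diff(hs * sin(deg(40))) > 0))
  # perpendicular limit: tau = 90 gives p = h exactly
  expect_identical(solve_height_known_parallel(0.5, 90), 0.5)
})

test_that("step projections need a row-1 reference", {
  b <- toy_bundle()
  b$stereocilia <- b$stereocilia[b$stereocilia$row != "1", ]
  v <- image_view(50, "medial", parallel_angle_deg = 10)
  expect_error(render_projection("a2", b, v, "step_1_to_2"), "row-1")
  expect_error(render_projection("a2", b, v, "step_1_to_2"), "toy")
})

test_that("two-view solving inverts the forward model in closed form", {
  sol <- solve_height_two_view(2.4 * sin(deg(10)), 2.4 * sin(deg(30)), 20)
  expect_equal(sol$height_um, 2.4, tolerance = 1e-12)
  expect_equal(sol$alpha_deg, 10, tolerance = 1e-12)
  # equal projections force alpha = 90 - tau/2
  sol2 <- solve_height_two_view(1, 1, 20)
  expect_equal(sol2$alpha_deg, 80, tolerance = 1e-12)
  expect_equal(sol2$height_um, 1 / sin(deg(80)), tolerance = 1e-12)
  expect_error(solve_height_two_view(0, 0, 20), "undetermined")
  # beam-parallel first view: alpha = 0
  sol3 <- solve_height_two_view(0, 2.4 * sin(deg(20)), 20)
  expect_equal(sol3$height_um, 2.4)
  expect_equal(sol3$alpha_deg, 0)
})

test_that("two-view and reference-angle methods agree", {
  set.seed(11)
  h <- runif(200, 0.3, 3)
  alpha <- runif(200, 1, 30)
  dtau <- runif(200, 5, 50)
  p1 <- h * sin(deg(alpha))
  p2 <- h * sin(deg(alpha + dtau))
  sol <- solve_height_two_view(p1, p2, dtau)
  expect_equal(sol$height_um, h, tolerance = 1e-9)
  expect_equal(sol$alpha_deg, alpha, tolerance = 1e-9)
  # one-view solution at the recovered alpha matches to 1e-9 relative
  h1v <- solve_height_known_parallel(p1, sol$alpha_deg)
  expect_equal(h1v, sol$height_um, tolerance = 1e-9)
})

test_that("reference-angle solving inverts the projection", {
  expect_equal(solve_height_known_parallel(1.2, 30), 2.4)
  expect_equal(solve_height_known_parallel(1.2, -30), 2.4)
  expect_error(solve_height_known_parallel(1.0, 0), "tau")
  expect_error(solve_height_known_parallel(1.0, 0.5), "tau")
  expect_error(solve_height_known_parallel(-0.1, 30), "non-negative")
})

test_that("parallel angle is recovered from a tilt series", {
  th <- c(-20, -10, 0, 10, 20)
  p <- 2.4 * abs(sin(deg(th - 5)))
  expect_equal(find_parallel_angle(th, p), 5, tolerance = 0.1)
  # exact zero projection wins immediately
  expect_equal(find_parallel_angle(c(-10, 5, 20), c(0.62, 0, 0.62)), 5)
  # strictly monotone series: minimum not bracketed
  th2 <- seq(0, 52, by = 13)
  expect_error(find_parallel_angle(th2, 2.4 * sin(deg(th2 + 10))),
               "extrapolat")
  expect_error(find_parallel_angle(c(0, 10), c(1, 2)), "3 distinct")
})

test_that("front-view step inversion recovers shorter-row heights", {
  # degenerate geometry: step projection equals true height difference
  expect_equal(
    solve_row_height_front_view(1.0, 90, h1_um = 2.4, d_um = 0,
                                alpha_deg = 0, row = 2),
    1.4
  )
  # round trip through the signed forward model
  s <- stereostair:::project_step(2.4, 1.4, "2", 0.4, 10, 40)
  expect_equal(
    solve_row_height_front_view(s, 40, h1_um = 2.4, d_um = 0.4,
                                alpha_deg = 10, row = 2),
    1.4, tolerance = 1e-12
  )
  # zero height difference round-trips to h1
  s0 <- stereostair:::project_step(2.4, 2.4, "2", 0.4, 10, 40)
  expect_equal(
    solve_row_height_front_view(s0, 40, 2.4, 0.4, 10, 2),
    2.4, tolerance = 1e-12
  )
  expect_error(solve_row_height_front_view(5, 40, 2.4, 0.4, 10, 2),
               "inconsistent")
  expect_error(solve_row_height_front_view(0.4, 0, 2.4, 0.4, 10, 2), "tau")
})

test_that("step inversion stays exact at small tau, where the signed
           convention matters", {
  for (tau in c(5, 12, 30, 60, 85)) {
    s <- stereostair:::project_step(2.4, 2.1, "3", 0.4, 10, tau)
    expect_equal(
      solve_row_height_front_view(s, tau, 2.4, 0.4, 10, 3),
      2.1, tolerance = 1e-9
    )
  }
})

test_that("noise-free bundle reconstruction is exact for any tau", {
  for (seed in 1:5) {
    b <- generate_bundle(bundle_spec(n_supernumerary_mean = 0), seed = seed)
    err <- recon_errors(b, noiseless(seed + 100))
    expect_lt(max(abs(err)), 1e-6)
    # two-view route (lateral parallel angles withheld) is also exact
    err2 <- recon_errors(b, noiseless(seed + 200),
                         lateral_parallel_known = FALSE)
    expect_lt(max(abs(err2)), 1e-6)
  }
})

test_that("reconstruction delegates and marks the solver used", {
  b <- toy_bundle()
  r <- render_experiment(b, noiseless(3), seed = 3)
  rec <- reconstruct_bundle(r$projections, bundle_info_of(b))
  expect_setequal(rec$method[rec$row == "1"], "reference_angle")
  expect_setequal(rec$method[rec$row != "1"], "step_front_view")
  # single full-length view with known parallel angle equals the
  # one-view solver output
  one <- r$projections[r$projections$stereocilium_id == "a1", ][1, ]
  h_direct <- solve_height_known_parallel(
    one$value_um, one$stage_tilt_deg - one$parallel_angle_deg)
  rec_one <- reconstruct_bundle(one, bundle_info_of(b))
  expect_equal(rec_one$height_um, h_direct)
})

test_that("a stereocilium with insufficient views is unresolved, not dropped", {
  b <- toy_bundle()
  r <- render_experiment(b, noiseless(4), seed = 4)
  p <- r$projections
  # keep only one lateral view of a1 and withhold its parallel angle
  p <- p[!(p$stereocilium_id == "a1" & p$stage_tilt_deg != 0), ]
  p$parallel_angle_deg[p$stereocilium_id == "a1"] <- NA
  rec <- reconstruct_bundle(p, bundle_info_of(b))
  a1 <- rec[rec$stereocilium_id == "a1", ]
  expect_false(a1$resolved)
  expect_true(is.na(a1$height_um))
  expect_true("a1" %in% rec$stereocilium_id)
})

test_that("image views validate the angle of view", {
  v <- image_view(30, "lateral", parallel_angle_deg = 10)
  expect_equal(v$tau_deg, 20)
  expect_error(image_view(120, "medial", parallel_angle_deg = 10), "90")
})
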