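# Synthetic bundle generator, treatment model, and renderer.

test_that("blocked fraction follows single-site saturation", {
  expect_equal(blocked_fraction(0, 10), 0)
  expect_equal(blocked_fraction(100, 100 / 3), 0.75)
  expect_equal(blocked_fraction(30, 10 / 3), 0.90)
  expect_error(blocked_fraction(10, 0), "positive")
  expect_error(blocked_fraction(-1, 10), "non-negative")
})

test_that("bundle generation is a pure function of spec and seed", {
  b1 <- generate_bundle(bundle_spec(), seed = 7)
  b2 <- generate_bundle(bundle_spec(), seed = 7)
  expect_identical(b1$stereocilia, b2$stereocilia)
  b3 <- generate_bundle(bundle_spec(), seed = 8)
  expect_false(identical(b1$stereocilia$height_um, b3$stereocilia$height_um))
})

test_that("degenerate variance collapses heights onto the row means", {
  spec <- bundle_spec(row_height_sds = c(0, 0, 0), n_supernumerary_mean = 0)
  b <- generate_bundle(spec, seed = 1)
  for (i in 1:3) {
    expect_true(all(b$stereocilia$height_um[b$stereocilia$row == as.character(i)] ==
                      spec$row_height_means[i]))
  }
})

test_that("generated heights match their population means (law of large
           numbers) and the staircase ordering holds on row means", {
  spec <- bundle_spec(n_per_row = c(10, 10000, 10), n_supernumerary_mean = 0)
  b <- generate_bundle(spec, seed = 99)
  h2 <- b$stereocilia$height_um[b$stereocilia$row == "2"]
  se <- 0.12 / sqrt(length(h2))
  expect_lt(abs(mean(h2) - 1.4), 3 * se)
  means <- tapply(b$stereocilia$height_um,
                  factor(b$stereocilia$row, levels = c("1", "2", "3")),
                  mean)
  expect_true(all(diff(means) < 0))
})

test_that("zero dose leaves the bundle untouched", {
  b <- generate_bundle(bundle_spec(), seed = 2)
  t0 <- treatment_spec("benzamil", dose_uM = 0)
  expect_identical(apply_treatment(b, t0, seed = 3), b)
})

test_that("row-1 stereocilia are bit-identical under any treatment", {
  b <- generate_bundle(bundle_spec(), seed = 4)
  for (drug in c("benzamil", "amiloride")) {
    tr <- apply_treatment(b, treatment_spec(drug), seed = 5)
    r1_before <- b$stereocilia[b$stereocilia$row == "1", ]
    r1_after <- tr$stereocilia[tr$stereocilia$row == "1", ]
    expect_identical(r1_before, r1_after)
    # tip-link presence unchanged on surviving stereocilia
    common <- intersect(b$stereocilia$id, tr$stereocilia$id)
    expect_identical(
      b$stereocilia$has_tip_link[match(common, b$stereocilia$id)],
      tr$stereocilia$has_tip_link[match(common, tr$stereocilia$id)]
    )
  }
})

test_that("degenerate retraction parameters halve affected heights exactly", {
  b <- generate_bundle(bundle_spec(n_supernumerary_mean = 0), seed = 6)
  tr <- treatment_spec("custom", dose_uM = 1e12, ic50_uM = 1e-6,
                       retract_prob_max = 1,
                       retract_fraction_range = c(0.5, 0.5),
                       prune_prob_max = 0)
  expect_equal(stereostair:::effect_fraction(tr), 1, tolerance = 1e-12)
  after <- apply_treatment(b, tr, seed = 7)
  sel <- b$stereocilia$row %in% c("2", "3")
  expect_equal(after$stereocilia$height_um[sel],
               b$stereocilia$height_um[sel] / 2, tolerance = 1e-9)
})

test_that("treatment cannot be aimed at row 1", {
  expect_error(treatment_spec(affects_rows = c("1", "2")), "never")
})

test_that("expected shortening is non-decreasing along the dose grid", {
  doses <- c(0, 5.5, 10, 30)  # benzamil grid
  exp_loss <- vapply(doses, function(d) {
    expected_shortening(treatment_spec("benzamil", dose_uM = d), 1.4)
  }, numeric(1))
  expect_true(all(diff(exp_loss) >= 0))
  expect_equal(exp_loss[1], 0)
  # simulated mean shortening is monotone too (seeded)
  sim_loss <- vapply(doses, function(d) {
    tr <- treatment_spec("benzamil", dose_uM = d)
    loss <- vapply(1:60, function(s) {
      b <- generate_bundle(bundle_spec(n_supernumerary_mean = 0), seed = s)
      a <- apply_treatment(b, tr, seed = s + 1000)
      sel <- b$stereocilia$row == "2"
      mean(b$stereocilia$height_um[sel] - a$stereocilia$height_um[sel])
    }, numeric(1))
    mean(loss)
  }, numeric(1))
  expect_true(all(diff(sim_loss) > -0.01))
})

test_that("realised row-2 shortening matches its analytic expectation", {
  tr <- treatment_spec("benzamil")
  spec <- bundle_spec(n_per_row = c(5, 1000, 5), n_supernumerary_mean = 0)
  b <- generate_bundle(spec, seed = 8)
  a <- apply_treatment(b, tr, seed = 9)
  sel <- b$stereocilia$row == "2"
  loss <- b$stereocilia$height_um[sel] - a$stereocilia$height_um[sel]
  expected <- expected_shortening(tr, 1.4)
  se <- sd(loss) / sqrt(length(loss))
  expect_lt(abs(mean(loss) - expected), 3 * se)
})

test_that("supernumerary pruning thins but never adds stereocilia", {
  b <- generate_bundle(bundle_spec(), seed = 10)
  a <- apply_treatment(b, treatment_spec("benzamil"), seed = 11)
  expect_lte(count_supernumerary(a), count_supernumerary(b))
  # ranked rows are never pruned
  expect_identical(sum(a$stereocilia$row %in% c("1", "2", "3")),
                   sum(b$stereocilia$row %in% c("1", "2", "3")))
})

test_that("noise-free rendering equals the forward model and renders are
           seed-deterministic", {
  b <- toy_bundle()
  r <- render_experiment(b, noiseless(12), seed = 12)
  lat <- r$projections[r$projections$kind == "full_length" &
                         r$projections$stage_tilt_deg == 0, ]
  expect_equal(lat$value_um, 2.4 * abs(sin(deg(-10))))
  r2 <- render_experiment(b, noise_spec(seed = 13))
  r3 <- render_experiment(b, noise_spec(seed = 13))
  expect_identical(r2, r3)
  r4 <- render_experiment(b, noise_spec(seed = 14))
  expect_false(identical(r2$projections$value_um, r4$projections$value_um))
})

test_that("multiplicative projection noise is unbiased", {
  n <- 1000
  st <- tibble::tibble(
    id = sprintf("s%04d", 1:n), row = "1", height_um = 2.4,
    shaft_diameter_um = 0.25, tip_length_um = 0.12, tip_gamma = 0.5,
    has_tip_link = FALSE, ref_id = NA_character_
  )
  b <- bundle("big", "OHC", insertion_tilt_deg = 10, row_spacing_um = 0.4,
              stereocilia = st)
  r <- render_experiment(b, noise_spec(projection_noise_cv = 0.05, seed = 15))
  p <- r$projections[r$projections$stage_tilt_deg == -20, ]
  truth <- 2.4 * abs(sin(deg(-30)))
  se <- sd(p$value_um) / sqrt(nrow(p))
  expect_lt(abs(mean(p$value_um) - truth), 3 * se)
})

test_that("cohorts separate generation and noise seed streams", {
  spec <- bundle_spec(n_per_row = c(3, 3, 3), n_supernumerary_mean = 0)
  c1 <- generate_cohort(spec, noise = noise_spec(seed = 100),
                        n_control = 2, n_treated = 2, seed = 50)
  c2 <- generate_cohort(spec, noise = noise_spec(seed = 101),
                        n_control = 2, n_treated = 2, seed = 50)
  expect_identical(c1$truth, c2$truth)
  expect_false(identical(c1$control$projections$value_um,
                         c2$control$projections$value_um))
  # empty cohort: no error, empty tables
  c0 <- generate_cohort(spec, n_control = 0, n_treated = 0, seed = 1)
  expect_equal(nrow(c0$truth), 0)
  expect_equal(nrow(c0$control$projections), 0)
})

test_that("cohort ground-truth row-2 deficit matches the treatment model", {
  spec <- bundle_spec(n_per_row = c(2, 50, 2), n_supernumerary_mean = 0)
  co <- generate_cohort(spec, treatment_spec("benzamil"),
                        noise = noise_spec(seed = 1), n_control = 20,
                        n_treated = 20, seed = 60)
  h2c <- co$truth$height_um[co$truth$row == "2" & co$truth$group == "control"]
  h2t <- co$truth$height_um[co$truth$row == "2" & co$truth$group == "treated"]
  expected <- expected_shortening(treatment_spec("benzamil"), 1.4)
  se <- sqrt(var(h2c) / length(h2c) + var(h2t) / length(h2t))
  expect_lt(abs((mean(h2c) - mean(h2t)) - expected), 3 * se)
})
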