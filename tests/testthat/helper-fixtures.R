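# Shared fixtures, built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

deg <- function(x) x * pi / 180

# A small deterministic bundle with known geometry for hand checks.
toy_bundle <- function(alpha = 10, d = 0.4) {
  bundle(
    id = "toy", cell_type = "OHC",
    insertion_tilt_deg = alpha, row_spacing_um = d,
    stereocilia = tibble::tibble(
      id = c("a1", "a2", "a3"),
      row = c("1", "2", "3"),
      height_um = c(2.4, 1.4, 0.7),
      shaft_diameter_um = c(0.25, 0.22, 0.18),
      tip_length_um = c(0.12, 0.25, 0.2),
      tip_gamma = c(0.5, 1, 1),
      has_tip_link = c(FALSE, TRUE, TRUE),
      ref_id = c(NA, "a1", "a1")
    )
  )
}

noiseless <- function(seed = 1) {
  noise_spec(projection_noise_cv = 0, diameter_noise_sd_um = 0, seed = seed)
}

bundle_info_of <- function(b) {
  tibble::tibble(bundle_id = b$id, row_spacing_um = b$row_spacing_um,
                 insertion_tilt_deg = b$insertion_tilt_deg)
}

# Reconstruction error of every ranked stereocilium of a bundle after a
# noise-free (or noisy) render.
recon_errors <- function(b, noise = noiseless(), ...) {
  r <- render_experiment(b, noise, seed = noise$seed %||% 1, ...)
  rec <- reconstruct_bundle(r$projections, bundle_info_of(b))
  truth <- b$stereocilia[, c("id", "height_um")]
  m <- merge(rec, truth, by.x = "stereocilium_id", by.y = "id",
             suffixes = c("_hat", "_true"))
  m$height_um_hat - m$height_um_true
}

# One control-vs-benzamil cohort at the headline scale (~100
# stereocilia per row per group); returns Welch p values per row on
# reconstructed heights.
headline_cohort_pvalues <- function(seed) {
  co <- generate_cohort(
    spec = bundle_spec(n_per_row = c(10, 10, 10), n_supernumerary_mean = 0),
    treatment = treatment_spec("benzamil"),
    noise = noise_spec(projection_noise_cv = 0.05),
    n_control = 10, n_treated = 10, seed = seed
  )
  info <- dplyr::bind_rows(co$control$bundle_info, co$treated$bundle_info)
  rec <- dplyr::bind_rows(
    reconstruct_bundle(co$control$projections, info) |>
      dplyr::mutate(group = "control"),
    reconstruct_bundle(co$treated$projections, info) |>
      dplyr::mutate(group = "treated")
  )
  vapply(c("1", "2", "3"), function(r) {
    sub <- rec[rec$row == r & rec$resolved, ]
    welch_t(sub$height_um[sub$group == "control"],
            sub$height_um[sub$group == "treated"])$p_value
  }, numeric(1))
}

# Textbook-formula oracles, independent of the stats module's path
# through stats::t.test.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_student <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
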