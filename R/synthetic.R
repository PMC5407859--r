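# Synthetic hair-bundle generator, dose-dependent treatment-effect
# model, and forward projection renderer. The generator's defaults
# define the study conditions the analysis is validated under: OHC
# staircases of three ranked rows plus supernumerary stereocilia,
# imaged from two lateral views and one medial (front) view.

#' Fraction of MET current blocked at a given dose
#'
#' Single-site saturation model with Hill coefficient 1:
#' `blocked = dose / (dose + ic50)`. The default IC50s used elsewhere
#' in the package are back-solved from the ~75% block at 100 uM
#' amiloride (IC50 100/3 uM) and ~90% block at 30 uM benzamil
#' (IC50 10/3 uM).
#'
#' @param dose_uM Blocker concentration, uM (>= 0).
#' @param ic50_uM Half-blocking concentration, uM (> 0).
#' @return Blocked fraction in `[0, 1)` (vectorised).
#' @export
#' @examples
#' blocked_fraction(30, 10 / 3)
blocked_fraction <- function(dose_uM, ic50_uM) {
  if (any(ic50_uM <= 0)) stop("ic50_uM must be positive")
  if (any(dose_uM < 0)) stop("dose_uM must be non-negative")
  dose_uM / (dose_uM + ic50_uM)
}

DEFAULT_IC50 <- c(amiloride = 100 / 3, benzamil = 10 / 3)

#' Specification of a synthetic bundle population
#'
#' Defaults describe a mid-cochlear outer hair cell (OHC) bundle at
#' the ages studied: three ranked rows with staircase height means
#' 2.4 / 1.4 / 0.7 um (an internal fixture choice; recovery is always
#' scored against generated ground truth, never against these
#' defaults), shared insertion tilt 10 degrees, inter-row base spacing
#' 0.4 um, and a Poisson number of supernumerary stereocilia with the
#' observed control mean (10.9 per OHC; use 25.1 for IHC). `"IHC"`
#' presets differ by taller, thicker stereocilia and more
#' supernumeraries.
#'
#' @param cell_type `"OHC"` or `"IHC"`.
#' @param n_per_row Integer counts of stereocilia in rows 1-3.
#' @param n_supernumerary_mean Poisson mean of rank >= 4 / unranked
#'   stereocilia per bundle.
#' @param row_height_means,row_height_sds Per-row height normal
#'   parameters, um (truncated at > 0); means must be strictly
#'   decreasing with rank.
#' @param insertion_tilt_deg,row_spacing_um Shared bundle geometry.
#' @param shaft_diameters_um Per-row mid-shaft diameters, um.
#' @param tip_length_um,tip_gamma Per-row tip-profile defaults
#'   (rows 1-3; row 1 blunt, rows 2-3 conical wedges).
#' @param supernumerary_height_mean,supernumerary_height_sd Height
#'   normal parameters of supernumerary stereocilia, um.
#' @param tip_link_prob Probability that a row-2/3 stereocilium bears
#'   a tip link.
#' @return A list of class `"bundle_spec"`.
#' @export
bundle_spec <- function(cell_type = c("OHC", "IHC"),
                        n_per_row = c(10, 10, 10),
                        n_supernumerary_mean = NULL,
                        row_height_means = NULL,
                        row_height_sds = NULL,
                        insertion_tilt_deg = 10,
                        row_spacing_um = 0.4,
                        shaft_diameters_um = NULL,
                        tip_length_um = c(0.12, 0.25, 0.2),
                        tip_gamma = c(0.5, 1, 1),
                        supernumerary_height_mean = 0.35,
                        supernumerary_height_sd = 0.1,
                        tip_link_prob = 0.9) {
  cell_type <- match.arg(cell_type)
  ihc <- cell_type == "IHC"
  n_supernumerary_mean <- n_supernumerary_mean %||% if (ihc) 25.1 else 10.9
  row_height_means <- row_height_means %||%
    if (ihc) c(3.2, 1.6, 0.8) else c(2.4, 1.4, 0.7)
  row_height_sds <- row_height_sds %||% c(0.15, 0.12, 0.08)
  shaft_diameters_um <- shaft_diameters_um %||%
    if (ihc) c(0.4, 0.35, 0.3) else c(0.25, 0.22, 0.18)
  stopifnot(
    length(n_per_row) == 3, all(n_per_row >= 0),
    length(row_height_means) == 3, all(diff(row_height_means) < 0),
    length(row_height_sds) == 3, all(row_height_sds >= 0),
    n_supernumerary_mean >= 0,
    insertion_tilt_deg >= 0, insertion_tilt_deg < 90, row_spacing_um >= 0,
    length(shaft_diameters_um) == 3, all(shaft_diameters_um > 0),
    length(tip_length_um) == 3, all(tip_length_um >= 0),
    length(tip_gamma) == 3, all(tip_gamma > 0),
    tip_link_prob >= 0, tip_link_prob <= 1
  )
  structure(
    list(cell_type = cell_type, n_per_row = as.integer(n_per_row),
         n_supernumerary_mean = n_supernumerary_mean,
         row_height_means = row_height_means,
         row_height_sds = row_height_sds,
         insertion_tilt_deg = insertion_tilt_deg,
         row_spacing_um = row_spacing_um,
         shaft_diameters_um = shaft_diameters_um,
         tip_length_um = tip_length_um, tip_gamma = tip_gamma,
         supernumerary_height_mean = supernumerary_height_mean,
         supernumerary_height_sd = supernumerary_height_sd,
         tip_link_prob = tip_link_prob),
    class = "bundle_spec"
  )
}

#' Specification of a MET-blocker treatment model
#'
#' The realised effect scales with `f = blocked_fraction(dose, ic50) *
#' duration_scale * effect_scale`. Each affected stereocilium either
#' undergoes deep retraction (probability `retract_prob_max * f`;
#' height multiplied by `1 - U(lo, hi)`) or graded shortening (loss
#' drawn from `N(shorten_mean_max * f, (shorten_sd_max *
#' variance_inflation * f)^2)` truncated at loss >= 0); its tip shape
#' exponent gamma increases by `taper_gamma_shift_max * f`. Row-1
#' stereocilia are never affected; tip-link presence is unchanged.
#' Supernumerary stereocilia are additionally pruned by binomial
#' thinning with probability `prune_prob_max * f`.
#'
#' @param drug Drug name; `"amiloride"` and `"benzamil"` fill in
#'   default IC50s and, for amiloride, a larger height-variance
#'   inflation.
#' @param dose_uM Applied concentration, uM.
#' @param ic50_uM Half-blocking concentration, uM.
#' @param retract_prob_max Probability of deep retraction at full
#'   block.
#' @param retract_fraction_range `(lo, hi)` fraction of height lost in
#'   deep retraction.
#' @param shorten_mean_max_um,shorten_sd_max_um Graded shortening
#'   parameters at full block, um.
#' @param taper_gamma_shift_max Additive gamma increase at full block.
#' @param variance_inflation Multiplier on the shortening SD.
#' @param duration_scale Fraction of the full effect realised (models
#'   shorter incubations; 5 hr ~ 0.35 of the 24 hr effect).
#' @param effect_scale Overall magnitude scale (use ~0.5 for IHC,
#'   whose shortening is smaller than OHC).
#' @param prune_prob_max Supernumerary thinning probability at full
#'   block.
#' @param affects_rows Rows subject to the effect; row 1 is never
#'   allowed.
#' @return A list of class `"treatment_spec"`.
#' @export
treatment_spec <- function(drug = "benzamil",
                           dose_uM = if (drug == "amiloride") 100 else 30,
                           ic50_uM = NULL,
                           retract_prob_max = 0.2,
                           retract_fraction_range = c(0.5, 0.9),
                           shorten_mean_max_um = 0.4,
                           shorten_sd_max_um = 0.15,
                           taper_gamma_shift_max = 1,
                           variance_inflation =
                             if (drug == "amiloride") 1.8 else 1,
                           duration_scale = 1,
                           effect_scale = 1,
                           prune_prob_max = 0.4,
                           affects_rows = c("2", "3", "supernumerary")) {
  ic50_uM <- ic50_uM %||% unname(DEFAULT_IC50[drug])
  if (is.null(ic50_uM) || is.na(ic50_uM)) {
    stop("no default IC50 for drug '", drug, "'; supply ic50_uM")
  }
  affects_rows <- as.character(affects_rows)
  if ("1" %in% affects_rows) {
    stop("row 1 (tallest, non-transducing) can never be in affects_rows")
  }
  ok_rows <- c("2", "3", "supernumerary")
  if (any(!affects_rows %in% ok_rows)) {
    stop("affects_rows must be drawn from: ", paste(ok_rows, collapse = ", "))
  }
  stopifnot(
    dose_uM >= 0, ic50_uM > 0,
    retract_prob_max >= 0, retract_prob_max <= 1,
    length(retract_fraction_range) == 2,
    retract_fraction_range[1] <= retract_fraction_range[2],
    all(retract_fraction_range >= 0), all(retract_fraction_range <= 1),
    shorten_mean_max_um >= 0, shorten_sd_max_um >= 0,
    variance_inflation > 0, duration_scale >= 0, duration_scale <= 1,
    effect_scale >= 0, effect_scale <= 1,
    prune_prob_max >= 0, prune_prob_max <= 1
  )
  structure(
    list(drug = drug, dose_uM = dose_uM, ic50_uM = ic50_uM,
         retract_prob_max = retract_prob_max,
         retract_fraction_range = retract_fraction_range,
         shorten_mean_max_um = shorten_mean_max_um,
         shorten_sd_max_um = shorten_sd_max_um,
         taper_gamma_shift_max = taper_gamma_shift_max,
         variance_inflation = variance_inflation,
         duration_scale = duration_scale,
         effect_scale = effect_scale,
         prune_prob_max = prune_prob_max,
         affects_rows = affects_rows),
    class = "treatment_spec"
  )
}

#' Measurement-noise specification
#'
#' @param projection_noise_cv Coefficient of variation of the
#'   multiplicative Gaussian noise applied to every projection.
#' @param diameter_noise_sd_um Additive Gaussian SD on diameter
#'   measurements, um.
#' @param seed Integer seed for the measurement-noise stream (kept
#'   separate from the bundle-generation stream).
#' @return A list of class `"noise_spec"`.
#' @export
noise_spec <- function(projection_noise_cv = 0.05,
                       diameter_noise_sd_um = 0.01,
                       seed = NULL) {
  stopifnot(projection_noise_cv >= 0, diameter_noise_sd_um >= 0)
  structure(list(projection_noise_cv = projection_noise_cv,
                 diameter_noise_sd_um = diameter_noise_sd_um,
                 seed = seed),
            class = "noise_spec")
}

# Truncated normal (> lower), by rejection; means are far from the
# truncation point in all default regimes so rejection is cheap.
rtruncnorm_pos <- function(n, mean, sd, lower = 0) {
  if (n == 0) return(numeric(0))
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  x <- rnorm(n, mean, sd)
  for (iter in 1:1000) {
    bad <- which(x <= lower)
    if (length(bad) == 0) return(x)
    x[bad] <- rnorm(length(bad), mean[bad], sd[bad])
  }
  stop("truncated-normal rejection sampling failed to converge")
}

#' Generate one synthetic bundle
#'
#' Heights are drawn per row from normals truncated at > 0, the
#' supernumerary count from a Poisson, and tip links as Bernoulli
#' trials on rows 2-3. Each row-2/3 stereocilium is paired (cyclically
#' by index) with a row-1 partner that serves as the reference for
#' step projections and as its tip-link target. Output is a pure
#' function of `(spec, seed)`.
#'
#' @param spec A [bundle_spec()].
#' @param seed Integer seed.
#' @param id Bundle identifier.
#' @return A [bundle()] object.
#' @export
generate_bundle <- function(spec, seed, id = "b1") {
  stopifnot(inherits(spec, "bundle_spec"))
  withr::with_seed(seed, {
    n <- spec$n_per_row
    ids <- character(0); rows <- character(0); heights <- numeric(0)
    shaft <- numeric(0); tipL <- numeric(0); tipG <- numeric(0)
    refs <- character(0)
    row1_ids <- sprintf("r1_%02d", seq_len(n[1]))
    for (i in 1:3) {
      if (n[i] == 0) next
      rid <- sprintf("r%d_%02d", i, seq_len(n[i]))
      ids <- c(ids, rid)
      rows <- c(rows, rep(as.character(i), n[i]))
      heights <- c(heights, rtruncnorm_pos(n[i], spec$row_height_means[i],
                                           spec$row_height_sds[i]))
      shaft <- c(shaft, rep(spec$shaft_diameters_um[i], n[i]))
      tipL <- c(tipL, rep(spec$tip_length_um[i], n[i]))
      tipG <- c(tipG, rep(spec$tip_gamma[i], n[i]))
      refs <- c(refs, if (i == 1 || n[1] == 0) rep(NA_character_, n[i]) else {
        row1_ids[(seq_len(n[i]) - 1) %% n[1] + 1]
      })
    }
    n_sn <- rpois(1, spec$n_supernumerary_mean)
    if (n_sn > 0) {
      sn_rows <- sample(c("4", "5", "unranked"), n_sn, replace = TRUE,
                        prob = c(0.4, 0.3, 0.3))
      ids <- c(ids, sprintf("sn_%02d", seq_len(n_sn)))
      rows <- c(rows, sn_rows)
      heights <- c(heights, rtruncnorm_pos(n_sn,
                                           spec$supernumerary_height_mean,
                                           spec$supernumerary_height_sd,
                                           lower = 0.02))
      shaft <- c(shaft, rep(0.6 * spec$shaft_diameters_um[3], n_sn))
      tipL <- c(tipL, rep(0.05, n_sn))
      tipG <- c(tipG, rep(0.5, n_sn))
      refs <- c(refs, rep(NA_character_, n_sn))
    }
    link <- rep(FALSE, length(ids))
    shorter <- rows %in% c("2", "3")
    link[shorter] <- runif(sum(shorter)) < spec$tip_link_prob
    st <- tibble(id = ids, row = rows, height_um = heights,
                 shaft_diameter_um = shaft, tip_length_um = tipL,
                 tip_gamma = tipG, has_tip_link = link, ref_id = refs)
    bundle(id = id, cell_type = spec$cell_type,
           insertion_tilt_deg = spec$insertion_tilt_deg,
           row_spacing_um = spec$row_spacing_um, stereocilia = st)
  })
}

# Realised effect fraction of a treatment.
effect_fraction <- function(treatment) {
  blocked_fraction(treatment$dose_uM, treatment$ic50_uM) *
    treatment$duration_scale * treatment$effect_scale
}

#' Expected height loss of an affected stereocilium under a treatment
#'
#' Analytic expectation of the two-component shortening mixture: with
#' probability `retract_prob_max * f` a deep retraction losing
#' `height * U(lo, hi)`, otherwise graded shortening with a normal
#' loss truncated at >= 0. Ignores the cap of the loss at the full
#' height, which is negligible in the default regimes.
#'
#' @param treatment A [treatment_spec()].
#' @param height_um Pre-treatment height, um.
#' @return Expected loss, um (vectorised over `height_um`).
#' @export
expected_shortening <- function(treatment, height_um) {
  f <- effect_fraction(treatment)
  p_deep <- min(1, treatment$retract_prob_max * f)
  mu <- treatment$shorten_mean_max_um * f
  sigma <- treatment$shorten_sd_max_um * treatment$variance_inflation * f
  graded <- if (sigma == 0) max(mu, 0) else {
    z <- mu / sigma
    mu + sigma * dnorm(z) / pnorm(z)
  }
  deep <- height_um * mean(treatment$retract_fraction_range)
  p_deep * deep + (1 - p_deep) * graded
}

#' Apply a treatment model to a bundle
#'
#' Shortens and re-shapes the affected rows according to the
#' treatment's dose-dependent mixture model and thins the
#' supernumerary set. Row-1 stereocilia are bit-identical before and
#' after; tip-link presence is unchanged on surviving stereocilia.
#'
#' @param bundle A [bundle()] object.
#' @param treatment A [treatment_spec()].
#' @param seed Integer seed.
#' @return A modified [bundle()] object.
#' @export
apply_treatment <- function(bundle, treatment, seed) {
  stopifnot(inherits(bundle, "bundle"), inherits(treatment, "treatment_spec"))
  f <- effect_fraction(treatment)
  if (f == 0) return(bundle)
  withr::with_seed(seed, {
    st <- bundle$stereocilia
    affected <- st$row %in% setdiff(treatment$affects_rows, "supernumerary")
    if ("supernumerary" %in% treatment$affects_rows) {
      affected <- affected | is_supernumerary(st$row)
    }
    idx <- which(affected)
    if (length(idx) > 0) {
      deep <- runif(length(idx)) < treatment$retract_prob_max * f
      h <- st$height_um[idx]
      lo <- treatment$retract_fraction_range[1]
      hi <- treatment$retract_fraction_range[2]
      h[deep] <- h[deep] * (1 - runif(sum(deep), lo, hi))
      n_grad <- sum(!deep)
      if (n_grad > 0) {
        mu <- treatment$shorten_mean_max_um * f
        sigma <- treatment$shorten_sd_max_um * treatment$variance_inflation * f
        loss <- if (sigma == 0) rep(max(mu, 0), n_grad) else {
          rtruncnorm_pos(n_grad, mu, sigma, lower = 0)
        }
        h[!deep] <- h[!deep] - loss
      }
      st$height_um[idx] <- pmax(h, 0.02)  # a fully resorbed core is not modelled
      st$tip_gamma[idx] <- st$tip_gamma[idx] + treatment$taper_gamma_shift_max * f
    }
    if ("supernumerary" %in% treatment$affects_rows) {
      sn <- which(is_supernumerary(st$row))
      if (length(sn) > 0) {
        pruned <- sn[runif(length(sn)) < treatment$prune_prob_max * f]
        if (length(pruned) > 0) st <- st[-pruned, , drop = FALSE]
      }
    }
    bundle$stereocilia <- st
    bundle
  })
}

# Default acquisition geometry for one bundle: two lateral views (one
# looking along the surface normal, one 20 degrees further from
# parallel) and one medial view 40 degrees past parallel for step
# projections. In the package's stage frame the parallel angle equals
# the insertion tilt.
default_views <- function(alpha_deg, lateral_parallel_known = TRUE) {
  lat_parallel <- if (lateral_parallel_known) alpha_deg else NA_real_
  tibble(
    view_id = c("L1", "L2", "M1"),
    side = c("lateral", "lateral", "medial"),
    stage_tilt_deg = c(0, -20, alpha_deg + 40),
    parallel_angle_deg = c(lat_parallel, lat_parallel, alpha_deg)
  )
}

#' Render noisy SEM measurements for a set of bundles
#'
#' Runs every stereocilium and view through the forward projection
#' model and perturbs projections with multiplicative Gaussian noise
#' (diameter measurements with additive noise). Row-1 stereocilia get
#' full-length projections in both lateral views; rows 2-3 get a
#' signed step projection against their row-1 partner in the medial
#' view. Deterministic given the noise seed.
#'
#' @param bundles A [bundle()] or list of bundles.
#' @param noise A [noise_spec()]; its `seed` (or the `seed` argument)
#'   drives the noise stream.
#' @param seed Seed used when `noise$seed` is `NULL`.
#' @param lateral_parallel_known Record the parallel angle on lateral
#'   views? Set `FALSE` to force reconstruction through the two-view
#'   solver.
#' @param diameter_positions_um Axial positions for diameter
#'   measurements (default: 0.025/0.05/0.1/0.2 um plus the shaft).
#' @return List with tibbles `projections` (columns `bundle_id`,
#'   `cell_type`, `stereocilium_id`, `ref_stereocilium_id`, `row`,
#'   `kind`, `side`, `stage_tilt_deg`, `parallel_angle_deg`,
#'   `value_um`) and `diameters`.
#' @export
render_experiment <- function(bundles, noise = noise_spec(), seed = NULL,
                              lateral_parallel_known = TRUE,
                              diameter_positions_um =
                                c(DEFAULT_DIAMETER_POSITIONS,
                                  shaft_position())) {
  if (inherits(bundles, "bundle")) bundles <- list(bundles)
  stopifnot(all(vapply(bundles, inherits, logical(1), "bundle")))
  seed <- noise$seed %||% seed
  if (is.null(seed)) stop("a noise seed is required (noise$seed or seed)")

  one_bundle <- function(b) {
    v <- default_views(b$insertion_tilt_deg, lateral_parallel_known)
    st <- b$stereocilia
    row1 <- st[st$row == "1", , drop = FALSE]
    proj <- list()
    if (nrow(row1) > 0) {
      for (k in which(v$side == "lateral")) {
        tau <- v$stage_tilt_deg[k] - b$insertion_tilt_deg
        proj[[length(proj) + 1]] <- tibble(
          stereocilium_id = row1$id, ref_stereocilium_id = NA_character_,
          row = row1$row, kind = "full_length", side = v$side[k],
          stage_tilt_deg = v$stage_tilt_deg[k],
          parallel_angle_deg = v$parallel_angle_deg[k],
          value_um = project_full_length(row1$height_um, tau)
        )
      }
    }
    shorter <- st[st$row %in% c("2", "3") & !is.na(st$ref_id), , drop = FALSE]
    if (nrow(shorter) > 0 && nrow(row1) > 0) {
      k <- which(v$side == "medial")[1]
      tau <- v$stage_tilt_deg[k] - b$insertion_tilt_deg
      h1 <- row1$height_um[match(shorter$ref_id, row1$id)]
      proj[[length(proj) + 1]] <- tibble(
        stereocilium_id = shorter$id, ref_stereocilium_id = shorter$ref_id,
        row = shorter$row,
        kind = ifelse(shorter$row == "2", "step_1_to_2", "step_1_to_3"),
        side = v$side[k], stage_tilt_deg = v$stage_tilt_deg[k],
        parallel_angle_deg = v$parallel_angle_deg[k],
        value_um = project_step(h1, shorter$height_um, shorter$row,
                                b$row_spacing_um, b$insertion_tilt_deg, tau)
      )
    }
    p <- bind_rows(proj)
    if (nrow(p) > 0) {
      p <- p %>% mutate(bundle_id = b$id, cell_type = b$cell_type,
                        .before = 1)
    }
    ranked <- st[st$row %in% c("1", "2", "3"), , drop = FALSE]
    d <- bind_rows(lapply(seq_len(nrow(ranked)), function(i) {
      prof <- diameter_profile(ranked$tip_length_um[i], ranked$tip_gamma[i],
                               ranked$shaft_diameter_um[i],
                               diameter_positions_um)
      tibble(bundle_id = b$id, cell_type = b$cell_type,
             stereocilium_id = ranked$id[i], row = ranked$row[i],
             position_um = prof$position_um, value_um = prof$diameter_um)
    }))
    list(projections = p, diameters = d)
  }

  parts <- lapply(bundles, one_bundle)
  projections <- bind_rows(lapply(parts, `[[`, "projections"))
  diameters <- bind_rows(lapply(parts, `[[`, "diameters"))
  withr::with_seed(seed, {
    if (nrow(projections) > 0 && noise$projection_noise_cv > 0) {
      projections$value_um <- projections$value_um *
        (1 + rnorm(nrow(projections), 0, noise$projection_noise_cv))
      # noise cannot flip the sign of a physical length
      full <- projections$kind == "full_length"
      projections$value_um[full] <- pmax(projections$value_um[full], 0)
    }
    if (nrow(diameters) > 0 && noise$diameter_noise_sd_um > 0) {
      diameters$value_um <- pmax(
        diameters$value_um + rnorm(nrow(diameters), 0,
                                   noise$diameter_noise_sd_um), 0.001)
    }
  })
  list(projections = projections, diameters = diameters)
}

# Link annotations for a bundle: every tip link becomes a top-cap,
# axis-positive, upward link to the row-1/row-2 partner; a fraction of
# unlinked shorter stereocilia get a distractor lateral link so the
# classifier's exclusion rules are exercised end to end.
render_links <- function(bundles, seed, distractor_prob = 0.3) {
  if (inherits(bundles, "bundle")) bundles <- list(bundles)
  withr::with_seed(seed, {
    bind_rows(lapply(bundles, function(b) {
      st <- b$stereocilia
      shorter <- st[st$row %in% c("2", "3"), , drop = FALSE]
      if (nrow(shorter) == 0) return(NULL)
      out <- list()
      linked <- shorter[shorter$has_tip_link, , drop = FALSE]
      if (nrow(linked) > 0) {
        out[[1]] <- tibble(
          bundle_id = b$id,
          origin_stereocilium_id = linked$id,
          target_stereocilium_id = linked$ref_id,
          origin_region = "top_cap",
          origin_row = linked$row,
          target_row = "1",
          axis_sign = 1, elevation_sign = 1
        )
      }
      unlinked <- shorter[!shorter$has_tip_link, , drop = FALSE]
      if (nrow(unlinked) > 0) {
        keep <- runif(nrow(unlinked)) < distractor_prob
        if (any(keep)) {
          u <- unlinked[keep, , drop = FALSE]
          out[[2]] <- tibble(
            bundle_id = b$id,
            origin_stereocilium_id = u$id,
            target_stereocilium_id = u$id,  # lateral neighbour, same row
            origin_region = "tip_hemisphere_other",
            origin_row = u$row,
            target_row = u$row,
            axis_sign = 0, elevation_sign = 0
          )
        }
      }
      bind_rows(out)
    }))
  })
}

#' Generate a matched control/treated cohort
#'
#' Mirrors the paired experimental design: control and treated bundles
#' drawn from the same population spec and processed in parallel, with
#' the hidden ground truth kept for recovery scoring. The
#' bundle-generation and measurement-noise seed streams are separate,
#' so changing only the noise seed changes measurements but not ground
#' truth.
#'
#' @param spec A [bundle_spec()].
#' @param treatment A [treatment_spec()] applied to the treated arm.
#' @param noise A [noise_spec()].
#' @param n_control,n_treated Bundles per arm.
#' @param seed Master seed for bundle generation; the noise stream
#'   uses `noise$seed` or a fixed offset of `seed`.
#' @return List with elements `control` and `treated` (each a list of
#'   `projections`, `diameters`, `links`, `bundle_info`) and `truth`
#'   (tidy ground-truth stereocilia table across both arms, with a
#'   `group` column).
#' @export
generate_cohort <- function(spec = bundle_spec(),
                            treatment = treatment_spec(),
                            noise = noise_spec(),
                            n_control = 10, n_treated = 10, seed = 1) {
  seeds <- withr::with_seed(seed, sample.int(2^31 - 10,
                                             2 * (n_control + n_treated) + 3))
  noise_seed <- noise$seed %||% seeds[length(seeds)]
  noise_seed <- noise_seed %% (2^31 - 10)  # room for small offsets
  make_arm <- function(n, group, seed_offset, treat) {
    bundles <- lapply(seq_len(n), function(i) {
      b <- generate_bundle(spec, seeds[seed_offset + i],
                           id = sprintf("%s_%02d", group, i))
      if (!is.null(treat)) {
        b <- apply_treatment(b, treat,
                             seeds[seed_offset + n_control + n_treated + i])
      }
      b
    })
    bundles
  }
  control <- make_arm(n_control, "ctl", 0, NULL)
  treated <- make_arm(n_treated, "trt", n_control, treatment)

  pack_arm <- function(bundles, group, arm_noise_seed) {
    if (length(bundles) == 0) {
      return(list(
        projections = tibble(), diameters = tibble(), links = tibble(),
        bundle_info = tibble(bundle_id = character(),
                             cell_type = character(), group = character(),
                             insertion_tilt_deg = numeric(),
                             row_spacing_um = numeric(),
                             n_supernumerary = integer())
      ))
    }
    rendered <- render_experiment(bundles, noise, seed = arm_noise_seed)
    info <- tibble(
      bundle_id = vapply(bundles, `[[`, character(1), "id"),
      cell_type = vapply(bundles, `[[`, character(1), "cell_type"),
      group = group,
      insertion_tilt_deg = vapply(bundles, `[[`, numeric(1),
                                  "insertion_tilt_deg"),
      row_spacing_um = vapply(bundles, `[[`, numeric(1), "row_spacing_um"),
      n_supernumerary = vapply(bundles, count_supernumerary, numeric(1))
    )
    links <- render_links(bundles, seed = arm_noise_seed + 1)
    c(rendered, list(links = links, bundle_info = info))
  }

  truth <- bind_rows(
    if (length(control) > 0) {
      bundles_to_table(control) %>% mutate(group = "control")
    },
    if (length(treated) > 0) {
      bundles_to_table(treated) %>% mutate(group = "treated")
    }
  )
  list(
    control = pack_arm(control, "control", noise_seed),
    treated = pack_arm(treated, "treated", noise_seed + 2),
    truth = truth
  )
}
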