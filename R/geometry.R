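# Forward projection model and inverse height solvers.
#
# Forward model (normative for the whole package): stereocilium axis
# u = (sin a, 0, cos a), beam b = (sin(a+tau), 0, cos(a+tau)), row-i
# base at (-(i-1)*d, 0, 0), tip_i = base_i + h_i*u. The image-plane
# projection of a vector v is P(v) = v - (v.b)b, |P(u)| = |sin tau|.
# A full-length projection is p = h*|sin tau|. A step projection is
# the SIGNED component of tip_1 - tip_i along the projected
# stereocilia axis (positive when the row-1 tip projects beyond the
# shorter tip); algebra on the model gives
#   s = (h1 - h_i)*sin(tau) - (i-1)*d*cos(a + tau).
# Signed steps keep the front-view inverse well posed at small tau,
# where the magnitude convention is ambiguous.

# Minimum usable |angle of view|, degrees. Below this the inverse
# error amplification (~ 1/sin tau) makes measurements unusable.
TAU_MIN_DEG <- 1

#' Construct an SEM image view
#'
#' A view is one SEM acquisition geometry: the stage tilt, the side of
#' the bundle it faces, and the stage tilt at which stereocilia are
#' parallel to the beam (the "parallel angle", determined per bundle).
#' The angle of view `tau_deg` is always recomputed as
#' `stage_tilt_deg - parallel_angle_deg`; medial ("front") views have
#' positive tau, lateral ("back") views negative.
#'
#' @param stage_tilt_deg Stage tilt of the acquisition, degrees.
#' @param side `"medial"`, `"lateral"` or `"top"`.
#' @param parallel_angle_deg Stage tilt at which stereocilia are
#'   parallel to the beam; `NA` when not determined for this bundle.
#' @return A one-row tibble with columns `stage_tilt_deg`, `side`,
#'   `parallel_angle_deg`, `tau_deg`.
#' @export
#' @examples
#' image_view(50, "medial", parallel_angle_deg = 10)
image_view <- function(stage_tilt_deg,
                       side = c("medial", "lateral", "top"),
                       parallel_angle_deg = NA_real_) {
  side <- match.arg(side)
  stopifnot(is.numeric(stage_tilt_deg), length(stage_tilt_deg) == 1)
  tau <- stage_tilt_deg - parallel_angle_deg
  if (!is.na(tau) && abs(tau) > 90) {
    stop("angle of view |tau| must be <= 90 degrees for a usable view, got ",
         signif(tau, 4))
  }
  tibble(
    stage_tilt_deg = stage_tilt_deg,
    side = side,
    parallel_angle_deg = as.numeric(parallel_angle_deg),
    tau_deg = as.numeric(tau)
  )
}

# Vectorised forward projections -------------------------------------------

project_full_length <- function(height_um, tau_deg) {
  height_um * abs(sin(deg2rad(tau_deg)))
}

# Signed step projection between a row-1 tip (height h1) and a row-`row`
# tip (height h_row), with inter-row base spacing d and insertion tilt
# alpha, seen at angle of view tau.
project_step <- function(h1_um, h_row_um, row, d_um, alpha_deg, tau_deg) {
  rank <- row_rank(row)
  (h1_um - h_row_um) * sin(deg2rad(tau_deg)) -
    (rank - 1) * d_um * cos(deg2rad(alpha_deg + tau_deg))
}

#' Render one projection measurement from the forward model
#'
#' Numeric oracle realising the forward projection model for a single
#' stereocilium of a bundle under a given view. Full-length projections
#' are `h * |sin tau|` (non-negative); step projections are signed
#' along the tip-ward projected stereocilia axis, measured against the
#' stereocilium's row-1 reference partner (its `ref_id` if set,
#' otherwise the first row-1 stereocilium of the bundle).
#'
#' @param stereocilium_id Identifier of the stereocilium within `bundle`.
#' @param bundle A [bundle()] object.
#' @param view A view tibble from [image_view()].
#' @param kind `"full_length"`, `"step_1_to_2"` or `"step_1_to_3"`.
#' @return Projected length in micrometres (signed for step kinds).
#' @export
render_projection <- function(stereocilium_id, bundle, view,
                              kind = c("full_length", "step_1_to_2",
                                       "step_1_to_3")) {
  kind <- match.arg(kind)
  stopifnot(inherits(bundle, "bundle"))
  st <- bundle$stereocilia[bundle$stereocilia$id == stereocilium_id, ]
  if (nrow(st) != 1) {
    stop("stereocilium '", stereocilium_id, "' not found in bundle '",
         bundle$id, "'")
  }
  tau <- view$tau_deg
  if (is.na(tau)) stop("view has no defined angle of view (tau)")
  if (kind == "full_length") {
    return(project_full_length(st$height_um, tau))
  }
  row1 <- bundle$stereocilia[bundle$stereocilia$row == "1", ]
  if (nrow(row1) == 0) {
    stop("bundle '", bundle$id,
         "' has no row-1 stereocilium to reference a step projection")
  }
  ref_id <- if (!is.null(st$ref_id) && !is.na(st$ref_id) &&
                st$ref_id %in% row1$id) st$ref_id else row1$id[1]
  h1 <- row1$height_um[row1$id == ref_id]
  expected_row <- if (kind == "step_1_to_2") "2" else "3"
  if (st$row != expected_row) {
    stop("kind '", kind, "' requires a row-", expected_row,
         " stereocilium, got row ", st$row)
  }
  project_step(h1, st$height_um, st$row, bundle$row_spacing_um,
               bundle$insertion_tilt_deg, tau)
}

# Inverse solvers -----------------------------------------------------------

#' Solve stereocilium height from two projections at known tilt separation
#'
#' Two SEM images of the same (tallest-row) stereocilium taken from the
#' same side of the bundle at stage tilts separated by
#' `tau_separation_deg` give projections `p1 = h sin(alpha)` and
#' `p2 = h sin(alpha + tau_separation)`, where `alpha` is the angle
#' between the stereocilium and the beam in the first image (the
#' insertion tilt when the first image looks along the surface normal).
#' The system is solved in closed form:
#' `cot(alpha) = (p2/p1 - cos tau) / sin tau`, `h = p1 / sin(alpha)`.
#'
#' All arguments are vectorised and recycled.
#'
#' @param p1_um,p2_um Projected lengths in the first and second image, um.
#' @param tau_separation_deg Tilt separation between the images,
#'   degrees, in (0, 180).
#' @return Tibble with columns `height_um` and `alpha_deg` (alpha in
#'   `[0, 90)`; `alpha = 0` means the stereocilium was beam-parallel in
#'   the first image).
#' @export
#' @examples
#' solve_height_two_view(2.4 * sin(deg2rad(10)), 2.4 * sin(deg2rad(30)), 20)
solve_height_two_view <- function(p1_um, p2_um, tau_separation_deg) {
  n <- max(length(p1_um), length(p2_um), length(tau_separation_deg))
  p1 <- rep_len(as.numeric(p1_um), n)
  p2 <- rep_len(as.numeric(p2_um), n)
  tau <- rep_len(as.numeric(tau_separation_deg), n)
  if (any(!is.finite(p1)) || any(!is.finite(p2)) || any(!is.finite(tau))) {
    stop("non-finite inputs")
  }
  if (any(p1 < 0) || any(p2 < 0)) {
    stop("projections must be non-negative")
  }
  if (any(tau <= 0 | tau >= 180)) {
    stop("tau_separation_deg must lie in (0, 180)")
  }
  if (any(p1 == 0 & p2 == 0)) {
    stop("p1 = p2 = 0: height undetermined (no projection information)")
  }
  t <- deg2rad(tau)
  alpha <- numeric(n)
  zero1 <- p1 == 0
  # p1 = 0 means the stereocilium was beam-parallel in image 1.
  alpha[zero1] <- 0
  if (any(!zero1)) {
    cot_a <- (p2[!zero1] / p1[!zero1] - cos(t[!zero1])) / sin(t[!zero1])
    if (any(cot_a <= 0)) {
      stop("no insertion tilt in (0, 90) degrees is consistent with ",
           "these projections (implied cot(alpha) <= 0); check that both ",
           "views are on the same side of the parallel angle")
    }
    alpha[!zero1] <- atan2(1, cot_a)
  }
  h <- ifelse(zero1, p2 / sin(t), p1 / sin(alpha))
  tibble(height_um = h, alpha_deg = rad2deg(alpha))
}

#' Solve stereocilium height from one projection at known angle of view
#'
#' When the parallel angle of the bundle is known, a single projection
#' at angle of view tau determines the height: `h = p / |sin tau|`.
#'
#' @param p_um Projected length, um (non-negative).
#' @param tau_deg Angle of view, degrees; `|tau|` must be at least 1
#'   degree (smaller angles amplify measurement error as 1/sin tau).
#' @return Height in um (vectorised).
#' @export
#' @examples
#' solve_height_known_parallel(1.2, 30)
solve_height_known_parallel <- function(p_um, tau_deg) {
  n <- max(length(p_um), length(tau_deg))
  p <- rep_len(as.numeric(p_um), n)
  tau <- rep_len(as.numeric(tau_deg), n)
  if (any(!is.finite(p)) || any(!is.finite(tau))) stop("non-finite inputs")
  if (any(p < 0)) stop("projections must be non-negative")
  if (any(abs(tau) < TAU_MIN_DEG)) {
    stop("|tau| < ", TAU_MIN_DEG, " degree: projection carries no usable ",
         "length information (beam nearly parallel to the stereocilium)")
  }
  if (any(abs(tau) > 90)) stop("|tau| must be <= 90 degrees")
  p / abs(sin(deg2rad(tau)))
}

#' Find the stage tilt at which stereocilia are parallel to the beam
#'
#' Fits the forward model `p(theta) = h * |sin(theta - theta0)|` to a
#' tilt series of projected lengths by least squares (h and theta0
#' free) and returns the parallel angle theta0. The fit is used rather
#' than the sampled minimum because tilt grids are coarse (typically
#' 5--10 degree steps).
#'
#' @param stage_tilt_deg Stage tilts of the series, degrees (at least 3
#'   distinct values spanning the projection minimum).
#' @param p_um Projected lengths, um.
#' @return The parallel angle, degrees.
#' @export
#' @examples
#' th <- c(-20, -10, 0, 10, 20)
#' find_parallel_angle(th, 2.4 * abs(sin(deg2rad(th - 5))))
find_parallel_angle <- function(stage_tilt_deg, p_um) {
  theta <- as.numeric(stage_tilt_deg)
  p <- as.numeric(p_um)
  stopifnot(length(theta) == length(p))
  if (any(!is.finite(theta)) || any(!is.finite(p))) stop("non-finite inputs")
  if (any(p < 0)) stop("projections must be non-negative")
  if (length(unique(theta)) < 3) {
    stop("need at least 3 distinct stage tilts to locate the minimum")
  }
  o <- order(theta)
  theta <- theta[o]
  p <- p[o]
  if (any(p == 0)) {
    # Exact zero projection: the beam was parallel at that tilt.
    z <- unique(theta[p == 0])
    if (length(z) > 1) {
      stop("zero projections at multiple distinct stage tilts: ",
           "inconsistent series")
    }
    return(z)
  }
  dp <- diff(p)
  if (all(dp > 0) || all(dp < 0)) {
    stop("projection series is strictly monotone: the parallel angle lies ",
         "outside the sampled tilt range (refusing to extrapolate)")
  }
  rss <- function(theta0) {
    s <- abs(sin(deg2rad(theta - theta0)))
    ss <- sum(s^2)
    if (ss == 0) return(sum(p^2))
    h <- sum(p * s) / ss
    sum((p - h * s)^2)
  }
  grid <- seq(min(theta), max(theta), by = 0.25)
  r <- vapply(grid, rss, numeric(1))
  best <- grid[which.min(r)]
  lo <- max(min(theta), best - 0.5)
  hi <- min(max(theta), best + 0.5)
  optimize(rss, lower = lo, upper = hi, tol = 1e-6)$minimum
}

#' Solve a shorter-row height from a front-view step projection
#'
#' Inverts the signed step-projection model
#' `s = (h1 - h_row) sin(tau) - (row-1) d cos(alpha + tau)` for the
#' shorter-row height:
#' `h_row = h1 - (s + (row-1) d cos(alpha + tau)) / sin(tau)`.
#'
#' @param p_step_um Signed step projection, um (positive when the
#'   row-1 tip projects beyond the shorter tip along the projected
#'   stereocilia axis).
#' @param tau_deg Angle of view, degrees (`|tau| >= 1`).
#' @param h1_um Height of the row-1 reference stereocilium, um.
#' @param d_um Inter-row base spacing, um.
#' @param alpha_deg Insertion tilt of the bundle, degrees.
#' @param row Row rank of the shorter stereocilium (2 or 3).
#' @return Height of the shorter-row stereocilium, um (vectorised).
#' @export
#' @examples
#' solve_row_height_front_view(1.0, 90, h1_um = 2.4, d_um = 0,
#'                             alpha_deg = 0, row = 2)
solve_row_height_front_view <- function(p_step_um, tau_deg, h1_um, d_um,
                                        alpha_deg, row) {
  rank <- row_rank(row)
  if (any(!rank %in% c(2, 3))) stop("row must be 2 or 3")
  n <- max(lengths(list(p_step_um, tau_deg, h1_um, d_um, alpha_deg, rank)))
  s <- rep_len(as.numeric(p_step_um), n)
  tau <- rep_len(as.numeric(tau_deg), n)
  h1 <- rep_len(as.numeric(h1_um), n)
  d <- rep_len(as.numeric(d_um), n)
  alpha <- rep_len(as.numeric(alpha_deg), n)
  rank <- rep_len(rank, n)
  if (any(abs(tau) < TAU_MIN_DEG)) {
    stop("|tau| < ", TAU_MIN_DEG,
         " degree: step projection carries no usable information")
  }
  if (any(h1 <= 0)) stop("h1_um must be positive")
  if (any(d < 0)) stop("d_um must be non-negative")
  w <- (s + (rank - 1) * d * cos(deg2rad(alpha + tau))) / sin(deg2rad(tau))
  h <- h1 - w
  if (any(h <= 0)) {
    stop("implied shorter-row height <= 0: step measurement inconsistent ",
         "with the supplied h1/d/alpha/tau")
  }
  h
}

# Bundle reconstruction -----------------------------------------------------

#' Reconstruct stereocilia heights for one or more bundles
#'
#' Applies the package's inverse procedures to a measurement table:
#' row-1 heights come from the reference-angle method (when the
#' parallel angle of the view is recorded) or from two-view solving
#' (two full-length projections of the same stereocilium at different
#' tilts, same side); rows 2--3 then come from front-view step
#' inversion. Each reconstructed height records which solver produced
#' it; stereocilia with insufficient views are returned with
#' `resolved = FALSE` rather than dropped.
#'
#' @param measurements Measurement table as read by
#'   [read_measurements()] (or built by [render_experiment()]):
#'   one row per measured projection.
#' @param bundle_info Optional tibble with one row per bundle:
#'   `bundle_id`, `row_spacing_um` (the inter-row base distance d,
#'   an input of the method, required for step inversion) and
#'   optionally `insertion_tilt_deg` (fallback insertion tilt used
#'   when no view of the bundle determines the parallel angle).
#' @return Tibble with one row per stereocilium: `bundle_id`,
#'   `cell_type`, `stereocilium_id`, `row`, `height_um`, `method`
#'   (`"reference_angle"`, `"two_view"`, `"step_front_view"` or `NA`),
#'   `resolved`, and the per-bundle `alpha_deg` estimate used.
#' @export
reconstruct_bundle <- function(measurements, bundle_info = NULL) {
  m <- validate_measurements(measurements)
  m$tau_deg <- m$stage_tilt_deg - m$parallel_angle_deg

  full <- m[m$kind == "full_length", , drop = FALSE]
  if (any(full$value_um < 0, na.rm = TRUE)) {
    stop("full_length measurements must be non-negative")
  }

  # Reference-angle path: every full-length view with a known parallel
  # angle contributes one height estimate; estimates are averaged per
  # stereocilium.
  ref <- full %>%
    filter(!is.na(.data$tau_deg), abs(.data$tau_deg) >= TAU_MIN_DEG) %>%
    mutate(h = solve_height_known_parallel(.data$value_um, .data$tau_deg)) %>%
    group_by(.data$bundle_id, .data$cell_type, .data$stereocilium_id,
             .data$row) %>%
    summarise(height_um = mean(.data$h), .groups = "drop") %>%
    mutate(method = "reference_angle")

  # Two-view path for stereocilia without any usable reference-angle view.
  two_src <- full %>%
    anti_join(ref, by = c("bundle_id", "stereocilium_id")) %>%
    group_by(.data$bundle_id, .data$cell_type, .data$stereocilium_id,
             .data$row, .data$side) %>%
    filter(n_distinct(.data$stage_tilt_deg) >= 2) %>%
    ungroup()
  if (nrow(two_src) > 0) {
    two <- two_src %>%
      group_by(.data$bundle_id, .data$cell_type, .data$stereocilium_id,
               .data$row, .data$side) %>%
      dplyr::group_modify(function(d, g) {
        i <- which.min(d$value_um)
        j <- which.max(d$value_um)
        sol <- solve_height_two_view(d$value_um[i], d$value_um[j],
                                     abs(d$stage_tilt_deg[j] -
                                         d$stage_tilt_deg[i]))
        # Parallel-angle estimate implied by the solution. On the
        # lateral side stage tilt decreases away from parallel
        # (tau < 0), so theta0 = theta_near + |tau_near|; medial the
        # opposite.
        sgn <- if (g$side == "lateral") 1 else -1
        tibble(height_um = sol$height_um,
               theta0_deg = d$stage_tilt_deg[i] + sgn * sol$alpha_deg)
      }) %>%
      ungroup() %>%
      mutate(method = "two_view") %>%
      select(-"side")
  } else {
    two <- tibble(bundle_id = character(), cell_type = character(),
                  stereocilium_id = character(), row = character(),
                  height_um = numeric(), theta0_deg = numeric(),
                  method = character())
  }

  heights <- bind_rows(ref, two %>% select(-"theta0_deg"))

  # Per-bundle insertion tilt: in the package's stage frame the
  # parallel angle IS the insertion tilt, so pool recorded parallel
  # angles with two-view implied ones, falling back on bundle_info.
  alpha_obs <- bind_rows(
    m %>% filter(!is.na(.data$parallel_angle_deg)) %>%
      distinct(.data$bundle_id, .data$side, .data$stage_tilt_deg,
               alpha_deg = .data$parallel_angle_deg),
    two %>% distinct(.data$bundle_id, alpha_deg = .data$theta0_deg)
  ) %>%
    group_by(.data$bundle_id) %>%
    summarise(alpha_deg = mean(.data$alpha_deg), .groups = "drop")

  all_bundles <- unique(m$bundle_id)
  alpha_tab <- tibble(bundle_id = all_bundles) %>%
    left_join(alpha_obs, by = "bundle_id")
  if (!is.null(bundle_info) && "insertion_tilt_deg" %in% names(bundle_info)) {
    alpha_tab <- alpha_tab %>%
      left_join(bundle_info %>%
                  select("bundle_id", fallback = "insertion_tilt_deg"),
                by = "bundle_id") %>%
      mutate(alpha_deg = ifelse(is.na(.data$alpha_deg), .data$fallback,
                                .data$alpha_deg)) %>%
      select(-"fallback")
  }

  # Step inversion for rows 2-3.
  steps <- m[m$kind %in% c("step_1_to_2", "step_1_to_3"), , drop = FALSE]
  step_rec <- NULL
  if (nrow(steps) > 0) {
    if (is.null(bundle_info) || !"row_spacing_um" %in% names(bundle_info)) {
      stop("step measurements present but bundle_info$row_spacing_um ",
           "(inter-row base distance d) was not supplied")
    }
    row1_mean <- heights %>%
      filter(.data$row == "1") %>%
      group_by(.data$bundle_id) %>%
      summarise(h1_mean = mean(.data$height_um), .groups = "drop")
    ref_heights <- heights %>%
      select("bundle_id", ref_stereocilium_id = "stereocilium_id",
             h1_ref = "height_um")
    steps <- steps %>%
      left_join(alpha_tab, by = "bundle_id") %>%
      left_join(bundle_info %>% select("bundle_id", "row_spacing_um"),
                by = "bundle_id") %>%
      left_join(row1_mean, by = "bundle_id") %>%
      left_join(ref_heights, by = c("bundle_id", "ref_stereocilium_id")) %>%
      mutate(
        tau_deg = ifelse(is.na(.data$tau_deg),
                         .data$stage_tilt_deg - .data$alpha_deg,
                         .data$tau_deg),
        h1_use = ifelse(is.na(.data$h1_ref), .data$h1_mean, .data$h1_ref),
        step_row = ifelse(.data$kind == "step_1_to_2", "2", "3")
      )
    ok <- !is.na(steps$tau_deg) & abs(steps$tau_deg) >= TAU_MIN_DEG &
      !is.na(steps$h1_use) & !is.na(steps$alpha_deg) &
      !is.na(steps$row_spacing_um)
    h_step <- rep(NA_real_, nrow(steps))
    if (any(ok)) {
      w <- (steps$value_um[ok] +
              (row_rank(steps$step_row[ok]) - 1) * steps$row_spacing_um[ok] *
                cos(deg2rad(steps$alpha_deg[ok] + steps$tau_deg[ok]))) /
        sin(deg2rad(steps$tau_deg[ok]))
      h_cand <- steps$h1_use[ok] - w
      h_cand[h_cand <= 0] <- NA_real_  # inconsistent -> unresolved
      h_step[ok] <- h_cand
    }
    step_rec <- steps %>%
      mutate(height_um = h_step, method = "step_front_view") %>%
      group_by(.data$bundle_id, .data$cell_type, .data$stereocilium_id,
               .data$row, .data$method) %>%
      summarise(height_um = mean(.data$height_um), .groups = "drop")
  }

  out <- bind_rows(heights, step_rec)

  # Every stereocilium that appears in the table is reported.
  roster <- m %>% distinct(.data$bundle_id, .data$cell_type,
                           .data$stereocilium_id, .data$row)
  out <- roster %>%
    left_join(out, by = c("bundle_id", "cell_type", "stereocilium_id",
                          "row")) %>%
    mutate(resolved = !is.na(.data$height_um),
           method = ifelse(.data$resolved, .data$method, NA_character_)) %>%
    left_join(alpha_tab, by = "bundle_id") %>%
    arrange(.data$bundle_id, row_rank(.data$row), .data$stereocilium_id)
  out
}
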