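# Morphometric quantities: staircase steps, relative heights, tip
# diameter profiles, wedge-tip heights, tip-link classification,
# supernumerary counts.

#' Sentinel position for a mid-shaft diameter measurement
#'
#' Diameter positions are axial distances from the tip apex; the shaft
#' sentinel (`Inf`) selects the mid-shaft diameter, outside any tip
#' taper.
#'
#' @export
shaft_position <- function() Inf

# Default measurement positions near the tip (um from the apex), plus
# the shaft sentinel.
DEFAULT_DIAMETER_POSITIONS <- c(0.025, 0.05, 0.1, 0.2)

#' Stereocilium diameter at axial positions near the tip
#'
#' The tip taper is modelled by a one-parameter power-law family:
#' `diameter(s) = shaft_diameter * min(1, (s / L)^gamma)` at axial
#' distance `s` from the apex, where `L` is the axial extent of the
#' tapered region and `gamma` the shape exponent. `gamma ~ 0.5` gives a
#' blunt rounded tip, `gamma ~ 1` a conical wedge, and `gamma > 1` the
#' abnormally thin "pointed" tips seen after mechanotransduction block.
#'
#' @param tip_length_um Axial extent L of the tapered tip region, um
#'   (>= 0; 0 means no taper).
#' @param tip_gamma Shape exponent gamma (> 0).
#' @param shaft_diameter_um Mid-shaft diameter, um.
#' @param positions_um Axial distances from the apex, um (>= 0);
#'   [shaft_position()] (`Inf`) selects the shaft diameter.
#' @return Tibble with columns `position_um` and `diameter_um`.
#' @export
#' @examples
#' diameter_profile(0.3, 1, 0.2, c(0.15, shaft_position()))
diameter_profile <- function(tip_length_um, tip_gamma, shaft_diameter_um,
                             positions_um = c(DEFAULT_DIAMETER_POSITIONS,
                                              shaft_position())) {
  stopifnot(tip_length_um >= 0, tip_gamma > 0, shaft_diameter_um > 0)
  s <- as.numeric(positions_um)
  if (any(is.na(s) | s < 0)) stop("positions must be non-negative")
  frac <- if (tip_length_um == 0) rep(1, length(s)) else {
    pmin(1, (s / tip_length_um)^tip_gamma)
  }
  frac[is.infinite(s)] <- 1
  tibble(position_um = s, diameter_um = shaft_diameter_um * frac)
}

#' Wedge-tip height of a tapered stereocilium tip
#'
#' The wedge-tip height is the axial extent of the tip taper: the
#' smallest distance from the apex at which the diameter reaches
#' `threshold_fraction` of the shaft diameter. Under the power-law tip
#' family this is `L * threshold_fraction^(1/gamma)`.
#'
#' @inheritParams diameter_profile
#' @param threshold_fraction Fraction of the shaft diameter defining
#'   where the taper "meets" the shaft; default 0.95.
#' @return Wedge-tip height, um (vectorised over `tip_length_um` and
#'   `tip_gamma`).
#' @export
#' @examples
#' wedge_tip_height(0.3, 1)
wedge_tip_height <- function(tip_length_um, tip_gamma,
                             threshold_fraction = 0.95) {
  stopifnot(threshold_fraction > 0, threshold_fraction < 1)
  if (any(tip_length_um < 0)) stop("tip_length_um must be >= 0")
  if (any(tip_gamma <= 0)) stop("tip_gamma must be > 0")
  tip_length_um * threshold_fraction^(1 / tip_gamma)
}

#' Staircase steps from per-row heights
#'
#' Steps are height differences measured tip apex to tip apex:
#' `step_1_i = h1 - h_i`. Heights trace each stereocilium to its
#' highest point and ignore tip-shape changes.
#'
#' @param h1_um Row-1 reference height(s), um.
#' @param h2_um,h3_um Row-2 / row-3 heights, um (`NA` when the row is
#'   absent; the step is then reported absent, not zero).
#' @return Tibble with columns `step_1_2_um`, `step_1_3_um`.
#' @export
#' @examples
#' compute_steps(2.4, 1.4, 0.7)
compute_steps <- function(h1_um, h2_um = NA_real_, h3_um = NA_real_) {
  if (any(!is.na(h1_um) & h1_um <= 0)) stop("h1_um must be positive")
  tibble(step_1_2_um = h1_um - h2_um, step_1_3_um = h1_um - h3_um)
}

#' Staircase step directly from a front-view step projection
#'
#' Converts a signed step projection at known angle of view into the
#' height difference `h1 - h_row` without reconstructing absolute
#' heights; exactly consistent with [solve_row_height_front_view()].
#' This is the lighter measurement route for small staircase changes:
#' it needs fewer calculations than absolute height estimation.
#'
#' @inheritParams solve_row_height_front_view
#' @return Step `h1 - h_row`, um (vectorised).
#' @export
step_from_projection <- function(p_step_um, tau_deg, d_um, alpha_deg, row) {
  rank <- row_rank(row)
  if (any(!rank %in% c(2, 3))) stop("row must be 2 or 3")
  if (any(abs(tau_deg) < TAU_MIN_DEG)) {
    stop("|tau| < ", TAU_MIN_DEG, " degree: unusable view")
  }
  (p_step_um + (rank - 1) * d_um * cos(deg2rad(alpha_deg + tau_deg))) /
    sin(deg2rad(tau_deg))
}

#' Heights relative to the tallest row
#'
#' @param h_um Height(s), um.
#' @param h1_um Row-1 reference height of the same bundle, um (> 0).
#' @return Percent of the row-1 height, `100 * h / h1`.
#' @export
#' @examples
#' relative_heights(1.2, 2.4)
relative_heights <- function(h_um, h1_um) {
  if (any(h1_um <= 0)) stop("h1_um must be positive")
  100 * h_um / h1_um
}

#' Classify a link as a tip link
#'
#' A tip link extends obliquely from the top of a lower-row
#' stereocilium to the side of a taller stereocilium in the direction
#' of mechanosensitivity of the bundle. Operationally a link counts as
#' a tip link iff (i) it originates at the top cap of the shorter
#' stereocilium's tip, (ii) the origin row rank is larger (shorter)
#' than the target's, (iii) its mechanosensitivity-axis component
#' points toward taller rows, and (iv) it runs obliquely upward. Links
#' originating elsewhere on the tip hemisphere, or on the shaft, are
#' never tip links.
#'
#' @param origin_region `"top_cap"`, `"tip_hemisphere_other"` or
#'   `"shaft"`.
#' @param origin_row,target_row Row labels of origin and target
#'   stereocilia (`"1"`..`"5"` or `"unranked"`; unranked ranks below
#'   any numbered row).
#' @param axis_sign Sign of the link vector along the
#'   mechanosensitivity axis (+1 toward taller rows).
#' @param elevation_sign Sign of the link vector's vertical component
#'   (+1 upward).
#' @return Logical vector (vectorised over all arguments).
#' @export
#' @examples
#' classify_tip_link("top_cap", "2", "1", 1, 1)
classify_tip_link <- function(origin_region, origin_row, target_row,
                              axis_sign, elevation_sign) {
  regions <- c("top_cap", "tip_hemisphere_other", "shaft")
  if (any(!origin_region %in% regions)) {
    stop("origin_region must be one of: ", paste(regions, collapse = ", "))
  }
  origin_region == "top_cap" &
    row_rank(origin_row) > row_rank(target_row) &
    sign(axis_sign) > 0 &
    sign(elevation_sign) > 0
}

#' Percentage of stereocilia bearing tip links, summarised across cells
#'
#' Computes a per-cell percentage of stereocilia with tip links, then
#' the mean and standard error across cells (per-cell percentages are
#' reported as mean +/- SE).
#'
#' @param n_with_link,n_total Per-cell counts of linked and total
#'   stereocilia (`n_total > 0`).
#' @return Tibble with `n_cells`, `mean_pct`, `se_pct`.
#' @export
#' @examples
#' tip_link_percentage(c(5, 10), c(10, 10))
tip_link_percentage <- function(n_with_link, n_total) {
  if (length(n_with_link) == 0) stop("empty input")
  stopifnot(length(n_with_link) == length(n_total))
  if (any(n_total <= 0)) stop("n_total must be positive for every cell")
  if (any(n_with_link < 0 | n_with_link > n_total)) {
    stop("n_with_link must lie in [0, n_total]")
  }
  pct <- 100 * n_with_link / n_total
  k <- length(pct)
  se <- if (k == 1) {
    warning("single cell: standard error across cells is undefined")
    NA_real_
  } else {
    sd(pct) / sqrt(k)
  }
  tibble(n_cells = k, mean_pct = mean(pct), se_pct = se)
}

#' Count supernumerary stereocilia
#'
#' Supernumerary stereocilia are those of rank 4, rank 5 or unranked
#' (the rows pruned during development).
#'
#' @param x A [bundle()] object or a vector of row labels.
#' @return Integer count.
#' @export
count_supernumerary <- function(x) {
  rows <- if (inherits(x, "bundle")) x$stereocilia$row else as.character(x)
  sum(is_supernumerary(rows))
}

#' Per-stereocilium morphometry table
#'
#' Assembles the tidy morphometry table (one row per stereocilium)
#' from a heights table: relative heights and staircase steps against
#' the bundle's row-1 mean, wedge-tip heights when tip-profile columns
#' are present, and tip-link status when available.
#'
#' @param heights Tibble with columns `bundle_id`, `stereocilium_id`,
#'   `row`, `height_um` and optionally `cell_type`, `tip_length_um`,
#'   `tip_gamma`, `has_tip_link`, `group`.
#' @param wedge_threshold Threshold fraction passed to
#'   [wedge_tip_height()].
#' @return Tibble with columns `bundle_id`, `stereocilium_id`, `row`,
#'   `height_um`, `relative_height_pct`, `step_from_row1_um`, plus
#'   `wedge_tip_height_um` / `has_tip_link` when derivable. Steps and
#'   relative heights are `NA` for bundles with no resolved row-1
#'   height.
#' @export
bundle_morphometry <- function(heights, wedge_threshold = 0.95) {
  h <- as_tibble(heights)
  needed <- c("bundle_id", "stereocilium_id", "row", "height_um")
  missing <- setdiff(needed, names(h))
  if (length(missing) > 0) {
    stop("heights table lacks column(s): ", paste(missing, collapse = ", "))
  }
  h$row <- as.character(h$row)
  row1 <- h %>%
    filter(.data$row == "1", !is.na(.data$height_um)) %>%
    group_by(.data$bundle_id) %>%
    summarise(h1_mean_um = mean(.data$height_um), .groups = "drop")
  out <- h %>%
    left_join(row1, by = "bundle_id") %>%
    mutate(
      relative_height_pct = ifelse(
        !is.na(.data$h1_mean_um) & .data$h1_mean_um > 0,
        100 * .data$height_um / .data$h1_mean_um, NA_real_),
      step_from_row1_um = .data$h1_mean_um - .data$height_um
    )
  if (all(c("tip_length_um", "tip_gamma") %in% names(out))) {
    out$wedge_tip_height_um <- wedge_tip_height(
      out$tip_length_um, out$tip_gamma, wedge_threshold)
  }
  out %>% select(-"h1_mean_um")
}
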