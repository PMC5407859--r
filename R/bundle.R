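# Bundle container: one hair cell's stereocilia with shared geometry.

#' Construct a hair-bundle object
#'
#' A bundle holds the per-cell geometric parameters shared by all of
#' its stereocilia (insertion tilt alpha, inter-row base spacing d)
#' plus a tidy table of stereocilia. Ranked rows sit on base lines
#' spaced `d` apart along the mechanosensitivity axis: a row-i
#' stereocilium has `base_offset_um = -(i - 1) * d` (positive offsets
#' point lateral, toward row 1).
#'
#' @param id Bundle identifier.
#' @param cell_type `"OHC"` or `"IHC"`.
#' @param insertion_tilt_deg Shared insertion tilt alpha, degrees, in
#'   `[0, 90)`.
#' @param row_spacing_um Inter-row base distance d, um (>= 0).
#' @param stereocilia Tibble with columns `id`, `row` (`"1"`..`"5"` or
#'   `"unranked"`), `height_um`, `shaft_diameter_um`, `tip_length_um`,
#'   `tip_gamma`, `has_tip_link`, and optionally `ref_id` (row-1
#'   partner used for step projections).
#' @param cochlear_position_pct Percent distance from the apex.
#' @return An object of class `"bundle"`.
#' @export
bundle <- function(id, cell_type = c("OHC", "IHC"), insertion_tilt_deg,
                   row_spacing_um, stereocilia,
                   cochlear_position_pct = NA_real_) {
  cell_type <- match.arg(cell_type)
  stopifnot(
    is.numeric(insertion_tilt_deg), length(insertion_tilt_deg) == 1,
    insertion_tilt_deg >= 0, insertion_tilt_deg < 90,
    is.numeric(row_spacing_um), row_spacing_um >= 0
  )
  st <- as_tibble(stereocilia)
  needed <- c("id", "row", "height_um", "shaft_diameter_um")
  missing <- setdiff(needed, names(st))
  if (length(missing) > 0) {
    stop("stereocilia table lacks column(s): ", paste(missing, collapse = ", "))
  }
  st$row <- as.character(st$row)
  row_rank(st$row)  # validates labels
  if (any(st$height_um <= 0)) stop("heights must be positive")
  if (any(st$shaft_diameter_um <= 0)) stop("shaft diameters must be positive")
  if (anyDuplicated(st$id)) stop("duplicate stereocilium ids")
  if (!"ref_id" %in% names(st)) st$ref_id <- NA_character_
  st$base_offset_um <- -(pmin(row_rank(st$row), 4) - 1) * row_spacing_um
  structure(
    list(
      id = as.character(id),
      cell_type = cell_type,
      cochlear_position_pct = cochlear_position_pct,
      insertion_tilt_deg = insertion_tilt_deg,
      row_spacing_um = row_spacing_um,
      stereocilia = st
    ),
    class = "bundle"
  )
}

#' @export
print.bundle <- function(x, ...) {
  rows <- table(factor(x$stereocilia$row, levels = ROW_LEVELS))
  cat("<bundle ", x$id, "> ", x$cell_type,
      ", alpha = ", x$insertion_tilt_deg, " deg, d = ", x$row_spacing_um,
      " um\n  stereocilia: ",
      paste(sprintf("%s:%d", names(rows)[rows > 0], rows[rows > 0]),
            collapse = " "),
      "\n", sep = "")
  invisible(x)
}

# Flatten a list of bundles into one tidy stereocilia table.
bundles_to_table <- function(bundles) {
  bind_rows(lapply(bundles, function(b) {
    b$stereocilia %>%
      mutate(bundle_id = b$id, cell_type = b$cell_type,
             insertion_tilt_deg = b$insertion_tilt_deg,
             row_spacing_um = b$row_spacing_um)
  }))
}
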