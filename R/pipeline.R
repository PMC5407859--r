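# File formats, configuration, logging, and the end-to-end pipeline
# driver: simulate -> reconstruct -> morphometry -> stats. All tables
# are RFC-4180 CSV with a header row; lengths are serialised in um
# with 6 decimal places, angles in degrees; configs are YAML and the
# run manifest is JSON.

MEASUREMENT_COLUMNS <- c("bundle_id", "cell_type", "stereocilium_id",
                         "row", "kind", "side", "stage_tilt_deg",
                         "parallel_angle_deg", "value_um")
MEASUREMENT_NUMERIC <- c("stage_tilt_deg", "parallel_angle_deg", "value_um")
MEASUREMENT_KINDS <- c("full_length", "step_1_to_2", "step_1_to_3")

validate_measurements <- function(m) {
  m <- as_tibble(m)
  missing <- setdiff(MEASUREMENT_COLUMNS, names(m))
  if (length(missing) > 0) {
    stop("measurement table lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(m) == 0) stop("measurement table is empty")
  bad_kind <- !m$kind %in% MEASUREMENT_KINDS
  if (any(bad_kind)) {
    stop("unknown measurement kind(s): ",
         paste(unique(m$kind[bad_kind]), collapse = ", "))
  }
  if (!"ref_stereocilium_id" %in% names(m)) {
    m$ref_stereocilium_id <- NA_character_
  }
  m$row <- as.character(m$row)
  row_rank(m$row)
  for (col in MEASUREMENT_NUMERIC) m[[col]] <- as.numeric(m[[col]])
  m
}

#' Read a measurement-table CSV
#'
#' Validates the header and numeric columns; rows whose numeric fields
#' do not parse are rejected with their line numbers.
#'
#' @param path Path to a CSV with required columns `bundle_id`,
#'   `cell_type`, `stereocilium_id`, `row`, `kind`, `side`,
#'   `stage_tilt_deg`, `parallel_angle_deg`, `value_um` (empty
#'   `parallel_angle_deg` fields mean "not determined").
#' @return Validated measurement tibble.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = c("NA", ""))
  missing <- setdiff(MEASUREMENT_COLUMNS, names(raw))
  if (length(missing) > 0) {
    stop("measurement CSV ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0) stop("measurement CSV ", path, " has no data rows")
  for (col in MEASUREMENT_NUMERIC) {
    txt <- raw[[col]]
    num <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & is.na(num))
    if (length(bad) > 0) {
      stop("unparseable numeric in column '", col, "' of ", path,
           " at data line(s): ", paste(head(bad + 1, 10), collapse = ", "))
    }
    raw[[col]] <- num
  }
  validate_measurements(raw)
}

# Serialise with 6 decimal places on um/degree columns so that
# write -> read round trips are exact at the recorded precision.
format_table_for_csv <- function(x) {
  for (col in names(x)) {
    if (is.numeric(x[[col]])) {
      v <- x[[col]]
      out <- ifelse(is.na(v), NA_character_,
                    ifelse(is.infinite(v), ifelse(v > 0, "Inf", "-Inf"),
                           formatC(v, format = "f", digits = 6)))
      x[[col]] <- out
    }
  }
  x
}

#' Write a table as a measurement-style CSV
#'
#' Numeric columns are written with 6 decimal places (um and degree
#' scales), `NA` as an empty field.
#'
#' @param x Tibble to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  write.csv(format_table_for_csv(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an experiment configuration from YAML
#'
#' The YAML maps directly onto the constructor arguments of
#' [bundle_spec()], [treatment_spec()] and [noise_spec()], plus the
#' cohort fields `n_control`, `n_treated` and `seed`.
#'
#' @param path Path to a YAML file with top-level keys `bundle_spec`,
#'   `treatment`, `noise` (each optional; defaults apply), and
#'   optional `n_control`, `n_treated`, `seed`.
#' @return An experiment-config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  experiment_config(
    bundle_spec = do.call(bundle_spec, raw$bundle_spec %||% list()),
    treatment = do.call(treatment_spec, raw$treatment %||% list()),
    noise = do.call(noise_spec, raw$noise %||% list()),
    n_control = raw$n_control %||% 10,
    n_treated = raw$n_treated %||% 10,
    seed = raw$seed %||% 1
  )
}

#' Assemble an experiment configuration
#'
#' @param bundle_spec A [bundle_spec()].
#' @param treatment A [treatment_spec()].
#' @param noise A [noise_spec()].
#' @param n_control,n_treated Bundles per arm.
#' @param seed Master seed (mandatory for every stochastic stage).
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(bundle_spec = stereostair::bundle_spec(),
                              treatment = treatment_spec(),
                              noise = noise_spec(),
                              n_control = 10, n_treated = 10, seed = 1) {
  stopifnot(inherits(bundle_spec, "bundle_spec"),
            inherits(treatment, "treatment_spec"),
            inherits(noise, "noise_spec"),
            n_control >= 0, n_treated >= 0,
            is.numeric(seed), length(seed) == 1)
  structure(list(bundle_spec = bundle_spec, treatment = treatment,
                 noise = noise, n_control = n_control,
                 n_treated = n_treated, seed = as.integer(seed)),
            class = "experiment_config")
}

log_stage <- function(stage, ...) {
  message(sprintf("[stereostair] %-12s %s", stage, paste0(...)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (unless a pre-supplied measurement table is
#' given) -> reconstruct -> morphometry -> stats, writing
#' `measurements.csv`, `diameters.csv`, `links.csv`, `bundle_info.csv`,
#' `truth.csv`, `heights.csv`, `morphometry.csv`, `comparisons.csv`
#' and `manifest.json` into `out_dir`. Stage summaries are logged to
#' stderr. Re-running with the same config and seed reproduces
#' byte-identical CSVs.
#'
#' @param config An [experiment_config()] or path to a YAML config.
#' @param out_dir Output directory (created if needed).
#' @param measurements Optional pre-supplied measurement tibble or CSV
#'   path; when given, the simulate stage is skipped and `bundle_info`
#'   must be supplied.
#' @param bundle_info Optional bundle-info tibble (see
#'   [reconstruct_bundle()]) used with pre-supplied measurements.
#' @return Invisibly, a list with the output tables and the manifest.
#' @export
run_pipeline <- function(config, out_dir, measurements = NULL,
                         bundle_info = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- function(f) file.path(out_dir, f)

  links <- NULL
  per_cell_links <- NULL
  if (is.null(measurements)) {
    cohort <- generate_cohort(spec = config$bundle_spec,
                              treatment = config$treatment,
                              noise = config$noise,
                              n_control = config$n_control,
                              n_treated = config$n_treated,
                              seed = config$seed)
    meas <- bind_rows(
      cohort$control$projections %>%
        mutate(group = "control", .before = 1),
      cohort$treated$projections %>%
        mutate(group = "treated", .before = 1)
    )
    diam <- bind_rows(
      cohort$control$diameters %>% mutate(group = "control", .before = 1),
      cohort$treated$diameters %>% mutate(group = "treated", .before = 1)
    )
    links <- bind_rows(
      cohort$control$links %>% mutate(group = "control", .before = 1),
      cohort$treated$links %>% mutate(group = "treated", .before = 1)
    )
    bundle_info <- bind_rows(cohort$control$bundle_info,
                             cohort$treated$bundle_info)
    write_table_csv(meas, paths("measurements.csv"))
    write_table_csv(diam, paths("diameters.csv"))
    write_table_csv(links, paths("links.csv"))
    write_table_csv(bundle_info, paths("bundle_info.csv"))
    write_table_csv(cohort$truth, paths("truth.csv"))
    log_stage("simulate", nrow(meas), " projections, ", nrow(diam),
              " diameter measurements, ",
              nrow(bundle_info), " bundles")
  } else {
    if (is.character(measurements)) measurements <- read_measurements(measurements)
    meas <- validate_measurements(measurements)
    if (!"group" %in% names(meas)) meas$group <- "all"
    log_stage("simulate", "skipped (pre-supplied measurements, ",
              nrow(meas), " rows)")
  }

  recon <- tryCatch(
    reconstruct_bundle(meas, bundle_info = bundle_info),
    error = function(e) stop("stage 'reconstruct' failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  if ("group" %in% names(meas)) {
    recon <- recon %>%
      left_join(meas %>% distinct(.data$bundle_id, .data$group),
                by = "bundle_id")
  }
  write_table_csv(recon, paths("heights.csv"))
  log_stage("reconstruct", sum(recon$resolved), "/", nrow(recon),
            " stereocilia resolved")

  morph <- tryCatch(
    bundle_morphometry(recon %>% filter(.data$resolved)),
    error = function(e) stop("stage 'morphometry' failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  write_table_csv(morph, paths("morphometry.csv"))
  log_stage("morphometry", nrow(morph), " records")

  comparisons <- NULL
  if ("group" %in% names(morph) && length(unique(morph$group)) == 2) {
    comparisons <- compare_groups(
      morph %>% filter(.data$row %in% c("1", "2", "3")),
      measures = c("height_um", "relative_height_pct", "step_from_row1_um"),
      group_col = "group", by = "row", test = "welch"
    )
    if (!is.null(links) && nrow(links) > 0) {
      class_tbl <- links %>%
        mutate(is_tip_link = classify_tip_link(
          .data$origin_region, .data$origin_row, .data$target_row,
          .data$axis_sign, .data$elevation_sign))
      per_cell_links <- meas %>%
        filter(.data$row %in% c("2", "3")) %>%
        distinct(.data$group, .data$bundle_id, .data$stereocilium_id) %>%
        left_join(class_tbl %>%
                    select("bundle_id",
                           stereocilium_id = "origin_stereocilium_id",
                           "is_tip_link"),
                  by = c("bundle_id", "stereocilium_id")) %>%
        group_by(.data$group, .data$bundle_id) %>%
        summarise(n_with_link = sum(.data$is_tip_link %in% TRUE),
                  n_total = n(), .groups = "drop")
      comparisons <- bind_rows(
        comparisons,
        compare_tip_link_percentage(per_cell_links) %>% mutate(row = NA)
      )
    }
    if (!is.null(bundle_info) && "n_supernumerary" %in% names(bundle_info) &&
        "group" %in% names(bundle_info)) {
      sup <- compare_groups(bundle_info, measures = "n_supernumerary",
                            group_col = "group",
                            by = "cell_type", test = "welch") %>%
        rename(row = "cell_type")
      comparisons <- bind_rows(comparisons, sup)
    }
    write_table_csv(comparisons, paths("comparisons.csv"))
    log_stage("stats", nrow(comparisons), " contrasts")
  } else {
    log_stage("stats", "skipped (need exactly two groups)")
  }

  manifest <- list(
    package = "stereostair",
    version = as.character(utils::packageVersion("stereostair")),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    noise_seed = config$noise$seed,
    rows = list(
      measurements = nrow(meas),
      heights = nrow(recon),
      morphometry = nrow(morph),
      comparisons = if (is.null(comparisons)) 0L else nrow(comparisons)
    )
  )
  jsonlite::write_json(manifest, paths("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  log_stage("manifest", manifest$config_hash)
  invisible(list(measurements = meas, heights = recon, morphometry = morph,
                 comparisons = comparisons, manifest = manifest))
}
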