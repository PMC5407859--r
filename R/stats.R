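# Group-comparison layer: descriptive summaries with the SD/SE
# conventions used for hair-bundle morphometry, Welch and Student
# two-sample t tests, significance stars, and assembly of per-row
# comparison tables. Tests are two-sided and uncorrected for multiple
# comparisons (stars are reported per panel, as is conventional for
# this kind of morphometric figure).

#' Descriptive summary of one group
#'
#' @param x Numeric values.
#' @param label Group label.
#' @param dispersion `"SD"` (per-stereocilium metrics) or `"SE"`
#'   (per-cell percentages).
#' @return One-row tibble: `label`, `n`, `mean`, `dispersion_value`,
#'   `dispersion_kind`.
#' @export
group_summary <- function(x, label = "group", dispersion = c("SD", "SE")) {
  dispersion <- match.arg(dispersion)
  x <- x[is.finite(x)]
  if (length(x) < 1) stop("group '", label, "' has no finite values")
  s <- sd(x)
  tibble(label = label, n = length(x), mean = mean(x),
         dispersion_value = if (dispersion == "SD") s else s / sqrt(length(x)),
         dispersion_kind = dispersion)
}

two_sample_t <- function(sample_a, sample_b, var_equal, dispersion,
                         label_a = "a", label_b = "b") {
  a <- sample_a[is.finite(sample_a)]
  b <- sample_b[is.finite(sample_b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs n >= 2 finite values")
  }
  test <- if (var_equal) "student" else "welch"
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      tt <- list(statistic = c(t = 0),
                 parameter = c(df = length(a) + length(b) - 2), p.value = 1)
    } else {
      stop("both samples have zero variance and different means: ",
           "t statistic undefined")
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = var_equal)
  }
  tibble(
    label_a = label_a, n_a = length(a), mean_a = mean(a), sd_a = sd(a),
    label_b = label_b, n_b = length(b), mean_b = mean(b), sd_b = sd(b),
    dispersion_kind = dispersion,
    test = test,
    t_statistic = unname(tt$statistic),
    degrees_of_freedom = unname(tt$parameter),
    p_value = unname(tt$p.value),
    stars = significance_stars(unname(tt$p.value))
  )
}

#' Welch's unequal-variance two-sample t test
#'
#' Two-sided Welch t test (Welch--Satterthwaite degrees of freedom),
#' the convention for per-stereocilium height, step and diameter
#' comparisons, which are summarised as mean +/- SD.
#'
#' @param sample_a,sample_b Numeric samples (n >= 2 each; at least one
#'   with nonzero variance unless the means are equal).
#' @param label_a,label_b Group labels.
#' @return One-row comparison tibble with group summaries,
#'   `t_statistic`, `degrees_of_freedom`, `p_value` and `stars`.
#' @export
#' @examples
#' welch_t(rnorm(10), rnorm(10, 1))
welch_t <- function(sample_a, sample_b, label_a = "a", label_b = "b") {
  two_sample_t(sample_a, sample_b, var_equal = FALSE, dispersion = "SD",
               label_a = label_a, label_b = label_b)
}

#' Student's pooled-variance two-sample t test
#'
#' Two-sided pooled t test with `df = n_a + n_b - 2`, the convention
#' for per-cell percentage comparisons, which are summarised as
#' mean +/- SE.
#'
#' @inheritParams welch_t
#' @return One-row comparison tibble (as [welch_t()]).
#' @export
student_t <- function(sample_a, sample_b, label_a = "a", label_b = "b") {
  two_sample_t(sample_a, sample_b, var_equal = TRUE, dispersion = "SE",
               label_a = label_a, label_b = label_b)
}

#' Significance stars for a p value
#'
#' `"****"` for p < 0.0001, `"***"` for p < 0.001, `"**"` for p <
#' 0.01, `"*"` for p < 0.05, `"n.s."` otherwise.
#'
#' @param p P value(s) in `[0, 1]`.
#' @return Character vector of star labels.
#' @export
#' @examples
#' significance_stars(c(0.03, 0.2, 5e-5))
significance_stars <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p must lie in [0, 1]")
  cuts <- c(1e-4, 1e-3, 1e-2, 0.05)
  labels <- c("****", "***", "**", "*", "n.s.")
  labels[findInterval(p, cuts) + 1]
}

#' Per-row group comparisons of morphometric measures
#'
#' Builds a comparison table in the shape of a per-row,
#' control-vs-treated morphometry panel: one test per (row, measure)
#' cell. Per-stereocilium measures use Welch tests and mean +/- SD.
#' Contrasts with a missing group or fewer than two finite values per
#' group are skipped with a warning.
#'
#' @param data Morphometry tibble containing `group_col`, `by` and
#'   the measure columns.
#' @param measures Character vector of measure column names.
#' @param group_col Name of the two-level grouping column.
#' @param by Name of the stratifying column (default `"row"`).
#' @param test `"welch"` or `"student"`.
#' @return Comparison tibble with one row per (measure, stratum),
#'   ordered by measure then stratum; invariant to the row order of
#'   `data`.
#' @export
compare_groups <- function(data, measures, group_col = "group",
                           by = "row", test = c("welch", "student")) {
  test <- match.arg(test)
  data <- as_tibble(data)
  missing <- setdiff(c(measures, group_col, by), names(data))
  if (length(missing) > 0) {
    stop("data lacks column(s): ", paste(missing, collapse = ", "))
  }
  groups <- sort(unique(as.character(data[[group_col]])))
  if (length(groups) < 2) {
    warning("fewer than two groups in '", group_col,
            "': empty comparison table")
    return(tibble())
  }
  if (length(groups) > 2) {
    stop("compare_groups supports exactly two groups, got: ",
         paste(groups, collapse = ", "))
  }
  strata <- sort(unique(as.character(data[[by]])))
  out <- list()
  for (m in measures) {
    for (s in strata) {
      sub <- data[as.character(data[[by]]) == s, ]
      a <- sub[[m]][as.character(sub[[group_col]]) == groups[1]]
      b <- sub[[m]][as.character(sub[[group_col]]) == groups[2]]
      if (sum(is.finite(a)) < 2 || sum(is.finite(b)) < 2) {
        warning("skipping contrast ", m, " / ", by, " = ", s,
                ": a group has fewer than 2 finite values")
        next
      }
      cmp <- if (test == "welch") {
        welch_t(a, b, label_a = groups[1], label_b = groups[2])
      } else {
        student_t(a, b, label_a = groups[1], label_b = groups[2])
      }
      out[[length(out) + 1]] <- cmp %>%
        mutate(measure = m, !!by := s, .before = 1)
    }
  }
  bind_rows(out)
}

#' Compare tip-link percentages between groups across cells
#'
#' Reduces per-link classifications to a per-cell percentage of
#' shorter-row stereocilia bearing a tip link, then compares the two
#' groups with a Student t test on the per-cell percentages
#' (mean +/- SE convention).
#'
#' @param per_cell Tibble with columns `bundle_id`, `group`,
#'   `n_with_link`, `n_total`.
#' @return One-row comparison tibble.
#' @export
compare_tip_link_percentage <- function(per_cell) {
  needed <- c("bundle_id", "group", "n_with_link", "n_total")
  missing <- setdiff(needed, names(per_cell))
  if (length(missing) > 0) {
    stop("per_cell lacks column(s): ", paste(missing, collapse = ", "))
  }
  groups <- sort(unique(as.character(per_cell$group)))
  if (length(groups) != 2) stop("need exactly two groups")
  pct <- 100 * per_cell$n_with_link / per_cell$n_total
  student_t(pct[per_cell$group == groups[1]],
            pct[per_cell$group == groups[2]],
            label_a = groups[1], label_b = groups[2]) %>%
    mutate(measure = "tip_link_pct", .before = 1)
}
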