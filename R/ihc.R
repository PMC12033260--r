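#' Immunohistochemistry H-score
#'
#' Semiquantitative staining score: intensity (0 none, 1 weak, 2 moderate,
#' 3 strong) multiplied by the percentage of positive nuclei (0–100), giving
#' a score in \[0, 300\].
#'
#' @param intensity Integer(ish) vector in {0, 1, 2, 3}.
#' @param percentage Numeric vector in \[0, 100\].
#' @return Numeric vector `intensity * percentage`.
#' @examples
#' h_score(3, 100) # 300
#' h_score(2, 45)  # 90
#' @export
h_score <- function(intensity, percentage) {
  stopifnot(is.numeric(intensity), is.numeric(percentage))
  if (any(!intensity %in% 0:3)) {
    stop("intensity must be 0, 1, 2 or 3", call. = FALSE)
  }
  if (any(percentage < 0 | percentage > 100 | !is.finite(percentage))) {
    stop("percentage must lie in [0, 100]", call. = FALSE)
  }
  as.numeric(intensity) * as.numeric(percentage)
}

#' Convert pathologist percentage categories to midpoint percentages
#'
#' Some scoring sheets record the positive-nucleus percentage as a category
#' (0 = no expression, 1 = up to 10%, 2 = 10–20%, ... 10 = 90–100%) rather
#' than a raw percentage. This maps category `k >= 1` to the midpoint of its
#' 10-point interval (`10k - 5`) and 0 to 0.
#'
#' @param category Integer vector in 0..10.
#' @return Numeric percentages in \[0, 100\].
#' @export
ihc_category_to_percent <- function(category) {
  if (any(!category %in% 0:10)) {
    stop("category codes must be integers 0..10", call. = FALSE)
  }
  ifelse(category == 0, 0, 10 * category - 5)
}

#' Score IHC regions and compare region classes
#'
#' Adds H-scores to a table of scored regions, then contrasts the
#' immune-infiltrated regions against the remaining regions with an unpaired
#' two-sided (Welch) t-test — the comparison used to establish that
#' steroidogenic (CYP11A1-high) activity concentrates in immune-infiltrated
#' areas of the tumour.
#'
#' @param regions Data frame with columns `region_id`, `intensity`,
#'   `percentage` and `region_class` (one of `immune_infiltrated`, `tumour`,
#'   `stroma`, `other`).
#' @return `score_ihc_regions()`: the input as a tibble with an added
#'   `h_score` column. `region_activity_compare()`: a list with `class_means`
#'   (tibble of per-class mean H-scores) and `test` (the
#'   [compare_groups()] row for infiltrated vs rest).
#' @export
score_ihc_regions <- function(regions) {
  regions <- tibble::as_tibble(regions)
  needed <- c("region_id", "intensity", "percentage", "region_class")
  miss <- setdiff(needed, names(regions))
  if (length(miss)) {
    stop("regions table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dplyr::mutate(regions, h_score = h_score(.data$intensity, .data$percentage))
}

#' @rdname score_ihc_regions
#' @param var_equal Passed to [compare_groups()].
#' @export
region_activity_compare <- function(regions, var_equal = FALSE) {
  scored <- if ("h_score" %in% names(regions)) {
    tibble::as_tibble(regions)
  } else {
    score_ihc_regions(regions)
  }
  grp <- factor(ifelse(scored$region_class == "immune_infiltrated",
                       "immune_infiltrated", "other"),
                levels = c("immune_infiltrated", "other"))
  if (any(table(grp) < 2L) || nlevels(droplevels(grp)) < 2L) {
    stop("need at least 2 regions in each compared class", call. = FALSE)
  }
  class_means <- scored |>
    dplyr::group_by(.data$region_class) |>
    dplyr::summarise(n = dplyr::n(), mean_h_score = mean(.data$h_score),
                     .groups = "drop")
  list(
    class_means = class_means,
    test = compare_groups(scored$h_score, grp, var_equal = var_equal)
  )
}

#' Tumour size metrics from caliper measurements
#'
#' `tumour_volume()` applies the caliper volume convention
#' `(pi / 6) * shortest * longest` verbatim. Note this differs from the more
#' common ellipsoid approximation `length * width^2 / 2`: as stated it is
#' quadratic in length rather than cubic, so its unit is mm^2-scaled; it is
#' implemented exactly as stated rather than "corrected".
#' `burden_check()` applies the humane-endpoint rule
#' `(shortest + longest) / 2 <= limit` (15 mm by default).
#'
#' @param longest,shortest Caliper lengths in mm, `longest >= shortest >= 0`.
#' @param limit Mean-diameter limit in mm.
#' @return `tumour_volume()`: numeric volumes. `burden_check()`: logical,
#'   `TRUE` when within the limit. `tumour_metrics()`: the measurement table
#'   with `volume` and `within_limit` columns added.
#' @examples
#' tumour_volume(10, 5) # (pi/6) * 50
#' burden_check(20, 14) # FALSE: mean diameter 17 mm
#' @export
tumour_volume <- function(longest, shortest) {
  check_lengths(longest, shortest)
  (pi / 6) * shortest * longest
}

#' @rdname tumour_volume
#' @export
burden_check <- function(longest, shortest, limit = 15) {
  check_lengths(longest, shortest)
  (shortest + longest) / 2 <= limit
}

#' @rdname tumour_volume
#' @param measurements Data frame with `longest` and `shortest` columns (mm).
#' @export
tumour_metrics <- function(measurements, limit = 15) {
  measurements <- tibble::as_tibble(measurements)
  stopifnot(all(c("longest", "shortest") %in% names(measurements)))
  dplyr::mutate(
    measurements,
    volume = tumour_volume(.data$longest, .data$shortest),
    within_limit = burden_check(.data$longest, .data$shortest, limit = limit)
  )
}

check_lengths <- function(longest, shortest) {
  stopifnot(is.numeric(longest), is.numeric(shortest),
            length(longest) == length(shortest))
  if (any(shortest < 0 | longest < 0)) {
    stop("tumour lengths must be non-negative", call. = FALSE)
  }
  if (any(shortest > longest)) {
    stop("shortest length may not exceed longest length", call. = FALSE)
  }
  invisible(TRUE)
}
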