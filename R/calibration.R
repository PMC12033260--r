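#' Fit an LC-MS/MS calibration curve
#'
#' Ordinary least-squares regression of analyte / internal-standard peak-area
#' ratio on known spiked amount, as used to quantify steroids (e.g.
#' pregnenolone against its stable-isotope-labelled standard) from a mixed
#' calibration series.
#'
#' @param known_amounts Numeric vector of known concentrations (>= 2 distinct
#'   values).
#' @param observed_ratios Numeric vector of peak-area ratios, same length.
#' @return An object of class `calibration_curve` wrapping the `lm` fit, with
#'   `slope`, `intercept` and `residuals` components.
#' @examples
#' cal <- fit_calibration(c(0, 0.25, 0.5, 1), c(0.02, 0.26, 0.49, 1.01))
#' quantify(cal, 0.4)
#' @export
fit_calibration <- function(known_amounts, observed_ratios) {
  stopifnot(is.numeric(known_amounts), is.numeric(observed_ratios),
            length(known_amounts) == length(observed_ratios))
  if (length(known_amounts) < 2L) {
    stop("need at least two calibration points", call. = FALSE)
  }
  if (length(unique(known_amounts)) < 2L) {
    stop("degenerate calibration design: all known amounts identical",
         call. = FALSE)
  }
  fit <- stats::lm(observed_ratios ~ known_amounts)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope == 0) {
    stop("fitted slope is zero; curve cannot be inverted", call. = FALSE)
  }
  structure(
    list(
      slope = slope,
      intercept = unname(stats::coef(fit)[1L]),
      residuals = unname(stats::residuals(fit)),
      known_amounts = known_amounts,
      observed_ratios = observed_ratios,
      fit = fit
    ),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> ratio = %.6g + %.6g * amount (n = %d)\n",
              x$intercept, x$slope, length(x$known_amounts)))
  invisible(x)
}

#' Quantify an analyte from its peak-area ratio
#'
#' Inverse prediction on a fitted calibration line:
#' `amount = (ratio - intercept) / slope`. Amounts below zero are returned
#' as-is but flagged, so callers can decide how to treat sub-blank signals.
#'
#' @param curve A [fit_calibration()] result.
#' @param ratio Numeric vector of peak-area ratios.
#' @return Tibble with `ratio`, `amount` and `below_zero`.
#' @export
quantify <- function(curve, ratio) {
  stopifnot(inherits(curve, "calibration_curve"), is.numeric(ratio))
  if (curve$slope == 0) stop("calibration slope is zero", call. = FALSE)
  amount <- (ratio - curve$intercept) / curve$slope
  tibble::tibble(ratio = ratio, amount = amount, below_zero = amount < 0)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration curve fit
#'
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @return One row per coefficient with `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @method tidy calibration_curve
#' @export
tidy.calibration_curve <- function(x, ...) {
  sm <- stats::coef(summary(x$fit))
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p.value = unname(sm[, "Pr(>|t|)"])
  )
}

#' @rdname tidy.calibration_curve
#' @method glance calibration_curve
#' @export
glance.calibration_curve <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(
    r.squared = sm$r.squared,
    sigma = sm$sigma,
    n = length(x$known_amounts)
  )
}
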