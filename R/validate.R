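## Calibration linearity, LLOD/LLOQ and carry-over. LLOD = 3.3 sigma / s and
## LLOQ = 10 sigma / s from the ordinary least-squares fit of the response
## ratio on the concentration ratio.

#' Fit a calibration curve and estimate LLOD/LLOQ
#'
#' Ordinary least squares of response ratio `y` (analyte area / ISTD area) on
#' concentration ratio `x` (analyte conc / ISTD conc). `sigma`, the "standard
#' deviation of responses", defaults to the residual standard error of the
#' regression (`sigma_mode = "residual"`); alternatives are the standard
#' error of the fitted intercept (`"intercept"`) or the SD of supplied blank
#' responses (`"blank"`). `LLOD = 3.3 sigma / s`, `LLOQ = 10 sigma / s`; a
#' non-positive slope leaves both undefined with `flag = "nonpositive_slope"`.
#'
#' @param points Data frame with columns `x` and `y` (at least 3 distinct
#'   `x`).
#' @param analyte,istd Optional labels carried into the result.
#' @param sigma_mode `"residual"` (default), `"intercept"` or `"blank"`.
#' @param blank_responses Numeric vector of blank responses, required for
#'   `sigma_mode = "blank"`.
#' @return An object of class `calibration_fit`: a list with `analyte`,
#'   `istd`, `points`, `slope`, `intercept`, `r_squared`, `sigma`, `llod`,
#'   `lloq`, `flag`.
#' @examples
#' fit <- fit_calibration(data.frame(x = 1:5, y = 2 * (1:5)))
#' glance(fit)
#' @export
fit_calibration <- function(points, analyte = NA_character_,
                            istd = NA_character_,
                            sigma_mode = c("residual", "intercept", "blank"),
                            blank_responses = NULL) {
  sigma_mode <- match.arg(sigma_mode)
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  if (length(unique(points$x)) < 3) {
    stop("calibration needs at least 3 distinct concentration ratios",
      call. = FALSE
    )
  }
  fit <- stats::lm(y ~ x, data = points)
  sm <- suppressWarnings(summary(fit)) # perfect fits warn harmlessly
  slope <- unname(stats::coef(fit)[["x"]])
  intercept <- unname(stats::coef(fit)[["(Intercept)"]])
  sigma <- switch(sigma_mode,
    residual = sm$sigma,
    intercept = sm$coefficients["(Intercept)", "Std. Error"],
    blank = {
      if (is.null(blank_responses) || length(blank_responses) < 2) {
        stop("sigma_mode 'blank' needs >= 2 blank responses", call. = FALSE)
      }
      stats::sd(blank_responses)
    }
  )
  flag <- NA_character_
  llod <- lloq <- NA_real_
  if (slope > 0) {
    llod <- 3.3 * sigma / slope
    lloq <- 10 * sigma / slope
  } else {
    flag <- "nonpositive_slope"
  }
  structure(
    list(
      analyte = analyte, istd = istd, points = tibble::as_tibble(points),
      slope = slope, intercept = intercept,
      r_squared = sm$r.squared, sigma = sigma, sigma_mode = sigma_mode,
      llod = llod, lloq = lloq, flag = flag
    ),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("Calibration fit",
    if (!is.na(x$analyte)) paste0("for ", x$analyte) else "", "\n"
  )
  cat(sprintf(
    "  slope %.4g  intercept %.4g  R^2 %.4f\n  sigma %.4g (%s)  LLOD %.4g  LLOQ %.4g\n",
    x$slope, x$intercept, x$r_squared, x$sigma, x$sigma_mode, x$llod, x$lloq
  ))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Tidy a calibration fit
#'
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`term`, `estimate`).
#' @export
tidy.calibration_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' One-row summary of a calibration fit
#'
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `analyte`, `istd`, `slope`, `intercept`,
#'   `r_squared`, `sigma`, `llod`, `lloq`, `n_points`, `flag`.
#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(
    analyte = x$analyte, istd = x$istd, slope = x$slope,
    intercept = x$intercept, r_squared = x$r_squared, sigma = x$sigma,
    llod = x$llod, lloq = x$lloq, n_points = nrow(x$points), flag = x$flag
  )
}

#' Generic for broom-style tidying
#' @param x Object to tidy.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Generic for broom-style one-row summaries
#' @param x Object to summarise.
#' @param ... Passed to methods.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Linearity acceptance on R-squared
#'
#' @param fit A `calibration_fit`.
#' @param threshold Acceptance threshold (default 0.95).
#' @return `TRUE` iff `R^2 >= threshold`.
#' @export
r2_acceptance <- function(fit, threshold = 0.95) {
  stopifnot(inherits(fit, "calibration_fit"))
  fit$r_squared >= threshold
}

#' Carry-over percentage
#'
#' `100 * blank area / preceding standard area`, with the cohort summary
#' being the mean across analytes.
#'
#' @param blank_area,standard_area Peak areas (vectorized); standard areas
#'   must be positive (zero gives `NA`).
#' @return A list with `per_analyte` (percent vector) and `mean_pct`.
#' @examples
#' carryover_percent(1.2, 100)$mean_pct # 1.2
#' @export
carryover_percent <- function(blank_area, standard_area) {
  pct <- ifelse(standard_area > 0, 100 * blank_area / standard_area, NA_real_)
  list(per_analyte = pct, mean_pct = mean(pct, na.rm = TRUE))
}

#' Two-fold calibration dilution grid
#'
#' The 8-point two-fold dilution design descending from a top concentration
#' (default 5 pmol/uL, giving 0.039 at the lowest point).
#'
#' @param top Highest concentration (default 5).
#' @param n_points Number of points (default 8).
#' @return Numeric vector, ascending.
#' @export
dilution_series <- function(top = 5, n_points = 8) {
  sort(top / 2^(seq_len(n_points) - 1))
}
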