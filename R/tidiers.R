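#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration fit
#'
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @return One row per coefficient (`intercept`, `slope`), with standard
#'   errors when the fit carries its underlying model.
#' @export
tidy.calibration_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
  if (!is.null(x$model)) {
    s <- summary(x$model)$coefficients
    out$std.error <- s[, "Std. Error"]
    out$p.value <- s[, "Pr(>|t|)"]
  }
  out
}

#' @rdname tidy.calibration_fit
#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope,
    intercept = x$intercept,
    r.squared = x$r_squared,
    n_levels = length(x$concentrations %||% numeric())
  )
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return One-row tibble with the test name, statistic, p value and
#'   significance flag.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::tibble(
    test = x$test_name,
    statistic = x$statistic,
    p.value = x$p_value,
    significant = x$significant
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
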