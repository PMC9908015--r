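#' Background-subtract and excitation-normalise a raw spectrum
#'
#' corrected = (raw - background) / excitation, clipped at zero. The
#' background (bare film) and excitation spectra are resampled onto the
#' raw grid by linear interpolation; their grids must overlap the raw
#' grid.
#'
#' @param raw,background,excitation `spectrum` tibbles (columns
#'   `wavelength_nm`, `intensity`). `excitation` must be positive wherever
#'   it is evaluated.
#' @return A corrected `spectrum` on the raw grid.
#' @export
correct_spectrum <- function(raw, background, excitation) {
  wl <- raw$wavelength_nm
  resample <- function(s, what) {
    if (min(s$wavelength_nm) > max(wl) || max(s$wavelength_nm) < min(wl)) {
      stop(what, " grid does not overlap the raw grid", call. = FALSE)
    }
    stats::approx(s$wavelength_nm, s$intensity, xout = wl, rule = 2)$y
  }
  bg <- resample(background, "background")
  ex <- resample(excitation, "excitation")
  if (any(ex <= 0)) {
    stop("excitation spectrum must be positive over the raw grid", call. = FALSE)
  }
  intensity <- pmax((raw$intensity - bg) / ex, 0)
  new_spectrum(wl, intensity, meta = list(kind = "corrected"))
}

#' Construct a calibration line directly from coefficients
#'
#' RG = slope * ln(concentration) + intercept. Used to evaluate or invert
#' a published calibration without refitting.
#'
#' @param slope RG per ln(EU/ml).
#' @param intercept RG at 1 EU/ml.
#' @param r_squared Optional coefficient of determination.
#' @return An object of class `calibration_fit`.
#' @export
calibration_fit <- function(slope, intercept, r_squared = NA_real_) {
  structure(
    list(slope = slope, intercept = intercept, r_squared = r_squared,
         concentrations = NULL, rg_means = NULL, rg_sds = NULL,
         blanks = NULL, model = NULL),
    class = "calibration_fit"
  )
}

#' Fit the ln-linear RG calibration of a titration
#'
#' Ordinary least squares of the replicate-mean RG on the natural
#' logarithm of concentration. Blank rows (concentration 0) are excluded
#' from the fit but kept on the object for blank-significance testing.
#'
#' @param titration Data frame with columns `concentration_eu_ml`,
#'   `rg`, and optionally `replicate`.
#' @param use_replicate_means Fit on per-level replicate means (default,
#'   matching triplicate-averaged calibration points) or on every
#'   replicate.
#' @param log_base Base of the concentration logarithm (default e; the
#'   ln convention is required for published slope/intercept pairs to
#'   reproduce measured RG values).
#' @return A `calibration_fit` with slope, intercept, `r_squared`,
#'   per-level means/SDs, stored blanks and the underlying `lm`.
#' @export
fit_calibration <- function(titration, use_replicate_means = TRUE,
                            log_base = exp(1)) {
  stopifnot(is.data.frame(titration),
            all(c("concentration_eu_ml", "rg") %in% names(titration)))
  if (any(titration$concentration_eu_ml < 0)) {
    stop("negative concentrations are not allowed", call. = FALSE)
  }
  blanks <- dplyr::filter(titration, .data$concentration_eu_ml == 0)
  pts <- dplyr::filter(titration, .data$concentration_eu_ml > 0)
  levels <- pts |>
    dplyr::group_by(.data$concentration_eu_ml) |>
    dplyr::summarise(rg_mean = mean(.data$rg),
                     rg_sd = stats::sd(.data$rg),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$concentration_eu_ml)
  if (nrow(levels) < 3) {
    stop("need at least 3 distinct positive concentration levels",
         call. = FALSE)
  }
  fit_data <- if (use_replicate_means) {
    tibble::tibble(x = log(levels$concentration_eu_ml, base = log_base),
                   y = levels$rg_mean)
  } else {
    tibble::tibble(x = log(pts$concentration_eu_ml, base = log_base),
                   y = pts$rg)
  }
  model <- stats::lm(y ~ x, data = fit_data)
  # summary.lm warns on noiseless (perfect-fit) input; R^2 = 1 is still
  # the right answer there
  r2 <- suppressWarnings(summary(model)$r.squared)
  structure(
    list(slope = unname(stats::coef(model)[2]),
         intercept = unname(stats::coef(model)[1]),
         r_squared = r2,
         concentrations = levels$concentration_eu_ml,
         rg_means = levels$rg_mean,
         rg_sds = levels$rg_sd,
         blanks = blanks,
         model = model,
         log_base = log_base),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit: RG = %.4g ln(C) + %.4g, R^2 = %s>\n",
              x$slope, x$intercept,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared))))
  invisible(x)
}

#' Evaluate or invert a calibration line
#'
#' `predict_rg()` evaluates RG = slope * ln(C) + intercept;
#' `estimate_concentration()` inverts it, C = exp((RG - intercept)/slope).
#' The two are mutual inverses.
#'
#' @param fit A `calibration_fit`.
#' @param concentration Concentration(s) in EU/ml (> 0).
#' @param rg RG value(s).
#' @return Numeric vector of RG values / concentrations.
#' @export
predict_rg <- function(fit, concentration) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (any(concentration <= 0)) {
    stop("`concentration` must be positive", call. = FALSE)
  }
  fit$slope * log(concentration) + fit$intercept
}

#' @rdname predict_rg
#' @export
estimate_concentration <- function(fit, rg) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$slope == 0) stop("zero slope: calibration not invertible", call. = FALSE)
  exp((rg - fit$intercept) / fit$slope)
}

#' Bracket the limit of detection from per-level blank significance
#'
#' The LOD is reported as the bracket (highest concentration not
#' significantly different from blank, lowest significantly different
#' one). Significance flags may be supplied directly (`significant`
#' column) or computed from replicate RG values against blank replicates
#' using a two-sided pooled t test at `alpha`.
#'
#' @param levels Data frame with `concentration_eu_ml` plus either a
#'   logical `significant` column, or an `rg` column (replicate values;
#'   blank replicates as rows with concentration 0).
#' @param alpha Significance level (default 0.05).
#' @return Tibble with one row: `lower_eu_ml`, `upper_eu_ml`.
#' @export
estimate_lod <- function(levels, alpha = 0.05) {
  stopifnot(is.data.frame(levels), "concentration_eu_ml" %in% names(levels))
  if (!"significant" %in% names(levels)) {
    if (!"rg" %in% names(levels)) {
      stop("`levels` needs either a `significant` or an `rg` column",
           call. = FALSE)
    }
    blanks <- levels$rg[levels$concentration_eu_ml == 0]
    if (length(blanks) < 2) {
      stop("blank replicates (concentration 0) are required to derive ",
           "significance flags", call. = FALSE)
    }
    pos <- levels[levels$concentration_eu_ml > 0, ]
    by_level <- split(pos$rg, pos$concentration_eu_ml)
    levels <- tibble::tibble(
      concentration_eu_ml = as.numeric(names(by_level)),
      significant = vapply(by_level, function(v) {
        compare_groups(list(blank = blanks, level = v))$p_value < alpha
      }, logical(1))
    )
  }
  levels <- dplyr::arrange(dplyr::distinct(
    levels[, c("concentration_eu_ml", "significant")]),
    .data$concentration_eu_ml)
  flags <- levels$significant
  if (all(flags)) {
    stop("all levels significant: LOD bracket open below the tested range",
         call. = FALSE)
  }
  if (!any(flags)) {
    stop("no level significant: LOD bracket open above the tested range",
         call. = FALSE)
  }
  if (is.unsorted(as.integer(flags))) {
    stop("significance flags are not monotone in concentration; ",
         "no unambiguous bracket exists", call. = FALSE)
  }
  tibble::tibble(
    lower_eu_ml = max(levels$concentration_eu_ml[!flags]),
    upper_eu_ml = min(levels$concentration_eu_ml[flags])
  )
}

#' Convert endotoxin activity to mass concentration
#'
#' For this LPS preparation 10 EU corresponds to 1 ng, so ng/ml =
#' EU/ml / 10.
#'
#' @param concentration_eu_ml Concentration(s) in EU/ml (>= 0).
#' @return Concentration(s) in ng/ml.
#' @export
#' @examples
#' eu_to_ng(500) # 50
eu_to_ng <- function(concentration_eu_ml) {
  if (any(concentration_eu_ml < 0)) {
    stop("concentration must be non-negative", call. = FALSE)
  }
  concentration_eu_ml / 10
}

#' Compare RG values between groups
#'
#' Two groups: two-sided Student's t test (pooled variance by default,
#' Welch by flag). Three or more: one-way ANOVA. Significance is judged
#' at `alpha`.
#'
#' @param data Data frame with columns `value` and `group`, or a list of
#'   numeric vectors (optionally named).
#' @param mode `"auto"` (choose by number of groups), `"two-sample"`, or
#'   `"multi"`.
#' @param var_equal Pooled-variance t test (default TRUE).
#' @param alpha Significance level for the `significant` flag.
#' @return A `group_comparison`: list with `test_name`, `statistic`,
#'   `p_value`, `df`, `group_labels`, `significant`.
#' @export
compare_groups <- function(data, mode = c("auto", "two-sample", "multi"),
                           var_equal = TRUE, alpha = 0.05) {
  mode <- match.arg(mode)
  if (is.list(data) && !is.data.frame(data)) {
    labs <- names(data)
    if (is.null(labs)) labs <- paste0("group", seq_along(data))
    data <- tibble::tibble(
      value = unlist(data, use.names = FALSE),
      group = rep(labs, lengths(data))
    )
  }
  stopifnot(is.data.frame(data), all(c("value", "group") %in% names(data)))
  data$group <- factor(data$group)
  sizes <- table(data$group)
  if (any(sizes < 2)) stop("each group needs n >= 2", call. = FALSE)
  k <- nlevels(data$group)
  if (mode == "two-sample" && k != 2) {
    stop("two-sample mode requires exactly 2 groups", call. = FALSE)
  }
  if (mode == "auto") mode <- if (k == 2) "two-sample" else "multi"

  if (mode == "two-sample") {
    splitv <- split(data$value, data$group)
    if (all(vapply(splitv, stats::sd, numeric(1)) == 0)) {
      stop("degenerate variance: both groups are constant; ",
           "the t statistic is undefined", call. = FALSE)
    }
    ht <- stats::t.test(value ~ group, data = data, var.equal = var_equal)
    res <- list(test_name = ifelse(var_equal, "Student t (pooled)", "Welch t"),
                statistic = unname(ht$statistic),
                p_value = ht$p.value,
                df = unname(ht$parameter))
  } else {
    if (k < 3) stop("multi mode requires at least 3 groups", call. = FALSE)
    fit <- stats::aov(value ~ group, data = data)
    tab <- summary(fit)[[1]]
    res <- list(test_name = "one-way ANOVA",
                statistic = tab[["F value"]][1],
                p_value = tab[["Pr(>F)"]][1],
                df = unname(tab[["Df"]]))
  }
  res$group_labels <- levels(data$group)
  res$alpha <- alpha
  res$significant <- is.finite(res$p_value) && res$p_value < alpha
  class(res) <- "group_comparison"
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<%s: statistic = %.4g, p = %.4g%s>\n", x$test_name,
              x$statistic, x$p_value,
              if (x$significant) sprintf(" (significant at %.2g)", x$alpha) else ""))
  invisible(x)
}
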