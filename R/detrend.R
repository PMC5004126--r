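#' Detrending configuration
#'
#' Each series is split into a slowly varying seasonal baseline and a
#' high-frequency residual (the "~" series) by a sharp Fourier low-pass
#' filter: spectral bins with period shorter than `cutoff_period` days are
#' zeroed, bins with period greater than or equal to the cutoff (and the DC
#' term) are kept. Reactive variables (rainfall, discharge) get a zero
#' baseline so their residual is the raw series.
#'
#' @param cutoff_period Low-pass cutoff, days (default 50).
#' @param zero_baseline_variables Column names whose baseline is identically
#'   zero.
#' @param gapfill `"linear"` or `"mean"`: how missing values are filled
#'   before the transform (the residual is re-masked afterwards, so
#'   downstream statistics never see imputed values).
#' @param per_segment Transform each contiguous segment separately
#'   (default TRUE; a record with a winter hole would corrupt a joint
#'   transform).
#' @return A `detrend_config` object.
#' @export
detrend_config <- function(cutoff_period = 50,
                           zero_baseline_variables = c("rain", "q13", "q18"),
                           gapfill = c("linear", "mean"),
                           per_segment = TRUE) {
  gapfill <- match.arg(gapfill)
  if (cutoff_period <= 0) stop("cutoff_period must be > 0")
  structure(list(cutoff_period = cutoff_period,
                 zero_baseline_variables = zero_baseline_variables,
                 gapfill = gapfill, per_segment = per_segment),
            class = "detrend_config")
}

fill_gaps <- function(x, how) {
  m <- is.na(x)
  if (!any(m)) return(x)
  if (all(m)) stop("all-missing series")
  if (how == "mean") {
    x[m] <- mean(x[!m])
  } else {
    idx <- which(!m)
    x <- stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
  }
  x
}

#' Fourier low-pass seasonal baseline of one series
#'
#' Missing values are gap-filled, the secant through the two endpoints is
#' removed (it is re-attributed to the baseline; this suppresses the
#' wrap-around discontinuity a brick-wall DFT filter would otherwise leak
#' into the interior), the DFT is taken, all bins with period strictly below
#' the cutoff are zeroed, and the inverse transform plus the secant is
#' returned. The baseline is defined at every point, including originally
#' missing ones.
#'
#' @param x Numeric series on a uniform grid, `NA` for missing.
#' @param dt_minutes Sampling interval, minutes.
#' @param cutoff_period Cutoff, days.
#' @param gapfill `"linear"` or `"mean"`.
#' @return Baseline series, same length as `x`.
#' @export
fourier_lowpass_baseline <- function(x, dt_minutes, cutoff_period = 50,
                                     gapfill = "linear") {
  n <- length(x)
  if (n < 8L) stop("series too short (need >= 8 samples)")
  xf <- fill_gaps(x, gapfill)
  span_days <- n * dt_minutes / 1440
  if (span_days < 2 * cutoff_period)
    warning("record spans fewer than two cutoff periods; ",
            "baseline degenerates towards the mean")
  # secant through the endpoints, attributed to the (low-frequency) baseline
  chord <- xf[1L] + (xf[n] - xf[1L]) * (seq_len(n) - 1) / (n - 1)
  y <- xf - chord
  kmax <- floor(n * dt_minutes / (cutoff_period * 1440))  # period >= cutoff
  keep <- rep(FALSE, n)
  keep[1L] <- TRUE                       # DC
  if (kmax >= 1L) {
    k <- seq_len(min(kmax, floor((n - 1) / 2)))
    keep[1L + k] <- TRUE
    keep[n + 1L - k] <- TRUE
  }
  Fy <- stats::fft(y)
  Fy[!keep] <- 0
  chord + Re(stats::fft(Fy, inverse = TRUE)) / n
}

#' Detrend every column of a sensor table
#'
#' Applies [fourier_lowpass_baseline()] per variable (and per contiguous
#' segment when configured); variables listed in
#' `config$zero_baseline_variables` get a zero baseline. At every non-missing
#' point `baseline + residual == raw` exactly; the residual is missing
#' wherever the raw value is missing.
#'
#' @param x A [timetable] on a uniform grid (per segment).
#' @param config A [detrend_config].
#' @return A `detrend_result`: list with `baseline` and `residual`
#'   [timetable]s (residual column names carry a `~` suffix) and the config.
#' @export
detrend_table <- function(x, config = detrend_config()) {
  stopifnot(inherits(x, "timetable"))
  unknown <- setdiff(config$zero_baseline_variables, names(x$data))
  if (length(unknown) > 0L)
    stop("unknown variable(s) in zero_baseline_variables: ",
         paste(unknown, collapse = ", "))
  seg <- if (config$per_segment) tt_segments(x) else rep(1L, length(x$time))
  dt <- tt_dt_minutes(x)
  base <- x$data
  for (nm in names(x$data)) {
    if (nm %in% config$zero_baseline_variables) {
      base[[nm]] <- rep(0, nrow(base))
    } else {
      b <- numeric(nrow(base))
      for (s in unique(seg)) {
        i <- which(seg == s)
        b[i] <- fourier_lowpass_baseline(x$data[[nm]][i], dt,
                                         config$cutoff_period, config$gapfill)
      }
      base[[nm]] <- b
    }
  }
  resid <- x$data - base            # NA wherever raw is NA
  baseline_tt <- timetable(x$time, base)
  residual_tt <- timetable(x$time, stats::setNames(resid, paste0(names(resid), "~")))
  structure(list(baseline = baseline_tt, residual = residual_tt,
                 config = config), class = "detrend_result")
}

#' @export
print.detrend_result <- function(x, ...) {
  cat(sprintf("<detrend_result> %d variables, cutoff %g days, zero-baseline: %s\n",
              ncol(x$residual$data), x$config$cutoff_period,
              paste(x$config$zero_baseline_variables, collapse = ", ")))
  invisible(x)
}

#' Extract one residual series from a detrend result
#' @param x A `detrend_result`.
#' @param variable Raw variable name (without the `~` suffix).
#' @return Numeric vector with `NA` at missing points.
#' @export
residual_series <- function(x, variable) {
  nm <- paste0(variable, "~")
  if (!nm %in% names(x$residual$data)) stop("no residual column for ", variable)
  x$residual$data[[nm]]
}
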