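#' Gaussian mixture specification for the nitrate residual
#'
#' Describes the marginal distribution of the high-frequency nitrate residual
#' as a weighted sum of Gaussian components, plus the persistence of the
#' hidden concentration mode from one 15-min step to the next. The defaults
#' are the three-mode decomposition of the residual reported for the
#' Vollnkirchener Bach record: low / typical / high concentration modes with
#' weights 5/89/6%, means (-0.59, 0.0053, 0.46) and SDs (0.23, 0.21, 0.26)
#' in detrended mg/l.
#'
#' @param weights Component probabilities, summing to 1.
#' @param means Component means, residual concentration units.
#' @param sds Component SDs, > 0.
#' @param self_transition Mode persistence per time step, in `[0, 1)`:
#'   the stationary-weighted mean probability of staying in the current mode.
#' @return A `mixture_spec` object.
#' @export
mixture_spec <- function(weights = c(0.05, 0.89, 0.06),
                         means = c(-0.59, 0.0053, 0.46),
                         sds = c(0.23, 0.21, 0.26),
                         self_transition = 0.995) {
  if (length(weights) != length(means) || length(means) != length(sds))
    stop("weights, means and sds must have equal length")
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
  if (any(weights <= 0)) stop("weights must be positive")
  if (any(sds <= 0)) stop("sds must be > 0")
  if (self_transition < 0 || self_transition >= 1)
    stop("self_transition must be in [0, 1)")
  structure(list(weights = weights, means = means, sds = sds,
                 self_transition = self_transition), class = "mixture_spec")
}

#' Seasonal baseline specification
#'
#' Slowly varying deterministic baseline of a sensor variable:
#' `mean_level + amplitude * sin(2*pi*(t - phase)/period) + trend * t`
#' with `t` in days since the start of the record.
#'
#' @param amplitude Variable units.
#' @param period Days, > 0 (default one year).
#' @param phase Days.
#' @param trend Variable units per day.
#' @param mean_level Variable units.
#' @return A `seasonal_spec` object.
#' @export
seasonal_spec <- function(amplitude = 0, period = 365, phase = 0, trend = 0,
                          mean_level = 0) {
  if (period <= 0) stop("period must be > 0")
  structure(list(amplitude = amplitude, period = period, phase = phase,
                 trend = trend, mean_level = mean_level),
            class = "seasonal_spec")
}

eval_seasonal <- function(spec, t_days) {
  if (is.null(spec)) return(rep(0, length(t_days)))
  spec$mean_level + spec$amplitude * sin(2 * pi * (t_days - spec$phase) / spec$period) +
    spec$trend * t_days
}

#' Covariate specification for the synthetic generator
#'
#' A covariate is its seasonal baseline plus a per-mode additive shift plus
#' stationary AR(1) noise; `seasonal = NULL` means a zero baseline (reactive
#' variables such as rainfall and discharge). `nonneg = TRUE` rectifies the
#' series at zero.
#'
#' @param name Column identifier.
#' @param seasonal A [seasonal_spec] or NULL for a zero baseline.
#' @param mode_shifts Additive offset per mixture component, variable units.
#' @param noise_sd Stationary SD of the AR(1) noise, >= 0.
#' @param ar1_coeff AR(1) coefficient in `[0, 1)`.
#' @param nonneg Rectify the generated series at zero.
#' @return A `variable_spec` object.
#' @export
variable_spec <- function(name, seasonal = NULL, mode_shifts = c(0, 0, 0),
                          noise_sd = 1, ar1_coeff = 0.3, nonneg = FALSE) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (ar1_coeff < 0 || ar1_coeff >= 1) stop("ar1_coeff must be in [0, 1)")
  structure(list(name = name, seasonal = seasonal, mode_shifts = mode_shifts,
                 noise_sd = noise_sd, ar1_coeff = ar1_coeff, nonneg = nonneg),
            class = "variable_spec")
}

#' Missingness specification
#' @param missing_fraction Probability that any data cell is masked,
#'   in `[0, 1)`. Default 4%, the aggregate missingness of the study record.
#' @param seed Optional separate seed for the mask draw.
#' @return A `gap_spec` object.
#' @export
gap_spec <- function(missing_fraction = 0.04, seed = NULL) {
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("missing_fraction must be in [0, 1)")
  structure(list(missing_fraction = missing_fraction, seed = seed),
            class = "gap_spec")
}

#' Default two-season segment layout
#'
#' Two contiguous 15-min blocks mirroring the study's growing seasons:
#' 15,475 rows from 2013-03-05 12:45 and 16,721 rows from 2014-04-27 00:00
#' (32,196 rows in total).
#' @param dt_minutes Sampling interval.
#' @return List of segments, each `list(start = POSIXct, n = rows)`.
#' @export
default_segments <- function(dt_minutes = 15) {
  list(list(start = as.POSIXct("2013-03-05 12:45", tz = "UTC"), n = 15475L),
       list(start = as.POSIXct("2014-04-27 00:00", tz = "UTC"), n = 16721L))
}

#' Default 14-variable sensor roster
#'
#' Nitrate (`NO3`) plus 13 covariates named after the study's monitoring
#' network: discharge and water temperature at two gauges (q13/q18,
#' Wt13/Wt18), groundwater depth at three wells (GW3 lowland, GW25 hillslope,
#' GW32 riparian), air/soil temperature (At47/St24), soil moisture
#' (Smoist24), solar radiation (Sol71), rainfall intensity (rain) and
#' electric conductivity (Con47). Mode shifts encode the reported
#' directionality: the low mode has a shallower riparian water table, wetter
#' soil, lower radiation and conductivity; the high mode sits on hydrological
#' recession (lower discharge, deeper lowland water table, slightly wetter
#' soil than typical); rainfall has zero shift (no mode coupling). The
#' typical and high modes share the GW32 level so that contrast is null.
#'
#' @return Named list of [variable_spec]s, `NO3` first.
#' @export
default_variable_specs <- function() {
  sp <- list(
    variable_spec("NO3", seasonal_spec(1.2, 365, 80, 0, 4.5)),
    variable_spec("q13", NULL, c(0, 0, -2), 2, 0.3, nonneg = TRUE),
    variable_spec("q18", NULL, c(0, 0, -1), 1, 0.3, nonneg = TRUE),
    variable_spec("Wt13", seasonal_spec(6, 365, 110, 0, 10), c(0, 0, 0), 0.4),
    variable_spec("Wt18", seasonal_spec(6, 365, 110, 0, 9.5), c(0, 0, 0), 0.4),
    variable_spec("GW3", seasonal_spec(0.3, 365, 170, 0, 1.8), c(0, 0, 0.03), 0.05),
    variable_spec("GW25", seasonal_spec(0.6, 365, 170, 0, 3.5), c(0, 0, 0), 0.05),
    variable_spec("GW32", seasonal_spec(0.05, 365, 170, 0, 0.6), c(-0.04, 0, 0), 0.02),
    variable_spec("At47", seasonal_spec(9, 365, 110, 0, 9), c(0, 0, 0), 1.5),
    variable_spec("St24", seasonal_spec(6, 365, 120, 0, 8), c(0, 0, 0), 0.3),
    variable_spec("Smoist24", seasonal_spec(0.05, 365, 330, 0, 0.32),
                  c(0.02, 0, 0.005), 0.01),
    variable_spec("Sol71", seasonal_spec(120, 365, 110, 0, 180),
                  c(-40, 0, 0), 60, 0.3, nonneg = TRUE),
    variable_spec("rain", NULL, c(0, 0, 0), 0.5, 0.3, nonneg = TRUE),
    variable_spec("Con47", seasonal_spec(30, 365, 200, 0, 450), c(-20, 0, 0), 15)
  )
  names(sp) <- vapply(sp, `[[`, "", "name")
  sp
}

#' Mode transition matrix with a prescribed stationary distribution
#'
#' Constructs the Markov transition matrix
#' `P = (1 - r) I + r 1 w'` with `r = (1 - self_transition) / (1 - sum(w^2))`,
#' whose rows sum to 1, whose off-diagonal mass in every row is proportional
#' to the target weights, and whose stationary distribution is exactly `w`
#' for any admissible `r`. `self_transition` is the stationary-weighted mean
#' of the diagonal. For skewed weights and small `self_transition` the
#' implied diagonal can go negative, which is a configuration error.
#'
#' @param weights Target stationary probabilities (sum to 1).
#' @param self_transition Mean self-transition probability in `[0, 1)`.
#' @return A `K x K` transition matrix.
#' @export
stationary_transition <- function(weights, self_transition) {
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
  if (self_transition < 0 || self_transition >= 1)
    stop("self_transition must be in [0, 1)")
  r <- (1 - self_transition) / (1 - sum(weights^2))
  P <- (1 - r) * diag(length(weights)) +
    r * matrix(weights, length(weights), length(weights), byrow = TRUE)
  if (any(P < 0))
    stop("self_transition ", self_transition,
         " is incompatible with these weights (negative transition entries)")
  P
}

# Exact simulation of the (1-r)I + r 1w' chain: at each step redraw the state
# from w with probability r, else keep it. The first state is stationary.
simulate_mode_chain <- function(n, weights, self_transition) {
  r <- (1 - self_transition) / (1 - sum(weights^2))
  stationary_transition(weights, self_transition)  # validates admissibility
  redraw <- c(TRUE, stats::runif(n - 1L) < r)
  grp <- cumsum(redraw)
  states <- sample.int(length(weights), max(grp), replace = TRUE, prob = weights)
  states[grp]
}

#' Draw an i.i.d. sample from a mixture specification
#'
#' @param n Sample size.
#' @param spec A [mixture_spec] (or a fitted [em_fit] result).
#' @param labels Also return the component labels.
#' @return Numeric vector, or `list(x, labels)` when `labels = TRUE`.
#' @export
sample_mixture <- function(n, spec = mixture_spec(), labels = FALSE) {
  k <- sample.int(length(spec$weights), n, replace = TRUE, prob = spec$weights)
  x <- stats::rnorm(n, spec$means[k], spec$sds[k])
  if (labels) list(x = x, labels = k) else x
}

# Stationary AR(1) noise with marginal SD `sd`: e1 ~ N(0, sd^2),
# e_t = rho * e_{t-1} + sd * sqrt(1 - rho^2) * z_t.
ar1_noise <- function(n, sd, rho) {
  if (sd == 0) return(numeric(n))
  z <- stats::rnorm(n)
  if (rho == 0) return(z * sd)
  sd * as.numeric(stats::filter(c(z[1L], z[-1L] * sqrt(1 - rho^2)), rho,
                                method = "recursive"))
}

#' Generate a synthetic multivariate sensor table
#'
#' Emulates the statistical structure the downstream analysis assumes: a
#' hidden concentration mode follows a first-order Markov chain whose
#' stationary distribution equals the mixture weights; the nitrate analogue
#' is its seasonal baseline plus a Gaussian draw from the current mode's
#' component; every covariate is its baseline plus a per-mode shift plus
#' AR(1) noise; cells are then masked i.i.d. at the requested missingness.
#'
#' @param mixture A [mixture_spec].
#' @param variables Named list of [variable_spec]s; must contain
#'   `nitrate_var`.
#' @param segments List of `list(start = POSIXct, n = rows)` blocks
#'   (non-overlapping, in order); see [default_segments()].
#' @param gaps A [gap_spec].
#' @param seed Integer seed; same seed, same table bit for bit.
#' @param dt_minutes Sampling interval.
#' @param nitrate_var Name of the nitrate analogue column.
#' @return A [timetable] with one column per variable and, as attribute
#'   `mode_labels`, the hidden ground-truth mode index per row.
#' @export
generate_sensor_table <- function(mixture = mixture_spec(),
                                  variables = default_variable_specs(),
                                  segments = default_segments(),
                                  gaps = gap_spec(),
                                  seed = 1L,
                                  dt_minutes = 15,
                                  nitrate_var = "NO3") {
  K <- length(mixture$weights)
  if (!nitrate_var %in% names(variables))
    stop("no variable named as the nitrate analogue: ", nitrate_var)
  for (v in variables)
    if (length(v$mode_shifts) != K)
      stop("variable ", v$name, ": mode_shifts must have one entry per mixture component")
  ns <- vapply(segments, function(s) as.integer(s$n), 1L)
  if (any(ns <= 0L)) stop("zero-length segment")
  set.seed(as.integer(seed))

  times <- do.call(c, lapply(segments, function(s)
    s$start + seq(0, by = dt_minutes * 60, length.out = s$n)))
  if (any(diff(as.numeric(times)) <= 0)) stop("segments overlap or are out of order")
  epoch <- as.numeric(times[1L])
  t_days <- (as.numeric(times) - epoch) / 86400
  n <- length(times)

  lab <- unlist(lapply(ns, simulate_mode_chain,
                       weights = mixture$weights,
                       self_transition = mixture$self_transition))
  cols <- vector("list", length(variables))
  names(cols) <- names(variables)
  for (nm in names(variables)) {
    v <- variables[[nm]]
    base <- eval_seasonal(v$seasonal, t_days)
    if (nm == nitrate_var) {
      val <- base + stats::rnorm(n, mixture$means[lab], mixture$sds[lab])
    } else {
      noise <- unlist(lapply(ns, function(m)
        ar1_noise(m, v$noise_sd, v$ar1_coeff)))
      val <- base + v$mode_shifts[lab] + noise
    }
    if (v$nonneg) val <- pmax(val, 0)
    cols[[nm]] <- val
  }
  dat <- as.data.frame(cols, check.names = FALSE)
  if (gaps$missing_fraction > 0) {
    if (!is.null(gaps$seed)) set.seed(as.integer(gaps$seed))
    mask <- matrix(stats::runif(n * ncol(dat)) < gaps$missing_fraction,
                   n, ncol(dat))
    dat[mask] <- NA_real_
  }
  out <- timetable(times, dat)
  attr(out, "mode_labels") <- lab
  attr(out, "nitrate_var") <- nitrate_var
  out
}
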