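#' Time-stamped multivariate sensor table
#'
#' A `timetable` is the exchange object of the package: an ordered vector of
#' POSIXct timestamps on a fixed sampling grid (possibly split into contiguous
#' segments separated by larger gaps, e.g. a winter hole between two growing
#' seasons) plus one numeric column per sensor variable. Missing cells are
#' `NA`; the missingness mask is therefore `is.na()` of the data columns.
#'
#' @param time POSIXct vector, strictly increasing.
#' @param data data.frame of numeric columns, one row per timestamp.
#' @return An object of class `timetable`.
#' @export
timetable <- function(time, data) {
  if (!inherits(time, "POSIXct")) stop("`time` must be POSIXct")
  data <- as.data.frame(data)
  if (nrow(data) != length(time))
    stop("`data` must have one row per timestamp")
  if (length(time) > 1L) {
    dt <- diff(as.numeric(time))
    if (any(dt < 0)) stop("timestamps must be non-decreasing")
    if (any(dt == 0))
      stop("duplicate timestamp at ", format(time[which(dt == 0)[1L] + 1L]))
  }
  structure(list(time = time, data = data), class = "timetable")
}

#' @export
print.timetable <- function(x, ...) {
  cat(sprintf("<timetable> %d rows x %d variables, dt = %g min, %d segment(s)\n",
              nrow(x$data), ncol(x$data), tt_dt_minutes(x),
              max(tt_segments(x))))
  cat("  span:", format(x$time[1L]), "..", format(x$time[length(x$time)]), "\n")
  cat("  variables:", paste(names(x$data), collapse = ", "), "\n")
  miss <- mean(is.na(as.matrix(x$data)))
  cat(sprintf("  missing cells: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.timetable <- function(x) c(length(x$time), ncol(x$data))

#' Sampling interval of a timetable in minutes
#'
#' The modal (most common) spacing between consecutive timestamps; gaps wider
#' than this are treated as segment breaks.
#' @param x A `timetable`.
#' @return Numeric scalar, minutes.
#' @export
tt_dt_minutes <- function(x) {
  if (length(x$time) < 2L) return(NA_real_)
  d <- diff(as.numeric(x$time)) / 60
  as.numeric(names(sort(table(d), decreasing = TRUE))[1L])
}

#' Contiguous-segment index of each row
#'
#' Rows whose predecessor is more than one sampling interval away start a new
#' segment. Used by the detrender to transform each season separately.
#' @param x A `timetable`.
#' @return Integer vector of segment ids (1-based), one per row.
#' @export
tt_segments <- function(x) {
  n <- length(x$time)
  if (n < 2L) return(rep(1L, n))
  dt <- tt_dt_minutes(x) * 60
  brk <- diff(as.numeric(x$time)) > dt * 1.5
  c(1L, 1L + cumsum(brk))
}

#' Missingness mask of a timetable
#' @param x A `timetable`.
#' @return Logical matrix, TRUE where the cell is missing.
#' @export
tt_mask <- function(x) is.na(as.matrix(x$data))

#' Read a sensor table from CSV
#'
#' First column (or `timestamp_column`) holds ISO 8601 timestamps; remaining
#' columns are numeric. Empty or unparseable numeric cells become missing and
#' their count is reported. Non-monotone or duplicated timestamps are input
#' errors (the first offending timestamp is named).
#'
#' @param path CSV file path.
#' @param timestamp_column Name of the timestamp column (default: first).
#' @param sep,dec Field and decimal separators.
#' @return A [timetable].
#' @export
read_timetable <- function(path, timestamp_column = NULL, sep = ",", dec = ".") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL)
  if (is.null(timestamp_column)) timestamp_column <- names(raw)[1L]
  if (!timestamp_column %in% names(raw))
    stop("timestamp column not found: ", timestamp_column)
  tstr <- raw[[timestamp_column]]
  time <- as.POSIXct(tstr, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                    "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                    "%Y-%m-%d"))
  if (anyNA(time))
    stop("unparseable timestamp: ", tstr[which(is.na(time))[1L]])
  d <- diff(as.numeric(time))
  if (any(d < 0))
    stop("non-monotone timestamps at ", tstr[which(d < 0)[1L] + 1L])
  if (any(d == 0))
    stop("duplicate timestamp at ", tstr[which(d == 0)[1L] + 1L])
  vals <- raw[setdiff(names(raw), timestamp_column)]
  n_bad <- 0L
  vals[] <- lapply(vals, function(col) {
    num <- suppressWarnings(as.numeric(col))
    bad <- is.na(num) & !(col %in% c("", "NA"))
    n_bad <<- n_bad + sum(bad)
    num
  })
  if (n_bad > 0L)
    message(n_bad, " unparseable numeric cell(s) set to missing")
  timetable(time, vals)
}

#' Write a sensor table to CSV
#'
#' Timestamps are ISO 8601; missing cells are written empty. Numeric values
#' are written with round-trip (17 significant digit) precision so that
#' `read_timetable(write_timetable(x))` reproduces `x` exactly.
#'
#' @param x A [timetable].
#' @param path Output path.
#' @param extra Optional data.frame of extra columns (e.g. a ground-truth
#'   `_mode` label column) appended after the data columns.
#' @return `path`, invisibly.
#' @export
write_timetable <- function(x, path, extra = NULL) {
  stopifnot(inherits(x, "timetable"))
  fmt_num <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  out <- data.frame(timestamp = format(x$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (nm in names(x$data)) out[[nm]] <- fmt_num(x$data[[nm]])
  if (!is.null(extra))
    for (nm in names(extra)) out[[nm]] <- as.character(extra[[nm]])
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cadence alignment policy
#'
#' How to bring a heterogeneous-cadence series onto the analysis grid.
#' Aggregation uses half-open intervals `[t, t + dt)` stamped at `t`.
#'
#' @param target_dt Target sampling interval, minutes.
#' @param aggregator One of `"mean"`, `"last"`, `"linear"`
#'   (linear interpolation).
#' @param max_fill_gap For `"linear"`: widest source gap (minutes) across
#'   which interpolation is allowed; beyond it cells stay missing.
#' @return An `alignment_policy` object.
#' @export
alignment_policy <- function(target_dt = 15, aggregator = c("mean", "last", "linear"),
                             max_fill_gap = 180) {
  aggregator <- match.arg(aggregator)
  stopifnot(target_dt > 0, max_fill_gap >= 0)
  structure(list(target_dt = target_dt, aggregator = aggregator,
                 max_fill_gap = max_fill_gap), class = "alignment_policy")
}

#' Align a sensor table onto a uniform grid
#'
#' Output timestamps run from the floor of the first observation (to a
#' multiple of `target_dt` minutes) to the last observation. With
#' `aggregator = "mean"` (or `"last"`) every source point is assigned to the
#' half-open interval `[t, t + dt)`; intervals containing no source point are
#' missing. With `"linear"`, grid values are interpolated from the bracketing
#' non-missing source points unless those are more than `max_fill_gap` minutes
#' apart.
#'
#' @param x A [timetable].
#' @param policy An [alignment_policy].
#' @return A [timetable] on the uniform target grid.
#' @export
align <- function(x, policy = alignment_policy()) {
  stopifnot(inherits(x, "timetable"), inherits(policy, "alignment_policy"))
  if (length(x$time) == 0L) stop("empty table")
  dt <- policy$target_dt * 60
  t0 <- floor(as.numeric(x$time[1L]) / dt) * dt
  t1 <- as.numeric(x$time[length(x$time)])
  grid <- seq(t0, t1, by = dt)
  src_t <- as.numeric(x$time)
  idx <- findInterval(src_t, grid)  # interval [grid[i], grid[i+1])
  out <- lapply(x$data, function(v) {
    res <- rep(NA_real_, length(grid))
    if (policy$aggregator == "mean") {
      ok <- !is.na(v)
      if (any(ok)) {
        agg <- tapply(v[ok], idx[ok], mean)
        res[as.integer(names(agg))] <- as.numeric(agg)
      }
    } else if (policy$aggregator == "last") {
      ok <- !is.na(v)
      if (any(ok)) {
        agg <- tapply(v[ok], idx[ok], function(z) z[length(z)])
        res[as.integer(names(agg))] <- as.numeric(agg)
      }
    } else {
      ok <- which(!is.na(v))
      if (length(ok) >= 2L) {
        ap <- stats::approx(src_t[ok], v[ok], xout = grid, rule = 1)
        res <- ap$y
        # re-blank grid points whose bracketing source points are too far apart
        lo <- findInterval(grid, src_t[ok])
        gap_ok <- rep(FALSE, length(grid))
        inside <- lo >= 1L & lo < length(ok)
        gw <- src_t[ok][pmin(lo + 1L, length(ok))] - src_t[ok][pmax(lo, 1L)]
        gap_ok[inside] <- gw[inside] <= policy$max_fill_gap * 60
        on_src <- grid %in% src_t[ok]
        res[!(gap_ok | on_src)] <- NA_real_
      } else if (length(ok) == 1L && src_t[ok] %in% grid) {
        res[match(src_t[ok], grid)] <- v[ok]
      }
    }
    res
  })
  timetable(as.POSIXct(grid, tz = "UTC", origin = "1970-01-01"),
            as.data.frame(out, check.names = FALSE))
}
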