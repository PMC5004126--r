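#' Group a covariate's residual by the synchronous nitrate mode
#'
#' Every non-missing residual value of `variable` is placed in the class of
#' the synchronous nitrate label; rows where the nitrate label is missing
#' are dropped.
#'
#' @param assignment A `class_assignment` from [classify()], one label per
#'   row of the residual table.
#' @param residuals A `detrend_result` (or a [timetable] of residuals).
#' @param variable Variable name, with or without the `~` suffix.
#' @return Named list of numeric samples, one per class.
#' @export
group_by_mode <- function(assignment, residuals, variable) {
  tt <- if (inherits(residuals, "detrend_result")) residuals$residual else residuals
  nm <- if (variable %in% names(tt$data)) variable else paste0(variable, "~")
  if (!nm %in% names(tt$data)) stop("no residual column for ", variable)
  v <- tt$data[[nm]]
  if (length(v) != length(assignment$labels))
    stop("assignment and residuals are on different grids (",
         length(assignment$labels), " vs ", length(v), " rows)")
  keep <- !is.na(assignment$labels) & !is.na(v)
  split(v[keep], factor(assignment$class_names[assignment$labels[keep]],
                        levels = assignment$class_names))
}

#' Welch two-sample t-test
#'
#' `t = (mean_a - mean_b) / sqrt(s_a^2/n_a + s_b^2/n_b)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value; valid for
#' unequal sample sizes and unequal variances.
#'
#' @param a,b Numeric samples (each of size >= 2 with positive variance).
#' @return A `welch_test`: `t_stat`, `df`, `p_raw`, group means/SDs/sizes.
#' @export
welch_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  for (nm in c("a", "b")) {
    s <- get(nm)
    if (length(s) < 2L) stop("group ", nm, " has fewer than 2 observations")
    if (stats::var(s) <= 0) stop("group ", nm, " has zero variance")
  }
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(list(t_stat = t_stat, df = df, p_raw = p,
                 mean_a = mean(a), mean_b = mean(b),
                 sd_a = stats::sd(a), sd_b = stats::sd(b),
                 n_a = length(a), n_b = length(b)),
            class = "welch_test")
}

#' Pairwise mode comparison of environmental covariates
#'
#' For every variable, all pairwise class contrasts (low-typical, low-high,
#' typical-high for three modes) are tested with [welch_test()] and
#' Bonferroni-corrected: under the default `"global"` scope the multiplier is
#' `(number of class pairs) x (number of variables tested)`; `"per-variable"`
#' uses the number of class pairs only. A contrast is significant when the
#' corrected p-value is below `alpha`; pairs with an empty or degenerate
#' class are marked untestable rather than raising.
#'
#' @param groups Named list: per variable, the per-class sample list from
#'   [group_by_mode()].
#' @param alpha Significance level on the corrected p-value (default 0.01).
#' @param correction_scope `"global"` or `"per-variable"`.
#' @return A `comparison_table` data.frame: variable, pair, group sizes,
#'   means, SDs, `t_stat`, `df`, `p_raw`, `p_corrected`, `significant`,
#'   `untestable`.
#' @export
build_comparison <- function(groups, alpha = 0.01,
                             correction_scope = c("global", "per-variable")) {
  correction_scope <- match.arg(correction_scope)
  if (length(groups) == 0L) stop("no variables to compare")
  cls <- names(groups[[1L]])
  if (sum(vapply(groups[[1L]], length, 1L) > 0L) < 2L)
    stop("need at least 2 non-empty classes")
  pairs <- utils::combn(cls, 2L)
  n_pairs <- ncol(pairs)
  m <- if (correction_scope == "global") n_pairs * length(groups) else n_pairs
  rows <- list()
  for (v in names(groups)) {
    g <- groups[[v]]
    for (j in seq_len(n_pairs)) {
      c1 <- pairs[1L, j]; c2 <- pairs[2L, j]
      a <- g[[c1]]; b <- g[[c2]]
      testable <- length(a) >= 2L && length(b) >= 2L &&
        stats::var(a) > 0 && stats::var(b) > 0
      if (testable) {
        wt <- welch_test(a, b)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, pair = paste(c1, c2, sep = "-"),
          n_a = wt$n_a, n_b = wt$n_b, mean_a = wt$mean_a, mean_b = wt$mean_b,
          sd_a = wt$sd_a, sd_b = wt$sd_b, t_stat = wt$t_stat, df = wt$df,
          p_raw = wt$p_raw, p_corrected = min(1, m * wt$p_raw),
          significant = min(1, m * wt$p_raw) < alpha, untestable = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, pair = paste(c1, c2, sep = "-"),
          n_a = length(a), n_b = length(b), mean_a = NA_real_, mean_b = NA_real_,
          sd_a = NA_real_, sd_b = NA_real_, t_stat = NA_real_, df = NA_real_,
          p_raw = NA_real_, p_corrected = NA_real_,
          significant = FALSE, untestable = TRUE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "bonferroni_m") <- m
  attr(out, "correction_scope") <- correction_scope
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Render a comparison table in the one-row-per-variable layout
#'
#' Non-significant cells are the string `"n.s."`; significant cells carry the
#' corrected p-value; untestable cells are `"-"`.
#' @param x A `comparison_table`.
#' @return data.frame with one column per class pair.
#' @export
format_comparison <- function(x) {
  cell <- ifelse(x$untestable, "-",
                 ifelse(x$significant, sprintf("%.2g", x$p_corrected), "n.s."))
  out <- stats::reshape(data.frame(variable = x$variable, pair = x$pair,
                                   cell = cell),
                        idvar = "variable", timevar = "pair",
                        direction = "wide")
  names(out) <- sub("^cell\\.", "", names(out))
  rownames(out) <- NULL
  out
}

#' @export
print.comparison_table <- function(x, ...) {
  need <- c("variable", "pair", "untestable", "significant", "p_corrected")
  if (!all(need %in% names(x))) return(print.data.frame(x, ...))
  cat(sprintf("<comparison_table> alpha = %g, Bonferroni m = %d (%s scope)\n",
              attr(x, "alpha"), attr(x, "bonferroni_m"),
              attr(x, "correction_scope")))
  print(format_comparison(x), row.names = FALSE)
  invisible(x)
}

#' Write a comparison table as TSV
#' @param x A `comparison_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(x, path) {
  utils::write.table(format_comparison(x), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-class summary statistics and PDE curves
#'
#' For every variable and class: arithmetic mean, median, quartiles (linear
#' interpolation convention), 1.5 IQR whisker bounds (most extreme points
#' inside the fences), sample size, and the class-wise Pareto density curve.
#' Classes with fewer than 2 points report only mean and n.
#'
#' @param groups As for [build_comparison()].
#' @param with_pde Also compute a [pde_estimate()] per class (classes with
#'   >= 10 points only).
#' @return A `class_summary`: `table` data.frame plus `pde` (nested list,
#'   variable -> class -> `pde_curve`).
#' @export
class_summaries <- function(groups, with_pde = TRUE) {
  rows <- list()
  curves <- list()
  for (v in names(groups)) {
    for (cl in names(groups[[v]])) {
      s <- groups[[v]][[cl]]
      s <- s[is.finite(s)]
      if (length(s) == 0L) next
      if (length(s) < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, class = cl, n = length(s), mean = mean(s),
          q1 = NA_real_, median = NA_real_, q3 = NA_real_,
          whisker_lo = NA_real_, whisker_hi = NA_real_)
        next
      }
      q <- as.numeric(stats::quantile(s, c(0.25, 0.5, 0.75), type = 7))
      iqr <- q[3L] - q[1L]
      lo <- min(s[s >= q[1L] - 1.5 * iqr])
      hi <- max(s[s <= q[3L] + 1.5 * iqr])
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, class = cl, n = length(s), mean = mean(s),
        q1 = q[1L], median = q[2L], q3 = q[3L],
        whisker_lo = lo, whisker_hi = hi)
      if (with_pde && length(s) >= 10L && length(unique(s)) > 1L)
        curves[[v]][[cl]] <- pde_estimate(s)
    }
  }
  structure(list(table = do.call(rbind, rows), pde = curves),
            class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  cat("<class_summary>\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
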