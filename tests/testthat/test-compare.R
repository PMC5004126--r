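mk_assignment <- function(labels, K = 3) {
  structure(list(labels = labels,
                 class_names = c("low", "typical", "high")[seq_len(K)],
                 K = K), class = "class_assignment")
}
mk_residuals <- function(...) {
  d <- data.frame(...)
  timetable(grid15(nrow(d)), d)
}

test_that("group_by_mode partitions by the synchronous nitrate label", {
  asg <- mk_assignment(c(1L, 2L, 2L, 3L, NA, 1L))
  tt <- mk_residuals(`v~` = c(10, 20, 30, 40, 50, NA), check.names = FALSE)
  g <- group_by_mode(asg, tt, "v")
  expect_equal(g$low, 10)          # row 6 has a missing residual
  expect_equal(g$typical, c(20, 30))
  expect_equal(g$high, 40)         # row 5 has no nitrate label
  # all-typical labels leave the outer groups empty
  g2 <- group_by_mode(mk_assignment(rep(2L, 6)), tt, "v")
  expect_length(g2$low, 0)
  expect_length(g2$high, 0)
  expect_error(group_by_mode(mk_assignment(1:3), tt, "v"), "different grids")
  expect_error(group_by_mode(asg, tt, "nope"), "no residual column")
})

test_that("group sizes match classification rates from quadrature", {
  spec <- mixture_spec()
  set.seed(51)
  n <- 32196
  x <- sample_mixture(n, spec)
  asg <- classify(spec, x)
  b <- asg$boundaries
  # oracle: P(label = j) by integrating the mixture density over each region
  edges <- c(-Inf, b, Inf)
  p_class <- vapply(1:3, function(j)
    sum(spec$weights * (pnorm(edges[j + 1], spec$means, spec$sds) -
                        pnorm(edges[j], spec$means, spec$sds))), 1)
  freq <- tabulate(asg$labels, 3) / n
  expect_true(all(abs(freq - p_class) < 3 * sqrt(p_class * (1 - p_class) / n)))
})

test_that("welch_test reproduces the hand-computed example and t.test", {
  wt <- welch_test(1:5, 2:6)
  expect_equal(wt$t_stat, -1, tolerance = 1e-12)
  expect_equal(wt$df, 8, tolerance = 1e-12)
  expect_equal(wt$p_raw, 0.3466, tolerance = 1e-4)
  # identical samples: t = 0, p = 1
  wt0 <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(wt0$t_stat, 0)
  expect_equal(wt0$p_raw, 1)
  # antisymmetry
  set.seed(52)
  a <- rnorm(40); b <- rnorm(25, 0.5, 2)
  w1 <- welch_test(a, b); w2 <- welch_test(b, a)
  expect_equal(w1$t_stat, -w2$t_stat)
  expect_equal(w1$p_raw, w2$p_raw)
  # agreement with the stats::t.test oracle across random cases
  for (i in 1:10) {
    a <- rnorm(sample(5:50, 1), rnorm(1), runif(1, 0.5, 2))
    b <- rnorm(sample(5:50, 1), rnorm(1), runif(1, 0.5, 2))
    tt <- stats::t.test(a, b)
    wt <- welch_test(a, b)
    expect_equal(wt$t_stat, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(wt$df, unname(tt$parameter), tolerance = 1e-9)
    expect_equal(wt$p_raw, tt$p.value, tolerance = 1e-12)
  }
  # power: clearly separated large samples
  expect_lt(welch_test(rnorm(5000), rnorm(5000, 1))$p_raw, 1e-10)
  expect_error(welch_test(1, 1:5), "fewer than 2")
  expect_error(welch_test(c(2, 2, 2), 1:5), "zero variance")
})

test_that("Bonferroni correction and significance logic", {
  set.seed(53)
  g1 <- list(low = rnorm(30), typical = rnorm(40, 0.6), high = rnorm(35, 3))
  groups <- list(v1 = g1)
  cmp <- build_comparison(groups, alpha = 0.01, correction_scope = "per-variable")
  expect_equal(attr(cmp, "bonferroni_m"), 3L)       # one variable, 3 pairs
  # p_corrected = min(1, m * p_raw); never decreases; significant => raw < alpha
  expect_equal(cmp$p_corrected, pmin(1, 3 * cmp$p_raw))
  expect_true(all(cmp$p_corrected >= cmp$p_raw))
  expect_true(all(cmp$p_raw[cmp$significant] < 0.01))
  expect_equal(cmp$significant, cmp$p_corrected < 0.01)
  # the multiplication example: raw 0.004 with m = 3 -> 0.012 -> n.s. at 0.01
  expect_false(min(1, 3 * 0.004) < 0.01)
  # global scope multiplies by the number of variables as well
  cmp2 <- build_comparison(list(v1 = g1, v2 = g1), correction_scope = "global")
  expect_equal(attr(cmp2, "bonferroni_m"), 6L)
  expect_equal(cmp2$p_corrected, pmin(1, 6 * cmp2$p_raw))
})

test_that("empty classes are untestable, not fatal", {
  g <- list(v = list(low = numeric(0), typical = rnorm(20), high = rnorm(20, 1)))
  cmp <- build_comparison(g)
  expect_true(cmp$untestable[cmp$pair == "low-typical"])
  expect_true(cmp$untestable[cmp$pair == "low-high"])
  expect_false(cmp$untestable[cmp$pair == "typical-high"])
  fc <- format_comparison(cmp)
  expect_equal(fc$`low-typical`, "-")
  expect_error(build_comparison(list(v = list(low = numeric(0),
                                              typical = rnorm(5),
                                              high = numeric(0)))),
               "non-empty classes")
})

test_that("type-I error is nominal on null groups with iid noise", {
  # uncorrected tests at alpha = 0.01 on label-grouped pure noise
  set.seed(54)
  m <- 400
  hits <- 0L; total <- 0L
  for (i in seq_len(m)) {
    lab <- sample.int(3, 300, replace = TRUE, prob = c(0.2, 0.6, 0.2))
    v <- rnorm(300)
    g <- split(v, lab)
    for (pr in list(1:2, c(1, 3), 2:3)) {
      p <- welch_test(g[[pr[1]]], g[[pr[2]]])$p_raw
      hits <- hits + (p < 0.01); total <- total + 1L
    }
  }
  rate <- hits / total
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / total) + 0.003)
})

test_that("class summaries report boxplot statistics and class-wise PDE", {
  g <- list(v = list(low = c(1, 2, 3, 4, 5), typical = c(1, 2, 3, 4, 5),
                     high = c(7)))
  cs <- class_summaries(g, with_pde = FALSE)
  t1 <- cs$table[cs$table$class == "low", ]
  expect_equal(t1$median, 3)
  expect_equal(t1$q1, 2)
  expect_equal(t1$q3, 4)
  expect_equal(t1$whisker_lo, 1)
  expect_equal(t1$whisker_hi, 5)
  # identical samples give identical summaries
  t2 <- cs$table[cs$table$class == "typical", ]
  expect_equal(unlist(t1[-(1:2)]), unlist(t2[-(1:2)]), ignore_attr = TRUE)
  # n < 2: mean and n only
  t3 <- cs$table[cs$table$class == "high", ]
  expect_equal(t3$n, 1L)
  expect_equal(t3$mean, 7)
  expect_true(is.na(t3$median))
  # class-wise PDE curves appear for classes with enough points
  set.seed(55)
  g2 <- list(v = list(low = rnorm(200), typical = rnorm(300), high = rnorm(250)))
  cs2 <- class_summaries(g2)
  expect_s3_class(cs2$pde$v$low, "pde_curve")
})

test_that("class mean ordering follows the generator shifts for Sol71", {
  tab <- generate_sensor_table(seed = 6)
  det <- detrend_table(tab)
  asg <- classify(mixture_spec(), residual_series(det, "NO3"))
  g <- group_by_mode(asg, det, "Sol71")
  m <- vapply(g, mean, 1)
  expect_lt(m["low"], m["typical"])             # low mode: less radiation
  expect_lt(abs(m["typical"] - m["high"]), 15)  # typical ~ high
})
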