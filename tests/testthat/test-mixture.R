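test_that("K = 1 EM equals the closed-form Gaussian MLE", {
  set.seed(41)
  x <- rnorm(5000, 2, 1)
  fit <- em_fit(x, 1)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))        # MLE (1/n) variance
  expect_equal(fit$means, m, tolerance = 1e-9)
  expect_equal(fit$sds, s, tolerance = 1e-9)
  expect_equal(fit$weights, 1)
  expect_lt(abs(fit$means - 2), 3 / sqrt(5000))
  expect_lt(abs(fit$sds - 1), 0.05)
})

test_that("well-separated two-component means are recovered", {
  set.seed(42)
  x <- c(rnorm(1000, -3, 0.5), rnorm(1000, 3, 0.5))
  fit <- em_fit(x, 2, seed = 1)
  expect_lt(max(abs(fit$means - c(-3, 3))), 0.1)
  expect_lt(max(abs(fit$sds - 0.5)), 0.1)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(diff(fit$means) >= 0))   # sorted by mean
})

test_that("log-likelihood trace is monotone for plain and accelerated EM", {
  set.seed(43)
  for (rep in 1:20) {
    x <- c(rnorm(60, rnorm(1, 0, 2), runif(1, 0.5, 2)),
           rnorm(60, rnorm(1, 0, 2), runif(1, 0.5, 2)))
    for (acc in c(TRUE, FALSE)) {
      fit <- em_fit(x, 2, n_restarts = 1, max_iter = 200, accelerate = acc)
      expect_true(all(diff(fit$loglik_trace) >= -1e-7))
    }
  }
})

test_that("a user-defined start is honoured as-is and is deterministic", {
  set.seed(44)
  x <- c(rnorm(500, -1), rnorm(500, 1))
  init <- list(weights = c(0.5, 0.5), means = c(-1, 1), sds = c(1, 1))
  f1 <- em_fit(x, 2, init = init)
  f2 <- em_fit(x, 2, init = init)
  expect_identical(f1$means, f2$means)
  expect_error(em_fit(x, 2, init = list(weights = 1, means = 0, sds = 1)),
               "length K")
  expect_error(em_fit(rnorm(5), 2), "n > 3K")
})

test_that("select_k picks the right order on easy cases", {
  set.seed(45)
  sel1 <- select_k(rnorm(5000), 1, 4, "both", n_restarts = 2, tol = 1e-7)
  expect_equal(sel1$chosen_K, 1L)
  expect_true(sel1$agree)
  x2 <- c(rnorm(1000, -3, 0.5), rnorm(1000, 3, 0.5))
  sel2 <- select_k(x2, 1, 4, "BIC", n_restarts = 2, tol = 1e-7)
  expect_equal(sel2$chosen_K, 2L)
  # table invariants: the stated AIC/BIC formulas, n_params = 3K - 1
  tab <- sel2$table
  expect_equal(tab$n_params, 3 * tab$K - 1)
  expect_equal(tab$AIC, 2 * tab$n_params - 2 * tab$loglik)
  expect_equal(tab$BIC, tab$n_params * log(2000) - 2 * tab$loglik)
  expect_equal(tab$K[which.min(tab$BIC)], sel2$chosen_K)
})

test_that("AIC/BIC formulas agree with a hand-computed triple", {
  # K = 2, loglik = -100, n = 50: p = 5, AIC = 210, BIC = 5 ln 50 + 200
  expect_equal(nitratemodes:::aic_gmm(-100, 2), 210)
  expect_equal(nitratemodes:::bic_gmm(-100, 2, 50), 5 * log(50) + 200)
})

test_that("Bayes classification: posteriors, labels, ties and boundaries", {
  sym <- list(weights = c(0.5, 0.5), means = c(-1, 1), sds = c(1, 1))
  asg <- classify(sym, c(0, -30, 30, NA))
  expect_equal(asg$posteriors[1, ], c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(asg$labels[1], 1L)                  # tie goes to the lower mean
  expect_equal(asg$posteriors[2, 1], 1, tolerance = 1e-9)  # far-left limit
  expect_equal(asg$posteriors[3, 2], 1, tolerance = 1e-9)
  expect_true(is.na(asg$labels[4]))                # non-finite stays unclassified
  expect_equal(asg$boundaries, 0, tolerance = 1e-9)
  # posterior rows sum to 1
  set.seed(46)
  asg2 <- classify(mixture_spec(), rnorm(500))
  expect_equal(rowSums(asg2$posteriors), rep(1, 500), tolerance = 1e-9)
  expect_equal(asg2$labels, max.col(asg2$posteriors, ties.method = "first"))
  expect_equal(asg2$class_names, c("low", "typical", "high"))
})

test_that("the reported mixture parameters classify -0.59 as low", {
  # direct evaluation of the posterior formula as an independent oracle
  w <- c(0.05, 0.89, 0.06); m <- c(-0.59, 0.0053, 0.46); s <- c(0.23, 0.21, 0.26)
  post <- w * dnorm(-0.59, m, s)
  post <- post / sum(post)
  expect_equal(which.max(post), 1L)
  asg <- classify(mixture_spec(), -0.59)
  expect_equal(asg$labels[1], 1L)
  expect_equal(asg$posteriors[1, ], post, tolerance = 1e-12)
})

test_that("classification regions partition the line at the boundaries", {
  fit <- em_fit(sample_mixture(3000, separated_mixture()), 3, seed = 2)
  asg <- classify(fit, numeric(0))
  b <- asg$boundaries
  eps <- 1e-6
  probe <- classify(fit, c(b[1] - eps, b[1] + eps, b[2] - eps, b[2] + eps))
  expect_equal(probe$labels, c(1L, 2L, 2L, 3L))
})

test_that("goodness of fit behaves on matched, shifted and exact inputs", {
  set.seed(47)
  spec <- mixture_spec()
  x <- sample_mixture(10000, spec)
  fit <- structure(list(K = 3, weights = spec$weights, means = spec$means,
                        sds = spec$sds), class = "gmm_fit")
  g <- goodness_of_fit(fit, x)
  expect_gt(g$ks_p, 1e-4)             # data drawn from the model itself
  expect_gt(g$chi2_p, 1e-6)
  expect_true(all(diff(g$qq_pairs$empirical) >= 0))
  expect_true(all(diff(g$qq_pairs$model) >= 0))
  # gross misfit: shifted data pushes the KS statistic towards 1
  g2 <- goodness_of_fit(fit, x + 5)
  expect_gt(g2$ks_stat, 0.9)
  expect_lt(g2$ks_p, 1e-10)
  # matched data sit near the QQ diagonal (type-7 empirical quantiles)
  expect_lt(max(abs(g$qq_pairs$empirical - g$qq_pairs$model)), 0.05)
  expect_error(goodness_of_fit(fit, x, n_bins = 5000), "n_bins too large")
  expect_error(goodness_of_fit(fit, x[1:50], n_bins = 8), "n_bins too small")
})

test_that("KS p-values are roughly uniform under the null", {
  # parameters fixed (not re-fit), matching the simulation-oracle caveat
  spec <- mixture_spec()
  fit <- structure(list(K = 3, weights = spec$weights, means = spec$means,
                        sds = spec$sds), class = "gmm_fit")
  frac <- mean(vapply(1:100, function(s) {
    set.seed(1000 + s)
    goodness_of_fit(fit, sample_mixture(1000, spec), n_bins = 20)$ks_p < 0.05
  }, TRUE))
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 100) + 0.01)
})

test_that("mixture CDF inversion is accurate", {
  spec <- mixture_spec()
  p <- c(0.01, 0.2, 0.5, 0.9, 0.999)
  q <- qgmm(p, spec)
  expect_equal(pgmm(q, spec), p, tolerance = 1e-8)
  expect_true(all(diff(q) > 0))
})

test_that("fits serialize and restore through JSON", {
  set.seed(48)
  fit <- em_fit(rnorm(300, 5, 2), 1)
  p <- withr::local_tempfile(fileext = ".json")
  write_gmm_fit(fit, p)
  back <- read_gmm_fit(p)
  expect_equal(back$means, fit$means)
  expect_equal(back$sds, fit$sds)
  expect_equal(back$loglik, fit$loglik)
  expect_equal(back$K, fit$K)
})
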