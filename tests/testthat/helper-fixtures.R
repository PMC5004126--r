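# Small fixtures and independent oracles shared across test files.

# 15-min grid starting at a fixed instant
grid15 <- function(n, start = "2013-03-05 12:45") {
  as.POSIXct(start, tz = "UTC") + seq(0, by = 900, length.out = n)
}

# compact generator config for fast tests: two short segments, iid-ish noise
small_segments <- function(n1 = 600L, n2 = 700L) {
  list(list(start = as.POSIXct("2013-03-05 12:45", tz = "UTC"), n = n1),
       list(start = as.POSIXct("2014-04-27 00:00", tz = "UTC"), n = n2))
}

# brute-force stationary distribution of a transition matrix (linear solve)
stationary_solve <- function(P) {
  K <- nrow(P)
  A <- rbind(t(P) - diag(K), rep(1, K))
  as.numeric(qr.solve(A, c(rep(0, K), 1)))
}

# well-separated trimodal mixture (distinct from the overlapping default)
separated_mixture <- function() {
  mixture_spec(weights = c(0.25, 0.5, 0.25), means = c(-4, 0, 4),
               sds = c(0.5, 0.5, 0.5), self_transition = 0.9)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-12)), tol)
}
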