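# ZIP pmf, EM mixture fitting and the local fdr contract.

test_that("ZIP pmf reduces correctly and normalises", {
  expect_equal(dzip(0, pi0 = 1, lambda = 3), 1)
  expect_equal(dzip(0, pi0 = 0, lambda = 1), exp(-1), tolerance = 1e-12)
  expect_equal(sum(dzip(0:50, pi0 = 0.3, lambda = 0.5)), 1,
               tolerance = 1e-12)
  expect_equal(dzip(0:10, 0.3, 0.5),
               0.3 * (0:10 == 0) + 0.7 * dpois(0:10, 0.5),
               tolerance = 1e-12)
  expect_error(dzip(1, pi0 = 1.2, lambda = 1), "pi0")
  expect_error(dzip(1, pi0 = 0.5, lambda = -1), "lambda")
  expect_error(dzip(-1, 0.5, 1), "non-negative")
})

test_that("all-zero counts give a degenerate pure-null fit with no calls", {
  fit <- fit_null_mixture(integer(50))
  expect_true(fit$degenerate)
  expect_equal(fit$p0, 1)
  expect_equal(fit$f0[1], 1)
  expect_true(all(local_fdr(0:10, fit) == 1))
  pc <- structure(list(domain_acc = "d", cancer_type = "X",
                       model_length = 50L, counts = integer(50),
                       n_events = 0L), class = "position_counts")
  expect_equal(nrow(call_hotspots(pc, fit)), 0)
})

test_that("pure-null draws recover the ZIP parameters with p0 = 1", {
  withr::local_seed(11)
  x <- rzip(5000, 0.3, 0.5)
  fit <- fit_null_mixture(x)
  expect_gte(fit$p0, 0.99)
  expect_lt(abs(fit$pi0 - 0.3), 0.05)
  expect_lt(abs(fit$lambda0 / 0.5 - 1), 0.10)
  expect_true(fit$converged)
})

test_that("a 5% Poisson(6) signal is separated from the ZIP null", {
  withr::local_seed(12)
  n <- 2000
  sig <- runif(n) < 0.05
  x <- ifelse(sig, rpois(n, 6), rzip(n, 0.3, 0.5))
  fit <- fit_null_mixture(x)
  expect_lt(abs(fit$p0 - 0.95), 0.03)
  expect_gt(fit$lambda1, fit$lambda0)
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  withr::local_seed(13)
  for (i in 1:10) {
    n <- 500
    sig <- runif(n) < 0.05
    x <- ifelse(sig, rpois(n, 8), rzip(n, 0.4, 0.6))
    fit <- fit_null_mixture(x)
    tr <- fit$ll_trace
    if (length(tr) > 1)
      expect_true(all(diff(tr) >= -1e-8 * (abs(tr[-length(tr)]) + 1)))
  }
})

test_that("densities normalise over the capped support", {
  withr::local_seed(14)
  x <- c(rzip(400, 0.3, 0.5), rpois(20, 7))
  fit <- fit_null_mixture(x)
  expect_lt(abs(sum(fit$f0) - 1), 1e-10)
  expect_lt(abs(sum(fit$f) - 1), 1e-10)
})

test_that("local fdr follows p0*f0/f and is monotonised over counts", {
  # fixed-parameter fit object: evaluate the formula independently
  fit <- oncodomains:::.finish_fit(pi0 = 0.5, lambda0 = 1, p0 = 0.9,
                                   lambda1 = 6, loglik = 0,
                                   converged = TRUE, n_iter = 1L,
                                   degenerate = FALSE, N = 100L,
                                   jmax = 10L)
  f0_2 <- 0.5 * exp(-1) * 1^2 / 2         # (1-pi0) e^-lambda lambda^j / j!
  f1_2 <- exp(-6) * 6^2 / 2
  expected <- 0.9 * f0_2 / (0.9 * f0_2 + 0.1 * f1_2)
  expect_equal(local_fdr(2, fit), expected, tolerance = 1e-12)
  # monotone non-increasing over t >= 1, hence nested calls
  v <- local_fdr(1:30, fit)
  expect_true(all(diff(v) <= 1e-15))
  expect_true(all(v >= 0 & v <= 1))
  # pure-null fit: fdr identically 1
  null_fit <- oncodomains:::.finish_fit(pi0 = 0.3, lambda0 = 0.5, p0 = 1,
                                        lambda1 = NA_real_, loglik = 0,
                                        converged = TRUE, n_iter = 1L,
                                        degenerate = FALSE, N = 100L,
                                        jmax = 5L)
  expect_true(all(local_fdr(0:50, null_fit) == 1))
  expect_true(all(tail_fdr(0:50, null_fit) == 1))
  # never NaN, even far beyond the support
  expect_false(any(is.nan(local_fdr(c(100, 500), fit))))
})

test_that("hotspot calls are nested in the count", {
  withr::local_seed(15)
  x <- c(rzip(300, 0.3, 0.4), rpois(6, 9))
  pc <- structure(list(domain_acc = "d", cancer_type = "X",
                       model_length = length(x), counts = as.integer(x),
                       n_events = sum(x)), class = "position_counts")
  fit <- fit_null_mixture(x)
  calls <- call_hotspots(pc, fit)
  sig_counts <- calls$count[calls$significant]
  if (length(sig_counts)) {
    tmin <- min(sig_counts)
    expect_true(all(calls$significant[calls$count >= tmin]))
  }
  expect_true(all(calls$count >= 1))
})

test_that("short inputs are skipped with a warning, not fitted", {
  expect_warning(fit <- fit_null_mixture(c(0L, 1L, 0L)), "min_positions")
  expect_null(fit)
})

test_that("random background placement conserves events and is seeded", {
  expect_identical(simulate_random_background(0, 10), integer(10))
  a <- simulate_random_background(1000, 10, seed = 3)
  b <- simulate_random_background(1000, 10, seed = 3)
  expect_identical(a, b)
  expect_equal(sum(a), 1000)
  # 99.9% Poisson(100)-scale band per position
  expect_true(all(a >= qpois(5e-4, 100) & a <= qpois(1 - 5e-4, 100)))
})
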