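test_that("K = 1 EM reduces to the closed-form single normal", {
  set.seed(3)
  x <- rnorm(500, 2, 1.5)
  fit <- em_fit(x, 1, "V")
  expect_equal(fit$weights, 1)
  expect_equal(fit$means, mean(x), tolerance = 1e-10)
  expect_equal(fit$variances, mean((x - mean(x))^2), tolerance = 1e-8)
  expect_equal(fit$loglik,
               sum(dnorm(x, mean(x), sqrt(mean((x - mean(x))^2)), log = TRUE)),
               tolerance = 1e-8)
  # families agree at K = 1, including the parameter count
  fitE <- em_fit(x, 1, "E")
  expect_equal(fit$n_params, 2L)
  expect_equal(fitE$n_params, 2L)
  expect_equal(fit$bic, fitE$bic, tolerance = 1e-10)
})

test_that("EM finds the global optimum of a well-separated two-cluster toy", {
  x <- c(-5.1, -4.9, -5.0, 4.9, 5.1, 5.0)
  fit <- em_fit(x, 2, "V")
  expect_true(fit$converged)
  expect_equal(fit$means, c(-5, 5), tolerance = 0.05)
  expect_equal(fit$weights, c(0.5, 0.5), tolerance = 1e-6)
  expect_gte(fit$loglik, oracle_best_loglik(x, 2, "V", 200, seed = 9) - 1e-6)
})

test_that("EM recovers generating parameters of a balanced two-component mixture", {
  sim <- simulate_mixture(mixture_spec(c(0.5, 0.5), c(-4, 4), c(1, 1),
                                       10000, seed = 5))
  fit <- em_fit(sim$values, 2, "V")
  expect_lt(max(abs(fit$means - c(-4, 4))), 0.1)
  expect_lt(max(abs(fit$weights - 0.5)), 0.02)
})

test_that("mixture log-likelihood is stable and matches naive summation", {
  # density exactly 1 at the mean when sigma^2 = 1/(2*pi)
  m <- make_model(1, 0, 1 / (2 * pi))
  expect_equal(mixture_loglik(0, m), 0, tolerance = 1e-12)

  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(100, 0, 3)
    w <- c(0.3, 0.7); mu <- c(-2, 2); v <- c(1, 4)
    mod <- make_model(w, mu, v)
    expect_equal(mixture_loglik(x, mod), naive_loglik(x, w, mu, v),
                 tolerance = 1e-10)
    # duplicating a point adds exactly its contribution
    expect_equal(mixture_loglik(c(x, x[1]), mod),
                 mixture_loglik(x, mod) + mixture_loglik(x[1], mod),
                 tolerance = 1e-10)
  }
})

test_that("BIC uses the maximize convention 2*loglik - p*log(n)", {
  set.seed(4)
  x <- rnorm(200)
  fit <- em_fit(x, 2, "V")
  expect_equal(fit$bic, 2 * fit$loglik - fit$n_params * log(fit$n))
  expect_equal(model_bic(fit), fit$bic)
  expect_equal(fit$n_params, 5L)           # 3K - 1
  expect_equal(em_fit(x, 2, "E")$n_params, 4L)  # 2K
})

test_that("model selection picks one component for unimodal data and the argmax of its own table", {
  set.seed(8)
  x <- rnorm(5000)
  best <- select_model(x)
  expect_equal(best$K, 1L)
  ok <- best$bic_table[best$bic_table$converged, ]
  expect_gte(best$bic, max(ok$bic) - 1e-12)
})

test_that("BIC selection recovers the three-component generating spec", {
  sim <- simulate_mixture(mixture_spec(c(0.2, 0.5, 0.3), c(-4, 0, 4),
                                       c(1, 1, 1), 10000, seed = 42))
  best <- select_model(sim$values)
  expect_equal(best$K, 3L)
  expect_lt(max(abs(best$means - c(-4, 0, 4))), 0.1)
  expect_lt(max(abs(best$weights - c(0.2, 0.5, 0.3))), 0.03)
})

test_that("responsibilities are normalized posteriors", {
  set.seed(13)
  x <- rnorm(50)
  m1 <- em_fit(x, 1, "V")
  expect_true(all(responsibilities(x, m1) == 1))

  mod <- make_model(c(0.5, 0.5), c(-10, 10), c(1, 1))
  r <- responsibilities(c(-10, 10, 0.5), mod)
  expect_true(all(abs(rowSums(r) - 1) < 1e-12))
  expect_gt(r[1, 1], 0.999)  # point at a far-separated component mean
  expect_gt(r[2, 2], 0.999)
})

test_that("mixture density integrates to one and components sum to the total", {
  mod <- make_model(c(0.25, 0.75), c(-3, 2), c(1, 2.25))
  grid <- seq(-20, 20, length.out = 20001)
  d <- mixture_density(mod, grid, components = TRUE)
  expect_equal(rowSums(d$components), d$total, tolerance = 1e-12)
  trap <- sum((d$total[-1] + d$total[-length(grid)]) / 2 * diff(grid))
  expect_equal(trap, 1, tolerance = 1e-6)
  # standard normal density at its mean
  expect_equal(mixture_density(make_model(1, 0, 1), 0), 0.3989, tolerance = 5e-4)
})

test_that("per-iteration log-likelihood never decreases", {
  set.seed(17)
  datasets <- list(rnorm(300),
                   c(rnorm(200, -3), rnorm(100, 3)),
                   rexp(250),        # misspecified data too
                   runif(150, -5, 5))
  for (x in datasets) for (K in 1:3) for (fam in c("E", "V")) {
    tr <- em_fit(x, K, fam)$loglik_trace
    expect_true(all(diff(tr) >= -1e-8))
  }
})

test_that("converged loglik matches a 200-restart brute-force oracle on small data", {
  set.seed(23)
  for (i in 1:3) {
    x <- c(rnorm(25, -2), rnorm(25, 2))
    for (K in 1:2) {
      fit <- em_fit(x, K, "V", fit_config(n_starts = 5, seed = i))
      expect_gte(fit$loglik, oracle_best_loglik(x, K, "V", 200, seed = i) - 1e-6)
    }
  }
})

test_that("fitted parameters are invariant to input order", {
  sim <- simulate_mixture(mixture_spec(c(0.4, 0.6), c(-2, 3), c(1, 1),
                                       2000, seed = 31))
  x <- sim$values
  set.seed(99)
  xs <- sample(x)
  f1 <- em_fit(x, 2, "V")
  f2 <- em_fit(xs, 2, "V")
  expect_equal(f1$means, f2$means, tolerance = 1e-9)
  expect_equal(f1$weights, f2$weights, tolerance = 1e-9)
  expect_equal(f1$variances, f2$variances, tolerance = 1e-9)
})

test_that("degenerate all-equal data yield a flagged single component at the floor", {
  fit <- em_fit(rep(3.5, 20), 1, "V")
  expect_true(fit$degenerate)
  expect_equal(fit$K, 1L)
  expect_equal(fit$means, 3.5)
  expect_lte(fit$variances, .Machine$double.eps)
})

test_that("n < K and non-finite values are hard errors", {
  expect_error(em_fit(c(1, 2), 3, "V"), "n < K")
  expect_error(em_fit(c(1, NA), 1, "V"), "finite")
  expect_error(select_model(numeric(0)), "empty")
})

test_that("fit agrees with an independent reference implementation (mclust)", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))  # Mclust resolves helpers via search path
  sim <- simulate_mixture(mixture_spec(c(0.2, 0.5, 0.3), c(-4, 0, 4),
                                       c(1, 1, 1), 5000, seed = 77))
  x <- unname(sim$values)
  ours <- em_fit(x, 3, "V")
  ref <- mclust::Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  expect_lt(max(abs(ours$means - sort(ref$parameters$mean))), 0.05)
  expect_lt(max(abs(ours$weights -
                      ref$parameters$pro[order(ref$parameters$mean)])), 0.01)
  # and BIC-based choice of K agrees on this dataset
  ref_sel <- mclust::Mclust(x, G = 1:6, modelNames = c("E", "V"),
                            verbose = FALSE)
  expect_equal(select_model(x, fit_config(k_range = 1:6))$K,
               as.integer(ref_sel$G))
})
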