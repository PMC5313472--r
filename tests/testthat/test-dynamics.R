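test_that("level correlation is a no-intercept regression through deviations", {
  a <- c(0.7, 0.9, 1.0, 1.3, 1.4)
  expect_equal(fit_correlation(a, a)$xi, 1)
  set.seed(21)
  reps <- purrr::map_dbl(1:40, function(r) {
    aj <- rnorm(120, 1, 0.4)
    al <- 1 + 0.5 * (aj - 1) + rnorm(120, 0, 0.2)
    fit_correlation(aj, al)$xi
  })
  expect_lt(abs(mean(reps) - 0.5), 3 * sd(reps) / sqrt(length(reps)))
  indep <- purrr::map_dbl(1:40, function(r) {
    fit_correlation(rnorm(120, 1, 0.4), rnorm(120, 1, 0.4))$xi
  })
  expect_lt(abs(mean(indep)), 3 * sd(indep) / sqrt(length(indep)))
  expect_error(fit_correlation(rep(1, 10), rnorm(10)),
               class = "fapr_insufficient_data")
})

test_that("future levels shrink toward the herd average", {
  expect_equal(predict_next_alpha(1.10, 0.5), 1.05)
  expect_equal(predict_next_alpha(1, 0.77), 1)
  expect_equal(predict_next_alpha(1.3, 1), 1.3)
  expect_equal(predict_next_alpha(0.8, 0), 1)
})

test_that("survival curve has half-asymptote at M, logistic special case, limits", {
  for (nu in c(0.5, 1, 3)) {
    p <- list(A = 0.9, B = 0.03, nu = nu, M = 150)
    expect_equal(eval_survival(p, 150), 0.45, tolerance = 1e-12)
    s <- eval_survival(p, seq(0, 600, 5))
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= p$A + 1e-12))
    expect_lt(eval_survival(p, 5000), 1e-9)
  }
  p1 <- list(A = 0.8, B = 0.04, nu = 1, M = 120)
  t <- seq(0, 400, 10)
  expect_equal(eval_survival(p1, t),
               0.8 * (1 - 1 / (1 + exp(-0.04 * (t - 120)))),
               tolerance = 1e-12)
})

test_that("survival fit recovers parameters given good days-open coverage", {
  truth <- list(A = 0.88, B = 0.03, nu = 1.5, M = 180)
  set.seed(31)
  ests <- purrr::map_dfr(1:30, function(r) {
    d <- round(runif(2000, 25, 420))
    y <- runif(2000) < eval_survival(truth, d)
    as.data.frame(as.list(fit_survival(
      tibble::tibble(days_open = d, survived = y))$params))
  })
  for (nm in names(truth)) {
    se <- sd(ests[[nm]]) / sqrt(nrow(ests))
    expect_lt(abs(mean(ests[[nm]]) - truth[[nm]]),
              3 * se + 0.05 * abs(truth[[nm]]))
  }
})

test_that("survival fit degenerates gracefully when everyone survives", {
  d <- tibble::tibble(days_open = round(runif(60, 30, 200)), survived = 1)
  f <- fit_survival(d)
  s <- eval_survival(f, seq(30, 200, 10))
  expect_true(all(s > 0.95))
  expect_error(fit_survival(d[1:5, ]), class = "fapr_insufficient_data")
})

test_that("final-lactation fractions normalise and match a geometric oracle", {
  expect_equal(fit_gamma(c(3, 3, 3), j = 2)$gamma[1], 1)
  set.seed(41)
  # cows survive each further parity with probability q: final parity
  # beyond j is a truncated geometric
  q <- 0.6
  final <- 1 + rgeom(20000, prob = 1 - q)
  g <- fit_gamma(final, j = 1, n_max = 8)
  expect_equal(sum(g$gamma), 1)
  analytic <- dgeom(0:6, prob = 1 - q)
  analytic[7] <- 1 - sum(analytic[1:6])  # mass folded into the horizon
  expect_equal(g$gamma, analytic, tolerance = 0.03)
  for (j in 1:4) expect_equal(sum(fit_gamma(final, j, 8)$gamma), 1)
  expect_error(fit_gamma(c(1, 2), j = 5), class = "fapr_insufficient_data")
})

test_that("exponential smoothing obeys its limit cases and equivariance", {
  expect_equal(update_smoothed(0.8, 1.4, 1), 1.4)
  expect_equal(update_smoothed(0.8, 1.4, 0), 0.8)
  expect_error(update_smoothed(1, 1, 1.2), class = "fapr_domain_error")
  x <- rep(1.23, 10)
  expect_equal(smooth_series(x, 0.37, x0 = 1.23), x)
  set.seed(51)
  y <- rnorm(30, 1, 0.3)
  a <- 2.5; b <- -0.7
  expect_equal(smooth_series(a * y + b, 0.3, x0 = a * 1 + b),
               a * smooth_series(y, 0.3, x0 = 1) + b)
  # NA observations carry the previous smoothed value forward
  z <- c(1, NA, 2)
  expect_equal(smooth_series(z, 0.5, x0 = 1), c(1, 1, 1.5))
})

test_that("smoothing factor estimation tracks the process character", {
  set.seed(61)
  walks <- lapply(1:60, function(i) cumsum(rnorm(25, 0, 0.3)) + 1)
  lam_walk <- estimate_lambda(walks)$lambda
  expect_gt(lam_walk, 0.8)
  iid <- lapply(1:60, function(i) rnorm(25, 1, 0.3))
  lam_iid <- estimate_lambda(iid)$lambda
  expect_lt(lam_iid, 0.2)
  expect_error(estimate_lambda(list(c(1, 2))),
               class = "fapr_insufficient_data")
})

test_that("grid search finds the argmin of the stated objective", {
  set.seed(71)
  seqs <- lapply(1:15, function(i) rnorm(12, 1, 0.2) + seq(0, 0.5, length = 12))
  est <- estimate_lambda(seqs)
  # independent brute-force evaluation of the objective
  sse_at <- function(lam) {
    sum(vapply(seqs, function(x) {
      n <- length(x)
      sm <- smooth_series(x, lam, x0 = 1)
      fut <- vapply(seq_len(n - 1), function(t) mean(x[(t + 1):n]), 1)
      sum((sm[seq_len(n - 1)] - fut)^2)
    }, 1))
  }
  grid <- seq(0, 1, 0.01)
  brute <- grid[which.min(vapply(grid, sse_at, 1))]
  expect_equal(est$lambda, brute)
  expect_equal(est$sse, sse_at(brute), tolerance = 1e-10)
})
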