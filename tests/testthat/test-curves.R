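test_that("milk curve reduces to the Wood form for open cows and scales in alpha", {
  p <- list(a = 15, b = 0.2, c = 0.003, d = 2e-6)
  dims <- c(5, 50, 150, 305)
  expect_equal(eval_milk_curve(p, 1, dims, pregnant = FALSE),
               p$a * dims^p$b * exp(-p$c * dims))
  expect_equal(eval_milk_curve(p, 2, dims, FALSE),
               2 * eval_milk_curve(p, 1, dims, FALSE))
  # pregnancy with positive d only ever lowers yield after conception
  open <- eval_milk_curve(p, 1, 100:400, FALSE)
  preg <- eval_milk_curve(p, 1, 100:400, TRUE, dim_p = 100)
  expect_true(all(preg <= open))
  expect_error(eval_milk_curve(p, 1, 0), class = "fapr_domain_error")
  expect_error(eval_milk_curve(p, 1, 120, TRUE, dim_p = 150),
               class = "fapr_domain_error")
})

test_that("both pregnancy-term groupings are available and differ as intended", {
  p <- c(a = 15, b = 0.2, c = 0.003, d = 2e-6)
  lit <- eval_milk_curve(p, 1, 300, TRUE, 100, parse = "literal")
  add <- eval_milk_curve(p, 1, 300, TRUE, 100, parse = "additive")
  expect_equal(lit, 15 * 300^0.2 * exp(-(0.003 + 2e-6 * 200) * 300))
  expect_equal(add, 15 * 300^0.2 * exp(-0.003 * 300 - 2e-6 * 200))
  expect_false(isTRUE(all.equal(lit, add)))
})

test_that("tSCC curve is positive, increasing in its level, and clamps overflow", {
  p <- true_scc_curve()
  dims <- seq(0, 500, 25)
  v <- eval_scc_curve(p, 1, dims)
  expect_true(all(v > 0))
  for (a in c(0.8, 0.95, 1.05, 1.2)) {
    expect_true(all(eval_scc_curve(p, a, dims) <
                      eval_scc_curve(p, a + 0.05, dims)))
  }
  expect_warning(big <- eval_scc_curve(p, 8, 300),
                 class = "fapr_clamp_warning")
  expect_true(is.finite(big))
})

test_that("herd curves fitted on noise-free data reproduce the generator", {
  # many cows all at level 1, no observation noise
  recs <- dplyr::bind_rows(lapply(1:25, function(i) {
    r <- curve_records(dims = seq(5, 300, 15) + i %% 7)
    r$cow_id <- sprintf("T1-C%02d", i)
    r
  }))
  fit_m <- fit_herd_curve(recs, "milk", min_lactations = 20)
  tm <- true_milk_curve()
  dims <- c(10, 100, 300)
  expect_equal(eval_milk_curve(fit_m, 1, dims),
               eval_milk_curve(tm, 1, dims), tolerance = 1e-4)
  fit_s <- fit_herd_curve(recs, "scc", min_lactations = 20)
  ts <- true_scc_curve()
  expect_equal(eval_scc_curve(fit_s, 1, dims),
               eval_scc_curve(ts, 1, dims), tolerance = 1e-3)
})

test_that("herd curve fit refuses too few lactations", {
  recs <- dplyr::bind_rows(lapply(1:5, function(i) {
    r <- curve_records(); r$cow_id <- sprintf("T1-C%02d", i); r
  }))
  expect_error(fit_herd_curve(recs, "milk", min_lactations = 20),
               class = "fapr_insufficient_data")
})

test_that("herd-curve fit recovers truth under cow-level spread and noise", {
  # moderate replicate study at the generator's own noise levels
  cfg0 <- generator_config(seed = 1)
  ests <- purrr::map_dfr(1:8, function(r) {
    sim <- simulate_herds(generator_config(seed = 300 + r))
    recs <- derive_records(sim$records) %>%
      dplyr::mutate(pg = parity_group(parity)) %>%
      backdate_pregnancy() %>%
      dplyr::filter(pg == "1")
    f <- fit_herd_curve(recs, "milk")
    tibble::tibble(a = f$params[["a"]], b = f$params[["b"]],
                   c = f$params[["c"]])
  })
  truth <- cfg0$milk_curves[cfg0$milk_curves$pg == "1", ]
  for (nm in c("a", "b", "c")) {
    se <- stats::sd(ests[[nm]]) / sqrt(nrow(ests))
    expect_lt(abs(mean(ests[[nm]]) - truth[[nm]]),
              3 * se + 0.02 * abs(truth[[nm]]) + 1e-9)
  }
})

test_that("cow level fits are exact on proportional data and default otherwise", {
  tm <- true_milk_curve()
  base <- curve_records()
  f1 <- fit_cow_level(base, tm, "milk")
  expect_equal(f1$alpha, 1, tolerance = 1e-10)
  up <- curve_records(alpha_m = 1.10)
  f2 <- fit_cow_level(up, tm, "milk")
  expect_equal(f2$alpha, 1.10, tolerance = 1e-10)
  short <- curve_records(dims = seq(10, 250, 60))  # 5 points
  f3 <- fit_cow_level(short, tm, "milk")
  expect_false(f3$fittable)
  expect_equal(f3$alpha, 1)
  # dam information shifts the default toward the dam's level
  f4 <- fit_cow_level(short, tm, "milk", dam_alpha = 1.5, dam_xi = 0.3)
  expect_equal(f4$alpha, 1.15)
  zero <- dplyr::mutate(base, milk_kg = 0, ecm_kg = 0)
  expect_error(fit_cow_level(zero, tm, "milk"),
               class = "fapr_domain_error")
})

test_that("tSCC cow level round-trips through the fitted exponent", {
  ts <- true_scc_curve()
  for (am in c(0.9, 1, 1.08)) {
    r <- curve_records()
    r$tscc <- eval_scc_curve(ts, am, r$dim)
    r$scc <- r$tscc / r$milk_kg
    f <- fit_cow_level(r, ts, "scc")
    expect_equal(f$alpha, am, tolerance = 1e-5)
  }
})

test_that("per-record levels invert the curves consistently", {
  tm <- true_milk_curve(); ts <- true_scc_curve()
  r <- curve_records(alpha_m = 1.2)
  expect_equal(record_level(r, tm, "milk"), rep(1.2, nrow(r)))
  r2 <- curve_records()
  r2$tscc <- eval_scc_curve(ts, 1.05, r2$dim)
  expect_equal(record_level(r2, ts, "scc"), rep(1.05, nrow(r2)),
               tolerance = 1e-8)
})
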