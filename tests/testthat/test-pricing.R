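test_that("price interpolation passes through the published anchors", {
  sch <- build_price_function()
  expect_equal(price_correction(sch, 100), 2)   # sub-200 band midpoint
  expect_equal(price_correction(sch, 450), -4)  # 400-500 band midpoint
  grid <- seq(0, 1000, 5)
  expect_true(all(diff(price_correction(sch, grid)) <= 1e-12))
  bad <- tibble::tibble(lower = c(0, 400), upper = c(200, 500),
                        pct = c(-4, 2))
  expect_error(build_price_function(bad), class = "fapr_config_error")
})

test_that("extrapolation beyond the outer anchors is linear", {
  sch <- build_price_function()
  slope <- (-4 - 2) / (450 - 100)
  expect_equal(price_correction(sch, 0), 2 + slope * (0 - 100))
  expect_equal(price_correction(sch, 700), -4 + slope * (700 - 450))
})

test_that("bulk-tank delta follows the weighted-mean arithmetic", {
  # two cows, equal milk, SCC 100 and 300: removing the 300 cow
  expect_equal(delta_bulk_scc(300, 20, 100 * 20 + 300 * 20, 40), -100)
  # cow at the milk-weighted mean changes nothing
  expect_equal(delta_bulk_scc(200, 15, 200 * 60, 60), 0)
  set.seed(81)
  for (i in 1:20) {
    scc <- runif(30, 50, 800); milk <- runif(30, 10, 40)
    tc <- sum(scc * milk); tm <- sum(milk)
    bulk <- tc / tm
    hi <- which.max(scc); lo <- which.min(scc)
    expect_lt(delta_bulk_scc(scc[hi], milk[hi], tc, tm), 0)
    expect_gt(delta_bulk_scc(scc[lo], milk[lo], tc, tm), 0)
  }
  # single-cow herd: removal empties the tank
  expect_equal(delta_bulk_scc(250, 30, 250 * 30, 30), -250)
  expect_error(delta_bulk_scc(100, 10, 1000, 0), class = "fapr_domain_error")
})

test_that("PVM equals ECM at the bulk mean and charges high-SCC cows", {
  sch <- build_price_function()
  tc <- 150 * 2000; tm <- 2000; te <- 1995
  expect_equal(compute_pvm(28, 150, 30, tc, tm, te, sch), 28)
  expect_lt(compute_pvm(28, 700, 30, tc, tm, te, sch), 28)
  expect_gt(compute_pvm(28, 50, 30, tc, tm, te, sch), 28)
  expect_error(compute_pvm(28, 150, 30, 0, 0, 0, sch),
               class = "fapr_domain_error")
})

test_that("a cow's influence on the bulk tank dilutes in a larger herd", {
  # the marginal bulk-SCC shift shrinks with herd size; under a globally
  # linear correction the first-order price charge is size-invariant, so
  # the dilution of the raw stepwise scheme survives interpolation only
  # through the scheme's curvature
  herd <- function(n_cows) {
    scc <- rep(240, n_cows); milk <- rep(30, n_cows); scc[1] <- 900
    list(tc = sum(scc * milk), tm = sum(milk))
  }
  s <- herd(20); l <- herd(200)
  d_small <- delta_bulk_scc(900, 30, s$tc, s$tm)
  d_large <- delta_bulk_scc(900, 30, l$tc, l$tm)
  expect_lt(abs(d_large), abs(d_small))
  # with a kinked (piecewise) scheme the per-kg charge differs by size
  kinked <- build_price_function(
    tibble::tibble(lower = c(0, 200, 400), upper = c(200, 300, 500),
                   pct = c(2, 0, -4)))
  pvm_small <- compute_pvm(29, 900, 30, s$tc, s$tm, 0.999 * s$tm, kinked)
  pvm_large <- compute_pvm(29, 900, 30, l$tc, l$tm, 0.999 * l$tm, kinked)
  expect_false(isTRUE(all.equal(pvm_small, pvm_large)))
})

test_that("PVM is monotone non-increasing in the cow's own SCC", {
  sch <- build_price_function()
  tc <- 180 * 3000; tm <- 3000; te <- 2990
  sccs <- seq(20, 2000, 20)
  pv <- compute_pvm(28, sccs, 30, tc, tm, te, sch)
  expect_true(all(diff(pv) <= 1e-12))
})

test_that("summed PVM-ECM differences match the first-order price effect", {
  # with a linear scheme over the traversed range, the per-cow charges
  # add up to the herd-level price change of removing each cow in turn
  sch <- build_price_function()
  set.seed(91)
  scc <- runif(40, 80, 260); milk <- runif(40, 15, 40)
  ecm <- milk * 0.999
  tc <- sum(scc * milk); tm <- sum(milk); te <- sum(ecm)
  pv <- compute_pvm(ecm, scc, milk, tc, tm, te, sch)
  deltas <- delta_bulk_scc(scc, milk, tc, tm)
  slope <- (-4 - 2) / (450 - 100)
  expect_equal(sum(pv - ecm), sum(-slope * deltas) / 100 * te,
               tolerance = 1e-9)
})

test_that("realized and curve-predicted PVM agree on identical inputs", {
  model <- fixture_model()
  ops <- as.list(model$ops[1, ])
  sch <- model$scheme
  mc <- herd_curve(model, ops$herd_id, "1", "milk")
  sc <- herd_curve(model, ops$herd_id, "1", "scc")
  t <- c(50, 150, 250)
  pred <- predict_pvm_curve(mc, sc, t, 1.1, 1.02, FALSE, NA, ops, sch)
  ecm <- eval_milk_curve(mc, 1.1, t)
  tscc <- eval_scc_curve(sc, 1.02, t)
  milk <- ecm / ops$ecm_factor
  manual <- compute_pvm(ecm, tscc / milk, milk,
                        ops$bulk_scc * ops$total_milk, ops$total_milk,
                        ops$total_ecm, sch)
  expect_equal(pred, manual, tolerance = 1e-12)
})

test_that("predicted PVM decreases in the SCC level and matches ECM at the bulk point", {
  model <- fixture_model()
  ops <- as.list(model$ops[1, ])
  mc <- herd_curve(model, ops$herd_id, "1", "milk")
  sc <- herd_curve(model, ops$herd_id, "1", "scc")
  t <- seq(20, 280, 20)
  lower <- predict_pvm_curve(mc, sc, t, 1, 0.98, FALSE, NA, ops,
                             model$scheme)
  higher <- predict_pvm_curve(mc, sc, t, 1, 1.02, FALSE, NA, ops,
                              model$scheme)
  expect_true(all(higher < lower))
})
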