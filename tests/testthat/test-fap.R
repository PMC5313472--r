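test_that("predicted dry-off day follows the reproduction calendar", {
  expect_equal(predict_dim_l(150, TRUE, 100), 326)
  expect_equal(predict_dim_l(10, FALSE), 287)
  expect_equal(predict_dim_l(300, FALSE), 526)
  expect_equal(predict_dim_l(c(150, 10, 300), c(TRUE, FALSE, FALSE),
                             c(100, NA, NA)), c(326, 287, 526))
})

test_that("current-lactation production matches the day-loop oracle", {
  model <- fixture_model()
  h <- model$ops$herd_id[1]
  st <- list(parity = 2, dim = 120, pregnant = TRUE, dim_p = 95,
             alpha_m = 1.15, alpha_c = 0.97)
  cur <- fap_current(st, herd_curve(model, h, 2, "milk"),
                     herd_curve(model, h, 2, "scc"),
                     model$ops[model$ops$herd_id == h, ], model$scheme,
                     model$constants)
  expect_equal(cur$dim_l, 95 + 282 - 56)
  expect_equal(cur$t_rc, cur$dim_l - 120 + 56)
  expect_equal(cur$fp_c,
               oracle_fp(model, h, "2", 120:cur$dim_l, 1.15, 0.97,
                         TRUE, 95),
               tolerance = 1e-9)
  expect_equal(cur$fap_c, cur$fp_c / cur$t_rc)
})

test_that("a cow at her dry-off day averages a single day over the dry period", {
  model <- fixture_model()
  h <- model$ops$herd_id[1]
  st <- list(parity = 1, dim = 326, pregnant = TRUE, dim_p = 100,
             alpha_m = 1, alpha_c = 1)
  cur <- fap_current(st, herd_curve(model, h, 1, "milk"),
                     herd_curve(model, h, 1, "scc"),
                     model$ops[model$ops$herd_id == h, ], model$scheme,
                     model$constants)
  expect_equal(cur$t_rc, 56)
  expect_equal(cur$fap_c,
               oracle_fp(model, h, "1", 326, 1, 1, TRUE, 100) / 56)
  # past dry-off: zero with a warning
  st$dim <- 340
  expect_warning(
    late <- fap_current(st, herd_curve(model, h, 1, "milk"),
                        herd_curve(model, h, 1, "scc"),
                        model$ops[model$ops$herd_id == h, ], model$scheme,
                        model$constants),
    class = "fapr_edge_warning")
  expect_equal(late$fp_c, 0)
})

test_that("future-lactation production shrinks with the chained correlations", {
  model <- fixture_model()
  h <- model$ops$herd_id[1]
  st <- list(parity = 1, dim = 60, pregnant = FALSE, dim_p = NA,
             alpha_m = 1.2, alpha_c = 1.01)
  ff <- fap_future(st, model, h, 2, model$constants)
  xi_m <- chain_xi(model, h, 1, 2, "milk")
  xi_c <- chain_xi(model, h, 1, 2, "scc")
  expect_equal(ff$fp_f,
               oracle_fp(model, h, "2", 3:287,
                         1 + xi_m * (1.2 - 1), 1 + xi_c * (1.01 - 1)),
               tolerance = 1e-9)
  expect_equal(ff$fap_f, ff$fp_f / 343)
  expect_error(fap_future(st, model, h, 99), class = "fapr_domain_error")
  # xi = 1 keeps the cow's level; xi = 0 gives the average cow
  m1 <- model; m1$xi$xi <- 1
  f1 <- fap_future(st, m1, h, 2, model$constants)
  expect_equal(f1$fp_f, oracle_fp(model, h, "2", 3:287, 1.2, 1.01),
               tolerance = 1e-9)
  m0 <- model; m0$xi$xi <- 0
  f0 <- fap_future(st, m0, h, 2, model$constants)
  expect_equal(f0$fp_f, oracle_fp(model, h, "2", 3:287, 1, 1),
               tolerance = 1e-9)
})

test_that("skip-lactation correlations chain per-step coefficients", {
  model <- fixture_model()
  h <- model$ops$herd_id[1]
  x <- model$xi
  x12 <- x$xi[x$step == 1 & x$family == "milk"]
  x23 <- x$xi[x$step == 2 & x$family == "milk"]
  expect_equal(chain_xi(model, h, 1, 3, "milk"), x12 * x23)
})

test_that("the survival-weighted combination collapses correctly at S = 0 and S = 1", {
  model <- fixture_model()
  h <- model$ops$herd_id[1]
  st <- list(parity = 2, dim = 100, pregnant = FALSE, dim_p = NA,
             alpha_m = 1.05, alpha_c = 1)
  # force S = 0: survival asymptote microscopically small
  m0 <- model
  m0$survival$A <- 1e-12
  r0 <- fap(st, m0, h)
  expect_equal(r0$fap, r0$fap_c, tolerance = 1e-9)
  # force S = 1 and all survivors stopping at the next lactation
  m1 <- model
  m1$survival$A <- 1; m1$survival$B <- 1e-4; m1$survival$M <- 1e6
  m1$gamma$gamma <- as.numeric(m1$gamma$l == m1$gamma$j + 1)
  r1 <- fap(st, m1, h)
  expect_equal(r1$s, 1, tolerance = 1e-4)
  expect_equal(r1$fap,
               (1 - r1$s) * r1$fap_c +
                 r1$s * (r1$fp_c + r1$future$fp_f[1]) /
                 (r1$t_rc + model$constants$t_s),
               tolerance = 1e-9)
})

test_that("fap matches a Monte-Carlo life-course simulator", {
  model <- fixture_model()
  h <- model$ops$herd_id[1]
  set.seed(101)
  for (case in 1:4) {
    st <- list(parity = sample(1:3, 1), dim = sample(30:250, 1),
               pregnant = case %% 2 == 0, dim_p = NA,
               alpha_m = runif(1, 0.8, 1.3), alpha_c = runif(1, 0.97, 1.03))
    if (st$pregnant) st$dim_p <- sample(50:min(200, st$dim), 1)
    r <- fap(st, model, h)
    # independent life-course sampler
    n_mc <- 1e5
    j <- st$parity
    ls <- (j + 1):model$constants$n_max
    course_vals <- c(r$fap_c, (r$fp_c + cumsum(r$future$fp_f)) /
                       (r$t_rc + (ls - j) * model$constants$t_s))
    surv <- runif(n_mc) < r$s
    pick <- ifelse(surv,
                   1 + sample(length(ls), n_mc, replace = TRUE,
                              prob = r$future$gamma),
                   1)
    draws <- course_vals[pick]
    mc_se <- sd(draws) / sqrt(n_mc)
    expect_lt(abs(mean(draws) - r$fap), 3 * mc_se + 1e-9)
    # the combined value lies between the extreme life courses
    expect_gte(r$fap, min(course_vals) - 1e-9)
    expect_lte(r$fap, max(course_vals) + 1e-9)
  }
})

test_that("fap weights are a probability distribution over life courses", {
  model <- fixture_model()
  h <- model$ops$herd_id[1]
  st <- list(parity = 1, dim = 80, pregnant = FALSE, dim_p = NA,
             alpha_m = 1, alpha_c = 1)
  r <- fap(st, model, h)
  expect_equal((1 - r$s) + r$s * sum(r$future$gamma), 1, tolerance = 1e-9)
})

test_that("fap rises with the milk level and falls with the SCC level", {
  model <- fixture_model()
  h <- model$ops$herd_id[1]
  base <- list(parity = 1, dim = 100, pregnant = FALSE, dim_p = NA,
               alpha_m = 1, alpha_c = 1)
  f_m <- vapply(seq(0.7, 1.4, 0.1), function(am) {
    st <- base; st$alpha_m <- am; fap(st, model, h)$fap
  }, 1)
  expect_true(all(diff(f_m) > 0))
  f_c <- vapply(seq(0.9, 1.1, 0.025), function(ac) {
    st <- base; st$alpha_c <- ac; fap(st, model, h)$fap
  }, 1)
  expect_true(all(diff(f_c) < 0))
})

test_that("pregnant cows late in lactation outrank open cows of equal level", {
  model <- fixture_model()
  h <- model$ops$herd_id[1]
  for (j in 1:2) {
    open <- fap(list(parity = j, dim = 280, pregnant = FALSE, dim_p = NA,
                     alpha_m = 1, alpha_c = 1), model, h)
    preg <- fap(list(parity = j, dim = 280, pregnant = TRUE, dim_p = 120,
                     alpha_m = 1, alpha_c = 1), model, h)
    expect_gte(preg$fap, open$fap)
  }
})

test_that("per-cow-day scoring is deterministic and complete", {
  model <- fixture_model()
  sim <- fixture_sim()
  sub_cows <- head(unique(sim$records$cow_id), 40)
  recs <- dplyr::filter(sim$records, cow_id %in% sub_cows)
  p1 <- predict_fap(recs, model)
  p2 <- predict_fap(recs, model)
  expect_identical(p1, p2)
  expect_true(all(c("fap", "fap_c", "s", "dim_l", "alpha_m_s",
                    "alpha_c_s") %in% names(p1)))
  in_window <- dplyr::filter(recs, test_date > model$train_range[2],
                             milk_kg > 0)
  expect_equal(nrow(p1), nrow(in_window))
})
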