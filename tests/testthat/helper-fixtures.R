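# Shared fixtures: one small simulated herd and one fitted model, built once
# per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_herds(generator_config(seed = 20260925))
  }
  .fixture_env$sim
}

fixture_model <- function() {
  if (is.null(.fixture_env$model)) {
    sim <- fixture_sim()
    sp <- train_test_split(sim$records, "2009-01-01")
    .fixture_env$model <- fit_herd_model(sp$train)
  }
  .fixture_env$model
}

fixture_validation <- function() {
  if (is.null(.fixture_env$validation)) {
    .fixture_env$validation <- compare_predictors(fixture_sim()$records,
                                                  fixture_model())
  }
  .fixture_env$validation
}

# true generator curves as parameter lists
true_milk_curve <- function(pg = "1") {
  cfg <- generator_config(seed = 1)
  row <- cfg$milk_curves[cfg$milk_curves$pg == pg, ]
  list(a = row$a, b = row$b, c = row$c, d = row$d, parse = "literal")
}

true_scc_curve <- function(pg = "1") {
  cfg <- generator_config(seed = 1)
  row <- cfg$scc_curves[cfg$scc_curves$pg == pg, ]
  list(a = row$a, b = row$b, c = row$c, d = row$d, parse = "default")
}

# noise-free records tracing a known milk/tSCC curve for one cow
curve_records <- function(alpha_m = 1, alpha_c_mult = 1, dims = seq(5, 300, 15),
                          pg = "1", pregnant_from = NA) {
  mc <- true_milk_curve(pg)
  sc <- true_scc_curve(pg)
  preg <- !is.na(pregnant_from) & dims >= pregnant_from
  ecm <- alpha_m * eval_milk_curve(mc, 1, dims, preg, pregnant_from)
  fat <- 4.0; protein <- 3.4
  milk <- ecm / (0.122 * fat + 0.077 * protein + 0.249)
  tscc <- alpha_c_mult * eval_scc_curve(sc, 1, dims)
  tibble::tibble(
    herd_id = "T1", cow_id = "T1-C1", test_date = as.Date("2006-01-01") + dims,
    parity = if (pg == "3+") 3L else as.integer(pg), dim = as.integer(dims),
    milk_kg = milk, fat_pct = fat, protein_pct = protein,
    scc = tscc / milk, pregnant = preg,
    dim_p = ifelse(preg, as.integer(pregnant_from), NA_integer_),
    dam_id = NA_character_,
    ecm_kg = ecm, tscc = tscc)
}

# Day-by-day oracle: independent re-implementation of the production sums
# using only the curve evaluators and the pricing primitives.
oracle_fp <- function(model, herd_id, pg, t_seq, alpha_m, alpha_c,
                      pregnant = FALSE, dim_p = NA) {
  ops <- as.list(model$ops[model$ops$herd_id == herd_id, ])
  mc <- herd_curve(model, herd_id, pg, "milk")
  sc <- herd_curve(model, herd_id, pg, "scc")
  tot <- 0
  for (t in t_seq) {
    ecm <- eval_milk_curve(mc, alpha_m, t, pregnant, dim_p)
    tscc <- eval_scc_curve(sc, alpha_c, t)
    milk <- ecm / ops$ecm_factor
    if (milk > 0) {
      tot <- tot + compute_pvm(ecm, tscc / milk, milk,
                               ops$bulk_scc * ops$total_milk,
                               ops$total_milk, ops$total_ecm, model$scheme)
    }
  }
  tot
}
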