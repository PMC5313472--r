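# Reproducible synthetic evaluation of FAP accuracy: the package's own
# analogue of the multi-herd train/test validation design.

#' Synthetic multi-herd FAP accuracy experiment
#'
#' Generates a population of synthetic herds, trains the full herd model on
#' the first years, scores every test-period cow-day with FAP, and
#' summarises, per herd, the deviation from the realized weighted
#' future-mean PVM.  Herds averaging fewer than `min_cows` lactating cows
#' per recording date in the training period are excluded before fitting.
#'
#' @param seed Integer seed driving the generator.
#' @param n_herds Number of herds (default 20).
#' @param cows_per_herd Herd size (default 100).
#' @param years Total simulated years (default 4).
#' @param train_years Years used for training; the rest are the test
#'   period (default 3).
#' @param tests_per_year Recording frequency (default 11).
#' @param min_cows Herd-size inclusion threshold (default 50).
#' @return List: `validation` (a `fap_validation`), `per_herd_fap` (per
#'   herd: mean and SD of FAP minus realized), `mean_herd_deviation`
#'   (mean over herds of the signed herd-mean deviation, kg/day - the
#'   centre of the herd-deviation distribution),
#'   `mean_abs_herd_deviation` and `median_abs_herd_deviation` (mean and
#'   median of the absolute herd-mean deviations), `n_herds`.
#' @export
fap_accuracy_experiment <- function(seed, n_herds = 20,
                                    cows_per_herd = 100, years = 4,
                                    train_years = 3, tests_per_year = 11,
                                    min_cows = 50) {
  cfg <- generator_config(n_herds = n_herds, cows_per_herd = cows_per_herd,
                          years = years, tests_per_year = tests_per_year,
                          seed = seed)
  sim <- simulate_herds(cfg)
  split_date <- min(sim$records$test_date) + round(train_years * 365.25)
  sp <- train_test_split(sim$records, split_date)
  train <- filter_herds_min_size(sp$train, min_cows = min_cows)
  kept <- unique(train$herd_id)
  model <- fit_herd_model(train)
  v <- compare_predictors(
    filter(sim$records, .data$herd_id %in% kept), model,
    from_date = split_date)
  ph <- filter(v$per_herd, .data$predictor == "fap")
  list(validation = v,
       per_herd_fap = ph,
       mean_herd_deviation = mean(ph$mean_diff),
       mean_abs_herd_deviation = mean(abs(ph$mean_diff)),
       median_abs_herd_deviation = median(abs(ph$mean_diff)),
       n_herds = nrow(ph))
}
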