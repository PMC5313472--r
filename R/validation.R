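# Evaluation harness: FAP and naive predictors against the realized
# weighted future-mean PVM, per herd, with rank-sum comparisons.

#' Realized weighted future-mean production value
#'
#' The non-parametric benchmark a predictor is judged against: the mean of
#' the cow's future PVM observations, down-weighted by
#' `(281 + 61 - 56)/(281 + 61)` to account for the unobserved dry periods
#' between lactations (observations only exist while the cow milks).
#'
#' @param pvm_future Numeric vector of the cow's PVM observations strictly
#'   after the prediction day.
#' @param weight Dry-off weight (default `(281 + 61 - 56)/(281 + 61)`).
#' @return Weighted mean, kg/day; `NA` when no future observation exists.
#' @export
realized_future_value <- function(pvm_future,
                                  weight = (281 + 61 - 56) / (281 + 61)) {
  pvm_future <- pvm_future[!is.na(pvm_future)]
  if (length(pvm_future) == 0) return(NA_real_)
  mean(pvm_future) * weight
}

#' Compare FAP with naive predictors of future production
#'
#' For every cow-day in the test window, computes FAP and three naive
#' competitors from the cow's PVM history up to that day - the latest PVM,
#' the mean of the last three, and the lifetime mean - and the realized
#' weighted future-mean PVM from her observations after that day.
#' Cow-days without any future observation are excluded (and counted); all
#' predictors are evaluated on the identical cow-day set.  Differences are
#' aggregated per herd (cow-days weighted equally), and the per-herd
#' absolute mean errors of each predictor pair are compared across herds
#' with the Wilcoxon rank-sum test with continuity correction.
#'
#' @param records Canonical records covering training and test periods.
#' @param model A `herd_model` fitted on the training period.
#' @param from_date Start of the test window (default: day after the
#'   model's training range).
#' @param scheme Price scheme for realized PVM (default: the model's).
#' @return Object of class `fap_validation`: `per_herd` (per herd and
#'   predictor: mean, SD and mean absolute difference vs the realized
#'   value, `n` cow-days), `cow_days` (the underlying table), `tests`
#'   (pairwise rank-sum results, NULL with < 2 herds), `n_excluded`.
#' @export
compare_predictors <- function(records, model, from_date = NULL,
                               scheme = NULL) {
  scheme <- scheme %||% model$scheme
  from_date <- from_date %||% (model$train_range[2] + 1)
  scored <- predict_fap(records, model, from_date = from_date)
  pvm_tab <- add_pvm(derive_records(records), scheme) %>%
    filter(!is.na(.data$pvm)) %>%
    arrange(.data$herd_id, .data$cow_id, .data$test_date)
  hist_stats <- pvm_tab %>%
    group_by(.data$herd_id, .data$cow_id) %>%
    mutate(
      latest_pvm = .data$pvm,
      lifetime_mean_pvm = cumsum(.data$pvm) / row_number(),
      mean_last3_pvm = (.data$pvm +
                          lag(.data$pvm, 1, default = NA) +
                          lag(.data$pvm, 2, default = NA)),
      mean_last3_pvm = dplyr::case_when(
        row_number() >= 3 ~ .data$mean_last3_pvm / 3,
        row_number() == 2 ~ (.data$pvm + lag(.data$pvm, 1)) / 2,
        TRUE ~ .data$pvm),
      n_future = n() - row_number(),
      future_sum = sum(.data$pvm) - cumsum(.data$pvm),
      realized = ifelse(.data$n_future > 0,
                        .data$future_sum / .data$n_future *
                          (281 + 61 - 56) / (281 + 61), NA_real_)) %>%
    ungroup() %>%
    select("herd_id", "cow_id", "test_date", "latest_pvm",
           "mean_last3_pvm", "lifetime_mean_pvm", "realized")
  cow_days <- scored %>%
    inner_join(hist_stats, by = c("herd_id", "cow_id", "test_date"))
  n_excluded <- sum(is.na(cow_days$realized))
  cow_days <- filter(cow_days, !is.na(.data$realized))
  long <- cow_days %>%
    tidyr::pivot_longer(c("fap", "latest_pvm", "mean_last3_pvm",
                          "lifetime_mean_pvm"),
                        names_to = "predictor", values_to = "prediction")
  per_herd <- long %>%
    group_by(.data$herd_id, .data$predictor) %>%
    summarise(mean_diff = mean(.data$prediction - .data$realized),
              sd_diff = sd(.data$prediction - .data$realized),
              mean_abs_diff = mean(abs(.data$prediction - .data$realized)),
              n = n(), .groups = "drop")
  tests <- NULL
  if (length(unique(per_herd$herd_id)) >= 2) {
    preds <- unique(per_herd$predictor)
    pairs <- utils::combn(preds, 2, simplify = FALSE)
    tests <- purrr::map_dfr(pairs, function(pr) {
      a <- per_herd$mean_abs_diff[per_herd$predictor == pr[1]]
      b <- per_herd$mean_abs_diff[per_herd$predictor == pr[2]]
      wt <- suppressWarnings(wilcox.test(a, b, correct = TRUE))
      tibble(predictor_a = pr[1], predictor_b = pr[2],
             mean_abs_a = mean(a), mean_abs_b = mean(b),
             statistic = unname(wt$statistic), p_value = wt$p.value)
    })
  } else {
    inform("compare_predictors(): fewer than 2 herds; rank-sum tests skipped.")
  }
  structure(list(per_herd = per_herd, cow_days = cow_days, tests = tests,
                 n_excluded = n_excluded),
            class = "fap_validation")
}

#' @export
print.fap_validation <- function(x, ...) {
  cat(sprintf("<fap_validation> %d herd(s), %d cow-days (%d excluded)\n",
              length(unique(x$per_herd$herd_id)), nrow(x$cow_days),
              x$n_excluded))
  sm <- x$per_herd %>%
    group_by(.data$predictor) %>%
    summarise(mean_abs_diff = mean(.data$mean_abs_diff),
              mean_diff = mean(.data$mean_diff), .groups = "drop") %>%
    arrange(.data$mean_abs_diff)
  print(sm)
  invisible(x)
}

#' @method tidy fap_validation
#' @export
tidy.fap_validation <- function(x, ...) x$per_herd

#' @method glance fap_validation
#' @export
glance.fap_validation <- function(x, ...) {
  x$per_herd %>%
    group_by(.data$predictor) %>%
    summarise(mean_abs_diff = mean(.data$mean_abs_diff),
              mean_diff = mean(.data$mean_diff),
              sd_diff = mean(.data$sd_diff), .groups = "drop")
}

#' Histograms of per-herd prediction error
#'
#' The distribution over herds of the mean (left) and SD (right) of the
#' difference between each predictor and the realized weighted future-mean
#' PVM.
#'
#' @param object A `fap_validation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fap_validation
#' @export
autoplot.fap_validation <- function(object, ...) {
  d <- object$per_herd %>%
    tidyr::pivot_longer(c("mean_diff", "sd_diff"), names_to = "measure",
                        values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey40") +
    ggplot2::facet_grid(predictor ~ measure, scales = "free_x") +
    ggplot2::labs(x = "kg milk/day vs realized future PVM", y = "herds") +
    ggplot2::theme_minimal()
}
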