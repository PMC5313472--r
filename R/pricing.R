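# Production value of milk: ECM corrected for the cow's marginal effect on
# the bulk-tank SCC price penalty.

#' Default SCC price-correction bands
#'
#' The two published anchors of the Danish bulk-milk pricing structure: a
#' bulk SCC below 200 (×1000 cells/mL) earns a +2% milk-price premium, and
#' a bulk SCC between 400 and 500 a -4% penalty.  Any national scheme can
#' be supplied as a tibble of bands in the same shape (and via the YAML
#' config for the command-line tools).
#'
#' @return Tibble with columns `lower`, `upper` (band bounds, ×1000
#'   cells/mL) and `pct` (price correction, percent).
#' @export
default_price_steps <- function() {
  tibble(lower = c(0, 400), upper = c(200, 500), pct = c(2, -4))
}

#' Build a continuous price-correction function from stepwise bands
#'
#' The raw scheme is a step function, so a marginal change in bulk SCC
#' usually moves the price not at all; interpolation makes every change
#' count.  Each band contributes an anchor at its midpoint with its
#' correction; the function is piecewise linear through the anchors and
#' linearly extrapolated beyond the outermost ones (constant when a single
#' band is given).  Corrections must be non-increasing in SCC.
#'
#' @param steps Tibble with `lower`, `upper`, `pct` (see
#'   [default_price_steps()]).
#' @return Object of class `fapr_price_scheme`; call it via
#'   [price_correction()].
#' @export
build_price_function <- function(steps = default_price_steps()) {
  steps <- arrange(as_tibble(steps), .data$lower)
  if (any(steps$upper <= steps$lower)) {
    abort("build_price_function(): bands need upper > lower.",
          class = "fapr_config_error")
  }
  if (is.unsorted(rev(steps$pct))) {
    abort("build_price_function(): corrections must be non-increasing in SCC.",
          class = "fapr_config_error")
  }
  anchors <- tibble(scc = (steps$lower + steps$upper) / 2, pct = steps$pct)
  structure(list(steps = steps, anchors = anchors),
            class = "fapr_price_scheme")
}

#' Evaluate a price-correction scheme
#'
#' @param scheme A `fapr_price_scheme` from [build_price_function()].
#' @param scc_b Bulk-tank SCC, ×1000 cells/mL; vectorised.
#' @return Price correction in percent (positive = premium), continuous and
#'   non-increasing in `scc_b`.
#' @export
price_correction <- function(scheme, scc_b) {
  a <- scheme$anchors
  if (nrow(a) == 1) return(rep(a$pct, length(scc_b)))
  slope_lo <- (a$pct[2] - a$pct[1]) / (a$scc[2] - a$scc[1])
  n <- nrow(a)
  slope_hi <- (a$pct[n] - a$pct[n - 1]) / (a$scc[n] - a$scc[n - 1])
  out <- approx(a$scc, a$pct, xout = scc_b, rule = 2)$y
  lo <- scc_b < a$scc[1]
  hi <- scc_b > a$scc[n]
  out[lo] <- a$pct[1] + slope_lo * (scc_b[lo] - a$scc[1])
  out[hi] <- a$pct[n] + slope_hi * (scc_b[hi] - a$scc[n])
  out
}

#' @export
print.fapr_price_scheme <- function(x, ...) {
  cat("<fapr_price_scheme>\n")
  print(x$steps)
  invisible(x)
}

#' Change in bulk-tank SCC when one cow is removed
#'
#' The cow's marginal contribution to the bulk tank: the milk-weighted mean
#' SCC of the herd-day without the cow, minus the mean with her included.
#' Negative when the cow's SCC exceeds the bulk mean (removing her cleans
#' the tank).
#'
#' @param scc Cow SCC, ×1000 cells/mL.
#' @param milk_kg Cow milk, kg.
#' @param total_cells Herd-day total cell load including the cow
#'   (`sum(scc * milk)`).
#' @param total_milk Herd-day total milk including the cow, kg (> 0).
#' @return Change in bulk SCC, ×1000 cells/mL; vectorised over the cow
#'   arguments.  For a single-cow herd (removal empties the tank) the
#'   change is `-scc`.
#' @export
delta_bulk_scc <- function(scc, milk_kg, total_cells, total_milk) {
  if (any(total_milk <= 0)) {
    abort("delta_bulk_scc(): total milk must be positive.",
          class = "fapr_domain_error")
  }
  rest_milk <- total_milk - milk_kg
  with_cow <- total_cells / total_milk
  ifelse(rest_milk > 1e-9,
         (total_cells - scc * milk_kg) / rest_milk - with_cow,
         -scc)
}

#' Production value of milk for one cow on one herd day
#'
#' \deqn{PVM_c = ECM_c + \big[f^C(SCC_B) - f^C(SCC_B + \Delta_c SCC_B)\big]
#'   \sum_i ECM_i / 100}
#' The cow is credited (or charged) the share of the herd's total bulk ECM
#' that her presence adds to (or subtracts from) the interpolated price
#' correction \eqn{f^C} (percent, hence the /100).  In a large herd the
#' correction dilutes and PVM approaches ECM.
#'
#' @param ecm_kg Cow ECM, kg/day.
#' @param scc Cow SCC, ×1000 cells/mL.
#' @param milk_kg Cow milk, kg/day.
#' @param total_cells,total_milk,total_ecm Herd-day totals including the
#'   cow.
#' @param scheme A `fapr_price_scheme`.
#' @return PVM, kg/day; vectorised over the cow arguments.
#' @export
compute_pvm <- function(ecm_kg, scc, milk_kg, total_cells, total_milk,
                        total_ecm, scheme = build_price_function()) {
  if (any(total_milk <= 0) || any(total_ecm <= 0)) {
    abort("compute_pvm(): empty herd day (no milk).",
          class = "fapr_domain_error")
  }
  scc_b <- total_cells / total_milk
  delta <- delta_bulk_scc(scc, milk_kg, total_cells, total_milk)
  ecm_kg + (price_correction(scheme, scc_b) -
              price_correction(scheme, scc_b + delta)) / 100 * total_ecm
}

#' Add realized PVM to a herd-recording table
#'
#' Computes each record's PVM against its own herd-day (all lactating cows
#' of the same herd on the same test date).
#'
#' @param records Derived records (need `ecm_kg`, `tscc`).
#' @param scheme A `fapr_price_scheme`.
#' @return `records` with a `pvm` column (NA for zero-milk rows).
#' @export
add_pvm <- function(records, scheme = build_price_function()) {
  records %>%
    group_by(.data$herd_id, .data$test_date) %>%
    mutate(
      pvm = {
        milking <- .data$milk_kg > 0
        tc <- sum(.data$tscc[milking])
        tm <- sum(.data$milk_kg[milking])
        te <- sum(.data$ecm_kg[milking])
        ifelse(milking & tm > 0,
               compute_pvm(.data$ecm_kg, .data$scc, .data$milk_kg,
                           tc, tm, te, scheme),
               NA_real_)
      }
    ) %>%
    ungroup()
}

#' Predicted PVM curve for a cow at a future day in milk
#'
#' Evaluates the predicted PVM at day `t` of the (current or future)
#' lactation: curve-predicted ECM and tSCC at the cow's smoothed levels,
#' priced against the herd's bulk-tank operating point (milk-weighted mean
#' bulk SCC and mean daily totals over the training period), which is
#' assumed constant into the future.  Predicted tSCC is converted back to
#' SCC per mL through the predicted milk before entering the bulk tank.
#'
#' @param milk_curve,scc_curve Fitted `fapr_curve` objects for the cow's
#'   parity group.
#' @param t Day in milk; vectorised.
#' @param alpha_m,alpha_c Smoothed cow levels.
#' @param pregnant,dim_p Reproduction state at prediction time.
#' @param ops Herd operating point: list/one-row tibble with `bulk_scc`,
#'   `total_milk`, `total_ecm`, `ecm_factor` (kg ECM per kg milk at the
#'   herd's average fat/protein).
#' @param scheme A `fapr_price_scheme`.
#' @return Predicted PVM, kg/day (0 where predicted milk is 0).
#' @export
predict_pvm_curve <- function(milk_curve, scc_curve, t, alpha_m, alpha_c,
                              pregnant = FALSE, dim_p = NA_real_, ops,
                              scheme = build_price_function()) {
  ecm <- eval_milk_curve(milk_curve, alpha_m, t, pregnant, dim_p)
  tscc <- eval_scc_curve(scc_curve, alpha_c, t)
  milk <- ecm / ops$ecm_factor
  total_cells <- ops$bulk_scc * ops$total_milk
  delta <- delta_bulk_scc(ifelse(milk > 0, tscc / milk, 0), milk,
                          total_cells, ops$total_milk)
  pvm <- ecm + (price_correction(scheme, ops$bulk_scc) -
                  price_correction(scheme, ops$bulk_scc + delta)) / 100 *
    ops$total_ecm
  ifelse(milk > 0, pvm, 0)
}
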