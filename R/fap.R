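# Future average production: lactation end dates, future production of the
# current and future lactations, and the survival-weighted combination.

#' Predicted last day in milk of the current lactation
#'
#' A pregnant cow dries off `gestation - dry_period` days after conception
#' (`DIM_L = DIM_P + 282 - 56` at the defaults).  An open cow is assumed to
#' conceive either immediately or at the average `days_to_conception`,
#' whichever is later: `DIM_L = max(DIM + 226, 287)` at the defaults.
#'
#' @param dim Current days in milk.
#' @param pregnant Logical.
#' @param dim_p Day of conception (required where pregnant).
#' @param constants [repro_constants()].
#' @return Predicted last day in milk; vectorised.
#' @export
predict_dim_l <- function(dim, pregnant, dim_p = NA_real_,
                          constants = repro_constants()) {
  lact <- constants$gestation - constants$dry_period
  ifelse(pregnant,
         dim_p + lact,
         pmax(dim + lact, constants$days_to_conception + lact))
}

#' Future production of the remainder of the current lactation
#'
#' Sums the predicted PVM day by day from the current DIM to the predicted
#' last day in milk (inclusive, integer days):
#' `FP_C = sum(f_PVM(t))`, and averages over the remaining time in the
#' parity including the dry period: `FAP_C = FP_C / (DIM_L - DIM + 56)`.
#'
#' @param state One-row tibble/list: `dim`, `pregnant`, `dim_p`,
#'   `alpha_m`, `alpha_c` (smoothed levels).
#' @param milk_curve,scc_curve Fitted curves for the cow's current parity
#'   group.
#' @param ops Herd operating point (see [predict_pvm_curve()]).
#' @param scheme Price scheme.
#' @param constants [repro_constants()].
#' @return List: `fp_c` (kg), `fap_c` (kg/day), `dim_l`, `t_rc` (days).
#' @export
fap_current <- function(state, milk_curve, scc_curve, ops,
                        scheme = build_price_function(),
                        constants = repro_constants()) {
  dim_l <- predict_dim_l(state$dim, state$pregnant, state$dim_p, constants)
  t_rc <- dim_l - state$dim + constants$dry_period
  if (state$dim > dim_l) {
    warn("fap_current(): cow past predicted dry-off; FP_C set to 0.",
         class = "fapr_edge_warning")
    return(list(fp_c = 0, fap_c = 0, dim_l = dim_l, t_rc = t_rc))
  }
  t <- seq(max(state$dim, 1), dim_l)
  pvm <- predict_pvm_curve(milk_curve, scc_curve, t,
                           state$alpha_m, state$alpha_c,
                           state$pregnant, state$dim_p, ops, scheme)
  fp_c <- sum(pvm)
  list(fp_c = fp_c, fap_c = fp_c / t_rc, dim_l = dim_l, t_rc = t_rc)
}

#' Future production of a future lactation
#'
#' A future lactation `l > j` runs over the standard lactation of
#' `days_to_conception + gestation - dry_period` days (287 at the
#' defaults), summed from day 3 to avoid the singularity of the lactation
#' curve near calving.  The cow's levels are shrunk toward the herd
#' average with the chained inter-lactation correlations before
#' evaluating the PVM curve of the future parity group.  The average
#' divides by the standard time in a parity,
#' `T_S = gestation + days_to_conception` (343 days at the defaults).
#'
#' @param state As in [fap_current()] plus `parity`.
#' @param model A `herd_model`.
#' @param herd_id Herd.
#' @param l Future parity (`l > parity`, `l <= n_max`).
#' @param constants [repro_constants()].
#' @return List: `fp_f` (kg), `fap_f` (kg/day), `xi_m`, `xi_c`.
#' @export
fap_future <- function(state, model, herd_id, l,
                       constants = repro_constants()) {
  j <- state$parity
  if (l <= j) abort("fap_future(): l must exceed current parity.",
                    class = "fapr_domain_error")
  if (l > constants$n_max) {
    abort("fap_future(): l exceeds the lactation horizon n_max.",
          class = "fapr_domain_error")
  }
  xi_m <- chain_xi(model, herd_id, j, l, "milk")
  xi_c <- chain_xi(model, herd_id, j, l, "scc")
  a_m <- predict_next_alpha(state$alpha_m, xi_m)
  a_c <- predict_next_alpha(state$alpha_c, xi_c)
  dim_l_std <- constants$days_to_conception + constants$gestation -
    constants$dry_period
  t <- seq(3, dim_l_std)
  ops <- model$ops[model$ops$herd_id == herd_id, ]
  pvm <- predict_pvm_curve(herd_curve(model, herd_id, l, "milk"),
                           herd_curve(model, herd_id, l, "scc"),
                           t, a_m, a_c, FALSE, NA_real_, ops, model$scheme)
  fp_f <- sum(pvm)
  list(fp_f = fp_f, fap_f = fp_f / constants$t_s, xi_m = xi_m, xi_c = xi_c)
}

#' Future average production of one cow at one point in time
#'
#' The survival-weighted combination over possible life courses: with
#' probability `1 - S` the cow leaves after the current lactation and her
#' future average is `FAP_C`; with probability `S` she reaches a final
#' lactation `l` with probability `gamma[l]`, producing the current
#' remainder plus every future lactation up to `l` over the corresponding
#' lifetime:
#' \deqn{FAP = (1 - S)\,FAP_C + S \sum_{l=j+1}^{n} \gamma_{jl}
#'   \frac{FP_C + \sum_{m=j+1}^{l} FP^F_{jm}}{T_{RC} + (l - j)\,T_S}}
#' Survival is evaluated at the cow's current days open; a pregnant cow
#' stopped accruing days open at conception, so `S` is taken at `dim_p`.
#'
#' @param state One-row tibble/list: `parity`, `dim`, `pregnant`, `dim_p`,
#'   `alpha_m`, `alpha_c`.
#' @param model A `herd_model`.
#' @param herd_id Herd.
#' @param constants Overrides the model's constants when given.
#' @return Object of class `fap_result`: list with `fap`, `fap_c`, `fp_c`,
#'   `dim_l`, `t_rc`, `s`, and a tibble `future` (per future lactation
#'   `l`: `gamma`, `fp_f`, `fap_f`, cumulative life-course average).
#' @export
fap <- function(state, model, herd_id, constants = NULL) {
  ctx <- .fap_ctx(model, herd_id, constants)
  .fap_with_ctx(state, ctx)
}

# Precomputed per-herd lookup tables so scoring many cow-days does not pay
# repeated model-table filtering.
.fap_ctx <- function(model, herd_id, constants = NULL) {
  constants <- constants %||% model$constants
  pgs <- c("1", "2", "3+")
  curves <- lapply(setNames(pgs, pgs), function(pg) {
    list(milk = herd_curve(model, herd_id, pg, "milk"),
         scc = herd_curve(model, herd_id, pg, "scc"))
  })
  surv <- lapply(setNames(pgs, pgs), function(pg)
    herd_survival(model, herd_id, pg))
  gm <- model$gamma[model$gamma$herd_id == herd_id, ]
  gamma <- lapply(seq_len(constants$n_max - 1), function(j) {
    gj <- gm[gm$j == j, ]
    if (nrow(gj) == 0) {
      abort(sprintf("fap(): no survival fractions for herd %s parity %d.",
                    herd_id, j), class = "fapr_model_incomplete")
    }
    setNames(gj$gamma, gj$l)
  })
  xt <- model$xi[model$xi$herd_id == herd_id, ]
  xi_step <- lapply(c(milk = "milk", scc = "scc"), function(fam) {
    v <- vapply(1:3, function(s) {
      row <- xt[xt$step == s & xt$family == fam, ]
      if (nrow(row) == 0) {
        abort(sprintf("fap(): no correlation for herd %s step %d (%s).",
                      herd_id, s, fam), class = "fapr_model_incomplete")
      }
      row$xi[1]
    }, 1)
    v
  })
  ops <- as.list(model$ops[model$ops$herd_id == herd_id, ])
  if (length(ops$bulk_scc) == 0) {
    abort(sprintf("fap(): no operating point for herd %s.", herd_id),
          class = "fapr_model_incomplete")
  }
  list(curves = curves, surv = surv, gamma = gamma, xi_step = xi_step,
       ops = ops, scheme = model$scheme, constants = constants)
}

.fap_with_ctx <- function(state, ctx) {
  constants <- ctx$constants
  j <- state$parity
  pg_j <- parity_group(j)
  cur <- fap_current(state, ctx$curves[[pg_j]]$milk, ctx$curves[[pg_j]]$scc,
                     ctx$ops, ctx$scheme, constants)
  days_open <- if (isTRUE(state$pregnant)) state$dim_p else state$dim
  s <- eval_survival(ctx$surv[[pg_j]], days_open)
  n_max <- constants$n_max
  if (j >= n_max) {
    res <- list(fap = cur$fap_c, fap_c = cur$fap_c, fp_c = cur$fp_c,
                dim_l = cur$dim_l, t_rc = cur$t_rc, s = 0,
                future = tibble(l = integer(), gamma = numeric(),
                                fp_f = numeric(), fap_f = numeric(),
                                course_avg = numeric()))
    return(structure(res, class = "fap_result"))
  }
  ls <- (j + 1):n_max
  # chained correlations from j to each l
  steps <- pmin(j:(n_max - 1), 3)
  xi_m <- cumprod(ctx$xi_step$milk[steps])
  xi_c <- cumprod(ctx$xi_step$scc[steps])
  dim_l_std <- constants$days_to_conception + constants$gestation -
    constants$dry_period
  t_fut <- seq(3, dim_l_std)
  fp_f <- vapply(seq_along(ls), function(k) {
    pg_l <- parity_group(ls[k])
    sum(predict_pvm_curve(
      ctx$curves[[pg_l]]$milk, ctx$curves[[pg_l]]$scc, t_fut,
      predict_next_alpha(state$alpha_m, xi_m[k]),
      predict_next_alpha(state$alpha_c, xi_c[k]),
      FALSE, NA_real_, ctx$ops, ctx$scheme))
  }, 1)
  gamma <- ctx$gamma[[j]]
  gv <- as.numeric(gamma[as.character(ls)])
  gv[is.na(gv)] <- 0
  course_avg <- (cur$fp_c + cumsum(fp_f)) /
    (cur$t_rc + (ls - j) * constants$t_s)
  fap_val <- (1 - s) * cur$fap_c + s * sum(gv * course_avg)
  fut <- tibble(l = ls, fp_f = fp_f, fap_f = fp_f / constants$t_s,
                gamma = gv, course_avg = course_avg)
  structure(
    list(fap = fap_val, fap_c = cur$fap_c, fp_c = cur$fp_c,
         dim_l = cur$dim_l, t_rc = cur$t_rc, s = s, future = fut),
    class = "fap_result")
}

#' @export
print.fap_result <- function(x, ...) {
  cat(sprintf(
    "<fap_result> FAP %.2f kg/day (current-lactation FAP %.2f, S %.3f)\n",
    x$fap, x$fap_c, x$s))
  invisible(x)
}

#' @method tidy fap_result
#' @export
tidy.fap_result <- function(x, ...) {
  mutate(x$future, fap = x$fap, fap_c = x$fap_c, fp_c = x$fp_c,
         dim_l = x$dim_l, t_rc = x$t_rc, s = x$s)
}

#' Smoothed cow states at every test day
#'
#' Runs each cow's records (in time order, across lactations) through the
#' exponential smoother: every record is converted into an instantaneous
#' relative level against its herd curve, and the smoothed milk and tSCC
#' levels after each test day become the cow's state on that day.  Heifers
#' start at level 1 unless their dam has records, in which case the start
#' is the dam's final smoothed level shrunk with `dam_xi`.
#'
#' @param records Canonical records (training plus any test-period records
#'   available up to each prediction date).
#' @param model A `herd_model`.
#' @param dam_xi Dam-offspring correlation for initial levels
#'   (default 0.3).
#' @return `records` with columns `alpha_m_s`, `alpha_c_s` (smoothed
#'   levels after that test day).
#' @export
cow_states <- function(records, model, dam_xi = 0.3) {
  recs <- derive_records(records) %>%
    mutate(pg = parity_group(.data$parity)) %>%
    arrange(.data$herd_id, .data$cow_id, .data$test_date)
  lam <- setNames(model$lambda$lambda, model$lambda$quantity)
  for (fam in c("milk", "scc")) {
    col <- if (fam == "milk") "x_m" else "x_c"
    recs[[col]] <- NA_real_
    combos <- distinct(recs, .data$herd_id, .data$pg)
    for (i in seq_len(nrow(combos))) {
      idx <- recs$herd_id == combos$herd_id[i] & recs$pg == combos$pg[i]
      cr <- herd_curve(model, combos$herd_id[i], combos$pg[i], fam)
      recs[[col]][idx] <- record_level(recs[idx, ], cr, family = fam)
    }
  }
  smooth_one <- function(d, x0m, x0c) {
    d$alpha_m_s <- smooth_series(d$x_m, lam[["milk"]], x0 = x0m)
    d$alpha_c_s <- smooth_series(d$x_c, lam[["scc"]], x0 = x0c)
    d
  }
  # pass 1: every cow from 1, collect final levels for dam initialisation
  pass1 <- recs %>%
    group_by(.data$herd_id, .data$cow_id) %>%
    group_modify(~smooth_one(.x, 1, 1)) %>%
    ungroup()
  dam_final <- pass1 %>%
    group_by(.data$herd_id, .data$cow_id) %>%
    summarise(dam_m = last(.data$alpha_m_s), dam_c = last(.data$alpha_c_s),
              .groups = "drop")
  out <- pass1 %>%
    left_join(rename(dam_final, dam_id = "cow_id"),
              by = c("herd_id", "dam_id")) %>%
    group_by(.data$herd_id, .data$cow_id) %>%
    group_modify(function(d, key) {
      if (!is.na(d$dam_m[1]) && d$parity[1] == 1) {
        d <- smooth_one(d, predict_next_alpha(d$dam_m[1], dam_xi),
                        predict_next_alpha(d$dam_c[1], dam_xi))
      }
      d
    }) %>%
    ungroup()
  out %>%
    select(-"dam_m", -"dam_c") %>%
    arrange(.data$herd_id, .data$cow_id, .data$test_date)
}

#' FAP for every cow on every test day of a prediction window
#'
#' The day-to-day deliverable: for each record in the window, the cow's
#' smoothed state is built from all of her records up to and including
#' that day, and the survival-weighted future average production is
#' computed against the trained model.
#'
#' @param records Canonical records covering each cow's history up to the
#'   prediction days (training records plus test-period records).
#' @param model A `herd_model`.
#' @param from_date Only records on/after this date are scored (default:
#'   the day after the model's training range).
#' @param constants Override the model's reproduction constants.
#' @return Tibble, one row per scored cow-day: identifiers, state
#'   (`dim`, `pregnant`, `dim_p`, smoothed levels), `dim_l`, `fp_c`,
#'   `fap_c`, `s`, `fap`.
#' @export
predict_fap <- function(records, model, from_date = NULL,
                        constants = NULL) {
  constants <- constants %||% model$constants
  from_date <- from_date %||% (model$train_range[2] + 1)
  states <- cow_states(records, model)
  score <- filter(states, .data$test_date >= from_date,
                  .data$herd_id %in% model$ops$herd_id,
                  .data$milk_kg > 0)
  if (nrow(score) == 0) return(tibble())
  ctxs <- lapply(setNames(nm = unique(score$herd_id)), function(h)
    .fap_ctx(model, h, constants))
  n <- nrow(score)
  out_cols <- matrix(NA_real_, n, 5,
                     dimnames = list(NULL,
                                     c("dim_l", "fp_c", "fap_c", "s", "fap")))
  for (i in seq_len(n)) {
    st <- list(parity = score$parity[i], dim = score$dim[i],
               pregnant = score$pregnant[i], dim_p = score$dim_p[i],
               alpha_m = score$alpha_m_s[i], alpha_c = score$alpha_c_s[i])
    r <- .fap_with_ctx(st, ctxs[[score$herd_id[i]]])
    out_cols[i, ] <- c(r$dim_l, r$fp_c, r$fap_c, r$s, r$fap)
  }
  res <- as_tibble(out_cols)
  bind_cols(
    select(score, "herd_id", "cow_id", "test_date", "parity", "dim",
           "pregnant", "dim_p", alpha_m_s = "alpha_m_s",
           alpha_c_s = "alpha_c_s"),
    res)
}
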