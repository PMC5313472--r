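# Assemble all fitted components for a set of herds into one model object.

#' Parity group of a lactation number
#'
#' Herd curves are shared within first, second, and third-and-later
#' lactations.
#'
#' @param parity Integer parity (>= 1).
#' @return Character vector in `{"1", "2", "3+"}`.
#' @export
parity_group <- function(parity) {
  ifelse(parity >= 3, "3+", as.character(parity))
}

#' Reproduction calendar constants
#'
#' Defaults for Holstein herds: gestation 282 days, dry period 56 days,
#' average time to conception 61 days.  `t_s = gestation +
#' days_to_conception` (343 days) is the standard time spent per future
#' parity; `n_max` caps the lactation horizon.
#'
#' @param gestation,dry_period,days_to_conception Days.
#' @param n_max Maximum lactation number considered (default 8).
#' @param t_s Standard time in a parity (default `gestation +
#'   days_to_conception`); override to use an alternative convention.
#' @return Named list of constants.
#' @export
repro_constants <- function(gestation = 282, dry_period = 56,
                            days_to_conception = 61, n_max = 8,
                            t_s = NULL) {
  stopifnot(gestation > 0, dry_period > 0, days_to_conception > 0,
            n_max >= 2)
  list(gestation = gestation, dry_period = dry_period,
       days_to_conception = days_to_conception, n_max = n_max,
       t_s = t_s %||% (gestation + days_to_conception))
}

#' Fit the full herd model
#'
#' Runs the whole training pipeline on a herd-recording table:
#'
#' 1. derive ECM and tSCC, flag fittable lactations;
#' 2. per herd and parity group, fit the milk and tSCC herd curves (cow
#'    levels fixed at 1);
#' 3. per cow-lactation, fit the relative levels `alpha_m`, `alpha_c`;
#' 4. per herd, regress later level deviations on earlier ones to get the
#'    inter-lactation correlations `xi` (pooled across herds when thin);
#' 5. per herd and parity group, fit the survival curve in days open on
#'    cows at or above herd-average milk level, and the distribution
#'    `gamma` of the final lactation reached by survivors;
#' 6. estimate the smoothing factor `lambda` per quantity by grid search;
#' 7. record each herd's bulk-tank operating point (milk-weighted bulk SCC,
#'    mean daily totals, ECM factor), frozen for prediction.
#'
#' @param records Canonical records tibble (training period).
#' @param scheme Price scheme (default [default_price_steps()]).
#' @param constants Reproduction constants ([repro_constants()]).
#' @param min_points Minimum records for a cow-level fit (default 6).
#' @param min_lactations Minimum lactations for a herd-curve fit
#'   (default 20).
#' @param min_pairs Minimum cow pairs for a herd-specific `xi`
#'   (default 10).
#' @param min_cows_survival Minimum cows for a herd/parity survival fit
#'   before falling back to the herd pool (default 25).
#' @param completion_margin Days before the end of the data a cow's last
#'   record must lie for her history to count as completed (default 120).
#' @param milk_parse,scc_parse Curve groupings (see [eval_milk_curve()],
#'   [eval_scc_curve()]).
#' @return Object of class `herd_model`.
#' @export
fit_herd_model <- function(records, scheme = build_price_function(),
                           constants = repro_constants(),
                           min_points = 6, min_lactations = 20,
                           min_pairs = 10, min_cows_survival = 25,
                           completion_margin = 120,
                           milk_parse = "literal", scc_parse = "default") {
  recs <- derive_records(records) %>%
    filter_fittable(min_points = min_points) %>%
    mutate(pg = parity_group(.data$parity)) %>%
    backdate_pregnancy()

  curves <- .fit_all_curves(recs, min_lactations, milk_parse, scc_parse)
  levels <- .fit_all_levels(recs, curves, min_points)
  xi <- .fit_all_xi(levels, min_pairs, constants$n_max)
  cohort <- build_survival_cohort(recs, levels,
                                  completion_margin = completion_margin)
  survival <- .fit_all_survival(cohort, min_cows_survival)
  gamma <- .fit_all_gamma(recs, completion_margin, constants$n_max)
  lambda <- .fit_lambda(recs, curves)
  ops <- .herd_operating_points(recs)

  structure(
    list(curves = curves, levels = levels, xi = xi, survival = survival,
         gamma = gamma, lambda = lambda, ops = ops, scheme = scheme,
         constants = constants,
         settings = list(min_points = min_points,
                         min_lactations = min_lactations,
                         min_pairs = min_pairs,
                         min_cows_survival = min_cows_survival,
                         completion_margin = completion_margin,
                         milk_parse = milk_parse, scc_parse = scc_parse),
         train_range = range(recs$test_date)),
    class = "herd_model")
}

.fit_all_curves <- function(recs, min_lactations, milk_parse, scc_parse) {
  groups <- distinct(recs, .data$herd_id, .data$pg)
  purrr::pmap_dfr(groups, function(herd_id, pg) {
    d <- filter(recs, .data$herd_id == !!herd_id, .data$pg == !!pg)
    purrr::map_dfr(c("milk", "scc"), function(fam) {
      parse <- if (fam == "milk") milk_parse else scc_parse
      fit <- fit_herd_curve(d, family = fam,
                            min_lactations = min_lactations, parse = parse)
      tibble(herd_id = herd_id, pg = pg, family = fam,
             a = fit$params[["a"]], b = fit$params[["b"]],
             c = fit$params[["c"]], d = fit$params[["d"]],
             parse = parse, resid_sd = fit$resid_sd,
             n_lactations = fit$n_lactations)
    })
  })
}

.curve_from_row <- function(row) {
  structure(list(family = row$family,
                 params = c(a = row$a, b = row$b, c = row$c, d = row$d),
                 parse = row$parse, resid_sd = row$resid_sd,
                 converged = TRUE, n_lactations = row$n_lactations,
                 n_obs = NA_integer_),
            class = "fapr_curve")
}

#' Look up a fitted herd curve
#'
#' @param model A `herd_model`.
#' @param herd_id Herd identifier.
#' @param pg Parity group (`"1"`, `"2"`, `"3+"`) or integer parity.
#' @param family `"milk"` or `"scc"`.
#' @return A `fapr_curve`.
#' @export
herd_curve <- function(model, herd_id, pg, family) {
  if (is.numeric(pg)) pg <- parity_group(pg)
  row <- filter(model$curves, .data$herd_id == !!herd_id, .data$pg == !!pg,
                .data$family == !!family)
  if (nrow(row) != 1) {
    abort(sprintf("herd_curve(): no fitted %s curve for herd %s, group %s.",
                  family, herd_id, pg), class = "fapr_model_incomplete")
  }
  .curve_from_row(row)
}

.fit_all_levels <- function(recs, curves, min_points) {
  all_lact <- distinct(recs, .data$herd_id, .data$pg, .data$cow_id,
                       .data$parity)
  combos <- distinct(recs, .data$herd_id, .data$pg)
  out <- purrr::pmap_dfr(combos, function(herd_id, pg) {
    sub <- recs[recs$herd_id == herd_id & recs$pg == pg &
                  recs$milk_kg > 0 & recs$dim >= 1, ]
    res <- purrr::map_dfr(c("milk", "scc"), function(fam) {
      cr <- .curve_from_row(
        curves[curves$herd_id == herd_id & curves$pg == pg &
                 curves$family == fam, ])
      if (fam == "milk") {
        g <- eval_milk_curve(cr, 1, sub$dim, sub$pregnant, sub$dim_p)
        lev <- sub %>%
          mutate(.g = g) %>%
          group_by(.data$cow_id, .data$parity) %>%
          summarise(n_points = n(),
                    alpha = sum(.data$ecm_kg * .data$.g) /
                      sum(.data$.g^2), .groups = "drop")
      } else {
        s2 <- sub[sub$tscc > 0, ]
        p <- .as_curve_params(cr)
        parse <- cr$parse
        key <- paste(s2$cow_id, s2$parity, sep = "\r")
        idx <- split(seq_len(nrow(s2)), key)
        lev <- purrr::map_dfr(idx, function(ii) {
          ly <- log(s2$tscc[ii])
          dimv <- s2$dim[ii]
          a <- optimize(function(al)
            sum((ly - .scc_log_curve(p, al, dimv, parse))^2),
            interval = c(-10, 10), tol = 1e-9)$minimum
          tibble(cow_id = s2$cow_id[ii[1]], parity = s2$parity[ii[1]],
                 n_points = length(ii), alpha = a)
        })
      }
      mutate(lev, family = fam,
             fittable = .data$n_points >= min_points,
             alpha = ifelse(.data$fittable, .data$alpha, 1))
    })
    mutate(res, herd_id = herd_id, pg = pg)
  })
  # lactations with no usable records at all still get a default level
  missing <- all_lact %>%
    tidyr::expand_grid(family = c("milk", "scc")) %>%
    anti_join(out, by = c("herd_id", "pg", "cow_id", "parity", "family"))
  bind_rows(out, mutate(missing, alpha = 1, n_points = 0L,
                        fittable = FALSE)) %>%
    select("cow_id", "parity", "alpha", "n_points", "fittable", "herd_id",
           "pg", "family")
}

.fit_all_xi <- function(levels, min_pairs, n_max) {
  fl <- filter(levels, .data$fittable)
  pairs <- fl %>%
    inner_join(fl, by = c("herd_id", "cow_id", "family"),
               relationship = "many-to-many",
               suffix = c("_j", "_l")) %>%
    filter(.data$parity_l == .data$parity_j + 1) %>%
    mutate(step = pmin(.data$parity_j, 3))  # steps from parity >= 3 pooled
  combos <- tidyr::expand_grid(
    herd_id = unique(levels$herd_id),
    step = 1:3,
    family = c("milk", "scc"))
  purrr::pmap_dfr(combos, function(herd_id, step, family) {
    own <- filter(pairs, .data$herd_id == !!herd_id, .data$step == !!step,
                  .data$family == !!family)
    pooled_used <- nrow(own) < min_pairs
    use <- if (pooled_used) {
      filter(pairs, .data$step == !!step, .data$family == !!family)
    } else own
    est <- tryCatch(fit_correlation(use$alpha_j, use$alpha_l),
                    error = function(e) tibble(xi = 0.3, se = NA_real_,
                                               n_pairs = nrow(use)))
    tibble(herd_id = herd_id, step = step, family = family,
           xi = est$xi, n_pairs = est$n_pairs, pooled = pooled_used)
  })
}

#' Chained inter-lactation correlation from parity j to parity l
#'
#' Direct estimates exist for one-lactation steps; a jump over several
#' lactations multiplies the per-step coefficients
#' (`xi_jl = prod(xi_{m,m+1})`), steps beyond parity 3 reusing the 3+
#' estimate.
#'
#' @param model A `herd_model`.
#' @param herd_id Herd.
#' @param j,l Current and future parity (`l > j`).
#' @param family `"milk"` or `"scc"`.
#' @return Scalar correlation.
#' @export
chain_xi <- function(model, herd_id, j, l, family) {
  stopifnot(l > j)
  steps <- pmin(j:(l - 1), 3)
  x <- model$xi
  vals <- vapply(steps, function(s) {
    row <- x[x$herd_id == herd_id & x$step == s & x$family == family, ]
    if (nrow(row) == 0) {
      abort(sprintf("chain_xi(): no correlation for herd %s step %d (%s).",
                    herd_id, s, family), class = "fapr_model_incomplete")
    }
    row$xi[1]
  }, 1)
  prod(vals)
}

#' Build the survival cohort from records
#'
#' One row per completed cow-lactation: days open at conception (or, for
#' cows that never conceived in that lactation, the last observed day in
#' milk, taken as the exit day), whether a later lactation of the same cow
#' appears in the data, and the cow's fitted milk level.  A lactation only
#' enters if its outcome is resolved inside the data window: either the
#' next lactation is observed, or the cow's records stop at least
#' `completion_margin` days before the end of the data (so absence means
#' culling, not truncation).
#'
#' @param recs Derived records with a `pg` column.
#' @param levels Fitted cow levels (from the model).
#' @param completion_margin Days (default 120).
#' @return Tibble: `herd_id`, `cow_id`, `parity`, `pg`, `days_open`,
#'   `survived`, `alpha_m`.
#' @export
build_survival_cohort <- function(recs, levels,
                                  completion_margin = 120) {
  max_date <- max(recs$test_date)
  cow_last <- recs %>%
    group_by(.data$herd_id, .data$cow_id) %>%
    summarise(last_date = max(.data$test_date),
              max_parity = max(.data$parity), .groups = "drop")
  lact <- recs %>%
    group_by(.data$herd_id, .data$cow_id, .data$parity, .data$pg) %>%
    summarise(
      conc = if (any(.data$pregnant, na.rm = TRUE))
        max(.data$dim_p, na.rm = TRUE) else NA_real_,
      last_dim = max(.data$dim), .groups = "drop") %>%
    left_join(cow_last, by = c("herd_id", "cow_id")) %>%
    mutate(
      survived = .data$parity < .data$max_parity,
      resolved = .data$survived |
        .data$last_date <= max_date - completion_margin,
      days_open = ifelse(is.na(.data$conc), .data$last_dim, .data$conc))
  ml <- filter(levels, .data$family == "milk") %>%
    select("herd_id", "cow_id", "parity", alpha_m = "alpha")
  lact %>%
    filter(.data$resolved) %>%
    left_join(ml, by = c("herd_id", "cow_id", "parity")) %>%
    select("herd_id", "cow_id", "parity", "pg", "days_open", "survived",
           "alpha_m")
}

.fit_all_survival <- function(cohort, min_cows_survival) {
  high <- filter(cohort, !is.na(.data$alpha_m), .data$alpha_m >= 1)
  combos <- distinct(cohort, .data$herd_id, .data$pg)
  purrr::pmap_dfr(combos, function(herd_id, pg) {
    own <- filter(high, .data$herd_id == !!herd_id, .data$pg == !!pg)
    pooled_used <- nrow(own) < min_cows_survival
    use <- if (pooled_used) {
      filter(high, .data$herd_id == !!herd_id)  # pool parities within herd
    } else own
    fit <- tryCatch(fit_survival(use, min_cows = min_cows_survival),
                    error = function(e) NULL)
    if (is.null(fit)) {   # last resort: pool across herds
      fit <- fit_survival(filter(high, .data$pg == !!pg), min_cows = 2)
      pooled_used <- TRUE
    }
    tibble(herd_id = herd_id, pg = pg,
           A = fit$params[["A"]], B = fit$params[["B"]],
           nu = fit$params[["nu"]], M = fit$params[["M"]],
           n_cows = fit$n_cows, pooled = pooled_used)
  })
}

#' Look up a fitted survival curve
#'
#' @param model A `herd_model`.
#' @param herd_id Herd.
#' @param pg Parity group or integer parity.
#' @return A `fapr_survival`.
#' @export
herd_survival <- function(model, herd_id, pg) {
  if (is.numeric(pg)) pg <- parity_group(pg)
  row <- filter(model$survival, .data$herd_id == !!herd_id,
                .data$pg == !!pg)
  if (nrow(row) != 1) {
    abort(sprintf("herd_survival(): no fit for herd %s group %s.",
                  herd_id, pg), class = "fapr_model_incomplete")
  }
  structure(list(params = c(A = row$A, B = row$B, nu = row$nu, M = row$M),
                 n_cows = row$n_cows, converged = TRUE),
            class = "fapr_survival")
}

# Final-lactation distribution by life-table chaining: per-parity
# continuation probabilities from all resolved lactations (next parity
# observed, or the cow gone well before the end of the data), so long
# careers inform the estimate even when no single cow completes her whole
# career inside the training window.  gamma_jl = prod(p_{j+1..l-1}) *
# (1 - p_l), with the tail mass folded into the horizon.
.fit_all_gamma <- function(recs, completion_margin, n_max) {
  max_date <- max(recs$test_date)
  cow_last <- recs %>%
    group_by(.data$herd_id, .data$cow_id) %>%
    summarise(last_date = max(.data$test_date),
              max_parity = max(.data$parity), .groups = "drop")
  lact <- recs %>%
    distinct(.data$herd_id, .data$cow_id, .data$parity) %>%
    left_join(cow_last, by = c("herd_id", "cow_id")) %>%
    mutate(survived = .data$parity < .data$max_parity,
           resolved = .data$survived |
             .data$last_date <= max_date - completion_margin) %>%
    filter(.data$resolved)
  cont_rate <- function(d, m) {
    own <- d$survived[d$parity == m]
    if (length(own) >= 10) return(mean(own))
    grp <- d$survived[parity_group(d$parity) == parity_group(m)]
    if (length(grp) >= 10) return(mean(grp))
    NA_real_
  }
  purrr::map_dfr(unique(recs$herd_id), function(h) {
    own <- filter(lact, .data$herd_id == h)
    p <- vapply(seq_len(n_max - 1), function(m) {
      r <- cont_rate(own, m)
      if (is.na(r)) r <- cont_rate(lact, m)   # pool across herds
      if (is.na(r)) r <- 0                    # no data at this parity
      r
    }, 1)
    purrr::map_dfr(1:(n_max - 1), function(j) {
      ls <- (j + 1):n_max
      gamma <- vapply(ls, function(l) {
        keep <- if (l > j + 1) prod(p[(j + 1):(l - 1)]) else 1
        if (l < n_max) keep * (1 - p[l]) else keep
      }, 1)
      tibble(herd_id = h, j = j, l = ls, gamma = gamma)
    })
  })
}

.fit_lambda <- function(recs, curves) {
  purrr::map_dfr(c("milk", "scc"), function(fam) {
    seqs <- recs %>%
      group_by(.data$herd_id, .data$pg) %>%
      group_modify(function(grp, key) {
        cr <- .curve_from_row(
          curves[curves$herd_id == key$herd_id & curves$pg == key$pg &
                   curves$family == fam, ])
        grp$x <- record_level(grp, cr, family = fam)
        grp
      }) %>%
      ungroup() %>%
      arrange(.data$herd_id, .data$cow_id, .data$test_date)
    xs <- split(seqs$x, paste(seqs$herd_id, seqs$cow_id))
    est <- estimate_lambda(xs)
    mutate(est, quantity = fam)
  })
}

.herd_operating_points <- function(recs) {
  recs %>%
    filter(.data$milk_kg > 0) %>%
    group_by(.data$herd_id, .data$test_date) %>%
    summarise(day_milk = sum(.data$milk_kg), day_ecm = sum(.data$ecm_kg),
              day_cells = sum(.data$tscc), .groups = "drop_last") %>%
    summarise(bulk_scc = sum(.data$day_cells) / sum(.data$day_milk),
              total_milk = mean(.data$day_milk),
              total_ecm = mean(.data$day_ecm),
              ecm_factor = mean(.data$day_ecm / .data$day_milk),
              .groups = "drop")
}

#' @export
print.herd_model <- function(x, ...) {
  cat(sprintf(
    "<herd_model> %d herd(s), trained %s to %s\n",
    length(unique(x$curves$herd_id)), x$train_range[1], x$train_range[2]))
  lam <- setNames(x$lambda$lambda, x$lambda$quantity)
  cat(sprintf("  lambda: milk %.2f, scc %.2f\n",
              lam[["milk"]], lam[["scc"]]))
  cat(sprintf("  %d curve fits, %d cow-lactation levels\n",
              nrow(x$curves), nrow(distinct(x$levels, .data$herd_id,
                                            .data$cow_id, .data$parity))))
  invisible(x)
}

#' @method tidy herd_model
#' @export
tidy.herd_model <- function(x, ...) {
  curves <- x$curves %>%
    tidyr::pivot_longer(c("a", "b", "c", "d"), names_to = "term",
                        values_to = "estimate") %>%
    mutate(component = paste0("curve_", .data$family)) %>%
    select("herd_id", "component", group = "pg", "term", "estimate")
  surv <- x$survival %>%
    tidyr::pivot_longer(c("A", "B", "nu", "M"), names_to = "term",
                        values_to = "estimate") %>%
    mutate(component = "survival") %>%
    select("herd_id", "component", group = "pg", "term", "estimate")
  xi <- x$xi %>%
    mutate(component = paste0("xi_", .data$family),
           group = as.character(.data$step), term = "xi") %>%
    select("herd_id", "component", "group", "term", estimate = "xi")
  lam <- x$lambda %>%
    mutate(herd_id = NA_character_,
           component = paste0("lambda_", .data$quantity),
           group = NA_character_, term = "lambda") %>%
    select("herd_id", "component", "group", "term", estimate = "lambda")
  bind_rows(curves, surv, xi, lam)
}

#' @method glance herd_model
#' @export
glance.herd_model <- function(x, ...) {
  lam <- setNames(x$lambda$lambda, x$lambda$quantity)
  tibble(n_herds = length(unique(x$curves$herd_id)),
         n_cow_lactations = nrow(distinct(x$levels, .data$herd_id,
                                          .data$cow_id, .data$parity)),
         lambda_milk = lam[["milk"]], lambda_scc = lam[["scc"]],
         train_start = x$train_range[1], train_end = x$train_range[2])
}

#' Serialize a herd model to JSON
#'
#' Round-trips exactly to the printed precision (all numerics written with
#' full double precision); the curve parses and constants travel in the
#' file so a reloaded model predicts identically.
#'
#' @param model A `herd_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_herd_model <- function(model, path) {
  payload <- list(
    format = "fapr_herd_model", version = 1L,
    curves = model$curves, levels = model$levels, xi = model$xi,
    survival = model$survival, gamma = model$gamma, lambda = model$lambda,
    ops = model$ops, scheme_steps = model$scheme$steps,
    constants = model$constants, settings = model$settings,
    train_range = as.character(model$train_range))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Read a herd model written by [write_herd_model()]
#'
#' @param path Path to the JSON file.
#' @return A `herd_model`.
#' @export
read_herd_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "fapr_herd_model")) {
    abort("read_herd_model(): not a herd-model file.",
          class = "fapr_config_error")
  }
  structure(
    list(curves = as_tibble(p$curves), levels = as_tibble(p$levels),
         xi = as_tibble(p$xi), survival = as_tibble(p$survival),
         gamma = as_tibble(p$gamma), lambda = as_tibble(p$lambda),
         ops = as_tibble(p$ops),
         scheme = build_price_function(as_tibble(p$scheme_steps)),
         constants = p$constants, settings = p$settings,
         train_range = as.Date(unlist(p$train_range))),
    class = "herd_model")
}
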