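# Herd-level lactation (Wood-type, pregnancy-extended) and total-SCC curves
# with per-cow multiplicative levels alpha.

#' Evaluate the herd milk (ECM) curve for one cow
#'
#' The herd-average lactation curve is a Wood curve `a * DIM^b * exp(-c*DIM)`
#' extended with a pregnancy term so that lactations running past day 305
#' decline realistically after conception.  Two algebraic groupings of the
#' pregnancy term are supported:
#'
#' * `"literal"` (default): `a * DIM^b * exp(-(c + I_P*d*(DIM - DIM_P)) * DIM)`
#' * `"additive"`: `a * DIM^b * exp(-c*DIM - I_P*d*(DIM - DIM_P))`
#'
#' `I_P` is 1 for a pregnant cow, 0 otherwise; `DIM_P` is the day of
#' conception.  A cow's own expected yield is `alpha_m` times the herd
#' curve: `alpha_m` is the cow's production level relative to the average
#' cow of that parity group in that herd.
#'
#' @param params Named numeric vector or list with elements `a`, `b`, `c`,
#'   `d` (and optionally `parse`).
#' @param alpha_m Cow milk level relative to the average cow (default 1).
#' @param dim Days in milk (>= 1); vectorised.
#' @param pregnant Logical; vectorised or scalar.
#' @param dim_p Day of conception (DIM units), required where `pregnant`.
#' @param parse Pregnancy-term grouping, `"literal"` or `"additive"`.
#' @return Expected ECM, kg/day.
#' @export
eval_milk_curve <- function(params, alpha_m = 1, dim, pregnant = FALSE,
                            dim_p = NA_real_,
                            parse = c("literal", "additive")) {
  parse <- .curve_parse(params, parse)
  p <- .as_curve_params(params)
  if (any(dim < 1)) {
    abort("eval_milk_curve(): dim must be >= 1.", class = "fapr_domain_error")
  }
  n <- max(length(dim), length(pregnant), length(dim_p), length(alpha_m))
  dim <- rep_len(dim, n)
  pregnant <- rep_len(pregnant, n)
  dim_p <- rep_len(dim_p, n)
  if (any(pregnant & (is.na(dim_p) | dim_p > dim))) {
    abort("eval_milk_curve(): pregnant rows need dim_p <= dim.",
          class = "fapr_domain_error")
  }
  preg_days <- ifelse(pregnant, pmax(dim - dim_p, 0), 0)
  expo <- if (parse == "literal") {
    -(p["c"] + p["d"] * preg_days) * dim
  } else {
    -p["c"] * dim - p["d"] * preg_days
  }
  unname(alpha_m * p["a"] * dim^p["b"] * exp(expo))
}

#' Evaluate the herd total-SCC curve for one cow
#'
#' Total test-day somatic cell count (tSCC = SCC x milk) follows a
#' double-exponential curve in days in milk, inspired by the Wilmink
#' test-day model: a slowly rising long-term component and a decaying
#' early-lactation component,
#' \deqn{f(DIM) = \exp\!\big(e^{\alpha^C a + b\,DIM} +
#'   d\,e^{-e^{c} DIM} - e\big)}
#' with `e` Euler's number (absorbable into `a`).  `alpha_c` is the cow's
#' tSCC level relative to the average cow; because it sits inside the inner
#' exponent, output is strictly increasing in `alpha_c` whenever `a > 0`.
#' An alternative `"power"` grouping replaces the early component with
#' `exp(-exp(c) * DIM^d)`.
#'
#' The inner exponent is clamped at `exp_cap` (log of the largest value the
#' outer exponential may take) to guard against overflow for extreme
#' levels; a warning reports when the clamp engages.
#'
#' @param params Named vector/list with `a`, `b`, `c`, `d`.
#' @param alpha_c Cow tSCC level relative to the average cow (default 1).
#' @param dim Days in milk (>= 0); vectorised.
#' @param parse `"default"` or `"power"`.
#' @param exp_cap Clamp on the log-scale value (default 500).
#' @return Expected tSCC, (×1000 cells/mL)·kg; strictly positive.
#' @export
eval_scc_curve <- function(params, alpha_c = 1, dim,
                           parse = c("default", "power"), exp_cap = 500) {
  parse <- .curve_parse(params, parse)
  p <- .as_curve_params(params)
  if (any(dim < 0)) {
    abort("eval_scc_curve(): dim must be >= 0.", class = "fapr_domain_error")
  }
  log_f <- .scc_log_curve(p, alpha_c, dim, parse)
  if (any(log_f > exp_cap)) {
    warn("eval_scc_curve(): log-scale value clamped to exp_cap.",
         class = "fapr_clamp_warning")
    log_f <- pmin(log_f, exp_cap)
  }
  unname(exp(log_f))
}

.scc_log_curve <- function(p, alpha_c, dim, parse = "default") {
  inner <- pmin(alpha_c * p["a"] + p["b"] * dim, 700)
  early <- if (parse == "power") {
    exp(-exp(p["c"]) * dim^p["d"])
  } else {
    p["d"] * exp(-exp(p["c"]) * dim)
  }
  exp(inner) + early - exp(1)
}

.as_curve_params <- function(params) {
  if (inherits(params, "fapr_curve")) params <- params$params
  p <- unlist(params[c("a", "b", "c", "d")])
  if (length(p) != 4 || any(is.na(p))) {
    abort("curve params must provide numeric a, b, c, d.",
          class = "fapr_domain_error")
  }
  p
}

.curve_parse <- function(params, parse) {
  stored <- if (inherits(params, "fapr_curve")) params$parse else
    if (is.list(params)) params$parse else NULL
  if (!is.null(stored)) stored else match.arg(parse, parse)
}

#' Fit a herd-level curve for one parity group
#'
#' Nonlinear least squares (Levenberg-Marquardt) with all cow levels fixed
#' at 1, so the fitted curve describes the average cow of the parity group
#' in this herd.  Milk (ECM) is fitted on the natural scale; tSCC on the
#' log scale (variance stabilisation, consistent with the double-exponential
#' form).  Starting values derive from Wood-curve heuristics (scale from
#' observed level, `b ~ 0.2`, `c ~ 0.002`); on non-convergence up to
#' `n_starts` deterministic perturbations of the start are tried and the
#' best converged attempt kept.
#'
#' @param records Derived records (see [derive_records()]) for one herd and
#'   one parity group; rows with `milk_kg == 0` are ignored (dry/missing).
#' @param family `"milk"` or `"scc"`.
#' @param min_lactations Minimum distinct cow-lactations required
#'   (default 20).
#' @param parse Curve grouping, passed to the evaluators.
#' @param n_starts Number of perturbed starts (default 5).
#' @return An object of class `fapr_curve`: list with `family`, `params`
#'   (a, b, c, d), `parse`, `resid_sd` (log scale for tSCC), `converged`,
#'   `n_lactations`, `n_obs`.
#' @export
fit_herd_curve <- function(records, family = c("milk", "scc"),
                           min_lactations = 20, parse = NULL, n_starts = 5) {
  family <- match.arg(family)
  parse <- parse %||% if (family == "milk") "literal" else "default"
  d <- filter(records, .data$milk_kg > 0, .data$dim >= 1)
  n_lact <- nrow(distinct(d, .data$cow_id, .data$parity))
  if (n_lact < min_lactations) {
    abort(sprintf(
      "fit_herd_curve(): %d lactation(s) in group, need at least %d.",
      n_lact, min_lactations), class = "fapr_insufficient_data")
  }
  if (family == "milk") {
    fit <- .fit_milk_nls(d, parse, n_starts)
  } else {
    fit <- .fit_scc_nls(d, parse, n_starts)
  }
  structure(
    list(family = family, params = fit$params, parse = parse,
         resid_sd = fit$resid_sd, converged = fit$converged,
         n_lactations = n_lact, n_obs = nrow(d)),
    class = "fapr_curve")
}

.perturb_grid <- function(n_starts) {
  # deterministic multiplicative perturbations of the heuristic start
  facs <- c(1, 0.5, 2, 0.8, 1.25, 0.65, 1.5, 0.9, 1.1)
  facs[seq_len(min(n_starts, length(facs)))]
}

.fit_milk_nls <- function(d, parse, n_starts) {
  d$preg_days <- ifelse(d$pregnant & !is.na(d$dim_p),
                        pmax(d$dim - d$dim_p, 0), 0)
  # without pregnant records the pregnancy slope has no gradient: fix d = 0
  has_preg <- any(d$preg_days > 0)
  form <- if (!has_preg) {
    ecm_kg ~ a * dim^b * exp(-c * dim)
  } else if (parse == "literal") {
    ecm_kg ~ a * dim^b * exp(-(c + dd * preg_days) * dim)
  } else {
    ecm_kg ~ a * dim^b * exp(-c * dim - dd * preg_days)
  }
  b0 <- 0.2; c0 <- 0.002
  a0 <- median(d$ecm_kg / (d$dim^b0 * exp(-c0 * d$dim)))
  best <- NULL
  for (f in .perturb_grid(n_starts)) {
    start <- list(a = a0 * f, b = b0 * f, c = c0 * f, dd = 1e-6)
    lower <- c(a = 1e-9, b = -2, c = -0.05, dd = 0)
    upper <- c(a = Inf, b = 3, c = 0.05, dd = 1e-2)
    if (!has_preg) {
      start$dd <- NULL
      lower <- lower[1:3]; upper <- upper[1:3]
    }
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nlsLM(form, data = d, start = start,
                          lower = lower, upper = upper,
                          control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      if (is.null(best) || deviance(fit) < deviance(best)) best <- fit
      if (f == 1) break  # heuristic start converged; accept
    }
  }
  out <- .package_nls(best, c(a = "a", b = "b", c = "c",
                              d = if (has_preg) "dd" else "c"))
  if (!has_preg) out$params[["d"]] <- 0
  out
}

.fit_scc_nls <- function(d, parse, n_starts) {
  d <- filter(d, .data$tscc > 0)
  d$log_tscc <- log(d$tscc)
  form <- if (parse == "power") {
    log_tscc ~ exp(a + b * dim) + exp(-exp(c) * dim^dd) - exp(1)
  } else {
    log_tscc ~ exp(a + b * dim) + dd * exp(-exp(c) * dim) - exp(1)
  }
  a0 <- log(pmax(median(d$log_tscc) + exp(1), 0.1))
  best <- NULL
  for (f in .perturb_grid(n_starts)) {
    start <- list(a = a0 * f, b = 5e-4 * f, c = -2.5, dd = 0.5 * f)
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nlsLM(form, data = d, start = start,
                          lower = c(a = -10, b = -0.05, c = -8, dd = 0),
                          upper = c(a = 10, b = 0.05, c = 2, dd = 20),
                          control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      if (is.null(best) || deviance(fit) < deviance(best)) best <- fit
      if (f == 1) break
    }
  }
  .package_nls(best, c(a = "a", b = "b", c = "c", d = "dd"))
}

.package_nls <- function(fit, name_map) {
  if (is.null(fit)) {
    abort("fit_herd_curve(): nonlinear fit failed to converge from any start.",
          class = "fapr_fit_error")
  }
  cf <- coef(fit)
  params <- setNames(cf[unname(name_map)], names(name_map))
  list(params = params,
       resid_sd = sqrt(deviance(fit) / max(1, df.residual(fit))),
       converged = TRUE)
}

#' Fit a cow's relative level against a fitted herd curve
#'
#' With the herd parameters fixed, a single level per cow-lactation remains.
#' For milk the model is linear in the level, so the least-squares estimate
#' is the closed-form weighted ratio
#' `alpha = sum(y * g) / sum(g^2)` with `g` the herd curve at each record's
#' DIM (including that record's pregnancy state).  For tSCC the level sits
#' inside the exponent and is found by one-dimensional least squares on the
#' log scale.  Lactations with fewer than `min_points` milk recordings are
#' not fitted: their level defaults to 1, or to a dam-derived prior when
#' `dam_alpha` is given (see [predict_next_alpha()]).
#'
#' @param records Derived records for one cow-lactation.
#' @param curve A fitted `fapr_curve` (or params list) for the cow's herd
#'   and parity group.
#' @param family `"milk"` or `"scc"`.
#' @param min_points Minimum milk recordings (default 6).
#' @param dam_alpha Optional smoothed level of the dam.
#' @param dam_xi Dam-offspring level correlation used with `dam_alpha`
#'   (default 0.3).
#' @return One-row tibble: `cow_id`, `parity`, `alpha`, `n_points`,
#'   `fittable`.
#' @export
fit_cow_level <- function(records, curve, family = c("milk", "scc"),
                          min_points = 6, dam_alpha = NULL, dam_xi = 0.3) {
  family <- match.arg(family)
  if (nrow(records) > 0 && all(records$milk_kg == 0)) {
    abort("fit_cow_level(): all milk records zero.",
          class = "fapr_domain_error")
  }
  d <- filter(records, .data$milk_kg > 0, .data$dim >= 1)
  default_alpha <- if (is.null(dam_alpha)) 1 else
    predict_next_alpha(dam_alpha, dam_xi)
  out <- tibble(cow_id = records$cow_id[1], parity = records$parity[1],
                alpha = default_alpha, n_points = nrow(d), fittable = FALSE)
  if (nrow(d) < min_points) return(out)
  if (family == "milk") {
    if (all(d$ecm_kg == 0)) {
      abort("fit_cow_level(): all milk records zero.",
            class = "fapr_domain_error")
    }
    g <- eval_milk_curve(curve, 1, d$dim, d$pregnant, d$dim_p)
    alpha <- sum(d$ecm_kg * g) / sum(g^2)
  } else {
    d <- filter(d, .data$tscc > 0)
    if (nrow(d) < min_points) return(out)
    ly <- log(d$tscc)
    p <- .as_curve_params(curve)
    parse <- .curve_parse(curve, "default")
    obj <- function(alpha) sum((ly - .scc_log_curve(p, alpha, d$dim, parse))^2)
    alpha <- optimize(obj, interval = c(-10, 10), tol = 1e-9)$minimum
  }
  out$alpha <- alpha
  out$fittable <- TRUE
  out
}

#' Per-record relative level against a herd curve
#'
#' Converts each test-day record into an instantaneous relative level `x`
#' against the fitted herd curve at that DIM: for milk `x = ECM / f(DIM)`;
#' for tSCC the single-point inversion of the curve in `alpha_c`.  These
#' per-record levels are what the exponential smoother consumes.
#'
#' @param records Derived records.
#' @param curve Fitted `fapr_curve` for the records' herd and parity group.
#' @param family `"milk"` or `"scc"`.
#' @return Numeric vector of levels (NA where undefined, e.g. zero milk).
#' @export
record_level <- function(records, curve, family = c("milk", "scc")) {
  family <- match.arg(family)
  if (family == "milk") {
    g <- eval_milk_curve(curve, 1, pmax(records$dim, 1), records$pregnant,
                         records$dim_p)
    x <- records$ecm_kg / g
    x[records$milk_kg <= 0 | records$dim < 1] <- NA_real_
  } else {
    p <- .as_curve_params(curve)
    parse <- .curve_parse(curve, "default")
    early <- if (parse == "power") {
      exp(-exp(p["c"]) * records$dim^p["d"])
    } else {
      p["d"] * exp(-exp(p["c"]) * records$dim)
    }
    inner <- log(records$tscc) + exp(1) - early
    x <- ifelse(inner > 0 & records$tscc > 0,
                (log(pmax(inner, 1e-12)) - p["b"] * records$dim) / p["a"],
                NA_real_)
    x[records$milk_kg <= 0] <- NA_real_
  }
  unname(x)
}

#' @export
print.fapr_curve <- function(x, ...) {
  cat(sprintf("<fapr_curve> %s curve (%s parse), %d lactations, %d obs\n",
              x$family, x$parse, x$n_lactations, x$n_obs))
  print(round(x$params, 6))
  invisible(x)
}

#' @method tidy fapr_curve
#' @export
tidy.fapr_curve <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' @method glance fapr_curve
#' @export
glance.fapr_curve <- function(x, ...) {
  tibble(family = x$family, parse = x$parse, resid_sd = x$resid_sd,
         converged = x$converged, n_lactations = x$n_lactations,
         n_obs = x$n_obs)
}
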