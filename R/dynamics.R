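# Temporal machinery: inter-lactation level correlations (xi), survival in
# days open (sigmoid), survival fractions (gamma), exponential smoothing.

#' Inter-lactation level correlation
#'
#' A cow's relative level in a later lactation regresses toward 1: the
#' deviation carries over with coefficient `xi`,
#' `(alpha_l - 1) = xi * (alpha_j - 1)`.  `xi` is the slope of the
#' no-intercept regression of later deviations on earlier deviations over
#' cows observed in both lactations.  Estimates based on fewer than
#' `min_pairs` cows should be replaced by a pooled estimate (the caller
#' pools across herds); this function fits one (j, l) combination.
#'
#' @param alpha_j,alpha_l Paired levels of the same cows in the earlier and
#'   later lactation.
#' @return One-row tibble: `xi`, `se`, `n_pairs`.
#' @export
fit_correlation <- function(alpha_j, alpha_l) {
  ok <- is.finite(alpha_j) & is.finite(alpha_l)
  x <- alpha_j[ok] - 1
  y <- alpha_l[ok] - 1
  if (length(x) < 2 || var(x) == 0) {
    abort("fit_correlation(): need >= 2 pairs with variance in the predictor.",
          class = "fapr_insufficient_data")
  }
  fit <- lm(y ~ x - 1)
  tibble(xi = unname(coef(fit)[1]),
         se = suppressWarnings(unname(sqrt(diag(vcov(fit)))[1])),
         n_pairs = length(x))
}

#' Shrink a level toward the herd average for a future lactation
#'
#' `1 + xi * (alpha - 1)`: a cow producing 10% above average with
#' `xi = 0.5` is predicted 5% above average next lactation.
#'
#' @param alpha Current relative level (> 0).
#' @param xi Inter-lactation correlation.
#' @return Predicted level for the future lactation.
#' @export
predict_next_alpha <- function(alpha, xi) {
  1 + xi * (alpha - 1)
}

#' Sigmoid survival curve in days open
#'
#' Probability that a cow not yet pregnant at `dim_open` days in milk
#' reaches a further lactation:
#' \deqn{S(t) = A - \frac{A}{\left[1 + (2^\nu - 1)
#'   e^{-B (t - M)}\right]^{1/\nu}}}
#' A generalised (Richards) logistic decay from asymptote `A` at small days
#' open to 0 for cows that stay open very long; `M` is the half-asymptote
#' point (`S(M) = A/2`), `B` the decay rate per day, `nu` the asymmetry.
#' `nu = 1` gives the standard logistic.
#'
#' @param params Named vector/list with `A`, `B`, `nu`, `M`.
#' @param dim_open Days open (days in milk while not pregnant); vectorised.
#' @return Survival probability in `[0, A]`, non-increasing in `dim_open`.
#' @export
eval_survival <- function(params, dim_open) {
  p <- .as_survival_params(params)
  if (any(dim_open < 0)) {
    abort("eval_survival(): dim_open must be >= 0.",
          class = "fapr_domain_error")
  }
  z <- pmin(-p["B"] * (dim_open - p["M"]), 700)
  unname(p["A"] - p["A"] / (1 + (2^p["nu"] - 1) * exp(z))^(1 / p["nu"]))
}

.as_survival_params <- function(params) {
  if (inherits(params, "fapr_survival")) params <- params$params
  p <- unlist(params[c("A", "B", "nu", "M")])
  if (length(p) != 4 || any(is.na(p))) {
    abort("survival params must provide numeric A, B, nu, M.",
          class = "fapr_domain_error")
  }
  p
}

#' Fit the survival curve from per-lactation outcomes
#'
#' The cohort has one row per completed cow-lactation: the days open at
#' conception, and whether the cow produced milk in a subsequent
#' lactation.  Days open are binned and the curve fitted by weighted
#' nonlinear least squares to the empirical fraction surviving per bin:
#' first with bin counts as weights, then one reweighting step with
#' inverse binomial variances at the fitted probabilities.  The logistic
#' sub-family (`nu = 1`, the parameterisation the method is built
#' around) is fitted first; the full asymmetric family is kept only when
#' an F-test on the residual sums of squares supports the extra
#' asymmetry parameter - with sparse coverage of the curve's shoulders,
#' `B` and `nu` trade off along a ridge (for large `nu` the family
#' degenerates to an exponential in `B/nu`) and the parsimonious fit is
#' the stabler estimate.  Yield groups (binned cow milk level) allow
#' exploration of survival by production; the final herd estimate uses
#' only cows at or above the herd-average milk level (`alpha_m >= 1`),
#' whose survival is stable in level, avoiding the manager's
#' cull-the-low-yielder bias.
#'
#' @param cohort Tibble with columns `days_open`, `survived` (logical or
#'   0/1) and optionally `alpha_m`.
#' @param min_cows Minimum rows needed to attempt a fit (default 25).
#' @param bin_width Days-open bin width (default 30).
#' @return Object of class `fapr_survival`: `params` (A, B, nu, M),
#'   `n_cows`, `converged`.
#' @export
fit_survival <- function(cohort, min_cows = 25, bin_width = 30) {
  d <- filter(cohort, is.finite(.data$days_open))
  d$survived <- as.numeric(d$survived)
  if (nrow(d) < min_cows) {
    abort(sprintf("fit_survival(): %d cows, need at least %d.",
                  nrow(d), min_cows),
          class = "fapr_insufficient_data")
  }
  if (all(d$survived == 1)) {
    # degenerate: no deaths observed over the range; flat curve at ~1
    return(structure(
      list(params = c(A = 1, B = 0.02, nu = 1,
                      M = max(d$days_open) + 300),
           n_cows = nrow(d), converged = TRUE, degenerate = TRUE),
      class = "fapr_survival"))
  }
  agg <- d %>%
    mutate(days_open = floor(.data$days_open / bin_width) * bin_width +
             bin_width / 2) %>%
    group_by(.data$days_open) %>%
    summarise(frac = mean(.data$survived), cnt = n(), .groups = "drop")
  A0 <- min(max(agg$frac), 0.99)
  M0 <- unname(quantile(d$days_open, 0.6))
  fit_family <- function(formula, starts, lower, upper, w) {
    best <- NULL
    for (start in starts) {
      fit <- tryCatch(
        suppressWarnings(
          minpack.lm::nlsLM(formula, data = agg, start = start, weights = w,
                            lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(maxiter = 300))),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || deviance(fit) < deviance(best))) {
        best <- fit
      }
    }
    best
  }
  form3 <- frac ~ A - A / (1 + exp(-B * (days_open - M)))
  starts3 <- lapply(c(1, 0.6, 1.6), function(f)
    list(A = A0, B = 0.03 * f, M = M0))
  lo3 <- c(A = 0.01, B = 1e-4, M = 0); up3 <- c(A = 1, B = 0.5, M = 1200)
  stage1 <- fit_family(form3, starts3, lo3, up3, agg$cnt)
  w <- if (!is.null(stage1)) {
    ph <- pmin(pmax(fitted(stage1), 0.03), 0.97)
    agg$cnt / (ph * (1 - ph))
  } else agg$cnt
  best3 <- fit_family(form3, starts3, lo3, up3, w)
  starts4 <- unlist(lapply(c(1, 0.6, 1.6), function(f)
    lapply(c(0.7, 1.5, 3), function(nu0)
      list(A = A0, B = 0.03 * f, nu = nu0, M = M0))), recursive = FALSE)
  best4 <- fit_family(
    frac ~ A - A / (1 + (2^nu - 1) * exp(-B * (days_open - M)))^(1 / nu),
    starts4, c(A = 0.01, B = 1e-4, nu = 0.25, M = 0),
    c(A = 1, B = 0.5, nu = 4, M = 1200), w)
  if (is.null(best3) && is.null(best4)) {
    abort("fit_survival(): no start converged.", class = "fapr_fit_error")
  }
  use4 <- FALSE
  if (!is.null(best3) && !is.null(best4)) {
    nb <- nrow(agg)
    f_stat <- (deviance(best3) - deviance(best4)) /
      (deviance(best4) / max(nb - 4, 1))
    use4 <- nb > 5 && f_stat > stats::qf(0.95, 1, nb - 4)
  } else if (is.null(best3)) {
    use4 <- TRUE
  }
  params <- if (use4) {
    coef(best4)[c("A", "B", "nu", "M")]
  } else {
    c(A = unname(coef(best3)["A"]), B = unname(coef(best3)["B"]),
      nu = 1, M = unname(coef(best3)["M"]))
  }
  structure(
    list(params = params, n_cows = nrow(d), converged = TRUE,
         degenerate = FALSE),
    class = "fapr_survival")
}

#' @export
print.fapr_survival <- function(x, ...) {
  cat(sprintf("<fapr_survival> %d cows\n", x$n_cows))
  print(round(x$params, 5))
  invisible(x)
}

#' @method tidy fapr_survival
#' @export
tidy.fapr_survival <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' Default yield-group bins for survival exploration
#'
#' Cows are binned by their milk level `alpha_m` into below-average
#' (`< 0.9`), average (`0.9`-`1.1`) and above-average (`> 1.1`) groups.
#'
#' @param alpha_m Numeric vector of milk levels.
#' @return Factor with levels `"<0.9"`, `"0.9-1.1"`, `">1.1"`.
#' @export
yield_group <- function(alpha_m) {
  cut(alpha_m, breaks = c(-Inf, 0.9, 1.1, Inf),
      labels = c("<0.9", "0.9-1.1", ">1.1"))
}

#' Distribution of the final lactation reached, given survival
#'
#' For cows that survived beyond parity `j`, `gamma[l]` is the fraction
#' whose final (last reached) lactation was `l`.  Lactations beyond
#' `n_max` are folded into `n_max`; the result sums to 1 over
#' `l in (j, n_max]`.
#'
#' @param final_parity Integer vector: final parity of completed cow
#'   histories.
#' @param j Current parity.
#' @param n_max Horizon (default 8).
#' @return Tibble with columns `l` and `gamma`.
#' @export
fit_gamma <- function(final_parity, j, n_max = 8) {
  fp <- final_parity[!is.na(final_parity)]
  fp <- pmin(fp, n_max)
  fp <- fp[fp > j]
  if (length(fp) == 0) {
    abort(sprintf(
      "fit_gamma(): no completed histories beyond parity %d.", j),
      class = "fapr_insufficient_data")
  }
  tab <- table(factor(fp, levels = (j + 1):n_max))
  tibble(l = (j + 1):n_max, gamma = as.numeric(tab) / length(fp))
}

#' One step of exponential smoothing
#'
#' `x_smooth_t = lambda * x_t + (1 - lambda) * x_smooth_{t-1}`: the running
#' estimate of a cow's current level, balancing responsiveness to the
#' latest test day against noise suppression.
#'
#' @param x_prev Previous smoothed value.
#' @param x_t New observation.
#' @param lambda Smoothing factor in `[0, 1]`.
#' @return Updated smoothed value.
#' @export
update_smoothed <- function(x_prev, x_t, lambda) {
  if (any(lambda < 0 | lambda > 1)) {
    abort("update_smoothed(): lambda must be in [0, 1].",
          class = "fapr_domain_error")
  }
  lambda * x_t + (1 - lambda) * x_prev
}

#' Smooth a whole observation series
#'
#' Applies [update_smoothed()] along a series, skipping NA observations,
#' starting from `x0` (1 for a heifer with no information; a dam-derived
#' value otherwise).
#'
#' @param x Numeric vector of per-test-day levels (NAs skipped).
#' @param lambda Smoothing factor.
#' @param x0 Initial value (default 1).
#' @return Vector of smoothed values, same length as `x` (entries where `x`
#'   is NA carry the previous smoothed value forward).
#' @export
smooth_series <- function(x, lambda, x0 = 1) {
  out <- numeric(length(x))
  s <- x0
  for (t in seq_along(x)) {
    if (!is.na(x[t])) s <- update_smoothed(s, x[t], lambda)
    out[t] <- s
  }
  out
}

#' Estimate the smoothing factor from training sequences
#'
#' Grid search over `lambda in {0, 0.01, ..., 1}` minimising, over all cows
#' and all interior time points `t_n`, the squared difference between the
#' smoothed value at `t_n` and the mean of all strictly later observations
#' of the same cow.  The optimum balances how quickly the smoother should
#' follow genuine level changes against chasing test-day noise.
#'
#' @param sequences List of numeric vectors, one per cow, each the cow's
#'   per-test-day levels in time order (length >= 3 to contribute).
#' @param x0 Initial smoothed value per sequence (default 1).
#' @param grid Candidate lambdas (default `seq(0, 1, 0.01)`).
#' @return One-row tibble: `lambda`, `sse`, `n_sequences`, `n_terms`.
#' @export
estimate_lambda <- function(sequences, x0 = 1, grid = seq(0, 1, by = 0.01)) {
  seqs <- lapply(sequences, function(x) x[!is.na(x)])
  seqs <- seqs[vapply(seqs, length, 1L) >= 3]
  if (length(seqs) == 0) {
    abort("estimate_lambda(): no usable sequences (need >= 3 points).",
          class = "fapr_insufficient_data")
  }
  # future mean at t excludes the current point
  fut <- lapply(seqs, function(x) {
    n <- length(x)
    rev(cumsum(rev(x)))[-1] / ((n - 1):1)  # mean of x[(t+1):n] for t < n
  })
  n_terms <- sum(vapply(fut, length, 1L))
  # one pass per sequence, vectorised over the whole lambda grid
  sse <- numeric(length(grid))
  for (i in seq_along(seqs)) {
    x <- seqs[[i]]
    s <- rep(x0, length(grid))
    for (t in seq_len(length(x) - 1)) {
      s <- grid * x[t] + (1 - grid) * s
      sse <- sse + (s - fut[[i]][t])^2
    }
  }
  best <- which.min(sse)
  tibble(lambda = grid[best], sse = sse[best],
         n_sequences = length(seqs), n_terms = n_terms)
}
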