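# Seeded synthetic-herd generator: herd recording data with known ground
# truth, structurally matched to the model the package fits.

#' Generator configuration
#'
#' Defaults describe a typical commercial Holstein herd on 11-per-year
#' milk recording.  Herd-average lactation curves are calibrated so mean
#' ECM by parity sits at the centre of the reported commercial ranges
#' (about 25.7 kg in parity 1 and 30.3 kg in parity 3+); cow milk levels
#' are N(1, 0.4) (truncated at `alpha_min`), tSCC levels log-normal with
#' unit median and a comparable 40% spread; consecutive-lactation level
#' deviations carry over with correlation 0.3.  Cow levels also drift
#' slowly within a lactation (random walk, `drift_sd` per test) so the
#' smoother has genuine signal to track.  Days open average exactly 61
#' days overall - prompt conceivers plus a repeat-breeder tail (default
#' 15%, mean 140 days open) covering the descending limb of the survival
#' curve; survival to the next lactation
#' is Bernoulli at the survival curve evaluated at realized days open
#' (culling is driven only by the survival curve, matching the model's
#' assumptions; no yield-dependent manager bias).
#'
#' @param n_herds,cows_per_herd,years Herd count, herd size, duration.
#' @param tests_per_year Recording frequency, 6 or 11.
#' @param milk_curves,scc_curves Tibbles (pg, a, b, c, d) of true herd
#'   curves per parity group.
#' @param survival Tibble (pg, A, B, nu, M) of true survival parameters.
#' @param alpha_sd SD of cow milk levels around 1 (default 0.4).
#' @param alpha_min Lower truncation of milk levels (default 0.05).
#' @param log_alpha_c_sd SD of log tSCC levels (default 0.39, ~40% spread).
#' @param xi True consecutive-lactation level correlation (default 0.3,
#'   both quantities).
#' @param drift_sd Within-lactation level random-walk step SD per test
#'   (default 0.02, both quantities on their level scales).
#' @param milk_noise_sd Observation noise on test-day ECM, kg
#'   (default 2.5).
#' @param log_tscc_noise_sd Observation noise on log tSCC (default 0.5).
#' @param fat_mean,fat_sd,protein_mean,protein_sd Test-day fat and protein
#'   percent.
#' @param days_open_mean Overall mean days open (default 61).
#' @param repeat_breeder_frac Fraction with long days open (default 0.15).
#' @param preg_recognition Days from conception to a recorded positive
#'   pregnancy status (default 35).
#' @param cull_bias Yield-dependent manager bias: survival is scaled by
#'   `1 + cull_bias * (alpha_m - 1)` (clamped to probabilities).  0 (the
#'   default) keeps culling driven only by the survival curve, matching
#'   the model's assumptions; positive values emulate managers who
#'   preferentially cull low producers, for robustness experiments.
#' @param constants [repro_constants()].
#' @param parity_init Initial parity distribution (parities 1..4).
#' @param seed Mandatory integer seed.
#' @return List of class `fapr_generator_config`.
#' @export
generator_config <- function(
    n_herds = 1, cows_per_herd = 100, years = 4, tests_per_year = 11,
    milk_curves = tibble(
      pg = c("1", "2", "3+"),
      a = c(17.10, 15.67, 14.58),
      b = c(0.15, 0.22, 0.25),
      c = c(0.0020, 0.0028, 0.0030),
      d = 3e-6),
    scc_curves = tibble(
      pg = c("1", "2", "3+"),
      a = c(2.30, 2.34, 2.37),
      b = 4e-4, c = -2.5, d = 0.6),
    survival = tibble(
      pg = c("1", "2", "3+"),
      A = c(0.92, 0.88, 0.82),
      B = 0.035, nu = 1,
      M = c(180, 160, 140)),
    alpha_sd = 0.4, alpha_min = 0.05, log_alpha_c_sd = 0.39,
    xi = 0.3, drift_sd = 0.02,
    milk_noise_sd = 2.5, log_tscc_noise_sd = 0.5,
    fat_mean = 4.0, fat_sd = 0.25, protein_mean = 3.4, protein_sd = 0.12,
    days_open_mean = 61, repeat_breeder_frac = 0.15,
    preg_recognition = 35, cull_bias = 0,
    constants = repro_constants(),
    parity_init = c(0.40, 0.28, 0.17, 0.15),
    seed = NULL) {
  if (is.null(seed)) {
    abort("generator_config(): a seed is mandatory.",
          class = "fapr_config_error")
  }
  if (!tests_per_year %in% c(6, 11)) {
    abort("generator_config(): tests_per_year must be 6 or 11.",
          class = "fapr_config_error")
  }
  stopifnot(alpha_sd >= 0, log_alpha_c_sd >= 0, drift_sd >= 0,
            milk_noise_sd >= 0, log_tscc_noise_sd >= 0,
            repeat_breeder_frac >= 0, repeat_breeder_frac <= 1)
  structure(as.list(environment()), class = "fapr_generator_config")
}

.draw_alpha_m <- function(n, cfg) {
  x <- rnorm(n, 1, cfg$alpha_sd)
  while (any(x < cfg$alpha_min)) {
    bad <- x < cfg$alpha_min
    x[bad] <- rnorm(sum(bad), 1, cfg$alpha_sd)
  }
  x
}

.draw_days_open <- function(n, cfg) {
  # mixture with overall mean exactly days_open_mean: prompt conceivers
  # plus a repeat-breeder tail (mean 140 d) covering the survival descent
  long <- runif(n) < cfg$repeat_breeder_frac
  mean_long <- 140
  mean_typ <- (cfg$days_open_mean -
                 cfg$repeat_breeder_frac * mean_long) /
    (1 - cfg$repeat_breeder_frac)
  d <- 21 + stats::rgamma(n, shape = 2, scale = pmax(mean_typ - 21, 5) / 2)
  d[long] <- 21 + stats::rgamma(sum(long), shape = 2,
                                scale = (mean_long - 21) / 2)
  round(d)
}

#' Simulate herd-recording data with known ground truth
#'
#' Cows progress through lactations on the herd's test calendar: levels
#' drawn at lactation start (correlated with the previous lactation),
#' drifting slowly within the lactation; test-day ECM is the true herd
#' curve times the current level plus Gaussian noise, tSCC the true curve
#' times a log-normal level and noise; conception day is drawn per
#' lactation, pregnancy appears in the records after a recognition lag,
#' dry-off follows conception by `gestation - dry_period` days, and
#' survival to the next lactation is Bernoulli at the true survival curve
#' evaluated at realized days open.  Exiting cows are replaced by fresh
#' parity-1 heifers, keeping herd size stable.  Fully reproducible from
#' the config seed.
#'
#' @param config A [generator_config()].
#' @return List with `records` (canonical schema tibble) and `truth`
#'   (list: `cow_lactations` tibble of per-lactation true levels - both
#'   the lactation-start draw and the realized within-lactation mean -
#'   days open and outcomes; `config` the generating configuration).
#' @export
simulate_herds <- function(config) {
  if (!inherits(config, "fapr_generator_config")) {
    abort("simulate_herds(): config must come from generator_config().",
          class = "fapr_config_error")
  }
  set.seed(config$seed)
  cfg <- config
  start <- as.Date("2006-01-01")
  end <- start + round(cfg$years * 365.25)
  step <- round(365 / cfg$tests_per_year)
  test_dates <- seq(start, end, by = step)
  lact_len <- cfg$constants$gestation - cfg$constants$dry_period

  all_records <- vector("list", cfg$n_herds)
  all_truth <- vector("list", cfg$n_herds)
  for (h in seq_len(cfg$n_herds)) {
    herd_id <- sprintf("H%03d", h)
    rec_acc <- list(); truth_acc <- list(); cow_counter <- 0L
    # active cows: list of (calving_date, parity, alpha_m, beta_c)
    queue <- lapply(seq_len(cfg$cows_per_herd), function(i) {
      list(calving = start - sample.int(280, 1),
           parity = sample(seq_along(cfg$parity_init), 1,
                           prob = cfg$parity_init))
    })
    qi <- 0L
    while (qi < length(queue)) {
      qi <- qi + 1L
      q <- queue[[qi]]
      cow_counter <- cow_counter + 1L
      cow_id <- sprintf("%s-C%05d", herd_id, cow_counter)
      alpha_m <- .draw_alpha_m(1, cfg)
      beta_c <- rnorm(1, 0, cfg$log_alpha_c_sd)
      calving <- q$calving; parity <- q$parity
      exited <- FALSE; exit_date <- end + 1
      repeat {
        pg <- parity_group(parity)
        mc <- cfg$milk_curves[cfg$milk_curves$pg == pg, ]
        sc <- cfg$scc_curves[cfg$scc_curves$pg == pg, ]
        sv <- cfg$survival[cfg$survival$pg == pg, ]
        days_open <- .draw_days_open(1, cfg)
        dry_dim <- days_open + lact_len
        dates <- test_dates[test_dates > calving &
                              test_dates <= calving + dry_dim]
        nrec <- length(dates)
        if (nrec > 0) {
          dim <- as.integer(dates - calving)
          # within-lactation random-walk drift of both levels
          am <- pmax(alpha_m + cumsum(rnorm(nrec, 0, cfg$drift_sd)),
                     cfg$alpha_min)
          bc <- beta_c + cumsum(rnorm(nrec, 0, cfg$drift_sd))
          preg <- dim >= days_open + cfg$preg_recognition
          ecm_true <- am * eval_milk_curve(
            list(a = mc$a, b = mc$b, c = mc$c, d = mc$d, parse = "literal"),
            1, dim, pregnant = dim > days_open, dim_p = days_open)
          ecm_obs <- pmax(ecm_true + rnorm(nrec, 0, cfg$milk_noise_sd), 0.5)
          fat <- pmax(rnorm(nrec, cfg$fat_mean, cfg$fat_sd), 1)
          protein <- pmax(rnorm(nrec, cfg$protein_mean, cfg$protein_sd), 1)
          milk <- ecm_obs / (0.122 * fat + 0.077 * protein + 0.249)
          tscc_true <- exp(bc) * eval_scc_curve(
            list(a = sc$a, b = sc$b, c = sc$c, d = sc$d,
                 parse = "default"), 1, dim)
          tscc_obs <- tscc_true * exp(rnorm(nrec, 0, cfg$log_tscc_noise_sd))
          rec_acc[[length(rec_acc) + 1L]] <- tibble(
            herd_id = herd_id, cow_id = cow_id, test_date = dates,
            parity = as.integer(parity), dim = dim,
            milk_kg = round(milk, 2), fat_pct = round(fat, 2),
            protein_pct = round(protein, 2),
            scc = round(tscc_obs / milk, 1),
            pregnant = preg,
            dim_p = ifelse(preg, as.integer(days_open), NA_integer_),
            dam_id = NA_character_)
          am_end <- am[nrec]; bc_end <- bc[nrec]
        } else {
          am_end <- alpha_m; bc_end <- beta_c
        }
        p_surv <- eval_survival(
          list(A = sv$A, B = sv$B, nu = sv$nu, M = sv$M), days_open)
        if (cfg$cull_bias != 0) {
          p_surv <- min(max(p_surv * (1 + cfg$cull_bias * (alpha_m - 1)),
                            0), 1)
        }
        survived <- runif(1) < p_surv
        truth_acc[[length(truth_acc) + 1L]] <- tibble(
          herd_id = herd_id, cow_id = cow_id, parity = as.integer(parity),
          calving_date = calving, alpha_m = alpha_m,
          alpha_c_mult = exp(beta_c),
          alpha_m_real = if (nrec > 0) mean(am) else alpha_m,
          log_alpha_c_real = if (nrec > 0) mean(bc) else beta_c,
          days_open = days_open,
          survived = survived, n_records = nrec)
        exit_date <- calving + dry_dim
        if (!survived) { exited <- TRUE; break }
        if (exit_date > end) break
        # next lactation: deviations carry over with correlation xi
        calving <- calving + days_open + cfg$constants$gestation
        parity <- parity + 1L
        alpha_m <- max(1 + cfg$xi * (am_end - 1) +
                         rnorm(1, 0, cfg$alpha_sd * sqrt(1 - cfg$xi^2)),
                       cfg$alpha_min)
        beta_c <- cfg$xi * bc_end +
          rnorm(1, 0, cfg$log_alpha_c_sd * sqrt(1 - cfg$xi^2))
        if (calving > end) break
      }
      # replacement heifer takes the stall after an exit inside the window
      if (exited && exit_date <= end - 30) {
        queue[[length(queue) + 1L]] <- list(
          calving = exit_date + sample.int(30, 1), parity = 1L)
      }
    }
    all_records[[h]] <- bind_rows(rec_acc)
    all_truth[[h]] <- bind_rows(truth_acc)
  }
  records <- bind_rows(all_records) %>%
    arrange(.data$herd_id, .data$cow_id, .data$test_date)
  list(records = records,
       truth = list(cow_lactations = bind_rows(all_truth), config = cfg))
}

#' Split records at a calendar date
#'
#' @param records Canonical records.
#' @param split_date Records strictly before the date form the training
#'   set; the rest the test set.  Cows may span both.
#' @return List with `train` and `test` tibbles.
#' @export
train_test_split <- function(records, split_date) {
  split_date <- as.Date(split_date)
  list(train = filter(records, .data$test_date < split_date),
       test = filter(records, .data$test_date >= split_date))
}

#' Drop herds below a minimum average size
#'
#' Herds whose average number of lactating cows per recording date (in the
#' given records, typically the training period) is below `min_cows` are
#' excluded.
#'
#' @param records Canonical records.
#' @param min_cows Minimum average lactating cows per test date
#'   (default 50).
#' @return Records of the retained herds.
#' @export
filter_herds_min_size <- function(records, min_cows = 50) {
  keep <- records %>%
    filter(.data$milk_kg > 0) %>%
    count(.data$herd_id, .data$test_date) %>%
    group_by(.data$herd_id) %>%
    summarise(avg = mean(.data$n), .groups = "drop") %>%
    filter(.data$avg >= min_cows) %>%
    pull(.data$herd_id)
  filter(records, .data$herd_id %in% keep)
}
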