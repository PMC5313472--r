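# Plots for fitted herd models and FAP profiles.

#' Fitted herd curves
#'
#' Lactation (ECM) and total-SCC curves of the average cow per parity
#' group for one herd.
#'
#' @param object A `herd_model`.
#' @param herd_id Herd to plot (default: first herd in the model).
#' @param dim_max Last day in milk shown (default 400).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot herd_model
#' @export
autoplot.herd_model <- function(object, herd_id = NULL, dim_max = 400,
                                ...) {
  herd_id <- herd_id %||% object$curves$herd_id[1]
  grid <- tidyr::expand_grid(pg = unique(object$curves$pg),
                             dim = seq(3, dim_max, by = 2))
  d <- grid %>%
    group_by(.data$pg) %>%
    group_modify(function(g, key) {
      mc <- herd_curve(object, herd_id, key$pg, "milk")
      sc <- herd_curve(object, herd_id, key$pg, "scc")
      tibble(dim = g$dim,
             `ECM (kg/day)` = eval_milk_curve(mc, 1, g$dim),
             `tSCC (x1000 cells)` = eval_scc_curve(sc, 1, g$dim))
    }) %>%
    ungroup() %>%
    tidyr::pivot_longer(-c("pg", "dim"), names_to = "quantity",
                        values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$dim, .data$value,
                                  colour = .data$pg)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "days in milk", y = NULL, colour = "parity group",
                  title = paste("Herd", herd_id)) +
    ggplot2::theme_minimal()
}

#' FAP profile over a lactation
#'
#' FAP as a function of days in milk for a cow of given parity and levels,
#' for the pregnant (conception at the average days open) and open cases.
#'
#' @param model A `herd_model`.
#' @param herd_id Herd.
#' @param parity Parity of the cow.
#' @param alpha_m,alpha_c Smoothed levels (default 1: the average cow).
#' @param dim_grid Days in milk at which to evaluate (default every 10 d
#'   to 305).
#' @return Tibble with `dim`, `pregnant`, `fap` plus a ggplot in
#'   attribute-free form via [autoplot()]-style usage; plot with
#'   `plot_fap_profile()`'s return value and ggplot2.
#' @export
fap_profile <- function(model, herd_id, parity = 1, alpha_m = 1,
                        alpha_c = 1, dim_grid = seq(5, 305, by = 10)) {
  dto <- model$constants$days_to_conception
  purrr::map_dfr(dim_grid, function(dd) {
    purrr::map_dfr(c(FALSE, TRUE), function(pr) {
      if (pr && dd <= dto) return(tibble())
      st <- list(parity = parity, dim = dd, pregnant = pr,
                 dim_p = if (pr) dto else NA_real_,
                 alpha_m = alpha_m, alpha_c = alpha_c)
      r <- fap(st, model, herd_id)
      tibble(dim = dd, pregnant = pr, fap = r$fap, fap_c = r$fap_c,
             s = r$s)
    })
  })
}

#' Plot FAP profiles by parity
#'
#' Profiles of FAP over days in milk for parities 1-3 of the average cow,
#' pregnant (solid) and open (dotted).
#'
#' @param model A `herd_model`.
#' @param herd_id Herd (default: first in the model).
#' @param parities Parities to show (default 1:3).
#' @return A ggplot object.
#' @export
plot_fap_profiles <- function(model, herd_id = NULL, parities = 1:3) {
  herd_id <- herd_id %||% model$curves$herd_id[1]
  d <- purrr::map_dfr(parities, function(p) {
    mutate(fap_profile(model, herd_id, parity = p), parity = factor(p))
  })
  ggplot2::ggplot(d, ggplot2::aes(.data$dim, .data$fap,
                                  colour = .data$parity,
                                  linetype = .data$pregnant)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid",
                                              `FALSE` = "dotted")) +
    ggplot2::labs(x = "days in milk", y = "FAP (kg milk/day)",
                  linetype = "pregnant") +
    ggplot2::theme_minimal()
}
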