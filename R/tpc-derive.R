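#' Derive Pmax and Topt posteriors by two-stage grid search
#'
#' For each posterior draw the population-level curve is evaluated on a
#' coarse equally spaced grid over `[tmin, tmax]`; around the coarse argmax
#' (one coarse step either side, clipped to the limits) a fine grid is then
#' evaluated, and its argmax gives `t_opt` with value `p_max`.
#'
#' @param draws a `tpc_draws` object from [fit_hierarchical_tpc()], or a
#'   data frame with columns `pop_tmin`, `pop_tmax`, `pop_a`, `pop_b`,
#'   `pop_c` (one row per draw).
#' @param n_coarse,n_fine grid sizes for the two stages.
#' @return Data frame with one row per draw: `p_max` (m/s), `t_opt`
#'   (degrees C).
#' @export
derive_pmax_topt <- function(draws, n_coarse = 50L, n_fine = 100L) {
  df <- if (inherits(draws, "tpc_draws")) draws$draws else draws
  need <- paste0("pop_", tpc_param_names)
  if (!all(need %in% names(df)) || nrow(df) == 0L)
    stop_input("derive_pmax_topt: draws must be non-empty with columns %s",
               paste(need, collapse = ", "))
  n <- nrow(df)
  p_max <- t_opt <- numeric(n)
  for (d in seq_len(n)) {
    tmin <- df$pop_tmin[d]; tmax <- df$pop_tmax[d]
    a <- df$pop_a[d]; b <- df$pop_b[d]; cc <- df$pop_c[d]
    coarse <- seq(tmin, tmax, length.out = n_coarse)
    pc <- kamykowski_raw(coarse, tmin, tmax, a, b, cc)
    j <- which.max(pc)
    lo <- coarse[max(j - 1L, 1L)]
    hi <- coarse[min(j + 1L, n_coarse)]
    fine <- seq(lo, hi, length.out = n_fine)
    pf <- kamykowski_raw(fine, tmin, tmax, a, b, cc)
    jf <- which.max(pf)
    p_max[d] <- pf[jf]
    t_opt[d] <- fine[jf]
  }
  data.frame(p_max = p_max, t_opt = t_opt)
}

#' Pointwise posterior bands of the population performance curve
#'
#' @param draws as in [derive_pmax_topt()].
#' @param t_grid temperatures (degrees C) at which to evaluate the bands.
#' @return Data frame with columns `temperature_c`, `q025`, `q25`,
#'   `median`, `q75`, `q975` — the 95% and 50% pointwise credible bands and
#'   the median; bands are nested by construction of the quantiles.
#' @export
posterior_curve_bands <- function(draws, t_grid) {
  df <- if (inherits(draws, "tpc_draws")) draws$draws else draws
  if (length(t_grid) == 0L)
    stop_input("posterior_curve_bands: t_grid must be non-empty")
  curves <- vapply(seq_len(nrow(df)), function(d) {
    kamykowski_raw(t_grid, df$pop_tmin[d], df$pop_tmax[d], df$pop_a[d],
                   df$pop_b[d], df$pop_c[d])
  }, numeric(length(t_grid)))
  curves <- matrix(curves, nrow = length(t_grid))
  qs <- apply(curves, 1, stats::quantile,
              probs = c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
  data.frame(temperature_c = t_grid, q025 = qs[1, ], q25 = qs[2, ],
             median = qs[3, ], q75 = qs[4, ], q975 = qs[5, ])
}

#' Posterior summary of a fitted TPC model
#'
#' @param fit a `tpc_draws` object.
#' @param probs quantiles reported for each population-level quantity.
#' @return Data frame of medians/intervals for the natural-scale population
#'   parameters, `sigma_obs`, and the derived `p_max` / `t_opt`.
#' @export
summarise_tpc_fit <- function(fit, probs = c(0.025, 0.5, 0.975)) {
  stopifnot(inherits(fit, "tpc_draws"))
  der <- derive_pmax_topt(fit)
  qty <- cbind(fit$draws[paste0("pop_", tpc_param_names)],
               sigma_obs = fit$draws$sigma_obs, der)
  out <- data.frame(quantity = names(qty),
                    t(apply(qty, 2, stats::quantile, probs = probs)),
                    check.names = FALSE, row.names = NULL)
  names(out)[-1] <- sprintf("q%g", probs * 100)
  out
}
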