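#' Configuration for the synthetic thermal-trait generator
#'
#' Describes a two-factor acclimation experiment: `n_groups` acclimation
#' groups, each with its own true population TPC, and
#' `n_individuals_per_group` individuals whose parameters scatter around
#' the group truth. Each individual contributes one CTmin and one CTmax
#' record (zero performance, with a ramp-rate covariate) plus one sprint
#' record per test temperature.
#'
#' @param n_groups number of acclimation groups.
#' @param n_individuals_per_group individuals per group (>= 2).
#' @param pop_params_per_group list of [tpc_params()] of length `n_groups`.
#' @param sd_individual named numeric vector of between-individual SDs, one
#'   per TPC parameter (natural units).
#' @param sd_obs observation noise on sprint speed (m/s).
#' @param test_temperatures strictly increasing test temperatures (C).
#' @param ramp_rate_range length-2 range of the heating/cooling ramp rate
#'   covariate (C/min) attached to the critical-limit records.
#' @param seed integer seed; the whole dataset is reproducible from
#'   `(config, seed)`.
#' @return A list of class `synth_thermal_config`.
#' @export
synth_thermal_config <- function(n_groups = 2L,
                                 n_individuals_per_group = 15L,
                                 pop_params_per_group = list(
                                   tpc_params(6.5, 42.5, 0.786, 0.09, 0.886),
                                   tpc_params(8.0, 44.5, 0.918, 0.09, 0.761)
                                 ),
                                 sd_individual = c(tmin = 0.7, tmax = 0.7,
                                                   a = 0.06, b = 0.01,
                                                   c = 0.04),
                                 sd_obs = 0.05,
                                 test_temperatures = c(15, 20, 25, 30, 35, 37),
                                 ramp_rate_range = c(0.8, 1.7),
                                 seed = 1L) {
  n_groups <- chk_count(n_groups, "n_groups")
  n_ind <- chk_count(n_individuals_per_group, "n_individuals_per_group",
                     min = 2L)
  if (length(pop_params_per_group) != n_groups)
    stop_input("configuration error: 'pop_params_per_group' must have %d entries",
               n_groups)
  if (!all(tpc_param_names %in% names(sd_individual)))
    stop_input("configuration error: 'sd_individual' must name all of %s",
               paste(tpc_param_names, collapse = ", "))
  chk_pos(sd_individual, "sd_individual")
  if (!is.numeric(sd_obs) || sd_obs < 0)
    stop_input("configuration error: 'sd_obs' must be >= 0")
  if (length(test_temperatures) < 2L ||
      any(diff(test_temperatures) <= 0))
    stop_input("configuration error: 'test_temperatures' must be strictly increasing")
  if (length(ramp_rate_range) != 2L || ramp_rate_range[1] > ramp_rate_range[2])
    stop_input("configuration error: 'ramp_rate_range' must be an increasing pair")
  structure(list(n_groups = n_groups,
                 n_individuals_per_group = n_ind,
                 pop_params_per_group = pop_params_per_group,
                 sd_individual = sd_individual[tpc_param_names],
                 sd_obs = as.numeric(sd_obs),
                 test_temperatures = as.numeric(test_temperatures),
                 ramp_rate_range = as.numeric(ramp_rate_range),
                 seed = as.integer(seed)),
            class = "synth_thermal_config")
}

#' Generate a synthetic thermal-trait dataset with known truth
#'
#' Individual parameters are drawn as `pop + Normal(0, sd_individual)` on
#' the natural scale (with `b`, `c`, `a` floored at a small positive value
#' and `tmin < tmax` enforced). CTmin/CTmax rows use the individual's own
#' true limits as the recorded temperature and exactly zero performance;
#' sprint rows are the clamped curve plus Gaussian noise, floored at zero.
#'
#' @param cfg a [synth_thermal_config()].
#' @return A list with `traits` (long data frame with columns
#'   `individual_id`, `group`, `kind`, `temperature_c`, `performance_ms`,
#'   `ramp_rate_c_per_min`) and `truth` (population and per-individual
#'   parameters plus the config echo).
#' @export
gen_thermal_dataset <- function(cfg) {
  if (!inherits(cfg, "synth_thermal_config"))
    stop_input("gen_thermal_dataset: cfg must be a synth_thermal_config")
  with_derived_seed(cfg$seed, "thermal", {
    rows <- list()
    indiv_truth <- list()
    temps <- cfg$test_temperatures
    for (g in seq_len(cfg$n_groups)) {
      pop <- cfg$pop_params_per_group[[g]]
      gname <- sprintf("G%d", g)
      for (i in seq_len(cfg$n_individuals_per_group)) {
        id <- sprintf("%s_ind%02d", gname, i)
        th <- unlist(pop[tpc_param_names]) +
          stats::rnorm(5, 0, cfg$sd_individual)
        names(th) <- tpc_param_names
        th[c("a", "b", "c")] <- pmax(th[c("a", "b", "c")], 1e-4)
        if (th["tmin"] >= th["tmax"])
          th[c("tmin", "tmax")] <- c(min(th["tmin"], th["tmax"]) - 0.5,
                                     max(th["tmin"], th["tmax"]) + 0.5)
        ramp <- stats::runif(2, cfg$ramp_rate_range[1], cfg$ramp_rate_range[2])
        mu <- kamykowski_raw(temps, th["tmin"], th["tmax"], th["a"],
                             th["b"], th["c"])
        y <- pmax(0, mu + stats::rnorm(length(temps), 0, cfg$sd_obs))
        rows[[id]] <- data.frame(
          individual_id = id, group = gname,
          kind = c("ctmin_anchor", "ctmax_anchor",
                   rep("sprint", length(temps))),
          temperature_c = c(th[["tmin"]], th[["tmax"]], temps),
          performance_ms = c(0, 0, y),
          ramp_rate_c_per_min = c(ramp, rep(NA_real_, length(temps))),
          stringsAsFactors = FALSE)
        indiv_truth[[id]] <- c(group = gname, th)
      }
    }
    traits <- do.call(rbind, rows)
    rownames(traits) <- NULL
    truth <- list(
      population = lapply(cfg$pop_params_per_group,
                          function(p) unlist(p[tpc_param_names])),
      individuals = do.call(rbind, lapply(names(indiv_truth), function(id) {
        v <- indiv_truth[[id]]
        data.frame(individual_id = id, group = v[["group"]],
                   tmin = as.numeric(v[["tmin"]]),
                   tmax = as.numeric(v[["tmax"]]),
                   a = as.numeric(v[["a"]]), b = as.numeric(v[["b"]]),
                   c = as.numeric(v[["c"]]), stringsAsFactors = FALSE)
      })),
      config = cfg)
    list(traits = traits, truth = truth)
  })
}
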