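#' Thermal performance curve parameters
#'
#' Container for the five parameters of the asymmetric double-exponential
#' (Kamykowski-type) thermal performance curve
#' \deqn{P(T) = a (1 - e^{-b (T - t_{min})}) (1 - e^{-c (t_{max} - T)})}
#' clamped at zero: performance is zero at and beyond the critical thermal
#' limits `tmin` and `tmax`.
#'
#' @param tmin lower zero-performance temperature (degrees C).
#' @param tmax upper zero-performance temperature (degrees C).
#' @param a performance scale (m/s).
#' @param b rise rate of the ascending limb (1/degrees C).
#' @param c fall rate of the descending limb (1/degrees C).
#' @return A named list of class `tpc_params`.
#' @export
tpc_params <- function(tmin, tmax, a, b, c) {
  for (v in list(tmin, tmax, a, b, c))
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop_input("tpc_params: all parameters must be finite scalars")
  if (tmin >= tmax) stop_input("tpc_params: tmin must be < tmax")
  if (a <= 0 || b <= 0 || c <= 0)
    stop_input("tpc_params: a, b and c must be > 0")
  structure(list(tmin = tmin, tmax = tmax, a = a, b = b, c = c),
            class = "tpc_params")
}

tpc_param_names <- c("tmin", "tmax", "a", "b", "c")

#' Evaluate the clamped Kamykowski performance curve
#'
#' @param temp body temperature(s), degrees C (vectorised).
#' @param params a [tpc_params()] object (or named list with the same
#'   fields).
#' @return Predicted performance (m/s), non-negative; exactly zero at
#'   `tmin`, `tmax` and outside that interval.
#' @examples
#' p <- tpc_params(10, 40, 1, 0.2, 0.2)
#' kamykowski_performance(25, p)   # (1 - exp(-3))^2
#' @export
kamykowski_performance <- function(temp, params) {
  if (is.null(params$tmin) || params$tmin >= params$tmax ||
      params$a <= 0 || params$b <= 0 || params$c <= 0)
    stop_input("kamykowski_performance: invalid parameters")
  kamykowski_raw(temp, params$tmin, params$tmax, params$a, params$b,
                 params$c)
}

# vectorised clamped core, no validation
kamykowski_raw <- function(temp, tmin, tmax, a, b, c) {
  p <- a * (1 - exp(-b * (temp - tmin))) * (1 - exp(-c * (tmax - temp)))
  p[p < 0] <- 0
  p[temp <= tmin | temp >= tmax] <- 0
  p
}

# unclamped double-exponential: negative beyond the limits. Used as the
# likelihood mean so the zero anchors identify the limits from both sides
# (the clamped version is flat in tmax beyond the hottest observation).
kamykowski_unclamped <- function(temp, tmin, tmax, a, b, c) {
  a * (1 - exp(-b * (temp - tmin))) * (1 - exp(-c * (tmax - temp)))
}

#' Heuristic starting values and box bounds for the TPC parameters
#'
#' Mirrors the usual nonlinear-least-squares warm start: the critical-limit
#' anchors centre `tmin`/`tmax`, the largest observed performance centres
#' `a`, and the rate parameters get a broad positive box.
#'
#' @param obs a data frame of performance observations with columns `kind`
#'   (`"sprint"`, `"ctmin_anchor"`, `"ctmax_anchor"`), `temperature_c` and
#'   `performance_ms`.
#' @return A data frame with one row per parameter and columns `init`,
#'   `lower`, `upper` (class `param_bounds`).
#' @export
estimate_start_bounds <- function(obs) {
  need <- c("kind", "temperature_c", "performance_ms")
  if (!all(need %in% names(obs)))
    stop_input("estimate_start_bounds: obs must have columns %s",
               paste(need, collapse = ", "))
  missing_kinds <- setdiff(c("ctmin_anchor", "ctmax_anchor"), obs$kind)
  if (length(missing_kinds))
    stop_input("estimate_start_bounds: missing anchor kinds: %s",
               paste(missing_kinds, collapse = ", "))
  sprint <- obs[obs$kind == "sprint", , drop = FALSE]
  if (nrow(sprint) < 3L)
    stop_input("estimate_start_bounds: need >= 3 sprint rows, got %d",
               nrow(sprint))
  tmin_init <- mean(obs$temperature_c[obs$kind == "ctmin_anchor"])
  tmax_init <- mean(obs$temperature_c[obs$kind == "ctmax_anchor"])
  a_init <- max(sprint$performance_ms)
  if (a_init <= 0)
    stop_input("estimate_start_bounds: all sprint performances are zero")
  out <- data.frame(
    parameter = tpc_param_names,
    init  = c(tmin_init, tmax_init, a_init, 0.1, 0.1),
    lower = c(tmin_init - 10, tmax_init - 10, 0.1 * a_init, 1e-3, 1e-3),
    upper = c(tmin_init + 10, tmax_init + 10, 10 * a_init, 10, 10),
    stringsAsFactors = FALSE
  )
  class(out) <- c("param_bounds", "data.frame")
  out
}

#' Logit-bounded reparameterisation
#'
#' Maps an unconstrained value `eta` to the interval `(lower, upper)` via
#' `lower + (upper - lower) * plogis(eta)`, and back. Used both by the
#' hierarchical sampler and when converting posterior draws to the natural
#' scale.
#'
#' @param eta unconstrained value(s).
#' @param lower,upper box bounds.
#' @return `to_bounded()` gives values in `(lower, upper)`;
#'   `to_unconstrained()` inverts it.
#' @export
to_bounded <- function(eta, lower, upper) {
  lower + (upper - lower) * stats::plogis(eta)
}

#' @rdname to_bounded
#' @param theta bounded value(s) strictly inside `(lower, upper)`.
#' @export
to_unconstrained <- function(theta, lower, upper) {
  stats::qlogis((theta - lower) / (upper - lower))
}
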