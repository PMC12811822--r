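# Hierarchical Bayesian TPC estimation.
#
# Model (per acclimation group, fitted independently):
#   theta_{ik} = L_k + (U_k - L_k) * inv_logit(mu_k + sigma_k * z_{ik})
#   z_{ik} ~ N(0, 1)                       (non-centred deviations)
#   y_j ~ N(max(0, P(T_j; theta_{i(j)})), sigma_obs)
# CTmin/CTmax records enter the likelihood as ordinary observations with
# y = 0. Priors: mu_k ~ N(eta0_k, 1.5) with eta0_k the unconstrained image
# of the warm-start init; sigma_k ~ half-N(0, 0.5); sigma_obs ~
# half-N(0, sd(y)). Sampling uses an adaptive Metropolis-within-Gibbs
# kernel (scalar updates for population quantities, 5-d block updates per
# individual), adapted only during warmup.

#' Fit the hierarchical thermal-performance-curve model
#'
#' @param obs data frame with columns `individual_id`, `kind`,
#'   `temperature_c`, `performance_ms` (anchors carry zero performance).
#' @param bounds parameter bounds from [estimate_start_bounds()]; computed
#'   from `obs` when `NULL`.
#' @param n_chains,n_warmup,n_sampling MCMC run lengths.
#' @param seed integer seed; chains use sub-seeds derived from it, so a
#'   fixed seed gives bit-identical draws.
#' @param rhat_threshold convergence is flagged (not silently accepted)
#'   when any split R-hat exceeds this value.
#' @return An object of class `tpc_draws`: a list with `draws` (one row per
#'   draw, columns `.chain`, `.iteration`, population-level quantities
#'   `mu_*`, `sigma_*`, `pop_*` (natural scale), `sigma_obs`, and
#'   individual deviations `z_*`), `diagnostics` (split R-hat and effective
#'   sample size per quantity), `converged`, `divergences` (count of
#'   numerically invalid proposals after warmup), `bounds`, and
#'   `individual_ids`.
#' @export
fit_hierarchical_tpc <- function(obs, bounds = NULL, n_chains = 4L,
                                 n_warmup = 1000L, n_sampling = 1000L,
                                 seed = 1L, rhat_threshold = 1.05) {
  need <- c("individual_id", "kind", "temperature_c", "performance_ms")
  if (!all(need %in% names(obs)))
    stop_input("fit_hierarchical_tpc: obs must have columns %s",
               paste(need, collapse = ", "))
  ids <- sort(unique(obs$individual_id))
  if (length(ids) < 2L)
    stop_input("fit_hierarchical_tpc: need >= 2 individuals")
  if (all(obs$performance_ms == 0))
    stop_input("fit_hierarchical_tpc: degenerate data (all performances zero)")
  if (is.null(bounds)) bounds <- estimate_start_bounds(obs)
  L <- bounds$lower; U <- bounds$upper
  eta0 <- to_unconstrained(pmin(pmax(bounds$init, L + 1e-6 * (U - L)),
                                U - 1e-6 * (U - L)), L, U)

  ind_idx <- match(obs$individual_id, ids)
  tvec <- obs$temperature_c
  yvec <- obs$performance_ms
  n_ind <- length(ids)
  sdy <- stats::sd(yvec)

  chains <- lapply(seq_len(n_chains), function(ch) {
    run_tpc_chain(tvec, yvec, ind_idx, n_ind, L, U, eta0, sdy,
                  n_warmup, n_sampling,
                  chain_seed = derive_seed(seed, sprintf("tpc-chain-%d", ch)))
  })

  draw_mats <- lapply(chains, `[[`, "draws")
  qn <- colnames(draw_mats[[1]])
  all_draws <- do.call(rbind, draw_mats)
  draws_df <- data.frame(
    .chain = rep(seq_len(n_chains), each = n_sampling),
    .iteration = rep(seq_len(n_sampling), times = n_chains),
    all_draws, check.names = FALSE)

  diag_df <- data.frame(
    quantity = qn,
    rhat = vapply(qn, function(q) split_rhat(
      lapply(draw_mats, function(m) m[, q])), numeric(1)),
    ess = vapply(qn, function(q) ess_basic(
      lapply(draw_mats, function(m) m[, q])), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  converged <- all(is.na(diag_df$rhat) | diag_df$rhat <= rhat_threshold)
  if (!converged)
    warning(sprintf(
      "fit_hierarchical_tpc: %d quantities have split R-hat > %.2f; results flagged as non-converged",
      sum(diag_df$rhat > rhat_threshold, na.rm = TRUE), rhat_threshold),
      call. = FALSE)

  structure(list(draws = draws_df, diagnostics = diag_df,
                 converged = converged,
                 divergences = sum(vapply(chains, `[[`, numeric(1), "bad")),
                 bounds = bounds, individual_ids = ids,
                 n_chains = n_chains, n_sampling = n_sampling,
                 seed = seed),
            class = "tpc_draws")
}

# one adaptive MwG chain; returns draws matrix (n_sampling x n_quantities).
# Kernel per stored iteration: `sweeps` repetitions of
#   (1) scalar random-walk updates of mu_k, log sigma_k, log sigma_obs
#       (non-centred: z held fixed),
#   (2) a joint update of the 5-vector mu using the empirical warmup
#       covariance (Haario-style), to traverse the ridge between the upper
#       limit and the fall rate,
#   (3) per-individual block updates of z_i with per-individual adaptive
#       proposal covariance,
#   (4) interweaved centred moves holding the individual-level eta fixed:
#       exact Gibbs for mu_k given eta and sigma, and a scale move on
#       sigma_k with z rescaled so the likelihood is untouched.
# The centred/non-centred interweaving is what lets the population location
# and spread mix when the individual curves are tightly identified.
run_tpc_chain <- function(tvec, yvec, ind_idx, n_ind, L, U, eta0, sdy,
                          n_warmup, n_sampling, chain_seed, sweeps = 2L) {
  withr::with_seed(chain_seed, {
    K <- 5L
    mu <- eta0 + stats::rnorm(K, 0, 0.3)   # overdispersed chain starts
    lsig <- rep(log(0.1), K)
    lso <- log(max(0.5 * sdy, 0.01))
    z <- matrix(0, n_ind, K)
    rows_of <- split(seq_along(tvec), ind_idx)

    theta_fun <- function(mu, lsig, z) {
      eta <- sweep(z * rep(exp(lsig), each = n_ind), 2, mu, "+")
      to_bounded(eta, matrix(L, n_ind, K, byrow = TRUE),
                 matrix(U, n_ind, K, byrow = TRUE))
    }
    mean_fun <- function(theta, rows = seq_along(tvec)) {
      ii <- ind_idx[rows]
      kamykowski_unclamped(tvec[rows], theta[ii, 1L], theta[ii, 2L],
                     theta[ii, 3L], theta[ii, 4L], theta[ii, 5L])
    }

    theta <- theta_fun(mu, lsig, z)
    mval <- mean_fun(theta)
    loglik <- function(m, so, rows = seq_along(tvec))
      sum(stats::dnorm(yvec[rows], m, so, log = TRUE))
    lp_pop <- function(mu, lsig, lso) {
      sig <- exp(lsig); so <- exp(lso)
      sum(stats::dnorm(mu, eta0, 1.5, log = TRUE)) +
        sum(stats::dnorm(sig, 0, 0.5, log = TRUE) + lsig) +
        stats::dnorm(so, 0, sdy, log = TRUE) + lso
    }

    ll <- loglik(mval, exp(lso))
    bad <- 0L

    # proposal scales (log), adapted in 25-iter batches during warmup
    ls_scalar <- rep(log(0.15), 2L * K + 1L)  # mu (1..5), lsig (6..10), lso (11)
    ls_block <- rep(log(0.25), n_ind)
    acc_scalar <- numeric(2L * K + 1L)
    acc_block <- numeric(n_ind)

    n_iter <- n_warmup + n_sampling
    qn <- c(paste0("mu_", tpc_param_names),
            paste0("sigma_", tpc_param_names), "sigma_obs",
            paste0("pop_", tpc_param_names),
            paste0("z_", rep(seq_len(n_ind), each = K), "_",
                   rep(tpc_param_names, n_ind)))
    out <- matrix(NA_real_, n_sampling, length(qn),
                  dimnames = list(NULL, qn))

    # running moments for the adaptive joint proposals
    mu_hist_mean <- rep(0, K); mu_hist_m2 <- matrix(0, K, K)
    z_hist_mean <- matrix(0, n_ind, K)
    z_hist_m2 <- array(0, c(K, K, n_ind))
    hist_n <- 0L
    mu_chol <- NULL
    z_chol <- vector("list", n_ind)

    for (it in seq_len(n_iter)) {
      for (sw in seq_len(sweeps)) {
        # (1) scalar non-centred updates
        for (s in seq_len(2L * K + 1L)) {
          mu_p <- mu; lsig_p <- lsig; lso_p <- lso
          step <- stats::rnorm(1, 0, exp(ls_scalar[s]))
          if (s <= K) mu_p[s] <- mu[s] + step
          else if (s <= 2L * K) lsig_p[s - K] <- lsig[s - K] + step
          else lso_p <- lso + step
          if (s <= 2L * K) {
            theta_p <- theta_fun(mu_p, lsig_p, z)
            mval_p <- mean_fun(theta_p)
          } else {
            theta_p <- theta; mval_p <- mval
          }
          ll_p <- loglik(mval_p, exp(lso_p))
          lr <- (ll_p + lp_pop(mu_p, lsig_p, lso_p)) -
            (ll + lp_pop(mu, lsig, lso))
          if (!is.finite(lr)) { if (it > n_warmup) bad <- bad + 1L; lr <- -Inf }
          if (log(stats::runif(1)) < lr) {
            mu <- mu_p; lsig <- lsig_p; lso <- lso_p
            theta <- theta_p; mval <- mval_p; ll <- ll_p
            acc_scalar[s] <- acc_scalar[s] + 1
          }
        }

        # (2) joint adaptive update of all five mu components
        if (!is.null(mu_chol)) {
          mu_p <- mu + drop(mu_chol %*% stats::rnorm(K))
          theta_p <- theta_fun(mu_p, lsig, z)
          mval_p <- mean_fun(theta_p)
          ll_p <- loglik(mval_p, exp(lso))
          lr <- (ll_p + lp_pop(mu_p, lsig, lso)) -
            (ll + lp_pop(mu, lsig, lso))
          if (!is.finite(lr)) { if (it > n_warmup) bad <- bad + 1L; lr <- -Inf }
          if (log(stats::runif(1)) < lr) {
            mu <- mu_p; theta <- theta_p; mval <- mval_p; ll <- ll_p
          }
        }

        # (3) per-individual block updates of z_i
        so <- exp(lso)
        sig <- exp(lsig)
        for (i in seq_len(n_ind)) {
          ri <- rows_of[[i]]
          eps <- stats::rnorm(K)
          zi_p <- z[i, ] + if (is.null(z_chol[[i]]))
            exp(ls_block[i]) * eps
          else exp(ls_block[i]) * drop(z_chol[[i]] %*% eps)
          th_p <- to_bounded(mu + sig * zi_p, L, U)
          m_p <- kamykowski_unclamped(tvec[ri], th_p[1L], th_p[2L], th_p[3L],
                                th_p[4L], th_p[5L])
          ll_i_old <- loglik(mval[ri], so, ri)
          ll_i_new <- sum(stats::dnorm(yvec[ri], m_p, so, log = TRUE))
          lr <- (ll_i_new - 0.5 * sum(zi_p^2)) -
            (ll_i_old - 0.5 * sum(z[i, ]^2))
          if (!is.finite(lr)) { if (it > n_warmup) bad <- bad + 1L; lr <- -Inf }
          if (log(stats::runif(1)) < lr) {
            z[i, ] <- zi_p; theta[i, ] <- th_p
            mval[ri] <- m_p
            ll <- ll + (ll_i_new - ll_i_old)
            acc_block[i] <- acc_block[i] + 1
          }
        }

        # (4) centred interweaving: hold eta (hence the likelihood) fixed
        sig <- exp(lsig)
        eta <- sweep(z * rep(sig, each = n_ind), 2, mu, "+")
        # exact Gibbs for mu_k | eta, sigma (eta_ik ~ N(mu_k, sigma_k^2))
        prec <- n_ind / sig^2 + 1 / 1.5^2
        mcond <- (colSums(eta) / sig^2 + eta0 / 1.5^2) / prec
        mu <- stats::rnorm(K, mcond, 1 / sqrt(prec))
        # scale move on each sigma_k with z rescaled (likelihood untouched)
        for (k in seq_len(K)) {
          s <- stats::rnorm(1, 0, 0.3)
          lsig_k_p <- lsig[k] + s
          zk_old <- (eta[, k] - mu[k]) / sig[k]
          zk_new <- (eta[, k] - mu[k]) / exp(lsig_k_p)
          lr <- (stats::dnorm(exp(lsig_k_p), 0, 0.5, log = TRUE) + lsig_k_p -
                   0.5 * sum(zk_new^2)) -
            (stats::dnorm(sig[k], 0, 0.5, log = TRUE) + lsig[k] -
               0.5 * sum(zk_old^2)) - s * n_ind
          if (is.finite(lr) && log(stats::runif(1)) < lr) {
            lsig[k] <- lsig_k_p
            sig[k] <- exp(lsig_k_p)
          }
        }
        z <- sweep(eta, 2, mu, "-") / rep(sig, each = n_ind)
        # theta/mval/ll unchanged by construction
      }

      # accumulate moments during warmup, refresh the joint proposals
      if (it <= n_warmup) {
        hist_n <- hist_n + 1L
        d0 <- mu - mu_hist_mean
        mu_hist_mean <- mu_hist_mean + d0 / hist_n
        mu_hist_m2 <- mu_hist_m2 + tcrossprod(d0, mu - mu_hist_mean)
        dz <- z - z_hist_mean
        z_hist_mean <- z_hist_mean + dz / hist_n
        dz2 <- z - z_hist_mean
        for (i in seq_len(n_ind))
          z_hist_m2[, , i] <- z_hist_m2[, , i] + tcrossprod(dz[i, ], dz2[i, ])
        if (hist_n >= 100L && it %% 50L == 0L) {
          mu_chol <- tryCatch(
            t(chol(mu_hist_m2 / (hist_n - 1L) * (2.38^2 / K) +
                     diag(1e-8, K))),
            error = function(e) mu_chol)
          for (i in seq_len(n_ind)) {
            newc <- tryCatch(
              t(chol(z_hist_m2[, , i] / (hist_n - 1L) * (2.38^2 / K) +
                       diag(1e-8, K))),
              error = function(e) z_chol[[i]])
            if (is.null(z_chol[[i]]) && !is.null(newc)) ls_block[i] <- 0
            z_chol[[i]] <- newc
          }
        }
      }

      # batch scale adaptation (warmup only)
      if (it <= n_warmup && it %% 25L == 0L) {
        nb <- 25 * sweeps
        delta <- min(0.05, 1 / sqrt(it / 25))
        ls_scalar <- ls_scalar +
          ifelse(acc_scalar / nb > 0.44, delta, -delta)
        ls_block <- ls_block +
          ifelse(acc_block / nb > 0.25, delta, -delta)
        acc_scalar[] <- 0; acc_block[] <- 0
      }

      if (it > n_warmup) {
        out[it - n_warmup, ] <- c(mu, exp(lsig), exp(lso),
                                  to_bounded(mu, L, U), t(z))
      }
    }
    list(draws = out, bad = as.numeric(bad))
  })
}

#' Split R-hat potential-scale-reduction diagnostic
#'
#' Each chain is split in half and the classical between/within variance
#' ratio is computed over the resulting sequences. Returns `NA` for
#' quantities with (numerically) zero variance.
#'
#' @param chains list of numeric vectors, one per chain (equal lengths).
#' @return Scalar R-hat.
#' @export
split_rhat <- function(chains) {
  half <- unlist(lapply(chains, function(x) {
    n2 <- floor(length(x) / 2)
    list(x[seq_len(n2)], x[seq_len(n2) + n2])
  }), recursive = FALSE)
  n <- length(half[[1]])
  means <- vapply(half, mean, numeric(1))
  vars <- vapply(half, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= 1e-12 * (mean(means)^2 + 1e-30)) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# basic effective sample size: Geyer-style truncated autocovariance sum,
# averaged over chains
ess_basic <- function(chains) {
  N <- length(chains[[1]]); M <- length(chains)
  W <- mean(vapply(chains, stats::var, numeric(1)))
  if (!is.finite(W) || W <= 0) return(NA_real_)
  max_lag <- min(N - 2L, 200L)
  rho <- rep(0, max_lag)
  for (x in chains) {
    ac <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                     demean = TRUE)$acf[-1]
    rho <- rho + ac / M
  }
  s <- 0
  t <- 1L
  while (t + 1L <= max_lag) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2L
  }
  max(M * N / (1 + 2 * s), 1)
}
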