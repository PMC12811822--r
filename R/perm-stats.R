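# Permutation inference for the behavioural experiments.
#
# p-values use the add-one estimator p = (b + 1) / (m + 1), where b is the
# number of permuted statistics >= the observed one (ties count as
# exceedances). When b = 0 the estimate is reported together with the
# resolution floor 1/m, matching the "p < 2e-5" reporting style at
# m = 50,000.

perm_result <- function(stat, df_num, df_den, m, b, seed,
                        stat_name = "F") {
  structure(list(statistic = stat, stat_name = stat_name,
                 df_num = df_num, df_den = df_den,
                 n_perm = m, exceed_count = b,
                 p_est = (b + 1) / (m + 1),
                 p_floor = 1 / m,
                 below_floor = (b == 0L),
                 seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test: %s = %.4g (df %s, %s), m = %d\n",
              x$stat_name, x$statistic,
              format(x$df_num), format(x$df_den), x$n_perm))
  if (x$below_floor)
    cat(sprintf("  p < %.3g (no permuted statistic reached the observed one)\n",
                x$p_floor))
  else cat(sprintf("  p = %.4g\n", x$p_est))
  invisible(x)
}

# RSS of y projected off an orthonormal basis Q; y may be a matrix (columns
# are permuted responses)
.rss <- function(Q, y) {
  y <- as.matrix(y)
  colSums(y^2) - colSums((crossprod(Q, y))^2)
}

#' Permutation ANCOVA (Freedman-Lane)
#'
#' Tests a group effect on `y` adjusted for a continuous covariate. The
#' observed F compares the covariate-only model against covariate + group.
#' The null distribution permutes the reduced-model residuals, adds them
#' back to the reduced-model fit, and recomputes F (Freedman-Lane), so the
#' covariate's contribution is preserved under the null.
#'
#' @param y numeric response.
#' @param group factor-like group labels (>= 2 levels, each with >= 2
#'   observations).
#' @param covariate numeric covariate (e.g. body-temperature change rate).
#' @param m number of permutations (default 50000).
#' @param seed RNG seed (default 123).
#' @return A `perm_test` object; see also [print.perm_test()].
#' @export
perm_ancova <- function(y, group, covariate, m = 50000L, seed = 123L) {
  group <- as.factor(group)
  n <- length(y)
  if (length(group) != n || length(covariate) != n)
    stop_input("perm_ancova: y, group and covariate must have equal length")
  if (nlevels(droplevels(group)) < 2L)
    stop_input("perm_ancova: need >= 2 groups")
  if (any(table(droplevels(group)) < 2L))
    stop_input("perm_ancova: design error - singleton group")
  if (stats::sd(covariate) == 0)
    stop_input("perm_ancova: degenerate design - constant covariate")
  if (m < 1L) stop_input("perm_ancova: m must be >= 1")
  group <- droplevels(group)

  X_red <- cbind(1, covariate)
  X_full <- cbind(X_red, stats::model.matrix(~group)[, -1, drop = FALSE])
  Q_red <- qr.Q(qr(X_red))
  Q_full <- qr.Q(qr(X_full))
  p_full <- ncol(X_full)
  q <- p_full - ncol(X_red)

  f_stat <- function(yy) {
    rss_r <- .rss(Q_red, yy)
    rss_f <- .rss(Q_full, yy)
    ((rss_r - rss_f) / q) / (rss_f / (n - p_full))
  }
  F_obs <- f_stat(y)

  fit_red <- Q_red %*% crossprod(Q_red, y)
  res_red <- y - fit_red
  withr::with_seed(seed, {
    perm_idx <- replicate(m, sample.int(n))
  })
  Y_star <- matrix(res_red[perm_idx], n, m) + as.vector(fit_red)
  F_perm <- f_stat(Y_star)
  b <- sum(F_perm >= F_obs)
  perm_result(F_obs, q, n - p_full, m, b, seed)
}

# split-plot sums of squares for a complete within-subject design;
# ymat: subjects x within-levels, grp: between level per subject
.splitplot_F <- function(ymat, grp) {
  n <- nrow(ymat); t <- ncol(ymat)
  a <- nlevels(grp)
  subj_means <- rowMeans(ymat)
  grand <- mean(ymat)
  grp_means <- tapply(subj_means, grp, mean)
  n_g <- tabulate(grp)
  within_means <- colMeans(ymat)
  # cell means (between x within)
  cell <- rowsum(ymat, grp) / as.vector(n_g)

  ss_between <- t * sum(n_g * (grp_means - grand)^2)
  ss_subj <- t * sum((subj_means - grp_means[grp])^2)
  ss_within <- n * sum((within_means - grand)^2)
  ss_cells <- sum(n_g * rowSums((cell - grand)^2))
  ss_int <- ss_cells - ss_between - ss_within
  ss_tot <- sum((ymat - grand)^2)
  ss_res <- ss_tot - ss_between - ss_subj - ss_within - ss_int

  df_b <- a - 1; df_s <- n - a
  df_w <- t - 1; df_i <- (a - 1) * (t - 1); df_r <- (n - a) * (t - 1)
  ms <- function(ss, df) if (df > 0) ss / df else NA_real_
  denom_s <- ms(ss_subj, df_s); denom_r <- ms(ss_res, df_r)
  c(F_between = if (denom_s > 0) ms(ss_between, df_b) / denom_s else 0,
    F_within = if (denom_r > 0) ms(ss_within, df_w) / denom_r else 0,
    F_interaction = if (denom_r > 0) ms(ss_int, df_i) / denom_r else 0)
}

# reshape long (y, subject, within) into subjects x within matrix; errors
# listing subjects with missing cells
.splitplot_matrix <- function(y, subject, within) {
  subject <- as.factor(subject); within <- as.factor(within)
  tab <- table(subject, within)
  bad <- rownames(tab)[apply(tab != 1L, 1, any)]
  if (length(bad))
    stop_input("split-plot design error: subjects without exactly one observation per within level: %s",
               paste(bad, collapse = ", "))
  ymat <- matrix(NA_real_, nlevels(subject), nlevels(within),
                 dimnames = list(levels(subject), levels(within)))
  ymat[cbind(as.integer(subject), as.integer(within))] <- y
  ymat
}

#' Permutation split-plot (repeated-measures) ANOVA
#'
#' Between-subject factor (e.g. acclimation temperature) crossed with a
#' within-subject factor (e.g. test temperature) measured once per subject
#' and level. Classical split-plot F statistics; permutation null
#' distributions use two schemes: whole-subject profiles are permuted
#' across between-group labels for the between effect, and within-level
#' labels are permuted independently inside each subject (one shared
#' permutation per iteration) for the within and interaction effects.
#'
#' @param y numeric response (long format).
#' @param subject subject identifiers.
#' @param between between-subject factor (one level per subject).
#' @param within within-subject factor (complete design).
#' @param m permutations (default 50000).
#' @param seed RNG seed (default 123).
#' @param effects which effects to permute (all three by default); the
#'   observed F statistics are always reported.
#' @return List of class `splitplot_test` with `perm_test` entries
#'   `between`, `within`, `interaction` (NULL when not permuted).
#' @export
perm_splitplot <- function(y, subject, between, within, m = 50000L,
                           seed = 123L,
                           effects = c("between", "within", "interaction")) {
  effects <- match.arg(effects, several.ok = TRUE)
  subject <- as.factor(subject); within <- as.factor(within)
  ymat <- .splitplot_matrix(y, subject, within)
  grp_by_subj <- tapply(as.character(between), subject, function(g) {
    u <- unique(g)
    if (length(u) != 1L)
      stop_input("split-plot design error: subject with several between levels")
    u
  })
  grp <- factor(grp_by_subj[rownames(ymat)])
  n <- nrow(ymat); t <- ncol(ymat); a <- nlevels(grp)
  F_obs <- .splitplot_F(ymat, grp)

  do_between <- "between" %in% effects
  do_wi <- any(c("within", "interaction") %in% effects)
  b_cnt <- c(between = 0L, within = 0L, interaction = 0L)
  withr::with_seed(seed, {
    if (do_between) {
      # the between-subject F depends on the data only through subject
      # means, so all m permutations are evaluated as one matrix product
      sm <- rowMeans(ymat)
      perm_idx <- replicate(m, sample.int(n))
      M <- matrix(sm[perm_idx], n, m)
      G <- stats::model.matrix(~ grp - 1)
      n_g <- colSums(G)
      gsum <- crossprod(G, M)                      # a x m group sums
      gmean2 <- gsum^2 / n_g
      grand <- mean(sm)
      ss_b <- colSums(gmean2) - n * grand^2
      ss_s <- colSums(M^2) - colSums(gmean2)
      Fb <- (ss_b / (a - 1)) / (ss_s / (n - a))
      Fb[!is.finite(Fb)] <- 0
      b_cnt["between"] <- sum(Fb >= F_obs[["F_between"]])
    }
    for (r in seq_len(m)) {
      if (do_wi) {
        ymat_p <- ymat
        for (i in seq_len(n)) ymat_p[i, ] <- ymat[i, sample.int(t)]
        Fw <- .splitplot_F(ymat_p, grp)
        if (Fw[["F_within"]] >= F_obs[["F_within"]])
          b_cnt["within"] <- b_cnt["within"] + 1L
        if (Fw[["F_interaction"]] >= F_obs[["F_interaction"]])
          b_cnt["interaction"] <- b_cnt["interaction"] + 1L
      }
    }
  })

  res <- list(
    between = if (do_between)
      perm_result(F_obs[["F_between"]], a - 1, n - a, m,
                  b_cnt[["between"]], seed),
    within = if (do_wi)
      perm_result(F_obs[["F_within"]], t - 1, (n - a) * (t - 1), m,
                  b_cnt[["within"]], seed),
    interaction = if (do_wi)
      perm_result(F_obs[["F_interaction"]], (a - 1) * (t - 1),
                  (n - a) * (t - 1), m,
                  b_cnt[["interaction"]], seed),
    F_obs = F_obs, n_subjects = n, n_within = t, n_between = a)
  class(res) <- "splitplot_test"
  res
}

#' Simple main effects of the between factor at each within level
#'
#' After a significant interaction, the between-group difference is tested
#' at each within level with a two-sample permutation test on the absolute
#' mean difference, and p-values are Holm-adjusted across levels.
#'
#' @inheritParams perm_splitplot
#' @return Data frame with one row per within level: observed `abs_diff`,
#'   `p_raw`, `p_holm`, `below_floor`.
#' @export
posthoc_simple_effects <- function(y, subject, between, within, m = 50000L,
                                   seed = 123L) {
  within <- as.factor(within); between <- as.factor(between)
  if (nlevels(droplevels(between)) != 2L)
    stop_input("posthoc_simple_effects: exactly two between levels required")
  lev <- levels(within)
  p_raw <- numeric(length(lev)); obs <- numeric(length(lev))
  bf <- logical(length(lev))
  for (j in seq_along(lev)) {
    sel <- within == lev[j]
    yy <- y[sel]; gg <- droplevels(between[sel])
    d_obs <- abs(diff(tapply(yy, gg, mean)))
    nn <- length(yy)
    withr::with_seed(derive_seed(seed, paste0("posthoc-", lev[j])), {
      d_perm <- replicate(m, {
        gp <- gg[sample.int(nn)]
        abs(diff(tapply(yy, gp, mean)))
      })
    })
    b <- sum(d_perm >= d_obs)
    obs[j] <- d_obs
    p_raw[j] <- (b + 1) / (m + 1)
    bf[j] <- b == 0L
  }
  data.frame(within_level = lev, abs_diff = obs, p_raw = p_raw,
             p_holm = holm_adjust(p_raw), below_floor = bf,
             stringsAsFactors = FALSE)
}

#' Holm step-down adjustment
#'
#' Sorts p ascending, multiplies the i-th smallest by (k - i + 1), enforces
#' a running maximum and caps at 1; returned in input order. Matches
#' `p.adjust(method = "holm")`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
holm_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop_input("holm_adjust: p-values must be in [0, 1]")
  k <- length(p)
  if (k == 0L) return(numeric(0))
  o <- order(p)
  adj <- pmin(1, cummax(p[o] * (k - seq_len(k) + 1)))
  out <- numeric(k)
  out[o] <- adj
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q(i) = min over j >= i of p(j) * k / j, capped at 1; returned in input
#' order. Matches `p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop_input("bh_adjust: p-values must be in [0, 1]")
  k <- length(p)
  if (k == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * k / (k - seq_len(k) + 1)))
  out <- numeric(k)
  out[o] <- adj
  out
}

#' Wilcoxon rank tests for selected-temperature comparisons
#'
#' Signed-rank test for paired data (e.g. the same individuals under light
#' vs dark), rank-sum test for unpaired comparisons between acclimation
#' groups. Exact enumeration when the effective sample size is <= 12 and
#' there are no ties, tie-corrected normal approximation otherwise;
#' two-sided throughout.
#'
#' @param x,y numeric samples (equal length when `paired`).
#' @param paired logical.
#' @return List with `statistic`, `p_value`, `method`, `exact`.
#' @export
rank_tests <- function(x, y, paired = FALSE) {
  if (paired) {
    if (length(x) != length(y))
      stop_input("rank_tests: paired samples must have equal length")
    d <- x - y
    d <- d[d != 0]
    if (length(d) == 0L)
      stop_input("rank_tests: undefined statistic - all paired differences are zero")
    exact <- length(d) <= 12L && !any(duplicated(abs(d)))
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                              exact = exact,
                                              correct = !exact))
  } else {
    exact <- (length(x) + length(y)) <= 12L && !any(duplicated(c(x, y)))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = !exact))
  }
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = wt$method, exact = exact)
}

#' Fisher's exact test for the overlap of two gene sets
#'
#' Builds the 2x2 membership table of `set_a` x `set_b` over `universe`,
#' reports the sample odds ratio ad/bc and a two-sided exact p-value
#' obtained by summing hypergeometric probabilities not exceeding that of
#' the observed table.
#'
#' @param set_a,set_b character vectors (subsets of `universe`).
#' @param universe character vector of all considered genes.
#' @return List of class `overlap_test`: `table` (a, b, c, d), `odds_ratio`,
#'   `p_value`, `overlap_pct` (percentage of `set_a` shared with `set_b`),
#'   `universe_size`.
#' @export
fisher_overlap <- function(set_a, set_b, universe) {
  if (length(universe) == 0L)
    stop_input("fisher_overlap: empty universe")
  universe <- unique(universe)
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop_input("fisher_overlap: sets must be subsets of the universe")
  a <- length(intersect(set_a, set_b))
  b <- length(set_a) - a
  cc <- length(set_b) - a
  d <- length(universe) - a - b - cc
  or <- if (b * cc == 0) {
    if (a * d > 0) Inf else NaN
  } else (a * d) / (b * cc)

  # two-sided exact p: hypergeometric over all tables with fixed margins
  m <- a + b          # size of set A
  k <- a + cc         # size of set B
  N <- a + b + cc + d
  support <- max(0L, k + m - N):min(k, m)
  probs <- stats::dhyper(support, m, N - m, k)
  p_obs <- stats::dhyper(a, m, N - m, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  structure(list(table = c(a = a, b = b, c = cc, d = d),
                 odds_ratio = or, p_value = min(1, p),
                 overlap_pct = if (length(set_a)) 100 * a / length(set_a)
                 else NA_real_,
                 universe_size = N),
            class = "overlap_test")
}
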