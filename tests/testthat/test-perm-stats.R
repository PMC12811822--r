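test_that("permutation ANCOVA detects nothing when groups are identical", {
  withr::with_seed(3, {
    cov <- runif(30)
    y <- rep(2 + 3 * cov[1:15], 2)  # identical across groups
  })
  r <- perm_ancova(y, rep(c("A", "B"), each = 15), rep(cov[1:15], 2),
                   m = 500, seed = 1)
  expect_lt(r$statistic, 1e-20)
  expect_gt(r$p_est, 0.95)
  expect_false(r$below_floor)
})

test_that("permutation ANCOVA reports the 1/m floor when unreachable", {
  # strong group separation, m = 50,000: no permuted F reaches F_obs
  withr::with_seed(4, {
    cov <- runif(56, 0.8, 1.7)
    y <- c(rnorm(28, 6, 0.5), rnorm(28, 10, 0.5)) + 0.3 * cov
  })
  r <- perm_ancova(y, rep(c("A", "B"), each = 28), cov, m = 50000,
                   seed = 123)
  expect_true(r$below_floor)
  expect_equal(r$p_floor, 2e-5)
  expect_equal(r$exceed_count, 0)
  expect_output(print(r), "p < 2e-05")
})

test_that("permutation ANCOVA validates its design", {
  y <- rnorm(10); g <- rep(c("A", "B"), each = 5)
  expect_error(perm_ancova(y, g, rep(1, 10), m = 10), "constant covariate")
  expect_error(perm_ancova(y, rep(c("A", "B"), c(9, 1)), runif(10),
                           m = 10), "singleton")
  expect_error(perm_ancova(y, rep("A", 10), runif(10), m = 10),
               ">= 2 groups")
  expect_error(perm_ancova(y[1:5], g, runif(10), m = 10), "equal length")
})

test_that("a fixed seed gives bit-identical permutation p-values", {
  withr::with_seed(5, {
    y <- rnorm(24); g <- rep(c("A", "B"), 12); cov <- runif(24)
  })
  r1 <- perm_ancova(y, g, cov, m = 2000, seed = 99)
  r2 <- perm_ancova(y, g, cov, m = 2000, seed = 99)
  expect_identical(r1$p_est, r2$p_est)
  # relabelling group identities leaves p unchanged
  g2 <- ifelse(g == "A", "Z", "Y")
  r3 <- perm_ancova(y, g2, cov, m = 2000, seed = 99)
  expect_identical(r1$p_est, r3$p_est)
})

test_that("split-plot F statistics match the classical aov decomposition", {
  withr::with_seed(2, {
    n <- 12; t <- 4
    subj <- rep(sprintf("s%02d", 1:n), each = t)
    wi <- factor(rep(1:t, n))
    bw <- factor(rep(rep(c("A", "B"), each = n / 2), each = t))
    y <- rnorm(n * t) + 0.5 * (bw == "B") + 0.3 * as.integer(wi) +
      0.4 * (bw == "B") * (wi == 2)
  })
  sp <- perm_splitplot(y, subj, bw, wi, m = 50, seed = 1)
  av <- summary(stats::aov(y ~ bw * wi + Error(factor(subj))))
  expect_equal(sp$F_obs[["F_between"]], av[[1]][[1]]$F[1],
               tolerance = 1e-10)
  expect_equal(sp$F_obs[["F_within"]], av[[2]][[1]]$F[1],
               tolerance = 1e-10)
  expect_equal(sp$F_obs[["F_interaction"]], av[[2]][[1]]$F[2],
               tolerance = 1e-10)
  expect_equal(sp$between$df_num, 1)
  expect_equal(sp$between$df_den, n - 2)
  expect_equal(sp$interaction$df_num, (2 - 1) * (t - 1))
})

test_that("split-plot handles constant data and incomplete designs", {
  n <- 8; t <- 3
  subj <- rep(1:n, each = t); wi <- rep(1:t, n)
  bw <- rep(rep(c("A", "B"), each = n / 2), each = t)
  y0 <- rep(1, n * t)
  sp <- perm_splitplot(y0, subj, bw, wi, m = 20, seed = 1)
  expect_equal(unname(sp$F_obs), rep(0, 3))
  expect_error(perm_splitplot(y0[-1], subj[-1], bw[-1], wi[-1], m = 10),
               "subjects without exactly one")
})

test_that("an interaction planted in the generator is detected", {
  # group-specific temperature response
  withr::with_seed(6, {
    n <- 16; t <- 5
    subj <- rep(sprintf("i%02d", 1:n), each = t)
    wi <- rep(1:t, n)
    bw <- rep(rep(c("A", "B"), each = n / 2), each = t)
    slope <- ifelse(bw == "B", 0.5, 0.1)
    y <- rnorm(n * t, sd = 0.4) + slope * wi
  })
  sp <- perm_splitplot(y, subj, bw, wi, m = 2000, seed = 7)
  expect_lt(sp$interaction$p_est, 0.01)
})

test_that("simple-effect post hocs localise a single-level effect", {
  localised <- vapply(1:20, function(s) {
    withr::with_seed(1000 + s, {
      n <- 16; t <- 4
      subj <- rep(sprintf("i%02d", 1:n), each = t)
      wi <- rep(1:t, n)
      bw <- rep(rep(c("A", "B"), each = n / 2), each = t)
      y <- rnorm(n * t, sd = 0.5) + 1.8 * (bw == "B" & wi == 3)
    })
    ph <- posthoc_simple_effects(y, subj, bw, wi, m = 400, seed = s)
    which.min(ph$p_holm) == 3
  }, logical(1))
  expect_gte(mean(localised), 0.95)

  # identical groups: all adjusted p near 1
  withr::with_seed(11, {
    n <- 8; t <- 3
    subj <- rep(1:n, each = t); wi <- rep(1:t, n)
    bw <- rep(rep(c("A", "B"), each = n / 2), each = t)
    base <- rnorm(n / 2 * t)
    y <- c(base, base)  # group B repeats group A exactly
  })
  ph0 <- posthoc_simple_effects(y, subj, bw, wi, m = 400, seed = 2)
  expect_true(all(ph0$p_holm > 0.95))
  expect_equal(nrow(ph0), t)
})

test_that("Holm and BH match worked examples and stats::p.adjust", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.9)), c(0.03, 0.03, 0.9))
  expect_equal(holm_adjust(0.3), 0.3)
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  withr::with_seed(12, {
    for (i in 1:200) {
      p <- runif(sample(1:40, 1))
      expect_lt(max(abs(holm_adjust(p) - p.adjust(p, "holm"))), 1e-12)
      expect_lt(max(abs(bh_adjust(p) - p.adjust(p, "BH"))), 1e-12)
    }
  })
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
  # BH output sorted is non-decreasing for sorted input
  p <- sort(runif(10))
  expect_true(all(diff(bh_adjust(p)) >= 0))
})

test_that("rank tests use exact enumeration without ties and reject degenerate input", {
  # all five paired differences positive and distinct: p = 2/2^5
  r <- rank_tests(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5), paired = TRUE)
  expect_true(r$exact)
  expect_equal(r$p_value, 2 / 32)
  expect_error(rank_tests(1:5, 1:5, paired = TRUE), "all paired differences")
  expect_error(rank_tests(1:4, 1:5, paired = TRUE), "equal length")
  # unpaired matches the standard implementation
  withr::with_seed(3, { x <- rnorm(20); y <- rnorm(20, 0.5) })
  r2 <- rank_tests(x, y)
  expect_equal(r2$p_value,
               suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))$p.value)
})

test_that("rank-sum test holds its level under the null", {
  withr::with_seed(14, {
    rej <- mean(vapply(1:500, function(i) {
      rank_tests(rnorm(10), rnorm(10))$p_value < 0.05
    }, logical(1)))
  })
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("Fisher overlap reproduces hypergeometric enumeration and edge cases", {
  u <- paste0("g", 1:300)
  ab <- fisher_overlap(u[1:50], u[1:50], u)
  expect_identical(ab$odds_ratio, Inf)
  # a*d == b*c gives OR 1
  u4 <- paste0("x", 1:4)
  or1 <- fisher_overlap(u4[1:2], u4[c(1, 3)], u4)
  expect_equal(or1$odds_ratio, 1)
  expect_error(fisher_overlap("a", "b", character(0)), "empty universe")
  expect_error(fisher_overlap("zz", u4[1], u4), "subsets")
  # random tables match fisher.test (same two-sided rule)
  withr::with_seed(15, {
    for (i in 1:50) {
      n <- sample(40:400, 1)
      uu <- paste0("g", seq_len(n))
      A <- sample(uu, sample(5:(n / 2), 1))
      B <- sample(uu, sample(5:(n / 2), 1))
      fo <- fisher_overlap(A, B, uu)
      ft <- fisher.test(matrix(fo$table[c("a", "b", "c", "d")], 2,
                               byrow = TRUE))
      expect_equal(fo$p_value, ft$p.value, tolerance = 1e-9)
    }
  })
})
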