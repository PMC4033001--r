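test_that("Fisher exact handles degenerate tables and validates input", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2, 2)), 1)
  expect_error(fisher_exact_2x2(matrix(c(1, -1, 0, 1), 2, 2)), "non-negative")
  expect_error(fisher_exact_2x2(matrix(c(1.5, 0, 0, 1), 2, 2)), "integers")
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "empty")
  expect_error(fisher_exact_2x2(matrix(1, 3, 2)), "2x2")
})

test_that("Fisher exact is invariant to transposition and row/column swaps", {
  m <- matrix(c(6, 8, 10, 4), 2, 2)
  p <- fisher_exact_2x2(m)
  expect_equal(fisher_exact_2x2(t(m)), p)
  expect_equal(fisher_exact_2x2(m[2:1, 2:1]), p)
})

test_that("the mixed ANOVA matches aov's split-plot decomposition, balanced or not", {
  make_data <- function(ns, k, seed) {
    set.seed(seed)
    do.call(rbind, lapply(seq_len(sum(ns)), function(s) {
      g <- if (s <= ns[1]) "A" else "B"
      data.frame(subject = sprintf("s%02d", s), group = g,
                 session = factor(paste0("t", seq_len(k))),
                 dv = rnorm(1, ifelse(g == "A", 0, 0.6)) +
                   seq_len(k) * 0.2 + rnorm(k))
    }))
  }
  for (cfg in list(list(ns = c(4, 4), k = 3, seed = 1),
                   list(ns = c(5, 8), k = 4, seed = 2))) {
    d <- make_data(cfg$ns, cfg$k, cfg$seed)
    res <- mixed_anova(d, "dv", "subject", "group", "session")
    fit <- summary(aov(dv ~ group * session + Error(subject / session),
                       data = d))
    btw <- fit[["Error: subject"]][[1]]
    win <- fit[["Error: subject:session"]][[1]]
    expect_equal(res$ss, c(btw["group", "Sum Sq"], win["session", "Sum Sq"],
                           win["group:session", "Sum Sq"]), tolerance = 1e-10)
    expect_equal(res$f, c(btw["group", "F value"], win["session", "F value"],
                          win["group:session", "F value"]), tolerance = 1e-10)
    expect_equal(res$p, c(btw["group", "Pr(>F)"], win["session", "Pr(>F)"],
                          win["group:session", "Pr(>F)"]), tolerance = 1e-10)
    expect_equal(attr(res, "ss_subject_error"), btw["Residuals", "Sum Sq"],
                 tolerance = 1e-10)
    expect_equal(attr(res, "ss_within_error"), win["Residuals", "Sum Sq"],
                 tolerance = 1e-10)
    # sums of squares are conserved
    expect_equal(sum(res$ss) + attr(res, "ss_subject_error") +
                   attr(res, "ss_within_error"), attr(res, "ss_total"))
  }
})

test_that("Mauchly's W agrees with stats::mauchly.test on the pooled covariance", {
  set.seed(9)
  n <- 24; k <- 4
  Y <- matrix(rnorm(n * k), n, k)
  Y[, 2] <- Y[, 2] * 1.8
  Y[, 3] <- Y[, 3] + 0.3 * Y[, 1]
  grp <- rep(c("A", "B"), each = n / 2)
  d <- data.frame(subject = rep(sprintf("s%02d", 1:n), each = k),
                  group = rep(grp, each = k),
                  session = factor(rep(1:k, n)),
                  dv = as.numeric(t(Y)))
  res <- mixed_anova(d, "dv", "subject", "group", "session")
  mt <- mauchly.test(lm(Y ~ grp), X = ~1)
  expect_equal(res$mauchly_w[2], unname(mt$statistic), tolerance = 1e-10)
  # first-order chi-square approximation vs mauchly.test's refined p
  expect_equal(res$mauchly_p[2], mt$p.value, tolerance = 0.005)
})

test_that("with two within levels epsilon is exactly 1 and the corrected p equals the uncorrected", {
  set.seed(4)
  d <- expand.grid(subject = sprintf("s%02d", 1:10),
                   session = c("PRE", "POST"))
  d$group <- rep(rep(c("A", "B"), each = 5), 2)
  d$dv <- rnorm(20)
  res <- mixed_anova(d, "dv", "subject", "group", "session")
  expect_identical(res$gg_epsilon[2], 1)
  expect_equal(res$p_gg[2], res$p[2])
  expect_equal(res$p_gg[3], res$p[3])
})

test_that("epsilon stays in (1/(k-1), 1] and approaches 1 under compound symmetry", {
  set.seed(6)
  for (k in c(3, 4, 5)) {
    n <- 12
    d <- do.call(rbind, lapply(1:n, function(s) {
      data.frame(subject = s, group = ifelse(s <= n / 2, "A", "B"),
                 session = factor(1:k), dv = rnorm(1) + rnorm(k, 0, runif(k, 0.5, 2)))
    }))
    eps <- mixed_anova(d, "dv", "subject", "group", "session")$gg_epsilon[2]
    expect_gt(eps, 1 / (k - 1))
    expect_lte(eps, 1)
  }
  # compound symmetry: subject intercept + iid noise, large n
  set.seed(7)
  n <- 300; k <- 3
  d <- do.call(rbind, lapply(1:n, function(s) {
    data.frame(subject = s, group = ifelse(s <= n / 2, "A", "B"),
               session = factor(1:k), dv = rnorm(1, 0, 1.5) + rnorm(k))
  }))
  expect_gt(mixed_anova(d, "dv", "subject", "group", "session")$gg_epsilon[2],
            0.97)
})

test_that("incomplete designs are rejected rather than imputed", {
  d <- expand.grid(subject = sprintf("s%d", 1:6), session = c("a", "b", "c"))
  d$group <- rep(c("A", "B"), 9)[1:18]
  d$group <- ifelse(d$subject %in% c("s1", "s2", "s3"), "A", "B")
  d$dv <- rnorm(18)
  expect_error(mixed_anova(d[-1, ], "dv", "subject", "group", "session"),
               "incomplete design")
})

test_that("Tukey HSD matches the t test for two cells and flags a far-shifted cell", {
  # identical means: all adjusted p near 1
  same <- tukey_hsd(c(a = 5, b = 5, c = 5), error_ms = 2, df_error = 20,
                    n_per_cell = 8)
  expect_true(all(same$p_adj > 0.999))

  # two cells: studentized range with q = t * sqrt(2) reproduces the t test
  two <- tukey_hsd(c(a = 4.2, b = 5.1), error_ms = 1.7, df_error = 14,
                   n_per_cell = 8)
  t_stat <- (5.1 - 4.2) / sqrt(1.7 * (1 / 8 + 1 / 8))
  expect_equal(two$p_adj, 2 * pt(-abs(t_stat), 14), tolerance = 1e-7)

  # one cell far away: its pairs significant, the close pair not
  far <- tukey_hsd(c(a = 5, b = 5.2, c = 12), error_ms = 1, df_error = 30,
                   n_per_cell = 10)
  expect_lt(far$p_adj[far$pair == "a - c"], 0.001)
  expect_lt(far$p_adj[far$pair == "b - c"], 0.001)
  expect_gt(far$p_adj[far$pair == "a - b"], 0.8)
  expect_error(tukey_hsd(c(1, 2), error_ms = 0, df_error = 5, n_per_cell = 3),
               "non-positive")
})

test_that("the Friedman statistic matches rank algebra and the exact oracle", {
  # constant ratings: no evidence
  flat <- matrix(3, 10, 4)
  expect_equal(friedman_test(flat)$chi2, 0)
  expect_equal(friedman_test(flat)$p, 1)

  # perfect common ordering, k = 3: chi2 = 2n
  for (n in c(5, 9)) {
    m <- matrix(rep(c(1, 2, 3), each = n), n, 3)
    ft <- friedman_test(m)
    expect_equal(ft$chi2, 2 * n)
    expect_identical(ft$df, 2L)
  }

  # agrees with base R when there are no ties
  set.seed(11)
  m <- matrix(rnorm(30), 10, 3)
  expect_equal(friedman_test(m)$chi2,
               unname(friedman.test(m)$statistic))
  expect_equal(friedman_test(m)$p, friedman.test(m)$p.value)

  expect_error(friedman_test(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
  expect_error(friedman_test(matrix(1, 3, 1)), "conditions")
})

test_that("Mann-Whitney reports W and a tie/continuity-corrected Z", {
  x <- c(2, 4, 6, 8)
  same <- mann_whitney(x, x)
  expect_equal(same$Z, 0)
  expect_equal(same$p, 1)

  low <- mann_whitney(1:5, 11:15)
  expect_equal(low$W, 0) # x entirely below y: minimal rank sum
  expect_lt(low$p, 0.02)

  # agreement with wilcox.test's normal approximation
  set.seed(2)
  a <- rnorm(12); b <- rnorm(15, 0.8)
  mw <- mann_whitney(a, b)
  wt <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mw$W, unname(wt$statistic))
  expect_equal(mw$p, wt$p.value, tolerance = 1e-10)

  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Welch's t uses Satterthwaite degrees of freedom", {
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$t, 0)

  # equal variances and sizes: df = 2n - 2
  x <- c(1, 2, 3, 4); y <- c(11, 12, 13, 14) # same spread
  expect_equal(welch_t(x, y)$df, 6)

  # direct formula evaluation
  set.seed(3)
  a <- rnorm(9); b <- rnorm(14, 0.5, 2)
  got <- welch_t(a, b)
  va <- var(a) / 9; vb <- var(b) / 14
  t_manual <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_manual <- (va + vb)^2 / (va^2 / 8 + vb^2 / 13)
  expect_equal(got$t, t_manual)
  expect_equal(got$df, df_manual)
  expect_equal(got$p, 2 * pt(-abs(t_manual), df_manual))
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("minimization assigns a symmetric first pair one to each group", {
  cand <- data.frame(age = c(60, 60), sex = c("F", "F"),
                     barthel_pre = c(50, 50), pegboard_pre_s = c(40, 40))
  res <- assign_minimized(cand, assignment_state(), seed = 1)
  expect_setequal(res$labels, c("together", "in_turn"))
  # tie-breaking is reproducible and seed-dependent
  res2 <- assign_minimized(cand, assignment_state(), seed = 1)
  expect_identical(res$labels, res2$labels)
})

test_that("the size rule dominates a batch of one", {
  st <- assignment_state()
  st <- assign_minimized(draw_candidates(3), st, seed = 2)$state
  counts <- table(factor(st$roster$group, c("together", "in_turn")))
  lone <- draw_candidates(1)
  res <- assign_minimized(lone, st, seed = 3)
  expect_identical(res$labels, names(counts)[which.min(counts)])
})

test_that("minimization never violates the size constraint and beats random allocation", {
  set.seed(123)
  n_acc <- 60
  min_imb <- numeric(n_acc)
  for (i in seq_len(n_acc)) {
    st <- assignment_state()
    remaining <- 28L
    while (remaining > 0L) {
      m <- min(remaining, sample(2:3, 1))
      if (remaining - m == 1L) m <- m - 1L # avoid stranding a singleton
      if (m == 0L) m <- 1L
      st <- assign_minimized(draw_candidates(m), st, seed = i * 1000L + remaining)$state
      remaining <- remaining - m
      sizes <- table(factor(st$roster$group, c("together", "in_turn")))
      expect_lte(abs(sizes[1] - sizes[2]), 1L)
    }
    min_imb[i] <- imbalance_oracle(st$roster)
  }
  rand_imb <- replicate(400, {
    roster <- draw_candidates(28)
    roster$group <- sample(rep(c("together", "in_turn"), 14))
    imbalance_oracle(roster)
  })
  expect_lt(median(min_imb), median(rand_imb))
  expect_lt(quantile(min_imb, 0.9), median(rand_imb))
})

test_that("batch sizes outside 1-3 and missing covariates are rejected", {
  expect_error(assign_minimized(draw_candidates(4), assignment_state()),
               "batch size")
  bad <- data.frame(age = 50)
  expect_error(assign_minimized(bad, assignment_state()), "covariates")
})

test_that("log transforms map 1 to 0, e to 1, and refuse non-positive values", {
  d <- data.frame(id = 1:3, median_iti_ms = c(1, exp(1), 400))
  out <- log_transform_outcomes(d, "median_iti_ms")
  expect_equal(out$median_iti_ms, c(0, 1, log(400)))
  expect_match(out$transform[1], "log")
  bad <- data.frame(v = c(3, 0))
  expect_error(log_transform_outcomes(bad, "v"), "row 2")
})

test_that("log transforming right-skewed interval outcomes reduces residual skewness", {
  set.seed(17)
  n <- 20; k <- 3
  d <- do.call(rbind, lapply(1:n, function(s) {
    data.frame(subject = s, group = ifelse(s <= n / 2, "A", "B"),
               session = factor(1:k),
               median_iti_ms = rlnorm(k, log(300) + rnorm(1, 0, 0.3), 0.4))
  }))
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  resid_skew <- function(dd, col) {
    cell <- ave(dd[[col]], dd$group, dd$session)
    subj <- ave(dd[[col]], dd$subject) - ave(dd[[col]], dd$group)
    skew(dd[[col]] - cell - subj)
  }
  before <- resid_skew(d, "median_iti_ms")
  after <- resid_skew(log_transform_outcomes(d, "median_iti_ms"),
                      "median_iti_ms")
  expect_lt(abs(after), abs(before))
})
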