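#' Two-sided Fisher exact test for a 2x2 contingency table
#'
#' Exact two-sided p-value under the convention that sums the hypergeometric
#' probabilities of all tables with the observed margins that are no more
#' probable than the observed table (the rule behind `stats::fisher.test`,
#' which this wraps after validation).
#'
#' @param table A 2x2 matrix of non-negative integer counts (rows = category,
#'   columns = group).
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) {
    stop("validation error: need a 2x2 table", call. = FALSE)
  }
  if (any(is.na(table)) || any(table < 0) || any(table != round(table))) {
    stop("validation error: counts must be non-negative integers", call. = FALSE)
  }
  if (sum(table) < 1) stop("validation error: empty table", call. = FALSE)
  stats::fisher.test(table)$p.value
}

# k-1 orthonormal within-subject contrasts
orthonormal_contrasts <- function(k) {
  h <- stats::contr.helmert(k)
  qr.Q(qr(h))
}

#' Mixed (split-plot) repeated-measures ANOVA
#'
#' Fits the classical univariate mixed ANOVA for one between-subjects factor
#' and one within-subjects factor on a complete, within-balanced design
#' (every subject observed exactly once at every within level; group sizes
#' may differ). Reports the full sum-of-squares decomposition, F tests,
#' Mauchly's sphericity test on the orthonormalized within-subject contrasts
#' (when the within factor has 3+ levels), the Greenhouse-Geisser epsilon
#' estimated from the contrast covariance eigenvalues, both the uncorrected
#' and epsilon-corrected p-values, and generalized eta-squared (effect SS
#' over effect SS plus all subject-level error SS).
#'
#' When Mauchly's test is significant at `sphericity_alpha`, the corrected
#' p-value is flagged as the headline p (`p_headline`); both p-values are
#' always reported.
#'
#' @param data Long-format data frame.
#' @param dv,subject,between,within Column names of the dependent variable,
#'   subject identifier, between-subjects factor and within-subjects factor.
#' @param sphericity_alpha Significance gate for Mauchly's test (default
#'   0.05).
#' @return An object of class `anova_result`: a data frame with one row per
#'   effect (`between`, `within`, `interaction`) and columns `ss`, `df`,
#'   `ms`, `f`, `df_error`, `p`, `mauchly_w`, `mauchly_p`, `gg_epsilon`,
#'   `p_gg`, `p_headline`, `eta2_g`; error strata are kept in attributes
#'   `ss_subject_error`, `df_subject_error`, `ss_within_error`,
#'   `df_within_error`, `ss_total`.
#' @export
mixed_anova <- function(data, dv, subject, between, within,
                        sphericity_alpha = 0.05) {
  for (col in c(dv, subject, between, within)) {
    if (!col %in% names(data)) {
      stop("mixed_anova(): no column '", col, "' in data", call. = FALSE)
    }
  }
  y <- data[[dv]]
  if (anyNA(y)) stop("incomplete design: missing dv values", call. = FALSE)
  subj <- factor(data[[subject]])
  grp <- factor(data[[between]])
  win <- factor(data[[within]])
  a <- nlevels(grp)
  k <- nlevels(win)
  if (a < 2L) stop("mixed_anova(): need >= 2 groups", call. = FALSE)
  if (k < 2L) stop("mixed_anova(): need >= 2 within levels", call. = FALSE)

  tab <- table(subj, win)
  if (any(tab != 1L)) {
    stop("incomplete design: every subject must be observed exactly once at every within level",
         call. = FALSE)
  }
  subj_grp <- tapply(as.integer(grp), subj, function(g) {
    u <- unique(g)
    if (length(u) != 1L) stop("incomplete design: subject in several groups",
                              call. = FALSE)
    u
  })
  n_g <- table(factor(subj_grp, levels = seq_len(a)))
  if (any(n_g < 2L)) stop("mixed_anova(): need >= 2 subjects per group", call. = FALSE)
  n_s <- sum(n_g)

  m <- mean(y)
  m_subj <- tapply(y, subj, mean)
  m_grp <- tapply(y, grp, mean)
  m_win <- tapply(y, win, mean)
  m_cell <- tapply(y, list(grp, win), mean)

  ss_total <- sum((y - m)^2)
  ss_between_subj <- k * sum((m_subj - m)^2)
  ss_group <- k * sum(n_g * (m_grp - m)^2)
  ss_subj_err <- ss_between_subj - ss_group
  ss_within_subj <- sum((y - m_subj[subj])^2)
  ss_session <- n_s * sum((m_win - m)^2)
  ss_cells <- sum(rep(as.numeric(n_g), times = k) * as.numeric((m_cell - m)^2))
  ss_int <- ss_cells - ss_group - ss_session
  ss_win_err <- ss_within_subj - ss_session - ss_int

  df_group <- a - 1L
  df_subj_err <- n_s - a
  df_session <- k - 1L
  df_int <- (a - 1L) * (k - 1L)
  df_win_err <- (n_s - a) * (k - 1L)

  ms_subj_err <- ss_subj_err / df_subj_err
  ms_win_err <- ss_win_err / df_win_err

  # Mauchly W and GG epsilon from the pooled within-group covariance of the
  # subject-by-level response matrix, projected on orthonormal contrasts
  Y <- matrix(NA_real_, n_s, k)
  subj_levels <- levels(subj)
  for (i in seq_len(n_s)) {
    rows <- subj == subj_levels[i]
    Y[i, as.integer(win[rows])] <- y[rows]
  }
  grp_of_subj <- subj_grp
  S <- matrix(0, k, k)
  for (g in seq_len(a)) {
    Yg <- Y[grp_of_subj == g, , drop = FALSE]
    Yc <- scale(Yg, center = TRUE, scale = FALSE)
    S <- S + crossprod(Yc)
  }
  S <- S / (n_s - a)
  C <- orthonormal_contrasts(k)
  A <- t(C) %*% S %*% C
  lambda <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  gg_eps <- sum(lambda)^2 / ((k - 1) * sum(lambda^2))

  if (k >= 3L) {
    d <- k - 1L
    W <- det(A) / (sum(diag(A)) / d)^d
    df_w <- d * (d + 1L) / 2L - 1L
    mult <- (n_s - a) - (2 * d^2 + d + 2) / (6 * d)
    chi2_w <- -mult * log(W)
    mauchly_p <- stats::pchisq(chi2_w, df_w, lower.tail = FALSE)
  } else {
    W <- NA_real_
    mauchly_p <- NA_real_
    gg_eps <- 1 # a single contrast is always spherical
  }

  f_group <- (ss_group / df_group) / ms_subj_err
  f_session <- (ss_session / df_session) / ms_win_err
  f_int <- (ss_int / df_int) / ms_win_err

  p_group <- stats::pf(f_group, df_group, df_subj_err, lower.tail = FALSE)
  p_session <- stats::pf(f_session, df_session, df_win_err, lower.tail = FALSE)
  p_int <- stats::pf(f_int, df_int, df_win_err, lower.tail = FALSE)
  p_session_gg <- stats::pf(f_session, gg_eps * df_session, gg_eps * df_win_err,
                            lower.tail = FALSE)
  p_int_gg <- stats::pf(f_int, gg_eps * df_int, gg_eps * df_win_err,
                        lower.tail = FALSE)

  err_ss <- ss_subj_err + ss_win_err
  eta2 <- function(ss_eff) ss_eff / (ss_eff + err_ss)
  violated <- !is.na(mauchly_p) && mauchly_p < sphericity_alpha

  out <- data.frame(
    effect = c(between, within, paste0(between, ":", within)),
    ss = c(ss_group, ss_session, ss_int),
    df = c(df_group, df_session, df_int),
    ms = c(ss_group / df_group, ss_session / df_session, ss_int / df_int),
    f = c(f_group, f_session, f_int),
    df_error = c(df_subj_err, df_win_err, df_win_err),
    p = c(p_group, p_session, p_int),
    mauchly_w = c(NA_real_, W, W),
    mauchly_p = c(NA_real_, mauchly_p, mauchly_p),
    gg_epsilon = c(NA_real_, gg_eps, gg_eps),
    p_gg = c(NA_real_, p_session_gg, p_int_gg),
    p_headline = c(p_group,
                   if (violated) p_session_gg else p_session,
                   if (violated) p_int_gg else p_int),
    eta2_g = c(eta2(ss_group), eta2(ss_session), eta2(ss_int)),
    row.names = NULL
  )
  class(out) <- c("anova_result", "data.frame")
  attr(out, "ss_subject_error") <- ss_subj_err
  attr(out, "df_subject_error") <- df_subj_err
  attr(out, "ss_within_error") <- ss_win_err
  attr(out, "df_within_error") <- df_win_err
  attr(out, "ss_total") <- ss_total
  attr(out, "sphericity_violated") <- violated
  out
}

#' @export
print.anova_result <- function(x, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, 4)
  print(df)
  invisible(x)
}

#' Tukey HSD pairwise contrasts from fitted cell means
#'
#' Studentized-range-based adjusted p-values for all pairwise comparisons of
#' cell means, given the error mean square and degrees of freedom of the
#' ANOVA stratum the means were estimated in. Unequal cell sizes use the
#' Tukey-Kramer standard error.
#'
#' @param cell_means Named numeric vector of cell means.
#' @param error_ms Error mean square.
#' @param df_error Error degrees of freedom.
#' @param n_per_cell Cell sizes (scalar or vector matching `cell_means`).
#' @return Data frame with one row per pair: `pair`, `diff`, `q`, `p_adj`.
#' @export
tukey_hsd <- function(cell_means, error_ms, df_error, n_per_cell) {
  if (error_ms <= 0) stop("error: non-positive error mean square", call. = FALSE)
  kk <- length(cell_means)
  if (kk < 2L) stop("need at least two cells", call. = FALSE)
  if (length(n_per_cell) == 1L) n_per_cell <- rep(n_per_cell, kk)
  if (is.null(names(cell_means))) names(cell_means) <- paste0("cell", seq_len(kk))
  pairs <- utils::combn(kk, 2L)
  i <- pairs[1L, ]
  j <- pairs[2L, ]
  se <- sqrt(error_ms / 2 * (1 / n_per_cell[i] + 1 / n_per_cell[j]))
  d <- unname(cell_means[j] - cell_means[i])
  q <- abs(d) / se
  data.frame(
    pair = paste(names(cell_means)[i], "-", names(cell_means)[j]),
    diff = d,
    q = q,
    p_adj = stats::ptukey(q, kk, df_error, lower.tail = FALSE),
    row.names = NULL
  )
}

#' Friedman rank test for complete block designs, with tie correction
#'
#' Ranks each subject's ratings across conditions (mid-ranks for ties) and
#' tests whether the condition rank sums differ. The statistic
#' `(k - 1) * sum_j (R_j - n(k+1)/2)^2 / (sum_ij r_ij^2 - n k (k+1)^2 / 4)`
#' reduces to the classical Friedman chi-squared when there are no ties.
#'
#' @param ratings Matrix or data frame, subjects in rows, conditions in
#'   columns; complete (no missing cells), at least 2 conditions.
#' @return List with `chi2`, `df` (`k - 1`) and `p`.
#' @export
friedman_test <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("error: design must be complete (no missing cells)",
                           call. = FALSE)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (k < 2L) stop("error: need >= 2 conditions", call. = FALSE)
  if (n < 1L) stop("error: need >= 1 subject", call. = FALSE)
  r <- t(apply(ratings, 1L, rank))
  Rj <- colSums(r)
  denom <- sum(r^2) - n * k * (k + 1)^2 / 4
  if (denom <= 0) {
    # all subjects tied across every condition: no evidence against the null
    return(list(chi2 = 0, df = k - 1L, p = 1))
  }
  chi2 <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / denom
  list(chi2 = chi2, df = k - 1L,
       p = stats::pchisq(chi2, k - 1L, lower.tail = FALSE))
}

#' Mann-Whitney rank-sum test (normal approximation)
#'
#' Reports the rank-sum statistic `W` (the number of pairs where an `x`
#' observation exceeds a `y` observation, counting ties half; the convention
#' of `stats::wilcox.test`), the tie-corrected, continuity-corrected normal
#' approximation `Z`, and the two-sided p-value.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `W`, `Z` and `p`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("error: both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  N <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(W = W, Z = 0, p = 1))
  cc <- if (W > mu) 0.5 else if (W < mu) -0.5 else 0
  Z <- (W - mu - cc) / sqrt(sigma2)
  list(W = W, Z = Z, p = min(1, 2 * stats::pnorm(-abs(Z))))
}

#' Welch two-sample t test
#'
#' Unequal-variance t test with Welch-Satterthwaite (fractional) degrees of
#' freedom; wraps `stats::t.test(var.equal = FALSE)`.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return List with `t`, `df` and `p`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("error: each sample needs n >= 2", call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Empty assignment state for minimization randomization
#'
#' @param covariates Covariates balanced between groups; non-numeric columns
#'   (such as sex) are balanced as proportions.
#' @param groups The two group labels.
#' @return An object of class `assignment_state`.
#' @export
assignment_state <- function(covariates = c("age", "sex", "barthel_pre",
                                            "pegboard_pre_s"),
                             groups = c("together", "in_turn")) {
  stopifnot(length(groups) == 2L)
  structure(list(roster = NULL, covariates = covariates, groups = groups),
            class = "assignment_state")
}

# standardized covariate imbalance between the two groups of a roster
roster_imbalance <- function(roster, covariates, groups) {
  ia <- roster$group == groups[1L]
  ib <- roster$group == groups[2L]
  if (!any(ia) || !any(ib)) return(0)
  total <- 0
  for (cv in covariates) {
    v <- roster[[cv]]
    if (is.numeric(v)) {
      s <- stats::sd(v)
      d <- abs(mean(v[ia]) - mean(v[ib]))
      total <- total + if (s > 0) d / s else 0
    } else {
      lev <- sort(unique(as.character(v)))[1L]
      total <- total + abs(mean(v[ia] == lev) - mean(v[ib] == lev))
    }
  }
  total
}

#' Quasi-random group assignment by covariate minimization
#'
#' Assigns a batch of 1-3 candidate patients to the two groups by
#' enumerating every labelling that keeps the group sizes within one of
#' each other, scoring each resulting roster by the summed standardized
#' covariate imbalance (absolute group-mean difference over the pooled SD
#' for numeric covariates; absolute proportion difference for categorical
#' ones), and choosing the labelling with minimal imbalance. Ties are
#' broken uniformly at random, reproducibly by `seed`. Batches of 2 or 3
#' reflect typical accrual; a batch of 1 covers accrual tails, where the
#' group-size rule dominates.
#'
#' @param candidates Data frame of 1-3 patients carrying the state's
#'   covariate columns.
#' @param state An [assignment_state()].
#' @param seed Integer seed for tie-breaking.
#' @return List with `labels` (group per candidate) and `state` (updated,
#'   with candidates appended to the roster).
#' @export
assign_minimized <- function(candidates, state = assignment_state(), seed = 1L) {
  stopifnot(inherits(state, "assignment_state"))
  m <- nrow(candidates)
  if (is.null(m) || m < 1L || m > 3L) {
    stop("error: batch size must be 1, 2 or 3", call. = FALSE)
  }
  missing_cv <- setdiff(state$covariates, names(candidates))
  if (length(missing_cv) > 0L) {
    stop("error: candidates lack covariates: ",
         paste(missing_cv, collapse = ", "), call. = FALSE)
  }
  groups <- state$groups
  n_a <- if (is.null(state$roster)) 0L else sum(state$roster$group == groups[1L])
  n_b <- if (is.null(state$roster)) 0L else sum(state$roster$group == groups[2L])

  grids <- expand.grid(rep(list(groups), m), stringsAsFactors = FALSE)
  scores <- rep(NA_real_, nrow(grids))
  for (r in seq_len(nrow(grids))) {
    lab <- unlist(grids[r, ], use.names = FALSE)
    if (abs(n_a + sum(lab == groups[1L]) - (n_b + sum(lab == groups[2L]))) > 1L) next
    cand <- candidates[, state$covariates, drop = FALSE]
    cand$group <- lab
    roster <- if (is.null(state$roster)) cand else
      rbind(state$roster[, c(state$covariates, "group"), drop = FALSE], cand)
    scores[r] <- roster_imbalance(roster, state$covariates, groups)
  }
  if (all(is.na(scores))) {
    stop("error: no labelling satisfies the group-size constraint", call. = FALSE)
  }
  best <- which(scores <= min(scores, na.rm = TRUE) + 1e-12)
  set.seed(as.integer(seed))
  pick <- if (length(best) == 1L) best else sample(best, 1L)
  labels <- unlist(grids[pick, ], use.names = FALSE)

  cand <- candidates[, state$covariates, drop = FALSE]
  cand$group <- labels
  state$roster <- if (is.null(state$roster)) cand else
    rbind(state$roster[, c(state$covariates, "group"), drop = FALSE], cand)
  list(labels = labels, state = state)
}

#' Natural-log transform outcome columns before analysis
#'
#' Applies `log()` to the named columns and records the transform in a
#' provenance column `transform` (and attribute `"transforms"`). Tapping
#' outcomes (median interval, CV) are analyzed on the log scale, where
#' their right-skewed distributions are closer to the ANOVA's normality
#' assumption.
#'
#' @param data Data frame.
#' @param fields Column names to transform; all values must be > 0.
#' @return The transformed data frame.
#' @export
log_transform_outcomes <- function(data, fields) {
  for (f in fields) {
    if (!f %in% names(data)) stop("no column '", f, "'", call. = FALSE)
    v <- data[[f]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad) > 0L) {
      stop(sprintf("error: non-positive value in '%s' at row %d", f, bad[1L]),
           call. = FALSE)
    }
    data[[f]] <- log(v)
  }
  data$transform <- paste0("log(", paste(fields, collapse = ","), ")")
  attr(data, "transforms") <- fields
  data
}
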