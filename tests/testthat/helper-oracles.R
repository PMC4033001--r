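# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: brute-force scans, exhaustive enumeration, and
# base R model fits.

# exact Friedman p by dynamic programming over per-subject column
# permutations of the observed (mid-)ranks; ties allowed because the
# tie-correction denominator is permutation-invariant within subjects
friedman_exact_oracle <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  perm_idx <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  perm_idx <- perm_idx[apply(perm_idx, 1, function(r) length(unique(r)) == k), ,
                       drop = FALSE]
  r <- t(apply(ratings, 1, rank))
  states <- new.env(hash = TRUE)
  assign(paste(rep(0, k - 1), collapse = ","), 1, envir = states)
  for (s in seq_len(n)) {
    nxt <- new.env(hash = TRUE)
    for (key in ls(states)) {
      v <- as.numeric(strsplit(key, ",")[[1]])
      pr <- get(key, envir = states)
      for (q in seq_len(nrow(perm_idx))) {
        nv <- v + r[s, perm_idx[q, seq_len(k - 1)]]
        nk <- paste(nv, collapse = ",")
        old <- if (exists(nk, envir = nxt)) get(nk, envir = nxt) else 0
        assign(nk, old + pr / nrow(perm_idx), envir = nxt)
      }
    }
    states <- nxt
  }
  Rtot <- sum(r)
  Rj_obs <- colSums(r)
  obs <- sum((Rj_obs - n * (k + 1) / 2)^2)
  p <- 0
  for (key in ls(states)) {
    Rpart <- as.numeric(strsplit(key, ",")[[1]])
    Rj <- c(Rpart, Rtot - sum(Rpart))
    if (sum((Rj - n * (k + 1) / 2)^2) >= obs - 1e-9) {
      p <- p + get(key, envir = states)
    }
  }
  p
}

# exact two-sided Mann-Whitney p by enumerating all choose(N, n1) group splits
mw_exact_oracle <- function(x, y) {
  n1 <- length(x)
  N <- n1 + length(y)
  r <- rank(c(x, y))
  mu <- n1 * length(y) / 2
  W_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(N, n1)
  W_all <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-9)
}

# brute-force landmark scan: first supra-threshold sample of each
# contiguous supra-threshold run, and the first sub-threshold sample after
# it (no refractory bookkeeping; valid for well-separated pulses)
brute_force_landmarks <- function(trace, threshold = 0.05) {
  above <- trace$samples > threshold
  d <- diff(c(FALSE, above, FALSE))
  run_start <- which(d == 1L)
  run_end <- which(d == -1L) - 1L
  keep <- run_end < length(trace$samples) # need an actual drop below
  ms <- 1000 / trace$sample_rate_hz
  t0 <- trace$start_sample
  list(onset_ms = (t0 + run_start[keep] - 1L) * ms,
       offset_ms = (t0 + run_end[keep]) * ms)
}

# square-pulse trace builder for handcrafted detection cases
pulse_trace <- function(segments_ms, level, duration_ms = 2000,
                        rate_hz = 1000, base = 0) {
  n <- duration_ms * rate_hz / 1000
  x <- rep(base, n)
  t_ms <- (seq_len(n) - 1L) / rate_hz * 1000
  for (i in seq_along(segments_ms)) {
    seg <- segments_ms[[i]]
    x[t_ms >= seg[1] & t_ms < seg[2]] <- level[i]
  }
  force_trace(x, rate_hz, units = "newton")
}

# accrual covariate pool for minimization tests
draw_candidates <- function(m) {
  data.frame(
    age = round(runif(m, 30, 75)),
    sex = sample(c("F", "M"), m, replace = TRUE),
    barthel_pre = round(runif(m, 25, 80)),
    pegboard_pre_s = runif(m, 15, 120)
  )
}

# summed standardized imbalance, recomputed independently of the package
imbalance_oracle <- function(roster) {
  ia <- roster$group == "together"
  ib <- roster$group == "in_turn"
  tot <- 0
  for (cv in c("age", "barthel_pre", "pegboard_pre_s")) {
    v <- roster[[cv]]
    s <- sd(v)
    tot <- tot + if (s > 0) abs(mean(v[ia]) - mean(v[ib])) / s else 0
  }
  tot + abs(mean(roster$sex[ia] == "F") - mean(roster$sex[ib] == "F"))
}
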