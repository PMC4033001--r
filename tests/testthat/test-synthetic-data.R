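test_that("generator parameters are validated", {
  expect_error(tap_gen_params(mean_iti = 0), "mean_iti")
  expect_error(tap_gen_params(duration_s = -1), "duration_s")
  expect_error(tap_gen_params(soft_tap_rate = 1.5), "rates")
  expect_error(tap_gen_params(peak_force = 0), "peak_force")
  expect_error(tap_gen_params(dwell_ms = 15, pulse_rise_ms = 10,
                              pulse_fall_ms = 10), "dwell")
  expect_error(paced_gen_params(tempo_bpm = 0), "tempo_bpm")
  expect_error(cohort_gen_params(n_per_group = 1), "n_per_group")
  expect_error(cohort_gen_params(pegboard_pre_sd = -1), "sd")
})

test_that("identical (params, seed) give bit-identical traces; seeds differ", {
  p <- tap_gen_params(noise_sd = 0.01, soft_tap_rate = 0.05,
                      double_tap_rate = 0.05, pause_rate = 0.05)
  a <- generate_unpaced_trace(p, seed = 42)
  b <- generate_unpaced_trace(p, seed = 42)
  expect_identical(a, b)
  c <- generate_unpaced_trace(p, seed = 43)
  expect_false(identical(a$trace$samples, c$trace$samples))

  pp <- paced_gen_params(noise_sd = 0.01)
  expect_identical(generate_paced_trace(pp, seed = 7),
                   generate_paced_trace(pp, seed = 7))
})

test_that("trace length equals duration times sample rate", {
  g <- generate_unpaced_trace(tap_gen_params(duration_s = 10), seed = 1)
  expect_length(g$trace$samples, 30000L)
  gp <- generate_paced_trace(paced_gen_params(duration_s = 20), seed = 1)
  expect_length(gp$trace$samples, 60000L)
})

test_that("zero-noise, zero-CV generation yields exactly regular ground-truth intervals", {
  g <- generate_unpaced_trace(tap_gen_params(mean_iti = 300, iti_cv = 0,
                                             noise_sd = 0), seed = 3)
  expect_equal(diff(g$truth$contact_ms), rep(300, nrow(g$truth) - 1L))
})

test_that("ground-truth interval CV approaches the requested CV at large n", {
  g <- generate_unpaced_trace(tap_gen_params(mean_iti = 250, iti_cv = 0.1,
                                             duration_s = 120), seed = 11)
  itis <- diff(g$truth$contact_ms)
  expect_gt(length(itis), 300)
  expect_equal(sd(itis) / mean(itis), 0.1, tolerance = 0.1)
  expect_equal(mean(itis), 250, tolerance = 0.02)
})

test_that("pauses appear as flagged ground-truth gaps longer than 2000 ms", {
  g <- generate_unpaced_trace(tap_gen_params(pause_rate = 0.2,
                                             duration_s = 30), seed = 2)
  expect_true(any(g$truth$after_pause))
  gaps <- diff(g$truth$contact_ms)
  expect_true(any(gaps > 2000))
  # every tap flagged after_pause sits > 2000 ms after its predecessor
  flagged <- which(g$truth$after_pause)
  expect_true(all(gaps[flagged - 1L] > 2000))
})

test_that("paced clicks are spaced at exactly 60000/tempo ms and zero asynchrony puts taps on the clicks", {
  g <- generate_paced_trace(paced_gen_params(mean_asynchrony_ms = 0,
                                             asynchrony_sd_ms = 0,
                                             noise_sd = 0), seed = 1)
  expect_equal(diff(g$schedule$click_times_ms),
               rep(60000 / 69, length(g$schedule$click_times_ms) - 1L))
  expect_equal(g$schedule$inter_click_ms, 869.5652, tolerance = 1e-6)
  expect_equal(g$truth$contact_ms, g$truth$click_ms)
})

test_that("the paced circular mean phase matches the requested asynchrony by construction", {
  g <- generate_paced_trace(paced_gen_params(mean_asynchrony_ms = -50,
                                             asynchrony_sd_ms = 20,
                                             duration_s = 120), seed = 8)
  ph <- compute_phases(g$truth$contact_ms, g$schedule)
  est <- resultant_length(ph)
  expected <- -2 * pi * 50 / (60000 / 69)
  # circular SE ~ sd_phase / sqrt(n)
  se <- (2 * pi * 20 / (60000 / 69)) / sqrt(length(ph))
  expect_equal(est$mean_phase_rad, expected, tolerance = 4 * se / abs(expected))
})

test_that("generated paced asynchronies follow the requested wrapped normal (KS)", {
  g <- generate_paced_trace(paced_gen_params(mean_asynchrony_ms = -30,
                                             asynchrony_sd_ms = 40,
                                             duration_s = 240), seed = 13)
  # sd 40 ms on an 870 ms cycle: wrapping mass is negligible, so the
  # plain normal is the reference distribution
  ks <- suppressWarnings(ks.test(g$truth$asynchrony_ms, "pnorm", -30, 40))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohorts are reproducible and structurally complete", {
  co <- generate_cohort(cohort_gen_params(seed = 9))
  expect_identical(co, generate_cohort(cohort_gen_params(seed = 9)))
  expect_identical(nrow(co$patients), 28L)
  expect_equal(as.numeric(table(co$patients$group)), c(14, 14))
  expect_identical(nrow(co$poms), 56L)
  items <- as.matrix(co$poms[, sprintf("item_%02d", 1:35)])
  expect_true(all(items %in% 1:5))
  expect_identical(nrow(co$faces), 28L * 12L)
  expect_true(all(co$faces$rating %in% 1:7))
  expect_true(all(co$patients$pegboard_pre_s > 0))
})

test_that("cohort CSV export writes the three tables", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_gen_params(n_per_group = 3, seed = 1))
  write_cohort(co, dir)
  pts <- read.csv(file.path(dir, "patients.csv"))
  expect_identical(nrow(pts), 6L)
  expect_identical(nrow(read.csv(file.path(dir, "poms.csv"))), 12L)
  expect_identical(nrow(read.csv(file.path(dir, "faces.csv"))), 72L)
})

test_that("a faces trend in one group only is picked up by the Friedman test in that group", {
  co <- generate_cohort(cohort_gen_params(
    faces_trend = c(together = 0, in_turn = 0.25), seed = 4))
  per_group_p <- sapply(c("together", "in_turn"), function(gr) {
    ids <- co$patients$patient_id[co$patients$group == gr]
    f <- co$faces[co$faces$patient_id %in% ids & co$faces$time_index %in% c(1, 6, 12), ]
    m <- matrix(f$rating[order(f$patient_id, f$time_index)], ncol = 3,
                byrow = TRUE)
    friedman_test(m)$p
  })
  expect_lt(per_group_p["in_turn"], 0.01)
  expect_gt(per_group_p["together"], 0.05)
})
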