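test_that("antisaccade designs are balanced and seed-reproducible", {
  d <- generate_task_design("AS", seed = 1)
  expect_equal(nrow(d), 80)
  expect_equal(sum(d$ps_x_deg < 0), 40)
  expect_equal(sum(d$ps_x_deg > 0), 40)
  expect_true(all(abs(d$ps_x_deg) == 15))
  expect_true(all(d$fp_duration_ms >= 2000 & d$fp_duration_ms <= 4000))
  expect_true(all(d$intertrial_ms >= 2000 & d$intertrial_ms <= 3000))
  expect_identical(d, generate_task_design("AS", seed = 1))
  expect_false(identical(d$ps_x_deg,
                         generate_task_design("AS", seed = 2)$ps_x_deg))
})

test_that("Go/NoGo designs balance cue colour and the eight locations", {
  d <- generate_task_design("GnG", seed = 1)
  expect_equal(nrow(d), 80)
  expect_equal(unname(table(d$condition)[c("Go", "NoGo")]), c(40L, 40L),
               ignore_attr = TRUE)
  expect_equal(unname(table(d$location_index)), rep(10L, 8),
               ignore_attr = TRUE)
  ecc <- sqrt(d$ps_x_deg^2 + d$ps_y_deg^2)
  expect_equal(ecc, rep(15, 80), tolerance = 1e-9)
  expect_error(generate_task_design("bogus"), "arg")
})

test_that("cognitive score generator recovers requested moments and corr", {
  tabs <- load_correlation_tables()
  m5 <- correlation_matrix(tabs$cognitive, measure_info()$measure[1:6])
  cp <- default_cognitive_params()$patient
  x <- generate_cognitive_scores(5000, cp$means, cp$sds, m5, seed = 7)
  expect_equal(dim(x), c(5000, 6))
  expect_equal(cor(x[, "DS"], x[, "SC"]), 0.63, tolerance = 0.05)
  expect_equal(unname(colMeans(x)), unname(cp$means), tolerance = 0.05 * max(cp$means))
  # independence case
  xi <- generate_cognitive_scores(5000, cp$means, cp$sds, diag(6), seed = 8)
  off <- cor(xi)[upper.tri(diag(6))]
  expect_true(all(abs(off) < 0.05))
  # degenerate scale
  x0 <- generate_cognitive_scores(10, cp$means, rep(0, 6), diag(6), seed = 9)
  expect_true(all(apply(x0, 1, function(r) all(r == cp$means))))
  expect_error(generate_cognitive_scores(0, cp$means, cp$sds, diag(6)), "n")
  ns <- matrix(c(1, 0.5, 0.2, 1), 2, 2)
  expect_error(generate_cognitive_scores(5, 1:2, c(1, 1), ns), "symmetric")
})

test_that("trial outcomes respect accuracy boundaries and rates", {
  d <- generate_task_design("AS", seed = 3)
  all_correct <- generate_trial_outcomes(d, 1, seed = 1, miss_prob = 0)
  expect_true(all(all_correct$outcome == "correct"))
  none_correct <- generate_trial_outcomes(d, 0, seed = 1, miss_prob = 0)
  expect_false(any(none_correct$outcome == "correct"))
  big <- do.call(rbind, replicate(125, d, simplify = FALSE))  # 10000 trials
  out <- generate_trial_outcomes(big, 0.75, seed = 3, miss_prob = 0)
  expect_equal(mean(out$outcome == "correct"), 0.75, tolerance = 0.02 / 0.75)
  expect_error(generate_trial_outcomes(d, 1.2), "\\[0, 1\\]")
})

test_that("error latencies are drawn with a lower mean than correct ones", {
  d <- generate_task_design("AS", seed = 4)
  big <- do.call(rbind, replicate(30, d, simplify = FALSE))
  out <- generate_trial_outcomes(big, 0.5, seed = 5, miss_prob = 0)
  lat_c <- out$latency_ms[out$outcome == "correct"]
  lat_e <- out$latency_ms[out$outcome == "error"]
  expect_gt(mean(lat_c), mean(lat_e))
  expect_true(all(out$latency_ms > 80 & out$latency_ms < 900, na.rm = TRUE))
})

test_that("gaze traces land on the commanded endpoint at the sample spacing", {
  tr <- fake_trial(ps_x = 15, ps_onset = 2400)
  out <- tr
  out$outcome <- "correct"; out$latency_ms <- 300
  out$target_x_deg <- -15; out$target_y_deg <- 0
  gz <- generate_gaze_trace(tr, out, noise_sd = 0.05, seed = 11)
  expect_equal(diff(gz$t_ms)[1], 4)
  expect_equal(max(abs(diff(gz$t_ms) - 4)), 0, tolerance = 1e-9)
  tail_mean <- mean(gz$x_deg[gz$t_ms > 2400 + 300 + 100])
  expect_equal(tail_mean, -15, tolerance = 0.1)
  # withheld response: excursion stays inside the response threshold
  hold <- tr; hold$outcome <- "correct"; hold$latency_ms <- NA
  hold$target_x_deg <- NA; hold$target_y_deg <- NA
  gz0 <- generate_gaze_trace(tr, hold, noise_sd = 0.15, seed = 12)
  expect_lt(max(sqrt(gz0$x_deg^2 + gz0$y_deg^2)), 2)
  expect_error(generate_gaze_trace(tr, out, sampling_rate = 0), "sampling_rate")
})

test_that("measure-level cohorts have the configured shape and ranges", {
  cfg <- simulation_config(n_patients = 40, n_controls = 20, seed = 2)
  coh <- simulate_cohort(cfg, level = "measures")
  expect_equal(nrow(coh), 60)
  expect_equal(sum(coh$group == "patient"), 40)
  expect_true(all(measure_info()$measure %in% names(coh)))
  expect_true(all(coh$ASEs >= 0 & coh$ASEs <= 1))
  expect_true(all(coh$GnGEs >= 0 & coh$GnGEs <= 1))
  expect_true(all(coh[, c("VM", "DS", "TMT", "VF", "SC", "TL")] >= 0))
  # bit-identical under the same config + seed
  expect_identical(coh, simulate_cohort(cfg, level = "measures"))
})

test_that("simulation config validates its invariants", {
  expect_error(simulation_config(n_patients = 0), "n_patients")
  expect_error(simulation_config(target_correlation = diag(5)), "12 x 12")
  bad <- target_correlation_matrix(); bad[1, 2] <- 2; bad[2, 1] <- 2
  expect_error(simulation_config(target_correlation = bad), "\\[-1, 1\\]")
  asym <- target_correlation_matrix(); asym[1, 2] <- 0
  expect_error(simulation_config(target_correlation = asym), "symmetric")
})
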