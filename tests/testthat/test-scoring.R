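test_that("primary saccade selection: first qualifying after onset", {
  ev <- rbind(fake_saccade(2120, x1 = 15), fake_saccade(2300, x1 = -15))
  ps <- primary_saccade(ev, 2000)
  expect_equal(ps$onset_ms, 2120)
  expect_null(primary_saccade(ev, 2500))
  expect_null(primary_saccade(ev[0, ], 2000))
  # amplitude gating skips the small saccade (brute-force: first with amp >= 2)
  ev2 <- rbind(fake_saccade(2100, x1 = 0.8), fake_saccade(2250, x1 = 14))
  cand <- ev2[ev2$onset_ms >= 2000 & ev2$amplitude_deg >= 2, ]
  expect_equal(primary_saccade(ev2, 2000, 2)$onset_ms, min(cand$onset_ms))
  expect_equal(primary_saccade(ev2, 2000, 2)$amplitude_deg, 14)
})

test_that("antisaccade trials classify by direction and latency window", {
  tr <- fake_trial(ps_x = 15, ps_onset = 2000)
  # away from the stimulus: correct
  ok <- score_antisaccade_trial(tr, fake_saccade(2300, x1 = -15))
  expect_equal(ok$classification, "correct")
  expect_equal(ok$latency_ms, 300)
  # toward the stimulus: reflexive error
  err <- score_antisaccade_trial(tr, fake_saccade(2200, x1 = 15))
  expect_equal(err$classification, "error")
  expect_equal(err$latency_ms, 200)
  # anticipatory
  low <- score_antisaccade_trial(tr, fake_saccade(2075, x1 = -15))
  expect_equal(low$classification, "discarded")
  expect_equal(low$discard_reason, "latency_low")
  # late
  high <- score_antisaccade_trial(tr, fake_saccade(2950, x1 = -15))
  expect_equal(high$discard_reason, "latency_high")
  # no response
  expect_equal(score_antisaccade_trial(tr, NULL)$classification, "miss")
  expect_error(score_antisaccade_trial(fake_trial(task = "GnG"), NULL), "AS")
})

test_that("Go/NoGo trials follow the instructed response rules", {
  go <- fake_trial(task = "GnG", condition = "Go", ps_x = 15, ps_onset = 2000)
  hit <- score_gonogo_trial(go, fake_saccade(2350, x1 = 15))
  expect_equal(hit$classification, "correct")
  expect_equal(hit$latency_ms, 350)
  expect_equal(score_gonogo_trial(go, NULL)$classification, "miss")
  wrong_way <- score_gonogo_trial(go, fake_saccade(2350, x1 = -15))
  expect_equal(wrong_way$classification, "error")
  nogo <- fake_trial(task = "GnG", condition = "NoGo", ps_x = 15,
                     ps_onset = 2000)
  expect_equal(score_gonogo_trial(nogo, NULL)$classification, "correct")
  slip <- score_gonogo_trial(nogo, fake_saccade(2280, x1 = 15))
  expect_equal(slip$classification, "error")
  expect_equal(slip$latency_ms, 280)
  expect_error(score_gonogo_trial(fake_trial(task = "AS"), NULL), "GnG")
})

test_that("direction tolerance separates adjacent diamond locations", {
  # stimulus at 45 degrees; saccade due right (0 deg) is 45 off: error
  go <- fake_trial(task = "GnG", condition = "Go",
                   ps_x = 15 * cos(pi / 4), ps_y = 15 * sin(pi / 4),
                   ps_onset = 2000)
  to_right <- fake_saccade(2300, x1 = 15, y1 = 0)
  expect_equal(score_gonogo_trial(go, to_right)$classification, "error")
  to_target <- fake_saccade(2300, x1 = 15 * cos(pi / 4), y1 = 15 * sin(pi / 4))
  expect_equal(score_gonogo_trial(go, to_target)$classification, "correct")
})

test_that("performance accuracy counts correct over counted trials", {
  sc <- data.frame(classification = c(rep("correct", 59), rep("error", 21)))
  expect_equal(performance_accuracy(sc), 0.7375)
  expect_equal(performance_accuracy(data.frame(classification = rep("correct", 5))), 1)
  expect_equal(performance_accuracy(data.frame(classification = rep("error", 40))), 0)
  # discarded trials drop from both numerator and denominator by default
  sc2 <- data.frame(classification = c(rep("correct", 30), rep("error", 10),
                                       rep("discarded", 40)))
  expect_equal(performance_accuracy(sc2), 0.75)
  expect_equal(performance_accuracy(sc2, denominator = "all"), 0.375)
  expect_error(performance_accuracy(data.frame(classification = rep("discarded", 3))),
               "countable")
})

test_that("every trial gets exactly one classification (partition)", {
  d <- rbind(generate_task_design("AS", seed = 6),
             generate_task_design("GnG", seed = 6))
  out <- generate_trial_outcomes(d, 0.7, seed = 7, miss_prob = 0.05)
  scores <- lapply(seq_len(nrow(out)), function(i) {
    ev <- if (!is.na(out$latency_ms[i])) {
      fake_saccade(out$ps_onset_ms[i] + out$latency_ms[i],
                   x1 = out$target_x_deg[i], y1 = out$target_y_deg[i])
    } else NULL
    score_trial(out[i, ], ev)
  })
  scores <- do.call(rbind, scores)
  expect_equal(nrow(scores), nrow(d))
  tab <- table(scores$classification)
  expect_equal(sum(tab), nrow(d))
  expect_true(all(names(tab) %in% c("correct", "error", "miss", "discarded")))
})

test_that("no latency outside the filter window reaches a summary", {
  tr <- fake_trial(ps_onset = 2000)
  scores <- rbind(
    score_antisaccade_trial(tr, fake_saccade(2300, x1 = -15)),
    score_antisaccade_trial(tr, fake_saccade(2040, x1 = -15)),   # 40 ms
    score_antisaccade_trial(tr, fake_saccade(2990, x1 = -15)),   # 990 ms
    score_antisaccade_trial(tr, fake_saccade(2200, x1 = 15)))
  kept <- scores[scores$classification != "discarded", ]
  expect_true(all(kept$latency_ms >= 80 & kept$latency_ms <= 900, na.rm = TRUE))
  s <- summarize_subject(scores, "s1", "patient")
  expect_equal(s$asl_median_ms, 300)   # only the in-window correct trial
  expect_equal(s$asel_median_ms, 200)
})

test_that("subject summaries expose the six network measures", {
  tr <- fake_trial(ps_onset = 2000)
  as_scores <- rbind(
    score_antisaccade_trial(tr, fake_saccade(2200, x1 = -15)),
    score_antisaccade_trial(tr, fake_saccade(2300, x1 = -15)),
    score_antisaccade_trial(tr, fake_saccade(2400, x1 = -15)))
  go <- fake_trial(task = "GnG", condition = "Go", ps_onset = 2000)
  ng <- fake_trial(task = "GnG", condition = "NoGo", ps_onset = 2000)
  gng_scores <- rbind(
    score_gonogo_trial(go, fake_saccade(2350, x1 = 15)),
    score_gonogo_trial(go, NULL),
    score_gonogo_trial(ng, NULL),
    score_gonogo_trial(ng, fake_saccade(2280, x1 = 15)))
  s <- summarize_subject(rbind(as_scores, gng_scores), "s1", "patient")
  expect_equal(s$asl_median_ms, 300)  # odd-length median
  expect_true(is.na(s$asel_median_ms))  # no AS errors at all
  expect_equal(s$ase_proportion, 0)
  expect_equal(s$go_pa, 0.5)     # the Go miss counts as incorrect
  expect_equal(s$nogo_pa, 0.5)
  expect_equal(s$gngl_median_ms, 350)
  expect_equal(s$gngel_median_ms, 280)
  expect_equal(s$gnge_proportion, 0.5)
  m <- oculomotor_measures(s)
  expect_equal(m$ASLs, 300)
  expect_true(is.na(m$ASELs))
  expect_error(summarize_subject(as_scores[0, ], "s2", "patient"), "scorable")
})

test_that("summary accuracy converges to the embedded accuracy", {
  d <- generate_task_design("AS", seed = 8)
  big <- do.call(rbind, replicate(125, d, simplify = FALSE))
  big$trial_id <- seq_len(nrow(big))
  out <- generate_trial_outcomes(big, 0.9, seed = 9, miss_prob = 0)
  scores <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
    ev <- if (!is.na(out$latency_ms[i])) {
      fake_saccade(out$ps_onset_ms[i] + out$latency_ms[i],
                   x1 = out$target_x_deg[i], y1 = out$target_y_deg[i])
    } else NULL
    score_trial(out[i, ], ev)
  }))
  s <- summarize_subject(scores, "s1", "patient")
  expect_equal(s$as_pa, 0.9, tolerance = 0.02 / 0.9)
})
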