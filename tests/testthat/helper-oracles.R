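# Independently coded brute-force oracles: textbook formulas and
# sample-by-sample scans, kept deliberately naive and separate from the
# package implementation.

oracle_t_pooled <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_f <- function(a, b) {
  f <- var(a) / var(b)
  d1 <- length(a) - 1; d2 <- length(b) - 1
  tail <- pf(f, d1, d2)
  list(statistic = f, df = c(d1, d2), p = 2 * min(tail, 1 - tail))
}

oracle_kruskal <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tapply(r, g, length)) - 3 * (n + 1)
  ties <- table(x)
  h <- h / (1 - sum(ties^3 - ties) / (n^3 - n))
  df <- length(groups) - 1
  list(statistic = h, df = df, p = pchisq(h, df, lower.tail = FALSE))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, statistic = t, df = n - 2, p = 2 * pt(-abs(t), n - 2))
}

oracle_influence <- function(x, y) {
  n <- length(x)
  xb <- mean(x); sxx <- sum((x - xb)^2)
  b1 <- sum((x - xb) * (y - mean(y))) / sxx
  b0 <- mean(y) - b1 * xb
  e <- y - b0 - b1 * x
  h <- 1 / n + (x - xb)^2 / sxx
  s2 <- sum(e^2) / (n - 2)
  rstd <- e / sqrt(s2 * (1 - h))
  cooks <- e^2 * h / (2 * s2 * (1 - h)^2)
  s2i <- (sum(e^2) - e^2 / (1 - h)) / (n - 3)
  rstud <- e / sqrt(s2i * (1 - h))
  dfits <- rstud * sqrt(h / (1 - h))
  list(leverage = h, std_residual = rstd, cooks_d = cooks, dfits = dfits)
}

# sample-by-sample scan for suprathreshold velocity runs with duration and
# peak validation; returns onset/offset indices
oracle_saccade_runs <- function(speed, t, vt, min_ms, peak) {
  runs <- list()
  i <- 1
  n <- length(speed)
  while (i <= n) {
    if (!is.na(speed[i]) && speed[i] >= vt) {
      j <- i
      while (j < n && !is.na(speed[j + 1]) && speed[j + 1] >= vt) j <- j + 1
      if (t[j] - t[i] >= min_ms && max(speed[i:j]) >= peak) {
        runs[[length(runs) + 1]] <- c(i, j)
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  runs
}

# noiseless trace: fixation at (x0, y0), raised-cosine steps defined by
# rows (onset_ms, dx, dy, duration_ms)
make_step_trace <- function(total_ms, steps = NULL, rate = 250,
                            x0 = 0, y0 = 0, noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, total_ms, by = 1000 / rate)
  x <- rep(x0, length(t)) + rnorm(length(t), 0, noise)
  y <- rep(y0, length(t)) + rnorm(length(t), 0, noise)
  if (!is.null(steps)) {
    for (k in seq_len(nrow(steps))) {
      ph <- pmin(pmax((t - steps$onset_ms[k]) / steps$duration_ms[k], 0), 1)
      prof <- (1 - cos(pi * ph)) / 2
      x <- x + steps$dx[k] * prof
      y <- y + steps$dy[k] * prof
    }
  }
  data.frame(t_ms = t, x_deg = x, y_deg = y, valid = TRUE)
}

# one AS/GnG trial row for scoring tests
fake_trial <- function(task = "AS", condition = "none", ps_x = 15, ps_y = 0,
                       ps_onset = 2000, trial_id = 1) {
  data.frame(trial_id = trial_id, task = task, condition = condition,
             location_index = NA_integer_, ps_x_deg = ps_x, ps_y_deg = ps_y,
             fp_duration_ms = ps_onset, ps_onset_ms = ps_onset,
             intertrial_ms = 2500, stringsAsFactors = FALSE)
}

# saccade event row as detect_events would emit it
fake_saccade <- function(onset, offset = onset + 50, x0 = 0, y0 = 0,
                         x1 = 15, y1 = 0) {
  data.frame(kind = "saccade", onset_ms = onset, offset_ms = offset,
             start_x_deg = x0, start_y_deg = y0, end_x_deg = x1,
             end_y_deg = y1,
             amplitude_deg = sqrt((x1 - x0)^2 + (y1 - y0)^2),
             peak_velocity_dps = 400, stringsAsFactors = FALSE)
}
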