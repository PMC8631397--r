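# Synthetic cohorts: task designs, trial outcomes, gaze traces and
# measure-level profiles with the statistical structure the analysis assumes.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Default per-group latency parameters (ms)
#'
#' Mean and SD of the positive saccade-latency distributions for correct and
#' erroneous responses in the antisaccade and Go/NoGo tasks, calibrated to
#' the published group-level values. Latencies are drawn from a shifted
#' lognormal (shift = the 80 ms analysis floor) truncated to the
#' (80, 900) ms analysis window.
#'
#' @return Named list with elements `patient` and `control`, each holding
#'   `as_correct`, `as_error`, `go_correct`, `nogo_error` (`c(mean, sd)`)
#'   and `shift`.
#' @export
default_latency_params <- function() {
  list(
    patient = list(shift = 80,
                   as_correct = c(mean = 361, sd = 139),
                   as_error   = c(mean = 241, sd = 114),
                   go_correct = c(mean = 409, sd = 156),
                   nogo_error = c(mean = 355, sd = 154)),
    control = list(shift = 80,
                   as_correct = c(mean = 276, sd = 87),
                   as_error   = c(mean = 228, sd = 67),
                   go_correct = c(mean = 379, sd = 136),
                   nogo_error = c(mean = 297, sd = 81))
  )
}

#' Default per-group accuracy parameters
#'
#' Subject-level performance accuracies are drawn from a logit-normal
#' distribution whose location matches the published group median and whose
#' scale is fitted to the published quartile range on the logit scale.
#'
#' @return Named list with elements `patient` and `control`, each holding
#'   `as`, `go`, `nogo`: `c(median, q1, q3)` on \[0, 1\].
#' @export
default_accuracy_params <- function() {
  list(
    patient = list(as   = c(median = 0.738, q1 = 0.619, q3 = 0.888),
                   go   = c(median = 0.900, q1 = 0.800, q3 = 0.975),
                   nogo = c(median = 0.600, q1 = 0.475, q3 = 0.713)),
    control = list(as   = c(median = 0.963, q1 = 0.913, q3 = 0.988),
                   go   = c(median = 0.9875, q1 = 0.975, q3 = 0.995),
                   nogo = c(median = 0.800, q1 = 0.725, q3 = 0.850))
  )
}

#' Default per-group cognitive test score moments
#'
#' Means and SDs of the six battery sub-tests (VM, DS, TMT, VF, SC, TL),
#' calibrated to the published group results.
#'
#' @return Named list with elements `patient` and `control`, each holding
#'   numeric vectors `means` and `sds` named by measure.
#' @export
default_cognitive_params <- function() {
  meas <- c("VM", "DS", "TMT", "VF", "SC", "TL")
  mk <- function(means, sds) {
    names(means) <- meas; names(sds) <- meas
    list(means = means, sds = sds)
  }
  list(
    patient = mk(c(43.5, 18.9, 63.7, 51.4, 49.1, 16.9),
                 c(11.2, 3.8, 14.4, 13.4, 13.5, 3.8)),
    control = mk(c(51.1, 22.4, 75.3, 60.2, 64.3, 19.6),
                 c(6.9, 2.8, 12.0, 12.6, 9.5, 2.4))
  )
}

#' Default per-group oculomotor summary-measure moments
#'
#' Subject-level means and SDs for the six oculomotor network measures
#' (latency medians in ms; error measures as proportions). Latency moments
#' follow the published group means/SDs; error-proportion moments are
#' matched to the published medians and quartile ranges
#' (SD approximated as IQR / 1.349).
#'
#' @return Named list with elements `patient` and `control`, each holding
#'   `means` and `sds` named by measure.
#' @export
default_oculomotor_params <- function() {
  meas <- c("ASLs", "ASELs", "ASEs", "GnGLs", "GnGELs", "GnGEs")
  mk <- function(means, sds) {
    names(means) <- meas; names(sds) <- meas
    list(means = means, sds = sds)
  }
  list(
    patient = mk(c(361, 241, 0.100, 409, 355, 0.400),
                 c(139, 114, 0.158, 156, 154, 0.176)),
    control = mk(c(276, 228, 0.038, 379, 297, 0.200),
                 c(87, 67, 0.046, 136, 81, 0.093))
  )
}

#' Simulation configuration for a synthetic cohort
#'
#' Bundles and validates all generator parameters: cohort sizes, latency and
#' accuracy distributions per group, cognitive-score moments, the 12 x 12
#' target correlation matrix over the network measures, and gaze-stream
#' parameters.
#'
#' @param n_patients,n_controls Group sizes (>= 1).
#' @param seed Integer seed driving every random draw of the cohort.
#' @param latency_params See [default_latency_params()].
#' @param accuracy_params See [default_accuracy_params()].
#' @param cognitive_params See [default_cognitive_params()].
#' @param oculomotor_params See [default_oculomotor_params()].
#' @param target_correlation Symmetric 12 x 12 correlation matrix in
#'   canonical measure order; repaired to positive semidefinite if needed.
#' @param sampling_rate Gaze sampling rate in Hz (default 250).
#' @param noise_sd Fixation noise SD in degrees (default 0.15).
#' @param miss_prob Probability that a commanded response is omitted
#'   (default 0.02).
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_patients = 93, n_controls = 41, seed = 1,
                              latency_params = default_latency_params(),
                              accuracy_params = default_accuracy_params(),
                              cognitive_params = default_cognitive_params(),
                              oculomotor_params = default_oculomotor_params(),
                              target_correlation = target_correlation_matrix(),
                              sampling_rate = 250, noise_sd = 0.15,
                              miss_prob = 0.02) {
  stopifnot(n_patients >= 1, n_controls >= 1,
            sampling_rate > 0, noise_sd >= 0,
            miss_prob >= 0, miss_prob <= 1)
  tc <- target_correlation
  if (!is.matrix(tc) || nrow(tc) != 12 || ncol(tc) != 12) {
    stop("target_correlation must be a 12 x 12 matrix")
  }
  if (!isSymmetric(tc, tol = 1e-8)) stop("target_correlation must be symmetric")
  if (any(abs(diag(tc) - 1) > 1e-8)) stop("target_correlation must have unit diagonal")
  if (any(abs(tc) > 1 + 1e-8)) stop("target_correlation entries must lie in [-1, 1]")
  for (g in c("patient", "control")) {
    if (any(cognitive_params[[g]]$sds < 0)) stop("cognitive SDs must be >= 0")
    if (any(oculomotor_params[[g]]$sds < 0)) stop("oculomotor SDs must be >= 0")
  }
  structure(list(n_patients = n_patients, n_controls = n_controls,
                 seed = as.integer(seed),
                 latency_params = latency_params,
                 accuracy_params = accuracy_params,
                 cognitive_params = cognitive_params,
                 oculomotor_params = oculomotor_params,
                 target_correlation = nearest_correlation(tc),
                 sampling_rate = sampling_rate, noise_sd = noise_sd,
                 miss_prob = miss_prob),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  groups: %d patients, %d controls (seed %d)\n",
              x$n_patients, x$n_controls, x$seed))
  cat(sprintf("  gaze: %g Hz, fixation noise %g deg, miss prob %g\n",
              x$sampling_rate, x$noise_sd, x$miss_prob))
  invisible(x)
}

#' Generate a pseudorandom task design
#'
#' Antisaccade (`"AS"`): 80 trials, the left (-15 deg) and right (+15 deg)
#' peripheral locations 40 times each. Go/NoGo (`"GnG"`): 80 trials, 40 Go
#' and 40 NoGo cues over 8 locations in a diamond formation, each location
#' used 10 times (5 per cue colour). Fixation intervals are drawn uniformly
#' from 2000-4000 ms and intertrial gaps from 2000-3000 ms.
#'
#' @param task `"AS"` or `"GnG"`.
#' @param seed Optional integer seed; identical seeds give identical designs.
#' @param eccentricity_deg Stimulus eccentricity (default 15).
#' @return A data frame of trial specifications with columns `trial_id`,
#'   `task`, `condition` (`none`/`Go`/`NoGo`), `location_index` (0-7 for
#'   GnG, `NA` for AS), `ps_x_deg`, `ps_y_deg`, `fp_duration_ms`,
#'   `ps_onset_ms` and `intertrial_ms`.
#' @export
#' @examples
#' d <- generate_task_design("AS", seed = 1)
#' table(sign(d$ps_x_deg))
generate_task_design <- function(task = c("AS", "GnG"), seed = NULL,
                                 eccentricity_deg = 15) {
  task <- match.arg(task)
  .with_seed(seed, {
    n <- 80
    if (task == "AS") {
      side <- sample(rep(c(-1, 1), each = 40))
      df <- data.frame(trial_id = seq_len(n), task = task, condition = "none",
                       location_index = NA_integer_,
                       ps_x_deg = side * eccentricity_deg, ps_y_deg = 0,
                       stringsAsFactors = FALSE)
    } else {
      # balanced jointly: 5 Go + 5 NoGo at each of the 8 diamond locations
      loc <- rep(0:7, each = 10)
      cond <- rep(rep(c("Go", "NoGo"), each = 5), times = 8)
      ord <- sample.int(n)
      loc <- loc[ord]; cond <- cond[ord]
      ang <- loc * pi / 4
      df <- data.frame(trial_id = seq_len(n), task = task, condition = cond,
                       location_index = loc,
                       ps_x_deg = round(eccentricity_deg * cos(ang), 10),
                       ps_y_deg = round(eccentricity_deg * sin(ang), 10),
                       stringsAsFactors = FALSE)
    }
    df$fp_duration_ms <- stats::runif(n, 2000, 4000)
    df$ps_onset_ms <- df$fp_duration_ms
    df$intertrial_ms <- stats::runif(n, 2000, 3000)
    df
  })
}

.mvn_scores <- function(n, means, sds, corr) {
  k <- length(means)
  stopifnot(length(sds) == k, nrow(corr) == k, ncol(corr) == k)
  if (!isSymmetric(unname(corr), tol = 1e-8)) stop("corr must be symmetric")
  if (any(abs(diag(corr) - 1) > 1e-8)) stop("corr must have unit diagonal")
  if (any(sds < 0)) stop("sds must be >= 0")
  corr <- nearest_correlation(unname(corr))
  sigma <- diag(sds, k) %*% corr %*% diag(sds, k)
  x <- MASS::mvrnorm(n, mu = means, Sigma = sigma)
  if (n == 1) x <- matrix(x, nrow = 1)
  colnames(x) <- names(means)
  x
}

#' Generate correlated cognitive test profiles
#'
#' Draws `n` profiles from a multivariate normal with the requested means,
#' SDs and correlation matrix. A non-positive-semidefinite correlation
#' matrix is first repaired by [nearest_correlation()]. Negative impossible
#' scores are clipped at 0.
#'
#' @param n Number of profiles (>= 1).
#' @param means,sds Numeric vectors of equal length (named by measure).
#' @param corr Correlation matrix of matching dimension.
#' @param seed Optional integer seed.
#' @return An `n` x `length(means)` numeric matrix.
#' @export
generate_cognitive_scores <- function(n, means, sds, corr, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("n must be >= 1")
  .with_seed(seed, pmax(.mvn_scores(n, means, sds, corr), 0))
}

# shifted lognormal with target mean/sd, truncated to the analysis window
.rlatency <- function(n, mean, sd, shift = 80, window = c(80, 900)) {
  stopifnot(mean > shift, sd > 0)
  m <- mean - shift
  s2 <- log(1 + (sd / m)^2)
  mu <- log(m) - s2 / 2
  out <- shift + stats::rlnorm(n, mu, sqrt(s2))
  bad <- which(out <= window[1] | out >= window[2])
  while (length(bad)) {
    out[bad] <- shift + stats::rlnorm(length(bad), mu, sqrt(s2))
    bad <- bad[out[bad] <= window[1] | out[bad] >= window[2]]
  }
  out
}

# logit-normal accuracy draw matched to median and quartiles
.raccuracy <- function(n, q) {
  mu <- stats::qlogis(q[["median"]])
  sigma <- (stats::qlogis(q[["q3"]]) - stats::qlogis(q[["q1"]])) /
    (2 * stats::qnorm(0.75))
  stats::plogis(stats::rnorm(n, mu, max(sigma, 0)))
}

#' Generate per-trial outcome labels and latencies
#'
#' Each antisaccade trial is labelled `correct` with probability
#' `subject_accuracy` and `error` (a reflexive saccade toward the stimulus)
#' otherwise, with a small probability `miss_prob` of omitting the response
#' entirely. Go trials are `correct` (saccade to the stimulus) or `miss`
#' (gaze maintained, counted as incorrect); NoGo trials are `correct` (gaze
#' maintained) or `error` (reflexive saccade toward the stimulus). Latencies
#' come from the shifted-lognormal distributions in `latency_params`; error
#' latencies have a lower mean than correct ones.
#'
#' @param design Trial design from [generate_task_design()].
#' @param subject_accuracy Probability of a correct response; a single value
#'   or a vector named `AS`, `Go`, `NoGo`.
#' @param latency_params One group's entry of [default_latency_params()].
#' @param seed Optional integer seed.
#' @param miss_prob Probability of a missed response on AS trials.
#' @return The design with added columns `outcome`
#'   (`correct`/`error`/`miss`), `latency_ms` (`NA` when no saccade) and
#'   `target_x_deg`, `target_y_deg` (saccade goal, `NA` when none).
#' @export
generate_trial_outcomes <- function(design, subject_accuracy,
                                    latency_params = default_latency_params()$patient,
                                    seed = NULL, miss_prob = 0.02) {
  if (any(subject_accuracy < 0) || any(subject_accuracy > 1)) {
    stop("subject_accuracy must lie in [0, 1]")
  }
  acc_for <- function(key) {
    if (length(subject_accuracy) == 1) subject_accuracy
    else if (key %in% names(subject_accuracy)) unname(subject_accuracy[[key]])
    else stop("subject_accuracy missing entry for ", key)
  }
  lp <- latency_params
  .with_seed(seed, {
    n <- nrow(design)
    outcome <- character(n)
    latency <- rep(NA_real_, n)
    tx <- rep(NA_real_, n); ty <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (design$task[i] == "AS") {
        if (stats::runif(1) < miss_prob) {
          outcome[i] <- "miss"
        } else if (stats::runif(1) < acc_for("AS")) {
          outcome[i] <- "correct"
          latency[i] <- .rlatency(1, lp$as_correct[["mean"]],
                                  lp$as_correct[["sd"]], lp$shift)
          tx[i] <- -design$ps_x_deg[i]; ty[i] <- -design$ps_y_deg[i]
        } else {
          outcome[i] <- "error"
          latency[i] <- .rlatency(1, lp$as_error[["mean"]],
                                  lp$as_error[["sd"]], lp$shift)
          tx[i] <- design$ps_x_deg[i]; ty[i] <- design$ps_y_deg[i]
        }
      } else if (design$condition[i] == "Go") {
        if (stats::runif(1) < acc_for("Go")) {
          outcome[i] <- "correct"
          latency[i] <- .rlatency(1, lp$go_correct[["mean"]],
                                  lp$go_correct[["sd"]], lp$shift)
          tx[i] <- design$ps_x_deg[i]; ty[i] <- design$ps_y_deg[i]
        } else {
          outcome[i] <- "miss"
        }
      } else { # NoGo
        if (stats::runif(1) < acc_for("NoGo")) {
          outcome[i] <- "correct"
        } else {
          outcome[i] <- "error"
          latency[i] <- .rlatency(1, lp$nogo_error[["mean"]],
                                  lp$nogo_error[["sd"]], lp$shift)
          tx[i] <- design$ps_x_deg[i]; ty[i] <- design$ps_y_deg[i]
        }
      }
    }
    out <- design
    out$outcome <- outcome
    out$latency_ms <- latency
    out$target_x_deg <- tx
    out$target_y_deg <- ty
    out
  })
}

#' Synthesize a gaze-sample stream for one trial
#'
#' Produces a 250 Hz (configurable) sample stream: Gaussian fixation noise
#' around the central fixation point during the fixation interval, then - if
#' the embedded outcome includes a saccade - a smooth raised-cosine
#' displacement of the commanded amplitude starting at stimulus onset plus
#' the embedded latency. Saccade duration follows a main-sequence
#' approximation (2.2 ms/deg x amplitude + 21 ms).
#'
#' @param trial One row of a trial design (with `ps_onset_ms`).
#' @param outcome The matching row of [generate_trial_outcomes()] output
#'   (needs `latency_ms`, `target_x_deg`, `target_y_deg`); defaults to
#'   `trial` itself when the columns are merged.
#' @param sampling_rate Samples per second (> 0).
#' @param noise_sd Per-sample positional noise SD in degrees.
#' @param seed Optional integer seed.
#' @param post_ms Recording time after stimulus onset (default 1500 ms).
#' @return A data frame with columns `t_ms`, `x_deg`, `y_deg`, `valid`, with
#'   attributes `sampling_rate`, `ps_onset_ms` and `truth` (the embedded
#'   outcome label and latency).
#' @export
generate_gaze_trace <- function(trial, outcome = trial, sampling_rate = 250,
                                noise_sd = 0.15, seed = NULL, post_ms = 1500) {
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  dt <- 1000 / sampling_rate
  onset <- trial$ps_onset_ms
  .with_seed(seed, {
    t <- seq(0, onset + post_ms, by = dt)
    n <- length(t)
    x <- stats::rnorm(n, 0, noise_sd)
    y <- stats::rnorm(n, 0, noise_sd)
    has_saccade <- !is.na(outcome$latency_ms) && !is.na(outcome$target_x_deg)
    if (has_saccade) {
      amp <- sqrt(outcome$target_x_deg^2 + outcome$target_y_deg^2)
      dur <- 2.2 * amp + 21
      t0 <- onset + outcome$latency_ms
      phase <- pmin(pmax((t - t0) / dur, 0), 1)
      prof <- (1 - cos(pi * phase)) / 2
      x <- x + outcome$target_x_deg * prof
      y <- y + outcome$target_y_deg * prof
    }
    out <- data.frame(t_ms = t, x_deg = x, y_deg = y, valid = TRUE)
    attr(out, "sampling_rate") <- sampling_rate
    attr(out, "ps_onset_ms") <- onset
    attr(out, "truth") <- list(outcome = outcome$outcome %||% NA_character_,
                               latency_ms = outcome$latency_ms %||% NA_real_)
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full synthetic cohort
#'
#' At `level = "measures"` each subject's 12 network measures (6 cognitive +
#' 6 oculomotor) are drawn directly from a per-group multivariate normal
#' with the configured moments and the target correlation matrix; cognitive
#' scores are clipped at 0 and error proportions to \[0, 1\]. At
#' `level = "gaze"` each subject additionally receives full antisaccade and
#' Go/NoGo trial designs, embedded trial outcomes and raw gaze traces -
#' substantially heavier, intended for modest cohort sizes.
#'
#' @param config A [simulation_config()].
#' @param level `"measures"` or `"gaze"`.
#' @return For `"measures"`: a data frame `subject_id`, `group`, then the 12
#'   measures. For `"gaze"`: a list with `subjects`, `cognitive`, `trials`
#'   (designs + embedded outcomes) and `gaze` (long sample table).
#' @export
simulate_cohort <- function(config = simulation_config(),
                            level = c("measures", "gaze")) {
  level <- match.arg(level)
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    if (level == "measures") {
      groups <- list(patient = config$n_patients, control = config$n_controls)
      rows <- lapply(names(groups), function(g) {
        n <- groups[[g]]
        means <- c(config$cognitive_params[[g]]$means,
                   config$oculomotor_params[[g]]$means)
        sds <- c(config$cognitive_params[[g]]$sds,
                 config$oculomotor_params[[g]]$sds)
        x <- .mvn_scores(n, means, sds, config$target_correlation)
        x[, 1:6] <- pmax(x[, 1:6], 0)                      # scores >= 0
        x[, c("ASEs", "GnGEs")] <- pmin(pmax(x[, c("ASEs", "GnGEs")], 0), 1)
        x[, c("ASLs", "ASELs", "GnGLs", "GnGELs")] <-
          pmax(x[, c("ASLs", "ASELs", "GnGLs", "GnGELs")], 80)
        data.frame(subject_id = paste0(substr(g, 1, 1), sprintf("%03d", seq_len(n))),
                   group = g, x, stringsAsFactors = FALSE, check.names = FALSE)
      })
      return(do.call(rbind, c(rows, list(make.row.names = FALSE))))
    }
    # gaze level
    subjects <- data.frame(
      subject_id = c(paste0("p", sprintf("%03d", seq_len(config$n_patients))),
                     paste0("c", sprintf("%03d", seq_len(config$n_controls)))),
      group = rep(c("patient", "control"),
                  c(config$n_patients, config$n_controls)),
      stringsAsFactors = FALSE)
    n_all <- nrow(subjects)
    subjects$as_accuracy <- NA_real_
    subjects$go_accuracy <- NA_real_
    subjects$nogo_accuracy <- NA_real_
    cog_rows <- vector("list", n_all)
    trial_rows <- vector("list", n_all)
    gaze_rows <- vector("list", n_all)
    for (i in seq_len(n_all)) {
      g <- subjects$group[i]
      ap <- config$accuracy_params[[g]]
      acc <- c(AS = .raccuracy(1, ap$as), Go = .raccuracy(1, ap$go),
               NoGo = .raccuracy(1, ap$nogo))
      subjects$as_accuracy[i] <- acc[["AS"]]
      subjects$go_accuracy[i] <- acc[["Go"]]
      subjects$nogo_accuracy[i] <- acc[["NoGo"]]
      cp <- config$cognitive_params[[g]]
      cog <- generate_cognitive_scores(1, cp$means, cp$sds,
                                       config$target_correlation[1:6, 1:6])
      cog_rows[[i]] <- data.frame(subject_id = subjects$subject_id[i],
                                  cog, stringsAsFactors = FALSE,
                                  check.names = FALSE)
      per_task <- lapply(c("AS", "GnG"), function(task) {
        design <- generate_task_design(task)
        out <- generate_trial_outcomes(design, acc,
                                       config$latency_params[[g]],
                                       miss_prob = config$miss_prob)
        traces <- lapply(seq_len(nrow(out)), function(k) {
          tr <- generate_gaze_trace(out[k, ],
                                    sampling_rate = config$sampling_rate,
                                    noise_sd = config$noise_sd)
          data.frame(subject_id = subjects$subject_id[i],
                     trial_id = out$trial_id[k], task = task,
                     tr, stringsAsFactors = FALSE)
        })
        out$subject_id <- subjects$subject_id[i]
        list(trials = out, gaze = do.call(rbind, traces))
      })
      trial_rows[[i]] <- do.call(rbind, lapply(per_task, `[[`, "trials"))
      gaze_rows[[i]] <- do.call(rbind, lapply(per_task, `[[`, "gaze"))
    }
    list(subjects = subjects,
         cognitive = do.call(rbind, cog_rows),
         trials = do.call(rbind, trial_rows),
         gaze = do.call(rbind, gaze_rows))
  })
}
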