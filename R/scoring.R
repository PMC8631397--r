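# Trial classification for the antisaccade and Go/NoGo paradigms, the
# saccade-latency filter, and per-subject summary measures.

#' Select the primary saccade of a trial
#'
#' The first detected saccade with onset at or after stimulus onset and
#' amplitude at least `min_amplitude_deg`. Returns `NULL` when no saccade
#' qualifies (a valid outcome: the trial is a miss or a correctly withheld
#' response).
#'
#' @param events Event table from [detect_events()] (time-ordered).
#' @param ps_onset_ms Peripheral-stimulus onset time.
#' @param min_amplitude_deg Minimum amplitude to count as a response
#'   (default 2).
#' @return One-row data frame (the saccade event) or `NULL`.
#' @export
primary_saccade <- function(events, ps_onset_ms, min_amplitude_deg = 2) {
  if (is.null(events) || nrow(events) == 0) return(NULL)
  sel <- events$kind == "saccade" &
    events$onset_ms >= ps_onset_ms &
    events$amplitude_deg >= min_amplitude_deg
  if (!any(sel)) return(NULL)
  events[which(sel)[1], , drop = FALSE]
}

.trial_score <- function(trial, classification, latency = NA_real_,
                         reason = "none", saccade = NULL) {
  data.frame(trial_id = trial$trial_id, task = trial$task,
             condition = trial$condition, classification = classification,
             latency_ms = latency, discard_reason = reason,
             saccade_onset_ms = if (is.null(saccade)) NA_real_ else saccade$onset_ms,
             saccade_amplitude_deg = if (is.null(saccade)) NA_real_ else saccade$amplitude_deg,
             stringsAsFactors = FALSE)
}

.apply_latency_filter <- function(latency, window) {
  if (latency < window[1]) return("latency_low")
  if (latency > window[2]) return("latency_high")
  "none"
}

#' Score one antisaccade trial
#'
#' The primary saccade's latency (onset minus stimulus onset) is filtered to
#' the analysis window; out-of-window trials are discarded regardless of
#' direction. A surviving saccade directed opposite the stimulus (by the
#' sign of its horizontal displacement) is correct; a saccade toward the
#' stimulus is a reflexive antisaccade error. With no qualifying saccade the
#' trial is a miss.
#'
#' @param trial One row of an AS trial design (needs `task`, `condition`,
#'   `trial_id`, `ps_x_deg`, `ps_onset_ms`).
#' @param events Event table for the trial.
#' @param latency_window Inclusive latency bounds in ms (default
#'   `c(80, 900)`).
#' @param min_amplitude_deg Passed to [primary_saccade()].
#' @return One-row data frame: `trial_id`, `task`, `condition`,
#'   `classification` (`correct`/`error`/`miss`/`discarded`), `latency_ms`,
#'   `discard_reason`, `saccade_onset_ms`, `saccade_amplitude_deg`.
#' @export
score_antisaccade_trial <- function(trial, events, latency_window = c(80, 900),
                                    min_amplitude_deg = 2) {
  if (trial$task != "AS") stop("score_antisaccade_trial requires an AS trial")
  ps <- primary_saccade(events, trial$ps_onset_ms, min_amplitude_deg)
  if (is.null(ps)) return(.trial_score(trial, "miss"))
  latency <- ps$onset_ms - trial$ps_onset_ms
  reason <- .apply_latency_filter(latency, latency_window)
  if (reason != "none") {
    return(.trial_score(trial, "discarded", latency, reason, ps))
  }
  dir <- sign(ps$end_x_deg - ps$start_x_deg)
  cls <- if (dir != 0 && dir == -sign(trial$ps_x_deg)) "correct" else "error"
  .trial_score(trial, cls, latency, "none", ps)
}

# absolute angular difference between a saccade's direction and the
# direction from its start toward the stimulus, in degrees
.direction_error_deg <- function(saccade, ps_x, ps_y) {
  sacc_ang <- atan2(saccade$end_y_deg - saccade$start_y_deg,
                    saccade$end_x_deg - saccade$start_x_deg)
  targ_ang <- atan2(ps_y - saccade$start_y_deg, ps_x - saccade$start_x_deg)
  d <- abs(sacc_ang - targ_ang) %% (2 * pi)
  min(d, 2 * pi - d) * 180 / pi
}

#' Score one Go/NoGo trial
#'
#' Go: a latency-filtered primary saccade whose direction matches the
#' stimulus within `direction_tolerance_deg` is correct; a saccade elsewhere
#' is an error; no saccade is a miss (counted as incorrect in Go
#' performance accuracy). NoGo: no qualifying saccade is correct; a
#' saccade toward the stimulus is a reflexive error whose latency is
#' recorded as an error latency.
#'
#' @inheritParams score_antisaccade_trial
#' @param direction_tolerance_deg Angular tolerance for "toward the
#'   stimulus" (default 22.5, half the 45-degree spacing of the 8-location
#'   diamond).
#' @return One-row score data frame (see [score_antisaccade_trial()]).
#' @export
score_gonogo_trial <- function(trial, events, latency_window = c(80, 900),
                               min_amplitude_deg = 2,
                               direction_tolerance_deg = 22.5) {
  if (trial$task != "GnG") stop("score_gonogo_trial requires a GnG trial")
  ps <- primary_saccade(events, trial$ps_onset_ms, min_amplitude_deg)
  go <- trial$condition == "Go"
  if (is.null(ps)) {
    return(.trial_score(trial, if (go) "miss" else "correct"))
  }
  latency <- ps$onset_ms - trial$ps_onset_ms
  reason <- .apply_latency_filter(latency, latency_window)
  if (reason != "none") {
    return(.trial_score(trial, "discarded", latency, reason, ps))
  }
  toward <- .direction_error_deg(ps, trial$ps_x_deg, trial$ps_y_deg) <=
    direction_tolerance_deg
  cls <- if (go) {
    if (toward) "correct" else "error"
  } else {
    "error"  # fixation broken on a NoGo trial
  }
  .trial_score(trial, cls, latency, "none", ps)
}

#' Score one trial, dispatching on task
#' @inheritParams score_gonogo_trial
#' @export
score_trial <- function(trial, events, latency_window = c(80, 900),
                        min_amplitude_deg = 2, direction_tolerance_deg = 22.5) {
  if (trial$task == "AS") {
    score_antisaccade_trial(trial, events, latency_window, min_amplitude_deg)
  } else if (trial$task == "GnG") {
    score_gonogo_trial(trial, events, latency_window, min_amplitude_deg,
                       direction_tolerance_deg)
  } else {
    stop("unknown task: ", trial$task)
  }
}

#' Performance accuracy over a set of trial scores
#'
#' Correct responses divided by the number of counted trials. By default
#' latency-discarded trials are excluded from both numerator and
#' denominator, so the measure reflects decision quality among analysable
#' trials; `denominator = "all"` includes them.
#'
#' @param scores Data frame of trial scores (needs `classification`).
#' @param denominator `"counted"` (default) or `"all"`.
#' @return A proportion in \[0, 1\].
#' @export
performance_accuracy <- function(scores, denominator = c("counted", "all")) {
  denominator <- match.arg(denominator)
  total <- if (denominator == "all") nrow(scores)
           else sum(scores$classification != "discarded")
  if (total == 0) stop("no countable trials")
  sum(scores$classification == "correct") / total
}

#' Per-subject oculomotor summary measures
#'
#' Computes the six network measures and task performance accuracies from a
#' subject's full set of trial scores: AS performance accuracy, median and
#' mean correct-AS latency (ASLs), median AS error latency (ASELs, `NA`
#' when the subject made no AS errors), AS error proportion (ASEs), Go and
#' NoGo performance accuracies, median correct-Go latency (GnGLs), median
#' NoGo error latency (GnGELs) and NoGo error proportion (GnGEs). Medians
#' are computed over non-discarded trials only.
#'
#' @param scores Data frame of trial scores for one subject (AS and GnG).
#' @param subject_id,group Identifiers carried into the output.
#' @param denominator Performance-accuracy denominator convention, see
#'   [performance_accuracy()].
#' @return One-row data frame of summary measures.
#' @export
summarize_subject <- function(scores, subject_id = NA_character_,
                              group = NA_character_,
                              denominator = c("counted", "all")) {
  denominator <- match.arg(denominator)
  if (nrow(scores) == 0 || all(scores$classification == "discarded")) {
    stop("no scorable trials for subject ", subject_id)
  }
  as_sc <- scores[scores$task == "AS", , drop = FALSE]
  go_sc <- scores[scores$task == "GnG" & scores$condition == "Go", , drop = FALSE]
  ng_sc <- scores[scores$task == "GnG" & scores$condition == "NoGo", , drop = FALSE]
  counted <- function(df) df[df$classification != "discarded", , drop = FALSE]
  lat_of <- function(df, cls) {
    v <- df$latency_ms[df$classification == cls]
    v[!is.na(v)]
  }
  pa <- function(df) {
    if (nrow(df) == 0) return(NA_real_)
    tryCatch(performance_accuracy(df, denominator), error = function(e) NA_real_)
  }
  med <- function(v) if (length(v)) stats::median(v) else NA_real_
  prop_err <- function(df) {
    cc <- counted(df)
    if (nrow(cc) == 0) return(NA_real_)
    sum(cc$classification == "error") / nrow(cc)
  }
  as_correct <- lat_of(counted(as_sc), "correct")
  data.frame(
    subject_id = subject_id, group = group,
    as_pa = pa(as_sc),
    asl_median_ms = med(as_correct),
    asl_mean_ms = if (length(as_correct)) mean(as_correct) else NA_real_,
    asel_median_ms = med(lat_of(counted(as_sc), "error")),
    ase_proportion = prop_err(as_sc),
    go_pa = pa(go_sc),
    nogo_pa = pa(ng_sc),
    gngl_median_ms = med(lat_of(counted(go_sc), "correct")),
    gngel_median_ms = med(lat_of(counted(ng_sc), "error")),
    gnge_proportion = prop_err(ng_sc),
    stringsAsFactors = FALSE)
}

#' Map subject summaries to the six oculomotor network measures
#'
#' @param summaries Data frame of rows from [summarize_subject()].
#' @return Data frame `subject_id`, `group`, `ASLs`, `ASELs`, `ASEs`,
#'   `GnGLs`, `GnGELs`, `GnGEs`.
#' @export
oculomotor_measures <- function(summaries) {
  data.frame(subject_id = summaries$subject_id, group = summaries$group,
             ASLs = summaries$asl_median_ms,
             ASELs = summaries$asel_median_ms,
             ASEs = summaries$ase_proportion,
             GnGLs = summaries$gngl_median_ms,
             GnGELs = summaries$gngel_median_ms,
             GnGEs = summaries$gnge_proportion,
             stringsAsFactors = FALSE)
}
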