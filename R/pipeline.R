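# End-to-end orchestration: simulate -> detect -> score -> stats -> network
# -> report, as one reproducible run driven by a single config and seed.

#' Assemble a pipeline run configuration
#'
#' Exactly one input source must be given: a `simulation` block (arguments
#' for [simulation_config()]) for a synthetic cohort, or `tables_dir`, a
#' directory of published-correlation-table fixtures, for a network-only
#' run.
#'
#' @param simulation Named list of [simulation_config()] arguments, or
#'   `NULL`.
#' @param tables_dir Directory with the three fixture CSVs, or `NULL`.
#' @param seed Integer master seed.
#' @param detection Named list of [detection_params()] arguments.
#' @param scoring Named list: `latency_window`, `min_amplitude_deg`,
#'   `direction_tolerance_deg`, `denominator`.
#' @param stats Named list: `alpha`, `pooled`, plus [influence_cutoffs()]
#'   arguments.
#' @param network Named list: `tau`, `alpha`, `group`.
#' @param output_dir Artifact directory (`NULL`: no files written).
#' @return A validated `run_config` list.
#' @export
run_config <- function(simulation = NULL, tables_dir = NULL, seed = 1,
                       detection = list(), scoring = list(),
                       stats = list(), network = list(),
                       output_dir = NULL) {
  if (is.null(simulation) == is.null(tables_dir)) {
    stop("exactly one of 'simulation' or 'tables_dir' must be given")
  }
  if (!is.null(tables_dir) && !dir.exists(tables_dir)) {
    stop("tables_dir does not exist: ", tables_dir)
  }
  scoring <- utils::modifyList(list(latency_window = c(80, 900),
                                    min_amplitude_deg = 2,
                                    direction_tolerance_deg = 22.5,
                                    denominator = "counted"), scoring)
  stats <- utils::modifyList(list(alpha = 0.05, pooled = TRUE), stats)
  network <- utils::modifyList(list(tau = 0.4, alpha = 0.05,
                                    group = "patient"), network)
  structure(list(simulation = simulation, tables_dir = tables_dir,
                 seed = as.integer(seed), detection = detection,
                 scoring = scoring, stats = stats, network = network,
                 output_dir = output_dir),
            class = "run_config")
}

#' Read / write a run configuration as JSON
#' @param path JSON file path.
#' @return [read_run_config()]: a `run_config`; [write_run_config()]:
#'   `path`, invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# FNV-1a hash of the canonical JSON encoding of the config
.config_hash <- function(config) {
  txt <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                          null = "null")
  bytes <- utf8ToInt(as.character(txt))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

#' Detect events for every trial of a cohort gaze table
#'
#' @param gaze Long gaze table (`subject_id`, `trial_id`, `task`, `t_ms`,
#'   `x_deg`, `y_deg`, `valid`).
#' @param params A [detection_params()].
#' @return Long event table with `subject_id`, `trial_id`, `task` prepended.
#' @export
detect_cohort_events <- function(gaze, params = detection_params()) {
  key <- interaction(gaze$subject_id, gaze$task, gaze$trial_id, drop = TRUE)
  parts <- split(gaze, key)
  out <- lapply(parts, function(g) {
    ev <- detect_events(g[, c("t_ms", "x_deg", "y_deg", "valid")], params)
    if (nrow(ev) == 0) return(NULL)
    data.frame(subject_id = g$subject_id[1], trial_id = g$trial_id[1],
               task = g$task[1], ev, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Score every trial of a cohort from detected events
#'
#' @param trials Trial design table (per subject, with `ps_onset_ms` etc.).
#' @param events Output of [detect_cohort_events()].
#' @param scoring Scoring parameter list (see [run_config()]).
#' @return Data frame of trial scores with `subject_id` prepended.
#' @export
score_cohort_trials <- function(trials, events,
                                scoring = list(latency_window = c(80, 900),
                                               min_amplitude_deg = 2,
                                               direction_tolerance_deg = 22.5)) {
  rows <- lapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    ev <- events[events$subject_id == tr$subject_id &
                 events$task == tr$task &
                 events$trial_id == tr$trial_id, , drop = FALSE]
    sc <- score_trial(tr, ev, scoring$latency_window,
                      scoring$min_amplitude_deg,
                      scoring$direction_tolerance_deg)
    sc$subject_id <- tr$subject_id
    sc
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group-level statistics with influence-based subject exclusion
#'
#' Within each group, the latency-accuracy regression
#' (`asl_median_ms ~ as_pa`) is screened with [regression_influence()];
#' flagged subjects are excluded before the performance-accuracy /
#' latency-median Pearson correlations, mirroring the analysis order of the
#' source design. Between groups, correct-antisaccade latency medians are
#' compared by Student's t and the variance F-test, and by Kruskal-Wallis
#' across groups.
#'
#' @param summaries Subject summary table ([summarize_subject()] rows with
#'   `subject_id`, `group`).
#' @param stats_params List with `alpha`, `pooled` and optional
#'   [influence_cutoffs()] overrides.
#' @return List with `excluded` (subject ids and triggering criteria),
#'   `correlations`, `group_tests`.
#' @export
cohort_statistics <- function(summaries, stats_params = list(alpha = 0.05,
                                                             pooled = TRUE)) {
  cut_args <- stats_params[intersect(names(stats_params),
                                     names(formals(influence_cutoffs)))]
  cuts <- do.call(influence_cutoffs, cut_args)
  excluded <- list()
  correlations <- list()
  for (g in unique(summaries$group)) {
    sub <- summaries[summaries$group == g, , drop = FALSE]
    ok <- stats::complete.cases(sub[, c("as_pa", "asl_median_ms")])
    sub <- sub[ok, , drop = FALSE]
    if (nrow(sub) >= 4 && stats::var(sub$as_pa) > 0) {
      rep_ <- regression_influence(sub$as_pa, sub$asl_median_ms, cuts)
      flag <- which(rep_$flagged)
      if (length(flag)) {
        excluded[[g]] <- data.frame(subject_id = sub$subject_id[flag],
                                    group = g,
                                    criteria = rep_$criteria[flag],
                                    stringsAsFactors = FALSE)
      }
      kept <- sub[setdiff(seq_len(nrow(sub)), flag), , drop = FALSE]
      if (nrow(kept) >= 3 && stats::var(kept$as_pa) > 0 &&
          stats::var(kept$asl_median_ms) > 0) {
        correlations[[paste0(g, "_as_pa_vs_asl")]] <-
          pearson(kept$as_pa, kept$asl_median_ms)
      }
      if (all(c("go_pa", "gngl_median_ms") %in% names(kept))) {
        ok2 <- stats::complete.cases(kept[, c("go_pa", "gngl_median_ms")])
        k2 <- kept[ok2, , drop = FALSE]
        if (nrow(k2) >= 3 && stats::var(k2$go_pa) > 0 &&
            stats::var(k2$gngl_median_ms) > 0) {
          correlations[[paste0(g, "_go_pa_vs_gngl")]] <-
            pearson(k2$go_pa, k2$gngl_median_ms)
        }
      }
    }
  }
  groups <- split(summaries$asl_median_ms[!is.na(summaries$asl_median_ms)],
                  summaries$group[!is.na(summaries$asl_median_ms)])
  group_tests <- list()
  if (length(groups) >= 2 && all(lengths(groups) >= 2)) {
    a <- groups[[1]]; b <- groups[[2]]
    group_tests$asl_t <- students_t(a, b,
                                    pooled = isTRUE(stats_params$pooled))
    if (stats::var(a) > 0 && stats::var(b) > 0) {
      group_tests$asl_f <- variance_f_test(a, b)
    }
    group_tests$asl_kw <- kruskal_wallis(groups)
  }
  list(excluded = if (length(excluded))
         do.call(rbind, c(excluded, list(make.row.names = FALSE))) else NULL,
       correlations = correlations, group_tests = group_tests)
}

.test_to_list <- function(t) {
  list(method = t$method, statistic = t$statistic, df = t$df,
       p_value = t$p_value, n = t$n, estimate = t$estimate)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order - simulate, detect, score,
#' statistics, network, report - writing each stage's artifact to
#' `output_dir` when given. A fixture-table configuration runs the network
#' stage only. The report is a plain list, regenerable bit-identically from
#' the same config and seed (it carries no timestamps).
#'
#' @param config A [run_config()].
#' @return A `run_report` list: per-stage record counts, exclusion lists,
#'   statistics, network summaries, package version, config echo and hash,
#'   seed.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  emit <- function(df, name) {
    if (!is.null(out_dir) && !is.null(df)) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
  }
  report <- list(package = "oculonet",
                 version = as.character(utils::packageVersion("oculonet")),
                 seed = config$seed,
                 config_hash = .config_hash(config),
                 config = unclass(config),
                 stages = list())

  net_param <- config$network
  if (!is.null(config$tables_dir)) {
    tabs <- load_correlation_tables(config$tables_dir)
    corr <- combine_correlation_tables(tabs)
    report$stages$input <- list(source = "fixture_tables",
                                pairs = nrow(corr))
  } else {
    sim_args <- config$simulation
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    sim_cfg <- do.call(simulation_config, sim_args)
    cohort <- simulate_cohort(sim_cfg, level = "gaze")
    emit(cohort$gaze, "gaze.csv")
    emit(cohort$trials, "trials.csv")
    emit(cohort$cognitive, "cognitive_scores.csv")
    report$stages$simulate <- list(
      n_subjects = nrow(cohort$subjects),
      n_trials = nrow(cohort$trials),
      n_samples = nrow(cohort$gaze))

    det <- do.call(detection_params, config$detection)
    events <- detect_cohort_events(cohort$gaze, det)
    emit(events, "events.csv")
    report$stages$detect <- list(
      n_events = nrow(events),
      n_saccades = sum(events$kind == "saccade"))

    scores <- score_cohort_trials(cohort$trials, events, config$scoring)
    emit(scores, "trial_scores.csv")
    grp <- stats::setNames(cohort$subjects$group, cohort$subjects$subject_id)
    summaries <- do.call(rbind, lapply(split(scores, scores$subject_id),
      function(s) summarize_subject(s, s$subject_id[1],
                                    unname(grp[s$subject_id[1]]),
                                    config$scoring$denominator)))
    rownames(summaries) <- NULL
    emit(summaries, "subject_summaries.csv")
    report$stages$score <- list(
      n_trials_scored = nrow(scores),
      n_discarded_latency = sum(scores$classification == "discarded"),
      classification_counts = as.list(table(scores$classification)))

    st <- cohort_statistics(summaries, config$stats)
    emit(st$excluded, "excluded_subjects.csv")
    report$stages$stats <- list(
      excluded = if (is.null(st$excluded)) list()
                 else split(st$excluded$criteria, st$excluded$subject_id),
      correlations = lapply(st$correlations, .test_to_list),
      group_tests = lapply(st$group_tests, .test_to_list))

    keep_grp <- summaries$group == net_param$group
    if (!is.null(st$excluded)) {
      keep_grp <- keep_grp & !(summaries$subject_id %in% st$excluded$subject_id)
    }
    oc <- oculomotor_measures(summaries[keep_grp, , drop = FALSE])
    cg <- cohort$cognitive[match(oc$subject_id, cohort$cognitive$subject_id),
                           , drop = FALSE]
    mt <- measure_table(cbind(cg[, setdiff(names(cg), "subject_id")],
                              oc[, setdiff(names(oc), c("subject_id", "group"))],
                              stringsAsFactors = FALSE))
    corr <- suppressWarnings(correlation_table(mt))
    report$stages$input <- list(source = "simulation",
                                group = net_param$group,
                                n_subjects_in_network = nrow(oc))
  }
  emit(as.data.frame(corr), "correlation_table.csv")

  full <- build_full_network(corr, net_param$alpha)
  thr <- build_thresholded_network(corr, net_param$tau)
  if (!is.null(out_dir)) {
    export_network(full, file.path(out_dir, "network_full.graphml"), "graphml")
    export_network(thr, file.path(out_dir, "network_thresholded.graphml"),
                   "graphml")
    export_network(thr, file.path(out_dir, "network_thresholded.edgelist.tsv"),
                   "edgelist")
  }
  centrality <- data.frame(node = full$nodes$name, domain = full$nodes$domain,
                           degree_full = node_degree(full),
                           cross_domain_degree_full = cross_domain_degree(full),
                           degree_thresholded = node_degree(thr),
                           cross_domain_degree_thresholded = cross_domain_degree(thr),
                           stringsAsFactors = FALSE)
  rownames(centrality) <- NULL
  emit(centrality, "centrality.csv")
  report$stages$network <- list(
    full_edges = nrow(full$edges),
    thresholded_edges = nrow(thr$edges),
    central_full = if (nrow(full$edges)) central_nodes(full) else character(0),
    central_thresholded = if (nrow(thr$edges)) central_nodes(thr)
                          else character(0),
    centrality = centrality)
  class(report) <- "run_report"
  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", force = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("oculonet run report (version %s, seed %d, config %s)\n",
              x$version, x$seed, x$config_hash))
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    scalars <- st[vapply(st, function(v) is.atomic(v) && length(v) == 1,
                         logical(1))]
    cat(sprintf("  %s: %s\n", nm,
                paste(names(scalars), unlist(scalars), sep = "=",
                      collapse = ", ")))
  }
  invisible(x)
}
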