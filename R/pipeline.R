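# Cohort-level orchestration: simulate -> events -> photometry -> tracking
# over a (mice x phases x days x tests) layout, with a manifest and tidy
# report tables.

#' Simulate one complete session (behavior + photometry + pose)
#'
#' Thin wrapper chaining [run_task_state_machine()],
#' [generate_photometry()] and optionally [generate_pose_track()].
#'
#' @param task,agent,photo Configurations for the three generators.
#' @param day,test_index Session coordinates.
#' @param mouse Mouse identifier.
#' @param with_pose Also generate a pose track?
#' @return List with `log`, `truth`, `recording`, and optionally `pose`.
#' @export
simulate_session <- function(task, agent, photo = photometry_config(),
                             day = 1L, test_index = 1L, mouse = "m01",
                             with_pose = FALSE) {
  sim <- run_task_state_machine(task, agent, day, test_index, mouse)
  ph <- generate_photometry(sim$log, sim$truth, photo)
  out <- list(log = sim$log, truth = ph$truth, recording = ph$recording)
  if (with_pose)
    out$pose <- generate_pose_track(sim$log, task, agent)
  out
}

#' Build a validated run configuration
#'
#' @param mice Character vector of mouse ids (or an integer count).
#' @param phases Phases to run, subset of `c("I","II","III")`.
#' @param seed Master seed; per-mouse agent/photometry streams derive from
#'   it.
#' @param task_args,agent_args,photo_args Named lists of overrides passed
#'   to [task_config()], [agent_config()], [photometry_config()].
#' @param days Optional override of training days (applied to every phase).
#' @param with_pose Generate pose tracks as well?
#' @param dff_window_s,threshold_sd,association_window_s Photometry
#'   analysis parameters.
#' @return A `run_config` list.
#' @export
run_config <- function(mice = 2L, phases = c("I", "II", "III"), seed = 1L,
                       task_args = list(), agent_args = list(),
                       photo_args = list(), days = NULL,
                       with_pose = FALSE, dff_window_s = 30,
                       threshold_sd = 2, association_window_s = 2) {
  if (is.numeric(mice)) mice <- sprintf("m%02d", seq_len(mice))
  phases <- match.arg(phases, several.ok = TRUE)
  known <- list(task_args = task_args, agent_args = agent_args,
                photo_args = photo_args)
  allowed <- list(task_args = names(formals(task_config)),
                  agent_args = names(formals(agent_config)),
                  photo_args = names(formals(photometry_config)))
  for (block in names(known)) {
    bad <- setdiff(names(known[[block]]), allowed[[block]])
    if (length(bad))
      stop("unknown ", block, " key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  structure(list(mice = mice, phases = phases, seed = as.integer(seed),
                 task_args = task_args, agent_args = agent_args,
                 photo_args = photo_args, days = days,
                 with_pose = isTRUE(with_pose),
                 dff_window_s = dff_window_s, threshold_sd = threshold_sd,
                 association_window_s = association_window_s),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are the arguments of
#'   [run_config()]. Unknown keys are an error naming the key.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), names(formals(run_config)))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(run_config, raw)
}

#' Run the full pipeline over a simulated cohort
#'
#' For every (mouse, phase, day, test): simulates the session, writes the
#' raw files, reads them back through the parsers, segments/classifies
#' trials, computes behavioral metrics, processes the photometry
#' (delta-F/F, isosbestic subtraction, peak detection, behavioral linking),
#' and accumulates report tables. Cohort-level outputs are written under
#' `out_dir/reports/` and a manifest (config snapshot, package version,
#' per-file checksums) under `out_dir/manifest.json`.
#'
#' @param config A [run_config()].
#' @param out_dir Output root directory.
#' @return Invisibly, a list with the report tables (`behavior_per_trial`,
#'   `behavior_per_test`, `behavior_summary`, `peaks`, `amplitude_by_day`,
#'   `qc`) and the manifest path.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  per_trial <- list(); peaks_all <- list(); qc <- list()
  files <- character(0)
  for (mi in seq_along(config$mice)) {
    mouse <- config$mice[mi]
    for (phase in config$phases) {
      task <- do.call(task_config, c(list(phase = phase), config$task_args,
                                     if (!is.null(config$days))
                                       list(days = config$days)))
      agent <- do.call(agent_config,
                       c(config$agent_args,
                         list(rng_seed = config$seed + 131 * mi)))
      photo <- do.call(photometry_config,
                       c(config$photo_args,
                         list(rng_seed = config$seed + 131 * mi + 17)))
      for (day in seq_len(task$days)) {
        for (test in seq_len(task$tests_per_day)) {
          ses <- simulate_session(task, agent, photo, day, test, mouse,
                                  with_pose = config$with_pose)
          sdir <- file.path(out_dir, mouse, paste0("phase", phase),
                            sprintf("day%02d_test%d", day, test))
          files <- c(files, write_session(ses$log, ses$recording, ses$pose,
                                          ses$truth, sdir))
          log <- read_event_log(file.path(sdir, "events.tsv"))
          rec <- read_photometry(file.path(sdir, "photometry.csv"))
          seg <- classify_trials(segment_trials(log, task))
          per_trial[[length(per_trial) + 1L]] <- compute_metrics(seg)
          trace <- process_recording(rec, window_s = config$dff_window_s)
          pk <- detect_peaks(trace, threshold_sd = config$threshold_sd)
          pk <- link_peaks_to_behavior(pk, behavior_anchor_events(seg),
                                       config$association_window_s)
          if (nrow(pk)) {
            pk$mouse <- mouse; pk$phase <- phase
            pk$day <- day; pk$test <- test
            peaks_all[[length(peaks_all) + 1L]] <- pk
          }
          masked_pct <- if (!is.null(ses$pose))
            100 * mean(ses$pose$data$likelihood < 0.6) else NA_real_
          qc[[length(qc) + 1L]] <- data.frame(
            mouse = mouse, phase = phase, day = day, test = test,
            n_trials = nrow(seg$trials), session_sd = trace$session_sd,
            n_peaks = nrow(pk), pct_masked_pose = masked_pct,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  behavior_per_trial <- do.call(rbind, per_trial)
  behavior_per_test <- summarize_tests(behavior_per_trial)
  behavior_summary <- aggregate_by_day(behavior_per_test)
  peaks <- if (length(peaks_all)) do.call(rbind, peaks_all) else
    data.frame()
  amplitude_by_day <- if (nrow(peaks)) peak_amplitude_by_day(peaks) else
    data.frame()
  qc <- do.call(rbind, qc)

  rep_dir <- file.path(out_dir, "reports")
  dir.create(rep_dir, showWarnings = FALSE)
  tables <- list(behavior_per_trial = behavior_per_trial,
                 behavior_per_test = behavior_per_test,
                 behavior_summary = behavior_summary,
                 peaks = peaks, amplitude_by_day = amplitude_by_day,
                 qc = qc)
  for (nm in names(tables)) {
    p <- file.path(rep_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    files <- c(files, p)
  }
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("photoperant")),
    seed = config$seed,
    config = unclass(config),
    files = data.frame(path = substring(files, nchar(out_dir) + 2L),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(tables, list(manifest_path = manifest_path)))
}

#' Summary figures from the report tables
#'
#' Behavior-by-day panels (per-mouse traces in grey, cohort mean in
#' colour), group-mean peri-event traces with SEM ribbons, and trial x time
#' heatmaps. Written as PDF files into `out_dir`.
#'
#' @param tables List returned by [run_pipeline()] (or the
#'   `behavior_per_test` table alone).
#' @param out_dir Directory for the figure files.
#' @param peri Optional output of [peri_event_group_means()] for the
#'   ribbon panel.
#' @param pem Optional `peri_event_matrix` for the heatmap panel.
#' @return Character vector of figure paths written (empty, with a
#'   warning, when the tables are empty).
#' @export
make_figures <- function(tables, out_dir, peri = NULL, pem = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  bt <- if (is.data.frame(tables)) tables else tables$behavior_per_test
  if (is.null(bt) || !nrow(bt)) {
    warning("empty behavior table; skipping behavior figure", call. = FALSE)
  } else {
    bt$timepoint <- bt$day + (bt$test - 1) / max(bt$test)
    for (metric in c("latency_first_lick_s", "pct_successful_trials")) {
      if (all(is.na(bt[[metric]]))) next
      coh <- stats::aggregate(bt[[metric]],
                              by = list(phase = bt$phase,
                                        timepoint = bt$timepoint),
                              FUN = mean, na.rm = TRUE)
      gg <- ggplot2::ggplot(bt, ggplot2::aes(x = .data$timepoint,
                                             y = .data[[metric]])) +
        ggplot2::geom_line(ggplot2::aes(group = .data$mouse),
                           colour = "grey60", linewidth = 0.3) +
        ggplot2::geom_line(data = coh,
                           ggplot2::aes(x = .data$timepoint, y = .data$x),
                           colour = "darkorange", linewidth = 1) +
        ggplot2::facet_wrap(~phase, scales = "free_x") +
        ggplot2::labs(x = "day (and test)", y = metric,
                      caption = "grey: individual mice; orange: cohort mean") +
        ggplot2::theme_minimal()
      p <- file.path(out_dir, paste0("behavior_", metric, ".pdf"))
      ggplot2::ggsave(p, gg, width = 8, height = 3.2)
      paths <- c(paths, p)
    }
  }
  if (!is.null(peri) && nrow(peri)) {
    gg <- ggplot2::ggplot(peri, ggplot2::aes(x = .data$time_s,
                                             y = .data$mean,
                                             colour = .data$outcome,
                                             fill = .data$outcome)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           alpha = 0.25, colour = NA) +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
      ggplot2::labs(x = "time from event (s)", y = "dF/F") +
      ggplot2::theme_minimal()
    p <- file.path(out_dir, "peri_event_means.pdf")
    ggplot2::ggsave(p, gg, width = 6, height = 4)
    paths <- c(paths, p)
  }
  if (!is.null(pem) && nrow(pem$mat)) {
    df <- data.frame(trial = rep(seq_len(nrow(pem$mat)), ncol(pem$mat)),
                     time_s = rep(pem$time_s, each = nrow(pem$mat)),
                     dff = as.vector(pem$mat))
    gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s,
                                           y = .data$trial,
                                           fill = .data$dff)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::scale_y_reverse() +
      ggplot2::labs(x = "time from event (s)", y = "trial") +
      ggplot2::theme_minimal()
    p <- file.path(out_dir, "peri_event_heatmap.pdf")
    ggplot2::ggsave(p, gg, width = 6, height = 4)
    paths <- c(paths, p)
  }
  paths
}
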