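# Session container, CSV-bundle readers/writers, pipeline configuration,
# and end-to-end orchestration.
#
# On-disk session bundle (one directory):
#   session.json      - metadata (ids, sampling rate, duration, roi info)
#   traces.csv        - long table: time_s, roi_id, compartment, F, F_np
#   behavior.csv      - time_s, speed_cmps, whisk_energy
#   ground_truth.json - optional (synthetic sessions only)

#' Construct a session
#'
#' @param session_id,mouse_id,group Identifiers.
#' @param sampling_rate Hz, shared by all traces and the behavior trace.
#' @param duration Session length (s).
#' @param traces Named list of [roi_trace()] objects with unique
#'   `roi_id`s.
#' @param behavior A [behavior_trace()] (or plain data.frame with
#'   `speed_cmps`, `whisk_energy`).
#' @param ground_truth Optional ground-truth list (synthetic sessions).
#' @return Object of class `session`.
#' @export
session <- function(session_id, mouse_id, group, sampling_rate, duration,
                    traces, behavior, ground_truth = NULL) {
  assert_scalar_pos(sampling_rate, "sampling_rate")
  assert_scalar_pos(duration, "duration")
  n <- as.integer(round(duration * sampling_rate))
  ids <- vapply(traces, function(tr) tr$roi_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate roi_id in session: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(traces) <- ids
  for (tr in traces) {
    if (length(tr$F) != n) {
      stop(sprintf("trace '%s' has %d samples but the session expects %d",
                   tr$roi_id, length(tr$F), n))
    }
    if (!isTRUE(all.equal(tr$sampling_rate, sampling_rate))) {
      stop(sprintf("trace '%s' sampling rate differs from the session's",
                   tr$roi_id))
    }
  }
  if (!all(c("speed_cmps", "whisk_energy") %in% names(behavior))) {
    stop("behavior trace must have speed_cmps and whisk_energy channels")
  }
  if (nrow(behavior) != n) {
    stop(sprintf("behavior has %d samples but the traces have %d",
                 nrow(behavior), n))
  }
  if (!inherits(behavior, "behavior_trace")) {
    behavior <- behavior_trace(behavior$speed_cmps, behavior$whisk_energy,
                               sampling_rate)
  }
  structure(
    list(session_id = session_id, mouse_id = mouse_id, group = group,
         sampling_rate = sampling_rate, duration = n / sampling_rate,
         traces = traces, behavior = behavior,
         ground_truth = ground_truth),
    class = "session"
  )
}

#' @export
print.session <- function(x, ...) {
  comp <- table(vapply(x$traces, function(tr) tr$compartment, character(1)))
  cat(sprintf("session '%s' (mouse %s, group %s): %.0f s at %g Hz\n",
              x$session_id, x$mouse_id, x$group, x$duration,
              x$sampling_rate))
  cat("  ROIs:", paste(sprintf("%s=%d", names(comp), comp),
                       collapse = ", "), "\n")
  if (!is.null(x$ground_truth)) cat("  with ground truth\n")
  invisible(x)
}

#' ROI metadata table of a session
#'
#' @param session A `session`.
#' @return Data.frame: `roi_id`, `compartment`, `mouse_id`, `group`.
#' @export
session_roi_info <- function(session) {
  do.call(rbind, c(lapply(session$traces, function(tr) {
    data.frame(roi_id = tr$roi_id, compartment = tr$compartment,
               mouse_id = session$mouse_id, group = session$group)
  }), list(make.row.names = FALSE)))
}

#' Write a session as a CSV bundle
#'
#' @param session A `session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- as.integer(round(session$duration * session$sampling_rate))
  time_s <- (seq_len(n) - 1L) / session$sampling_rate
  tr_tab <- do.call(rbind, lapply(session$traces, function(tr) {
    data.frame(time_s = time_s, roi_id = tr$roi_id,
               compartment = tr$compartment, F = tr$F,
               F_np = if (is.null(tr$F_np)) NA_real_ else tr$F_np)
  }))
  utils::write.csv(tr_tab, file.path(dir, "traces.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(time_s = time_s,
               speed_cmps = session$behavior$speed_cmps,
               whisk_energy = session$behavior$whisk_energy),
    file.path(dir, "behavior.csv"), row.names = FALSE
  )
  meta <- list(session_id = session$session_id,
               mouse_id = session$mouse_id, group = session$group,
               sampling_rate = session$sampling_rate,
               duration = session$duration)
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(session$ground_truth)) {
    jsonlite::write_json(session$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(dir)
}

#' Load a session from a CSV bundle
#'
#' Validates the bundle and reports schema violations with context
#' (lengths, offending labels).
#'
#' @param path Bundle directory written by [write_session()].
#' @param format Only `"csv"` is supported.
#' @return A `session`.
#' @export
load_session <- function(path, format = c("csv")) {
  format <- match.arg(format)
  need <- c("session.json", "traces.csv", "behavior.csv")
  missing_files <- need[!file.exists(file.path(path, need))]
  if (length(missing_files)) {
    stop("session bundle at '", path, "' is missing: ",
         paste(missing_files, collapse = ", "))
  }
  meta <- jsonlite::read_json(file.path(path, "session.json"),
                              simplifyVector = TRUE)
  beh <- utils::read.csv(file.path(path, "behavior.csv"))
  if (!all(c("speed_cmps", "whisk_energy") %in% names(beh))) {
    stop("behavior.csv must have columns speed_cmps and whisk_energy")
  }
  tab <- utils::read.csv(file.path(path, "traces.csv"))
  bad <- setdiff(unique(tab$compartment), COMPARTMENTS)
  if (length(bad)) {
    stop("unknown compartment label(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(COMPARTMENTS, collapse = ", "))
  }
  traces <- lapply(split(tab, tab$roi_id), function(d) {
    d <- d[order(d$time_s), ]
    if (nrow(d) != nrow(beh)) {
      stop(sprintf("trace '%s' has %d samples but behavior has %d",
                   d$roi_id[1], nrow(d), nrow(beh)))
    }
    f_np <- if (all(is.na(d$F_np))) NULL else d$F_np
    roi_trace(d$roi_id[1], d$compartment[1], d$F, f_np,
              sampling_rate = meta$sampling_rate,
              session_id = meta$session_id, mouse_id = meta$mouse_id,
              group = meta$group)
  })
  gt_path <- file.path(path, "ground_truth.json")
  gt <- if (file.exists(gt_path)) {
    jsonlite::read_json(gt_path, simplifyVector = TRUE)
  }
  session(meta$session_id, meta$mouse_id, meta$group, meta$sampling_rate,
          meta$duration, traces,
          behavior_trace(beh$speed_cmps, beh$whisk_energy,
                         meta$sampling_rate),
          ground_truth = gt)
}

#' Write / read a state segmentation as BED-like TSV
#'
#' Columns `start_s`, `end_s`, `label`, tab-separated.
#'
#' @param segmentation A `state_segmentation`.
#' @param path Output file.
#' @return `path` invisibly ([write_segmentation()]); a
#'   `state_segmentation` ([read_segmentation()]).
#' @export
write_segmentation <- function(segmentation, path) {
  utils::write.table(as.data.frame(segmentation), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_segmentation
#' @param sampling_rate Hz of the session the segmentation belongs to.
#' @export
read_segmentation <- function(path, sampling_rate) {
  seg <- utils::read.table(path, sep = "\t", header = TRUE)
  attr(seg, "sampling_rate") <- sampling_rate
  attr(seg, "duration") <- max(seg$end_s)
  class(seg) <- c("state_segmentation", "data.frame")
  seg
}

#' Pipeline configuration
#'
#' Single structured container in which every analysis constant appears
#' exactly once: segmentation thresholds, dF/F and noise windows,
#' detection thresholds, modulation-index filters, transition windows and
#' bootstrap settings. Override any entry via `...`.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    speed_thresh = 1,        # cm/s locomotion threshold
    loc_merge_gap = 0.5,     # s, interruptions merged
    loc_min_duration = 0.5,  # s, bouts must strictly exceed
    whisk_smooth = 0.33,     # s moving-average window
    whisk_threshold_factor = 1.5,
    whisk_min_bout = 0.4,    # s
    whisk_merge_gap = 0.3,   # s
    whisk_mode = "multiplicative",
    whisk_order = "merge_first",
    dff_smooth_window = 5,   # s Savitzky-Golay window
    dff_percentile = 10,     # % baseline percentile
    sigma_window = 5,        # s least-noisy window
    k_astro = 2.0,           # sigma multiple, astrocytes
    k_neuron = 2.5,          # sigma multiple, neurons
    sigma_floor = 0.05,      # absolute dF/F fallback threshold
    max_event_duration = NULL,
    neuropil_alpha = 0.7,
    mi_guard = 2,            # s guard around locomotion for S_s
    mi_min_still = 2,        # s minimum residual still segment
    mi_min_loc = 3,          # s minimum locomotion bout in S_loc
    mi_min_whisk = 0.4,      # s minimum whisk bout in S_w
    mi_eps = 1e-6,
    trans_pre = 2,           # s before locomotion onset
    trans_post = 7,          # s after locomotion onset
    trans_min_loc = 3,       # s minimum bout for a transition
    trans_baseline_guard = 1,
    min_transitions = 3,     # for response reliability
    n_boot = 10000,
    bootstrap_alpha = 0.05
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown pipeline_config entries: ",
         paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from YAML
#'
#' Entries in the file override the [pipeline_config()] defaults.
#'
#' @param path YAML file with a flat mapping of config entries.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config[order(names(config))], tmp,
                       auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline on one session
#'
#' Stages, in order: linear detrend, neuropil subtraction (neurons), dF/F,
#' sigma, event detection, behavior segmentation, per-state event
#' summary, modulation indices, transition metrics. A stage failure aborts
#' with the failing stage named; when `out_dir` is given, outputs and a
#' manifest (config hash, seed, package version, stage outputs) are
#' written there.
#'
#' @param session A `session`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param seed Seed recorded in the manifest and used for any stage
#'   randomness (none in the per-session stages; kept for provenance).
#' @return List with `dff` (list of `dff_trace`), `events`,
#'   `segmentation`, `event_summary`, `modulation`, `transitions`,
#'   `response_table`, `activation`, `reliability`, `roi_info`, `config`.
#' @export
run_pipeline <- function(session, config = pipeline_config(),
                         out_dir = NULL, seed = NULL) {
  stopifnot(inherits(session, "session"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  roi_info <- session_roi_info(session)

  dff <- stage("preprocess", {
    lapply(session$traces, function(tr) {
      tr <- detrend_linear(tr)
      tr <- subtract_neuropil(tr, alpha = config$neuropil_alpha)
      d <- compute_dff(tr, smooth_window = config$dff_smooth_window,
                       percentile = config$dff_percentile)
      d$sigma <- estimate_sigma(d, window = config$sigma_window)
      d
    })
  })

  events <- stage("events", {
    ev <- lapply(dff, function(d) {
      k <- if (d$compartment == "Neuron") config$k_neuron else config$k_astro
      detect_events(d, k = k, sigma_floor = config$sigma_floor,
                    max_duration = config$max_event_duration)
    })
    out <- do.call(rbind, c(ev, list(make.row.names = FALSE)))
    rownames(out) <- NULL
    out
  })

  segmentation <- stage("segmentation", {
    segment_behavior(
      session$behavior, speed_thresh = config$speed_thresh,
      loc_merge_gap = config$loc_merge_gap,
      loc_min_duration = config$loc_min_duration,
      whisk_smooth = config$whisk_smooth,
      whisk_threshold_factor = config$whisk_threshold_factor,
      whisk_min_bout = config$whisk_min_bout,
      whisk_merge_gap = config$whisk_merge_gap,
      whisk_mode = config$whisk_mode, whisk_order = config$whisk_order
    )
  })

  event_summary <- stage("event_summary", {
    summarize_events_by_state(events, segmentation, roi_info)
  })

  modulation <- stage("modulation", {
    rows <- lapply(dff, function(d) {
      rbind(
        compute_locmi(d, segmentation, min_loc = config$mi_min_loc,
                      guard = config$mi_guard,
                      min_still = config$mi_min_still, eps = config$mi_eps),
        compute_whiskmi(d, segmentation, min_whisk = config$mi_min_whisk,
                        guard = config$mi_guard,
                        min_still = config$mi_min_still,
                        eps = config$mi_eps)
      )
    })
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    rownames(out) <- NULL
    out
  })

  transitions <- stage("transitions", {
    extract_transitions(segmentation, pre = config$trans_pre,
                        post = config$trans_post,
                        min_loc = config$trans_min_loc)
  })
  response_table <- stage("transition_responses", {
    transition_response_table(events, transitions, roi_info,
                              pre = config$trans_pre,
                              post = config$trans_post,
                              baseline_guard = config$trans_baseline_guard)
  })
  activation <- stage("activation_rate", activation_rate(response_table))
  reliability <- stage("response_reliability", {
    response_reliability(response_table,
                         min_transitions = config$min_transitions)
  })

  result <- list(
    session_id = session$session_id, mouse_id = session$mouse_id,
    group = session$group, dff = dff, events = events,
    segmentation = segmentation, event_summary = event_summary,
    modulation = modulation, transitions = transitions,
    response_table = response_table, activation = activation,
    reliability = reliability, roi_info = roi_info, config = config
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      segmentation = "segmentation.tsv", events = "events.csv",
      event_summary = "event_summary.csv", modulation = "modulation.csv",
      transitions = "transitions.csv", activation = "activation.csv",
      reliability = "reliability.csv"
    )
    write_segmentation(segmentation, file.path(out_dir, files$segmentation))
    for (nm in setdiff(names(files), "segmentation")) {
      utils::write.csv(result[[nm]], file.path(out_dir, files[[nm]]),
                       row.names = FALSE)
    }
    baseline <- data.frame(
      roi_id = vapply(dff, function(d) d$roi_id, character(1)),
      F0 = vapply(dff, function(d) d$F0, numeric(1)),
      sigma = vapply(dff, function(d) d$sigma, numeric(1))
    )
    jsonlite::write_json(baseline, file.path(out_dir, "baseline.json"),
                         dataframe = "columns", digits = NA)
    manifest <- list(
      package = "calmod",
      version = as.character(utils::packageVersion("calmod")),
      session_id = session$session_id, seed = seed,
      config = config[!vapply(config, is.null, logical(1))],
      config_hash = config_hash(config),
      outputs = c(unlist(files), baseline = "baseline.json")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    result$manifest <- manifest
  }
  result
}

#' Write tidy tables shaped for external mixed-model tools
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory.
#' @return `dir` invisibly.
#' @export
export_tidy_tables <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$event_summary,
                   file.path(dir, "events_by_state.csv"), row.names = FALSE)
  utils::write.csv(result$modulation, file.path(dir, "modulation.csv"),
                   row.names = FALSE)
  utils::write.csv(result$reliability, file.path(dir, "reliability.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Write a bootstrap comparison as JSON
#'
#' @param comparison A `bootstrap_comparison`.
#' @param path Output file.
#' @return `path` invisibly.
#' @export
write_comparison <- function(comparison, path) {
  out <- list(
    labels = comparison$labels, n_boot = comparison$n_boot,
    sided = comparison$sided, alpha = comparison$alpha,
    p_one = comparison$p_one, p_boot = comparison$p_boot,
    significant = comparison$significant,
    mean_a = comparison$mean_a, mean_b = comparison$mean_b,
    boot_mean_a = comparison$boot_mean_a,
    boot_mean_b = comparison$boot_mean_b,
    ci_a = comparison$ci_a, ci_b = comparison$ci_b
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
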