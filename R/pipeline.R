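#' Assemble a run configuration
#'
#' Bundles everything a full pipeline run needs: either a synthetic-data
#' configuration or paths to sample exports plus a trial-metadata CSV, the
#' filter parameters, the analyses to run, and the seed. The resolved
#' configuration is serialized alongside every run's outputs for
#' provenance.
#'
#' @param simulate A [synthetic_config()] to generate the dataset, or `NULL`
#'   to load data from `sample_files` + `meta_file`.
#' @param sample_files Character vector of sample-export paths (one per
#'   recording), used when `simulate` is `NULL`.
#' @param meta_file Trial-metadata CSV path (see [read_trial_meta()]).
#' @param dialect A [tsv_dialect()] for reading sample files.
#' @param params A [filter_params()].
#' @param timeline A [trial_timeline()].
#' @param analyses List of analysis cells; each element a list with
#'   `age_group`, `block`, `belief`. For each cell the pipeline runs the
#'   congruent-vs-incongruent averaged and per-timepoint pupil contrasts
#'   and the anticipatory-looking scores.
#' @param method Bayes-factor method for the pupil contrasts.
#' @param gaze_window Anticipatory-looking window (ms).
#' @param seed Integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(simulate = NULL, sample_files = NULL, meta_file = NULL,
                       dialect = tsv_dialect(), params = filter_params(),
                       timeline = trial_timeline(),
                       analyses = list(list(age_group = "9mo",
                                            block = "ObjectMemory",
                                            belief = "FB")),
                       method = "bic_lmm",
                       gaze_window = c(15000, 17000),
                       seed = 1) {
  if (is.null(simulate) && (is.null(sample_files) || is.null(meta_file)))
    stop("either a simulate config or sample_files + meta_file is required")
  structure(list(simulate = simulate, sample_files = sample_files,
                 meta_file = meta_file, dialect = dialect, params = params,
                 timeline = timeline, analyses = analyses, method = method,
                 gaze_window = gaze_window, seed = seed),
            class = "run_config")
}

#' Read a run configuration from a JSON or YAML file
#'
#' Keys mirror the arguments of [run_config()], [filter_params()] and
#' [trial_timeline()]; unknown keys are rejected. YAML files require the
#' yaml package.
#'
#' @param path Config file (`.json`, `.yaml`, or `.yml`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("sample_files", "meta_file", "analyses", "method",
             "gaze_window", "seed", "params", "timeline")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- raw[intersect(names(raw), c("sample_files", "meta_file", "method",
                                      "gaze_window", "seed"))]
  if (!is.null(raw$params)) args$params <- do.call(filter_params, raw$params)
  if (!is.null(raw$timeline)) args$timeline <- do.call(trial_timeline, raw$timeline)
  if (!is.null(raw$analyses)) {
    args$analyses <- if (is.data.frame(raw$analyses))
      lapply(seq_len(nrow(raw$analyses)), function(i) as.list(raw$analyses[i, ]))
    else raw$analyses
  }
  do.call(run_config, args)
}

write_run_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, preprocess, pupil analysis, and gaze analysis,
#' writing all outputs under `out_dir`: the resolved configuration, the
#' trace matrix and inclusion report, per-contrast averaged Bayes factors
#' with evidence labels, per-timepoint series and evidence windows,
#' anticipatory-looking scores with their signed-rank and binomial Bayes
#' factors, a summary table over the requested analysis cells, and a
#' manifest listing every stage with its output files and MD5 hashes.
#' Re-running with the same config and seed reproduces every output file
#' byte-for-byte.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`traces`,
#'   `summary`, `timecourses`, `gaze_scores`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(stages = list())
  written <- character(0)
  finish_stage <- function(stage, files) {
    manifest$stages[[stage]] <<- list(files = basename(files),
                                      md5 = unname(tools::md5sum(files)))
    written <<- c(written, files)
  }
  fail <- function(stage, e) {
    manifest$stages[[stage]] <<- list(error = conditionMessage(e))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  # stage: data ------------------------------------------------------------
  trials <- tryCatch({
    set.seed(config$seed)
    if (!is.null(config$simulate)) {
      generate_experiment(config$simulate)$trials
    } else {
      recs <- lapply(config$sample_files, read_samples, dialect = config$dialect)
      meta <- read_trial_meta(config$meta_file)
      unlist(lapply(recs, function(rec)
        segment_trials(rec, meta, config$timeline)), recursive = FALSE)
    }
  }, error = function(e) fail("data", e))
  cfg_path <- file.path(out_dir, "resolved_config.json")
  jsonlite::write_json(serialize_config(config), cfg_path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  finish_stage("data", cfg_path)

  # stage: preprocess ------------------------------------------------------
  traces <- tryCatch(preprocess_dataset(trials, config$params),
                     error = function(e) fail("preprocess", e))
  trace_path <- file.path(out_dir, "traces.csv")
  long <- do.call(rbind, lapply(seq_len(nrow(traces$rel)), function(i)
    data.frame(traces$meta[i, c("subject_id", "block", "belief", "outcome",
                                "trial_index")],
               grid_t_ms = traces$grid_t_ms, rel_change = traces$rel[i, ],
               row.names = NULL)))
  write_run_csv(long, trace_path)
  incl_path <- write_run_csv(traces$inclusion,
                             file.path(out_dir, "inclusion.csv"))
  finish_stage("preprocess", c(trace_path, incl_path))
  message(sum(traces$inclusion$included), "/", nrow(traces$inclusion),
          " trials included (",
          paste(names(table(traces$inclusion$reason)),
                table(traces$inclusion$reason), sep = "=", collapse = ", "),
          ")")

  # stage: pupil analysis --------------------------------------------------
  pupil <- tryCatch({
    summary_rows <- list(); timecourses <- list(); window_rows <- list()
    for (a in config$analyses) {
      subset <- a[c("age_group", "block", "belief")]
      label <- paste(unlist(subset), collapse = "_")
      avg <- averaged_outcome_bf(traces, subset = subset,
                                 method = config$method)
      tc <- per_timepoint_bf(traces, subset = subset, method = config$method)
      timecourses[[label]] <- tc
      series_path <- write_run_csv(
        tc$series, file.path(out_dir, paste0("timecourse_", label, ".csv")))
      if (nrow(tc$windows) > 0)
        window_rows[[label]] <- cbind(analysis = label, tc$windows)
      summary_rows[[label]] <- data.frame(
        analysis = label, a, contrast = "congruent_vs_incongruent",
        bf10 = avg$bf10, direction = if (!is.null(avg$direction))
          avg$direction else NA_real_,
        evidence = classify_bf(avg$bf10), method = avg$method,
        n_windows = nrow(tc$windows), stringsAsFactors = FALSE)
    }
    list(summary = do.call(rbind, summary_rows),
         windows = if (length(window_rows) > 0) do.call(rbind, window_rows)
           else data.frame(),
         timecourses = timecourses)
  }, error = function(e) fail("analyze_pupil", e))
  summary_path <- write_run_csv(pupil$summary,
                                file.path(out_dir, "summary.csv"))
  windows_path <- write_run_csv(pupil$windows,
                                file.path(out_dir, "windows.csv"))
  tc_paths <- file.path(out_dir, paste0("timecourse_",
                                        names(pupil$timecourses), ".csv"))
  finish_stage("analyze_pupil", c(summary_path, windows_path, tc_paths))

  # stage: gaze analysis ---------------------------------------------------
  gaze <- tryCatch({
    scores <- score_anticipatory_looking(trials, window = config$gaze_window)
    bf_rows <- list()
    for (a in config$analyses) {
      sel <- scores$age_group == a$age_group & scores$block == a$block &
        scores$belief == a$belief
      sc <- scores[sel, , drop = FALSE]
      per_subj <- tapply(sc$dls, sc$subject_id,
                         function(d) mean(d, na.rm = TRUE))
      d <- per_subj[!is.na(per_subj) & per_subj != 0]
      dls_bf <- if (length(d) >= 5)
        tryCatch(signed_rank_bf(d), error = function(e) NULL) else NULL
      fg <- aggregate_first_gaze(sc)
      fg_bf <- if (fg$n > 0) binomial_bf(fg$k, fg$n) else NULL
      label <- paste(unlist(a[c("age_group", "block", "belief")]),
                     collapse = "_")
      bf_rows[[label]] <- data.frame(
        analysis = label, n_dls = length(d),
        mean_dls = if (length(d) > 0) mean(d) else NA_real_,
        dls_W = if (!is.null(dls_bf)) dls_bf$W else NA_real_,
        dls_bf10 = if (!is.null(dls_bf)) dls_bf$bf10 else NA_real_,
        first_gaze_k = fg$k, first_gaze_n = fg$n,
        first_gaze_bf10 = if (!is.null(fg_bf)) fg_bf$bf10 else NA_real_,
        stringsAsFactors = FALSE)
    }
    list(scores = scores, bfs = do.call(rbind, bf_rows))
  }, error = function(e) fail("analyze_gaze", e))
  scores_path <- write_run_csv(gaze$scores, file.path(out_dir, "gaze_scores.csv"))
  gaze_bf_path <- write_run_csv(gaze$bfs, file.path(out_dir, "gaze_bfs.csv"))
  finish_stage("analyze_gaze", c(scores_path, gaze_bf_path))

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(traces = traces, summary = pupil$summary,
                 timecourses = pupil$timecourses, gaze_scores = gaze$scores,
                 gaze_bfs = gaze$bfs, manifest = manifest,
                 out_dir = out_dir))
}

serialize_config <- function(config) {
  list(simulate = if (!is.null(config$simulate))
         lapply(unclass(config$simulate), function(x)
           if (inherits(x, c("trial_timeline", "screen_geometry")))
             unclass(x) else x)
       else NULL,
       sample_files = config$sample_files,
       meta_file = config$meta_file,
       params = unclass(config$params),
       timeline = unclass(config$timeline),
       analyses = config$analyses,
       method = config$method,
       gaze_window = config$gaze_window,
       seed = config$seed)
}
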