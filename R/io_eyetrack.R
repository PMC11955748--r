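#' Column dialect for eye-tracker sample exports
#'
#' Maps the canonical sample fields onto the column names of a tab-separated
#' export. The defaults follow a Tobii-Studio-style TSV export with one
#' sample per row. Validity columns may be logical (`TRUE`/`FALSE`) or
#' numeric validity codes, in which case codes `<= valid_code_max` count as
#' valid.
#'
#' @param timestamp,pupil_left,pupil_right,valid_left,valid_right,gaze_x,gaze_y
#'   File column names for the corresponding canonical fields.
#' @param valid_code_max Largest numeric validity code still treated as valid.
#' @param sep Field separator.
#' @param screen A [screen_geometry()] attached to every recording read with
#'   this dialect.
#' @return A list of class `tsv_dialect`.
#' @export
tsv_dialect <- function(timestamp = "timestamp_ms",
                        pupil_left = "pupil_left_mm",
                        pupil_right = "pupil_right_mm",
                        valid_left = "validity_left",
                        valid_right = "validity_right",
                        gaze_x = "gaze_x_px",
                        gaze_y = "gaze_y_px",
                        valid_code_max = 1,
                        sep = "\t",
                        screen = screen_geometry()) {
  structure(list(
    columns = c(t_ms = timestamp,
                pupil_left_mm = pupil_left, pupil_right_mm = pupil_right,
                valid_left = valid_left, valid_right = valid_right,
                gaze_x_px = gaze_x, gaze_y_px = gaze_y),
    valid_code_max = valid_code_max,
    sep = sep,
    screen = screen
  ), class = "tsv_dialect")
}

#' Read an eye-tracker sample export
#'
#' Parses a tab-separated sample export into a recording: a data frame with
#' canonical columns `t_ms`, `pupil_left_mm`, `pupil_right_mm`, `valid_left`,
#' `valid_right`, `gaze_x_px`, `gaze_y_px` and the screen geometry attached
#' as an attribute. Unparseable numeric cells become `NA` (their count is
#' reported via a message); negative or otherwise unrealistic pupil values
#' are retained as-is at this stage -- filtering is the job of
#' [remove_invalid()], not the parser.
#'
#' @param path Path of the file to read.
#' @param dialect A [tsv_dialect()] describing the column layout.
#' @return A data frame of class `eyetrack_recording` with one row per
#'   sample, ordered as in the file, with attribute `screen`.
#' @seealso [write_samples()], [segment_trials()]
#' @export
read_samples <- function(path, dialect = tsv_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"), quote = "",
                           comment.char = "")
  if (nrow(raw) == 0L) stop("empty input: ", path, " contains no samples")
  cols <- dialect$columns
  missing_cols <- setdiff(unname(cols), names(raw))
  if (length(missing_cols) > 0L)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))

  n_bad <- 0L
  num <- function(v) {
    out <- suppressWarnings(as.numeric(v))
    n_bad <<- n_bad + sum(is.na(out) & !is.na(v))
    out
  }
  parse_valid <- function(v) {
    low <- tolower(trimws(v))
    out <- rep(NA, length(v))
    out[low %in% c("true", "t", "yes")] <- TRUE
    out[low %in% c("false", "f", "no")] <- FALSE
    todo <- is.na(out) & !is.na(v)
    codes <- suppressWarnings(as.numeric(low[todo]))
    out[todo] <- codes <= dialect$valid_code_max
    out[is.na(out)] <- FALSE
    as.logical(out)
  }

  rec <- data.frame(
    t_ms = num(raw[[cols[["t_ms"]]]]),
    pupil_left_mm = num(raw[[cols[["pupil_left_mm"]]]]),
    pupil_right_mm = num(raw[[cols[["pupil_right_mm"]]]]),
    valid_left = parse_valid(raw[[cols[["valid_left"]]]]),
    valid_right = parse_valid(raw[[cols[["valid_right"]]]]),
    gaze_x_px = num(raw[[cols[["gaze_x_px"]]]]),
    gaze_y_px = num(raw[[cols[["gaze_y_px"]]]])
  )
  if (n_bad > 0L)
    message(n_bad, " unparseable numeric cell(s) set to NA in ", basename(path))
  attr(rec, "screen") <- dialect$screen
  class(rec) <- c("eyetrack_recording", "data.frame")
  rec
}

#' Write a recording back to the sample-export dialect
#'
#' Inverse of [read_samples()]: numeric fields are written with 17
#' significant digits so that a read/write round trip reproduces finite
#' values bit-exactly and preserves missingness (written as empty cells).
#'
#' @param recording A recording as returned by [read_samples()] or built by
#'   the synthetic generator.
#' @param path Output file path.
#' @param dialect A [tsv_dialect()].
#' @return Invisibly, `path`.
#' @export
write_samples <- function(recording, path, dialect = tsv_dialect()) {
  cols <- dialect$columns
  fmt <- function(v) {
    if (is.logical(v)) return(ifelse(is.na(v), "", ifelse(v, "TRUE", "FALSE")))
    ifelse(is.na(v), "", sprintf("%.17g", v))
  }
  out <- lapply(names(cols), function(canon) fmt(recording[[canon]]))
  names(out) <- unname(cols)
  utils::write.table(as.data.frame(out, check.names = FALSE), path,
                     sep = dialect$sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a trial-metadata table
#'
#' The metadata CSV declares one row per trial with columns `subject_id`,
#' `age_group` (`9mo`/`18mo`), `block` (`ObjectMemory`/`ActionPrediction`),
#' `belief` (`TB`/`FB`), `outcome` (`congruent`/`incongruent`),
#' `congruent_side` (`left`/`right`), `trial_index` and `onset_ms` (trial
#' onset in recording time).
#'
#' @param path CSV file path.
#' @return A data frame with the columns above, validated against their
#'   enumerations.
#' @export
read_trial_meta <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trial_meta(meta)
  meta
}

validate_trial_meta <- function(meta) {
  required <- c("subject_id", "age_group", "block", "belief", "outcome",
                "congruent_side", "trial_index", "onset_ms")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0L)
    stop("trial metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  enums <- list(age_group = c("9mo", "18mo"),
                block = c("ObjectMemory", "ActionPrediction"),
                belief = c("TB", "FB"),
                outcome = c("congruent", "incongruent"),
                congruent_side = c("left", "right"))
  for (col in names(enums)) {
    bad <- setdiff(unique(meta[[col]]), enums[[col]])
    if (length(bad) > 0L)
      stop(sprintf("invalid %s value(s): %s", col, paste(bad, collapse = ", ")))
  }
  invisible(meta)
}

#' Segment a continuous recording into trials
#'
#' Cuts a recording at declared trial onsets: each trial receives exactly the
#' samples with `onset <= t < onset + trial_duration_ms`, re-timed to
#' trial-relative milliseconds. Onsets must be non-overlapping given the
#' timeline's trial duration.
#'
#' @param recording A recording data frame (see [read_samples()]).
#' @param trial_onsets A data frame with one row per trial: column `onset_ms`
#'   plus the trial-metadata columns (`subject_id`, `age_group`, `block`,
#'   `belief`, `outcome`, `congruent_side`, `trial_index`).
#' @param timeline A [trial_timeline()].
#' @return A list of trials; each trial is a list with elements `meta` (one-row
#'   data frame), `samples` (data frame of re-timed samples), and `timeline`.
#'   Trials whose onset lies beyond the recording end have zero samples and
#'   trigger a warning.
#' @export
segment_trials <- function(recording, trial_onsets, timeline = trial_timeline()) {
  if (nrow(trial_onsets) == 0L) return(list())
  if (is.null(trial_onsets$onset_ms)) stop("trial_onsets must have an onset_ms column")
  ord <- order(trial_onsets$onset_ms)
  onsets <- trial_onsets$onset_ms[ord]
  if (any(diff(onsets) < timeline$trial_duration_ms))
    stop("overlapping trial onsets given trial_duration_ms = ",
         timeline$trial_duration_ms)
  trials <- vector("list", length(onsets))
  for (i in seq_along(onsets)) {
    on <- onsets[i]
    idx <- which(recording$t_ms >= on &
                 recording$t_ms < on + timeline$trial_duration_ms)
    samples <- recording[idx, , drop = FALSE]
    samples$t_ms <- samples$t_ms - on
    rownames(samples) <- NULL
    meta <- trial_onsets[ord[i], setdiff(names(trial_onsets), "onset_ms"),
                         drop = FALSE]
    rownames(meta) <- NULL
    if (nrow(samples) == 0L)
      warning(sprintf("trial %d (onset %g ms) has zero samples", i, on))
    trials[[i]] <- structure(
      list(meta = meta, samples = samples, timeline = timeline,
           screen = attr(recording, "screen")),
      class = "pupil_trial")
  }
  trials
}

#' @export
print.pupil_trial <- function(x, ...) {
  cat("Pupil trial:", nrow(x$samples), "samples,",
    paste0(unlist(x$meta[c("subject_id", "block", "belief", "outcome")]),
           collapse = " / "), "\n")
  invisible(x)
}
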