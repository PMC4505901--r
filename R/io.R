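#' Write a trial to CSV with a YAML sidecar
#'
#' The trial CSV is tidy: columns `t`, `angle_x_deg`, `angle_y_deg`, and
#' either `emg_ecr, emg_ecu, emg_fcu, emg_fcr` (raw EMG, volts) or
#' `tension_ecr, ..., tension_fcr` (precomputed normalized envelopes). Task
#' metadata (`fs`, `task`, `direction`, central-hold sample range,
#' calibration file reference, ground truth if any) goes into a sidecar
#' YAML named `<csv>.yaml`.
#'
#' @param trial A `wrist_trial`.
#' @param path Path of the CSV file to write.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "wrist_trial"))
  df <- data.frame(t = trial$time,
                   angle_x_deg = trial$angle_deg[, 1],
                   angle_y_deg = trial$angle_deg[, 2])
  if (!is.null(trial$tension)) {
    tn <- as.matrix(trial$tension)
    df[paste0("tension_", c("ecr", "ecu", "fcu", "fcr"))] <-
      list(tn[, 1], tn[, 2], tn[, 3], tn[, 4])
  } else if (!is.null(trial$emg)) {
    em <- as.matrix(trial$emg)
    df[paste0("emg_", c("ecr", "ecu", "fcu", "fcr"))] <-
      list(em[, 1], em[, 2], em[, 3], em[, 4])
  }
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(fs = trial$fs, task = trial$task)
  if (!is.null(trial$direction)) meta$direction <- trial$direction
  if (!is.null(trial$hold_idx))
    meta$hold <- list(from = min(trial$hold_idx), to = max(trial$hold_idx))
  if (!is.null(trial$calibration)) meta$calibration <- trial$calibration
  if (!is.null(trial$truth))
    meta$truth <- list(M = trial$truth$M, B = trial$truth$B,
                       K = trial$truth$K, ratio = trial$truth$ratio)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a trial from CSV (+ YAML sidecar)
#'
#' Validates the schema (required columns, strictly increasing uniform time
#' base) and reports offending files and rows in errors.
#'
#' @param path Path to a trial CSV written in the [write_trial()] schema.
#' @return A `wrist_trial`.
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("no such trial file: ", path)
  df <- utils::read.csv(path)
  need <- c("t", "angle_x_deg", "angle_y_deg")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop(path, ": missing columns ", paste(miss, collapse = ", "))
  tn_cols <- paste0("tension_", c("ecr", "ecu", "fcu", "fcr"))
  emg_cols <- paste0("emg_", c("ecr", "ecu", "fcu", "fcr"))
  has_tn <- all(tn_cols %in% names(df))
  has_emg <- all(emg_cols %in% names(df))
  if (!has_tn && !has_emg)
    stop(path, ": needs the four emg_* or tension_* columns")
  meta_path <- paste0(path, ".yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  fs <- if (!is.null(meta$fs)) meta$fs else {
    dt <- stats::median(diff(df$t))
    1 / dt
  }
  bad <- which(diff(df$t) <= 0)
  if (length(bad) > 0L)
    stop(path, ": time not strictly increasing at row(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  tryCatch(validate_uniform_time(df$t, fs),
           error = function(e) stop(path, ": ", conditionMessage(e)))
  trial <- list(time = df$t, fs = fs,
                angle_deg = cbind(x = df$angle_x_deg, y = df$angle_y_deg),
                tension = if (has_tn)
                  as.matrix(stats::setNames(df[tn_cols],
                                            c("ECR", "ECU", "FCU", "FCR")))
                  else NULL,
                emg = if (has_emg && !has_tn) as.matrix(df[emg_cols])
                  else NULL,
                task = if (!is.null(meta$task)) meta$task else "step",
                direction = meta$direction,
                hold_idx = if (!is.null(meta$hold))
                  meta$hold$from:meta$hold$to else NULL,
                calibration = meta$calibration,
                truth = meta$truth)
  structure(trial, class = "wrist_trial")
}

#' Read several trials from paths, a directory, or a manifest
#'
#' @param paths Character vector of CSV paths, a single directory (all
#'   `*.csv` inside), or a manifest text file listing one CSV per line.
#' @return List of `wrist_trial` objects.
#' @export
read_trials <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.csv$", full.names = TRUE)
  else if (length(paths) == 1L && file.exists(paths) &&
           !grepl("\\.csv$", paths))
    paths <- readLines(paths)
  paths <- paths[nzchar(paths)]
  if (length(paths) == 0L) stop("no trial files found")
  lapply(paths, read_trial)
}

#' Read a cohort ratio table
#'
#' Long-format CSV with columns `subject_id`, `group`, `task`, `ratio`
#' (extra clinical columns are carried through as opaque metadata).
#'
#' @param path CSV path.
#' @return Data.frame.
#' @export
read_cohort_ratios <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "task", "ratio")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop(path, ": missing columns ", paste(miss, collapse = ", "))
  df
}

#' Bundled reference cohort of per-subject weight ratios
#'
#' The packaged reference table of B/K weight ratios for 10 control
#' subjects and 19 patients with cerebellar ataxia (spinocerebellar
#' degeneration or multiple system atrophy, cerebellar type), one ratio per
#' subject for each of the step-tracking and pursuit tasks, with clinical
#' metadata (age, sex, diagnosis, illness duration, activities-of-daily-
#' living grade) as opaque columns.
#'
#' @return Long-format data.frame (see [read_cohort_ratios()]).
#' @examples
#' compare_groups(reference_cohort())
#' @export
reference_cohort <- function() {
  read_cohort_ratios(system.file("extdata", "cohort_ratios.csv",
                                 package = "wristdecon"))
}

#' Bundled example joint-model fits
#'
#' Example identified (M, B, K) parameter triples for one control subject
#' and one patient, for each task: the inputs from which damping ratios and
#' torque reconstructions can be recomputed.
#'
#' @return Data.frame with columns `subject_type`, `task`, `M`, `B`, `K`.
#' @examples
#' with(reference_fits(), damping_ratio(M, B, K))
#' @export
reference_fits <- function() {
  utils::read.csv(system.file("extdata", "reference_fits.csv",
                              package = "wristdecon"),
                  stringsAsFactors = FALSE)
}
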