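# Plain-text interchange: BIDS-style events TSV, gaze TSV, motion text,
# and JSON configuration.

#' Write fixation events as a BIDS-style events table
#'
#' Columns: `onset` (s), `duration` (s), `trial_type`, `run`, `condition`,
#' `item_id`, `rank`.
#'
#' @param fixations Fixation events with `run_onset_ms` (or `onset_ms`),
#'   `duration_ms`, `item_type`, `run`, `item_id`, `rank`; `condition` is
#'   joined from `trials` when given.
#' @param path Output TSV path.
#' @param trials Optional trial table for the condition column.
#' @return Invisibly, `path`.
#' @export
write_events_tsv <- function(fixations, path, trials = NULL) {
  onset_ms <- if ("run_onset_ms" %in% names(fixations)) fixations$run_onset_ms
  else fixations$onset_ms
  condition <- if (!is.null(trials)) {
    trials$condition[match(paste(fixations$run, fixations$trial),
                           paste(trials$run, trials$trial))]
  } else NA_character_
  df <- data.frame(onset = onset_ms / 1000,
                   duration = fixations$duration_ms / 1000,
                   trial_type = fixations$item_type,
                   run = fixations$run, condition = condition,
                   item_id = fixations$item_id, rank = fixations$rank)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a gaze trace TSV (`time_ms`, `x_deg`, `y_deg`)
#'
#' @param trace Gaze trace data.frame.
#' @param path File path.
#' @return Invisibly `path` (write); the trace data.frame (read).
#' @export
write_gaze_tsv <- function(trace, path) {
  utils::write.table(trace[, c("time_ms", "x_deg", "y_deg")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gaze_tsv
#' @export
read_gaze_tsv <- function(path) {
  utils::read.delim(path, sep = "\t")
}

#' Read EyeLink-ASC-like sample lines
#'
#' Parses lines of the form `<time> <x> <y> ...` (non-numeric lines such as
#' messages and events are skipped) into a gaze trace. Coordinates are taken
#' as-is; unit conversion is the caller's concern.
#'
#' @param path Path to an ASC-like text file.
#' @return data.frame `time_ms`, `x_deg`, `y_deg`.
#' @export
read_asc_samples <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  keep <- vapply(parts, function(p) {
    length(p) >= 3 && !is.na(suppressWarnings(as.numeric(p[1]))) &&
      !is.na(suppressWarnings(as.numeric(p[2])))
  }, logical(1))
  m <- do.call(rbind, lapply(parts[keep], function(p) as.numeric(p[1:3])))
  data.frame(time_ms = m[, 1], x_deg = m[, 2], y_deg = m[, 3])
}

#' Write motion parameters as 6-column whitespace-delimited text
#'
#' @param motion Matrix (volumes x 6).
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_motion_txt <- function(motion, path) {
  utils::write.table(format(motion, digits = 8), path, sep = "  ",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a pipeline configuration as JSON
#'
#' Sub-configurations keep their structure; classes are restored on load.
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return Invisibly `path` (save); a `fixfmri_pipeline_config` (load).
#' @export
write_config_json <- function(config, path) {
  namedify <- function(x) {
    if (is.list(x)) return(lapply(unclass(x), namedify))
    if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
    x
  }
  jsonlite::write_json(namedify(unclass(config)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config()
  for (nm in names(raw)) {
    if (nm %in% c("gaze", "oculo", "glm", "mvpa")) {
      for (k in names(raw[[nm]])) cfg[[nm]][[k]] <- raw[[nm]][[k]]
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  cfg
}
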