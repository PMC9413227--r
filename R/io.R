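# Native on-disk formats.
#
# JSON schema (one file):
#   { "meta": {"sampling_rate", "duration", "population_label",
#              "pitch_um", "n_rows", "n_cols"},
#     "layout": [{"id", "x", "y"}],
#     "compartments": {"id": "label"},          # assigned electrodes only
#     "trains": {"id": [times_s]},
#     "sessions": [{"stimulated_electrode", "stimulus_times_s"}] }
#
# CSV directory dialect: meta.csv (key,value), layout.csv, compartments.csv,
# sessions.csv, and spikes/<electrode_id>.csv with a single `time_s` column.
#
# Spike and stimulus times are serialized at 0.1 ms resolution (the 10 kHz
# sampling period), so writing is deterministic and round-trips are exact.

TIME_DIGITS <- 4L

round_times <- function(x) round(as.numeric(x), TIME_DIGITS)

#' Save a recording to disk
#'
#' @param rec an `mea_recording`.
#' @param path output file (JSON) or directory (CSV dialect).
#' @param format `"json"` or `"csv_dir"`.
#' @return `path`, invisibly.
#' @seealso [load_recording()]
#' @export
save_recording <- function(rec, path, format = c("json", "csv_dir")) {
  format <- match.arg(format)
  validate_recording(rec)
  switch(format,
         json = save_recording_json(rec, path),
         csv_dir = save_recording_csv(rec, path))
  invisible(path)
}

save_recording_json <- function(rec, path) {
  lay <- rec$layout$positions
  comp <- rec$compartments
  comp_list <- if (is.null(comp)) {
    structure(list(), names = character(0))
  } else {
    keep <- !is.na(comp)
    as.list(comp[keep])
  }
  trains <- lapply(rec$trains, function(tr) round_times(tr$times))
  names(trains) <- vapply(rec$trains, function(tr) tr$electrode_id, "")
  obj <- list(
    meta = list(sampling_rate = rec$sampling_rate, duration = rec$duration,
                population_label = rec$population_label,
                pitch_um = rec$layout$pitch_um,
                n_rows = rec$layout$n_rows, n_cols = rec$layout$n_cols),
    layout = data.frame(id = lay$electrode_id, x = lay$x, y = lay$y,
                        stringsAsFactors = FALSE),
    compartments = comp_list,
    trains = trains,
    sessions = lapply(rec$sessions, function(s) {
      list(stimulated_electrode = s$stimulated_electrode,
           stimulus_times_s = round_times(s$stimulus_times))
    })
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(8), null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

save_recording_csv <- function(rec, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  dir.create(file.path(path, "spikes"), showWarnings = FALSE)
  meta <- data.frame(
    key = c("sampling_rate", "duration", "population_label",
            "pitch_um", "n_rows", "n_cols"),
    value = c(rec$sampling_rate, rec$duration, rec$population_label,
              rec$layout$pitch_um, rec$layout$n_rows, rec$layout$n_cols),
    stringsAsFactors = FALSE
  )
  utils::write.csv(meta, file.path(path, "meta.csv"), row.names = FALSE)
  lay <- rec$layout$positions
  utils::write.csv(data.frame(electrode_id = lay$electrode_id,
                              x = lay$x, y = lay$y),
                   file.path(path, "layout.csv"), row.names = FALSE)
  comp <- rec$compartments
  if (!is.null(comp)) {
    keep <- !is.na(comp)
    utils::write.csv(data.frame(electrode_id = names(comp)[keep],
                                label = unname(comp[keep])),
                     file.path(path, "compartments.csv"), row.names = FALSE)
  }
  if (length(rec$sessions)) {
    ses <- do.call(rbind, lapply(seq_along(rec$sessions), function(i) {
      s <- rec$sessions[[i]]
      data.frame(session = i, stimulated_electrode = s$stimulated_electrode,
                 stimulus_time_s = round_times(s$stimulus_times))
    }))
    utils::write.csv(ses, file.path(path, "sessions.csv"), row.names = FALSE)
  }
  for (tr in rec$trains) {
    utils::write.csv(data.frame(time_s = round_times(tr$times)),
                     file.path(path, "spikes", paste0(tr$electrode_id, ".csv")),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Load a recording from disk
#'
#' Reads the package's native JSON schema or the per-electrode CSV directory
#' dialect and validates every type invariant; malformed or missing fields
#' raise an error naming the offending field, unknown electrodes and
#' non-monotone spike times are rejected.
#'
#' @param path JSON file or CSV directory written by [save_recording()].
#' @param format `"json"` or `"csv_dir"`; guessed from `path` by default.
#' @return An `mea_recording`.
#' @export
load_recording <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (dir.exists(path)) "csv_dir" else "json"
  }
  format <- match.arg(format, c("json", "csv_dir"))
  if (!file.exists(path)) stop("load_recording: no such path: ", path, call. = FALSE)
  switch(format,
         json = load_recording_json(path),
         csv_dir = load_recording_csv(path))
}

need_field <- function(obj, field, where) {
  if (is.null(obj[[field]])) {
    stop("load_recording: missing field '", field, "' in ", where, call. = FALSE)
  }
  obj[[field]]
}

load_recording_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE, simplifyMatrix = FALSE)
  meta <- need_field(obj, "meta", "recording")
  duration <- need_field(meta, "duration", "meta")
  lay_df <- need_field(obj, "layout", "recording")
  if (!all(c("id", "x", "y") %in% names(lay_df))) {
    stop("load_recording: layout entries need fields id, x, y", call. = FALSE)
  }
  layout <- mea_layout_from_positions(
    data.frame(electrode_id = lay_df$id, x = lay_df$x, y = lay_df$y,
               stringsAsFactors = FALSE),
    pitch_um = meta$pitch_um %||% 200,
    n_rows = meta$n_rows %||% NA_integer_,
    n_cols = meta$n_cols %||% NA_integer_
  )
  comp <- rep(NA_character_, length(layout$electrode_ids))
  names(comp) <- layout$electrode_ids
  stored <- obj$compartments
  if (length(stored)) {
    unknown <- setdiff(names(stored), layout$electrode_ids)
    if (length(unknown)) {
      stop("load_recording: compartments reference unknown electrode ",
           unknown[1], call. = FALSE)
    }
    comp[names(stored)] <- unlist(stored)
  }
  comp <- structure(comp, class = "mea_compartments")
  trains_raw <- obj$trains %||% list()
  trains <- lapply(names(trains_raw), function(id) {
    spike_train(id, as.numeric(trains_raw[[id]]), t_start = 0, t_stop = duration)
  })
  ses_raw <- obj$sessions %||% list()
  if (is.data.frame(ses_raw)) {
    ses_raw <- lapply(seq_len(nrow(ses_raw)), function(i) {
      list(stimulated_electrode = ses_raw$stimulated_electrode[i],
           stimulus_times_s = ses_raw$stimulus_times_s[[i]])
    })
  }
  sessions <- lapply(ses_raw, function(s) {
    stimulation_session(need_field(s, "stimulated_electrode", "session"),
                        as.numeric(need_field(s, "stimulus_times_s", "session")))
  })
  mea_recording(layout = layout, trains = trains, compartments = comp,
                sessions = sessions, duration = duration,
                population_label = meta$population_label %||% "other",
                sampling_rate = meta$sampling_rate %||% 10000)
}

load_recording_csv <- function(path) {
  meta_path <- file.path(path, "meta.csv")
  if (!file.exists(meta_path)) {
    stop("load_recording: missing field 'meta.csv' in ", path, call. = FALSE)
  }
  meta_df <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  meta <- stats::setNames(as.list(meta_df$value), meta_df$key)
  duration <- as.numeric(need_field(meta, "duration", "meta.csv"))
  lay_df <- utils::read.csv(file.path(path, "layout.csv"), stringsAsFactors = FALSE)
  layout <- mea_layout_from_positions(
    data.frame(electrode_id = lay_df$electrode_id, x = lay_df$x, y = lay_df$y,
               stringsAsFactors = FALSE),
    pitch_um = as.numeric(meta$pitch_um %||% 200),
    n_rows = as.integer(meta$n_rows %||% NA), n_cols = as.integer(meta$n_cols %||% NA)
  )
  comp <- rep(NA_character_, length(layout$electrode_ids))
  names(comp) <- layout$electrode_ids
  comp_path <- file.path(path, "compartments.csv")
  if (file.exists(comp_path)) {
    cdf <- utils::read.csv(comp_path, stringsAsFactors = FALSE)
    unknown <- setdiff(cdf$electrode_id, layout$electrode_ids)
    if (length(unknown)) {
      stop("load_recording: compartments reference unknown electrode ",
           unknown[1], call. = FALSE)
    }
    comp[cdf$electrode_id] <- cdf$label
  }
  comp <- structure(comp, class = "mea_compartments")
  spike_files <- list.files(file.path(path, "spikes"), pattern = "\\.csv$",
                            full.names = TRUE)
  trains <- lapply(spike_files, function(f) {
    id <- sub("\\.csv$", "", basename(f))
    df <- utils::read.csv(f)
    if (!("time_s" %in% names(df))) {
      stop("load_recording: missing field 'time_s' in ", basename(f),
           call. = FALSE)
    }
    spike_train(id, df$time_s, t_start = 0, t_stop = duration)
  })
  sessions <- list()
  ses_path <- file.path(path, "sessions.csv")
  if (file.exists(ses_path)) {
    sdf <- utils::read.csv(ses_path, stringsAsFactors = FALSE)
    sessions <- lapply(split(sdf, sdf$session), function(g) {
      stimulation_session(g$stimulated_electrode[1], g$stimulus_time_s)
    })
    names(sessions) <- NULL
  }
  mea_recording(layout = layout, trains = trains, compartments = comp,
                sessions = sessions, duration = duration,
                population_label = as.character(meta$population_label %||% "other"),
                sampling_rate = as.numeric(meta$sampling_rate %||% 10000))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
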