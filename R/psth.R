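#' Post-stimulus time histogram of one electrode
#'
#' Counts spikes in half-open windows `[t_stim, t_stim + window_ms)` after
#' every stimulus of a session, bins them at `bin_ms` (half-open bins, so a
#' spike exactly at a stimulus time falls in bin 1) and divides each bin
#' count by the number of stimuli. The PSTH area is the sum of the
#' per-stimulus values; an electrode is responsive when its area is not
#' lower than 1 (strictly smaller areas mark the electrode unable to evoke
#' a minimal response).
#'
#' Stimulation windows may not overlap; at the 0.2 Hz protocol rate
#' (5 s spacing, 600 ms window) they never do, and nonconformant sessions
#' are rejected.
#'
#' @param train a [spike_train()].
#' @param session a [stimulation_session()].
#' @param window_ms post-stimulus observation window (default 600 ms).
#' @param bin_ms bin width (default 4 ms); must divide `window_ms`.
#' @return An object of class `psth`: list with `electrode_id`, `bin_ms`,
#'   `window_ms`, `bin_edges_ms` (length bins + 1), `values` (spikes per
#'   stimulus per bin), `counts` (raw spike counts per bin), `n_stimuli`,
#'   `area`, `raw_count_area` (`area * n_stimuli`), `normalized_area`
#'   (`NA` until [normalize_areas()]), `is_responsive`, `is_stimulated`.
#' @export
compute_psth <- function(train, session, window_ms = 600, bin_ms = 4) {
  stims <- session$stimulus_times
  if (length(stims) < 1) stop("compute_psth: session has no stimuli", call. = FALSE)
  if (window_ms %% bin_ms != 0) {
    stop("compute_psth: window_ms must be divisible by bin_ms", call. = FALSE)
  }
  window_s <- window_ms / 1000
  if (length(stims) > 1 && min(diff(stims)) < window_s) {
    stop("compute_psth: overlapping post-stimulus windows", call. = FALSE)
  }
  n_bins <- as.integer(window_ms / bin_ms)
  t <- train$times
  idx <- findInterval(t, stims)
  inside <- idx >= 1
  rel <- t[inside] - stims[pmax(idx[inside], 1)]
  # exact window and bin arithmetic in 0.1 ms ticks (the declared time
  # resolution), so spikes on a bin or window edge are never misplaced by
  # binary round-off
  ticks <- round(rel * 1e4)
  ticks <- ticks[ticks >= 0 & ticks < window_ms * 10]
  bins <- as.integer(ticks %/% (bin_ms * 10)) + 1L
  counts <- tabulate(bins, nbins = n_bins)
  values <- counts / length(stims)
  area <- sum(values)
  structure(list(
    electrode_id = train$electrode_id,
    bin_ms = bin_ms, window_ms = window_ms,
    bin_edges_ms = seq(0, window_ms, by = bin_ms),
    values = values, counts = counts,
    n_stimuli = length(stims),
    area = area, raw_count_area = sum(counts),
    normalized_area = NA_real_,
    is_responsive = area >= 1,
    is_stimulated = identical(train$electrode_id, session$stimulated_electrode)
  ), class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth> %s: area %.3f spikes/stimulus over %d stimuli%s\n",
              x$electrode_id, x$area, x$n_stimuli,
              if (x$is_responsive) "" else " (unresponsive)"))
  invisible(x)
}

#' PSTHs for every electrode of a recording
#'
#' @param rec an `mea_recording`.
#' @param session a [stimulation_session()] or an index into `rec$sessions`.
#' @param window_ms,bin_ms see [compute_psth()].
#' @param electrode_ids electrodes to include (default: all in the layout;
#'   electrodes without a stored train get an all-zero PSTH).
#' @return Named list of `psth` objects.
#' @export
compute_psths <- function(rec, session, window_ms = 600, bin_ms = 4,
                          electrode_ids = NULL) {
  if (is.numeric(session)) session <- rec$sessions[[session]]
  if (is.null(electrode_ids)) electrode_ids <- rec$layout$electrode_ids
  out <- lapply(electrode_ids, function(id) {
    compute_psth(get_train(rec, id), session, window_ms, bin_ms)
  })
  stats::setNames(out, electrode_ids)
}

#' Stack PSTH values into a matrix
#'
#' @param psths list of `psth` objects.
#' @return Numeric matrix, electrodes (rows) by bins (columns); row names are
#'   electrode identifiers.
#' @export
psth_matrix <- function(psths) {
  stopifnot(length(psths) >= 1)
  m <- do.call(rbind, lapply(psths, function(p) p$values))
  rownames(m) <- vapply(psths, function(p) p$electrode_id, "")
  m
}

#' Split PSTHs into responsive and unresponsive electrodes
#'
#' Electrodes whose PSTH area is strictly lower than `min_area` are removed
#' from downstream statistics; an area exactly at the threshold keeps the
#' electrode.
#'
#' @param psths list of `psth` objects.
#' @param min_area responsiveness threshold in spikes/stimulus (default 1).
#' @return List with elements `responsive` and `unresponsive`.
#' @export
filter_responsive <- function(psths, min_area = 1) {
  areas <- vapply(psths, function(p) p$area, 0)
  keep <- areas >= min_area
  list(responsive = psths[keep], unresponsive = psths[!keep])
}

#' Normalize PSTH areas to the maximum in scope
#'
#' Divides every area by the maximum area over the supplied set, so the
#' strongest electrode maps to 1 and values are comparable across networks
#' and configurations. The scope over which the maximum is taken (one
#' recording session, or a whole dataset) is the caller's choice and is
#' recorded in the result.
#'
#' @param psths list of `psth` objects (at least one with positive area).
#' @param scope label recorded on the result: `"per_recording"` (default)
#'   or `"per_dataset"`.
#' @return The list with `normalized_area` fields filled in; the scope and
#'   the maximum used are attached as attributes.
#' @export
normalize_areas <- function(psths, scope = c("per_recording", "per_dataset")) {
  scope <- match.arg(scope)
  areas <- vapply(psths, function(p) p$area, 0)
  mx <- max(areas)
  if (mx <= 0) {
    stop("normalize_areas: all PSTH areas are zero", call. = FALSE)
  }
  out <- lapply(psths, function(p) {
    p$normalized_area <- p$area / mx
    p
  })
  attr(out, "scope") <- scope
  attr(out, "max_area") <- mx
  out
}

#' Spatial map of PSTH areas
#'
#' Arranges per-electrode PSTH areas on the layout grid. Grid positions with
#' no electrode are `NA`; unresponsive electrodes keep their numeric area but
#' are marked `FALSE` in the responsiveness mask, so "no response" is
#' distinguishable from "no electrode" and from a true zero.
#'
#' @param psths list of `psth` objects.
#' @param layout an `mea_layout` covering every electrode in `psths`.
#' @param value `"area"`, `"raw_count_area"` or `"normalized_area"`.
#' @return List of class `mea_area_map` with matrices `values` and
#'   `responsive` (rows x cols of the layout).
#' @export
area_map <- function(psths, layout, value = c("area", "raw_count_area",
                                              "normalized_area")) {
  value <- match.arg(value)
  pos <- layout$positions
  if (!all(c("row", "col") %in% names(pos))) {
    stop("area_map: layout has no grid rows/cols", call. = FALSE)
  }
  ids <- vapply(psths, function(p) p$electrode_id, "")
  unknown <- setdiff(ids, pos$electrode_id)
  if (length(unknown)) {
    stop("area_map: unknown electrode ", unknown[1], call. = FALSE)
  }
  vals <- matrix(NA_real_, layout$n_rows, layout$n_cols)
  resp <- matrix(FALSE, layout$n_rows, layout$n_cols)
  at <- match(ids, pos$electrode_id)
  for (k in seq_along(psths)) {
    r <- pos$row[at[k]]; c <- pos$col[at[k]]
    vals[r, c] <- psths[[k]][[value]]
    resp[r, c] <- psths[[k]]$is_responsive
  }
  structure(list(values = vals, responsive = resp, value = value),
            class = "mea_area_map")
}
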