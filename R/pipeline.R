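#' Pipeline configuration
#'
#' Aggregates every stage parameter with the defaults used throughout the
#' analysis: 5-spike / 100 ms burst detection, a 0.1 spikes/s activity
#' threshold, 600 ms / 4 ms PSTHs with the area >= 1 responsiveness filter,
#' 50 ms class-mean smoothing, a 52 ms early-peak limit, 10% late-peak
#' prominence, a 0.3 separation threshold, the 650 ms sentinel latency and
#' a 0.05 significance level.
#'
#' @param seed RNG seed for every stochastic stage (k-means restarts).
#' @param spont_window spontaneous-analysis window `c(start, stop)` in
#'   seconds; `NULL` uses `[0, first stimulus)`.
#' @param active_threshold MFR activity threshold, spikes/s.
#' @param burst_min_spikes,burst_max_isi_ms burst-detection parameters.
#' @param psth_window_ms,psth_bin_ms PSTH geometry; the window must be
#'   divisible by the bin.
#' @param min_area PSTH-area responsiveness threshold (spikes/stimulus).
#' @param include_stimulated include the stimulated electrode's own PSTH in
#'   the statistics (it is always flagged; default `TRUE`).
#' @param normalize_scope scope label for [normalize_areas()].
#' @param classification a [classification_config()]; its seed is forced to
#'   `seed`.
#' @param detection a [ptsd_params()] (used only when starting from raw
#'   traces).
#' @param alpha significance level.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, spont_window = NULL,
                            active_threshold = 0.1, burst_min_spikes = 5L,
                            burst_max_isi_ms = 100, psth_window_ms = 600,
                            psth_bin_ms = 4, min_area = 1,
                            include_stimulated = TRUE,
                            normalize_scope = "per_recording",
                            classification = classification_config(seed = seed),
                            detection = ptsd_params(), alpha = 0.05) {
  if (psth_window_ms %% psth_bin_ms != 0) {
    stop("pipeline_config: psth_window_ms must be divisible by psth_bin_ms",
         call. = FALSE)
  }
  stopifnot(active_threshold >= 0, burst_min_spikes >= 2, burst_max_isi_ms > 0,
            min_area >= 0, alpha > 0, alpha < 1)
  classification$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), spont_window = spont_window,
                 active_threshold = active_threshold,
                 burst_min_spikes = as.integer(burst_min_spikes),
                 burst_max_isi_ms = burst_max_isi_ms,
                 psth_window_ms = psth_window_ms, psth_bin_ms = psth_bin_ms,
                 min_area = min_area, include_stimulated = include_stimulated,
                 normalize_scope = normalize_scope,
                 classification = classification, detection = detection,
                 alpha = alpha),
            class = "pipeline_config")
}

#' Run the full analysis on one recording
#'
#' Executes the stages in order: spontaneous metrics with the
#' active-electrode filter, then per stimulation session the PSTHs, the
#' responsiveness filter, area normalization, the early/late response
#' classification and the per-electrode latency map. Any stage failure
#' aborts with the session index and cause.
#'
#' @param rec an `mea_recording`.
#' @param config a [pipeline_config()].
#' @return Object of class `mea_report`: list with `population_label`,
#'   `config`, `spontaneous` (metrics, active, inactive), and `sessions`, a
#'   list with per-session `stim_electrode`, `stim_compartment`, `areas`
#'   (per-electrode table), `classification`, `latencies`.
#' @export
run_pipeline <- function(rec, config = pipeline_config()) {
  validate_recording(rec)
  metrics <- spontaneous_metrics(rec, window = config$spont_window,
                                 min_spikes = config$burst_min_spikes,
                                 max_isi_ms = config$burst_max_isi_ms,
                                 active_threshold = config$active_threshold)
  act <- filter_active(metrics, config$active_threshold)
  comp <- rec$compartments
  comp_of <- function(id) {
    if (is.null(comp)) NA_character_ else unname(comp[id])
  }
  sessions <- lapply(seq_along(rec$sessions), function(si) {
    ses <- rec$sessions[[si]]
    res <- tryCatch({
      psths <- compute_psths(rec, ses, config$psth_window_ms, config$psth_bin_ms)
      if (!config$include_stimulated) {
        psths <- psths[names(psths) != ses$stimulated_electrode]
      }
      split <- filter_responsive(psths, config$min_area)
      areas <- data.frame(
        electrode_id = names(psths),
        compartment = vapply(names(psths), comp_of, ""),
        area = vapply(psths, function(p) p$area, 0),
        raw_count_area = vapply(psths, function(p) p$raw_count_area, 0),
        normalized_area = NA_real_,
        responsive = vapply(psths, function(p) p$is_responsive, TRUE),
        stimulated = vapply(psths, function(p) p$is_stimulated, TRUE),
        stringsAsFactors = FALSE)
      rownames(areas) <- NULL
      classification <- NULL
      latencies <- NULL
      if (length(split$responsive) >= 1) {
        normed <- normalize_areas(split$responsive, config$normalize_scope)
        at <- match(names(normed), areas$electrode_id)
        areas$normalized_area[at] <-
          vapply(normed, function(p) p$normalized_area, 0)
        classification <- classify_responses(normed, config$classification)
        latencies <- assign_latencies(normed, classification)
        latencies$compartment <-
          vapply(latencies$electrode_id, comp_of, "")
      }
      list(session = si, stim_electrode = ses$stimulated_electrode,
           stim_compartment = comp_of(ses$stimulated_electrode),
           n_stimuli = length(ses$stimulus_times), areas = areas,
           classification = classification, latencies = latencies)
    }, error = function(e) {
      stop("run_pipeline: session ", si, " failed: ", conditionMessage(e),
           call. = FALSE)
    })
    res
  })
  structure(list(population_label = rec$population_label, config = config,
                 spontaneous = list(metrics = metrics, active = act$active,
                                    inactive = act$inactive),
                 sessions = sessions),
            class = "mea_report")
}

#' @export
print.mea_report <- function(x, ...) {
  cat(sprintf("<mea_report> %s: %d active electrodes, %d session(s)\n",
              x$population_label, nrow(x$spontaneous$active),
              length(x$sessions)))
  for (s in x$sessions) {
    n_resp <- sum(s$areas$responsive)
    k <- if (is.null(s$classification)) 0 else s$classification$k
    n_late <- if (is.null(s$latencies)) 0 else
      sum(s$latencies$has_late & !s$latencies$non_responding)
    cat(sprintf("  session %d (stim %s, %s): %d responsive, k = %d, %d late\n",
                s$session, s$stim_electrode, s$stim_compartment, n_resp, k,
                n_late))
  }
  invisible(x)
}

#' Cross-recording summary tables
#'
#' Condenses a set of pipeline reports into the tables the analysis is
#' ultimately about: pooled spontaneous metrics per culture, normalized PSTH
#' area distributions per population, compartment-mean early/late latencies
#' per population and stimulation site, evoked-response counts (a
#' compartment-session pair counts as an early response when it contains at
#' least one classified electrode, and as a late response when at least one
#' of its electrodes belongs to a class with a late component), and
#' population comparisons of areas and latencies.
#'
#' @param reports named list of `mea_report` objects.
#' @param design optional data frame (`recording_id`, `population`)
#'   overriding the population labels stored in the reports.
#' @param sentinel_ms late-latency sentinel (default from the first
#'   report's configuration).
#' @return List of class `mea_summary` with data frames `spontaneous`,
#'   `areas`, `latencies`, `compartment_means`, `counts`, and a list
#'   `comparisons` of [kruskal_wallis()] results (populations permitting).
#' @export
summarize_reports <- function(reports, design = NULL, sentinel_ms = NULL) {
  stopifnot(length(reports) >= 1)
  if (is.null(names(reports))) {
    names(reports) <- paste0("rec", seq_along(reports))
  }
  if (is.null(sentinel_ms)) {
    sentinel_ms <- reports[[1]]$config$classification$sentinel_ms
  }
  pop_of <- vapply(reports, function(r) r$population_label, "")
  if (!is.null(design)) {
    pop_of[design$recording_id] <- design$population
  }

  spont <- do.call(rbind, lapply(names(reports), function(nm) {
    a <- reports[[nm]]$spontaneous$active
    data.frame(recording_id = nm, population = pop_of[[nm]],
               n_active = nrow(a),
               mfr_mean = mean(a$mfr), mbr_mean = mean(a$mbr),
               bd_mean = mean(a$mean_bd_ms, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))

  areas <- do.call(rbind, lapply(names(reports), function(nm) {
    do.call(rbind, lapply(reports[[nm]]$sessions, function(s) {
      d <- s$areas[s$areas$responsive, , drop = FALSE]
      if (!nrow(d)) return(NULL)
      data.frame(recording_id = nm, population = pop_of[[nm]],
                 session = s$session, stim_compartment = s$stim_compartment,
                 compartment = d$compartment, electrode_id = d$electrode_id,
                 area = d$area, normalized_area = d$normalized_area,
                 stringsAsFactors = FALSE)
    }))
  }))

  latencies <- do.call(rbind, lapply(names(reports), function(nm) {
    do.call(rbind, lapply(reports[[nm]]$sessions, function(s) {
      d <- s$latencies
      if (is.null(d) || !nrow(d)) return(NULL)
      d <- d[!d$non_responding, , drop = FALSE]
      if (!nrow(d)) return(NULL)
      data.frame(recording_id = nm, population = pop_of[[nm]],
                 session = s$session, stim_compartment = s$stim_compartment,
                 compartment = d$compartment, electrode_id = d$electrode_id,
                 early_latency_ms = d$early_latency_ms,
                 late_latency_ms = d$late_latency_ms,
                 has_late = d$has_late, stringsAsFactors = FALSE)
    }))
  }))

  compartment_means <- NULL
  counts <- NULL
  if (!is.null(latencies) && nrow(latencies)) {
    keys <- interaction(latencies$recording_id, latencies$session,
                        latencies$compartment, drop = TRUE)
    compartment_means <- do.call(rbind, lapply(split(latencies, keys), function(g) {
      late_vals <- g$late_latency_ms[g$late_latency_ms < sentinel_ms]
      data.frame(recording_id = g$recording_id[1], population = g$population[1],
                 session = g$session[1], stim_compartment = g$stim_compartment[1],
                 compartment = g$compartment[1], n_electrodes = nrow(g),
                 early_mean_ms = mean(g$early_latency_ms),
                 late_present = length(late_vals) > 0,
                 late_mean_ms = if (length(late_vals)) mean(late_vals)
                                else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    rownames(compartment_means) <- NULL
    counts <- do.call(rbind, lapply(split(compartment_means,
                                          compartment_means$population),
                                    function(g) {
      data.frame(population = g$population[1],
                 n_early = nrow(g), n_late = sum(g$late_present),
                 stringsAsFactors = FALSE)
    }))
    rownames(counts) <- NULL
  }

  comparisons <- list()
  pops <- unique(pop_of)
  if (length(pops) >= 2 && !is.null(areas) && nrow(areas)) {
    comparisons$normalized_area <-
      kruskal_wallis(split(areas$normalized_area, areas$population))
  }
  if (length(pops) >= 2 && !is.null(compartment_means)) {
    comparisons$early_latency <-
      kruskal_wallis(split(compartment_means$early_mean_ms,
                           compartment_means$population))
    lt <- compartment_means[compartment_means$late_present, , drop = FALSE]
    if (nrow(lt) && length(unique(lt$population)) >= 2) {
      comparisons$late_latency <-
        kruskal_wallis(split(lt$late_mean_ms, lt$population))
    }
  }

  structure(list(spontaneous = spont, areas = areas, latencies = latencies,
                 compartment_means = compartment_means, counts = counts,
                 comparisons = comparisons, sentinel_ms = sentinel_ms),
            class = "mea_summary")
}

#' @export
print.mea_summary <- function(x, ...) {
  cat("<mea_summary>\n")
  cat("Spontaneous metrics (pooled over active electrodes):\n")
  print(x$spontaneous, row.names = FALSE)
  if (!is.null(x$counts)) {
    cat("Evoked-response counts (compartment-session pairs):\n")
    print(x$counts, row.names = FALSE)
  }
  for (nm in names(x$comparisons)) {
    cmp <- x$comparisons[[nm]]
    cat(sprintf("%s: H = %.3g, p = %.3g%s\n", nm, cmp$H, cmp$p_value,
                if (cmp$significant) " *" else ""))
  }
  invisible(x)
}
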