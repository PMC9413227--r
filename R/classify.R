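#' Configuration of the evoked-response classifier
#'
#' @param k_range candidate numbers of k-means classes (default 2..8); the
#'   value maximising the mean silhouette width is chosen.
#' @param smoothing_ms moving-average window applied to class-mean PSTHs
#'   (default 50 ms, realized as a centered 13-bin window at 4 ms bins).
#' @param early_limit_ms upper bound for the early peak (default 52 ms).
#' @param prominence_fraction minimum prominence of the late peak as a
#'   fraction of the early peak's prominence (default 0.10).
#' @param separation_threshold threshold on the peak-separation statistic
#'   above which a class counts as having a late component (default 0.3).
#' @param separation_form `"dip_depth"` (default) or `"literal_ratio"`; see
#'   [separation_statistic()].
#' @param sentinel_ms late-latency value assigned when no late component
#'   exists (default 650 ms, beyond the observation window).
#' @param normalize_features cluster on per-electrode max-normalized PSTHs
#'   instead of raw values (default `FALSE`).
#' @param nstart,iter_max k-means restarts and iteration cap.
#' @param seed RNG seed making the clustering deterministic.
#' @return A list of class `classification_config`.
#' @export
classification_config <- function(k_range = 2:8, smoothing_ms = 50,
                                  early_limit_ms = 52,
                                  prominence_fraction = 0.10,
                                  separation_threshold = 0.3,
                                  separation_form = c("dip_depth", "literal_ratio"),
                                  sentinel_ms = 650,
                                  normalize_features = FALSE,
                                  nstart = 10L, iter_max = 100L, seed = 1L) {
  stopifnot(all(k_range >= 1), smoothing_ms > 0, early_limit_ms > 0,
            prominence_fraction > 0, separation_threshold > 0, sentinel_ms > 0)
  structure(list(k_range = sort(unique(as.integer(k_range))),
                 smoothing_ms = smoothing_ms,
                 early_limit_ms = early_limit_ms,
                 prominence_fraction = prominence_fraction,
                 separation_threshold = separation_threshold,
                 separation_form = match.arg(separation_form),
                 sentinel_ms = sentinel_ms,
                 normalize_features = normalize_features,
                 nstart = as.integer(nstart), iter_max = as.integer(iter_max),
                 seed = as.integer(seed)),
            class = "classification_config")
}

with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Cluster PSTH profiles with k-means and silhouette model selection
#'
#' Feature vectors are the binned PSTH values (one row per responsive
#' electrode). For every candidate `k` (restricted to at most `n - 1` and to
#' the number of distinct profiles), k-means is run with multiple restarts
#' under a fixed seed and the mean silhouette width (Euclidean distance) is
#' evaluated; the `k` with the largest mean silhouette wins. When fewer than
#' two distinct profiles exist (silhouette undefined) a single class is
#' returned.
#'
#' @param psths list of responsive `psth` objects.
#' @param config a [classification_config()].
#' @return List with `labels` (named integer vector), `k`, `silhouette`
#'   (named per-k mean silhouette widths), `centers` (k x bins matrix).
#' @export
classify_psths <- function(psths, config = classification_config()) {
  if (length(psths) == 0) stop("classify_psths: no PSTHs", call. = FALSE)
  X <- psth_matrix(psths)
  if (config$normalize_features) {
    mx <- apply(X, 1, max)
    X <- X / ifelse(mx > 0, mx, 1)
  }
  n <- nrow(X)
  n_distinct <- nrow(unique(X))
  ks <- config$k_range[config$k_range <= n - 1 & config$k_range <= n_distinct &
                       config$k_range >= 2]
  one_class <- function() {
    list(labels = stats::setNames(rep(1L, n), rownames(X)), k = 1L,
         silhouette = stats::setNames(numeric(0), character(0)),
         centers = matrix(colMeans(X), nrow = 1))
  }
  if (n_distinct < 2 || length(ks) == 0) return(one_class())
  d <- stats::dist(X)
  fits <- with_preserved_rng(config$seed, {
    lapply(ks, function(k) {
      km <- stats::kmeans(X, centers = k, nstart = config$nstart,
                          iter.max = config$iter_max)
      sil <- cluster::silhouette(km$cluster, d)
      list(k = k, km = km, mean_sil = mean(sil[, "sil_width"]))
    })
  })
  sils <- vapply(fits, function(f) f$mean_sil, 0)
  best <- fits[[which.max(sils)]]
  list(labels = stats::setNames(as.integer(best$km$cluster), rownames(X)),
       k = best$k,
       silhouette = stats::setNames(sils, ks),
       centers = best$km$centers)
}

#' Centered moving average with shrinking edges
#'
#' @param x numeric vector.
#' @param window_bins odd window length in bins; at the edges the window is
#'   truncated to the available bins (shrinking-window mean), so the output
#'   has the same length as the input and a constant input is unchanged.
#' @return Smoothed vector.
#' @export
moving_average <- function(x, window_bins) {
  stopifnot(window_bins >= 1, window_bins %% 2 == 1)
  n <- length(x)
  h <- (window_bins - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

smoothing_bins <- function(smoothing_ms, bin_ms) {
  2L * as.integer(floor(smoothing_ms / (2 * bin_ms))) + 1L
}

#' Class-mean PSTH and its smoothed profile
#'
#' Averages the member PSTHs bin-wise and applies a centered moving average.
#' A 50 ms window at 4 ms bins becomes 13 bins (52 ms): the nearest odd bin
#' count, so peak positions are not shifted.
#'
#' @param psths list of member `psth` objects (at least one).
#' @param smoothing_ms moving-average window in ms (default 50).
#' @return List with `mean_psth` and `psth_smooth` (numeric vectors),
#'   `bin_ms`, and `window_bins` used for smoothing.
#' @export
class_mean_and_smooth <- function(psths, smoothing_ms = 50) {
  stopifnot(length(psths) >= 1)
  m <- psth_matrix(psths)
  mean_psth <- colMeans(m)
  w <- smoothing_bins(smoothing_ms, psths[[1]]$bin_ms)
  list(mean_psth = mean_psth,
       psth_smooth = moving_average(mean_psth, w),
       bin_ms = psths[[1]]$bin_ms, window_bins = w)
}

# indices of local maxima; plateaus contribute their first bin, edges count
local_maxima <- function(v) {
  n <- length(v)
  if (n == 1) return(1L)
  left <- c(-Inf, v[-n])
  right <- c(v[-1], -Inf)
  which(v > left & v >= right)
}

# prominence of peak i: height minus the higher of the two bases, where each
# base is the minimum between the peak and the nearest higher point (or the
# array edge); a side with no samples (peak at the edge) imposes no base
peak_prominence <- function(v, i) {
  h <- v[i]
  n <- length(v)
  left_min <- Inf
  j <- i - 1
  while (j >= 1 && v[j] <= h) {
    left_min <- min(left_min, v[j])
    j <- j - 1
  }
  right_min <- Inf
  j <- i + 1
  while (j <= n && v[j] <= h) {
    right_min <- min(right_min, v[j])
    j <- j + 1
  }
  bases <- c(left_min, right_min)
  bases <- bases[is.finite(bases)]
  if (length(bases) == 0) return(h)
  h - max(bases)
}

#' Early and late peaks of a smoothed class PSTH
#'
#' The early peak `x1` is the highest local maximum with bin centre within
#' the first `early_limit_ms` (52 ms by default). When an early peak exists,
#' a late peak `x2` is sought among local maxima beyond the early limit whose
#' prominence is at least `prominence_fraction` (10%) of the early peak's
#' prominence; the highest qualifying maximum wins. With no early peak the
#' class is non-responding for latency purposes.
#'
#' @param psth_smooth smoothed class profile (one value per bin).
#' @param config a [classification_config()].
#' @param bin_ms bin width in ms (default 4).
#' @return List with `x1_ms`, `x1_bin`, `x1_prominence`, `x2_ms`, `x2_bin`,
#'   `x2_prominence` (`NA` where absent).
#' @export
find_early_late_peaks <- function(psth_smooth, config = classification_config(),
                                  bin_ms = 4) {
  centers <- (seq_along(psth_smooth) - 0.5) * bin_ms
  peaks <- local_maxima(psth_smooth)
  none <- list(x1_ms = NA_real_, x1_bin = NA_integer_, x1_prominence = NA_real_,
               x2_ms = NA_real_, x2_bin = NA_integer_, x2_prominence = NA_real_)
  early <- peaks[centers[peaks] <= config$early_limit_ms]
  early <- early[psth_smooth[early] > 0]
  if (length(early) == 0) return(none)
  x1_bin <- early[which.max(psth_smooth[early])]
  x1_prom <- peak_prominence(psth_smooth, x1_bin)
  out <- none
  out$x1_ms <- centers[x1_bin]
  out$x1_bin <- x1_bin
  out$x1_prominence <- x1_prom
  late <- peaks[centers[peaks] > config$early_limit_ms]
  if (length(late)) {
    proms <- vapply(late, function(i) peak_prominence(psth_smooth, i), 0)
    qual <- late[proms >= config$prominence_fraction * x1_prom]
    if (length(qual)) {
      x2_bin <- qual[which.max(psth_smooth[qual])]
      out$x2_ms <- centers[x2_bin]
      out$x2_bin <- x2_bin
      out$x2_prominence <- peak_prominence(psth_smooth, x2_bin)
    }
  }
  out
}

#' Separation statistic between the early and late peaks
#'
#' Locates the local minimum `x_min` of the smoothed profile strictly
#' between the two peaks and quantifies how well the dip separates them.
#' The default `dip_depth` form is
#' `s = 1 - v / sqrt(p1 * p2)` where `v` is the profile at `x_min` and
#' `p1`, `p2` the profile at the two peaks: `s` is 1 for a dip to zero and 0
#' when the valley reaches the geometric mean of the peaks, so `s` grows
#' with separation and `s > 0.3` flags a genuine late component. The
#' `literal_ratio` form `s = v / (p1 * p2)` is provided for comparison.
#'
#' @param psth_smooth smoothed class profile.
#' @param x1_bin,x2_bin bin indices of the early and late peaks
#'   (`x1_bin < x2_bin`, profile positive at both).
#' @param form `"dip_depth"` or `"literal_ratio"`.
#' @param bin_ms bin width in ms.
#' @return List with `s`, `x_min_ms`, `x_min_bin`, `form`.
#' @export
separation_statistic <- function(psth_smooth, x1_bin, x2_bin,
                                 form = c("dip_depth", "literal_ratio"),
                                 bin_ms = 4) {
  form <- match.arg(form)
  stopifnot(x1_bin < x2_bin)
  p1 <- psth_smooth[x1_bin]
  p2 <- psth_smooth[x2_bin]
  if (p1 <= 0 || p2 <= 0) {
    stop("separation_statistic: profile not positive at the peaks", call. = FALSE)
  }
  interior <- (x1_bin + 1):(x2_bin - 1)
  if (length(interior) == 0 || x2_bin - x1_bin < 2) {
    stop("separation_statistic: no bins between the peaks", call. = FALSE)
  }
  x_min_bin <- interior[which.min(psth_smooth[interior])]
  v <- psth_smooth[x_min_bin]
  s <- switch(form,
              dip_depth = 1 - v / sqrt(p1 * p2),
              literal_ratio = v / (p1 * p2))
  list(s = s, x_min_ms = (x_min_bin - 0.5) * bin_ms, x_min_bin = x_min_bin,
       form = form)
}

#' Full response classification of a set of PSTHs
#'
#' Runs the class-level analysis end to end: k-means clustering with
#' silhouette model selection, class-mean smoothing, early/late peak
#' detection, and the separation statistic with its threshold. A class has a
#' late component (`has_late`) when a qualifying late peak exists and the
#' separation statistic exceeds the threshold; `time_threshold_ms` (the
#' dip location `x_min`) then divides early from late responses for the
#' class's electrodes. Classes without an early peak are marked
#' non-responding.
#'
#' @param psths list of responsive `psth` objects.
#' @param config a [classification_config()].
#' @return List of class `response_classification` with `classes` (list of
#'   per-class records), `labels`, `k`, `silhouette`, `config`.
#' @export
classify_responses <- function(psths, config = classification_config()) {
  cl <- classify_psths(psths, config)
  bin_ms <- psths[[1]]$bin_ms
  classes <- lapply(seq_len(cl$k), function(j) {
    members <- names(cl$labels)[cl$labels == j]
    ms <- class_mean_and_smooth(psths[members], config$smoothing_ms)
    pk <- find_early_late_peaks(ms$psth_smooth, config, bin_ms)
    rec <- list(class_id = j, member_electrodes = members,
                mean_psth = ms$mean_psth, psth_smooth = ms$psth_smooth,
                x1_ms = pk$x1_ms, x2_ms = pk$x2_ms,
                x1_prominence = pk$x1_prominence,
                x2_prominence = pk$x2_prominence,
                x_min_ms = NA_real_, s = NA_real_,
                separation_form = config$separation_form,
                has_late = FALSE,
                non_responding = is.na(pk$x1_ms),
                time_threshold_ms = NA_real_)
    if (!is.na(pk$x1_ms) && !is.na(pk$x2_ms)) {
      sep <- separation_statistic(ms$psth_smooth, pk$x1_bin, pk$x2_bin,
                                  config$separation_form, bin_ms)
      rec$x_min_ms <- sep$x_min_ms
      rec$s <- sep$s
      if (sep$s > config$separation_threshold) {
        rec$has_late <- TRUE
        rec$time_threshold_ms <- sep$x_min_ms
      } else {
        rec$x2_ms <- NA_real_   # peaks not separable: early-only class
      }
    }
    rec
  })
  structure(list(classes = classes, labels = cl$labels, k = cl$k,
                 silhouette = cl$silhouette, config = config),
            class = "response_classification")
}

#' @export
print.response_classification <- function(x, ...) {
  cat(sprintf("<response_classification> k = %d over %d electrodes\n",
              x$k, length(x$labels)))
  for (cls in x$classes) {
    cat(sprintf("  class %d: %d electrodes, x1 = %s ms, x2 = %s ms, s = %s%s\n",
                cls$class_id, length(cls$member_electrodes),
                format(cls$x1_ms), format(cls$x2_ms),
                format(round(cls$s, 3)),
                if (cls$has_late) " [late]" else ""))
  }
  invisible(x)
}

#' Per-electrode early and late latencies
#'
#' Assigns latencies to every classified electrode from its own PSTH,
#' bounded by the structure of its class: the early latency is the bin
#' centre of the largest PSTH value up to `min(early_limit, class time
#' threshold)`; when the class has a late component the late latency is the
#' largest value beyond the class time threshold, otherwise the sentinel
#' (650 ms, beyond the observation window) is assigned. Electrodes of
#' non-responding classes get `NA` latencies and are excluded from latency
#' statistics.
#'
#' @param psths list of the classified `psth` objects.
#' @param classification result of [classify_responses()].
#' @param config a [classification_config()] (defaults to the one stored in
#'   `classification`).
#' @return Data frame with `electrode_id`, `class_id`, `early_latency_ms`,
#'   `late_latency_ms`, `has_late`, `non_responding`.
#' @export
assign_latencies <- function(psths, classification,
                             config = classification$config) {
  labels <- classification$labels
  ids <- vapply(psths, function(p) p$electrode_id, "")
  missing <- setdiff(ids, names(labels))
  if (length(missing)) {
    stop("assign_latencies: electrode without class: ", missing[1],
         call. = FALSE)
  }
  rows <- lapply(psths, function(p) {
    j <- labels[[p$electrode_id]]
    cls <- classification$classes[[j]]
    centers <- (seq_along(p$values) - 0.5) * p$bin_ms
    if (cls$non_responding) {
      return(data.frame(electrode_id = p$electrode_id, class_id = j,
                        early_latency_ms = NA_real_, late_latency_ms = NA_real_,
                        has_late = FALSE, non_responding = TRUE,
                        stringsAsFactors = FALSE))
    }
    bound <- if (cls$has_late) min(config$early_limit_ms, cls$time_threshold_ms)
             else config$early_limit_ms
    early_bins <- which(centers <= bound)
    early <- centers[early_bins[which.max(p$values[early_bins])]]
    if (cls$has_late) {
      late_bins <- which(centers > cls$time_threshold_ms)
      late <- centers[late_bins[which.max(p$values[late_bins])]]
    } else {
      late <- config$sentinel_ms
    }
    data.frame(electrode_id = p$electrode_id, class_id = j,
               early_latency_ms = early, late_latency_ms = late,
               has_late = cls$has_late, non_responding = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
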