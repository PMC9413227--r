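#' Kolmogorov-Smirnov normality screening
#'
#' Screens each group for normality before the nonparametric comparisons.
#' Because the normal parameters are estimated from the sample, the
#' Lilliefors correction of the one-sample KS test is used for the decision;
#' the plain KS statistic against the fitted normal is reported alongside.
#' The screen is advisory: the pipeline always proceeds nonparametrically,
#' and evoked-response measures essentially never pass it.
#'
#' @param samples named list of numeric vectors (each of length >= 3).
#' @param alpha significance level for the decision (default 0.05).
#' @return Data frame with one row per group: `group`, `n`, `statistic`
#'   (Lilliefors D), `p_value`, `normal` (not rejected at `alpha`),
#'   `degenerate` (zero variance; normality rejected by convention).
#' @export
normality_screen <- function(samples, alpha = 0.05) {
  stopifnot(is.list(samples), length(samples) >= 1)
  if (is.null(names(samples))) names(samples) <- paste0("g", seq_along(samples))
  rows <- lapply(names(samples), function(g) {
    x <- samples[[g]]
    if (length(x) < 3) {
      stop("normality_screen: group '", g, "' has fewer than 3 values",
           call. = FALSE)
    }
    if (stats::sd(x) == 0) {
      return(data.frame(group = g, n = length(x), statistic = NA_real_,
                        p_value = NA_real_, normal = FALSE, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    lt <- nortest::lillie.test(x)
    data.frame(group = g, n = length(x),
               statistic = unname(lt$statistic), p_value = lt$p.value,
               normal = lt$p.value >= alpha, degenerate = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis comparison with group descriptors
#'
#' Rank-based nonparametric comparison of two or more independent groups,
#' computed on midranks with tie correction (latencies quantized at the
#' 4 ms bin width are heavily tied). Differences are called significant at
#' p < 0.05. Descriptors report mean, standard deviation, median and
#' quartiles per group for box-plot-style summaries. No multiple-testing
#' correction is applied; callers comparing many cells should count their
#' comparisons (see [site_comparisons()]).
#'
#' @param groups named list of at least two non-empty numeric vectors.
#' @param alpha significance level (default 0.05).
#' @return Object of class `mea_comparison`: list with `H`, `df`, `p_value`,
#'   `significant`, `alpha`, `descriptors` (data frame per group).
#' @export
kruskal_wallis <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes == 0)) {
    stop("kruskal_wallis: empty group '", names(groups)[sizes == 0][1], "'",
         call. = FALSE)
  }
  kt <- stats::kruskal.test(groups)
  desc <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(x), mean = mean(x), sd = stats::sd(x),
               q25 = q[1], median = q[2], q75 = q[3],
               stringsAsFactors = FALSE)
  }))
  rownames(desc) <- NULL
  structure(list(H = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value, significant = kt$p.value < alpha,
                 alpha = alpha, descriptors = desc),
            class = "mea_comparison")
}

#' @export
print.mea_comparison <- function(x, ...) {
  cat(sprintf("<mea_comparison> H = %.4g (df = %d), p = %.3g%s\n",
              x$H, x$df, x$p_value, if (x$significant) " *" else ""))
  print(x$descriptors, row.names = FALSE)
  invisible(x)
}

#' Stimulation-site comparison table
#'
#' Given per-observation response values labeled by population (e.g. Cx/Hp),
#' compartment, and stimulated compartment, computes (a) pairwise
#' population comparisons per compartment per stimulation site and (b)
#' within-population comparisons across compartments per stimulation site,
#' all with [kruskal_wallis()]. Cells with fewer than two groups or with an
#' empty group are skipped. The number of comparisons performed is attached
#' so users can apply their own multiplicity correction; raw p-values are
#' reported.
#'
#' @param data data frame with columns `value`, `population`, `compartment`,
#'   `stim_compartment` (extra columns ignored).
#' @param alpha significance level (default 0.05).
#' @return Tidy data frame: `comparison`, `stim_compartment`, `compartment`,
#'   `groups`, `n` (total), `H`, `p_value`, `significant`.
#' @export
site_comparisons <- function(data, alpha = 0.05) {
  need <- c("value", "population", "compartment", "stim_compartment")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("site_comparisons: missing column '", miss[1], "'", call. = FALSE)
  }
  data <- data[!is.na(data$value), , drop = FALSE]
  rows <- list()
  add_row <- function(comparison, stim, comp, groups) {
    groups <- groups[lengths(groups) > 0]
    if (length(groups) < 2) return()
    kw <- kruskal_wallis(groups, alpha)
    rows[[length(rows) + 1]] <<- data.frame(
      comparison = comparison, stim_compartment = stim, compartment = comp,
      groups = paste(names(groups), collapse = " vs "),
      n = sum(lengths(groups)), H = kw$H, p_value = kw$p_value,
      significant = kw$significant, stringsAsFactors = FALSE)
  }
  stims <- sort(unique(data$stim_compartment))
  comps <- sort(unique(data$compartment))
  pops <- sort(unique(data$population))
  for (st in stims) {
    d_st <- data[data$stim_compartment == st, , drop = FALSE]
    # between populations, per compartment
    if (length(pops) >= 2) {
      for (cp in comps) {
        d <- d_st[d_st$compartment == cp, , drop = FALSE]
        add_row("between_population", st, cp, split(d$value, d$population))
      }
    }
    # within population, across compartments
    for (p in pops) {
      d <- d_st[d_st$population == p, , drop = FALSE]
      add_row(paste0("within_", p), st, NA_character_,
              split(d$value, d$compartment))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(comparison = character(0), stim_compartment = character(0),
               compartment = character(0), groups = character(0),
               n = integer(0), H = numeric(0), p_value = numeric(0),
               significant = logical(0), stringsAsFactors = FALSE)
  attr(out, "n_comparisons") <- nrow(out)
  out
}
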