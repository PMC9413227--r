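test_that("moving average is centered, shrinking at edges, mass-aware", {
  expect_equal(moving_average(rep(2.5, 150), 13), rep(2.5, 150))
  imp <- rep(0, 150); imp[75] <- 1
  sm <- moving_average(imp, 13)
  expect_equal(sm[69:81], rep(1 / 13, 13))
  expect_equal(sum(sm[-(69:81)]), 0)
  # impulse at the first bin: window shrinks to 7 bins
  imp1 <- rep(0, 150); imp1[1] <- 1
  expect_equal(moving_average(imp1, 13)[1], 1 / 7)
  # 50 ms at 4 ms bins realizes as 13 bins
  expect_identical(meaevoked:::smoothing_bins(50, 4), 13L)
})

test_that("class mean of identical members equals the member", {
  v <- two_bump_profile(20, 1, 8)
  ps <- list(profile_as_psth("a", v), profile_as_psth("b", v))
  ms <- class_mean_and_smooth(ps)
  expect_equal(ms$mean_psth, v, ignore_attr = TRUE)
  expect_equal(ms$psth_smooth, moving_average(v, 13))
})

test_that("early and late peaks are located within a bin of the bumps", {
  v <- two_bump_profile(15, 1.0, 6, c2_ms = 199, a2 = 0.5, sd2_ms = 30)
  pk <- find_early_late_peaks(v)
  expect_lte(abs(pk$x1_ms - 15), 4)
  expect_lte(abs(pk$x2_ms - 199), 4)
  # oracle: the strict local maxima of the profile sit where the peaks were put
  lm <- oracle_strict_local_maxima(v)
  expect_true(pk$x1_bin %in% lm && pk$x2_bin %in% lm)

  # unimodal profile: no late peak
  pk1 <- find_early_late_peaks(two_bump_profile(10, 1, 5))
  expect_true(is.na(pk1$x2_ms))
  expect_lte(abs(pk1$x1_ms - 10), 4)

  # late bump with 5% prominence fails the 10% gate
  weak <- two_bump_profile(15, 1.0, 6, c2_ms = 250, a2 = 0.05, sd2_ms = 30)
  pk2 <- find_early_late_peaks(weak)
  expect_true(is.na(pk2$x2_ms))

  # no early peak at all: non-responding
  late_only <- two_bump_profile(300, 1, 30)
  pk3 <- find_early_late_peaks(late_only)
  expect_true(is.na(pk3$x1_ms))
})

test_that("separation statistic matches direct formula evaluation", {
  # piecewise profile with exactly known peak and valley values
  mk <- function(p1, v, p2) {
    prof <- rep(0.01, 150)
    prof[5] <- p1        # 18 ms
    prof[50] <- v        # 198 ms  (forced interior minimum below baseline?)
    prof[100] <- p2      # 398 ms
    prof
  }
  # dip to zero: s = 1
  prof <- mk(1, 0.01, 0.5); prof[30] <- 0
  s1 <- separation_statistic(prof, 5, 100, "dip_depth")
  expect_equal(s1$s, 1)
  expect_identical(s1$x_min_bin, 30L)

  # valley exactly at the geometric mean: s = 0
  prof2 <- rep(sqrt(0.5), 150); prof2[5] <- 1; prof2[100] <- 0.5
  s2 <- separation_statistic(prof2, 5, 100, "dip_depth")
  expect_equal(s2$s, 0)

  # frozen value: p1 = 1, p2 = 0.5, v = 0.35 -> 1 - 0.35/sqrt(0.5)
  prof3 <- rep(0.4, 150); prof3[5] <- 1; prof3[100] <- 0.5; prof3[60] <- 0.35
  s3 <- separation_statistic(prof3, 5, 100, "dip_depth")
  expect_equal(s3$s, 1 - 0.35 / sqrt(0.5))
  expect_gt(s3$s, 0.3)

  # literal product-ratio form
  s4 <- separation_statistic(prof3, 5, 100, "literal_ratio")
  expect_equal(s4$s, 0.35 / (1 * 0.5))
})

test_that("silhouette selects the constructed number of clusters", {
  set.seed(5)
  mk_cluster <- function(center_ms, n, prefix) {
    lapply(seq_len(n), function(i) {
      v <- two_bump_profile(center_ms, 1, 10) + rnorm(150, 0, 0.01)
      profile_as_psth(paste0(prefix, i), pmax(v, 0))
    })
  }
  ps <- c(mk_cluster(30, 8, "a"), mk_cluster(200, 8, "b"),
          mk_cluster(450, 8, "c"))
  names(ps) <- vapply(ps, function(p) p$electrode_id, "")
  cl <- classify_psths(ps, classification_config(k_range = 2:6, seed = 3))
  expect_identical(cl$k, 3L)
  # exhaustively verify the silhouette maximum really is at k = 3
  expect_identical(names(which.max(cl$silhouette)), "3")
  # members of each construction group share a label
  for (pre in c("a", "b", "c")) {
    labs <- cl$labels[startsWith(names(cl$labels), pre)]
    expect_identical(length(unique(labs)), 1L)
  }
})

test_that("degenerate identical profiles collapse to a single class", {
  v <- two_bump_profile(20, 1, 8)
  ps <- lapply(1:6, function(i) profile_as_psth(paste0("e", i), v))
  names(ps) <- paste0("e", 1:6)
  cl <- classify_psths(ps)
  expect_identical(cl$k, 1L)
  expect_true(all(cl$labels == 1L))
  expect_error(classify_psths(list()), "no PSTHs")
})

test_that("classification is deterministic and scale invariant", {
  sim <- simulate_psth_classes(seed = 9)
  cfg <- classification_config(seed = 17)
  r1 <- classify_responses(sim$psths, cfg)
  r2 <- classify_responses(sim$psths, cfg)
  expect_identical(r1$labels, r2$labels)
  expect_equal(r1$classes, r2$classes)

  scaled <- lapply(sim$psths, function(p) {
    p$values <- p$values * 4.2; p$area <- p$area * 4.2; p
  })
  r3 <- classify_responses(scaled, cfg)
  expect_identical(r3$labels, r1$labels)
  expect_equal(vapply(r3$classes, function(c) c$x1_ms, 0),
               vapply(r1$classes, function(c) c$x1_ms, 0))
  expect_equal(vapply(r3$classes, function(c) c$s, 0),
               vapply(r1$classes, function(c) c$s, 0))
})

test_that("late-component flags recover the generator's class structure", {
  n_ok <- 0; n_all <- 0
  for (seed in 1:10) {
    sim <- simulate_psth_classes(seed = seed)
    res <- classify_responses(sim$psths, classification_config(seed = 1))
    truth <- setNames(sim$truth$has_late, sim$truth$electrode_id)
    for (cls in res$classes) {
      maj <- mean(truth[cls$member_electrodes]) > 0.5
      n_all <- n_all + 1
      n_ok <- n_ok + (cls$has_late == maj)
      if (cls$has_late) {
        expect_gt(cls$s, 0.3)
        expect_lt(cls$x1_ms, cls$x_min_ms)
        expect_lt(cls$x_min_ms, cls$x2_ms)
        expect_lte(cls$x1_ms, 52)
        expect_gt(cls$x2_ms, 52)
      }
    }
  }
  expect_gte(n_ok / n_all, 0.95)
})

test_that("latencies follow the class windows and the 650 ms sentinel", {
  # early-only class, own peak at 20 ms
  early_only <- lapply(1:3, function(i) {
    profile_as_psth(paste0("e", i), two_bump_profile(20, 1.2, 4))
  })
  names(early_only) <- paste0("e", 1:3)
  res <- classify_responses(early_only, classification_config(seed = 1))
  lat <- assign_latencies(early_only, res)
  expect_equal(lat$early_latency_ms, rep(18, 3))   # bin [16,20) centre
  expect_equal(lat$late_latency_ms, rep(650, 3))
  expect_false(any(lat$has_late))

  # class with bumps at 12 and 180 ms: latencies split at x_min
  bimodal <- lapply(1:4, function(i) {
    profile_as_psth(paste0("b", i),
                    two_bump_profile(12, 1.2, 5, c2_ms = 180, a2 = 0.8,
                                     sd2_ms = 25))
  })
  names(bimodal) <- paste0("b", 1:4)
  res2 <- classify_responses(bimodal, classification_config(seed = 1))
  expect_true(res2$classes[[1]]$has_late)
  lat2 <- assign_latencies(bimodal, res2)
  expect_true(all(abs(lat2$early_latency_ms - 12) <= 4))
  expect_true(all(abs(lat2$late_latency_ms - 180) <= 4))
  # argmax on each side of the class time threshold, by direct scan
  tt <- res2$classes[[1]]$time_threshold_ms
  centers <- (seq_len(150) - 0.5) * 4
  v <- bimodal[[1]]$values
  expect_equal(lat2$early_latency_ms[1],
               centers[centers <= min(52, tt)][which.max(v[centers <= min(52, tt)])])
  expect_equal(lat2$late_latency_ms[1],
               centers[centers > tt][which.max(v[centers > tt])])

  # electrode without a class is an error
  stray <- profile_as_psth("zz", two_bump_profile(20, 1.2, 4))
  expect_error(assign_latencies(c(early_only, list(zz = stray)), res),
               "without class")
})

test_that("classes lacking an early peak are non-responding", {
  late_only <- lapply(1:3, function(i) {
    profile_as_psth(paste0("L", i), two_bump_profile(300, 1.5, 30))
  })
  names(late_only) <- paste0("L", 1:3)
  res <- classify_responses(late_only, classification_config(seed = 1))
  expect_true(all(vapply(res$classes, function(c) c$non_responding, TRUE)))
  lat <- assign_latencies(late_only, res)
  expect_true(all(is.na(lat$early_latency_ms)))
  expect_true(all(lat$non_responding))
})
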