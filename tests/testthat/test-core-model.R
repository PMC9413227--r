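test_that("standard layout has 120 distinct electrodes with corners absent", {
  lay <- mea_layout()
  expect_length(lay$electrode_ids, 120)
  expect_false(anyDuplicated(lay$electrode_ids) > 0)
  expect_false(anyDuplicated(lay$positions[, c("x", "y")]) > 0)
  # the four extreme corner positions are not populated
  expect_false("R01C01" %in% lay$electrode_ids)
  expect_false("R01C12" %in% lay$electrode_ids)
  expect_false("R12C01" %in% lay$electrode_ids)
  expect_false("R12C12" %in% lay$electrode_ids)
  # mid-edge electrodes are
  expect_true("R01C06" %in% lay$electrode_ids)
  full <- mea_layout(drop_corners = FALSE)
  expect_length(full$electrode_ids, 144)
})

test_that("compartment assignment is a partition with unassigned channels", {
  lay <- mea_layout()
  comp <- assign_compartments(lay)
  expect_s3_class(comp, "mea_compartments")
  expect_setequal(names(comp), lay$electrode_ids)
  # channel strip (column 7) stays unassigned
  col7 <- lay$positions$electrode_id[lay$positions$col == 7]
  expect_true(all(is.na(comp[col7])))
  # an electrode well inside the big chamber is assigned to it
  expect_identical(unname(comp["R06C03"]), "big")
  expect_identical(unname(comp["R03C10"]), "small_left")
  expect_identical(unname(comp["R09C10"]), "small_right")
})

test_that("disjoint rectangles tiling the array assign every electrode", {
  lay <- mea_layout()
  p <- lay$pitch_um
  tiles <- list(
    rect_region("a", c(-100, 3 * p + 100), c(-100, 11 * p + 100)),
    rect_region("b", c(4 * p - 100, 7 * p + 100), c(-100, 11 * p + 100)),
    rect_region("c", c(8 * p - 100, 11 * p + 100), c(-100, 11 * p + 100))
  )
  comp <- assign_compartments(lay, tiles)
  expect_false(anyNA(comp))
  # brute-force point-in-region check per electrode
  pos <- lay$positions
  brute <- vapply(seq_len(nrow(pos)), function(i) {
    hits <- vapply(tiles, function(r) {
      pos$x[i] >= r$xlim[1] && pos$x[i] <= r$xlim[2] &&
        pos$y[i] >= r$ylim[1] && pos$y[i] <= r$ylim[2]
    }, TRUE)
    tiles[[which(hits)]]$label
  }, "")
  expect_identical(unname(comp[pos$electrode_id]), brute)
  expect_identical(sum(table(comp)), 120L)
})

test_that("overlapping compartment regions are a configuration error", {
  lay <- mea_layout()
  bad <- list(rect_region("a", c(-100, 1200), c(-100, 2300)),
              rect_region("b", c(1000, 2300), c(-100, 2300)))
  expect_error(assign_compartments(lay, bad), "overlapping")
})

test_that("spike train and recording invariants are enforced", {
  expect_error(spike_train("e1", c(1, 1, 2), 0, 10), "strictly increasing")
  expect_error(spike_train("e1", c(3, 2), 0, 10), "strictly increasing")
  expect_error(spike_train("e1", c(1, 11), 0, 10), "outside")
  expect_error(spike_train("e1", numeric(0), 5, 5), "t_stop")
  expect_error(stimulation_session("e1", numeric(0)), "no stimulus")

  lay <- small_layout()
  tr <- list(spike_train("R01C01", c(1, 2), 0, 601))
  expect_error(
    mea_recording(lay, tr, duration = 600,
                  sessions = list()),
    NA
  ) # t_stop past duration is fine as long as spikes are inside
  bad <- list(spike_train("R01C01", c(601), 0, 700))
  expect_error(mea_recording(lay, bad, duration = 600), "exceeds duration")
  unknown <- list(spike_train("nope", c(1), 0, 600))
  expect_error(mea_recording(lay, unknown, duration = 600), "unknown electrode")
})

test_that("json save/load round-trips exactly and deterministically", {
  g <- generate_recording(hp_profile(), n_sessions = 2, session_len = 50,
                          spont_len = 30, seed = 42)
  r <- g$recording
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  save_recording(r, f1)
  save_recording(r, f2)
  expect_identical(readLines(f1), readLines(f2))
  r2 <- load_recording(f1)
  keep <- c("layout", "trains", "sessions", "duration", "population_label")
  expect_equal(r2[keep], r[keep])
  expect_equal(unclass(r2$compartments), unclass(r$compartments))
})

test_that("csv directory dialect round-trips spike trains and sessions", {
  g <- generate_recording(hp_profile(), n_sessions = 1, session_len = 50,
                          spont_len = 30, seed = 5)
  d <- tempfile()
  save_recording(g$recording, d, format = "csv_dir")
  r2 <- load_recording(d)
  expect_equal(r2$trains, g$recording$trains)
  expect_equal(r2$sessions, g$recording$sessions)
  expect_equal(r2$duration, g$recording$duration)
})

test_that("empty and malformed files behave per contract", {
  lay <- mea_layout()
  trains <- lapply(lay$electrode_ids, function(id) {
    spike_train(id, numeric(0), 0, 600)
  })
  r <- mea_recording(lay, trains, duration = 600)   # zero sessions
  f <- tempfile(fileext = ".json")
  save_recording(r, f)
  r2 <- load_recording(f)
  expect_length(r2$trains, 120)
  expect_true(all(vapply(r2$trains, function(t) length(t$times) == 0, TRUE)))
  expect_length(r2$sessions, 0)

  # spike beyond the declared duration is rejected on load
  txt <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  txt$trains[[1]] <- list(601.0)
  f_bad <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(txt, auto_unbox = TRUE), f_bad)
  expect_error(load_recording(f_bad), "outside|exceeds")

  # missing schema field is named
  txt2 <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  txt2$meta$duration <- NULL
  f_bad2 <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(txt2, auto_unbox = TRUE), f_bad2)
  expect_error(load_recording(f_bad2), "duration")
})

test_that("round-trip holds across randomized recordings", {
  for (seed in c(101, 202, 303)) {
    g <- generate_recording(cx_profile(), n_sessions = 1, session_len = 30,
                            spont_len = 20, seed = seed)
    f <- tempfile(fileext = ".json")
    save_recording(g$recording, f)
    r2 <- load_recording(f)
    expect_equal(r2$trains, g$recording$trains)
    expect_equal(r2$sessions, g$recording$sessions)
  }
})
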