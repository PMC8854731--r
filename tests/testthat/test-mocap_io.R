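test_that("trajectory files parse, infer the sampling rate, and round-trip", {
  # hand-written 2-frame file with one marker
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("frame\ttime\tm1_X\tm1_Y\tm1_Z",
               "0\t0\t0\t0\t0",
               "1\t0.008333333333333333\t1\t2\t3"), f)
  rec <- read_marker_recording(f)
  expect_equal(rec$positions[1, 1, ], c(0, 0, 0))
  expect_equal(rec$positions[2, 1, ], c(1, 2, 3))
  expect_equal(rec$sampling_rate, 120, tolerance = 1e-9)
  expect_false(any(rec$missing_mask))

  # full-precision round trip incl. missing cells and column order
  rec <- toy_recording(50, c("ankle", "wrist", "head"), rate = 120, seed = 2)
  rec$missing_mask[10:12, 2] <- TRUE
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_marker_recording(rec, f2)
  header <- strsplit(readLines(f2, n = 1), "\t")[[1]]
  expect_identical(header[3:11],
                   c("ankle_X", "ankle_Y", "ankle_Z", "wrist_X", "wrist_Y",
                     "wrist_Z", "head_X", "head_Y", "head_Z"))
  # masked samples are empty cells in the file
  row11 <- strsplit(readLines(f2)[12], "\t", fixed = TRUE)[[1]]
  expect_identical(row11[6:8], c("", "", ""))
  back <- read_marker_recording(f2)
  expect_identical(back$marker_labels, rec$marker_labels)
  expect_equal(back$missing_mask, rec$missing_mask, ignore_attr = TRUE)
  obs <- !rec$missing_mask
  expect_identical(back$positions[rep(obs, 3)], rec$positions[rep(obs, 3)])
  expect_equal(back$sampling_rate, rec$sampling_rate, tolerance = 1e-12)
})

test_that("malformed trajectory files are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("frame\ttime\tm1_X\tm1_Y", "0\t0\t0\t0", "1\t1\t1\t1"), f)
  expect_error(read_marker_recording(f), "multiple of 3")
  writeLines(c("time\tframe\tm1_X\tm1_Y\tm1_Z", "0\t0\t0\t0\t0",
               "1\t1\t1\t1\t1"), f)
  expect_error(read_marker_recording(f), "malformed header")
  writeLines(c("frame\ttime\tm1_X\tm1_Y\tm1_Z", "0\t0\t0\t0\t0"), f)
  expect_error(read_marker_recording(f), "fewer than 2 frames")
  writeLines(c("frame\ttime\tm1_X\tm1_Y\tm1_Z", "0\t0.5\t0\t0\t0",
               "1\t0.2\t1\t1\t1"), f)
  expect_error(read_marker_recording(f), "increasing")
})

test_that("fill_gaps interpolates bounded interior gaps and only those", {
  rec <- toy_recording(10, "m1", rate = 100, seed = 3)
  truth <- rec$positions[5, 1, ]
  rec$positions[5, 1, ] <- c(-999, -999, -999)
  rec$missing_mask[5, 1] <- TRUE
  filled <- fill_gaps(rec, max_gap = 1)
  expect_equal(filled$positions[5, 1, ],
               (rec$positions[4, 1, ] + rec$positions[6, 1, ]) / 2)
  expect_false(any(filled$missing_mask))
  # linear midpoint example
  rec2 <- marker_recording(array(c(0, 1, 2,  0, 1, 2,  0, 1, 2), c(3, 1, 3)),
                           "m", 100, missing_mask = matrix(c(FALSE, TRUE, FALSE)))
  rec2$positions[2, 1, ] <- 0
  out <- fill_gaps(rec2, max_gap = 2)
  expect_equal(out$positions[2, 1, ], c(1, 1, 1))
  # identity on gap-free input
  clean <- toy_recording(20, "m1", seed = 4)
  expect_identical(fill_gaps(clean, 3), clean)
  # errors: long gap, boundary gap
  rec3 <- toy_recording(10, "m1", seed = 5)
  rec3$missing_mask[4:6, 1] <- TRUE
  expect_error(fill_gaps(rec3, max_gap = 2), "exceeds max_gap")
  rec4 <- toy_recording(10, "m1", seed = 6)
  rec4$missing_mask[1, 1] <- TRUE
  expect_error(fill_gaps(rec4, max_gap = 5), "boundary")
})

test_that("trim_to_window keeps [start, end) with frame = round(t * rate)", {
  rec <- toy_recording(1200, "m1", rate = 120, seed = 7)
  expect_equal(dim(trim_to_window(rec, 0, 10)$positions)[1], 1200)
  w <- trim_to_window(rec, 2, 3)
  expect_equal(dim(w$positions)[1], 120)
  expect_equal(w$positions[1, 1, ], rec$positions[241, 1, ])  # original frame 240
  full <- trim_to_window(rec, 0, 10)
  expect_equal(full$positions, rec$positions)
  expect_error(trim_to_window(rec, 3, 3), "start < end")
  expect_error(trim_to_window(rec, 0, 11), "exceeds recording duration")
})

test_that("trimmed frame counts match round((end - start) * rate)", {
  rec <- toy_recording(500, "m1", rate = 60, seed = 8)
  for (win in list(c(0, 2), c(0.5, 3.25), c(1.1, 7.9))) {
    got <- dim(trim_to_window(rec, win[1], win[2])$positions)[1]
    expect_equal(got, round(win[2] * 60) - round(win[1] * 60))
  }
})

test_that("the default joint map has 20 joints and 12 pair groups", {
  map <- default_joint_map()
  expect_length(map$joint_definitions, 20)
  expect_length(map$pair_groups, 12)
  expect_true(all(c(map$root_joint, map$left_hip_joint, map$right_hip_joint)
                  %in% names(map$joint_definitions)))
  expect_setequal(unlist(map$pair_groups), names(map$joint_definitions))
})

test_that("joint-map configuration files parse and validate", {
  # shipped default config equals the in-code default
  cfg <- system.file("extdata", "default_joint_map.cfg",
                     package = "kinedecode")
  map <- read_marker_joint_map(cfg)
  ref <- default_joint_map()
  expect_identical(map$joint_definitions, ref$joint_definitions)
  expect_identical(map$pair_groups, ref$pair_groups)
  expect_identical(map$root_joint, ref$root_joint)

  # write/read round trip
  f <- withr::local_tempfile(fileext = ".cfg")
  write_marker_joint_map(ref, f)
  expect_identical(read_marker_joint_map(f)$joint_definitions,
                   ref$joint_definitions)

  # validation errors
  lines <- readLines(cfg)
  writeLines(grep("^root =", lines, value = TRUE, invert = TRUE), f)
  expect_error(read_marker_joint_map(f), "root")
  writeLines(c(lines, "group extra = head"), f)
  expect_error(read_marker_joint_map(f), "more than one pair group")
  expect_error(marker_joint_map(list(a = character(0)), "a", "a", "a",
                                list(g = "a")),
               "at least one marker")
})
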