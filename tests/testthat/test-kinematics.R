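test_that("derive_joints averages mapped markers per frame", {
  pos <- array(0, c(5, 3, 3))
  pos[, 2, 1] <- 2            # marker b at (2,0,0)
  pos[, 3, 1] <- 3            # marker c at (3,0,0)
  rec <- marker_recording(pos, c("a", "b", "c"), 100)
  map1 <- marker_joint_map(list(j1 = "a", j2 = "b", j3 = "c"),
                           "j1", "j2", "j3",
                           list(g1 = "j1", g2 = "j2", g3 = "j3"))
  jr <- derive_joints(rec, map1)
  expect_equal(jr$values[, 1, ], pos[, 1, ])          # single marker identity
  # midpoint of (0,0,0) and (2,0,0)
  map2 <- marker_joint_map(list(mid = c("a", "b"), j3 = "c"),
                           "mid", "mid", "j3",
                           list(g1 = "mid", g2 = "j3"))
  expect_equal(derive_joints(rec, map2)$values[1, 1, ], c(1, 0, 0))
  # mean of three markers at (0,0,0), (3,0,0), (0,3,0)
  pos3 <- array(0, c(2, 3, 3))
  pos3[, 2, 1] <- 3
  pos3[, 3, 2] <- 3
  rec3 <- marker_recording(pos3, c("a", "b", "c"), 100)
  map3 <- marker_joint_map(list(tri = c("a", "b", "c"), solo = "a"),
                           "tri", "tri", "solo",
                           list(g1 = "tri", g2 = "solo"))
  expect_equal(derive_joints(rec3, map3)$values[1, 1, ], c(1, 1, 0))
  # errors
  badmap <- marker_joint_map(list(j = "nope"), "j", "j", "j", list(g = "j"))
  expect_error(derive_joints(rec, badmap), "not present")
  rec$missing_mask[2, 1] <- TRUE
  expect_error(derive_joints(rec, map1), "missing samples")
})

test_that("to_local_coordinates centres the root and aligns the hips", {
  rec <- toy_marker_recording(duration = 2, rate = 60, seed = 9)
  map <- default_joint_map()
  loc <- to_local_coordinates(derive_joints(rec, map), map)
  ir <- match("root", loc$joint_labels)
  ihr <- match("hip_r", loc$joint_labels)
  il <- match("hip_l", loc$joint_labels)
  expect_lt(max(abs(loc$values[, ir, ])), 1e-9)
  # hip line along the mediolateral axis: zero anteroposterior component
  expect_lt(max(abs(loc$values[, ihr, 2] - loc$values[, il, 2])), 1e-9)
  expect_true(all(loc$values[, ihr, 1] - loc$values[, il, 1] > 0))
  # idempotence
  expect_equal(to_local_coordinates(loc, map)$values, loc$values)
})

test_that("local coordinates are invariant to global placement", {
  rec <- toy_marker_recording(duration = 2, rate = 60, seed = 10)
  map <- default_joint_map()
  ref <- to_local_coordinates(derive_joints(rec, map), map)
  th <- pi / 2
  moved <- rec
  x <- rec$positions[, , 1]; y <- rec$positions[, , 2]
  moved$positions[, , 1] <- cos(th) * x - sin(th) * y + 500
  moved$positions[, , 2] <- sin(th) * x + cos(th) * y + 500
  got <- to_local_coordinates(derive_joints(moved, map), map)
  expect_equal(got$values, ref$values, tolerance = 1e-10)
})

test_that("coincident hips make the rotation undefined", {
  vals <- array(0, c(5, 3, 3))
  vals[, 3, 3] <- 100   # third joint above, hips coincide at origin
  jr <- joint_recording(vals, c("root", "hl", "hr"), 60, "position", "global")
  map <- marker_joint_map(list(root = "root", hl = "hl", hr = "hr"),
                          "root", "hl", "hr",
                          list(g1 = "root", g2 = c("hl", "hr")))
  expect_error(to_local_coordinates(jr, map), "coincide")
})

test_that("Butterworth velocity is zero for constants and slope * rate for ramps", {
  n <- 200
  vals <- array(0, c(n, 2, 3))
  vals[, 1, ] <- 37                       # constant
  vals[, 2, 1] <- 2 * (seq_len(n) - 1)    # 2 mm/frame ramp
  jr <- toy_joint_recording(vals, rate = 120)
  v <- velocity_butterworth(jr)
  expect_lt(max(abs(v$values[, 1, ])), 1e-9)
  interior <- 30:(n - 30)
  expect_equal(v$values[interior, 2, 1], rep(240, length(interior)),
               tolerance = 1e-6)
})

test_that("Butterworth velocity matches the frozen reference implementation", {
  # Oracle: scipy.signal.butter(2, 24 / 60) + filtfilt of the explicit
  # central-difference stencil, frozen for the deterministic signal below.
  t <- 0:99
  x <- sin(0.31 * t) + 0.5 * sin(1.7 * t + 0.4) + 0.25 * sin(5.3 * t + 1.1)
  vals <- array(0, c(100, 1, 3))
  vals[, 1, 1] <- x
  v <- velocity_butterworth(toy_joint_recording(vals, rate = 120),
                            cutoff = 24, order = 2)$values[, 1, 1]
  expect_equal(v[1:5],
               c(41.78695728828805, 1.2351578011558768, 3.954424169777873,
                 32.692465959975685, 36.508138579158725), tolerance = 1e-9)
  expect_equal(sum(v), -147.50478725600652, tolerance = 1e-8)
  expect_equal(sum(v^2), 85537.48229463713, tolerance = 1e-6)
})

test_that("Butterworth velocity rejects unusable configurations", {
  vals <- array(withr::with_seed(1, rnorm(24)), c(8, 1, 3))
  jr <- toy_joint_recording(vals, rate = 40)
  expect_error(velocity_butterworth(jr, cutoff = 24), "Nyquist")
  expect_error(velocity_butterworth(jr, cutoff = 15), "warm-up")
})

test_that("Savitzky-Golay velocity is exact on low-degree polynomials", {
  n <- 60; fs <- 60
  tt <- (seq_len(n) - 1) / fs
  a <- 3.7
  vals <- array(0, c(n, 2, 3))
  vals[, 1, 1] <- a * tt^2
  vals[, 2, ] <- 5                        # constant
  v <- velocity_savgol(toy_joint_recording(vals, rate = fs))
  expect_equal(v$values[, 1, 1], 2 * a * tt, tolerance = 1e-8)
  expect_lt(max(abs(v$values[, 2, ])), 1e-8)
})

test_that("Savitzky-Golay velocity equals a windowed least-squares oracle", {
  n <- 100; fs <- 120
  x <- withr::with_seed(42, cumsum(rnorm(n)))
  vals <- array(0, c(n, 1, 3)); vals[, 1, 1] <- x
  v <- velocity_savgol(toy_joint_recording(vals, rate = fs),
                       window = 7, polyorder = 2)$values[, 1, 1]
  # oracle: per interior sample, fit a degree-2 polynomial to the 7-sample
  # window by lm() and evaluate its derivative at the centre
  for (i in seq(4, n - 3, by = 9)) {
    tt <- -3:3
    fit <- stats::lm(x[(i - 3):(i + 3)] ~ tt + I(tt^2))
    expect_equal(v[i], unname(coef(fit)[2]) * fs, tolerance = 1e-8)
  }
  expect_error(velocity_savgol(toy_joint_recording(vals, rate = fs),
                               window = 6), "odd")
})

test_that("both velocity estimators commute with sign flips", {
  rec <- toy_marker_recording(duration = 2, rate = 60, seed = 11)
  map <- default_joint_map()
  loc <- to_local_coordinates(derive_joints(rec, map), map)
  neg <- loc
  neg$values <- -neg$values
  expect_equal(velocity_butterworth(neg)$values,
               -velocity_butterworth(loc)$values, tolerance = 1e-9)
  expect_equal(velocity_savgol(neg)$values,
               -velocity_savgol(loc)$values, tolerance = 1e-9)
})
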