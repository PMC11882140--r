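test_that("sub-threshold points are linearly interpolated and masked", {
  tr <- tiny_track(x = c(0, 9, 2), likelihood = c(0.99, 0.50, 0.99))
  cl <- clean_pose(tr)
  expect_equal(cl$coords$nose_x, c(0, 1, 2))
  expect_equal(unname(cl$interpolated[, "nose"]), c(FALSE, TRUE, FALSE))
})

test_that("fully confident tracks pass through untouched", {
  tr <- tiny_track(x = c(0, 9, 2))
  cl <- clean_pose(tr)
  expect_equal(cl$coords$nose_x, c(0, 9, 2))
  expect_false(any(cl$interpolated))
})

test_that("edge dropouts are nearest-value filled and sparse parts error", {
  tr <- tiny_track(x = c(9, 1, 2, 3, 9), likelihood = c(0.1, 0.99, 0.99, 0.99, 0.2))
  cl <- clean_pose(tr)
  expect_equal(cl$coords$nose_x, c(1, 1, 2, 3, 3))
  bad <- tiny_track(x = 1:5, likelihood = c(0.99, 0.1, 0.1, 0.1, 0.1))
  expect_error(clean_pose(bad), "nose")
})

test_that("random dropout on a linear trajectory interpolates almost exactly", {
  n <- 400
  truth <- seq(0, 80, length.out = n)   # linear motion, step 0.2
  set.seed(10)
  lik <- ifelse(runif(n) < 0.09, 0.5, 0.99)
  lik[c(1, n)] <- 0.99
  x <- truth + ifelse(lik < 0.95, rnorm(n, 0, 30), 0)  # corrupted where dropped
  tr <- tiny_track(x = x, likelihood = lik)
  cl <- clean_pose(tr)
  step <- truth[2] - truth[1]
  expect_lt(max(abs(cl$coords$nose_x - truth)), step + 1e-9)
})

test_that("scale calibration averages pixel/physical distance over pairs", {
  expect_equal(calibrate_scale(rbind(c(0, 0), c(100, 0)), 10), 10)
  side <- 141.42
  square <- rbind(c(0, 0), c(side, 0), c(side, side), c(0, side))
  expect_equal(calibrate_scale(square, 10), 14.142)
  expect_error(calibrate_scale(rbind(c(1, 1), c(1, 1)), 10), "coincident")
})

test_that("scale is unbiased under zero-mean landmark jitter", {
  side <- 141.42
  square <- rbind(c(0, 0), c(side, 0), c(side, side), c(0, side))
  set.seed(4)
  est <- replicate(1000, calibrate_scale(square + rnorm(8, 0, 1), 10))
  expect_equal(mean(est), 14.142, tolerance = 0.005)
})

test_that("head position is the ear midpoint and is rotation-invariant", {
  n <- 20
  theta <- seq(0, 2 * pi, length.out = n)
  coords <- data.frame(
    ear_left_x = 5 + cos(theta), ear_left_y = 5 + sin(theta),
    ear_left_likelihood = rep(0.99, n),
    ear_right_x = 5 - cos(theta), ear_right_y = 5 - sin(theta),
    ear_right_likelihood = rep(0.99, n))
  tr <- structure(list(coords = coords, fps = 10, bodyparts = c("ear_left", "ear_right"),
                       landmarks = character(0), landmark_spacing = NA,
                       view = "above", units = "cm"),
                  class = "pose_track")
  hp <- head_position(tr)
  expect_equal(unname(hp[, 1]), rep(5, n))
  expect_equal(unname(hp[, 2]), rep(5, n))
  expect_equal(head_position(tiny_ears(0, 0, 2, 0))[1, ], c(x = 1, y = 0))
  expect_error(head_position(tiny_track(1:3)), "ear")
})

test_that("movement is path length over the half-open window", {
  xy <- cbind(rep(1, 100), rep(2, 100))
  expect_equal(movement_in_window(xy, 10, c(0, 5)), 0)
  # straight line at 2 cm/s for 5 s at 10 fps
  line <- cbind(seq(0, 19.8, by = 0.2), 0)
  m <- movement_in_window(line, 10, c(0, 5))
  expect_equal(m, 9.8)                       # 49 steps of 0.2 cm
  expect_lt(abs(m - 10), 0.2 + 1e-12)        # within one frame-step of 10
  # translation invariance
  expect_equal(movement_in_window(sweep(line, 2, c(100, -50), "+"), 10, c(0, 5)), m)
  expect_error(movement_in_window(line, 10, c(0, 0.05)), "fewer than 2")
})

test_that("reactivity is infusion minus baseline movement, zero for steady motion", {
  ev <- data.frame(trial = 1L, onset = 10, duration = 5, solution = "water")
  class(ev) <- c("event_log", "data.frame")
  n <- 200
  tr <- tiny_track(x = seq(0, by = 2, length.out = n))  # constant speed
  tr$units <- "cm"
  rt <- behavioral_reactivity(tr, ev, bodyparts = "nose")
  expect_equal(rt$reactivity_cm, 0, tolerance = 1e-9)
  expect_equal(rt$reactivity_cm, rt$infusion_cm - rt$baseline_cm)
})

test_that("an injected movement burst is recovered as reactivity", {
  ev <- make_event_schedule(100, iti_min = 10, iti_max = 20, seed = 5)
  tr <- simulate_pose_session(ev, "above", reactivity_gain = 4,
                              dropout_rate = 0, seed = 107)
  rt <- behavioral_reactivity(calibrate_track(clean_pose(tr)), ev)
  expect_equal(session_reactivity(rt), 4, tolerance = 0.05 * 4)
})

test_that("null reactivity gain yields near-zero reactivity for every part", {
  ev <- make_event_schedule(60, iti_min = 10, iti_max = 20, seed = 6)
  tr <- simulate_pose_session(ev, "below", reactivity_gain = 0,
                              dropout_rate = 0, seed = 8)
  rt <- behavioral_reactivity(calibrate_track(clean_pose(tr)), ev)
  for (p in unique(rt$bodypart))
    expect_lt(abs(session_reactivity(rt, p)), 0.25)
})

test_that("simulated dropout fraction matches the requested rate", {
  ev <- make_event_schedule(40, iti_min = 10, iti_max = 20, seed = 2)
  tr <- simulate_pose_session(ev, "above", dropout_rate = 0.09, seed = 9)
  frac <- mean(tr$coords$ear_left_likelihood < 0.95)
  expect_lt(abs(frac - 0.09), 0.02)
  expect_error(simulate_pose_session(ev, "sideways"), "arg")
  expect_error(simulate_pose_session(ev, dropout_rate = 1), "dropout_rate")
})

test_that("pose simulation is bitwise reproducible under a fixed seed", {
  ev <- small_events(3)
  a <- simulate_pose_session(ev, "above", dropout_rate = 0.1, seed = 33)
  b <- simulate_pose_session(ev, "above", dropout_rate = 0.1, seed = 33)
  expect_identical(a$coords, b$coords)
})

test_that("reactivity is invariant to rigid motion of the camera frame", {
  ev <- data.frame(trial = 1L, onset = 10, duration = 5, solution = "water")
  class(ev) <- c("event_log", "data.frame")
  set.seed(12)
  n <- 200
  x <- cumsum(rnorm(n)); y <- cumsum(rnorm(n))
  tr <- tiny_track(x = x, y = y); tr$units <- "cm"
  r0 <- behavioral_reactivity(tr, ev, bodyparts = "nose")$reactivity_cm
  th <- 0.7
  tr2 <- tr
  tr2$coords$nose_x <- cos(th) * x - sin(th) * y + 40
  tr2$coords$nose_y <- sin(th) * x + cos(th) * y - 13
  r2 <- behavioral_reactivity(tr2, ev, bodyparts = "nose")$reactivity_cm
  expect_equal(r2, r0, tolerance = 1e-10)
})
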