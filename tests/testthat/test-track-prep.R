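test_that("read_track_csv sorts, partitions by id and collapses duplicates", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(
    id = c("a", "a", "a", "b", "b"),
    timestamp = c(
      "2020-01-03 00:00", "2020-01-01 00:00", "2020-01-02 00:00",
      "2020-01-01 12:00", "2020-01-02 12:00"
    ),
    x = c(3, 1, 2, 10, 11), y = c(0, 0, 0, 5, 5)
  )
  write.csv(df, f, row.names = FALSE)
  tracks <- read_track_csv(f)
  expect_named(tracks, c("a", "b"))
  expect_equal(sum(vapply(tracks, nrow, integer(1))), nrow(df))
  expect_equal(tracks$a$x, c(1, 2, 3)) # time-sorted regardless of row order
  # out-of-order input reads to the same track as sorted input
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[order(df$timestamp), ], f2, row.names = FALSE)
  expect_equal(
    as.data.frame(read_track_csv(f2)$a),
    as.data.frame(tracks$a)
  )
  # duplicate timestamps collapse to the first occurrence, with a message
  df3 <- df[c(2, 2, 3), ]
  df3$x[2] <- 99
  f3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df3, f3, row.names = FALSE)
  expect_message(t3 <- read_track_csv(f3), "duplicate")
  expect_equal(nrow(t3$a), 2)
  expect_equal(t3$a$x[1], 1)
})

test_that("read_track_csv flags missing columns and bad timestamps", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = "a", when = "2020-01-01", x = 1, y = 2), f,
    row.names = FALSE
  )
  expect_error(read_track_csv(f), "required column")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(
    data.frame(
      id = "a", timestamp = c("2020-01-01", "not-a-date"),
      x = 1:2, y = 0
    ), f2,
    row.names = FALSE
  )
  expect_error(read_track_csv(f2), "row 2")
})

test_that("filter_dop removes locations exceeding the threshold in either axis", {
  tr <- make_track(0:9, rep(0, 10))
  tr$hdop <- c(rep(3, 9), 6)
  tr$vdop <- rep(2, 10)
  expect_equal(nrow(filter_dop(tr)), 9)
  # below threshold everywhere: identity
  tr2 <- tr
  tr2$hdop <- rep(3, 10)
  expect_equal(as.data.frame(filter_dop(tr2)), as.data.frame(tr2))
  # high vertical DOP alone removes the fix
  tr3 <- make_track(0:2, rep(0, 3))
  tr3$hdop <- c(3, 3, 3)
  tr3$vdop <- c(2, 7, 2)
  expect_equal(filter_dop(tr3)$time, c(0, 2))
  # tracks without DOP columns pass through untouched
  tr4 <- make_track(0:4, rep(0, 5))
  expect_equal(nrow(filter_dop(tr4)), 5)
})

test_that("rarefy_daily keeps the fix nearest noon, one per day", {
  tt <- c(0.1, 0.45, 0.9, 1.25, 1.6, 2.2) # days 0,1,2
  tr <- make_track(seq_along(tt), rep(0, 6), time = tt)
  rf <- rarefy_daily(tr)
  expect_equal(nrow(rf), 3)
  expect_equal(attr(rf, "dt_nominal"), 1)
  expect_equal(rf$time, c(0, 1, 2)) # snapped to the day index
  expect_equal(rf$x, c(2, 5, 6)) # 0.45, 1.6, 2.2 nearest noon
  # ties (11:00 vs 13:00) go to the earlier fix
  tr2 <- make_track(1:2, c(0, 0), time = c(11 / 24, 13 / 24))
  expect_equal(rarefy_daily(tr2)$x, 1)
  # already-daily noon track: coordinates unchanged
  tr3 <- make_track(1:4, rep(0, 4), time = (1:4) + 0.5)
  expect_equal(rarefy_daily(tr3)$x, 1:4)
})

test_that("subset_dates keeps the closed window and warns when empty", {
  tr <- make_track(1:10, rep(0, 10), time = 1:10)
  expect_equal(as.data.frame(subset_dates(tr, 1, 10)), as.data.frame(tr))
  expect_equal(subset_dates(tr, 3, 6)$time, 3:6)
  expect_warning(empty <- subset_dates(tr, 100, 200), "no locations")
  expect_equal(nrow(empty), 0)
  # Date bounds: locations after the end date are omitted, the end day kept
  days <- as.numeric(as.Date("2020-06-28")) + 0:6
  trd <- make_track(1:7, rep(0, 7), time = days + 0.6)
  kept <- subset_dates(trd, as.Date("2020-06-28"), as.Date("2020-07-01"))
  expect_equal(nrow(kept), 4)
  expect_true(all(kept$time < as.numeric(as.Date("2020-07-02"))))
})

test_that("check_gaps reports violations and is monotone in thresholds", {
  tr <- make_track(cumsum(c(0, rep(5, 9))), rep(0, 10), time = 0:9)
  expect_true(check_gaps(tr, 400, 14)$pass)
  # a 450 km jump fails the 400 km screen and is itemized
  x <- cumsum(c(0, rep(5, 4), 450, rep(5, 4)))
  tr2 <- make_track(x, rep(0, 10), time = 0:9)
  rep2 <- check_gaps(tr2, 400, 14)
  expect_false(rep2$pass)
  expect_equal(nrow(rep2$spatial), 1)
  expect_equal(rep2$spatial$value, 450)
  expect_equal(rep2$spatial$from_time, 4)
  # a 15-day hole fails the 14-day screen
  tr3 <- make_track(0:9, rep(0, 10), time = c(0:8, 24))
  rep3 <- check_gaps(tr3, 400, 14)
  expect_false(rep3$pass)
  expect_equal(nrow(rep3$temporal), 1)
  # monotone: loosening either threshold never turns pass into fail
  for (s in c(100, 451, 1000)) {
    for (d in c(1, 15, 30)) {
      r <- check_gaps(tr2, s, d)
      expect_equal(r$pass, s >= 450 && d >= 1)
    }
  }
})

test_that("split_at_southernmost splits at the minimum-northing fix", {
  y <- c(5, 3, 1, 0, 2, 4, 6)
  tr <- make_track(seq_along(y), y)
  sp <- split_at_southernmost(tr)
  expect_equal(nrow(sp$fall), 4)
  expect_equal(nrow(sp$spring), 4)
  expect_equal(sp$fall$y[4], 0)
  expect_equal(sp$spring$y[1], 0)
  # ties: earlier minimum wins
  y2 <- c(5, 0, 3, 0, 4)
  sp2 <- split_at_southernmost(make_track(seq_along(y2), y2))
  expect_equal(nrow(sp2$fall), 2)
  # constant northing: degenerate, flagged
  expect_warning(
    sp3 <- split_at_southernmost(make_track(1:5, rep(1, 5))),
    "degenerate"
  )
  expect_equal(nrow(sp3$fall), 1)
  expect_error(split_at_southernmost(make_track(1:2, 1:2)), "3 locations")
})

test_that("compute_steps reproduces the step/turn geometry", {
  # collinear equally spaced fixes: unit steps, zero turn at the third fix
  st <- compute_steps(make_track(c(0, 1, 2), c(0, 0, 0)))
  expect_equal(st$r, c(1, 1))
  expect_equal(st$valid_phi, c(FALSE, TRUE))
  expect_equal(st$phi[2], 0)
  # right-angle path turns +pi/2 (left turn positive)
  st2 <- compute_steps(make_track(c(0, 1, 1), c(0, 0, 1)))
  expect_equal(st2$phi[2], pi / 2)
  # clockwise turn is negative
  st3 <- compute_steps(make_track(c(0, 1, 1), c(0, 0, -1)))
  expect_equal(st3$phi[2], -pi / 2)
  # a missing fix masks the spanning step and the dependent angle
  tr <- make_track(c(0, 1, 2, 4, 5), rep(0, 5), time = c(0, 1, 2, 4, 5))
  st4 <- compute_steps(tr)
  expect_equal(st4$time, c(1, 2, 4, 5))
  expect_equal(st4$valid_r, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(st4$valid_phi, c(FALSE, TRUE, FALSE, FALSE))
  # rescale mode instead normalizes the displacement by elapsed time
  st5 <- compute_steps(tr, rescale_gaps = TRUE)
  expect_true(all(st5$valid_r))
  expect_equal(st5$r[3], 2 / 2) # 2 units in 2 days -> 1 per day
  # a zero-length step keeps r valid but masks dependent angles
  st6 <- compute_steps(make_track(c(0, 1, 1, 2), c(0, 0, 0, 0)))
  expect_equal(st6$r, c(1, 0, 1))
  expect_equal(st6$valid_phi, c(FALSE, FALSE, FALSE))
})

test_that("steps are rotation-invariant and reflections negate turns", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 30
    x <- cumsum(rnorm(n))
    y <- cumsum(rnorm(n))
    st <- compute_steps(make_track(x, y))
    th <- runif(1, -pi, pi)
    xr <- cos(th) * x - sin(th) * y
    yr <- sin(th) * x + cos(th) * y
    str <- compute_steps(make_track(xr, yr))
    expect_equal(str$r, st$r, tolerance = 1e-9)
    expect_equal(str$phi, st$phi, tolerance = 1e-9)
    stm <- compute_steps(make_track(x, -y))
    expect_equal(stm$r, st$r, tolerance = 1e-9)
    expect_equal(stm$phi[-1], -st$phi[-1], tolerance = 1e-9)
  }
})
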