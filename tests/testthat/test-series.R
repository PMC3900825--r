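test_that("a valid table of consecutive days round-trips through validation", {
  set.seed(1)
  d <- data.frame(date = as.Date("2001-01-01") + 0:364,
                  calls = rpois(365, 40), tarp_quit = runif(365, 0, 50),
                  tarp_nrt = runif(365, 0, 30))
  s <- quitline_series(d)
  expect_s3_class(s, "quitline_series")
  expect_identical(nrow(s), 365L)
  expect_identical(s$calls, as.integer(d$calls))

  f <- tempfile(fileext = ".csv")
  write_series(s, f)
  s2 <- read_series(f)
  expect_equal(s, s2, ignore_attr = TRUE)
})

test_that("structural defects are rejected with informative errors", {
  base <- data.frame(date = as.Date("2001-01-01") + 0:9,
                     calls = rep(5L, 10), tarp_quit = 1, tarp_nrt = 1)
  gap <- base
  gap$date[3:10] <- gap$date[3:10] + 1 # 2001-01-02 jumps to 2001-01-04
  expect_error(quitline_series(gap), "gap between 2001-01-02")

  neg <- base
  neg$calls[4] <- -1L
  expect_error(quitline_series(neg), "negative call count at row 4")

  frac <- base
  frac$calls <- frac$calls + 0.25
  expect_error(quitline_series(frac), "non-integer")

  bad_tarp <- base
  bad_tarp$tarp_quit <- as.character(bad_tarp$tarp_quit)
  expect_error(quitline_series(bad_tarp), "tarp_quit")

  expect_error(quitline_series(base[, -2]), "calls")
  expect_error(quitline_series(base[1:5, ]), "at least 8")
})

test_that("design matrices follow the calendar with Sunday as reference", {
  # 2000-08-06 is a Sunday, so the first response day is a Monday
  s <- make_series(calls = c(3, 7, 6, 5, 4, 4, 2, 1),
                   tarp_quit = c(0, 10, 8, 6, 0, 0, 0, 0),
                   tarp_nrt = 2)
  d <- build_design(s)
  expect_identical(dim(d$X), c(7L, 6L))
  expect_equal(unname(d$X[1, ]), c(1, 0, 0, 0, 0, 0)) # Monday
  expect_equal(unname(d$X[6, ]), c(0, 0, 0, 0, 0, 1)) # Saturday
  expect_equal(unname(d$X[7, ]), rep(0, 6))           # Sunday: all-zero
  expect_true(all(rowSums(d$X) %in% c(0, 1)))
  # Z = [X | TARPs of day j]
  expect_identical(d$Z[, 1:6], d$X)
  expect_equal(unname(d$Z[, 7]), s$tarp_quit[2:8])
  expect_equal(unname(d$Z[, 8]), s$tarp_nrt[2:8])
  # alignment: y_prev[k] = y_resp[k-1]
  expect_equal(d$y_prev[-1], d$y_resp[-7])
  expect_equal(d$y_prev[1], 3)
})

test_that("design construction does not depend on the start day of week", {
  # start on a Wednesday; day-of-week comes from the calendar
  s <- make_series(calls = rep(4L, 9), start = "2000-08-09", tarp_quit = 1)
  d <- build_design(s)
  expect_equal(unname(d$X[1, ]), c(0, 0, 0, 1, 0, 0)) # Thursday
  expect_equal(unname(d$X[4, ]), rep(0, 6))           # Sunday
})

test_that("build_design is deterministic", {
  set.seed(42)
  s <- make_series(rpois(30, 20), tarp_quit = runif(30), tarp_nrt = runif(30))
  expect_identical(build_design(s), build_design(s))
})
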