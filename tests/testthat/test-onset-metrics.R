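makeSquareActo <- function(onHour = 18, alpha = 12, days = 10,
                           binMinutes = 6, level = 30L) {
  nb <- as.integer(1440 / binMinutes)
  day <- rep(0L, nb)
  hrs <- ((seq_len(nb) - 1) * binMinutes / 60)
  active <- ((hrs - onHour) %% 24) < alpha
  day[active] <- level
  new("Actogram", animal = "t", sex = NA_character_,
      binMinutes = binMinutes, counts = rep(day, days),
      nightLux = rep(0.005, nb * days),
      condition = rep("dark", nb * days), lightsOffHour = onHour)
}

test_that("square wave active 18:00-06:00 detects onset 18 and offset 6", {
  a <- makeSquareActo()
  ph <- detectOnsetOffset(a, 5)
  expect_true(ph$valid)
  expect_equal(ph$onset, 18)
  expect_equal(ph$offset, 6)
})

test_that("an isolated noise bin does not shift the onset", {
  a <- makeSquareActo()
  nb <- as.integer(1440 / a@binMinutes)
  noisy <- a@counts
  noisy[(5 - 1) * nb + 121] <- 40L   # one 6-min bin at 12:00 of day 5
  a@counts <- noisy
  ph <- detectOnsetOffset(a, 5)
  expect_equal(ph$onset, 18)   # run-length rule rejects the single bin
})

test_that("a day with no qualifying run is flagged invalid", {
  a <- makeSquareActo()
  nb <- as.integer(1440 / a@binMinutes)
  quiet <- a@counts
  quiet[((3 - 1) * nb + 1):(3 * nb)] <- 0L
  a@counts <- quiet
  expect_false(detectOnsetOffset(a, 3)$valid)
})

test_that("injected onset jitter is recovered by the detector", {
  cfg <- smallConfig(studyDays = 12, conditionLux = c(dark = 0.005))
  reps <- vapply(1:6, function(s) {
    a <- simActogram(cfg, alpha = 10, jitterSD = 0.5, suppression = 0,
                     meanCounts = 40, seed = 1000 + s)
    ph <- dailyPhaseTable(a)
    sd(nightlux:::.unwrapOnsets(ph$onset[ph$valid]))
  }, numeric(1))
  expect_lt(abs(mean(reps) - 0.5), 0.15)
})

test_that("deterministic 12h square wave gives alpha 12 and onset error 0", {
  a <- makeSquareActo(alpha = 12)
  m <- circadianMetrics(a, "dark")
  expect_equal(m$alpha, 12, tolerance = 1e-9)
  expect_equal(m$onsetError, 0, tolerance = 1e-9)
  expect_equal(m$totalActivity, sum(a@counts) / 10)
})

test_that("onset error is zero on an exact drift line and shift-invariant", {
  onsets <- (18 - 0.5 * (0:9)) %% 24       # slope -0.5 h/day, period 23.5
  expect_equal(onsetError(onsets), 0, tolerance = 1e-9)
  expect_equal(onsetError((onsets + 3) %% 24), 0, tolerance = 1e-9)
})

test_that("onset error equals the independent regression-residual oracle", {
  set.seed(61)
  for (rep in 1:5) {
    days <- 1:10
    onsets <- 18 - 0.5 * days + rnorm(10, 0, 0.5)
    got <- onsetError(onsets, days)
    # closed-form least squares residual SD, computed independently
    X <- cbind(1, days)
    beta <- solve(t(X) %*% X, t(X) %*% onsets)
    resid <- onsets - X %*% beta
    expect_equal(got, sqrt(sum(resid^2) / (10 - 1)), tolerance = 1e-9)
  }
})

test_that("fewer than 3 valid onsets flags the onset error undefined", {
  expect_warning(v <- onsetError(c(18, NA, 17.5, NA, NA, NA, NA, NA, NA, NA)),
                 "fewer than 3")
  expect_true(is.na(v))
})

test_that("alpha and total activity respond monotonically to suppression", {
  cfg <- smallConfig(studyDays = 10)
  luxes <- c(0.005, 6, 20, 32)
  tot <- numeric(length(luxes)); alp <- numeric(length(luxes))
  for (i in seq_along(luxes)) {
    a <- simActogram(cfg, conditionLux = setNames(luxes[i], "c"),
                     jitterSD = 0.1, suppression = 0.012,
                     meanCounts = 30, seed = 500)
    m <- circadianMetrics(a, "c")
    tot[i] <- m$totalActivity; alp[i] <- m$alpha
  }
  expect_true(all(diff(tot) < 0))
  expect_true(all(diff(alp) < 0))
})
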