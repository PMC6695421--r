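test_that("every fitted circular density integrates to one", {
  set.seed(71)
  for (n in c(20, 200, 2000)) {
    d <- fitCircularDensity(runif(n, 0, 2 * pi))
    expect_equal(mean(d@density) * 2 * pi, 1, tolerance = 1e-6)
    expect_true(all(d@density >= 0))
  }
  expect_error(fitCircularDensity(runif(5, 0, 2 * pi)), "insufficient")
})

test_that("uniform samples approach the flat density 1/(2 pi)", {
  set.seed(72)
  d <- fitCircularDensity(runif(5000, 0, 2 * pi))
  expect_lt(max(abs(d@density - 1 / (2 * pi))), 0.15 / (2 * pi))
})

test_that("identical points with fixed kappa reproduce the bare kernel", {
  th <- rep(1.3, 50)
  d <- fitCircularDensity(th, kappa = 10)
  kernel <- exp(10 * cos(d@grid - 1.3)) / (2 * pi * besselI(10, 0))
  expect_equal(d@density, kernel, tolerance = 1e-10)
})

test_that("von Mises samples recover the analytic density at the mode", {
  set.seed(73)
  th <- rvonmises(2000, pi, 2)
  d <- fitCircularDensity(th)
  fAtPi <- evalCircularDensity(d, pi)
  analytic <- exp(2) / (2 * pi * besselI(2, 0))
  # bootstrap SE of the density at the mode
  boots <- vapply(1:100, function(i) {
    tb <- sample(th, replace = TRUE)
    nightlux:::.vmKde(pi, tb, d@kappa)
  }, numeric(1))
  expect_lt(abs(fAtPi - analytic), 3 * sd(boots) + 0.01)
})

test_that("activity level is 1 for uniform and matches the vM closed form", {
  set.seed(74)
  u <- estimateActivityLevel(runif(5000, 0, 2 * pi), B = 100, seed = 1)
  expect_equal(activityEstimate(u), 1, tolerance = 0.02)
  th <- rvonmises(4000, pi, 2)
  a <- estimateActivityLevel(th, B = 200, seed = 2)
  analytic <- besselI(2, 0) * exp(-2)    # 1/(2 pi max f) for vM(kappa = 2)
  expect_lt(abs(activityEstimate(a) - analytic), 3 * a@se + 0.01)
  expect_true(activityEstimate(a) <= 1 + 1e-6)
})

test_that("the Wald statistic follows its closed form", {
  a <- new("ActivityLevel", act = 0.5, se = 0.05, n = 100L,
           boot = numeric(0))
  b <- new("ActivityLevel", act = 0.4, se = 0.05, n = 100L,
           boot = numeric(0))
  w <- compareActivityLevels(a, b)
  expect_equal(w$w, 2, tolerance = 1e-12)
  expect_equal(w$p, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(compareActivityLevels(a, a)$w, 0)
  expect_equal(compareActivityLevels(a, a)$p, 1)
  zero <- new("ActivityLevel", act = 0.4, se = 0, n = 10L, boot = numeric(0))
  expect_error(compareActivityLevels(zero, zero), "standard error")
})

test_that("KS comparison handles identical and disjoint samples", {
  x <- runif(50, 0, 24)
  same <- compareActivityDistributions(x, x)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  a <- runif(60, 0, 6); b <- runif(60, 12, 18)
  disj <- compareActivityDistributions(a, b)
  expect_equal(disj$D, 1)
  expect_lt(disj$p, 1e-10)
  expect_error(compareActivityDistributions(runif(5), runif(50, 0, 24)),
               "at least 10")
})
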