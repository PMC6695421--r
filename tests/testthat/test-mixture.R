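test_that("constant data yield the degenerate-safe single component", {
  m <- fitIlluminationMixture(rep(5, 100), transform = "identity")
  expect_equal(nComponents(m), 1L)
  expect_equal(m@means, 5)
  expect_gt(m@variances, 0)
  expect_equal(sum(m@weights), 1)
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  set.seed(31)
  x <- c(rnorm(300, 0, 1), rnorm(300, 6, 1.4))
  for (K in 1:3) {
    fit <- nightlux:::.emFit(x, K, equalVariance = FALSE,
                             means0 = quantile(x, (seq_len(K) - 0.5) / K))
    expect_true(all(diff(fit$trace) > -1e-7))
  }
})

test_that("two separated components are recovered near generator truth", {
  set.seed(7)
  x <- c(rnorm(500, 0, 1), rnorm(500, 10, 1))
  m <- fitIlluminationMixture(x, kMax = 5, transform = "identity")
  expect_equal(nComponents(m), 2L)
  expect_equal(m@means[1], 0, tolerance = 0.2)
  expect_equal(m@means[2], 10, tolerance = 0.2)
  # independent EM oracle from random restarts (mclust, the field-standard
  # implementation) agrees on the maximized likelihood and means
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))   # Mclust needs its namespace attached
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(m@means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
  expect_equal(m@logLik, mc$loglik, tolerance = 0.01 * abs(mc$loglik))
})

test_that("BIC agrees with the -2 logLik + p ln n identity", {
  set.seed(8)
  x <- c(rnorm(200, 1, 0.5), rnorm(200, 5, 0.5))
  m <- fitIlluminationMixture(x, kMax = 3, transform = "identity")
  pPar <- (m@K - 1) + m@K + if (m@equalVariance) 1 else m@K
  expect_equal(m@BIC, -2 * m@logLik + pPar * log(length(x)),
               tolerance = 1e-8)
})

test_that("responsibilities are a proper posterior and weights sum to 1", {
  set.seed(9)
  x <- exp(rnorm(150, 1, 1))
  m <- fitIlluminationMixture(x, kMax = 4)
  expect_equal(rowSums(m@responsibilities), rep(1, length(x)),
               tolerance = 1e-9)
  expect_equal(sum(m@weights), 1, tolerance = 1e-9)
  expect_true(all(m@variances > 0))
})

test_that("cluster summary matches brute-force nearest-mean assignment", {
  set.seed(10)
  x <- c(rnorm(200, 2, 0.3), rnorm(200, 40, 2))
  m <- fitIlluminationMixture(x, kMax = 3, transform = "identity")
  s <- summarizeClusters(m)
  # oracle: assign by nearest component mean (valid for well-separated)
  assign <- apply(abs(outer(x, m@means, `-`)), 1, which.min)
  for (k in seq_len(m@K)) {
    expect_equal(s$median[k], median(x[assign == k]))
    expect_equal(s$max[k], max(x[assign == k]))
  }
  expect_true(all(diff(s$median) > 0))
})

test_that("K = 1 summary reduces to the plain median and max", {
  m <- fitIlluminationMixture(c(1, 2, 3), kMax = 1, transform = "identity")
  s <- summarizeClusters(m)
  expect_equal(s$median, 2)
  expect_equal(s$max, 3)
})

test_that("log-transform mode clusters lux spanning orders of magnitude", {
  set.seed(12)
  lux <- c(rlnorm(300, log(0.3), 0.25), rlnorm(300, log(20), 0.25))
  m <- fitIlluminationMixture(lux, kMax = 5, transform = "log")
  expect_equal(nComponents(m), 2L)
  s <- summarizeClusters(m)
  expect_equal(s$median[1], 0.3, tolerance = 0.12)
  expect_equal(s$median[2], 20, tolerance = 4)
})
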