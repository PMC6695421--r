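# One EM run for a univariate Gaussian mixture.
# Returns list(weights, means, vars, logLik, iterations, trace).
.emFit <- function(x, K, equalVariance, means0, tol = 1e-8, maxIter = 500,
                   varFloor = 1e-6) {
  n <- length(x)
  w <- rep(1 / K, K)
  mu <- means0
  v <- rep(max(var(x), varFloor), K)
  llOld <- -Inf
  trace <- numeric(0)
  resp <- matrix(1, n, K)
  for (it in seq_len(maxIter)) {
    # E step (log-space for stability)
    lg <- vapply(seq_len(K), function(k)
      log(w[k]) - 0.5 * log(2 * pi * v[k]) - (x - mu[k])^2 / (2 * v[k]),
      numeric(n))
    mx <- apply(lg, 1, max)
    lse <- mx + log(rowSums(exp(lg - mx)))
    ll <- sum(lse)
    resp <- exp(lg - lse)
    trace <- c(trace, ll)
    if (is.finite(llOld) && abs(ll - llOld) < tol * (1 + abs(ll))) break
    llOld <- ll
    # M step
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-12)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    if (equalVariance) {
      vAll <- sum(resp * (outer(x, mu, `-`))^2) / n
      v <- rep(max(vAll, varFloor), K)
    } else {
      v <- pmax(colSums(resp * (outer(x, mu, `-`))^2) / nk, varFloor)
    }
  }
  list(weights = w, means = mu, vars = v, logLik = ll, resp = resp,
       trace = trace)
}

#' Fit a univariate Gaussian finite mixture to illuminance values
#'
#' EM over a range of component counts K, with both equal-variance and
#' unequal-variance families scored by BIC = -2 logLik + p ln(n); the
#' minimum-BIC model is returned (ties broken toward smaller K).  Because
#' urban illuminance spans four orders of magnitude, the mixture is by
#' default fitted on ln(lux + 0.01); raw-lux fitting is available via
#' `transform = "identity"`.  Initialization uses quantile-based means plus
#' random restarts; the log-likelihood is non-decreasing across EM
#' iterations (up to convergence tolerance) and variances are floored.
#'
#' @param values illuminance values (lux), length >= 2.
#' @param kMax largest number of components to consider.
#' @param transform "log" (default, ln(lux + 0.01)) or "identity".
#' @param restarts EM restarts per (K, family); the first uses quantile
#'   initialization.
#' @param equalVarOnly restrict to the equal-variance family.
#' @param seed seed for the random restarts.
#' @return an [IlluminationMixture-class].
#' @examples
#' set.seed(1)
#' m <- fitIlluminationMixture(c(rnorm(100, 1, .1), rnorm(100, 30, 2)),
#'                             kMax = 4)
#' nComponents(m)
#' @export
fitIlluminationMixture <- function(values, kMax = 9, transform = c("log",
                                   "identity"), restarts = 10,
                                   equalVarOnly = FALSE, seed = 1) {
  transform <- match.arg(transform)
  if (length(values) < 1) stop("no values supplied")
  if (kMax < 1) stop("kMax must be >= 1")
  x <- if (transform == "log") log(values + 0.01) else values
  n <- length(x)

  # degenerate-safe path: (near-)constant data
  if (length(unique(x)) == 1L || var(x) < 1e-12) {
    resp <- matrix(1, n, 1)
    p <- 2
    ll <- sum(-0.5 * log(2 * pi * 1e-6))
    return(new("IlluminationMixture", K = 1L, weights = 1,
               means = mean(x), variances = 1e-6, logLik = ll,
               BIC = -2 * ll + p * log(n), responsibilities = resp,
               transform = transform, equalVariance = TRUE,
               data = as.numeric(values),
               bicTable = data.frame(K = 1L, family = "E",
                                     BIC = -2 * ll + p * log(n))))
  }

  set.seed(seed)
  families <- if (equalVarOnly) "E" else c("E", "V")
  best <- NULL
  rows <- list()
  for (K in seq_len(min(kMax, length(unique(x))))) {
    for (fam in families) {
      eq <- fam == "E"
      bestRun <- NULL
      for (r in seq_len(restarts)) {
        means0 <- if (r == 1)
          quantile(x, probs = (seq_len(K) - 0.5) / K, names = FALSE)
        else sort(sample(x, K))
        fit <- tryCatch(.emFit(x, K, eq, means0), error = function(e) NULL)
        if (is.null(fit)) next
        if (is.null(bestRun) || fit$logLik > bestRun$logLik) bestRun <- fit
      }
      if (is.null(bestRun)) next
      p <- (K - 1) + K + if (eq) 1 else K
      bic <- -2 * bestRun$logLik + p * log(n)
      rows[[length(rows) + 1L]] <- data.frame(K = K, family = fam, BIC = bic)
      better <- is.null(best) || bic < best$bic - 1e-9 ||
        (abs(bic - best$bic) <= 1e-9 && K < best$K)
      if (better)
        best <- list(K = K, eq = eq, bic = bic, fit = bestRun)
    }
  }
  ord <- order(best$fit$means)
  new("IlluminationMixture", K = as.integer(best$K),
      weights = best$fit$weights[ord], means = best$fit$means[ord],
      variances = best$fit$vars[ord], logLik = best$fit$logLik,
      BIC = best$bic,
      responsibilities = best$fit$resp[, ord, drop = FALSE],
      transform = transform, equalVariance = best$eq,
      data = as.numeric(values), bicTable = do.call(rbind, rows))
}

#' @rdname fitIlluminationMixture
#' @param x an IlluminationMixture
#' @export
setMethod("nComponents", "IlluminationMixture", function(x) x@K)

setMethod("show", "IlluminationMixture", function(object) {
  cat(sprintf(
    "IlluminationMixture: K = %d (%s variance, %s scale), BIC = %.2f\n",
    object@K, if (object@equalVariance) "equal" else "unequal",
    object@transform, object@BIC))
  print(data.frame(weight = round(object@weights, 3),
                   mean = round(object@means, 3),
                   variance = round(object@variances, 4)))
  invisible(NULL)
})

#' Hard cluster assignment of an IlluminationMixture
#'
#' @param mix an [IlluminationMixture-class].
#' @return integer vector: maximum-responsibility component per value,
#'   components ordered by increasing mean.
#' @export
clusterAssignments <- function(mix) {
  apply(mix@responsibilities, 1, which.max)
}

#' Per-cluster summary of an illumination mixture
#'
#' Assigns every fitted value to its maximum-responsibility component and
#' reports the per-cluster median and maximum illuminance (on the raw lux
#' scale) plus counts, with clusters ordered by increasing mean.
#'
#' @param mix an [IlluminationMixture-class].
#' @param values optional raw lux values (defaults to the fitting data).
#' @return data.frame cluster, n, median, max.
#' @export
summarizeClusters <- function(mix, values = mix@data) {
  if (length(values) != nrow(mix@responsibilities))
    stop("values must be the data the mixture was fitted on")
  cl <- clusterAssignments(mix)
  out <- data.frame(cluster = seq_len(mix@K))
  out$n <- as.integer(tabulate(cl, nbins = mix@K))
  out$median <- vapply(seq_len(mix@K), function(k)
    if (out$n[k]) median(values[cl == k]) else NA_real_, numeric(1))
  out$max <- vapply(seq_len(mix@K), function(k)
    if (out$n[k]) max(values[cl == k]) else NA_real_, numeric(1))
  out
}
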