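#' Chi-square periodogram of an actogram
#'
#' The Sokolove-Bushell statistic: for a candidate period spanning P bins,
#' the data are folded at P and
#' \deqn{Q_P = N \frac{\sum_h (M_h - \bar M)^2 / P}{\sum_i (x_i - \bar M)^2 / N}}
#' with M_h the mean of folded column h, which is distributed chi-square
#' with P - 1 degrees of freedom under serially independent noise.  The
#' peak period tau is the candidate maximizing Q_P among those exceeding
#' the chi-square 0.99 quantile line.
#'
#' @param acto an [Actogram-class], or a numeric count vector.
#' @param binMinutes bin width (min) when `acto` is a plain vector.
#' @param periodRange scanned period range in hours.
#' @param stepHours scan step; defaults to one bin (and is rounded to a
#'   whole number of bins — the statistic folds whole bins).
#' @param alpha significance level of the threshold line (0.01 quantile
#'   tail, i.e. the 0.99 chi-square quantile).
#' @return a [PeriodogramResult-class].
#' @examples
#' cfg <- simConfig(studyDays = 2, conditionLux = c(d = 0.005))
#' a <- simActogram(cfg, noise = "none", jitterSD = 0, alpha = 12)
#' # two days is below the scan minimum; use >= 7 days in practice
#' @export
chiSquarePeriodogram <- function(acto, binMinutes = NULL,
                                 periodRange = c(20, 28),
                                 stepHours = NULL, alpha = 0.01) {
  if (is(acto, "Actogram")) {
    counts <- as.numeric(acto@counts)
    binMinutes <- acto@binMinutes
  } else {
    counts <- as.numeric(acto)
    if (is.null(binMinutes)) stop("binMinutes required for a plain vector")
  }
  binH <- binMinutes / 60
  if (length(counts) * binH < 7 * 24)
    stop("at least 7 days of data are required")
  if (is.null(stepHours)) stepHours <- binH
  stepBins <- max(1L, round(stepHours / binH))

  pBins <- seq(round(periodRange[1] / binH), round(periodRange[2] / binH),
               by = stepBins)
  N <- length(counts)
  grand <- mean(counts)
  denom <- sum((counts - grand)^2)
  Qp <- numeric(length(pBins))
  if (denom == 0) {
    # all-zero (or constant) record: no significant period exists
    return(new("PeriodogramResult", periods = pBins * binH,
               Qp = rep(0, length(pBins)), df = pBins - 1,
               threshold = qchisq(1 - alpha, pBins - 1),
               tau = NA_real_, significant = FALSE))
  }
  for (k in seq_along(pBins)) {
    P <- pBins[k]
    colIdx <- ((seq_len(N) - 1) %% P) + 1
    colMeans <- rowsum(counts, colIdx) / tabulate(colIdx, nbins = P)
    Qp[k] <- N * (sum((colMeans - grand)^2) / P) / (denom / N)
  }
  thr <- qchisq(1 - alpha, pBins - 1)
  sig <- Qp > thr
  tau <- if (any(sig)) (pBins * binH)[which.max(ifelse(sig, Qp, -Inf))]
         else NA_real_
  new("PeriodogramResult", periods = pBins * binH, Qp = Qp,
      df = pBins - 1, threshold = thr, tau = tau,
      significant = any(sig))
}

#' @rdname chiSquarePeriodogram
#' @param x a PeriodogramResult
#' @export
setMethod("tauHat", "PeriodogramResult", function(x) x@tau)

setMethod("show", "PeriodogramResult", function(object) {
  cat(sprintf("PeriodogramResult: %d candidate periods in [%g, %g] h\n",
              length(object@periods), min(object@periods),
              max(object@periods)))
  if (object@significant)
    cat(sprintf("  tau = %.2f h (Qp = %.1f)\n", object@tau,
                object@Qp[which(object@periods == object@tau)]))
  else cat("  no significant period\n")
  invisible(NULL)
})
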