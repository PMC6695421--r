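# design formula for a spec: light + harmonics + light:harmonics + controls
.occurrenceFormula <- function(order, controls = TRUE) {
  harm <- unlist(lapply(seq_len(order), function(k)
    c(sprintf("sin(%d * theta)", k), sprintf("cos(%d * theta)", k))))
  terms <- c("light", harm, paste0("light:", harm))
  if (controls)
    terms <- c(terms, "humans", "residential", "denseResidential",
               "commercial", "industrial", "treeCover", "grassCover",
               "pavedCover", "dayLength", "dayLength2", "moon",
               "lnDistCenter")
  as.formula(paste("presence ~", paste(terms, collapse = " + ")))
}

# ridge-penalized logistic IRLS, used only as the separation fallback
.ridgeLogit <- function(X, y, lambda = 1e-3, maxIter = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxIter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p) + 1e-10
    z <- eta + (y - p) / W
    A <- crossprod(X * W, X) + diag(lambda, ncol(X))
    betaNew <- solve(A, crossprod(X * W, z))
    if (max(abs(betaNew - beta)) < 1e-8) { beta <- betaNew; break }
    beta <- betaNew
  }
  drop(beta)
}

#' Fit one camera-hour logistic occurrence model
#'
#' Maximum-likelihood logit of hourly presence on the light indicator,
#' sin/cos harmonics of the dusk phase up to the spec's order, their
#' light interactions, and the control covariates.
#' BIC = -2 logLik + p ln(n).  Complete separation (detected as
#' non-convergence or runaway coefficients) triggers a weakly
#' ridge-penalized refit with a warning.
#'
#' @param records camera-hour table from [buildCameraHourTable()].
#' @param spec model spec (default: the table's own spec attribute).
#' @param controls include the control covariates (TRUE for the analysis
#'   grid; FALSE gives the bare light x circadian model).
#' @return list of class "occurrenceFit": `spec`, `coefficients`,
#'   `logLik`, `BIC`, `n`, `fit` (the glm object), `penalized`.
#' @export
fitOccurrenceModel <- function(records, spec = attr(records, "spec"),
                               controls = TRUE) {
  if (sum(records$presence) == 0 || sum(records$presence) == nrow(records))
    stop("need at least one presence and one absence")
  fml <- .occurrenceFormula(spec$order, controls)
  sepWarn <- FALSE
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = records,
        model = FALSE, y = FALSE),   # drop heavy frames; predict() still works
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        sepWarn <<- TRUE
      invokeRestart("muffleWarning")
    })
  penalized <- FALSE
  if (!fit$converged ||
      (sepWarn && any(abs(coef(fit)) > 30, na.rm = TRUE))) {
    warning("possible separation: refitting with a weak ridge penalty")
    X <- model.matrix(fml, records)
    beta <- .ridgeLogit(X, records$presence)
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    ll <- sum(records$presence * log(p) + (1 - records$presence) * log1p(-p))
    fit$coefficients[] <- beta
    penalized <- TRUE
  } else {
    ll <- as.numeric(logLik(fit))
  }
  p <- sum(!is.na(coef(fit)))
  n <- nrow(records)
  structure(list(spec = spec, coefficients = coef(fit), logLik = ll,
                 BIC = -2 * ll + p * log(n), n = n, nPar = p, fit = fit,
                 penalized = penalized),
            class = "occurrenceFit")
}

#' @export
print.occurrenceFit <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "occurrenceFit [%s]: cutoff %g lux, buffer %g m, anchor %+g h, order %d\n",
    if (!is.null(s$group)) s$group else "group", s$cutoff, s$buffer,
    s$anchorOffset, s$order))
  cat(sprintf("  n = %d, logLik = %.1f, BIC = %.1f%s\n", x$n, x$logLik,
              x$BIC, if (x$penalized) " (penalized)" else ""))
  invisible(x)
}
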