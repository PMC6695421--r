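#' Normalized light/dark predicted-probability contrast
#'
#' For every camera-hour record, predicts the presence probability with the
#' light indicator forced to 1 (light) and to 0 (dark), all other
#' covariates unchanged; divides each vector by its own maximum over
#' camera-hours (normalizing away between-site abundance differences); and
#' reports the difference normalized-light minus normalized-dark, binned by
#' hours since the previous dusk.
#'
#' @param fit an "occurrenceFit".
#' @param records the camera-hour table the fit was estimated on.
#' @return list of class "probabilityContrast": `records` (with columns
#'   pLight, pDark, normLight, normDark, contrast, hsdBin) and `byBin`
#'   (median contrast per hours-since-dusk bin).
#' @export
probabilityContrast <- function(fit, records) {
  recL <- records; recL$light <- 1L
  recD <- records; recD$light <- 0L
  predictWith <- function(d) {
    if (fit$penalized) {
      fml <- .occurrenceFormula(fit$spec$order,
                                controls = "humans" %in%
                                  names(fit$coefficients))
      X <- model.matrix(fml, d)
      1 / (1 + exp(-drop(X %*% fit$coefficients)))
    } else {
      predict(fit$fit, newdata = d, type = "response")
    }
  }
  pLight <- predictWith(recL)
  pDark <- predictWith(recD)
  if (max(pLight) <= 0 || max(pDark) <= 0)
    stop("maximum predicted probability is zero; contrast undefined")
  out <- records
  out$pLight <- pLight
  out$pDark <- pDark
  out$normLight <- pLight / max(pLight)
  out$normDark <- pDark / max(pDark)
  out$contrast <- out$normLight - out$normDark
  out$hsdBin <- floor(records$hoursSinceDusk)
  med <- aggregate(contrast ~ hsdBin, data = out, FUN = median)
  structure(list(records = out, byBin = med), class = "probabilityContrast")
}

#' @export
print.probabilityContrast <- function(x, ...) {
  cat(sprintf("probabilityContrast over %d camera-hours\n", nrow(x$records)))
  cat(sprintf("  contrast range [%.3f, %.3f]; median by dusk-hour bin:\n",
              min(x$records$contrast), max(x$records$contrast)))
  print(head(x$byBin, 24))
  invisible(x)
}
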