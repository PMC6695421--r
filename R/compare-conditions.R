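#' Compare a circadian metric across light conditions
#'
#' Linear mixed model with an animal-level random intercept:
#' metric ~ condition + (1 | animal).  The overall condition effect is a
#' likelihood-ratio chi-square against the no-condition model (ML fits);
#' all pairwise condition contrasts use Tukey-Kramer (single-step)
#' adjustment, and compact-letter grouping is derived from adjusted
#' p < 0.05.  A singular random-effect fit falls back, with a warning, to a
#' fixed-effects model with animal as a blocking factor.
#'
#' @param metrics data.frame from [circadianMetricsTable()] (needs columns
#'   animal, condition and the metric).
#' @param metric metric column name ("totalActivity", "alpha",
#'   "onsetError", "tau").
#' @return list of class "conditionComparison": `metric`, `chisq`, `df`,
#'   `p`, `pairwise` (data.frame contrast, estimate, p), `letters` (named
#'   grouping letters), `model`.
#' @export
compareConditions <- function(metrics, metric) {
  stopifnot(metric %in% names(metrics))
  d <- metrics[, c("animal", "condition", metric)]
  names(d)[3] <- "y"
  d <- d[is.finite(d$y), ]
  if (length(unique(d$condition)) < 2) stop("need >= 2 conditions")
  if (length(unique(d$animal)) < 3) stop("need >= 3 animals")
  d$condition <- factor(d$condition, levels = unique(d$condition))
  d$animal <- factor(d$animal)

  # (near-)constant metric: no information, no effect; the Gaussian LRT is
  # numerically ill-defined at zero residual variance
  if (sd(d$y) < 1e-10 * (1 + abs(mean(d$y)))) {
    lv <- levels(d$condition)
    nPair <- choose(length(lv), 2)
    pairs <- outer(lv, lv, paste, sep = " - ")[lower.tri(diag(length(lv)))]
    return(structure(list(
      metric = metric, chisq = 0, df = length(lv) - 1L, p = 1,
      pairwise = data.frame(contrast = pairs, estimate = rep(0, nPair),
                            p = rep(1, nPair)),
      letters = setNames(rep("a", length(lv)), lv),
      fallback = FALSE, model = NULL), class = "conditionComparison"))
  }

  fallback <- FALSE
  fit <- tryCatch(
    suppressMessages(
      lme4::lmer(y ~ condition + (1 | animal), data = d, REML = FALSE)),
    error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(fit) && lme4::isSingular(fit, tol = 1e-5)) fit <- NULL
  if (is.null(fit)) {
    warning("singular mixed-model fit: falling back to animal-blocked ",
            "fixed-effects analysis")
    fallback <- TRUE
    fit <- lm(y ~ condition + animal, data = d)
    fit0 <- lm(y ~ animal, data = d)
    lrt <- anova(fit0, fit)
    # F-test recast as the LR chi-square for reporting consistency
    chisq <- as.numeric(2 * (logLik(fit) - logLik(fit0)))
    df <- lrt$Df[2]
  } else {
    fit0 <- suppressMessages(
      lme4::lmer(y ~ 1 + (1 | animal), data = d, REML = FALSE))
    lrt <- anova(fit0, fit)
    chisq <- lrt$Chisq[2]
    df <- lrt$Df[2]
  }
  p <- pchisq(chisq, df, lower.tail = FALSE)

  glt <- multcomp::glht(fit, linfct = multcomp::mcp(condition = "Tukey"))
  sm <- summary(glt)
  pw <- data.frame(contrast = names(sm$test$coefficients),
                   estimate = as.numeric(sm$test$coefficients),
                   p = as.numeric(sm$test$pvalues))
  degenerate <- any(!is.finite(pw$p))
  pw$p[!is.finite(pw$p)] <- 1      # zero-variance data: no evidence
  letters <- if (degenerate)
    setNames(rep("a", nlevels(d$condition)), levels(d$condition))
  else multcomp::cld(glt, level = 0.05)$mcletters$Letters

  structure(list(metric = metric, chisq = chisq, df = df, p = p,
                 pairwise = pw, letters = letters, fallback = fallback,
                 model = fit),
            class = "conditionComparison")
}

#' @export
print.conditionComparison <- function(x, ...) {
  cat(sprintf("conditionComparison [%s]: overall chi-square = %.2f (df %d), p = %.3g\n",
              x$metric, x$chisq, x$df, x$p))
  cat("  grouping letters:",
      paste(sprintf("%s=%s", names(x$letters), x$letters), collapse = " "),
      "\n")
  invisible(x)
}
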