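# interval overlap of [a, a+len) with bins on the 24 h circle, in hours
.circOverlap <- function(binStart, binWidth, a, len) {
  a <- a %% 24
  segs <- if (a + len <= 24) list(c(a, a + len))
          else list(c(a, 24), c(0, a + len - 24))
  out <- numeric(length(binStart))
  for (s in segs) {
    out <- out + pmax(0, pmin(s[2], binStart + binWidth) - pmax(s[1], binStart))
  }
  out
}

# lux-response defaults for active-phase length and onset jitter
.alphaAtLux <- function(config, lux) {
  config$alphaFloor +
    (config$alphaDark - config$alphaFloor) * exp(-lux / config$alphaLuxScale)
}

.jitterAtLux <- function(config, lux) {
  luxRef <- max(config$conditionLux)
  config$jitterDark +
    (config$jitterBright - config$jitterDark) * pmin(lux / luxRef, 1)
}

#' Generate one synthetic wheel-running actogram
#'
#' Activity is concentrated in a daily window of length alpha whose onset
#' drifts by (period - 24) h per day plus Gaussian jitter; per-bin counts
#' are Poisson with mean proportional to the window coverage of the bin,
#' scaled down by exp(-suppression * night lux).  Under the default
#' lux-response, alpha compresses toward `alphaFloor` and onset jitter grows
#' as nighttime illuminance increases, emulating the laboratory design of a
#' 12:12 schedule (1800 lux days) with nights stepped through increasing lux
#' every four weeks.
#'
#' @param config a [simConfig()] list.
#' @param animal,sex identifiers stored in the actogram.
#' @param period circadian period (h), in \[20, 28\].
#' @param alpha active-phase length (h); NULL uses the config lux-response.
#' @param meanCounts expected counts per fully active bin at 0 lux.
#' @param jitterSD onset jitter SD (h); NULL uses the config lux-response.
#' @param suppression activity suppression per lux (counts scale by
#'   exp(-suppression * lux)).
#' @param conditionLux named vector of nighttime lux per 4-week block
#'   (default from config).
#' @param noise "poisson" for Poisson counts, "none" for deterministic
#'   rounded rates (a noiseless square-wave actogram).
#' @param seed substream seed; default derives from config and animal id.
#' @return an [Actogram-class].
#' @examples
#' a <- simActogram(simConfig(studyDays = 7), animal = "m1", noise = "none",
#'                  jitterSD = 0, suppression = 0, alpha = 12)
#' sum(a@counts)
#' @export
simActogram <- function(config, animal = "a1", sex = NA_character_,
                        period = config$basePeriod, alpha = NULL,
                        meanCounts = config$meanCountsPerBin,
                        jitterSD = NULL,
                        suppression = config$suppressionPerLux,
                        conditionLux = config$conditionLux,
                        noise = c("poisson", "none"),
                        seed = NULL) {
  noise <- match.arg(noise)
  if (period < 20 || period > 28) stop("period must lie in [20, 28] h")
  if (!is.null(alpha) && alpha >= period)
    stop("invalid parameter: alpha must be smaller than period")
  if (is.null(seed))
    seed <- substreamSeed(config$seed, paste0("actogram:", animal))
  set.seed(seed)

  binH <- config$actogramBinMinutes / 60
  nb <- as.integer(1440 / config$actogramBinMinutes)
  nDays <- length(conditionLux) * config$studyDays
  condNames <- if (is.null(names(conditionLux)))
    paste0("cond", seq_along(conditionLux)) else names(conditionLux)

  binStart <- (seq_len(nb) - 1) * binH
  counts <- integer(0); luxVec <- numeric(0); condVec <- character(0)
  for (d in seq_len(nDays)) {
    block <- ((d - 1) %/% config$studyDays) + 1
    lux <- unname(conditionLux[block])
    alphaD <- if (is.null(alpha)) .alphaAtLux(config, lux) else alpha
    jitD <- if (is.null(jitterSD)) .jitterAtLux(config, lux) else jitterSD
    mult <- exp(-suppression * lux)
    onset <- config$lightsOffHour + (period - 24) * (d - 1) +
      (if (jitD > 0) rnorm(1, 0, jitD) else 0)
    cover <- .circOverlap(binStart, binH, onset, alphaD) / binH
    rate <- meanCounts * mult * cover
    cts <- if (noise == "poisson") rpois(nb, rate) else as.integer(round(rate))
    counts <- c(counts, as.integer(cts))
    luxVec <- c(luxVec, rep(lux, nb))
    condVec <- c(condVec, rep(condNames[block], nb))
  }
  new("Actogram", animal = animal, sex = sex,
      binMinutes = config$actogramBinMinutes, counts = counts,
      nightLux = luxVec, condition = condVec,
      lightsOffHour = config$lightsOffHour)
}

#' Generate the full laboratory cohort of actograms
#'
#' One actogram per animal with moderate animal-level heterogeneity in mean
#' counts, active-phase parameters and jitter, all deterministic given the
#' config seed.
#'
#' @param config a [simConfig()] list.
#' @return list of [Actogram-class] objects.
#' @export
simActograms <- function(config) {
  nM <- config$nAnimalsM; nF <- config$nAnimalsF
  ids <- c(paste0("m", seq_len(nM)), paste0("f", seq_len(nF)))
  sexes <- c(rep("M", nM), rep("F", nF))
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    set.seed(substreamSeed(config$seed, paste0("animal-params:", ids[i])))
    cfg <- config
    cfg$meanCountsPerBin <- config$meanCountsPerBin * exp(rnorm(1, 0, 0.2))
    cfg$alphaDark <- config$alphaDark + rnorm(1, 0, 0.2)
    cfg$alphaFloor <- config$alphaFloor + rnorm(1, 0, 0.15)
    jitMult <- exp(rnorm(1, 0, 0.15))
    cfg$jitterDark <- config$jitterDark * jitMult
    cfg$jitterBright <- config$jitterBright * jitMult
    out[[i]] <- simActogram(cfg, animal = ids[i], sex = sexes[i],
                            meanCounts = cfg$meanCountsPerBin)
  }
  names(out) <- ids
  out
}

setMethod("show", "Actogram", function(object) {
  nb <- as.integer(1440 / object@binMinutes)
  cat(sprintf("Actogram %s (%s): %d days of %g-min bins, %d total counts\n",
              object@animal, object@sex, length(object@counts) %/% nb,
              object@binMinutes, sum(object@counts)))
  cat("  conditions:", paste(unique(object@condition), collapse = ", "), "\n")
  invisible(NULL)
})
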