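# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All generator entry points use this
# so identical (config, seed) gives bit-identical output regardless of
# surrounding RNG use.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# 99.5th percentile; guards event thresholds against single-cell outliers
robustMax <- function(x, prob = 0.995) {
  stats::quantile(x, probs = prob, names = FALSE, na.rm = TRUE)
}

# unit-peak transient time course: saturating exponential rise to a plateau,
# then exponential decay, with the plateau length solved so that the full
# width at half-maximum equals `durationS`.
#   f(t) = 1 - exp(-t/riseS)                    for 0 <= t < plateauEnd
#   f(t) = f(plateauEnd) * exp(-(t-p)/decayS)   for t >= plateauEnd
transientKernel <- function(tS, durationS, riseS, decayS) {
  p <- plateauEnd(durationS, riseS, decayS)
  peak <- 1 - exp(-p / riseS)
  out <- numeric(length(tS))
  up <- tS >= 0 & tS < p
  dn <- tS >= p
  out[up] <- 1 - exp(-tS[up] / riseS)
  out[dn] <- peak * exp(-(tS[dn] - p) / decayS)
  out / peak
}

# plateau end time such that the kernel's FWHM equals durationS
plateauEnd <- function(durationS, riseS, decayS) {
  halfWidth <- function(p) {
    peak <- 1 - exp(-p / riseS)
    tUp <- -riseS * log(1 - peak / 2)
    (p + decayS * log(2)) - tUp
  }
  lo <- 1e-6
  if (halfWidth(lo) >= durationS) {
    # decay tail alone is wider than the requested duration; degenerate but
    # legal (short site-level events with slow indicators)
    return(lo)
  }
  stats::uniroot(function(p) halfWidth(p) - durationS,
                 lower = lo, upper = durationS + 10 * decayS)$root
}

# total above-threshold extent of the kernel (used to reason about merge
# gaps in tests)
kernelSupraExtent <- function(durationS, riseS, decayS, level) {
  p <- plateauEnd(durationS, riseS, decayS)
  peak <- 1 - exp(-p / riseS)
  tUp <- if (level < 1) -riseS * log(pmax(1e-12, 1 - level)) else p
  tDn <- p + decayS * log(1 / level)
  c(up = tUp, down = tDn)
}

# frame start times in seconds for a movie-like object
frameTimes <- function(object) {
  (seq_len(nFrames(object)) - 1L) * frameInterval(object)
}

# linear-interpolated upward crossing times of `trace` (sampled at `times`)
# through `level`; refractorySec suppresses re-crossings within a window
upCrossings <- function(trace, times, level, refractorySec = 1) {
  n <- length(trace)
  if (n < 2L) return(numeric(0))
  below <- trace[-n] < level
  above <- trace[-1] >= level
  idx <- which(below & above)
  if (length(idx) == 0L) return(numeric(0))
  frac <- (level - trace[idx]) / (trace[idx + 1L] - trace[idx])
  tc <- times[idx] + frac * (times[idx + 1L] - times[idx])
  keep <- c(TRUE, diff(tc) >= refractorySec)
  # drop crossings inside the refractory window of an accepted one
  out <- numeric(0)
  last <- -Inf
  for (t in tc) {
    if (t - last >= refractorySec) {
      out <- c(out, t)
      last <- t
    }
  }
  out
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
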