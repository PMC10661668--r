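#' @include AllClasses.R
NULL

#' Integral capacitance from a slow cyclic voltammogram
#'
#' For a CV swept at constant scan rate `v` over a potential window
#' `dV = max(V) - min(V)`, the integral double-layer capacitance is
#' `C = (integral of |i| dV over the loop) / (2 * v * dV)`, evaluated by
#' trapezoidal integration over the sampled branch(es). For an ideal
#' capacitor (rectangular CV of half-height `i_c`) this reduces to
#' `C = i_c / v`.
#'
#' @param cv a [SampledTrace-class] with `x` = potential (V, strictly
#'   increasing samples of the sweep; both branches may be supplied as
#'   separate traces and averaged) and `y` = current (A).
#' @param scanRate sweep rate, V/s (> 0).
#' @return capacitance in farads.
#' @export
capacitanceFromCV <- function(cv, scanRate) {
  stopifnot(is(cv, "SampledTrace"))
  validObject(cv)
  if (!is.numeric(scanRate) || length(scanRate) != 1L || scanRate <= 0)
    stop("scanRate must be a single value > 0")
  dV <- max(cv@x) - min(cv@x)
  if (dV <= 0) stop("CV must span a non-degenerate potential window")
  absI <- abs(cv@y)
  # the supplied samples cover one sweep branch; the closed loop contributes
  # twice the branch integral, cancelling the factor 2 in the denominator
  area <- sum(diff(cv@x) * (absI[-1] + absI[-length(absI)]) / 2)
  area / (scanRate * dV)
}

.fitLine <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  b <- if (sxx > 0) sum((x - mx) * (y - my)) / sxx else 0
  a <- my - b * mx
  res <- y - (a + b * x)
  sst <- sum((y - my)^2)
  list(intercept = a, slope = b, sse = sum(res^2),
       r2 = if (sst > 0) 1 - sum(res^2) / sst else 1)
}

#' Classify a constant-current voltage excursion
#'
#' Under constant current a purely capacitive interface charges linearly,
#' `dV/dt = i / C`; once faradaic reactions take over, the slope collapses.
#' The trace is fit with a single line and with the best two-segment
#' piecewise line (breakpoint found by exhaustive search minimizing the
#' summed residual). Classification:
#' \itemize{
#'   \item \strong{faradaic_dominant} - the fitted rise over the initial
#'     window is below `flatFraction` of the trace's voltage scale (flat from
#'     the start, as for a non-polarizable electrode); `C_eff` is `NA`.
#'   \item \strong{faradaic_onset} - the two-segment fit reduces the residual
#'     by at least `improveFraction` and the second slope falls below half
#'     the first: an initial capacitive ramp with a detected transition, whose
#'     breakpoint is reported as `transition_time`.
#'   \item \strong{capacitive} - otherwise; a strictly rising linear ramp
#'     (initial-segment R^2 >= `r2Min` for a clean call), no transition.
#' }
#' `C_eff = i / slope` is estimated from the initial segment.
#'
#' @param exc a [SampledTrace-class] with `x` = time (s), `y` = voltage (V).
#' @param i drive current, amperes (> 0).
#' @param initFraction fraction of samples forming the initial window
#'   (default 0.25, at least 4 samples).
#' @param improveFraction minimum relative residual improvement for the
#'   two-segment model to be accepted (default 0.10).
#' @param flatFraction rise-to-scale ratio below which the trace is flat
#'   (default 0.05).
#' @param r2Min minimum initial-segment R^2 for a clean capacitive call.
#' @return list with `slope` (V/s, initial segment), `C_eff` (F or NA),
#'   `regime`, `transition_time` (s or NA), `r2_initial`.
#' @export
analyzeExcursion <- function(exc, i, initFraction = 0.25,
                             improveFraction = 0.10, flatFraction = 0.05,
                             r2Min = 0.99) {
  stopifnot(is(exc, "SampledTrace"))
  validObject(exc)
  if (!is.numeric(i) || length(i) != 1L || i <= 0) stop("i must be > 0")
  t <- exc@x; V <- exc@y
  n <- length(t)
  if (n < 4L) stop("insufficient data: need at least 4 samples")

  nInit <- max(4L, ceiling(initFraction * n))
  init <- .fitLine(t[seq_len(nInit)], V[seq_len(nInit)])
  one <- .fitLine(t, V)

  # best two-segment fit: breakpoint between samples k and k+1
  best <- list(sse = Inf, k = NA_integer_, s1 = NA_real_, s2 = NA_real_)
  for (k in 2:(n - 2)) {
    f1 <- .fitLine(t[1:k], V[1:k])
    f2 <- .fitLine(t[(k + 1):n], V[(k + 1):n])
    sse <- f1$sse + f2$sse
    if (sse < best$sse)
      best <- list(sse = sse, k = k, s1 = f1$slope, s2 = f2$slope)
  }

  vScale <- max(abs(V), max(V) - min(V))
  initialRise <- abs(init$slope) * (t[n] - t[1])
  if (vScale <= 0 || initialRise < flatFraction * vScale) {
    return(list(slope = init$slope, C_eff = NA_real_,
                regime = "faradaic_dominant", transition_time = NA_real_,
                r2_initial = init$r2))
  }

  improved <- one$sse > 0 && (one$sse - best$sse) / one$sse >= improveFraction
  if (improved && abs(best$s2) < 0.5 * abs(best$s1)) {
    slope <- best$s1
    return(list(slope = slope, C_eff = i / slope, regime = "faradaic_onset",
                transition_time = (t[best$k] + t[best$k + 1]) / 2,
                r2_initial = init$r2))
  }

  if (init$r2 < r2Min)
    warning("initial segment deviates from linearity (R^2 = ",
            signif(init$r2, 3), "); capacitive call is tentative")
  list(slope = init$slope, C_eff = i / init$slope, regime = "capacitive",
       transition_time = NA_real_, r2_initial = init$r2)
}

#' Read a two-column sampled trace from CSV
#'
#' Header required; first column is the abscissa (time in seconds for
#' excursions, potential in volts for CV), second the ordinate, SI units.
#'
#' @param path CSV file path.
#' @return a [SampledTrace-class].
#' @export
readSampledTrace <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("trace CSV needs two columns")
  SampledTrace(df[[1]], df[[2]])
}
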