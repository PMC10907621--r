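#' Detect the normalization anchor of a Cyclin B1 trace
#'
#' In \code{"inflection"} mode the anchor is the last frame before
#' sustained degradation: the trace is smoothed with a 3-frame median
#' filter and the anchor is the frame starting the first run of at least
#' \code{k} consecutive frame-to-frame drops steeper than
#' \code{rate_threshold} times the plateau level. \code{"anaphase_onset"}
#' and \code{"manual"} modes pass the corresponding annotation through.
#'
#' @param trace A \linkS4class{CyclinTrace} with at least 8 frames.
#' @param mode \code{"inflection"} (default), \code{"anaphase_onset"} or
#'   \code{"manual"}.
#' @param rate_threshold Decline threshold as a fraction of the plateau
#'   level per frame (default 0.02).
#' @param k Number of consecutive declining frames required (default 3).
#' @param manual Anchor time passed through in \code{"manual"} mode.
#' @return Anchor time in minutes.
#' @examples
#' tr <- makeCyclinTrace(plateau_min = 30, decay_t_half = 20,
#'                       noise_sd = 0, seed = 1)
#' detectAnchor(tr)
#' @export
detectAnchor <- function(trace, mode = c("inflection", "anaphase_onset",
                                         "manual"),
                         rate_threshold = 0.02, k = 3L, manual = NULL) {
  stopifnot(is(trace, "CyclinTrace"))
  mode <- match.arg(mode)
  if (mode == "manual") {
    if (is.null(manual)) stop("manual mode requires 'manual'", call. = FALSE)
    return(manual)
  }
  if (mode == "anaphase_onset") {
    if (is.na(trace@anaphaseTime))
      stop("anaphase_onset mode requires an annotated anaphase time",
           call. = FALSE)
    return(trace@anaphaseTime)
  }
  times <- traceTimes(trace)
  if (length(times) < 8L)
    stop("need at least 8 frames spanning plateau and decline",
         call. = FALSE)
  sm <- medianFilter3(traceIntensity(trace))
  plateau <- max(sm)
  thr <- rate_threshold * plateau
  n <- length(sm)
  ## sustained decline, judged on two-frame spans: the 3-point median
  ## filter flattens every other single-frame difference on a noisy
  ## monotone stretch, so single-frame differences alone are fragile
  two_frame <- (sm[seq_len(n - 2L) + 2L] - sm[seq_len(n - 2L)]) / 2 < -thr
  run <- 0L
  for (i in seq_along(two_frame)) {
    run <- if (two_frame[i]) run + 1L else 0L
    if (run >= k) {
      start <- i - k + 1L
      ## refine to the first frame whose own forward difference is steep:
      ## the two-frame criterion can trigger one frame before the drop
      for (j in start:min(start + k, n - 1L)) {
        if (sm[j + 1L] - sm[j] < -thr) return(times[j])
      }
      return(times[start])
    }
  }
  stop("no sustained decline found in trace", call. = FALSE)
}

#' Normalize a Cyclin B1 trace to its anchor
#'
#' Rescales the background-subtracted intensity so that the value at the
#' anchor time is 100 percent.
#'
#' @param trace A \linkS4class{CyclinTrace}.
#' @param anchor Anchor time in minutes (a frame time).
#' @return The trace with its \code{normalized} slot filled (percent) and
#'   \code{anchorTime} set.
#' @export
normalizeTrace <- function(trace, anchor) {
  stopifnot(is(trace, "CyclinTrace"))
  i <- which.min(abs(traceTimes(trace) - anchor))
  ref <- traceIntensity(trace)[i]
  if (ref <= 0)
    stop("non-positive intensity at the anchor", call. = FALSE)
  trace@normalized <- 100 * traceIntensity(trace) / ref
  trace@anchorTime <- traceTimes(trace)[i]
  validObject(trace)
  trace
}

#' Cyclin B1 degradation half-life
#'
#' The time after the anchor at which the normalized signal first crosses
#' 50 percent, linearly interpolated between frames.
#'
#' @param trace A normalized \linkS4class{CyclinTrace} (see
#'   \code{\link{normalizeTrace}}).
#' @return Half-life in minutes. When the series never crosses 50 percent
#'   the value is censored at the last observation minus the anchor, with
#'   attribute \code{censored = TRUE}.
#' @export
degradationHalfLife <- function(trace) {
  stopifnot(is(trace, "CyclinTrace"))
  if (length(trace@normalized) == 0L || is.na(trace@anchorTime))
    stop("trace must be normalized first (normalizeTrace)", call. = FALSE)
  times <- traceTimes(trace)
  v <- trace@normalized
  after <- which(times >= trace@anchorTime)
  below <- after[v[after] < 50]
  if (length(below) == 0L) {
    out <- max(times) - trace@anchorTime
    attr(out, "censored") <- TRUE
    return(out)
  }
  j <- below[1L]
  if (j == 1L || v[j - 1L] < 50) {
    t50 <- times[j]
  } else {
    ## linear interpolation across the crossing frame pair
    t50 <- times[j - 1L] + (v[j - 1L] - 50) / (v[j - 1L] - v[j]) *
      (times[j] - times[j - 1L])
  }
  out <- t50 - trace@anchorTime
  attr(out, "censored") <- FALSE
  out
}

#' Maximum Cyclin B1 degradation rate
#'
#' Renormalizes the trace to 100 percent at its mitotic maximum (the
#' maximum intensity after mitotic entry) and estimates the slope in a
#' sliding least-squares window; the magnitude of the most negative slope
#' is the maximum degradation rate, in percent of the mitotic-entry-scale
#' signal per minute.
#'
#' @param trace A \linkS4class{CyclinTrace} with \code{mitoticEntryTime}
#'   defined.
#' @param window Sliding window length in frames (default 3).
#' @return Rate in percent per minute (non-negative). A trace with no
#'   declining window returns 0 with attribute \code{no_decline = TRUE}.
#' @export
maxDegradationRate <- function(trace, window = 3L) {
  stopifnot(is(trace, "CyclinTrace"))
  if (is.na(trace@mitoticEntryTime))
    stop("'mitoticEntryTime' must be defined", call. = FALSE)
  times <- traceTimes(trace)
  keep <- times >= trace@mitoticEntryTime
  times <- times[keep]
  v <- traceIntensity(trace)[keep]
  if (length(v) < window)
    stop("fewer frames than the sliding window", call. = FALSE)
  v <- 100 * v / max(v)
  slopes <- vapply(seq_len(length(v) - window + 1L), function(i) {
    idx <- i:(i + window - 1L)
    coef(lm(v[idx] ~ times[idx]))[[2L]]
  }, numeric(1))
  worst <- min(slopes)
  if (worst >= -1e-9) {
    out <- 0
    attr(out, "no_decline") <- TRUE
    return(out)
  }
  -worst
}
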