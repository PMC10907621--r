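## S4 containers for the pipeline's central objects. Tables exchanged with
## CSV (spot records, screen tables, event tables) remain plain data.frames.

#' Multi-channel 3D image volume
#'
#' Container for a 3D fluorescence z-stack with one or more channels and
#' physical voxel dimensions. Data are stored as a 4D array indexed
#' \code{[z, y, x, channel]} with 0-based voxel centers at
#' \code{(index - 1) * voxelSize} micrometers per axis.
#'
#' @slot data 4D numeric array \code{[z, y, x, channel]}, arbitrary
#'   intensity units (camera counts).
#' @slot voxelSize numeric(3), voxel edge length in micrometers, order
#'   \code{(z, y, x)}.
#' @slot channelNames character vector naming the channels, same length as
#'   \code{dim(data)[4]}.
#' @exportClass ImageVolume
setClass("ImageVolume",
  slots = c(data = "array", voxelSize = "numeric", channelNames = "character"))

setValidity("ImageVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, "'data' must be a 4D array [z, y, x, channel]")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "'voxelSize' must be 3 positive values (z, y, x)")
  if (length(dim(object@data)) == 4L &&
      length(object@channelNames) != dim(object@data)[4L])
    msg <- c(msg, "'channelNames' must match the number of channels")
  if (length(msg)) msg else TRUE
})

#' Construct an ImageVolume
#'
#' @param data 4D array \code{[z, y, x, channel]} or 3D array (taken as a
#'   single channel).
#' @param voxelSize numeric(3) voxel size in micrometers \code{(z, y, x)}.
#' @param channelNames character vector of channel names.
#' @return An \linkS4class{ImageVolume}.
#' @examples
#' v <- ImageVolume(array(0, c(4, 8, 8)), voxelSize = c(0.2, 0.065, 0.065),
#'                  channelNames = "reference")
#' voxelSize(v)
#' @export
ImageVolume <- function(data, voxelSize = c(0.2, 0.065, 0.065),
                        channelNames = NULL) {
  if (length(dim(data)) == 3L) data <- array(data, c(dim(data), 1L))
  if (is.null(channelNames))
    channelNames <- paste0("channel", seq_len(dim(data)[4L]))
  new("ImageVolume", data = data, voxelSize = as.numeric(voxelSize),
      channelNames = as.character(channelNames))
}

#' @describeIn ImageVolume Channel names.
#' @param x,object An \code{ImageVolume}.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname ImageVolume
#' @export
setMethod("channelNames", "ImageVolume", function(x) x@channelNames)

#' @describeIn ImageVolume Voxel size in micrometers (z, y, x).
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname ImageVolume
#' @export
setMethod("voxelSize", "ImageVolume", function(x) x@voxelSize)

#' @describeIn ImageVolume Extract one channel as a 3D array, or the full
#'   4D array when \code{channel} is missing.
#' @param channel Channel name or index.
#' @export
setGeneric("imageData", function(x, channel) standardGeneric("imageData"))

#' @rdname ImageVolume
#' @export
setMethod("imageData", "ImageVolume", function(x, channel) {
  if (missing(channel)) return(x@data)
  ch <- resolveChannel(x, channel)
  x@data[, , , ch, drop = TRUE]
})

setMethod("dim", "ImageVolume", function(x) dim(x@data))

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat("ImageVolume:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4L], "channel(s):", paste(object@channelNames, collapse = ", "), "\n")
  cat("  voxel size (z,y,x):",
      paste(signif(object@voxelSize, 3), collapse = " x "), "um\n")
})

resolveChannel <- function(x, channel) {
  if (is.character(channel)) {
    ch <- match(channel, x@channelNames)
    if (is.na(ch)) stop("unknown channel: ", channel, call. = FALSE)
    return(ch)
  }
  ch <- as.integer(channel)
  if (ch < 1L || ch > dim(x@data)[4L]) stop("channel index out of range")
  ch
}

#' Spindle reference frame
#'
#' The two spindle-pole centroids, plus derived quantities: the pole--pole
#' axis unit vector, the midline point (midpoint of the poles) and the
#' spindle length. Kinetochore positions are projected onto this frame by
#' \code{\link{axisPosition}}.
#'
#' @slot poleA,poleB numeric(3), pole centroids in micrometers (z, y, x);
#'   \code{poleA} precedes \code{poleB} lexicographically.
#' @slot multipolar logical, \code{TRUE} when more than two pole candidates
#'   were present and the two brightest were used.
#' @exportClass SpindleFrame
setClass("SpindleFrame",
  slots = c(poleA = "numeric", poleB = "numeric", multipolar = "logical"))

setValidity("SpindleFrame", function(object) {
  msg <- character()
  if (length(object@poleA) != 3L || length(object@poleB) != 3L)
    msg <- c(msg, "poles must be 3D coordinates (z, y, x)")
  else if (sqrt(sum((object@poleA - object@poleB)^2)) <= 0)
    msg <- c(msg, "spindle length must be > 0 (distinct poles)")
  if (length(msg)) msg else TRUE
})

#' Construct a SpindleFrame
#'
#' @param poleA,poleB numeric(3) pole centroids in micrometers (z, y, x).
#'   Poles are reordered lexicographically so the frame is deterministic.
#' @param multipolar logical flag, see class docs.
#' @return A \linkS4class{SpindleFrame}.
#' @examples
#' sf <- SpindleFrame(c(2, 1, 5), c(2, 11, 5))
#' spindleLength(sf)
#' @export
SpindleFrame <- function(poleA, poleB, multipolar = FALSE) {
  poleA <- as.numeric(poleA); poleB <- as.numeric(poleB)
  ord <- order(c(poleA[1], poleB[1]), c(poleA[2], poleB[2]),
               c(poleA[3], poleB[3]))
  poles <- list(poleA, poleB)[ord]
  new("SpindleFrame", poleA = poles[[1L]], poleB = poles[[2L]],
      multipolar = isTRUE(multipolar))
}

#' @describeIn SpindleFrame First pole centroid (micrometers, z,y,x).
#' @param x,object A \code{SpindleFrame}.
#' @export
setGeneric("poleA", function(x) standardGeneric("poleA"))
#' @rdname SpindleFrame
#' @export
setMethod("poleA", "SpindleFrame", function(x) x@poleA)

#' @describeIn SpindleFrame Second pole centroid.
#' @export
setGeneric("poleB", function(x) standardGeneric("poleB"))
#' @rdname SpindleFrame
#' @export
setMethod("poleB", "SpindleFrame", function(x) x@poleB)

#' @describeIn SpindleFrame Pole-to-pole distance in micrometers.
#' @export
setGeneric("spindleLength", function(x) standardGeneric("spindleLength"))
#' @rdname SpindleFrame
#' @export
setMethod("spindleLength", "SpindleFrame",
          function(x) sqrt(sum((x@poleB - x@poleA)^2)))

#' @describeIn SpindleFrame Unit vector along the pole--pole axis.
#' @export
setGeneric("spindleAxis", function(x) standardGeneric("spindleAxis"))
#' @rdname SpindleFrame
#' @export
setMethod("spindleAxis", "SpindleFrame", function(x) {
  v <- x@poleB - x@poleA
  v / sqrt(sum(v^2))
})

#' @describeIn SpindleFrame Midline point (midpoint of the two poles).
#' @export
setGeneric("spindleMidpoint", function(x) standardGeneric("spindleMidpoint"))
#' @rdname SpindleFrame
#' @export
setMethod("spindleMidpoint", "SpindleFrame",
          function(x) (x@poleA + x@poleB) / 2)

#' @describeIn SpindleFrame Whether >2 pole candidates were detected.
#' @export
setGeneric("isMultipolar", function(x) standardGeneric("isMultipolar"))
#' @rdname SpindleFrame
#' @export
setMethod("isMultipolar", "SpindleFrame", function(x) x@multipolar)

setMethod("show", "SpindleFrame", function(object) {
  cat("SpindleFrame\n")
  cat("  pole A (z,y,x um):", paste(signif(object@poleA, 4), collapse = ", "), "\n")
  cat("  pole B (z,y,x um):", paste(signif(object@poleB, 4), collapse = ", "), "\n")
  cat("  length:", signif(spindleLength(object), 4), "um",
      if (object@multipolar) " [multipolar: two brightest of >2 poles]", "\n")
})

#' Photoactivation decay trace
#'
#' Integrated intensity of a photoactivated tubulin band over time, split
#' into the activated spindle half and the contralateral
#' (non-photoactivated) half used for background subtraction. Frame 0 is
#' the first post-activation frame; the single pre-activation frame is
#' stored separately. Optionally carries per-frame intensity profiles along
#' the spindle axis for flux measurement.
#'
#' @slot times numeric, acquisition times in minutes from the first
#'   post-activation frame (default spacing 10 s).
#' @slot activated,contralateral numeric, integrated intensities per frame
#'   (arbitrary units), same length as \code{times}.
#' @slot preActivation numeric(2) \code{(activated, contralateral)} at the
#'   pre-activation frame, or numeric(0) when absent.
#' @slot profilePositions numeric, axis positions (micrometers) of the
#'   profile bins; numeric(0) when no profiles stored.
#' @slot profiles numeric matrix \code{[frame, position]} of intensities
#'   along the spindle axis, or 0-row matrix.
#' @slot anaphaseEntered logical; traces from cells that entered anaphase
#'   during the time-lapse are excluded from analysis.
#' @exportClass DecayTrace
setClass("DecayTrace",
  slots = c(times = "numeric", activated = "numeric",
            contralateral = "numeric", preActivation = "numeric",
            profilePositions = "numeric", profiles = "matrix",
            anaphaseEntered = "logical"))

setValidity("DecayTrace", function(object) {
  msg <- character()
  n <- length(object@times)
  if (length(object@activated) != n || length(object@contralateral) != n)
    msg <- c(msg, "'activated' and 'contralateral' must match 'times' length")
  if (n > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "'times' must be strictly increasing")
  if (nrow(object@profiles) > 0L) {
    if (nrow(object@profiles) != n)
      msg <- c(msg, "'profiles' must have one row per frame")
    if (ncol(object@profiles) != length(object@profilePositions))
      msg <- c(msg, "'profilePositions' must match profile columns")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DecayTrace
#'
#' @param times Times in minutes (frame 0 at time 0).
#' @param activated,contralateral Integrated intensities per frame.
#' @param preActivation Optional numeric(2) pre-activation intensities.
#' @param profilePositions,profiles Optional axis profile (positions in
#'   micrometers; matrix \code{[frame, position]}).
#' @param anaphaseEntered Logical exclusion flag.
#' @return A \linkS4class{DecayTrace}.
#' @export
DecayTrace <- function(times, activated, contralateral,
                       preActivation = numeric(0),
                       profilePositions = numeric(0),
                       profiles = matrix(numeric(0), 0, 0),
                       anaphaseEntered = FALSE) {
  new("DecayTrace", times = as.numeric(times),
      activated = as.numeric(activated),
      contralateral = as.numeric(contralateral),
      preActivation = as.numeric(preActivation),
      profilePositions = as.numeric(profilePositions),
      profiles = profiles, anaphaseEntered = isTRUE(anaphaseEntered))
}

#' @describeIn DecayTrace Frame times in minutes.
#' @param x,object A \code{DecayTrace}.
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))
#' @rdname DecayTrace
#' @export
setMethod("traceTimes", "DecayTrace", function(x) x@times)

#' @describeIn DecayTrace Activated-half integrated intensity.
#' @export
setGeneric("activatedIntensity", function(x) standardGeneric("activatedIntensity"))
#' @rdname DecayTrace
#' @export
setMethod("activatedIntensity", "DecayTrace", function(x) x@activated)

#' @describeIn DecayTrace Contralateral-half integrated intensity.
#' @export
setGeneric("contralateralIntensity",
           function(x) standardGeneric("contralateralIntensity"))
#' @rdname DecayTrace
#' @export
setMethod("contralateralIntensity", "DecayTrace", function(x) x@contralateral)

#' @describeIn DecayTrace Whether the cell entered anaphase (exclusion).
#' @export
setGeneric("anaphaseEntered", function(x) standardGeneric("anaphaseEntered"))
#' @rdname DecayTrace
#' @export
setMethod("anaphaseEntered", "DecayTrace", function(x) x@anaphaseEntered)

setMethod("length", "DecayTrace", function(x) length(x@times))

setMethod("show", "DecayTrace", function(object) {
  cat("DecayTrace:", length(object@times), "frames over",
      signif(max(object@times), 3), "min")
  if (nrow(object@profiles) > 0L)
    cat(";", ncol(object@profiles), "axis-profile bins")
  if (object@anaphaseEntered) cat(" [entered anaphase: excluded]")
  cat("\n")
})

#' Two-phase exponential decay fit
#'
#' Parameters of the model
#' \deqn{I(t) = f \cdot 2^{-t/t_{1/2,fast}} + (1-f) \cdot 2^{-t/t_{1/2,slow}}}
#' fitted to a normalized photoactivation decay. The fast phase reports the
#' turnover of bulk (non-kinetochore) spindle microtubules; the slow phase
#' reports the turnover of stable kinetochore-attached fibers (K-MT).
#'
#' @slot fracFast fraction of the signal decaying with the fast half-life,
#'   in \code{[0, 1]}.
#' @slot tHalfFast,tHalfSlow half-lives in minutes,
#'   \code{0 < tHalfFast <= tHalfSlow}.
#' @slot rss residual sum of squares of the fit.
#' @slot converged logical.
#' @slot atBound logical, \code{TRUE} when \code{tHalfSlow} sits at its
#'   upper identifiability bound (e.g. for a constant series).
#' @slot nFrames number of frames fitted.
#' @exportClass TwoPhaseFit
setClass("TwoPhaseFit",
  slots = c(fracFast = "numeric", tHalfFast = "numeric",
            tHalfSlow = "numeric", rss = "numeric", converged = "logical",
            atBound = "logical", nFrames = "integer"))

setValidity("TwoPhaseFit", function(object) {
  msg <- character()
  if (object@fracFast < -1e-9 || object@fracFast > 1 + 1e-9)
    msg <- c(msg, "'fracFast' must be in [0, 1]")
  if (object@tHalfFast <= 0 || object@tHalfSlow < object@tHalfFast - 1e-9)
    msg <- c(msg, "'tHalfFast' must be in (0, tHalfSlow]")
  if (length(msg)) msg else TRUE
})

#' @describeIn TwoPhaseFit Fast-phase fraction.
#' @param x,object A \code{TwoPhaseFit}.
#' @export
setGeneric("fracFast", function(x) standardGeneric("fracFast"))
#' @rdname TwoPhaseFit
#' @export
setMethod("fracFast", "TwoPhaseFit", function(x) x@fracFast)

#' @describeIn TwoPhaseFit Fast (bulk-spindle) half-life in minutes.
#' @export
setGeneric("tHalfFast", function(x) standardGeneric("tHalfFast"))
#' @rdname TwoPhaseFit
#' @export
setMethod("tHalfFast", "TwoPhaseFit", function(x) x@tHalfFast)

#' @describeIn TwoPhaseFit Slow (K-MT) half-life in minutes.
#' @export
setGeneric("tHalfSlow", function(x) standardGeneric("tHalfSlow"))
#' @rdname TwoPhaseFit
#' @export
setMethod("tHalfSlow", "TwoPhaseFit", function(x) x@tHalfSlow)

setMethod("show", "TwoPhaseFit", function(object) {
  cat(sprintf(
    "TwoPhaseFit: f_fast = %.3f, t1/2 fast = %.3g min, t1/2 slow (K-MT) = %.3g min\n",
    object@fracFast, object@tHalfFast, object@tHalfSlow))
  cat(sprintf("  rss = %.4g over %d frames; converged: %s%s\n", object@rss,
      object@nFrames, object@converged,
      if (object@atBound) "; slow half-life at upper bound" else ""))
})

#' Poleward flux measurement
#'
#' Position of the photoactivated band along the spindle axis per frame and
#' the fitted drift velocity. Positive velocity means poleward motion
#' (increasing distance from the midline on the activated side).
#'
#' @slot times numeric, frame times in minutes.
#' @slot bandPositions numeric, band (profile argmax) position per frame in
#'   micrometers.
#' @slot velocity numeric, drift velocity in micrometers per minute.
#' @slot r2 numeric, R-squared of the linear position-vs-time fit.
#' @slot unreliable logical, set when the band argmax hit the profile edge
#'   in more than half of the frames.
#' @exportClass FluxResult
setClass("FluxResult",
  slots = c(times = "numeric", bandPositions = "numeric",
            velocity = "numeric", r2 = "numeric", unreliable = "logical"))

#' @describeIn FluxResult Drift velocity (micrometers/min, poleward > 0).
#' @param x,object A \code{FluxResult}.
#' @export
setGeneric("fluxVelocity", function(x) standardGeneric("fluxVelocity"))
#' @rdname FluxResult
#' @export
setMethod("fluxVelocity", "FluxResult", function(x) x@velocity)

#' @describeIn FluxResult Band positions per frame (micrometers).
#' @export
setGeneric("bandPositions", function(x) standardGeneric("bandPositions"))
#' @rdname FluxResult
#' @export
setMethod("bandPositions", "FluxResult", function(x) x@bandPositions)

setMethod("show", "FluxResult", function(object) {
  cat(sprintf("FluxResult: velocity = %.3g um/min (r2 = %.3f)%s\n",
      object@velocity, object@r2,
      if (object@unreliable) " [unreliable: band at profile edge]" else ""))
})

#' Cyclin B1 live-cell intensity trace
#'
#' Background-subtracted Cyclin B1 intensity over time for one cell,
#' sampled at 2.5-minute intervals by default, with kinetic anchor times
#' (mitotic entry, metaphase inflection / anaphase onset) either annotated
#' or detected.
#'
#' @slot times numeric, minutes.
#' @slot intensity numeric, background-subtracted arbitrary units.
#' @slot mitoticEntryTime,anchorTime,anaphaseTime numeric (minutes), may be
#'   \code{NA} until annotated or detected.
#' @slot normalized numeric, percent series (100 at the anchor) or
#'   numeric(0) before normalization.
#' @exportClass CyclinTrace
setClass("CyclinTrace",
  slots = c(times = "numeric", intensity = "numeric",
            mitoticEntryTime = "numeric", anchorTime = "numeric",
            anaphaseTime = "numeric", normalized = "numeric"))

setValidity("CyclinTrace", function(object) {
  msg <- character()
  if (length(object@times) != length(object@intensity))
    msg <- c(msg, "'times' and 'intensity' lengths differ")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "'times' must be strictly increasing")
  ts <- c(object@mitoticEntryTime, object@anchorTime, object@anaphaseTime)
  ts <- ts[!is.na(ts)]
  if (length(ts) > 1L && any(diff(ts) < 0))
    msg <- c(msg, "entry <= anchor <= anaphase required where present")
  if (length(msg)) msg else TRUE
})

#' Construct a CyclinTrace
#'
#' @param times,intensity Numeric vectors (minutes; background-subtracted
#'   arbitrary units).
#' @param mitoticEntryTime,anchorTime,anaphaseTime Optional anchor times in
#'   minutes (\code{NA} when unknown).
#' @return A \linkS4class{CyclinTrace}.
#' @export
CyclinTrace <- function(times, intensity, mitoticEntryTime = NA_real_,
                        anchorTime = NA_real_, anaphaseTime = NA_real_) {
  new("CyclinTrace", times = as.numeric(times),
      intensity = as.numeric(intensity),
      mitoticEntryTime = as.numeric(mitoticEntryTime),
      anchorTime = as.numeric(anchorTime),
      anaphaseTime = as.numeric(anaphaseTime), normalized = numeric(0))
}

#' @describeIn CyclinTrace Anchor (inflection/anaphase-onset) time, minutes.
#' @param x,object A \code{CyclinTrace}.
#' @export
setGeneric("anchorTime", function(x) standardGeneric("anchorTime"))
#' @rdname CyclinTrace
#' @export
setMethod("anchorTime", "CyclinTrace", function(x) x@anchorTime)

#' @describeIn CyclinTrace Intensity series (arbitrary units).
#' @export
setGeneric("traceIntensity", function(x) standardGeneric("traceIntensity"))
#' @rdname CyclinTrace
#' @export
setMethod("traceIntensity", "CyclinTrace", function(x) x@intensity)

#' @rdname CyclinTrace
#' @export
setMethod("traceTimes", "CyclinTrace", function(x) x@times)

setMethod("length", "CyclinTrace", function(x) length(x@times))

setMethod("show", "CyclinTrace", function(object) {
  cat("CyclinTrace:", length(object@times), "frames,",
      signif(min(object@times), 3), "-", signif(max(object@times), 3), "min\n")
  cat("  entry:", object@mitoticEntryTime, " anchor:", object@anchorTime,
      " anaphase:", object@anaphaseTime, "(min)\n")
})

#' Four-parameter logistic dose-response fit
#'
#' Variable-slope (four-parameter) model
#' \deqn{y = bottom + (top - bottom) / (1 + (dose/IC_{50})^{hill})}
#' fitted to viability responses. On the percent-viability scale the
#' plateau toxicity is \code{100 - bottom}.
#'
#' @slot bottom,top response units (plateaus).
#' @slot ic50 half-maximal concentration (same units as the doses).
#' @slot hill slope factor.
#' @slot residuals per-observation residuals.
#' @slot plateauToxicity \code{100 - bottom}, percent (meaningful when the
#'   responses are percent viability).
#' @slot converged,flat logical; \code{flat} marks degenerate data where
#'   the hill slope and IC50 are unidentifiable.
#' @exportClass DoseResponseFit
setClass("DoseResponseFit",
  slots = c(bottom = "numeric", top = "numeric", ic50 = "numeric",
            hill = "numeric", residuals = "numeric",
            plateauToxicity = "numeric", converged = "logical",
            flat = "logical"))

#' @describeIn DoseResponseFit Fitted IC50.
#' @param x,object A \code{DoseResponseFit}.
#' @export
setGeneric("ic50", function(x) standardGeneric("ic50"))
#' @rdname DoseResponseFit
#' @export
setMethod("ic50", "DoseResponseFit", function(x) x@ic50)

#' @describeIn DoseResponseFit Hill slope.
#' @export
setGeneric("hillSlope", function(x) standardGeneric("hillSlope"))
#' @rdname DoseResponseFit
#' @export
setMethod("hillSlope", "DoseResponseFit", function(x) x@hill)

#' @describeIn DoseResponseFit Plateau toxicity (percent), 100 - bottom.
#' @export
setGeneric("plateauToxicity", function(x) standardGeneric("plateauToxicity"))
#' @rdname DoseResponseFit
#' @export
setMethod("plateauToxicity", "DoseResponseFit", function(x) x@plateauToxicity)

setMethod("show", "DoseResponseFit", function(object) {
  if (object@flat) {
    cat("DoseResponseFit: flat responses; hill/IC50 unidentifiable\n")
    return(invisible(NULL))
  }
  cat(sprintf(
    "DoseResponseFit: bottom = %.3g, top = %.3g, IC50 = %.4g, hill = %.3g\n",
    object@bottom, object@top, object@ic50, object@hill))
  cat(sprintf("  plateau toxicity = %.3g%%; converged: %s\n",
      object@plateauToxicity, object@converged))
})
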