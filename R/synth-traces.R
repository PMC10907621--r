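#' Generate a synthetic photoactivation decay series
#'
#' Emulates fluorescence dissipation after photoactivation of a tubulin
#' band: one pre-activation frame followed by \code{n_frames} frames at
#' 10-second spacing. The activated-half integrated intensity follows the
#' two-phase decay
#' \deqn{I(t) = A_0 [f \cdot 2^{-t/t_{fast}} + (1-f) \cdot 2^{-t/t_{slow}}] + b}
#' while the contralateral half carries the matched background \code{b}.
#' The band's intensity profile along the spindle axis drifts poleward at
#' the given flux velocity.
#'
#' @param t_fast,t_slow Fast and slow half-lives in minutes
#'   (\code{0 < t_fast < t_slow}).
#' @param frac_fast Fraction of signal in the fast phase, in \code{[0, 1]}.
#' @param flux Poleward drift velocity of the band, micrometers/minute.
#' @param noise_sd Gaussian noise sd as a fraction of the initial
#'   activated amplitude.
#' @param seed Integer seed.
#' @param n_frames Number of post-activation frames (default 37: 0 to
#'   6 min at 10-s spacing).
#' @param frame_interval Frame spacing in seconds (default 10).
#' @param amplitude Initial activated signal above background (arbitrary
#'   units).
#' @param background Background intensity on both spindle halves.
#' @param band_center Initial band position, micrometers from the midline
#'   (activated side positive).
#' @param band_sigma Gaussian band width, micrometers.
#' @param profile_spacing Axis profile bin spacing, micrometers.
#' @return A \linkS4class{DecayTrace} whose attributes \code{truth} record
#'   the planted parameters.
#' @examples
#' tr <- makePhotoactivationSeries(1.5, 10, 0.7, flux = 0.5,
#'                                 noise_sd = 0, seed = 1)
#' tr
#' @export
makePhotoactivationSeries <- function(t_fast, t_slow, frac_fast, flux = 0,
                                      noise_sd = 0, seed = 1L,
                                      n_frames = 37L, frame_interval = 10,
                                      amplitude = 1000, background = 200,
                                      band_center = 2, band_sigma = 0.75,
                                      profile_spacing = 0.25) {
  stopifnotScalar(t_fast, "t_fast", positive = TRUE)
  stopifnotScalar(t_slow, "t_slow", positive = TRUE)
  if (t_fast >= t_slow) stop("need 0 < t_fast < t_slow", call. = FALSE)
  if (frac_fast < 0 || frac_fast > 1)
    stop("'frac_fast' must be in [0, 1]", call. = FALSE)

  withSeed(seed, {
    t_min <- (seq_len(n_frames) - 1L) * frame_interval / 60
    decay <- frac_fast * 2^(-t_min / t_fast) +
      (1 - frac_fast) * 2^(-t_min / t_slow)
    noise <- function(k) rnorm(k, 0, noise_sd * amplitude)
    activated <- amplitude * decay + background + noise(n_frames)
    contralateral <- background + noise(n_frames)
    pre <- c(background, background) + noise(2L)

    positions <- seq(0, band_center + max(flux, 0) * max(t_min) + 3,
                     by = profile_spacing)
    centers <- band_center + flux * t_min
    profiles <- outer(seq_len(n_frames), seq_along(positions),
                      function(i, j) {
                        amplitude * decay[i] *
                          exp(-(positions[j] - centers[i])^2 /
                                (2 * band_sigma^2))
                      })
    profiles <- profiles + matrix(noise(length(profiles)),
                                  nrow = n_frames)

    tr <- DecayTrace(times = t_min, activated = activated,
                     contralateral = contralateral, preActivation = pre,
                     profilePositions = positions, profiles = profiles)
    attr(tr, "truth") <- list(t_fast = t_fast, t_slow = t_slow,
                              frac_fast = frac_fast, flux = flux,
                              band_centers = centers,
                              amplitude = amplitude,
                              background = background)
    tr
  })
}

#' Generate a synthetic Cyclin B1 degradation trace
#'
#' Produces a background-subtracted Cyclin B1 intensity series sampled
#' every 2.5 minutes: a mitotic plateau (optionally gently rising) from
#' mitotic entry, followed by degradation from the anchor (metaphase
#' inflection / anaphase-onset) time onward, either exponential with a
#' given half-life or linear at a given rate.
#'
#' @param plateau_min Plateau duration in minutes; the true anchor time is
#'   \code{plateau_min} after mitotic entry (entry at t = 0).
#' @param decay_t_half Exponential degradation half-life, minutes (used
#'   when \code{decline = "exponential"}).
#' @param anchor_mode Recorded detection mode; passed through to the truth
#'   attribute (\code{"inflection"} or \code{"anaphase_onset"}).
#' @param noise_sd Gaussian noise sd as a fraction of the plateau level.
#' @param seed Integer seed.
#' @param decline \code{"exponential"} or \code{"linear"}.
#' @param linear_rate Linear decline rate, percent of plateau per minute
#'   (used when \code{decline = "linear"}).
#' @param rise_rate Plateau rise, percent of plateau per minute (0 = flat).
#' @param duration_after Minutes simulated past the anchor.
#' @param frame_interval Sampling interval in minutes (default 2.5).
#' @param level Plateau intensity (arbitrary units).
#' @return A \linkS4class{CyclinTrace} with \code{mitoticEntryTime = 0};
#'   the attribute \code{truth} records the planted anchor time and
#'   kinetic parameters. The trace's \code{anchorTime} slot is left
#'   \code{NA}: detection is the analysis step under test.
#' @examples
#' tr <- makeCyclinTrace(plateau_min = 30, decay_t_half = 20,
#'                       noise_sd = 0, seed = 1)
#' attr(tr, "truth")$anchor_time
#' @export
makeCyclinTrace <- function(plateau_min = 30, decay_t_half = 20,
                            anchor_mode = "inflection", noise_sd = 0,
                            seed = 1L, decline = c("exponential", "linear"),
                            linear_rate = 5, rise_rate = 0,
                            duration_after = 60, frame_interval = 2.5,
                            level = 1000) {
  decline <- match.arg(decline)
  stopifnotScalar(plateau_min, "plateau_min", positive = TRUE)
  stopifnotScalar(decay_t_half, "decay_t_half", positive = TRUE)
  withSeed(seed, {
    times <- seq(0, plateau_min + duration_after, by = frame_interval)
    dt <- times - plateau_min
    base <- ifelse(times <= plateau_min,
                   level * (1 + rise_rate / 100 * times),
                   if (decline == "exponential")
                     level * (1 + rise_rate / 100 * plateau_min) *
                       2^(-(pmax(dt, 0)) / decay_t_half)
                   else
                     pmax(level * (1 + rise_rate / 100 * plateau_min) *
                            (1 - linear_rate / 100 * pmax(dt, 0)), 0))
    intensity <- base + rnorm(length(times), 0, noise_sd * level)
    tr <- CyclinTrace(times = times, intensity = intensity,
                      mitoticEntryTime = 0)
    attr(tr, "truth") <- list(anchor_time = plateau_min,
                              anchor_mode = anchor_mode,
                              decay_t_half = decay_t_half,
                              decline = decline,
                              linear_rate = linear_rate, level = level)
    tr
  })
}
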