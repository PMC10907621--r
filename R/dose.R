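#' Viability, toxicity and rescue metrics from control signals
#'
#' Endpoint-assay metrics computed from condition-mean signals:
#' \deqn{\%Viability = (S_{sample} - S_{DMN}) / (S_{DMSO} - S_{DMN})
#'   \times 100}
#' \deqn{\%Toxicity = 100 - \%Viability}
#' DMN (dimethylenastron) wells define the full-arrest baseline and DMSO
#' wells the vehicle (full-viability) reference. With
#' \code{signal_media} supplied, media wells replace DMN as the baseline
#' (media normalization, used when a perturbation rescues growth in DMN).
#'
#' @param signal_sample,signal_dmso,signal_dmn Condition-mean signals
#'   (arbitrary units).
#' @param signal_media Optional media-only baseline replacing
#'   \code{signal_dmn}.
#' @return A list with \code{viability} and \code{toxicity} (percent).
#' @examples
#' viabilityMetrics(0.6, 1.0, 0.2)  # 50% viability
#' @export
viabilityMetrics <- function(signal_sample, signal_dmso, signal_dmn,
                             signal_media = NULL) {
  baseline <- signal_media %||% signal_dmn
  stopifnotScalar(signal_sample, "signal_sample")
  stopifnotScalar(signal_dmso, "signal_dmso")
  stopifnotScalar(baseline, "baseline")
  denom <- signal_dmso - baseline
  if (denom == 0) stop("zero denominator (DMSO equals baseline)",
                       call. = FALSE)
  viability <- (signal_sample - baseline) / denom * 100
  list(viability = viability, toxicity = 100 - viability)
}

#' Percent viability rescue of a perturbation under drug
#'
#' \deqn{\%Rescue = (S_{sample,drug} - S_{WT,drug}) /
#'   (S_{WT,DMSO} - S_{WT,drug}) \times 100}
#' measures how far a perturbed line's signal under drug climbs from the
#' wild-type-under-drug level toward the wild-type vehicle level.
#'
#' @param signal_sample_drug Perturbed sample signal under the drug.
#' @param signal_wt_drug,signal_wt_dmso Wild-type signals under drug and
#'   vehicle.
#' @return Percent rescue (scalar).
#' @export
viabilityRescue <- function(signal_sample_drug, signal_wt_drug,
                            signal_wt_dmso) {
  stopifnotScalar(signal_sample_drug, "signal_sample_drug")
  stopifnotScalar(signal_wt_drug, "signal_wt_drug")
  stopifnotScalar(signal_wt_dmso, "signal_wt_dmso")
  denom <- signal_wt_dmso - signal_wt_drug
  if (denom == 0) stop("zero denominator", call. = FALSE)
  (signal_sample_drug - signal_wt_drug) / denom * 100
}

fourPLModel <- function(dose, bottom, top, log_ic50, hill) {
  bottom + (top - bottom) / (1 + (dose / exp(log_ic50))^hill)
}

#' Fit a variable-slope four-parameter dose-response curve
#'
#' Least-squares fit of
#' \deqn{y = bottom + (top - bottom) / (1 + (dose/IC_{50})^{hill})}
#' with the IC50 parameterized internally on the log scale and
#' multi-start over the hill-slope sign.
#'
#' @param doses Dose vector (> 0), at least 4 distinct values.
#' @param responses Response vector (same length).
#' @return A \linkS4class{DoseResponseFit}; \code{bottom <= top} after
#'   canonicalization. Flat (degenerate) responses yield a flagged fit
#'   (\code{flat = TRUE}) with unidentifiable hill/IC50 (NA).
#' @examples
#' d <- 10^seq(0, 3, length.out = 8)
#' y <- 20 + (100 - 20) / (1 + (d / 50)^1.2)
#' fitFourParameter(d, y)
#' @export
fitFourParameter <- function(doses, responses) {
  if (any(doses <= 0)) stop("doses must be > 0", call. = FALSE)
  if (length(unique(doses)) < 4L)
    stop("need at least 4 distinct doses", call. = FALSE)
  if (length(doses) != length(responses))
    stop("length mismatch", call. = FALSE)

  rng <- diff(range(responses))
  if (rng <= 1e-10 * max(abs(responses), 1)) {
    return(new("DoseResponseFit", bottom = mean(responses),
               top = mean(responses), ic50 = NA_real_, hill = NA_real_,
               residuals = responses - mean(responses),
               plateauToxicity = 100 - mean(responses),
               converged = FALSE, flat = TRUE))
  }

  mid <- exp(mean(log(range(doses))))
  best <- NULL
  for (hill0 in c(1, -1, 2, -2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        responses ~ fourPLModel(doses, bottom, top, log_ic50, hill),
        start = list(bottom = min(responses), top = max(responses),
                     log_ic50 = log(mid), hill = hill0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(par = coef(fit), rss = rss, res = resid(fit),
                   converged = fit$convInfo$isConv %||% TRUE)
  }
  if (is.null(best)) stop("four-parameter fit failed", call. = FALSE)

  par <- best$par
  bottom <- par[["bottom"]]; top <- par[["top"]]; hill <- par[["hill"]]
  ## canonical orientation: bottom <= top (sign flip of hill compensates)
  if (bottom > top) {
    tmp <- bottom; bottom <- top; top <- tmp
    hill <- -hill
  }
  new("DoseResponseFit", bottom = bottom, top = top,
      ic50 = exp(par[["log_ic50"]]), hill = hill,
      residuals = as.numeric(best$res),
      plateauToxicity = 100 - bottom,
      converged = isTRUE(best$converged), flat = FALSE)
}

#' Fit a dose-response curve from a plate table
#'
#' Convenience wrapper: converts raw plate absorbances to percent
#' viability using the plate's DMSO and DMN control means, then fits the
#' four-parameter model to the per-well viabilities.
#'
#' @param plate data.frame with \code{condition}, \code{dose},
#'   \code{absorbance} (as from \code{\link{makeViabilityPlate}}).
#' @return A list with \code{fit} (a \linkS4class{DoseResponseFit} on the
#'   percent-viability scale, so \code{plateauToxicity} is meaningful)
#'   and \code{viability} (per-well percent viabilities).
#' @export
fitPlate <- function(plate) {
  s_dmso <- mean(plate$absorbance[plate$condition == "DMSO"])
  s_dmn <- mean(plate$absorbance[plate$condition == "DMN"])
  sample <- plate[plate$condition == "sample", ]
  viab <- (sample$absorbance - s_dmn) / (s_dmso - s_dmn) * 100
  list(fit = fitFourParameter(sample$dose, viab),
       viability = data.frame(dose = sample$dose, viability = viab))
}

#' Classify drug sensitivity from 5-day toxicity
#'
#' Cell lines with more than 40 percent toxicity are sensitive; below 20
#' percent, insensitive; the gap is an explicit intermediate class.
#'
#' @param toxicity Percent toxicity (finite numeric vector).
#' @return Character vector: \code{"sensitive"}, \code{"insensitive"} or
#'   \code{"intermediate"}.
#' @examples
#' classifySensitivity(c(45, 15, 30))
#' @export
classifySensitivity <- function(toxicity) {
  if (!all(is.finite(toxicity)))
    stop("'toxicity' must be finite", call. = FALSE)
  ifelse(toxicity > 40, "sensitive",
         ifelse(toxicity < 20, "insensitive", "intermediate"))
}
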