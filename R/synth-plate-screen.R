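#' Generate a synthetic 96-well viability plate
#'
#' Emulates a 5-day endpoint (MTT-style) viability assay: triplicate
#' absorbance responses per dose following a four-parameter logistic
#' curve, plus DMSO (vehicle, full-viability) and DMN (arrest,
#' baseline-death) control wells.
#'
#' @param four_pl Numeric(4): \code{(bottom, top, ic50, hill)} of the true
#'   curve, on the absorbance scale.
#' @param doses Dose series (same units as \code{ic50}; must be > 0).
#' @param noise_sd Gaussian noise sd as a fraction of \code{top}.
#' @param seed Integer seed.
#' @param n_replicates Wells per dose and per control (default 3).
#' @return A data.frame with columns \code{well}, \code{condition}
#'   (\code{"sample"}, \code{"DMSO"}, \code{"DMN"}), \code{dose}
#'   (\code{NA} for controls) and \code{absorbance}. The attribute
#'   \code{truth} records the planted curve.
#' @examples
#' plate <- makeViabilityPlate(c(20, 100, 50, 1.2),
#'                             doses = 10^seq(0, 3, length.out = 8),
#'                             noise_sd = 0, seed = 1)
#' head(plate)
#' @export
makeViabilityPlate <- function(four_pl, doses, noise_sd = 0, seed = 1L,
                               n_replicates = 3L) {
  stopifnot(length(four_pl) == 4L)
  bottom <- four_pl[1L]; top <- four_pl[2L]
  ic50 <- four_pl[3L]; hill <- four_pl[4L]
  stopifnotScalar(ic50, "ic50", positive = TRUE)
  if (any(doses <= 0)) stop("doses must be > 0", call. = FALSE)
  withSeed(seed, {
    resp <- bottom + (top - bottom) / (1 + (doses / ic50)^hill)
    df <- rbind(
      data.frame(condition = "sample",
                 dose = rep(doses, each = n_replicates),
                 absorbance = rep(resp, each = n_replicates)),
      data.frame(condition = "DMSO", dose = NA_real_,
                 absorbance = rep(top, n_replicates)),
      data.frame(condition = "DMN", dose = NA_real_,
                 absorbance = rep(bottom, n_replicates)))
    df$absorbance <- df$absorbance + rnorm(nrow(df), 0, noise_sd * top)
    df <- cbind(well = sprintf("W%02d", seq_len(nrow(df))), df)
    attr(df, "truth") <- list(bottom = bottom, top = top, ic50 = ic50,
                              hill = hill)
    df
  })
}

#' Generate a synthetic CRISPR-screen gene table
#'
#' Emulates a per-gene beta-score table from paired control/treated
#' screens. Null genes have treated-minus-control score differences drawn
#' from \code{Normal(0, sigma)} with FDR uniform on \code{[0, 1]}; planted
#' hits are displaced by exactly \code{effect_sd_units * sigma} (half
#' positive = resistance, half negative = sensitization) with small FDR.
#'
#' @param n_genes Total number of genes.
#' @param n_hits Number of planted hits (\code{<= n_genes}).
#' @param effect_sd_units Displacement of hit deltas in units of the null
#'   standard deviation.
#' @param seed Integer seed.
#' @param sigma Null standard deviation of the score difference.
#' @param fdr_hit_max Hits receive FDR uniform on \code{[0, fdr_hit_max]}.
#' @return A data.frame with columns \code{gene}, \code{beta_control},
#'   \code{beta_treated}, \code{fdr} and the planted \code{true_class}
#'   (\code{"null"}, \code{"resistance"}, \code{"sensitization"}).
#' @examples
#' tab <- makeScreenTable(n_genes = 100, n_hits = 4,
#'                        effect_sd_units = 4, seed = 1)
#' table(tab$true_class)
#' @export
makeScreenTable <- function(n_genes, n_hits = 0L, effect_sd_units = 4,
                            seed = 1L, sigma = 1, fdr_hit_max = 0.05) {
  if (n_hits > n_genes) stop("'n_hits' must be <= 'n_genes'", call. = FALSE)
  withSeed(seed, {
    gene <- sprintf("gene%05d", seq_len(n_genes))
    beta_control <- rnorm(n_genes, 0, 0.5)
    delta <- rnorm(n_genes, 0, sigma)
    fdr <- runif(n_genes)
    true_class <- rep("null", n_genes)
    if (n_hits > 0L) {
      hit_idx <- sample.int(n_genes, n_hits)
      sign_up <- rep_len(c(1, -1), n_hits)
      delta[hit_idx] <- sign_up * effect_sd_units * sigma
      fdr[hit_idx] <- runif(n_hits, 0, fdr_hit_max)
      true_class[hit_idx] <- ifelse(sign_up > 0, "resistance",
                                    "sensitization")
    }
    data.frame(gene = gene, beta_control = beta_control,
               beta_treated = beta_control + delta, fdr = fdr,
               true_class = true_class, stringsAsFactors = FALSE)
  })
}
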