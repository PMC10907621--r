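#' Add treated-minus-control beta-score differences
#'
#' Computes \code{delta_beta = beta_treated - beta_control} per gene and
#' records the population mean and standard deviation of the delta as
#' attributes (\code{delta_mean}, \code{delta_sd}).
#'
#' @param table data.frame with \code{beta_control} and
#'   \code{beta_treated} columns.
#' @return The table with a \code{delta_beta} column.
#' @export
deltaBeta <- function(table) {
  if (!all(c("beta_control", "beta_treated") %in% names(table)))
    stop("'table' needs beta_control and beta_treated columns",
         call. = FALSE)
  table$delta_beta <- table$beta_treated - table$beta_control
  attr(table, "delta_mean") <- mean(table$delta_beta)
  attr(table, "delta_sd") <- sd(table$delta_beta)
  table
}

#' Select screen hits by beta-score deviation and FDR
#'
#' Genes whose treated-minus-control beta-score lies outside
#' \code{sd_multiplier} standard deviations from the population mean, and
#' whose FDR passes the cutoff, are hits: \code{"resistance"} above the
#' upper fence, \code{"sensitization"} below the lower fence,
#' \code{"none"} otherwise.
#'
#' @param table data.frame with a \code{delta_beta} column (see
#'   \code{\link{deltaBeta}}) and, unless \code{fdr_max = NULL}, an
#'   \code{fdr} column.
#' @param sd_multiplier Fence width in population SD units (default 1.5).
#' @param fdr_max FDR cutoff (e.g. 0.3, or 0.1 for a stricter screen);
#'   \code{NULL} disables the FDR gate.
#' @param direction \code{"both"} (default), \code{"resistance"} or
#'   \code{"sensitization"}.
#' @return The table with a \code{hit_class} column; fences are attached
#'   as attributes \code{fence_low}/\code{fence_high}.
#' @examples
#' tab <- deltaBeta(makeScreenTable(200, n_hits = 4, seed = 1))
#' table(selectHits(tab, fdr_max = 0.3)$hit_class)
#' @export
selectHits <- function(table, sd_multiplier = 1.5, fdr_max = 0.3,
                       direction = c("both", "resistance",
                                     "sensitization")) {
  direction <- match.arg(direction)
  if (!"delta_beta" %in% names(table))
    stop("run deltaBeta() first", call. = FALSE)
  mu <- mean(table$delta_beta)
  sdv <- sd(table$delta_beta)
  if (!is.finite(sdv) || sdv == 0)
    stop("zero standard deviation of delta_beta", call. = FALSE)
  hi <- mu + sd_multiplier * sdv
  lo <- mu - sd_multiplier * sdv
  fdr_ok <- if (is.null(fdr_max)) rep(TRUE, nrow(table)) else {
    if (!"fdr" %in% names(table))
      stop("'table' needs an fdr column (or set fdr_max = NULL)",
           call. = FALSE)
    table$fdr <= fdr_max
  }
  cls <- rep("none", nrow(table))
  cls[table$delta_beta > hi & fdr_ok] <- "resistance"
  cls[table$delta_beta < lo & fdr_ok] <- "sensitization"
  if (direction == "resistance") cls[cls == "sensitization"] <- "none"
  if (direction == "sensitization") cls[cls == "resistance"] <- "none"
  table$hit_class <- cls
  attr(table, "fence_low") <- lo
  attr(table, "fence_high") <- hi
  table
}

#' Gene-set enrichment among screen hits by Fisher's exact test
#'
#' Builds the 2x2 contingency table (hit / non-hit against in-set /
#' out-of-set over the screened universe) and evaluates enrichment with
#' the exact hypergeometric (Fisher) test, two-sided by default.
#'
#' @param hits Character vector of hit genes (subset of
#'   \code{universe}).
#' @param gene_set Character vector, the gene set to test (subset of
#'   \code{universe}).
#' @param universe Character vector of all screened genes.
#' @param alternative Passed to \code{\link[stats]{fisher.test}}
#'   (default \code{"two.sided"}).
#' @return A list with \code{odds_ratio} (sample odds ratio of the 2x2
#'   table), \code{p_value} and \code{table}.
#' @export
enrichmentFisher <- function(hits, gene_set, universe,
                             alternative = "two.sided") {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  hits <- unique(hits); gene_set <- unique(gene_set)
  if (!all(hits %in% universe) || !all(gene_set %in% universe))
    stop("hits and gene_set must be subsets of the universe",
         call. = FALSE)
  in_set <- universe %in% gene_set
  is_hit <- universe %in% hits
  tab <- matrix(c(sum(is_hit & in_set), sum(is_hit & !in_set),
                  sum(!is_hit & in_set), sum(!is_hit & !in_set)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("hit", "non_hit"),
                                c("in_set", "out_of_set")))
  ft <- fisher.test(tab, alternative = alternative)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = or, p_value = ft$p.value, table = tab)
}

#' Benjamini-Hochberg adjustment of enrichment p-values
#'
#' Optional multiple-testing correction across a collection of gene-set
#' enrichment p-values.
#'
#' @param p Numeric vector of p-values.
#' @return BH-adjusted p-values.
#' @export
adjustEnrichment <- function(p) stats::p.adjust(p, method = "BH")
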