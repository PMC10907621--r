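#' Fate vocabulary for mitotic event tables
#'
#' @return Character vector of permitted fate labels.
#' @export
mitoticFates <- function() {
  c("normal division", "multipolar division", "segregation error",
    "death in mitosis", "slippage", "cohesion loss")
}

#' Per-cell mitotic durations from event annotations
#'
#' Mitotic duration is the time from nuclear envelope breakdown (NEBD) to
#' anaphase onset; metaphase-to-anaphase duration is the time from the
#' appearance of the last, uninterrupted metaphase plate to anaphase
#' onset. Cells that never reach anaphase (death in mitosis, slippage)
#' get durations censored at the last observation time, flagged with
#' \code{censored = TRUE}.
#'
#' @param events data.frame with columns \code{cell_id}, \code{t_nebd},
#'   \code{t_last_metaphase}, \code{t_anaphase} (minutes; \code{NA}
#'   allowed), optional \code{t_last_observed} (required for censoring)
#'   and optional \code{condition}, \code{fate}.
#' @return The table with \code{duration_mitosis}, \code{duration_m2a}
#'   and \code{censored} columns added.
#' @examples
#' ev <- data.frame(cell_id = "c1", t_nebd = 10, t_last_metaphase = 35,
#'                  t_anaphase = 40)
#' computeDurations(ev)[, c("duration_mitosis", "duration_m2a")]
#' @export
computeDurations <- function(events) {
  if ("fate" %in% names(events) &&
      !all(is.na(events$fate) | events$fate %in% mitoticFates()))
    stop("unknown fate label(s); see mitoticFates()", call. = FALSE)
  ts <- events[, intersect(c("t_nebd", "t_last_metaphase", "t_anaphase"),
                           names(events)), drop = FALSE]
  bad <- apply(ts, 1L, function(r) {
    r <- r[!is.na(r)]
    length(r) > 1L && any(diff(r) < 0)
  })
  if (any(bad))
    stop("non-monotone timestamps in cell(s): ",
         paste(events$cell_id[bad], collapse = ", "), call. = FALSE)

  has_ana <- !is.na(events$t_anaphase)
  end <- ifelse(has_ana, events$t_anaphase,
                if ("t_last_observed" %in% names(events))
                  events$t_last_observed else NA_real_)
  events$duration_mitosis <- end - events$t_nebd
  events$duration_m2a <- end - events$t_last_metaphase
  events$censored <- !has_ana
  events
}

#' Summarize mitotic fates and durations per condition
#'
#' @param events Event table with \code{condition} and \code{fate}
#'   columns; duration summaries additionally use
#'   \code{duration_mitosis} when present (run
#'   \code{\link{computeDurations}} first).
#' @return A list with \code{fates} (per-condition fate proportions,
#'   summing to 1 within condition) and \code{durations} (per-condition
#'   mean and SD of mitotic duration).
#' @export
summarizeFates <- function(events) {
  if (!all(c("condition", "fate") %in% names(events)))
    stop("'events' needs condition and fate columns", call. = FALSE)
  conds <- unique(events$condition)
  fates <- do.call(rbind, lapply(conds, function(cd) {
    sub <- events[events$condition == cd, ]
    tab <- table(sub$fate)
    data.frame(condition = cd, fate = names(tab),
               n = as.integer(tab),
               proportion = as.numeric(tab) / nrow(sub),
               stringsAsFactors = FALSE)
  }))
  rownames(fates) <- NULL
  durations <- NULL
  if ("duration_mitosis" %in% names(events)) {
    durations <- do.call(rbind, lapply(conds, function(cd) {
      d <- events$duration_mitosis[events$condition == cd]
      data.frame(condition = cd, n = sum(!is.na(d)),
                 mean_duration = mean(d, na.rm = TRUE),
                 sd_duration = sd(d, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
    rownames(durations) <- NULL
  }
  list(fates = fates, durations = durations)
}

#' Ordinary least-squares correlation of a predictor with a response
#'
#' Fits \code{y ~ x} by OLS and reports the coefficient of determination
#' alongside slope and intercept; used to rank per-cell-line predictors
#' of drug sensitivity (e.g. toxicity against mitotic duration).
#'
#' @param x,y Numeric vectors (at least 3 finite points).
#' @return A list with \code{r2}, \code{slope} and \code{intercept}.
#' @examples
#' linearR2(1:5, c(2, 4, 6, 8, 10))$r2  # 1
#' @export
linearR2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 finite points", call. = FALSE)
  fit <- lm(y ~ x)
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 0,
       slope = coef(fit)[[2L]], intercept = coef(fit)[[1L]])
}
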