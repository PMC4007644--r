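# Transposon-mutant fitness evaluation.
#
# Pooled-fitness z-scores per (mutant gene, experiment) are grouped into
# simulatable conditions and converted to growth/no-growth calls with a
# cutoff (default -3.5): strongly negative scores mean the mutant failed to
# grow.  Calls are compared to model knockout predictions as a confusion
# summary, the cutoff can be swept, and growth rates/yields are computed
# from OD curves.

#' Call growth for one mutant under one condition
#'
#' Replicate experiments vote: a majority of z-scores above the cutoff
#' calls growth, a majority below calls no growth, and an exact tie is
#' undetermined (excluded from downstream accuracy).  A score exactly equal
#' to the cutoff counts as growth: the cutoff rule is strict on both sides,
#' so equality must be assigned to one side, and the boundary is kept with
#' the growing class.
#'
#' @param z Numeric vector of fitness z-scores (replicates of one mutant
#'   under one condition).
#' @param cutoff Fitness cutoff separating growth from no growth.
#' @return `"growth"`, `"no_growth"` or `"undetermined"`.
#' @export
call_growth <- function(z, cutoff = -3.5) {
  stopifnot(length(z) >= 1L, all(is.finite(z)))
  above <- sum(z >= cutoff)
  below <- sum(z < cutoff)
  if (above > below) "growth" else if (below > above) "no_growth" else "undetermined"
}

#' Growth calls for a fitness table
#'
#' @param records Data frame with columns `gene`, `condition`, `z` (one row
#'   per experiment replicate).
#' @param cutoff Fitness cutoff.
#' @return Data frame `gene`, `condition`, `call`.
#' @export
call_growth_table <- function(records, cutoff = -3.5) {
  stopifnot(all(c("gene", "condition", "z") %in% names(records)))
  agg <- stats::aggregate(z ~ gene + condition, data = records,
                          FUN = function(v) call_growth(v, cutoff))
  names(agg)[3] <- "call"
  agg
}

#' Score model knockout predictions against fitness growth calls
#'
#' Undetermined calls are excluded.  A false positive is model growth with
#' a no-growth call; a false negative is model no-growth with a growth
#' call.  Percentages are over the compared (non-undetermined, predicted)
#' pairs, so accuracy + FP + FN = 100.
#'
#' @param predictions Data frame `gene`, `condition`, `predicted` (logical:
#'   does the model predict the knockout grows?).
#' @param calls Data frame from [call_growth_table()].
#' @return A list of class `evaluation_summary`: `n_compared`, `accuracy`,
#'   `false_positive`, `false_negative` (percentages), `n_undetermined`,
#'   `n_missing` (calls with no matching prediction, logged and skipped).
#' @export
evaluate_predictions <- function(predictions, calls) {
  stopifnot(all(c("gene", "condition", "predicted") %in% names(predictions)))
  determined <- calls[calls$call != "undetermined", , drop = FALSE]
  merged <- merge(determined, predictions, by = c("gene", "condition"))
  n_missing <- nrow(determined) - nrow(merged)
  if (n_missing > 0L)
    message(n_missing, " growth call(s) had no model prediction; skipped")
  n <- nrow(merged)
  if (n == 0L) {
    return(structure(list(n_compared = 0L, accuracy = NA_real_,
                          false_positive = NA_real_, false_negative = NA_real_,
                          n_undetermined = sum(calls$call == "undetermined"),
                          n_missing = n_missing),
                     class = "evaluation_summary"))
  }
  obs_growth <- merged$call == "growth"
  fp <- sum(merged$predicted & !obs_growth)
  fn <- sum(!merged$predicted & obs_growth)
  structure(
    list(n_compared = n,
         accuracy = 100 * (n - fp - fn) / n,
         false_positive = 100 * fp / n,
         false_negative = 100 * fn / n,
         n_undetermined = sum(calls$call == "undetermined"),
         n_missing = n_missing),
    class = "evaluation_summary"
  )
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat("<evaluation_summary> n = ", x$n_compared,
      " (", x$n_undetermined, " undetermined excluded)\n",
      "  accuracy:        ", round(x$accuracy, 2), "%\n",
      "  false positives: ", round(x$false_positive, 2), "%\n",
      "  false negatives: ", round(x$false_negative, 2), "%\n", sep = "")
  invisible(x)
}

#' Sweep the fitness cutoff
#'
#' Re-calls growth at each cutoff and re-scores the predictions, as in a
#' cutoff sensitivity analysis.  At a cutoff below all scores every mutant
#' is called growth (no false negatives possible for the data side); far
#' above, every mutant is called no growth.
#'
#' @param records Fitness records as in [call_growth_table()].
#' @param predictions Predictions as in [evaluate_predictions()].
#' @param cutoffs Sorted numeric vector of cutoffs to evaluate.
#' @return Data frame: `cutoff`, `n_compared`, `accuracy`,
#'   `false_positive`, `false_negative`, `n_undetermined`.
#' @export
cutoff_sensitivity <- function(records, predictions, cutoffs) {
  stopifnot(!is.unsorted(cutoffs))
  do.call(rbind, lapply(cutoffs, function(ct) {
    s <- evaluate_predictions(predictions, call_growth_table(records, ct))
    data.frame(cutoff = ct, n_compared = s$n_compared, accuracy = s$accuracy,
               false_positive = s$false_positive,
               false_negative = s$false_negative,
               n_undetermined = s$n_undetermined)
  }))
}

#' Growth rate from an OD curve
#'
#' Least-squares slope of `ln(OD)` versus time on the selected window.  By
#' default the window slides over the curve (covering `window_fraction` of
#' the points) and the maximal slope is reported, which picks out the
#' exponential phase.
#'
#' @param times Time points (h), strictly increasing.
#' @param od OD600 readings, positive on the fitted window.
#' @param window Optional integer vector of indices to fit on; overrides
#'   the sliding window.
#' @param window_fraction Fraction of points per sliding window.
#' @return Growth rate (1/h).
#' @export
growth_rate <- function(times, od, window = NULL, window_fraction = 1/3) {
  stopifnot(length(times) == length(od), length(times) >= 3L,
            !is.unsorted(times, strictly = TRUE))
  fit_slope <- function(idx) {
    if (any(od[idx] <= 0)) stop("non-positive OD in fitted window")
    unname(stats::coef(stats::lm(log(od[idx]) ~ times[idx]))[2])
  }
  if (!is.null(window)) {
    stopifnot(length(window) >= 3L)
    return(fit_slope(window))
  }
  w <- max(3L, ceiling(window_fraction * length(times)))
  starts <- seq_len(length(times) - w + 1L)
  max(vapply(starts, function(s) fit_slope(s:(s + w - 1L)), numeric(1)))
}

#' Biomass yield from an OD curve
#'
#' Stationary-phase OD minus starting OD, divided by the substrate amount.
#' The stationary phase is detected as a terminal plateau: the last
#' `plateau_points` readings must lie within `plateau_tol` (relative) of
#' their mean.
#'
#' @param times Time points (h).
#' @param od OD600 readings.
#' @param substrate_mmol Substrate supplied (mmol), positive.
#' @param plateau_points Number of terminal readings tested for flatness.
#' @param plateau_tol Maximum relative spread of the terminal readings.
#' @return Yield (OD/mmol).
#' @export
biomass_yield <- function(times, od, substrate_mmol, plateau_points = 5L,
                          plateau_tol = 0.02) {
  stopifnot(length(times) == length(od), substrate_mmol > 0,
            length(od) >= plateau_points)
  tail_od <- utils::tail(od, plateau_points)
  if (diff(range(tail_od)) > plateau_tol * max(mean(tail_od), .Machine$double.eps))
    stop("no stationary-phase plateau detected in the last ", plateau_points,
         " readings")
  (mean(tail_od) - od[1]) / substrate_mmol
}
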