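## Steady-state exposure metrics over a standardized 28-day window: AUC by
## trapezoids, extrema of the total concentration, and the time-average
## AUC/28. Using the same 28-day window for the weekly and the every-4-week
## regimen keeps their AUCs commensurate (at periodic steady state a 28-day
## AUC equals four 7-day interval AUCs).

#' Steady-state evaluation window
#'
#' The final 28 days of the simulation horizon, aligned to dose times: for the
#' default 140-day (20-week) horizon this is `[112, 140]`, spanning exactly
#' four weekly intervals or one every-4-week interval.
#'
#' @param regimen An [regimen()] object with `horizon >= 28`.
#' @return Numeric `c(start, end)` in days.
#' @export
#' @examples
#' ss_window(regimen_scig())  # c(112, 140)
ss_window <- function(regimen) {
  if (regimen$horizon < 28) stopf("horizon must be >= 28 days")
  span <- regimen$horizon - regimen$first_dose_time
  if (abs(span / regimen$interval - round(span / regimen$interval)) > 1e-9) {
    stopf("horizon (%g) is not a whole number of dosing intervals (%g): window cannot align to dose times",
          regimen$horizon, regimen$interval)
  }
  if (abs(28 / regimen$interval - round(28 / regimen$interval)) > 1e-9) {
    stopf("a 28-day window does not span whole dosing intervals of %g days",
          regimen$interval)
  }
  c(regimen$horizon - 28, regimen$horizon)
}

#' Steady-state exposure metrics for one profile
#'
#' Minimum (trough) and maximum of the total concentration over the window,
#' AUC by the trapezoidal rule, and the average concentration `AUC / 28`.
#'
#' @param profile An `igsim_profile` (from [simulate_profile()]) whose grid
#'   covers the window with step <= 0.25 day.
#' @param window Numeric `c(start, end)`, normally [ss_window()] output; must
#'   span 28 days.
#' @return An object of class `igsim_exposure`: a list with `auc_ss`
#'   (g*days/L), `cmax_ss`, `cmin_ss`, `cave_ss` (g/L) and `window`.
#' @export
compute_metrics <- function(profile, window) {
  stopifnot(length(window) == 2, diff(window) > 0)
  if (abs(diff(window) - 28) > 1e-9) stopf("metrics window must span 28 days")
  inside <- profile$times >= window[1] - 1e-9 & profile$times <= window[2] + 1e-9
  tw <- profile$times[inside]
  if (length(tw) < 2 ||
      min(tw) > window[1] + 1e-9 || max(tw) < window[2] - 1e-9 ||
      max(diff(tw)) > 0.25 + 1e-9) {
    stopf("profile grid must cover [%g, %g] with step <= 0.25 day",
          window[1], window[2])
  }
  cw <- profile$conc_total[inside]
  auc <- pracma::trapz(tw, cw)
  structure(list(auc_ss = auc, cmax_ss = max(cw), cmin_ss = min(cw),
                 cave_ss = auc / 28, window = window),
            class = "igsim_exposure")
}

#' Percentage of subjects maintaining the trough threshold
#'
#' `100 * count(cmin_ss >= threshold) / n`, with an inclusive comparison. The
#' default threshold of 7 g/L is the hypothetical protective trough for
#' patients with PIDD on stable IgG replacement.
#'
#' @param metrics A data.frame with a `cmin_ss` column (e.g.
#'   `run_scenario()$metrics`), a list of `igsim_exposure` objects, or a
#'   numeric vector of troughs.
#' @param threshold Trough threshold in g/L (default 7).
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' threshold_fraction(c(6, 8, 10, 12)) # 75
threshold_fraction <- function(metrics, threshold = 7) {
  cmin <- if (is.data.frame(metrics)) {
    metrics$cmin_ss
  } else if (is.list(metrics)) {
    vapply(metrics, function(m) m$cmin_ss, numeric(1))
  } else {
    metrics
  }
  if (length(cmin) == 0 || is.null(cmin)) stopf("`metrics` must be non-empty")
  100 * sum(cmin >= threshold) / length(cmin)
}

## Vectorized metrics for a cohort concentration matrix (rows = subjects);
## numerically identical to compute_metrics() applied row-wise.
cohort_metrics <- function(conc, tgrid, window) {
  inside <- tgrid >= window[1] - 1e-9 & tgrid <= window[2] + 1e-9
  tw <- tgrid[inside]
  if (max(diff(tw)) > 0.25 + 1e-9) stopf("grid step exceeds 0.25 day over the window")
  m <- conc[, inside, drop = FALSE]
  dt <- diff(tw)
  w <- c(dt / 2, 0) + c(0, dt / 2) # trapezoid weights
  data.frame(
    auc_ss = as.numeric(m %*% w),
    cmax_ss = apply(m, 1, max),
    cmin_ss = apply(m, 1, min),
    cave_ss = as.numeric(m %*% w) / 28
  )
}
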