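#' Growth curve container
#'
#' @param time_min Strictly increasing timepoints in minutes.
#' @param od Optical density readings (OD595), same length, non-negative.
#' @return A `growth_curve` (data frame with columns `time_min`, `od`).
#' @export
growth_curve <- function(time_min, od) {
  if (length(time_min) < 2L)
    stop("growth curve needs at least two points", call. = FALSE)
  if (length(od) != length(time_min))
    stop("time_min and od must have equal length", call. = FALSE)
  if (any(diff(time_min) <= 0))
    stop("timepoints must be strictly increasing", call. = FALSE)
  if (any(od < 0)) stop("od must be non-negative", call. = FALSE)
  structure(data.frame(time_min = time_min, od = od),
            class = c("growth_curve", "data.frame"))
}

#' Centered moving-average smoothing
#'
#' Each reading is replaced by the mean of the window of `window` closest
#' measurements centered on it; the window is truncated (not reflected) at
#' the curve's edges. Timepoints are unchanged.
#'
#' @param curve A [growth_curve()].
#' @param window Odd window width in measurements (default 15, i.e. the 15
#'   closest 10-min readings).
#' @return A smoothed `growth_curve`.
#' @export
moving_average_smooth <- function(curve, window = 15L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be a positive odd integer", call. = FALSE)
  od <- curve$od
  n <- length(od)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, od))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  growth_curve(curve$time_min, sm)
}

#' Growth score of an OD time series
#'
#' After moving-average smoothing, computes the yield (maximum minus minimum
#' smoothed OD), the maximum slope (forward finite differences, OD per
#' minute) and the time to reach the maximum slope (from the first recorded
#' timepoint to the left endpoint of the first interval attaining it), and
#' scores growth as `yield * max_slope / t_max_slope`. Curves that never
#' rise (`max_slope <= 0`) or whose maximum slope occurs in the very first
#' interval (`t_max_slope = 0`) score 0 and are flagged.
#'
#' @param curve A [growth_curve()].
#' @param window Smoothing window (see [moving_average_smooth()]).
#' @return A `growth_score` list: `yield` (OD), `max_slope` (OD/min),
#'   `t_max_slope` (min), `score` (OD^2 min^-2), `flagged`.
#' @export
compute_growth_score <- function(curve, window = 15L) {
  sm <- moving_average_smooth(curve, window)
  yield <- max(sm$od) - min(sm$od)
  slopes <- diff(sm$od) / diff(sm$time_min)
  ## edge-truncated windows leave O(eps) jitter on constant stretches; a
  ## slope below numerical noise for the curve's OD scale counts as zero
  slope_tol <- 1e-10 * max(abs(sm$od), .Machine$double.eps) /
    min(diff(sm$time_min))
  slopes[abs(slopes) < slope_tol] <- 0
  max_slope <- max(slopes)
  ## first interval attaining the maximum, up to float jitter among
  ## mathematically equal slopes
  eps <- 1e-9 * max(abs(max_slope), .Machine$double.xmin)
  i <- which(slopes >= max_slope - eps)[1L]
  t_max_slope <- sm$time_min[i] - sm$time_min[1L]
  flagged <- max_slope <= 0 || t_max_slope == 0
  score <- if (flagged) 0 else yield * max_slope / t_max_slope
  structure(list(yield = yield, max_slope = max_slope,
                 t_max_slope = t_max_slope, score = score, flagged = flagged),
            class = "growth_score")
}

## 4PL decreasing dose-response: top at dose 0, bottom at saturating dose.
.four_pl <- function(x, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (x / ec50)^hill)
}

#' Fit a four-parameter logistic dose-response
#'
#' Least-squares fit of the decreasing 4PL
#' `f(x) = bottom + (top - bottom) / (1 + (x/ec50)^hill)` to growth scores
#' over a dose ladder, with multi-start Levenberg-Marquardt initialization
#' (ec50 over the positive-dose range, several Hill slopes). Responses are
#' typically scores normalized to the solvent-control mean so that top is
#' near 1; raw scores fit equally.
#'
#' @param dose Concentrations (same units as the desired EC50, e.g. uM),
#'   >= 4 distinct values.
#' @param response Growth scores, same length, finite.
#' @return A `dose_response_fit` list: `bottom`, `top`, `ec50`, `hill`,
#'   `residual_sse`, `unidentifiable` (TRUE for a degenerate flat fit).
#' @export
fit_four_pl <- function(dose, response) {
  stopifnot(length(dose) == length(response))
  if (length(unique(dose)) < 4L)
    stop("need at least four distinct doses", call. = FALSE)
  if (any(!is.finite(response)))
    stop("responses must be finite", call. = FALSE)
  if (any(dose < 0)) stop("doses must be non-negative", call. = FALSE)
  if (diff(range(response)) == 0) {
    return(structure(list(bottom = response[1L], top = response[1L],
                          ec50 = NA_real_, hill = NA_real_,
                          residual_sse = 0, unidentifiable = TRUE),
                     class = "dose_response_fit"))
  }
  pos <- sort(unique(dose[dose > 0]))
  ec50_starts <- stats::quantile(pos, c(0.1, 0.25, 0.5, 0.75, 0.9),
                                 names = FALSE)
  hill_starts <- c(0.5, 1, 2, 4)
  b0 <- min(response); t0 <- max(response)
  best <- NULL
  for (e0 in ec50_starts) for (h0 in hill_starts) {
    fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
      response ~ bottom + (top - bottom) / (1 + (dose / ec50)^hill),
      start = list(bottom = b0, top = t0, ec50 = e0, hill = h0),
      lower = c(-Inf, -Inf, 1e-12, 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    stop("4PL fit failed to converge from any start (",
         length(ec50_starts) * length(hill_starts), " starts; dose range ",
         paste(signif(range(dose), 3), collapse = "-"), ")", call. = FALSE)
  cf <- stats::coef(best$fit)
  ## orient so top >= bottom (the curve is decreasing in dose by convention)
  bottom <- min(cf[["bottom"]], cf[["top"]])
  top <- max(cf[["bottom"]], cf[["top"]])
  structure(list(bottom = bottom, top = top, ec50 = cf[["ec50"]],
                 hill = abs(cf[["hill"]]), residual_sse = best$sse,
                 unidentifiable = FALSE),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$unidentifiable) {
    cat("4PL fit: flat response, EC50 unidentifiable\n")
  } else {
    cat(sprintf("4PL fit: bottom %.4g, top %.4g, EC50 %.4g, Hill %.3g (SSE %.3g)\n",
                x$bottom, x$top, x$ec50, x$hill, x$residual_sse))
  }
  invisible(x)
}

#' Inhibitory concentration from a 4PL fit
#'
#' Solves `f(x) = top - fraction * (top - bottom)` in closed form:
#' `x = ec50 * (fraction / (1 - fraction))^(1/hill)`. With `fraction = 0.9`
#' this is the IC90; `fraction = 0.5` returns the EC50 exactly.
#'
#' @param fit A [fit_four_pl()] result with `top > bottom`.
#' @param fraction Inhibition fraction in (0, 1), default 0.9.
#' @param max_dose Optional highest tested dose; when given, the IC is
#'   reported as `NA` ("not reached") unless the fitted curve actually
#'   attains the requested inhibition relative to the uninhibited top
#'   (`(top - f(x)) / top >= fraction`) within 10x the tested range. This
#'   guards against shallow fits whose span-based solution would call an
#'   "IC90" at a small absolute inhibition (a high fitted bottom), the
#'   situation in which a compound is excluded as non-inhibitory.
#' @return Concentration in the dose units, or `NA` if not reached.
#' @export
inhibitory_concentration <- function(fit, fraction = 0.9, max_dose = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  if (isTRUE(fit$unidentifiable) || !(fit$top > fit$bottom))
    stop("inhibitory concentration undefined: top must exceed bottom",
         call. = FALSE)
  ic <- fit$ec50 * (fraction / (1 - fraction))^(1 / fit$hill)
  if (!is.null(max_dose)) {
    limit <- 10 * max_dose
    f_limit <- .four_pl(limit, fit$bottom, fit$top, fit$ec50, fit$hill)
    reached <- ic <= limit && (fit$top - f_limit) / fit$top >= fraction
    if (!reached) return(NA_real_)
  }
  ic
}

#' Score a dose ladder and estimate the IC90
#'
#' Computes growth scores for replicate curves at each dose, normalizes them
#' to the mean solvent-control (dose 0) score, fits the 4PL and returns the
#' inhibitory concentration.
#'
#' @param curves List of [growth_curve()] objects.
#' @param dose Numeric vector of doses, one per curve (0 = solvent control).
#' @param window Smoothing window.
#' @param fraction Inhibition fraction (default 0.9 for IC90).
#' @param normalize Normalize scores to the dose-0 mean (default TRUE).
#' @return List with `scores` (data frame dose/score), `fit`, `ic`.
#' @export
score_dose_response <- function(curves, dose, window = 15L, fraction = 0.9,
                                normalize = TRUE) {
  stopifnot(length(curves) == length(dose))
  sc <- vapply(curves, function(cu) compute_growth_score(cu, window)$score, 0)
  if (normalize) {
    ctrl <- mean(sc[dose == 0])
    if (!is.finite(ctrl) || ctrl <= 0)
      stop("cannot normalize: no positive dose-0 control score", call. = FALSE)
    sc <- sc / ctrl
  }
  fit <- fit_four_pl(dose, sc)
  ic <- inhibitory_concentration(fit, fraction, max_dose = max(dose))
  list(scores = data.frame(dose = dose, score = sc), fit = fit, ic = ic)
}
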