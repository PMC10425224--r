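#' Observed time to first square by waterlogging duration
#'
#' The reproductive milestone recorded in the pot experiment: plants in
#' the control and 2-day treatments squared 25 days after emergence;
#' 4 and 6 days of waterlogging delayed squaring by 2 and 4 days; the
#' 8-14-day treatments never squared within the 30-day observation
#' window and are censored.
#'
#' @return Data frame with columns `duration` (days of waterlogging),
#'   `days_to_square` (`NA` where censored) and logical `censored`.
#' @export
squaring_observations <- function() {
  data.frame(duration = seq(0, 14, by = 2),
             days_to_square = c(25, 25, 27, 29, NA, NA, NA, NA),
             censored = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE,
                          TRUE))
}

#' Fit time-to-first-square against waterlogging duration
#'
#' Censored treatments are excluded; the remaining (duration,
#' days-to-square) points are fitted by least squares via [fit_family()].
#' The default quadratic on the four uncensored observations gives
#' coefficients (0.125, -0.05, 24.9).
#'
#' @param observations As [squaring_observations()]: columns `duration`,
#'   `days_to_square`, `censored`.
#' @param family Response family for the fit (default `"quadratic"`,
#'   matching the accelerating delay).
#' @return A `fit_result`.
#' @export
fit_square_timing <- function(observations = squaring_observations(),
                              family = "quadratic") {
  family <- match.arg(family, response_families())
  obs <- observations[!observations$censored, ]
  arity <- family_arity(family)
  if (nrow(obs) < arity + 1) {
    stop(sprintf("rank error: need at least %d uncensored observations",
                 arity + 1), call. = FALSE)
  }
  if (any(obs$days_to_square <= 0)) {
    stop("uncensored days_to_square must be positive", call. = FALSE)
  }
  pts <- data.frame(duration = obs$duration, index = obs$days_to_square)
  fit_family(pts, family)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Predict the day of first square for a waterlogging duration
#'
#' Evaluates a fitted squaring curve at the given duration. The rounded
#' day uses half-away-from-zero rounding (36.5 -> 37).
#'
#' @param fit A `fit_result` from [fit_square_timing()].
#' @param duration Days of waterlogging (`>= 0`).
#' @return List with `days` (real) and `day` (integer, rounded).
#' @export
#' @examples
#' fit <- fit_square_timing()
#' predict_square_day(fit, 0)$day    # 25
#' predict_square_day(fit, 10)$day   # 37
predict_square_day <- function(fit, duration) {
  stopifnot(inherits(fit, "fit_result"), duration >= 0)
  days <- evaluate_curve(fit$curve, duration)
  list(days = days, day = as.integer(round_half_away(days)))
}

#' Squaring delay of a treatment relative to the control
#'
#' Difference in observed days to first square between a treatment and
#' the 0-day control. Treatments that never squared within the
#' observation window return a censored marker rather than a number
#' (check with [is_censored()]).
#'
#' @param observations As [squaring_observations()].
#' @param duration Treatment duration to compare against the control.
#' @return Delay in days, or a censored marker.
#' @export
square_delay <- function(observations = squaring_observations(), duration) {
  ctrl <- observations[observations$duration == 0, ]
  trt <- observations[observations$duration == duration, ]
  if (nrow(ctrl) != 1 || nrow(trt) != 1) {
    stop("observations must contain exactly one row for the control and ",
         "the requested duration", call. = FALSE)
  }
  if (ctrl$censored) stop("control observation is censored", call. = FALSE)
  if (trt$censored) {
    return(structure(NA_real_, class = "censored_delay"))
  }
  trt$days_to_square - ctrl$days_to_square
}

#' Is a squaring delay censored?
#'
#' @param x Result of [square_delay()].
#' @return `TRUE` when the treatment never squared within the window.
#' @export
is_censored <- function(x) inherits(x, "censored_delay")

#' @export
print.censored_delay <- function(x, ...) {
  cat("<censored> no square within the observation window\n")
  invisible(x)
}
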