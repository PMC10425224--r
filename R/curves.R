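#' Response-function families
#'
#' Three families describe how a cotton growth or physiology parameter's
#' waterlogging stress response index (WSRI) changes with the duration of
#' waterlogging `x` (days):
#' \itemize{
#'   \item `linear`: `y = slope * x + intercept` (2 coefficients)
#'   \item `quadratic`: `y = a * x^2 + b * x + c` (3 coefficients)
#'   \item `exp_decay`: `y = a * exp(b * x)` with `b < 0` (2 coefficients)
#' }
#'
#' @return Character vector of the three family tags.
#' @export
response_families <- function() c("linear", "quadratic", "exp_decay")

#' Number of coefficients of a response family
#'
#' @param family One of `"linear"`, `"quadratic"`, `"exp_decay"`.
#' @return Integer coefficient count (2, 3, 2 respectively).
#' @export
family_arity <- function(family) {
  family <- match.arg(family, response_families())
  c(linear = 2L, quadratic = 3L, exp_decay = 2L)[[family]]
}

canonical_coef_names <- function(family) {
  switch(family,
    linear    = c("slope", "intercept"),
    quadratic = c("a", "b", "c"),
    exp_decay = c("amplitude", "rate")
  )
}

#' Construct a duration-response curve
#'
#' A `response_curve` holds one parameter's fitted WSRI-versus-duration
#' function: the family, its coefficients in canonical orientation, the fit
#' quality, and provenance flags.
#'
#' Canonical coefficient orientation is `(slope, intercept)` for linear,
#' `(a, b, c)` highest power first for quadratic, and `(amplitude, rate)`
#' for exponential decay (rate in 1/day, negative for a declining index).
#'
#' @param parameter_code Short code, e.g. `"PH"` for plant height.
#' @param family One of [response_families()].
#' @param coefficients Numeric vector of length [family_arity()].
#' @param description Free-text description of the plant parameter.
#' @param r_squared Goodness of fit in `(-Inf, 1]`, or `NA`.
#' @param flags Character vector drawn from `"column_swapped"` (printed
#'   linear coefficients were re-oriented), `"direction_conflict"` (sign of
#'   the printed slope contradicts the described direction of response) and
#'   `"intercept_anomaly"` (unstressed value far from the expected index
#'   of 1).
#' @return An object of class `response_curve`.
#' @export
response_curve <- function(parameter_code, family, coefficients,
                           description = "", r_squared = NA_real_,
                           flags = character()) {
  family <- match.arg(family, response_families())
  coefficients <- as.numeric(coefficients)
  arity <- family_arity(family)
  if (length(coefficients) != arity) {
    stop(sprintf("curve '%s': family '%s' needs %d coefficients, got %d",
                 parameter_code, family, arity, length(coefficients)),
         call. = FALSE)
  }
  if (any(!is.finite(coefficients))) {
    stop(sprintf("curve '%s': non-finite coefficients", parameter_code),
         call. = FALSE)
  }
  stopifnot(is.na(r_squared) || r_squared <= 1)
  bad <- setdiff(flags, c("column_swapped", "direction_conflict",
                          "intercept_anomaly"))
  if (length(bad)) stop("unknown flags: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  names(coefficients) <- canonical_coef_names(family)
  structure(
    list(parameter_code = parameter_code,
         description = description,
         family = family,
         coefficients = coefficients,
         r_squared = r_squared,
         flags = unique(flags)),
    class = "response_curve"
  )
}

#' @export
print.response_curve <- function(x, ...) {
  eq <- switch(x$family,
    linear    = sprintf("y = %g x + %g", x$coefficients[["slope"]],
                        x$coefficients[["intercept"]]),
    quadratic = sprintf("y = %g x^2 + %g x + %g", x$coefficients[["a"]],
                        x$coefficients[["b"]], x$coefficients[["c"]]),
    exp_decay = sprintf("y = %g exp(%g x)", x$coefficients[["amplitude"]],
                        x$coefficients[["rate"]])
  )
  cat(sprintf("<response_curve> %s (%s)\n  %s   R^2 = %s\n",
              x$parameter_code, x$description, eq,
              ifelse(is.na(x$r_squared), "NA", format(x$r_squared))))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Resolve the orientation of a printed linear coefficient pair
#'
#' Published linear rows give two numbers `(a, b)` whose roles are
#' ambiguous: the stated form is `y = a x + b`, but several rows only make
#' physical sense read the other way round. Because a stress response index
#' is 1 by construction at zero days of waterlogging, the orientation whose
#' intercept is nearest to 1 is chosen; ties keep the stated `y = a x + b`
#' reading.
#'
#' @param a_printed,b_printed The two printed coefficients, in column order.
#' @return A list with `slope` (1/day), `intercept`, and logical `swapped`
#'   (`TRUE` when the `(intercept, slope)` reading was selected).
#' @export
#' @examples
#' disambiguate_linear(-0.0696, 1.078)  # root length: printed order kept
#' disambiguate_linear(1.2, -0.051)     # photosynthesis: columns swapped
disambiguate_linear <- function(a_printed, b_printed) {
  stopifnot(is.finite(a_printed), is.finite(b_printed))
  score_a <- abs(b_printed - 1)  # candidate A: slope = a, intercept = b
  score_b <- abs(a_printed - 1)  # candidate B: slope = b, intercept = a
  if (score_b < score_a) {
    list(slope = b_printed, intercept = a_printed, swapped = TRUE)
  } else {
    list(slope = a_printed, intercept = b_printed, swapped = FALSE)
  }
}

#' Evaluate a response curve at a waterlogging duration
#'
#' @param curve A [response_curve].
#' @param duration Duration of waterlogging in days; must be `>= 0`.
#'   May be a vector.
#' @param mode `"raw"` returns the fitted value as-is; `"clamp_nonneg"`
#'   floors it at 0; `"clamp01"` additionally caps it at 1 (used where the
#'   value acts as a physical stress multiplier).
#' @return Numeric WSRI value(s), same length as `duration`.
#' @export
#' @examples
#' reg <- load_registry()
#' evaluate_curve(reg$entries$PH, 0)    # 1.056, the unstressed index
#' evaluate_curve(reg$entries$PH, 14)   # 0.4652
evaluate_curve <- function(curve, duration,
                           mode = c("raw", "clamp_nonneg", "clamp01")) {
  stopifnot(inherits(curve, "response_curve"))
  mode <- match.arg(mode)
  if (length(duration) == 0 || any(!is.finite(duration))) {
    stop("duration must be finite and non-empty", call. = FALSE)
  }
  if (any(duration < 0)) {
    stop("duration must be >= 0 (days of waterlogging)", call. = FALSE)
  }
  k <- curve$coefficients
  y <- switch(curve$family,
    linear    = k[["slope"]] * duration + k[["intercept"]],
    quadratic = k[["a"]] * duration^2 + k[["b"]] * duration + k[["c"]],
    exp_decay = k[["amplitude"]] * exp(k[["rate"]] * duration)
  )
  if (mode %in% c("clamp_nonneg", "clamp01")) y <- pmax(y, 0)
  if (mode == "clamp01") y <- pmin(y, 1)
  unname(y)
}

#' Evaluate a response curve along an ordered set of durations
#'
#' Elementwise [evaluate_curve()]; order and length are preserved.
#'
#' @inheritParams evaluate_curve
#' @param durations Non-empty numeric vector of durations (days, `>= 0`).
#' @return Numeric vector of WSRI values, one per duration.
#' @export
evaluate_trajectory <- function(curve, durations,
                                mode = c("raw", "clamp_nonneg", "clamp01")) {
  if (length(durations) == 0) stop("durations must be non-empty",
                                   call. = FALSE)
  mode <- match.arg(mode)
  vapply(durations, function(d) evaluate_curve(curve, d, mode), numeric(1))
}

#' Percent change of a parameter relative to its unstressed value
#'
#' Reported as `100 * (1 - y(duration) / y(0))`: positive for parameters
#' that decline under waterlogging, negative for those (flavonoids,
#' anthocyanins, NPQ) that increase.
#'
#' @inheritParams evaluate_curve
#' @return Percent change (a plain number, e.g. `55.9` for a 55.9% drop).
#' @export
percent_change <- function(curve, duration) {
  y0 <- evaluate_curve(curve, 0)
  if (y0 == 0) stop("percent change undefined: curve value at 0 days is 0",
                    call. = FALSE)
  100 * (1 - evaluate_curve(curve, duration) / y0)
}
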