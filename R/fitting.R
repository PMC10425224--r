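#' Least-squares fit of one response family
#'
#' Linear and quadratic families are solved exactly by ordinary least
#' squares; exponential decay `y = a exp(b x)` is fitted by
#' Levenberg-Marquardt nonlinear least squares started from a log-linear
#' regression of `log(index)` on duration over the strictly positive
#' points (falling back to amplitude = max index and a rate from the
#' first/last positive pair if that regression is unavailable).
#'
#' @param points Data frame with columns `duration` (days) and `index`
#'   (WSRI), one row per point. Order is irrelevant to the fit.
#' @param family One of [response_families()].
#' @param weights Optional nonnegative case weights (e.g. inverse
#'   variances); `NULL` for ordinary least squares.
#' @return An object of class `fit_result`: list with `curve`
#'   ([response_curve] with the fitted coefficients and R-squared),
#'   `residuals` (observed minus fitted, in input order), `n_points`,
#'   `converged`, `iterations`, and `std_errors` (named as the canonical
#'   coefficients; `NA` where not estimable).
#' @export
#' @examples
#' pts <- data.frame(duration = c(0, 2, 4, 6), index = c(1, 0.9, 0.8, 0.7))
#' fit_family(pts, "linear")$curve$coefficients  # slope -0.05, intercept 1
fit_family <- function(points, family, weights = NULL) {
  family <- match.arg(family, response_families())
  stopifnot(is.data.frame(points), all(c("duration", "index") %in%
                                         names(points)))
  x <- as.numeric(points$duration)
  y <- as.numeric(points$index)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values in fit input", call. = FALSE)
  }
  arity <- family_arity(family)
  if (length(unique(x)) < arity) {
    stop(sprintf("rank error: %s fit needs >= %d distinct durations, got %d",
                 family, arity, length(unique(x))), call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(x))

  iterations <- 0L
  converged <- TRUE
  if (family == "linear") {
    fit <- stats::lm(y ~ x, weights = weights)
    co <- stats::coef(fit)
    coefs <- c(co[["x"]], co[["(Intercept)"]])
    se <- se_from_lm(fit, c("x", "(Intercept)"))
  } else if (family == "quadratic") {
    x2 <- x^2
    fit <- stats::lm(y ~ x2 + x, weights = weights)
    co <- stats::coef(fit)
    coefs <- c(co[["x2"]], co[["x"]], co[["(Intercept)"]])
    se <- se_from_lm(fit, c("x2", "x", "(Intercept)"))
  } else {
    start <- exp_decay_start(x, y)
    dat <- data.frame(x = x, y = y)
    fit <- minpack.lm::nlsLM(
      y ~ a * exp(b * x), data = dat,
      start = list(a = start[1], b = start[2]), weights = weights,
      control = minpack.lm::nls.lm.control(maxiter = 200, ptol = 1e-10,
                                           ftol = 1e-12))
    coefs <- unname(stats::coef(fit)[c("a", "b")])
    iterations <- fit$convInfo$finIter
    converged <- isTRUE(fit$convInfo$isConv) || iterations < 200L
    se <- tryCatch(
      suppressWarnings(summary(fit))$coefficients[c("a", "b"), "Std. Error"],
      error = function(e) rep(NA_real_, 2))
  }
  fitted_vals <- switch(family,
    linear    = coefs[1] * x + coefs[2],
    quadratic = coefs[1] * x^2 + coefs[2] * x + coefs[3],
    exp_decay = coefs[1] * exp(coefs[2] * x))
  resid <- y - fitted_vals
  r2 <- if (length(x) >= arity + 1) {
    r_squared_values(y, fitted_vals)
  } else NA_real_
  curve <- response_curve("fit", family, coefs, r_squared = r2)
  structure(list(curve = curve,
                 residuals = resid,
                 n_points = length(x),
                 converged = converged,
                 iterations = as.integer(iterations),
                 std_errors = stats::setNames(unname(se),
                                              canonical_coef_names(family))),
            class = "fit_result")
}

se_from_lm <- function(fit, terms) {
  # noiseless inputs give a perfect fit; summary()'s warning about it is
  # expected here and the ~0 standard errors are meaningful
  tab <- suppressWarnings(summary(fit))$coefficients
  vapply(terms, function(t) {
    if (t %in% rownames(tab)) tab[t, "Std. Error"] else NA_real_
  }, numeric(1))
}

# log-linear starting values for y = a exp(b x); uses points with y > 1e-9
exp_decay_start <- function(x, y) {
  pos <- y > 1e-9
  if (sum(pos) < 2) {
    stop("exp_decay initialization error: fewer than two positive indices",
         call. = FALSE)
  }
  xp <- x[pos]; yp <- y[pos]
  if (length(unique(xp)) >= 2) {
    ll <- stats::lm(log(yp) ~ xp)
    c(exp(stats::coef(ll)[["(Intercept)"]]), stats::coef(ll)[["xp"]])
  } else {
    # degenerate duration spread among positives: first/last positive pair
    o <- order(xp)
    first <- o[1]; last <- o[length(o)]
    rate <- if (xp[last] > xp[first]) {
      log(yp[last] / yp[first]) / (xp[last] - xp[first])
    } else -0.1
    c(max(yp), rate)
  }
}

r_squared_values <- function(y, fitted_vals) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    stop("undefined R-squared: zero variance in indices", call. = FALSE)
  }
  1 - sum((y - fitted_vals)^2) / ss_tot
}

#' Coefficient of determination of a curve on data
#'
#' `1 - SS_res / SS_tot`, with the total sum of squares taken about the
#' mean index. Can be negative for a poor nonlinear fit.
#'
#' @inheritParams fit_family
#' @param curve A [response_curve] to score.
#' @return R-squared.
#' @export
r_squared <- function(points, curve) {
  stopifnot(nrow(points) >= 2)
  y <- as.numeric(points$index)
  fitted_vals <- evaluate_trajectory(curve, points$duration)
  r_squared_values(y, fitted_vals)
}

#' Fit all three families and choose one
#'
#' Fits linear, quadratic and exponential decay and returns the fit with
#' the highest R-squared, except that a simpler family (fewer
#' coefficients) wins whenever its R-squared is within the parsimony
#' margin of the best. The comparison is recorded in the result's
#' `selection` element.
#'
#' @inheritParams fit_family
#' @param margin Parsimony margin on R-squared (default 0.01).
#' @return A `fit_result` whose `selection` is a data frame of the
#'   per-family R-squared values with the chosen row marked.
#' @export
select_model <- function(points, weights = NULL, margin = 0.01) {
  if (nrow(points) < 4) {
    stop("model selection needs at least 4 points", call. = FALSE)
  }
  fits <- list()
  for (fam in response_families()) {
    fits[[fam]] <- tryCatch(fit_family(points, fam, weights),
                            error = function(e) NULL)
  }
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("no family could be fitted", call. = FALSE)
  r2 <- vapply(fits, function(f) f$curve$r_squared, numeric(1))
  arity <- vapply(names(fits), family_arity, integer(1))
  best <- max(r2)
  eligible <- r2 >= best - margin
  # among eligible fits, fewest coefficients; R-squared breaks arity ties
  ord <- order(!eligible, arity, -r2)
  chosen <- names(fits)[ord[1]]
  out <- fits[[chosen]]
  out$selection <- data.frame(family = names(fits), r_squared = unname(r2),
                              arity = unname(arity),
                              chosen = names(fits) == chosen,
                              stringsAsFactors = FALSE)
  out
}

#' Batch-fit duration-response curves to a WSRI table
#'
#' Reproduces the published workflow: per-parameter WSRI-versus-duration
#' points are fitted either with the family assignment of a registry
#' (`mode = "published_families"`) or by free model selection
#' (`mode = "auto_select"`).
#'
#' @param wsri A `wsri_table` from [compute_wsri()], or any data frame
#'   with columns `parameter`, `duration`, `index`.
#' @param mode Family source: the registry's assignment, or
#'   [select_model()] per parameter.
#' @param registry Registry supplying family assignments (and
#'   descriptions) in `published_families` mode; defaults to the packaged
#'   registry.
#' @return Named list of `fit_result`s, one per parameter; each result's
#'   `curve` carries the parameter code, so the batch is serializable with
#'   [registry_table()].
#' @export
fit_wsri_table <- function(wsri, mode = c("published_families", "auto_select"),
                           registry = load_registry()) {
  mode <- match.arg(mode)
  stopifnot(all(c("parameter", "duration", "index") %in% names(wsri)))
  params <- unique(wsri$parameter)
  out <- list()
  for (p in params) {
    pts <- wsri[wsri$parameter == p, c("duration", "index")]
    if (length(unique(pts$duration)) < 4) {
      stop(sprintf("parameter '%s' has fewer than 4 durations", p),
           call. = FALSE)
    }
    if (mode == "published_families") {
      entry <- registry$entries[[p]]
      if (is.null(entry)) {
        stop(sprintf("parameter '%s' not in registry", p), call. = FALSE)
      }
      fit <- fit_family(pts, entry$family)
      fit$curve$description <- entry$description
    } else {
      fit <- select_model(pts)
    }
    fit$curve$parameter_code <- p
    out[[p]] <- fit
  }
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s, %d points, R^2 = %s%s\n",
              x$curve$family, x$n_points,
              ifelse(is.na(x$curve$r_squared), "NA",
                     format(x$curve$r_squared, digits = 4)),
              if (x$converged) "" else " (not converged)"))
  print(x$curve)
  invisible(x)
}
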