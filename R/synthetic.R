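#' Default control-treatment means for the synthetic generator
#'
#' Unstressed (0-day) means in native units for all 26 registry
#' parameters. Only the mainstem leaf number (LN = 9.4 leaves) is an
#' observed control value; every other entry is a synthetic placeholder
#' of plausible magnitude for a 30-day-old potted cotton plant, present
#' so that the generator covers the full parameter set. Placeholders are
#' marked in the `source` attribute (`"observed"` vs `"synthetic"`).
#'
#' The WSRI pipeline is insensitive to these magnitudes: indices are
#' ratios to the control mean, so any strictly positive value yields the
#' same downstream curves.
#'
#' @return Named numeric vector over the 26 parameter codes, with a
#'   `source` attribute of the same shape.
#' @export
default_control_means <- function() {
  m <- c(
    PH = 30,      # plant height, cm
    SD = 6,       # stem diameter, mm
    LN = 9.4,     # mainstem leaves (observed control value)
    LA = 500,     # leaf area, cm^2
    DWL = 3.0,    # leaf dry weight, g
    DWS = 2.0,    # stem dry weight, g
    DWSh = 5.0,   # shoot dry weight, g
    DWT = 6.5,    # whole-plant dry weight, g
    RL = 1500,    # root length, cm
    RSA = 250,    # root surface area, cm^2
    RV = 3,       # root volume, cm^3
    RWD = 1.5,    # root dry weight, g
    RT = 2000,    # root tips, count
    RC = 1500,    # root crossings, count
    CHL = 35,     # chlorophyll index, Dualex units
    FL = 1.2,     # flavonoid index
    AN = 0.15,    # anthocyanin index
    NBI = 30,     # nitrogen balance index
    P = 30,       # photosynthesis, umol CO2 m^-2 s^-1
    E = 8,        # transpiration, mmol H2O m^-2 s^-1
    CiCa = 0.75,  # Ci/Ca ratio
    Gs = 0.5,     # stomatal conductance, mol m^-2 s^-1
    ETR = 150,    # electron transport rate, umol m^-2 s^-1
    PhiPS2 = 0.25,
    NPQ = 1.5,
    FvFm = 0.55
  )
  src <- rep("synthetic", length(m))
  names(src) <- names(m)
  src["LN"] <- "observed"
  attr(m, "source") <- src
  m
}

#' Configuration of a synthetic waterlogging experiment
#'
#' Describes the experimental design to emulate: by default the pot
#' study's eight treatments (0, 2, ..., 14 days of waterlogging) with
#' five replicates each. Treatment means are driven by the registry's
#' response curves scaled by the control means; replicate scatter is
#' Gaussian with a constant coefficient of variation.
#'
#' @param durations Treatment durations in days (must include 0).
#' @param n_reps Replicates per treatment (`>= 1`).
#' @param control_means Named positive vector of 0-day means; defaults to
#'   [default_control_means()].
#' @param cv Coefficient of variation of replicate noise (sd = `cv *`
#'   cell mean); 0.05 by default, 0 for noiseless tables.
#' @param registry Curve registry driving the treatment means.
#' @param seed Integer seed; generation is a pure function of it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(durations = seq(0, 14, by = 2), n_reps = 5L,
                             control_means = default_control_means(),
                             cv = 0.05, registry = load_registry(),
                             seed = 1L) {
  stopifnot(length(durations) >= 1, 0 %in% durations, n_reps >= 1,
            cv >= 0, is.numeric(seed))
  if (is.null(names(control_means)) || any(!nzchar(names(control_means)))) {
    stop("control_means must be a named vector", call. = FALSE)
  }
  if (any(control_means <= 0)) {
    stop("control_means must be strictly positive", call. = FALSE)
  }
  missing <- setdiff(names(control_means), names(registry$entries))
  if (length(missing)) {
    stop("control_means parameter(s) absent from registry: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(durations = sort(unique(durations)),
                 n_reps = as.integer(n_reps),
                 control_means = control_means, cv = cv,
                 registry = registry, seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a replicate-level synthetic treatment table
#'
#' For each parameter and duration the cell mean is
#' `control_mean * curve(duration)` (curve evaluated with a nonnegativity
#' clamp); each replicate is drawn independently from
#' `Normal(mean, cv * mean)` and floored at 0. Identical seeds give
#' identical tables; the caller's RNG state is untouched.
#'
#' @param config A [generator_config()].
#' @return A treatment table (`duration`, `replicate`, `parameter`,
#'   `value`) with `config$n_reps` rows per cell.
#' @export
#' @examples
#' tab <- generate_dataset(generator_config(seed = 7))
#' nrow(tab)   # 26 parameters x 8 durations x 5 replicates = 1040
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  params <- names(config$control_means)
  grid <- expand.grid(replicate = seq_len(config$n_reps),
                      duration = config$durations,
                      parameter = params,
                      stringsAsFactors = FALSE)
  mu_cell <- mapply(function(p, d) {
    config$control_means[[p]] *
      evaluate_curve(config$registry$entries[[p]], d, "clamp_nonneg")
  }, grid$parameter, grid$duration)
  values <- withr::with_seed(config$seed, {
    stats::rnorm(nrow(grid), mean = mu_cell, sd = config$cv * mu_cell)
  })
  out <- data.frame(duration = grid$duration,
                    replicate = grid$replicate,
                    parameter = grid$parameter,
                    value = pmax(0, values),
                    stringsAsFactors = FALSE)
  out <- out[order(out$parameter, out$duration, out$replicate), ]
  rownames(out) <- NULL
  out
}

#' Generate WSRI-space points for fitting tests
#'
#' Evaluates one registry curve at the given durations and adds
#' independent Gaussian noise directly on the index scale (no replicate
#' structure). `noise_sd = 0` returns the curve exactly.
#'
#' @param parameter_code Registry code of the curve to sample.
#' @param durations Durations in days (the design's eight by default).
#' @param noise_sd Standard deviation of additive index noise.
#' @param seed Integer seed.
#' @param registry Curve registry.
#' @return Data frame with columns `duration` and `index`.
#' @export
generate_wsri_points <- function(parameter_code,
                                 durations = seq(0, 14, by = 2),
                                 noise_sd = 0, seed = 1L,
                                 registry = load_registry()) {
  curve <- registry$entries[[parameter_code]]
  if (is.null(curve)) {
    stop(sprintf("unknown parameter code '%s'", parameter_code),
         call. = FALSE)
  }
  y <- evaluate_trajectory(curve, durations)
  noise <- withr::with_seed(seed,
                            stats::rnorm(length(durations), 0, noise_sd))
  data.frame(duration = durations, index = y + noise)
}
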