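#' Load a response-curve registry
#'
#' Reads a registry file (columns `parameter_code`, `description`, `family`,
#' `a`, `b`, `c`, `r_squared`; `c` empty for two-coefficient families) and
#' returns the curves with coefficients in canonical orientation. Linear
#' rows are stored as printed and re-oriented here via
#' [disambiguate_linear()]; provenance flags are populated:
#' \itemize{
#'   \item `column_swapped` — the printed linear pair was read as
#'     `(intercept, slope)`;
#'   \item `direction_conflict` — the disambiguated slope is positive
#'     although the parameter is described as declining under waterlogging
#'     (chlorophyll and the nitrogen balance index);
#'   \item `intercept_anomaly` — the unstressed value `y(0)` differs from 1
#'     by more than 0.5 (the NPQ row).
#' }
#'
#' The default source is the packaged transcription of the 26 published
#' cotton response curves (registry version `"published compilation, as printed 2023"`):
#' 6 quadratic, 5 exponential-decay and 15 linear entries.
#'
#' @param source Path to a registry file; defaults to the packaged registry.
#' @param negate_direction_conflicts If `TRUE`, slopes of curves flagged
#'   `direction_conflict` are negated so their index declines as described.
#'   Off by default: printed values are never silently altered.
#' @return An object of class `curve_registry`: a list with `entries`
#'   (named list of [response_curve]s) and `version`.
#' @export
#' @examples
#' reg <- load_registry()
#' length(reg$entries)            # 26
#' reg$entries$PH                 # plant height, quadratic
load_registry <- function(source = NULL, negate_direction_conflicts = FALSE) {
  if (is.null(source)) {
    source <- system.file("extdata", "response_registry.csv",
                          package = "cottonwl", mustWork = TRUE)
  }
  raw <- utils::read.csv(source, comment.char = "#",
                         stringsAsFactors = FALSE,
                         colClasses = c(parameter_code = "character",
                                        description = "character",
                                        family = "character"))
  needed <- c("parameter_code", "description", "family", "a", "b", "c",
              "r_squared")
  if (!all(needed %in% names(raw))) {
    stop("registry file lacks columns: ",
         paste(setdiff(needed, names(raw)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(raw$parameter_code)) {
    stop("duplicate parameter_code in registry: ",
         paste(unique(raw$parameter_code[duplicated(raw$parameter_code)]),
               collapse = ", "), call. = FALSE)
  }
  # parameters described as declining although their printed slope rises
  declining_conflicts <- c("CHL", "NBI")

  entries <- list()
  for (i in seq_len(nrow(raw))) {
    row <- raw[i, ]
    fam <- row$family
    if (!fam %in% response_families()) {
      stop(sprintf("registry row '%s': unknown family '%s'",
                   row$parameter_code, fam), call. = FALSE)
    }
    has_c <- is.finite(row$c)
    if (fam == "quadratic" && !has_c) {
      stop(sprintf("registry row '%s': quadratic needs 3 coefficients",
                   row$parameter_code), call. = FALSE)
    }
    if (fam != "quadratic" && has_c) {
      stop(sprintf("registry row '%s': family '%s' takes 2 coefficients but c is set",
                   row$parameter_code, fam), call. = FALSE)
    }
    flags <- character()
    if (fam == "linear") {
      d <- disambiguate_linear(row$a, row$b)
      if (d$swapped) flags <- c(flags, "column_swapped")
      slope <- d$slope
      if (slope > 0 && row$parameter_code %in% declining_conflicts) {
        flags <- c(flags, "direction_conflict")
        if (negate_direction_conflicts) slope <- -slope
      }
      coefs <- c(slope, d$intercept)
    } else if (fam == "quadratic") {
      coefs <- c(row$a, row$b, row$c)
    } else {
      coefs <- c(row$a, row$b)
    }
    curve <- response_curve(row$parameter_code, fam, coefs,
                            description = row$description,
                            r_squared = row$r_squared, flags = flags)
    if (abs(evaluate_curve(curve, 0) - 1) > 0.5) {
      curve$flags <- unique(c(curve$flags, "intercept_anomaly"))
    }
    entries[[row$parameter_code]] <- curve
  }
  structure(list(entries = entries, version = "published compilation, as printed 2023"),
            class = "curve_registry")
}

#' @export
print.curve_registry <- function(x, ...) {
  fams <- vapply(x$entries, `[[`, character(1), "family")
  cat(sprintf("<curve_registry> %d curves (%s)\n", length(x$entries),
              paste(sprintf("%s: %d", names(table(fams)), table(fams)),
                    collapse = ", ")))
  cat("  version:", x$version, "\n")
  invisible(x)
}

#' Export a registry (or batch of fits) as a flat table
#'
#' Produces the registry file schema: one row per curve with the
#' coefficients in canonical orientation, the fit quality, and
#' semicolon-separated flags. The inverse of [load_registry()] up to the
#' recorded orientation (exported linear rows are always canonical).
#'
#' @param registry A `curve_registry`, or a named list of [response_curve]s
#'   such as [fit_wsri_table()] returns (via their `$curve`).
#' @return A `data.frame` with columns `parameter_code`, `description`,
#'   `family`, `a`, `b`, `c`, `r_squared`, `flags`.
#' @export
registry_table <- function(registry) {
  curves <- if (inherits(registry, "curve_registry")) registry$entries
            else registry
  curves <- lapply(curves, function(x) {
    if (inherits(x, "fit_result")) x$curve else x
  })
  rows <- lapply(curves, function(cv) {
    k <- unname(cv$coefficients)
    data.frame(parameter_code = cv$parameter_code,
               description = cv$description,
               family = cv$family,
               a = k[1], b = k[2],
               c = if (length(k) == 3) k[3] else NA_real_,
               r_squared = cv$r_squared,
               flags = paste(cv$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(parameter_code = character(),
                      description = character(), family = character(),
                      a = numeric(), b = numeric(), c = numeric(),
                      r_squared = numeric(), flags = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a registry with its anomaly flags
#'
#' A human-readable account of the packaged curves: the flat coefficient
#' table plus one line per flagged anomaly (re-oriented linear rows,
#' direction conflicts, intercept anomalies).
#'
#' @param registry A `curve_registry`.
#' @return Invisibly, the [registry_table()]; prints the report.
#' @export
registry_report <- function(registry) {
  tab <- registry_table(registry)
  if (nrow(tab) == 0) {
    warning("empty registry: nothing to report")
    return(invisible(tab))
  }
  print(tab, digits = 4)
  flagged <- tab[nzchar(tab$flags), c("parameter_code", "flags")]
  cat("\nFlagged entries:\n")
  if (nrow(flagged) == 0) cat("  none\n")
  for (i in seq_len(nrow(flagged))) {
    cat(sprintf("  %-6s %s\n", flagged$parameter_code[i], flagged$flags[i]))
  }
  invisible(tab)
}
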