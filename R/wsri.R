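#' Treatment tables
#'
#' Replicate-level measurements are exchanged as long-format data frames
#' with columns `duration` (days of waterlogging, integer-valued),
#' `replicate` (id), `parameter` (short code) and `value` (the measurement
#' in its native units). The experimental design behind the packaged
#' curves is 8 treatments (0, 2, 4, 6, 8, 10, 12, 14 days) with 5
#' replicates each.
#'
#' @param x A data frame to validate/coerce.
#' @return The validated data frame (invisibly unchanged apart from column
#'   order).
#' @export
as_treatment_table <- function(x) {
  needed <- c("duration", "replicate", "parameter", "value")
  if (!is.data.frame(x) || !all(needed %in% names(x))) {
    stop("a treatment table needs columns duration, replicate, parameter, value",
         call. = FALSE)
  }
  if (!is.numeric(x$duration) || any(!is.finite(x$duration))) {
    stop("duration must be finite numeric days", call. = FALSE)
  }
  if (any(!is.finite(x$value))) stop("values must be finite", call. = FALSE)
  x[, needed]
}

#' Per-cell treatment means
#'
#' Arithmetic mean of the replicate values in every observed
#' (parameter, duration) cell. Cells with no records are absent from the
#' output, never zero-filled.
#'
#' @param table A treatment table (see [as_treatment_table()]).
#' @return A data frame with columns `parameter`, `duration`, `mean`,
#'   `sd` (replicate standard deviation, `NA` for singleton cells) and
#'   `n` (replicate count).
#' @export
treatment_means <- function(table) {
  table <- as_treatment_table(table)
  if (nrow(table) == 0) {
    return(data.frame(parameter = character(), duration = numeric(),
                      mean = numeric(), sd = numeric(), n = integer()))
  }
  key <- interaction(table$parameter, table$duration, drop = TRUE)
  split_vals <- split(table$value, key)
  first <- !duplicated(key)
  out <- data.frame(parameter = table$parameter[first],
                    duration = table$duration[first],
                    stringsAsFactors = FALSE)
  idx <- as.character(key[first])
  out$mean <- vapply(split_vals[idx], mean, numeric(1))
  out$sd <- vapply(split_vals[idx], stats::sd, numeric(1))
  out$n <- vapply(split_vals[idx], length, integer(1))
  out <- out[order(out$parameter, out$duration), ]
  rownames(out) <- NULL
  out
}

#' Compute the waterlogging stress response index
#'
#' The WSRI of parameter `p` at treatment duration `d` is the treatment
#' mean divided by the same parameter's 0-day (control) mean:
#' `WSRI(p, d) = mean(p, d) / mean(p, 0)`. The index is 1 at zero days by
#' construction (the control cell divided by itself) and 0 where
#' waterlogging is fully limiting. Parameters that are stimulated by
#' stress (flavonoids, anthocyanins, NPQ) legitimately exceed 1.
#'
#' @param table A treatment table with a duration-0 cell of nonzero mean
#'   for every parameter.
#' @return An object of class `wsri_table`: a data frame with columns
#'   `parameter`, `duration`, `index`, `n`, `sd_value` (replicate sd in
#'   native units), and attribute `control_means` (named vector).
#' @export
#' @examples
#' tab <- data.frame(duration = rep(c(0, 14), each = 2),
#'                   replicate = rep(1:2, 2),
#'                   parameter = "PH",
#'                   value = c(20, 20, 5, 5))
#' compute_wsri(tab)   # index 1 at 0 d, 0.25 at 14 d
compute_wsri <- function(table) {
  means <- treatment_means(table)
  ctrl <- means[means$duration == 0, ]
  control_means <- stats::setNames(ctrl$mean, ctrl$parameter)
  params <- unique(means$parameter)
  missing_ctrl <- setdiff(params, ctrl$parameter)
  if (length(missing_ctrl)) {
    stop("no 0-day control cell for parameter(s): ",
         paste(missing_ctrl, collapse = ", "), call. = FALSE)
  }
  zero_ctrl <- ctrl$parameter[ctrl$mean == 0]
  if (length(zero_ctrl)) {
    stop("control mean is zero for parameter(s): ",
         paste(zero_ctrl, collapse = ", "), call. = FALSE)
  }
  means$index <- means$mean / control_means[means$parameter]
  if (any(means$index < 0)) {
    warning("negative WSRI value(s) retained (negative measurements)")
  }
  out <- data.frame(parameter = means$parameter,
                    duration = means$duration,
                    index = unname(means$index),
                    n = means$n,
                    sd_value = means$sd,
                    stringsAsFactors = FALSE)
  structure(out, control_means = control_means,
            class = c("wsri_table", "data.frame"))
}

#' Check a treatment table against an expected design
#'
#' Report-only validation against the intended layout (by default the
#' 8-treatment, 5-replicate design): missing (parameter, duration) cells,
#' cells whose replicate count deviates from the expectation, and
#' duplicated (duration, replicate, parameter) keys.
#'
#' @param table A treatment table.
#' @param expected_durations Durations every parameter should cover.
#' @param expected_reps Expected replicate count per cell.
#' @return A list of class `design_report` with data frames
#'   `missing_cells`, `replicate_deviations`, `duplicate_keys` and a
#'   logical `clean`.
#' @export
validate_design <- function(table,
                            expected_durations = seq(0, 14, by = 2),
                            expected_reps = 5L) {
  table <- as_treatment_table(table)
  params <- sort(unique(table$parameter))
  grid <- expand.grid(parameter = params, duration = expected_durations,
                      stringsAsFactors = FALSE)
  counts <- treatment_means(table)[, c("parameter", "duration", "n")]
  merged <- merge(grid, counts, all.x = TRUE)
  missing_cells <- merged[is.na(merged$n), c("parameter", "duration")]
  deviations <- merged[!is.na(merged$n) & merged$n != expected_reps, ]
  key <- paste(table$duration, table$replicate, table$parameter, sep = "/")
  dup <- table[duplicated(key), c("duration", "replicate", "parameter")]
  dup <- unique(dup)
  rownames(missing_cells) <- rownames(deviations) <- rownames(dup) <- NULL
  structure(list(missing_cells = missing_cells,
                 replicate_deviations = deviations,
                 duplicate_keys = dup,
                 clean = nrow(missing_cells) == 0 && nrow(deviations) == 0 &&
                         nrow(dup) == 0),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  if (x$clean) {
    cat("<design_report> table matches the expected design\n")
    return(invisible(x))
  }
  cat("<design_report>\n")
  if (nrow(x$missing_cells)) {
    cat(sprintf("  %d missing cell(s), e.g. %s at %g d\n",
                nrow(x$missing_cells), x$missing_cells$parameter[1],
                x$missing_cells$duration[1]))
  }
  if (nrow(x$replicate_deviations)) {
    cat(sprintf("  %d cell(s) with unexpected replicate counts\n",
                nrow(x$replicate_deviations)))
  }
  if (nrow(x$duplicate_keys)) {
    cat(sprintf("  %d duplicated (duration, replicate, parameter) key(s)\n",
                nrow(x$duplicate_keys)))
  }
  invisible(x)
}
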