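test_that("packaged registry has the published composition", {
  reg <- load_registry()
  expect_s3_class(reg, "curve_registry")
  expect_length(reg$entries, 26)
  fams <- vapply(reg$entries, `[[`, character(1), "family")
  expect_equal(sum(fams == "quadratic"), 6)
  expect_equal(sum(fams == "exp_decay"), 5)
  expect_equal(sum(fams == "linear"), 15)
  expect_setequal(names(reg$entries)[fams == "quadratic"],
                  c("PH", "SD", "LN", "RWD", "RT", "RC"))
  expect_setequal(names(reg$entries)[fams == "exp_decay"],
                  c("LA", "DWL", "DWS", "DWSh", "DWT"))
})

test_that("registry coefficients satisfy their structural invariants", {
  reg <- load_registry()
  for (cv in reg$entries) {
    if (cv$family == "exp_decay") {
      expect_gt(cv$coefficients[["amplitude"]], 0)
      expect_lt(cv$coefficients[["rate"]], 0)
      # value at 0 days is the printed amplitude, exactly
      expect_identical(evaluate_curve(cv, 0), cv$coefficients[["amplitude"]])
    }
    if (cv$family == "quadratic") {
      expect_gte(cv$coefficients[["c"]], 0.9)
      expect_lte(cv$coefficients[["c"]], 1.2)
      expect_identical(evaluate_curve(cv, 0), cv$coefficients[["c"]])
    }
    if (cv$family == "linear" && cv$parameter_code != "NPQ") {
      expect_lte(abs(evaluate_curve(cv, 0) - 1), 0.5)
    }
  }
})

test_that("linear coefficient disambiguation picks the intercept nearest 1", {
  d <- disambiguate_linear(-0.0696, 1.078)   # root length, printed order fine
  expect_equal(d, list(slope = -0.0696, intercept = 1.078, swapped = FALSE))
  d <- disambiguate_linear(1.2, -0.051)      # photosynthesis, columns swapped
  expect_equal(d, list(slope = -0.051, intercept = 1.2, swapped = TRUE))
  # near-tie scored on |intercept - 1|: 0.948 (keep) vs 0.949 (swap)
  d <- disambiguate_linear(0.051, 0.052)
  expect_false(d$swapped)
  expect_equal(d$slope, 0.051)
})

test_that("registry flags mark swapped, conflicting and anomalous rows", {
  reg <- load_registry()
  flags <- lapply(reg$entries, `[[`, "flags")
  expect_true("column_swapped" %in% flags$P)
  expect_false("column_swapped" %in% flags$RL)
  expect_setequal(names(Filter(function(f) "direction_conflict" %in% f,
                               flags)), c("CHL", "NBI"))
  expect_setequal(names(Filter(function(f) "intercept_anomaly" %in% f,
                               flags)), "NPQ")
  # opt-in negation turns the conflicting slopes downward, others untouched
  neg <- load_registry(negate_direction_conflicts = TRUE)
  expect_equal(neg$entries$CHL$coefficients[["slope"]], -0.0055)
  expect_equal(neg$entries$NBI$coefficients[["slope"]], -0.020)
  expect_equal(neg$entries$FL$coefficients[["slope"]], 0.015)
})

test_that("malformed registry rows are rejected by name", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("parameter_code,description,family,a,b,c,r_squared",
               "XX,broken linear,linear,1,2,3,0.5"), tmp)
  expect_error(load_registry(tmp), "XX")
  writeLines(c("parameter_code,description,family,a,b,c,r_squared",
               "XX,a,linear,1,2,,0.5",
               "XX,b,linear,1,2,,0.5"), tmp)
  expect_error(load_registry(tmp), "duplicate")
})

test_that("curve evaluation matches hand arithmetic on published rows", {
  reg <- load_registry()
  expect_identical(evaluate_curve(reg$entries$PH, 0), 1.056)
  expect_equal(evaluate_curve(reg$entries$PH, 14),
               0.0032 * 196 - 0.087 * 14 + 1.056)
  expect_equal(evaluate_curve(reg$entries$PH, 14), 0.4652)
  expect_equal(evaluate_curve(reg$entries$LA, 6), 0.9770 * exp(-0.158 * 6))
  expect_equal(evaluate_curve(reg$entries$LA, 6), 0.3786, tolerance = 1e-4)
  expect_error(evaluate_curve(reg$entries$PH, -1), "duration")
})

test_that("clamping modes floor at 0 and cap at 1", {
  reg <- load_registry()
  expect_equal(evaluate_curve(reg$entries$Gs, 0, mode = "clamp01"), 1)
  expect_equal(evaluate_curve(reg$entries$Gs, 0, mode = "clamp_nonneg"), 1.4)
  # RC dips below zero at 14 d; the floor catches it
  expect_lt(evaluate_curve(reg$entries$RC, 14), 0)
  expect_identical(evaluate_curve(reg$entries$RC, 14, mode = "clamp_nonneg"),
                   0)
  steep <- response_curve("X", "linear", c(-0.2, 1))
  expect_identical(evaluate_curve(steep, 10, mode = "clamp01"), 0)
})

test_that("trajectory evaluation is an elementwise map preserving order", {
  reg <- load_registry()
  expect_equal(evaluate_trajectory(reg$entries$PH, c(0, 14)),
               c(1.056, 0.4652))
  expect_equal(evaluate_trajectory(reg$entries$RL, c(0, 14)),
               c(1.078, 1.078 - 0.0696 * 14))
  expect_error(evaluate_trajectory(reg$entries$PH, numeric(0)), "non-empty")
  set.seed(42)
  for (code in c("PH", "LA", "NPQ")) {
    d <- sort(runif(12, 0, 14))
    for (mode in c("raw", "clamp_nonneg", "clamp01")) {
      expect_identical(evaluate_trajectory(reg$entries[[code]], d, mode),
                       vapply(d, function(x)
                         evaluate_curve(reg$entries[[code]], x, mode),
                         numeric(1)))
    }
  }
})

test_that("exponential decay curves are strictly decreasing", {
  reg <- load_registry()
  for (code in c("LA", "DWL", "DWS", "DWSh", "DWT")) {
    y <- evaluate_trajectory(reg$entries[[code]], seq(0, 14, by = 0.5))
    expect_true(all(diff(y) < 0))
  }
})

test_that("percent change follows the reporting convention", {
  reg <- load_registry()
  expect_equal(percent_change(reg$entries$PH, 14),
               100 * (1 - 0.4652 / 1.056))
  expect_equal(percent_change(reg$entries$PH, 14), 55.95, tolerance = 1e-3)
  expect_equal(percent_change(reg$entries$LA, 0), 0)
  # flavonoids rise under stress: negative percent "decrease"
  expect_lt(percent_change(reg$entries$FL, 14), 0)
  zero <- response_curve("Z", "linear", c(1, 0))
  expect_error(percent_change(zero, 5), "undefined")
})

test_that("curve construction enforces family arity", {
  expect_error(response_curve("X", "linear", c(1, 2, 3)), "2 coefficients")
  expect_error(response_curve("X", "quadratic", c(1, 2)), "3 coefficients")
  expect_silent(response_curve("X", "exp_decay", c(1, -0.1)))
})
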