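# Independent oracles used across tests; these deliberately avoid the
# package's fitting code paths.

# brute-force per-cell means: plain sum/count loop
oracle_cell_means <- function(table) {
  out <- list()
  for (i in seq_len(nrow(table))) {
    key <- paste(table$parameter[i], table$duration[i], sep = "@")
    out[[key]] <- c(out[[key]], table$value[i])
  }
  vapply(out, function(v) sum(v) / length(v), numeric(1))
}

# grid-search least squares for a line y = s*x + i
oracle_grid_line <- function(x, y, s_range, i_range, step) {
  grid <- expand.grid(s = seq(s_range[1], s_range[2], by = step),
                      i = seq(i_range[1], i_range[2], by = step))
  sse <- mapply(function(s, i) sum((y - (s * x + i))^2), grid$s, grid$i)
  unlist(grid[which.min(sse), ])
}

# grid-search least squares for y = a*x^2 + b*x + c
oracle_grid_quad <- function(x, y, a_range, b_range, c_range, step) {
  grid <- expand.grid(a = seq(a_range[1], a_range[2], by = step),
                      b = seq(b_range[1], b_range[2], by = step),
                      c = seq(c_range[1], c_range[2], by = step))
  sse <- mapply(function(a, b, c) sum((y - (a * x^2 + b * x + c))^2),
                grid$a, grid$b, grid$c)
  unlist(grid[which.min(sse), ])
}

# closed-form normal equations for a polynomial fit (degree 1 or 2),
# returned highest power first
oracle_normal_equations <- function(x, y, degree) {
  X <- if (degree == 2) cbind(x^2, x, 1) else cbind(x, 1)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

design_durations <- seq(0, 14, by = 2)

# small treatment table for WSRI unit tests
toy_table <- function() {
  data.frame(duration = rep(c(0, 2, 14), each = 3),
             replicate = rep(1:3, 3),
             parameter = "PH",
             value = c(20, 20, 20, 18, 19, 20, 5, 5, 5))
}
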