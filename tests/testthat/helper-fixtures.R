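# shared fixtures: tiny in-code data sets used across test files

# minimal case_table without going through a monitoring series
make_case_table <- function(df, target) {
  stopifnot(target %in% names(df))
  ord <- c(setdiff(names(df), target), target)
  df <- df[, ord, drop = FALSE]
  attr(df, "target") <- target
  attr(df, "predictors") <- setdiff(names(df), target)
  class(df) <- c("case_table", "data.frame")
  df
}

# noiseless linear problem: O3 = 2 T + 3
linear_case_table <- function(n = 500, seed = 1, noise_sd = 0) {
  set.seed(seed)
  df <- data.frame(D = runif(n, 1, 366), H = runif(n, 0, 23),
                   T = runif(n, -10, 30))
  df$O3 <- 2 * df$T + 3 + rnorm(n, 0, noise_sd)
  df$O3 <- df$O3 - min(df$O3) + 0.1 # keep concentrations positive
  make_case_table(df, "O3")
}

# heteroscedastic target: error scale grows with the signal level, the regime
# sub-range modeling is designed for
hetero_case_table <- function(n = 2000, seed = 1) {
  set.seed(seed)
  df <- data.frame(T = runif(n, -5, 30), I = runif(n, 0, 800),
                   WS = rexp(n, 0.5))
  mu <- exp(1.5 + 0.002 * df$I + 0.03 * df$T - 0.1 * df$WS)
  df$PM10 <- mu * exp(rnorm(n, 0, 0.4))
  make_case_table(df, "PM10")
}

# small gap-free synthetic monitoring series (fast: single year)
complete_synthetic_series <- function(seed = 7, station = "zabrze",
                                      years = 2011) {
  vars <- synthetic_config(station = station)$variables
  generate_series(synthetic_config(
    years = years, seed = seed, station = station,
    missing_rates = stats::setNames(rep(0, length(vars)), vars),
    block_rate = 0))
}

# quick training config for tests (scaled-down protocol; the architecture and
# optimizer match the defaults)
quick_cfg <- function(seed = 1, restarts = 2, max_epochs = 120) {
  train_config(seed = seed, restarts = restarts, max_epochs = max_epochs)
}

# printed error tables fixture shipped with the package
printed_tables <- function() {
  path <- system.file("extdata", "printed_error_tables.csv",
                      package = "aqgapfill")
  utils::read.csv(path)
}

write_toy_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

# number of decimals a printed value carries (trailing zeros lost in parsing)
decimals <- function(x) {
  s <- sub("0+$", "", format(x, scientific = FALSE))
  if (!grepl(".", s, fixed = TRUE)) 0L else nchar(sub("^[^.]*\\.", "", s))
}
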