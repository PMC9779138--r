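#' Variable specification for one regression model
#'
#' Names the target pollutant and the ordered predictor list (which includes
#' the numeric time variables `D` and `H`).
#'
#' @param target variable name being modelled.
#' @param predictors character vector of predictor names; may include `D` and
#'   `H` plus any measured variable.
#' @return a `variable_spec` list.
#' @export
variable_spec <- function(target, predictors) {
  if (length(predictors) == 0) stop("predictors must be non-empty")
  if (target %in% predictors) stop("target cannot be one of its predictors")
  ok <- c("D", "H", AQ_VARIABLES)
  bad <- setdiff(c(target, predictors), ok)
  if (length(bad) > 0) stop("unknown variable(s): ", paste(bad, collapse = ", "))
  structure(list(target = target, predictors = predictors),
            class = "variable_spec")
}

#' Default predictor sets per station
#'
#' At an urban-background station ("zabrze" profile) all pollutants plus wind
#' speed, temperature and solar radiation are available as inputs; the rural
#' profile ("zloty_potok") adds relative humidity and lacks CO. The target is
#' always excluded from its own predictors; H and D are always included.
#'
#' @param target pollutant to model.
#' @param station `"zabrze"` or `"zloty_potok"`.
#' @return a [variable_spec()].
#' @export
default_variable_spec <- function(target, station = c("zabrze", "zloty_potok")) {
  station <- match.arg(station)
  pool <- if (station == "zabrze") {
    c("O3", "NO", "NO2", "SO2", "CO", "PM10", "WS", "T", "I")
  } else {
    c("O3", "NO", "NO2", "SO2", "CO", "PM10", "WS", "T", "I", "RH")
  }
  if (station == "zloty_potok" && target == "CO") {
    stop("CO is not measured at the rural profile station")
  }
  variable_spec(target, c("H", "D", setdiff(pool, target)))
}

#' Build a complete-case modeling table
#'
#' Keeps one row per hour at which the target and every predictor are present,
#' attaches the numeric time encodings, and records provenance. Rows stay in
#' chronological order.
#'
#' @param series a [monitoring_series()].
#' @param spec a [variable_spec()].
#' @param convention time encoding, see [encode_time()].
#' @return a `case_table`: data frame with columns `D`, `H`, measured
#'   predictors, and the target as last column; attributes `target`,
#'   `predictors`, `provenance`.
#' @export
build_case_table <- function(series, spec, convention = c("linear", "cosine")) {
  convention <- match.arg(convention)
  measured <- setdiff(c(spec$predictors, spec$target), c("D", "H"))
  absent <- setdiff(measured, names(series))
  if (length(absent) > 0) {
    stop("series lacks required variable(s): ", paste(absent, collapse = ", "))
  }
  te <- encode_time(series$timestamp, convention)
  cols <- c(
    list(D = te$D, H = te$H),
    stats::setNames(lapply(measured, function(v) series[[v]]), measured)
  )
  tab <- as.data.frame(cols)
  keep <- stats::complete.cases(tab)
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0) stop("no complete cases for target ", spec$target)
  rownames(tab) <- NULL
  # fixed column order: D, H, measured predictors, target last
  ord <- c(intersect(spec$predictors, c("D", "H")),
           setdiff(spec$predictors, c("D", "H")), spec$target)
  tab <- tab[, ord, drop = FALSE]
  attr(tab, "target") <- spec$target
  attr(tab, "predictors") <- spec$predictors
  attr(tab, "provenance") <- list(
    station_id = attr(series, "station_id"),
    target = spec$target,
    convention = convention,
    timestamps = series$timestamp[keep]
  )
  class(tab) <- c("case_table", "data.frame")
  tab
}

#' Subset a case table, preserving metadata
#'
#' @param table a `case_table`.
#' @param i row indices or logical mask.
#' @return a `case_table` with the same target/predictor metadata.
#' @export
case_table_subset <- function(table, i) {
  out <- as.data.frame(table)[i, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("target", "predictors")) attr(out, a) <- attr(table, a)
  prov <- attr(table, "provenance")
  if (!is.null(prov$timestamps)) prov$timestamps <- prov$timestamps[i]
  attr(out, "provenance") <- prov
  class(out) <- c("case_table", "data.frame")
  out
}

#' Seeded random train/validation/test split
#'
#' Assigns every case to exactly one of train (70%), validation (15%) and test
#' (15%). Counts follow largest-remainder apportionment, so each count is
#' within one case of its exact fraction; assignment is a uniformly random
#' permutation, reproducible at a fixed seed.
#'
#' @param table a `case_table` (or anything with rows).
#' @param seed integer seed.
#' @param fractions train/valid/test fractions summing to 1.
#' @return a `split_assignment`: factor of labels `train`/`valid`/`test` with
#'   attributes `fractions` and `seed`.
#' @export
split_train_valid_test <- function(table, seed,
                                   fractions = c(train = 0.70, valid = 0.15,
                                                 test = 0.15)) {
  n <- nrow(table)
  if (is.null(n)) n <- length(table)
  if (n < 7) stop("need at least 7 cases to populate all three splits, got ", n)
  stopifnot(abs(sum(fractions) - 1) < 1e-12)
  counts <- apportion_largest_remainder(n, fractions)
  labels <- rep(factor(c("train", "valid", "test"),
                       levels = c("train", "valid", "test")), counts)
  perm <- with_seed(seed, sample.int(n))
  out <- labels[perm] # uniform random placement of the label blocks
  attr(out, "fractions") <- fractions
  attr(out, "seed") <- seed
  class(out) <- c("split_assignment", class(out))
  out
}

# Largest-remainder (Hamilton) apportionment of n into round(n * fractions).
# Ties in the fractional remainders resolve in fraction order (train first).
apportion_largest_remainder <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  r <- n - sum(base)
  if (r > 0) {
    rem <- exact - base
    top <- order(rem, decreasing = TRUE)[seq_len(r)]
    base[top] <- base[top] + 1
  }
  as.integer(base)
}

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_state <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_state) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_state) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Deterministic seed fan-out: one master seed yields independent child seeds
# for splits, restarts and sub-ranges. Kept below 2^31 - 1.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (i in idx) {
    s <- (s * 48271 + as.double(i) + 1) %% 2147483647
  }
  as.integer(s)
}
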