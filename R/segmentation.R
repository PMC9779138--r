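#' Sort cases by a key and partition into equal-count sub-ranges
#'
#' Cases are stably sorted ascending by `key_values` and cut into `k`
#' contiguous blocks whose sizes differ by at most one; when `n` is not
#' divisible by `k` the extra cases go to the lowest-index sub-ranges.
#' Boundaries are the key value of the first case of each non-first block,
#' giving half-open routing intervals (last interval closed above).
#'
#' @param key_values numeric sorting key, one per case (real target values for
#'   RVS, stage-1 predictions for PVS).
#' @param k number of sub-ranges, `1 <= k <= n`.
#' @return a `subrange_partition`: list with `k`, `sizes`, `boundaries` (k-1
#'   cut values), `assignment` (1-based sub-range index per case, original
#'   order), `order` (the sorting permutation), and per-sub-range observed key
#'   `ranges` (k x 2 matrix).
#' @export
sort_and_partition <- function(key_values, k) {
  n <- length(key_values)
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k = ", k, " exceeds the number of cases n = ", n)
  sizes <- rep(n %/% k, k) + as.integer(seq_len(k) <= n %% k)
  ord <- order(key_values) # radix/stable: ties keep original order
  block <- rep.int(seq_len(k), sizes)
  assignment <- integer(n)
  assignment[ord] <- block
  starts <- cumsum(c(1L, sizes[-k]))
  boundaries <- key_values[ord][starts[-1]]
  ranges <- t(vapply(seq_len(k), function(i) {
    kv <- key_values[ord][block == i]
    c(min(kv), max(kv))
  }, numeric(2)))
  colnames(ranges) <- c("low", "high")
  structure(list(k = k, sizes = sizes, boundaries = boundaries,
                 assignment = assignment, order = ord, ranges = ranges),
            class = "subrange_partition")
}

new_segmented_model <- function(mode, k, submodels, boundaries, ranges, sizes,
                                target, stage1 = NULL, provenance = list()) {
  structure(list(mode = mode, k = as.integer(k), stage1 = stage1,
                 submodels = submodels, boundaries = boundaries,
                 ranges = ranges, sizes = sizes, target = target,
                 provenance = provenance),
            class = "segmented_model")
}

is_degenerate_marker <- function(x) inherits(x, "degenerate_marker")

# Train one sub-model on its routed cases with a fresh 70/15/15 split; a
# zero-variance target yields a degenerate marker (the observed constant),
# not a failure.
fit_submodel <- function(table, rows, cfg, subrange_index) {
  sub <- case_table_subset(table, rows)
  y <- sub[[attr(sub, "target")]]
  if (length(unique(y)) == 1L) {
    return(structure(list(constant = y[1], n = nrow(sub)),
                     class = "degenerate_marker"))
  }
  split <- split_train_valid_test(sub, seed = derive_seed(cfg$seed, 7, subrange_index))
  tryCatch(fit_best_of_restarts(sub, split, cfg),
           degenerate_segment = function(e) {
             structure(list(constant = e$constant, n = nrow(sub)),
                       class = "degenerate_marker")
           })
}

#' Fit an RVS (Real Values Sorting) segmented model
#'
#' Oracle segmentation: cases are sorted and partitioned by the \emph{real}
#' target concentration, and an independent perceptron is trained per
#' sub-range (each with its own seeded 70/15/15 split and best-of-restarts
#' selection). Because routing requires the true target, an RVS model
#' quantifies the potential of segmentation; it cannot route unseen cases.
#' `k = 1` reduces to the single full-range model.
#'
#' Sub-ranges whose target has zero variability become degenerate markers
#' (constant prediction, excluded from overall error aggregation).
#'
#' @param table a `case_table`.
#' @param k number of sub-ranges (the study uses 1, 2, 4, 8).
#' @param cfg a [train_config()].
#' @return a `segmented_model` with `mode = "RVS"`.
#' @export
fit_rvs <- function(table, k, cfg = train_config()) {
  target <- attr(table, "target")
  part <- sort_and_partition(table[[target]], k)
  submodels <- lapply(seq_len(part$k), function(i) {
    fit_submodel(table, part$assignment == i, cfg, i)
  })
  new_segmented_model("RVS", part$k, submodels, part$boundaries, part$ranges,
                      part$sizes, target,
                      provenance = list(seed = cfg$seed, n = nrow(table)))
}

#' Fit a PVS (Predicted Values Sorting) segmented model
#'
#' Practical segmentation in three steps: (1) train a full-range stage-1
#' perceptron and predict every case; (2) sort and partition all cases by the
#' stage-1 \emph{predicted} concentration; (3) train one sub-model per
#' sub-range on the cases routed there. The stage-1 boundaries are stored on
#' the predicted scale so unseen cases can be routed.
#'
#' @inheritParams fit_rvs
#' @return a `segmented_model` with `mode = "PVS"` and a `stage1` model.
#' @export
fit_pvs <- function(table, k, cfg = train_config()) {
  target <- attr(table, "target")
  split1 <- split_train_valid_test(table, seed = derive_seed(cfg$seed, 7, 0))
  stage1 <- fit_best_of_restarts(table, split1, cfg)
  pred1 <- predict(stage1, table)
  part <- sort_and_partition(pred1, k)
  submodels <- lapply(seq_len(part$k), function(i) {
    fit_submodel(table, part$assignment == i, cfg, i)
  })
  m <- new_segmented_model("PVS", part$k, submodels, part$boundaries,
                           part$ranges, part$sizes, target, stage1 = stage1,
                           provenance = list(seed = cfg$seed, n = nrow(table)))
  m$ranges_real <- t(vapply(seq_len(part$k), function(i) {
    y <- table[[target]][part$assignment == i]
    c(min(y), max(y))
  }, numeric(2)))
  m
}

#' Fit a full-range (single) model as a segmented model with k = 1
#'
#' @inheritParams fit_rvs
#' @return a `segmented_model` with `mode = "FULL"`, one sub-model.
#' @export
fit_full_range <- function(table, cfg = train_config()) {
  m <- fit_rvs(table, 1, cfg)
  m$mode <- "FULL"
  m
}

#' Route cases to a sub-range by stage-1 prediction
#'
#' PVS only: computes the stage-1 prediction p for each case and returns the
#' sub-range index i with boundary\[i-1\] <= p < boundary\[i\] (half-open;
#' p below all boundaries routes to 1, p at or above the last boundary to k).
#' RVS/FULL models cannot route unseen cases (the real target is unknown).
#'
#' @param model a `segmented_model`.
#' @param cases rows with the stage-1 model's input columns.
#' @return integer vector of 1-based sub-range indices.
#' @export
route_case <- function(model, cases) {
  if (model$mode != "PVS") {
    stop("unroutable model: ", model$mode,
         " cannot route unseen cases (real target value unknown)")
  }
  p <- predict(model$stage1, cases)
  findInterval(p, model$boundaries) + 1L
}

# Routing used in evaluation: RVS/FULL by real target value (oracle mode),
# PVS by stage-1 prediction.
route_for_evaluation <- function(model, table) {
  if (model$mode == "PVS") {
    route_case(model, table)
  } else {
    y <- table[[model$target]]
    findInterval(y, model$boundaries) + 1L
  }
}

#' Predict with a segmented model
#'
#' Each case is routed to a sub-range — PVS by its stage-1 prediction, RVS and
#' FULL by the real target value (oracle mode, so `newdata` must contain the
#' target; evaluation use only) — and predicted by that sub-range's model.
#' Cases routed to a degenerate sub-range get its constant target value.
#'
#' @param object a `segmented_model`.
#' @param newdata a `case_table` or data frame.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.segmented_model <- function(object, newdata, ...) {
  if (object$mode != "PVS" && !(object$target %in% names(newdata))) {
    stop(object$mode, " models route by the real target value; column '",
         object$target, "' is required (oracle mode)")
  }
  idx <- route_for_evaluation(object, newdata)
  out <- numeric(nrow(newdata))
  for (i in seq_len(object$k)) {
    rows <- idx == i
    if (!any(rows)) next
    sm <- object$submodels[[i]]
    out[rows] <- if (is_degenerate_marker(sm)) sm$constant
                 else predict(sm, newdata[rows, , drop = FALSE])
  }
  out
}

#' @export
print.segmented_model <- function(x, ...) {
  deg <- sum(vapply(x$submodels, is_degenerate_marker, logical(1)))
  cat(sprintf("<segmented_model> %s, k = %d, target %s, n = %s\n",
              x$mode, x$k, x$target,
              format(sum(x$sizes), big.mark = ",")))
  if (x$k > 1) {
    cat(" boundaries:", paste(signif(x$boundaries, 4), collapse = ", "), "\n")
  }
  if (deg > 0) cat(" degenerate sub-ranges:", deg, "\n")
  invisible(x)
}

#' Serialize / load a segmented model as JSON
#'
#' @param model a `segmented_model`.
#' @param path file path.
#' @return `path` invisibly; `read_segmented_model` returns the model.
#' @export
write_segmented_model <- function(model, path) {
  subs <- lapply(model$submodels, function(sm) {
    if (is_degenerate_marker(sm)) {
      list(kind = "degenerate_marker", constant = sm$constant, n = sm$n)
    } else mlp_to_list(sm)
  })
  doc <- list(kind = "segmented_model", mode = model$mode, k = model$k,
              target = model$target, boundaries = model$boundaries,
              sizes = model$sizes, ranges = model$ranges,
              stage1 = if (!is.null(model$stage1)) mlp_to_list(model$stage1),
              submodels = subs, provenance = model$provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_segmented_model
#' @export
read_segmented_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  subs <- lapply(doc$submodels, function(s) {
    if (identical(s$kind, "degenerate_marker")) {
      structure(list(constant = as.numeric(s$constant), n = as.integer(s$n)),
                class = "degenerate_marker")
    } else {
      mlp_from_json_list(s)
    }
  })
  stage1 <- if (!is.null(doc$stage1)) mlp_from_json_list(doc$stage1)
  ranges <- do.call(rbind, lapply(doc$ranges, as.numeric))
  colnames(ranges) <- c("low", "high")
  new_segmented_model(doc$mode, doc$k, subs,
                      as.numeric(unlist(doc$boundaries)), ranges,
                      as.integer(unlist(doc$sizes)), doc$target,
                      stage1 = stage1, provenance = doc$provenance)
}

# rebuild an mlp_model from its un-simplified JSON list form
mlp_from_json_list <- function(s) {
  s$par <- as.numeric(unlist(s$par))
  s$columns <- as.character(unlist(s$columns))
  s$scaling <- lapply(s$scaling, function(v) as.numeric(unlist(v)))
  s$p <- as.integer(s$p)
  s$h <- as.integer(s$h)
  for (f in c("sos_train", "sos_valid")) s[[f]] <- as.numeric(s[[f]])
  mlp_from_list(s)
}
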