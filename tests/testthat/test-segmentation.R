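test_that("sort_and_partition block sizes follow largest-remainder arithmetic", {
  # the published station case counts
  p1 <- sort_and_partition(seq_len(15536), 8)
  expect_equal(p1$sizes, rep(1942L, 8))
  p2 <- sort_and_partition(seq_len(15536), 4)
  expect_equal(p2$sizes, rep(3884L, 4))
  p3 <- sort_and_partition(runif(10), 2)
  expect_equal(p3$sizes, c(5L, 5L))
  # 36,460 is not divisible by 8: extras go to the lowest sub-ranges
  p4 <- sort_and_partition(seq_len(36460), 8)
  expect_equal(p4$sizes, c(rep(4558L, 4), rep(4557L, 4)))

  expect_error(sort_and_partition(runif(3), 4), "exceeds")
})

test_that("partition invariants hold over random inputs", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(10:500, 1)
    k <- sample(1:min(n, 9), 1)
    key <- rnorm(n)
    p <- sort_and_partition(key, k)
    expect_equal(sum(p$sizes), n)
    expect_lte(max(p$sizes) - min(p$sizes), 1)
    expect_true(all(diff(p$boundaries) >= 0))
    expect_equal(sort(unique(p$assignment)), seq_len(k))
    expect_equal(as.vector(table(p$assignment)), p$sizes)
    # every case's key lies within its sub-range's observed range
    for (j in seq_len(k)) {
      kv <- key[p$assignment == j]
      expect_true(all(kv >= p$ranges[j, "low"] & kv <= p$ranges[j, "high"]))
    }
    # blocks are ordered: max of block j <= min of block j+1
    if (k > 1) {
      highs <- p$ranges[-k, "high"]
      lows <- p$ranges[-1, "low"]
      expect_true(all(highs <= lows))
    }
  }
})

test_that("stable sort keeps tied cases in original order", {
  key <- c(2, 1, 2, 1, 2, 1)
  p <- sort_and_partition(key, 2)
  # the three 1s (cases 2, 4, 6) fill block 1; ties never jump blocks here
  expect_equal(p$assignment, c(2, 1, 2, 1, 2, 1))
  expect_equal(p$boundaries, 2)
})

test_that("RVS with k = 1 equals the full-range model", {
  tab <- hetero_case_table(400, seed = 11)
  cfg <- quick_cfg(seed = 11, max_epochs = 60)
  m1 <- fit_rvs(tab, 1, cfg)
  mf <- fit_full_range(tab, cfg)
  expect_identical(predict(m1, tab), predict(mf, tab))
  expect_equal(m1$k, 1L)
  expect_length(m1$boundaries, 0)
})

test_that("RVS partitions cover every case exactly once and train per sub-range", {
  tab <- hetero_case_table(600, seed = 12)
  cfg <- quick_cfg(seed = 12, max_epochs = 40)
  m <- fit_rvs(tab, 4, cfg)
  expect_equal(sum(m$sizes), nrow(tab))
  idx <- aqgapfill:::route_for_evaluation(m, tab)
  expect_equal(as.vector(table(idx)), m$sizes)
  # sub-models are distinct networks
  expect_equal(length(m$submodels), 4)
  expect_gt(length(unique(vapply(m$submodels, function(s) s$par[1], 1))), 1)
})

test_that("a constant-valued block becomes a degenerate marker, not a failure", {
  set.seed(13)
  n <- 200
  # half the cases share the exact detection-limit value, like a floor-censored
  # NO record; the rest are continuous above it
  df <- data.frame(T = runif(n, 0, 30),
                   NO = c(rep(0.5, n / 2), 0.5 + rexp(n / 2, 0.2)))
  tab <- make_case_table(df, "NO")
  m <- fit_rvs(tab, 2, quick_cfg(seed = 13, max_epochs = 40))
  deg <- vapply(m$submodels, aqgapfill:::is_degenerate_marker, logical(1))
  expect_identical(deg, c(TRUE, FALSE))
  expect_equal(m$submodels[[1]]$constant, 0.5)
  # degenerate sub-range predicts its constant
  pred <- predict(m, tab)
  expect_true(all(pred[tab$NO == 0.5 &
                         aqgapfill:::route_for_evaluation(m, tab) == 1] == 0.5))
  # overall error excludes the degenerate sub-range
  r <- evaluate(m, tab)
  expect_equal(r$excluded, 1L)
  expect_true(is.na(r$table$mae[1]))
  expect_equal(r$overall_mae, r$table$mae[2])
})

test_that("PVS routes by stage-1 prediction, self-consistently", {
  tab <- hetero_case_table(600, seed = 14)
  cfg <- quick_cfg(seed = 14, max_epochs = 60)
  m <- fit_pvs(tab, 4, cfg)
  expect_s3_class(m$stage1, "mlp_model")
  # re-routing the training cases reproduces the stored partition
  p <- sort_and_partition(predict(m$stage1, tab), 4)
  expect_identical(route_case(m, tab), p$assignment)
  expect_equal(as.vector(table(route_case(m, tab))), m$sizes)
})

test_that("route_case applies half-open boundary intervals", {
  tab <- hetero_case_table(300, seed = 15)
  m <- fit_pvs(tab, 4, quick_cfg(seed = 15, max_epochs = 40))
  b <- m$boundaries
  # synthesize a model whose stage-1 output we control via direct boundaries:
  # below all boundaries -> 1; exactly at boundary j -> j + 1; above all -> k
  expect_equal(findInterval(b[1] - 1e-9, b) + 1L, 1L)
  expect_equal(findInterval(b[2], b) + 1L, 3L)
  expect_equal(findInterval(b[3] + 10, b) + 1L, 4L)

  mr <- fit_rvs(tab, 2, quick_cfg(seed = 15, max_epochs = 40))
  expect_error(route_case(mr, tab), "unroutable")
  # RVS prediction without the target column is refused (oracle mode)
  expect_error(predict(mr, tab[, c("T", "I", "WS")]), "oracle")
})

test_that("predict_segmented equals the per-sub-range brute-force loop", {
  tab <- hetero_case_table(500, seed = 16)
  for (fitter in list(fit_rvs, fit_pvs)) {
    m <- fitter(tab, 4, quick_cfg(seed = 16, max_epochs = 40))
    pred <- predict(m, tab)
    idx <- aqgapfill:::route_for_evaluation(m, tab)
    oracle <- numeric(nrow(tab))
    for (i in 1:4) {
      rows <- which(idx == i)
      sm <- m$submodels[[i]]
      oracle[rows] <- if (aqgapfill:::is_degenerate_marker(sm)) sm$constant
                      else predict(sm, tab[rows, ])
    }
    expect_identical(pred, oracle)
    expect_true(all(is.finite(pred)))
  }
})

test_that("segmented model JSON round trip preserves behavior", {
  # JSON stores doubles at ~15-16 significant digits, so reloaded predictions
  # agree to ~1e-12 relative; only a case predicted exactly onto a boundary
  # could route differently, which the key-distance filter excludes
  tab <- linear_case_table(400, seed = 17, noise_sd = 4)
  m <- fit_pvs(tab, 2, quick_cfg(seed = 17, max_epochs = 60))
  f <- tempfile(fileext = ".json")
  write_segmented_model(m, f)
  m2 <- read_segmented_model(f)
  expect_equal(m2$mode, "PVS")
  expect_equal(m2$boundaries, m$boundaries, tolerance = 1e-12)
  p <- predict(m$stage1, tab)
  off_boundary <- abs(p - m$boundaries[1]) > 1e-9
  expect_identical(route_case(m2, tab)[off_boundary],
                   route_case(m, tab)[off_boundary])
  expect_equal(predict(m2, tab)[off_boundary], predict(m, tab)[off_boundary],
               tolerance = 1e-9)

  # degenerate markers survive the round trip
  df <- data.frame(T = runif(100), NO = c(rep(1, 50), 1 + rexp(50)))
  tabd <- make_case_table(df, "NO")
  md <- fit_rvs(tabd, 2, quick_cfg(seed = 18, max_epochs = 20))
  f2 <- tempfile(fileext = ".json")
  write_segmented_model(md, f2)
  md2 <- read_segmented_model(f2)
  expect_true(aqgapfill:::is_degenerate_marker(md2$submodels[[1]]))
  off <- tabd$NO != md$boundaries[1] # the boundary case itself is knife-edge
  expect_equal(predict(md2, tabd)[off], predict(md, tabd)[off],
               tolerance = 1e-9)
})
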