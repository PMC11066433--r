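test_that("gamma scan locates the fold where the branch count changes", {
  p <- endo_core()
  sc <- scan_parameter(p, "gamma", lo = 0.01, hi = 5, n_points = 64)
  expect_length(sc$fold_points, 1L)
  gs <- saddle_node_gamma(p)
  expect_equal(sc$fold_points, as.numeric(gs), tolerance = 1e-4)
  # counts change only at folds (pair creation: parity preserved)
  counts <- vapply(sc$branches, function(b) length(b$points), 0L)
  expect_true(all(counts %in% c(1L, 3L)))
  expect_true(all(diff(counts) %in% c(0L, 2L)))
  # upper branch is monotone increasing in gamma above the fold
  upper <- vapply(sc$branches[counts == 3L],
                  function(b) max(as.data.frame(b)$tgfb1), 0)
  expect_true(all(diff(upper) > 0))
})

test_that("degenerate scans are handled", {
  p <- endo_core()
  sc <- scan_parameter(p, "gamma", lo = 1, hi = 2, n_points = 2)
  expect_length(sc$fold_points, 0L)
  expect_error(scan_parameter(p, "K9", 0.1, 1), "valid names")
  expect_error(scan_parameter(p, "gamma", 2, 1), "lo < hi")
})

test_that("variational gamma fold matches the scan and scales correctly", {
  p <- endo_core()
  g1 <- as.numeric(saddle_node_gamma(p))
  expect_equal(g1, 0.074, tolerance = 0.01)
  # invariance: doubling a/d1 and K1 jointly leaves the fold unchanged
  p2 <- p; p2$a <- 2 * p2$a; p2$K1 <- 2 * p2$K1
  expect_equal(as.numeric(saddle_node_gamma(p2)), g1, tolerance = 1e-6)
  # the fold value is itself a fold: just above it two states, below one
  above <- default_core_params(c_d3 = g1 * 1.05)
  below <- default_core_params(c_d3 = g1 * 0.95)
  expect_equal(length(find_fixed_points(above)$points), 3L)
  expect_equal(length(find_fixed_points(below)$points), 1L)
})

test_that("K1 fold matches a K1 scan and the production-scale calibration", {
  p <- calibrate_cd3_for_k1_fold(k1_fold = 15)
  expect_equal(as.numeric(saddle_node_k1(p)), 15, tolerance = 1e-6)
  sc <- scan_parameter(p, "K1", lo = 5, hi = 30, n_points = 64)
  expect_length(sc$fold_points, 1L)
  expect_equal(sc$fold_points, 15, tolerance = 1e-3)
  # inside the fold: bistable; outside: monostable
  p14 <- p; p14$K1 <- 14
  p16 <- p; p16$K1 <- 16
  expect_equal(n_stable(find_fixed_points(p14)), 2L)
  expect_equal(n_stable(find_fixed_points(p16)), 1L)
})

test_that("bistability map matches per-cell oracle and shows asymmetry", {
  p <- calibrate_cd3_for_k1_fold(k1_fold = 15)
  bm <- bistability_map(p, k1_range = c(2, 30), k2_range = c(0.05, 30),
                        n_k1 = 9, n_k2 = 9)
  # every cell equals an independent fixed-point computation
  for (i in c(1, 5, 9)) {
    for (j in c(1, 5, 9)) {
      q <- p; q$K1 <- bm$k1_grid[i]; q$K2 <- bm$k2_grid[j]
      expect_equal(bm$state_count[i, j], n_stable(find_fixed_points(q)))
    }
  }
  # with production off only the zero state exists anywhere
  p0 <- p; p0$c <- 1e-9
  bm0 <- bistability_map(p0, k1_range = c(2, 30), k2_range = c(0.05, 30),
                         n_k1 = 5, n_k2 = 5)
  expect_true(all(bm0$state_count == 1L))
  # asymmetry: far enough beyond the K1 fold there is a K1 row along which
  # K2 variation never induces bistability (while K1 variation always can)
  p_row <- p; p_row$K1 <- 25
  k2s <- exp(seq(log(0.05), log(30), length.out = 12))
  counts_row <- vapply(k2s, function(k2) {
    q <- p_row; q$K2 <- k2
    n_stable(find_fixed_points(q))
  }, 0L)
  expect_true(all(counts_row == 1L))
  # while K1 variation at the middle K2 does produce both regimes
  expect_true(any(bm$state_count >= 2) && any(bm$state_count == 1))
})

test_that("refining the scan grid preserves stable-state counts", {
  p <- endo_core()
  coarse <- scan_parameter(p, "gamma", lo = 0.02, hi = 2, n_points = 17)
  fine <- scan_parameter(p, "gamma", lo = 0.02, hi = 2, n_points = 33)
  # the coarse grid is a subset of the fine grid (log-spaced, 2x+1 points)
  idx <- seq(1, 33, by = 2)
  expect_equal(fine$param_values[idx], coarse$param_values, tolerance = 1e-12)
  c_coarse <- vapply(coarse$branches, n_stable, 0L)
  c_fine <- vapply(fine$branches[idx], n_stable, 0L)
  expect_identical(c_coarse, c_fine)
})

test_that("diagrams and maps export as stable plain text", {
  p <- endo_core()
  sc <- scan_parameter(p, "gamma", lo = 0.05, hi = 1, n_points = 8)
  f1 <- tempfile(fileext = ".tsv")
  write_bifurcation_tsv(sc, f1)
  df <- utils::read.delim(f1)
  expect_named(df, c("param_value", "tgfb1", "thbs1", "fmod", "stability"))
  f2 <- tempfile(fileext = ".json")
  write_folds_json(sc, f2)
  j <- jsonlite::read_json(f2)
  expect_identical(j$param_name, "gamma")
  bm <- bistability_map(p, n_k1 = 3, n_k2 = 3)
  f3 <- tempfile(fileext = ".tsv")
  write_bistability_tsv(bm, f3)
  expect_named(utils::read.delim(f3), c("k1", "k2", "stable_count"))
})
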