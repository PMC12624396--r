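# Trajectory PCA, correlations, t-tests and regressions.

make_samples <- function(mat, times, n_rep) {
  # mat: list variable -> function(time, replicate) value
  grid <- expand.grid(time_s = times, replicate = seq_len(n_rep))
  dplyr::bind_rows(lapply(names(mat), function(v) {
    tibble::tibble(
      time_s = grid$time_s, replicate = grid$replicate, variable = v,
      value = mapply(mat[[v]], grid$time_s, grid$replicate)
    )
  }))
}

test_that("duplicated variables get identical loadings", {
  p <- random_panel(1, times = c(0, 15, 120, 600, 1800))
  dup <- p[p$metabolite == "DHAP", ]
  dup$metabolite <- "DHAP"
  # duplicate DHAP under a second name by swapping an unused metabolite
  twin <- p
  twin$amount_nmol_gFW[twin$metabolite == "shikimate"] <-
    twin$amount_nmol_gFW[twin$metabolite == "DHAP"]
  pca <- pca_trajectory(as_metabolite_panel(twin))
  l <- pca$loadings
  expect_equal(unlist(l[l$variable == "shikimate", -1]),
               unlist(l[l$variable == "DHAP", -1]), tolerance = 1e-9)
})

test_that("collinear trajectories put all variance on the first component", {
  base <- tibble::tibble(
    transition = "ML_to_LL",
    time_s = rep(c(0, 10, 100, 1000), each = 3),
    replicate = 1,
    metabolite = rep(c("a", "b", "c"), 4)
  )
  base$amount_nmol_gFW <- rep(c(1, 2, 3), 4) * rep(c(1, 2, 3, 4), each = 3)
  pca <- pca_trajectory(as_metabolite_panel(base))
  expect_equal(pca$variance_explained[1], 1, tolerance = 1e-9)
})

test_that("scores times loadings reconstructs the scaled data", {
  p <- random_panel(2, times = c(0, 5, 30, 300, 1800))
  pca <- pca_trajectory(p)
  scores <- as.matrix(pca$scores[, -1])
  loadings <- as.matrix(pca$loadings[, -1])
  recon <- scores %*% t(loadings)
  scaled <- pca$scaled
  attributes(scaled) <- attributes(scaled)["dim"]
  expect_equal(max(abs(recon - scaled)), 0, tolerance = 1e-8)
})

test_that("the largest loading of every component is positive", {
  pca <- pca_trajectory(random_panel(5, times = c(0, 10, 60, 600)))
  l <- as.matrix(pca$loadings[, -1])
  for (j in seq_len(ncol(l))) {
    expect_gt(l[which.max(abs(l[, j])), j], 0)
  }
})

test_that("perfectly dependent variables correlate at +-1", {
  times <- c(5, 10, 30, 60, 120)
  s <- make_samples(list(
    x = function(t, r) t + r,
    y = function(t, r) 2 * (t + r) + 1,
    z = function(t, r) -(t + r)
  ), times, 3)
  res <- correlate_with_an(s, an = NULL)
  expect_equal(res$r["x", "y"], 1, tolerance = 1e-12)
  expect_equal(res$r["x", "z"], -1, tolerance = 1e-12)
  expect_lt(res$p["x", "y"], 1e-10)
})

test_that("time zero is excluded from correlation samples", {
  s <- make_samples(list(
    x = function(t, r) if (t == 0) 1e6 else t + 0.01 * r,
    y = function(t, r) if (t == 0) -1e6 else t + 0.02 * r
  ), c(0, 5, 10, 30, 60), 3)
  res <- correlate_with_an(s, an = NULL, exclude_time_zero = TRUE)
  expect_equal(res$n, 12) # 4 post-transition times x 3 replicates
  expect_gt(res$r["x", "y"], 0.99)
})

test_that("constant variables are missing-flagged in correlations", {
  s <- make_samples(list(
    x = function(t, r) t + r,
    flat = function(t, r) 5
  ), c(5, 10, 30, 60), 3)
  res <- correlate_with_an(s, an = NULL)
  expect_true(is.na(res$r["x", "flat"]))
  expect_false(res$significant["x", "flat"])
})

test_that("independent normal pairs are rarely significant", {
  hits <- vapply(1:100, function(seed) {
    set.seed(seed)
    s <- tibble::tibble(
      time_s = rep(1:40, 2), replicate = 1,
      variable = rep(c("x", "y"), each = 40),
      value = rnorm(80)
    )
    res <- correlate_with_an(s, an = NULL, exclude_time_zero = FALSE)
    res$p["x", "y"] < 0.05
  }, logical(1))
  expect_lt(mean(hits), 0.10)
})

test_that("correlation and regression p-values match textbook formulas", {
  # 5-point fixture, brute-force oracle from first principles
  x <- c(1.2, 3.4, 2.2, 5.1, 4.0)
  y <- c(2.0, 3.9, 2.1, 6.2, 3.7)
  n <- 5
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
  p_hand <- 2 * pt(-abs(t_hand), df = n - 2)

  s <- tibble::tibble(
    time_s = 1:5, replicate = 1,
    variable = "y", value = y
  )
  an <- tibble::tibble(time_s = 1:5, An = x)
  res <- correlate_with_an(
    dplyr::bind_rows(s, tibble::tibble(time_s = 1:5, replicate = 1,
                                       variable = "x2", value = x)),
    an = an, exclude_time_zero = FALSE
  )
  expect_equal(res$r["y", "An"], r_hand, tolerance = 1e-12)
  expect_equal(res$p["y", "An"], p_hand, tolerance = 1e-10)

  reg <- regress_vs_an(s, "y", an, exclude_time_zero = FALSE)
  expect_equal(reg$p, p_hand, tolerance = 1e-10)
  expect_equal(reg$r2, r_hand^2, tolerance = 1e-12)
})

test_that("welch tests against time zero behave at the extremes", {
  p <- null_panel(1, n_met = 2, times = c(0, 10), n_rep = 4)
  # identical groups: copy time 0 into time 10
  q <- p
  q$amount_nmol_gFW[q$time_s == 10] <- q$amount_nmol_gFW[q$time_s == 0]
  res <- segment_tests(q)
  expect_equal(res$p, rep(1, nrow(res)), tolerance = 1e-12)

  shifted <- p
  sel <- shifted$time_s == 10
  shifted$amount_nmol_gFW[sel] <- shifted$amount_nmol_gFW[sel] + 100 # 10 sd
  res2 <- segment_tests(shifted)
  expect_true(all(res2$p < 0.001))
  expect_true(all(res2$stars == "***"))
})

test_that("groups with a single replicate are missing-flagged", {
  p <- null_panel(2, n_met = 1, times = c(0, 10), n_rep = 2)
  p <- p[!(p$time_s == 10 & p$replicate == 2), ]
  res <- segment_tests(as_metabolite_panel(p))
  expect_true(is.na(res$p))
})

test_that("segment endpoint tests are emitted per phase", {
  p <- null_panel(3, n_met = 2, times = panel_times(), n_rep = 4)
  seg <- phase_segmentation("ML_to_LL", 1800)
  res <- segment_tests(p, seg)
  expect_setequal(
    unique(res$comparison),
    c("vs_time_zero", "segment_0_15", "segment_15_120", "segment_120_1800")
  )
})

test_that("benjamini-hochberg adjustment is available but off by default", {
  p <- null_panel(4, n_met = 5, times = c(0, 10, 60), n_rep = 4)
  raw <- segment_tests(p)
  adj <- segment_tests(p, p_adjust = "BH")
  expect_true(all(adj$p >= raw$p - 1e-12))
})

test_that("paired recovery test recovers an exact shift and its significance", {
  base <- noiseless_ml_ll()
  shift_by <- function(tr, c) {
    out <- tibble::as_tibble(tr)
    out$An[out$time_s >= 1791] <- out$An[out$time_s >= 1791] + c
    as_gas_exchange_trace(out, basis = trace_basis(tr))
  }
  traces <- lapply(c(0.4, 0.4, 0.4, 0.4, 0.4), function(c) shift_by(base, c))
  res <- paired_recovery_test(traces)
  base_diff <- mean(base$An[base$time_s >= 1791]) -
    mean(base$An[base$time_s >= 250 & base$time_s <= 259])
  expect_equal(res$mean_diff, base_diff + 0.4, tolerance = 1e-9)

  # zero difference: compare a window with itself
  same <- paired_recovery_test(lapply(1:4, function(i) base),
                               window_a = c(100, 109), window_b = c(100, 109))
  expect_equal(same$p, 1)

  # replicate-level offsets plus noise: the configured recovery is detected
  set.seed(21)
  reps <- lapply(1:5, function(i) {
    tr <- generate_an_trace(ml_ll_scenario(seed = 100 + i), duration = 1800)
    tr$An <- tr$An + rnorm(1, 0, 2) # replicate offset
    tr
  })
  power <- paired_recovery_test(reps)
  expect_lt(power$p, 0.01)
  expect_gt(power$mean_diff, 0)
})

test_that("regressions report slope sign, r2 and sub-range reversals", {
  an <- tibble::tibble(time_s = 1:10, An = 1:10)
  s <- tibble::tibble(
    time_s = 1:10, replicate = 1, variable = "v",
    value = 2 * (1:10) + 1
  )
  res <- regress_vs_an(s, "v", an, exclude_time_zero = FALSE)
  expect_identical(res$slope_sign, "positive")
  expect_equal(res$r2, 1, tolerance = 1e-12)

  # piecewise series: steep rise to t = 5, then a shallow decline, so the
  # full-range slope is positive while the late sub-range slope is negative
  piece <- tibble::tibble(
    time_s = 1:10, replicate = 1, variable = "w",
    value = c(1:5 * 2, 10 - (1:5) * 0.5)
  )
  full <- regress_vs_an(piece, "w", an, exclude_time_zero = FALSE)
  late <- regress_vs_an(piece, "w", an, time_range = c(6, 10),
                        exclude_time_zero = FALSE)
  expect_identical(full$slope_sign, "positive")
  expect_identical(late$slope_sign, "negative")

  flat_an <- tibble::tibble(time_s = 1:10, An = 5)
  expect_error(regress_vs_an(s, "v", flat_an, exclude_time_zero = FALSE),
               "constant")
})
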