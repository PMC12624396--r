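# Kinetic fits, trough detection, carbon budgets and equivalences.

test_that("decay fit recovers noiseless generator parameters exactly", {
  tr <- noiseless_ml_ll(duration = 300, t_half_fast = 11,
                        trough_depth_frac = 0)
  fit <- fit_decay(tr, c(0, 120))
  expect_equal(fit$t_half, 11, tolerance = 1e-6)
  expect_equal(fit$t_lag, 4, tolerance = 1e-6)
  expect_equal(fit$A0, 135, tolerance = 1e-6)
  expect_equal(fit$Ainf, 53, tolerance = 1e-6)
})

test_that("decay fit is invariant to a uniform time shift when lag is free", {
  tr <- noiseless_ml_ll(duration = 200, t_half_fast = 8, trough_depth_frac = 0)
  shifted <- as_gas_exchange_trace(
    tibble::tibble(time_s = tr$time_s + 30, An = tr$An),
    basis = trace_basis(tr)
  )
  f1 <- fit_decay(tr, c(0, 150))
  f2 <- fit_decay(shifted, c(30, 180))
  expect_equal(f2$t_half, f1$t_half, tolerance = 1e-6)
  expect_equal(f2$t_lag - 30, f1$t_lag, tolerance = 1e-5)
})

test_that("constant traces are rejected as having no decay", {
  flat <- as_gas_exchange_trace(
    tibble::tibble(time_s = 0:60, An = 10), basis = "area"
  )
  expect_error(fit_decay(flat), "no decay")
})

test_that("rise decomposition recovers the configured phase fractions", {
  tr <- noiseless_ll_ml()
  fit <- decompose_rise(tr)
  expect_equal(fit$fractions, c(0.49, 0.00, 0.31, 0.20), tolerance = 0.02)
  expect_equal(fit$Ainf - fit$A0, 135 - 53, tolerance = 0.5)
})

test_that("a single-exponential rise yields one dominant component", {
  tr <- as_gas_exchange_trace(
    tibble::tibble(time_s = 0:600,
                   An = 10 + 15 * (1 - 2^(-(0:600) / 20))),
    basis = "area"
  )
  fit <- decompose_rise(tr)
  expect_gt(max(fit$fractions), 0.97)
})

test_that("sample order does not change the decomposition", {
  tr <- noiseless_ll_ml(duration = 600)
  perm <- sample(nrow(tr))
  shuffled <- tibble::as_tibble(tr)[perm, ]
  # the constructor enforces sorted time, so build by hand and sort inside
  f1 <- decompose_rise(tr)
  f2 <- decompose_rise(as_gas_exchange_trace(
    shuffled[order(shuffled$time_s), ], basis = trace_basis(tr)
  ))
  expect_equal(f1$fractions, f2$fractions, tolerance = 1e-9)
})

test_that("the trough detector finds the configured minimum", {
  tr <- noiseless_ml_ll()
  ref <- estimate_steady_state(tr, c(1740, 1800))
  trough <- detect_trough(tr, ref, c(60, 700))
  expect_true(trough$present)
  expect_equal(trough$t_trough, 250, tolerance = 10)
  expect_equal(trough$depth_frac, 0.06, tolerance = 0.05)
})

test_that("monotone traces yield a trough-absent result", {
  tr <- noiseless_ml_ll(duration = 300, trough_depth_frac = 0)
  res <- detect_trough(tr, 53, c(30, 300))
  expect_false(res$present)
  expect_true(is.na(res$t_trough))
})

test_that("a symmetric V locates its vertex", {
  y <- c(seq(20, 10, by = -0.1), seq(10.1, 20, by = 0.1))
  tr <- as_gas_exchange_trace(
    tibble::tibble(time_s = seq_along(y) - 1, An = y), basis = "area"
  )
  res <- detect_trough(tr, 20, c(10, 190), smooth_window = 5)
  expect_equal(res$t_trough, 100, tolerance = 2)
})

test_that("integrating a trace equal to its reference gives zero", {
  flat <- as_gas_exchange_trace(
    tibble::tibble(time_s = 0:100, An = 12), basis = "area"
  )
  out <- integrate_deviation(flat, 12, c(0, 100), delta_an = 5)
  expect_equal(out$integral, 0)
  expect_equal(out$equivalent_seconds, 0)
})

test_that("trapezoid matches the closed form for an exponential excess", {
  # excess (A0 - Ainf) e^{-kt} above the reference integrates to (A0-Ainf)/k
  k <- 0.05
  amp <- 9
  tr <- as_gas_exchange_trace(
    tibble::tibble(time_s = 0:400, An = 10 + amp * exp(-k * (0:400))),
    basis = "area"
  )
  out <- integrate_deviation(tr, 10, c(0, 400), delta_an = amp)
  expect_equal(out$integral, amp / k, tolerance = 0.005)
  expect_identical(out$sign, "gain")
})

test_that("budgets are additive over adjacent phases to machine precision", {
  tr <- noiseless_ml_ll()
  ref <- 53
  whole <- integrate_deviation(tr, ref, c(0, 1800), delta_an = 82)
  seg <- phase_segmentation("ML_to_LL", 1800)
  parts <- carbon_budget(tr, ref, seg, delta_an = 82)
  expect_equal(sum(parts$integral), whole$integral, tolerance = 1e-9)
  # equivalent_seconds = integral / delta exactly
  expect_identical(parts$equivalent_seconds, parts$integral / 82)
})

test_that("equivalent seconds do not depend on the rate basis", {
  tr <- noiseless_ml_ll()
  ar <- convert_basis(tr, to = "area")
  e_fw <- integrate_deviation(tr, 53, c(0, 120), delta_an = 82)
  e_ar <- integrate_deviation(ar, 53 / 5.5, c(0, 120), delta_an = 82 / 5.5)
  expect_equal(e_fw$equivalent_seconds, e_ar$equivalent_seconds,
               tolerance = 1e-9)
})

test_that("basis mismatch between trace and reference is rejected", {
  tr <- noiseless_ml_ll(duration = 200)
  ar <- convert_basis(tr, to = "area")
  ref_fw <- estimate_steady_state(tr, c(150, 200))
  expect_error(integrate_deviation(ar, ref_fw, c(0, 100), 82), "basis")
  expect_error(detect_trough(ar, ref_fw, c(50, 150)), "basis")
})

test_that("pool-time equivalents reproduce the printed arithmetic", {
  expect_equal(pool_time_equivalent(4760, 53), 89.8, tolerance = 0.001)
  expect_equal(pool_time_equivalent(4760, 135 - 53), 58.0, tolerance = 0.001)
  expect_equal(pool_time_equivalent(0, 7), 0)
  expect_error(pool_time_equivalent(100, 0), "> 0")
})

test_that("the energy budget is linear in its stoichiometry", {
  eb <- energy_budget(dhap_decline = 108, excess_co2 = 30)
  expect_equal(eb$nadph_supplied, 108)
  expect_equal(eb$atp_supplied, 108)
  expect_equal(eb$nadph_required, 60)
  expect_equal(eb$atp_required, 90)
  expect_equal(eb$feasibility_ratio[["NADPH"]], 108 / 60)

  none <- energy_budget(108, 0)
  expect_true(all(is.na(none$feasibility_ratio)))

  doubled <- energy_budget(108, 30, list(
    nadph_per_triose = 1, atp_per_triose = 1,
    nadph_per_co2 = 4, atp_per_co2 = 6
  ))
  expect_equal(doubled$nadph_required, 2 * eb$nadph_required)
  expect_equal(doubled$atp_required, 2 * eb$atp_required)
  expect_error(energy_budget(-1, 0), ">=")
})

test_that("phase segmentations are contiguous and cover the duration", {
  for (d in c("ML_to_LL", "LL_to_ML")) {
    seg <- phase_segmentation(d, 1800)
    expect_equal(seg$t_start[-1], seg$t_end[-nrow(seg)])
    expect_equal(seg$t_start[1], 0)
    expect_equal(seg$t_end[nrow(seg)], 1800)
  }
})
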