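# Synthetic generator: kinetic anchors, forward chamber model, panels.

test_that("assimilation is constant before the lag and decays to the target", {
  tr <- noiseless_ml_ll(duration = 300)
  expect_true(all(tr$An[tr$time_s < 4] == 135))
  expect_lt(abs(tr$An[tr$time_s == 300] - 53), 0.06 * 53)
})

test_that("half of the decay amplitude is reached one half-life after the lag", {
  # trough disabled so the curve is the pure lagged exponential
  tr <- noiseless_ml_ll(duration = 60, t_half_fast = 11, trough_depth_frac = 0)
  expect_equal(tr$An[tr$time_s == 4 + 11], 53 + 0.5 * (135 - 53),
               tolerance = 1e-12)
})

test_that("default decay calibration reproduces the percent-of-initial anchors", {
  tr <- noiseless_ml_ll(duration = 60)
  expect_equal(tr$An[tr$time_s == 15] / 135, 0.44, tolerance = 0.01)
  expect_equal(tr$An[tr$time_s == 10] / 135, 0.53, tolerance = 0.03)
  # the classic summary: A_n passes half its initial value ~11 s after the switch
  expect_equal(time_to_fraction_of_initial(tr, 0.5), 11, tolerance = 0.05)
})

test_that("trough of the default decay sits at the configured time and depth", {
  tr <- noiseless_ml_ll()
  expect_equal(tr$time_s[which.min(tr$An)], 250)
  expect_equal(min(tr$An), 53 * (1 - 0.06), tolerance = 1e-3)
})

test_that("rise curve honours lag, fractions and saturation", {
  tr <- noiseless_ll_ml(duration = 3000)
  expect_true(all(tr$An[tr$time_s < 5] == 53))
  expect_lt(abs(tr$An[tr$time_s == 3000] - 135), 0.01 * 135)
  # component half-lives bracket the plateau: by 15 s roughly the first
  # component's share of the rise is complete
  frac_15 <- (tr$An[tr$time_s == 15] - 53) / (135 - 53)
  expect_gt(frac_15, 0.35)
  expect_lt(frac_15, 0.60)
})

test_that("scenario invariants are enforced", {
  expect_error(ml_ll_scenario(A_initial = 53, A_final = 53), "differ")
  expect_error(ml_ll_scenario(t_half_fast = NaN), "finite")
  expect_error(ml_ll_scenario(trough_depth_frac = 0.6), "<=")
  expect_error(ll_ml_scenario(phase_fractions = c(0.5, 0.2, 0.2, 0.2)),
               "sum to 1")
  expect_error(ll_ml_scenario(phase_fractions = c(-0.1, 0.5, 0.4, 0.2)),
               ">= 0")
  expect_error(generate_an_trace(ml_ll_scenario(), duration = 2), "duration")
})

test_that("same seed reproduces a noisy trace bit for bit", {
  a <- generate_an_trace(ml_ll_scenario(seed = 42), duration = 120)
  b <- generate_an_trace(ml_ll_scenario(seed = 42), duration = 120)
  expect_identical(a$An, b$An)
  c <- generate_an_trace(ml_ll_scenario(seed = 43), duration = 120)
  expect_false(identical(a$An, c$An))
})

test_that("chamber model reaches the steady-state drawdown for constant A", {
  flat <- as_gas_exchange_trace(
    tibble::tibble(time_s = 0:200, An = 25), basis = "area"
  )
  ch <- chamber_config()
  raw <- generate_raw_chamber_signals(flat, ch)
  expect_equal(
    tail(raw$c_sample, 1),
    ch$c_reference - 25 * ch$leaf_area / (ch$flow * 1e-6),
    tolerance = 1e-9
  )
  # A == 0 -> sample converges to reference
  zero <- as_gas_exchange_trace(
    tibble::tibble(time_s = 0:200, An = c(10, rep(0, 200))), basis = "area"
  )
  raw0 <- generate_raw_chamber_signals(zero, ch)
  expect_equal(tail(raw0$c_sample, 1), ch$c_reference, tolerance = 1e-6)
})

test_that("a step in A relaxes the sample cell with time constant V/u", {
  ch <- chamber_config()
  tau <- ch$volume / (ch$flow * 1e-6)
  step <- as_gas_exchange_trace(
    tibble::tibble(time_s = 0:120, An = c(rep(25, 50), rep(10, 71))),
    basis = "area"
  )
  raw <- generate_raw_chamber_signals(step, ch)
  # closed form: c(t) = c_eq + (c0 - c_eq) exp(-(t - t0)/tau) after the step
  u <- ch$flow * 1e-6
  c_hi <- ch$c_reference - 25 * ch$leaf_area / u
  c_lo <- ch$c_reference - 10 * ch$leaf_area / u
  t0 <- 49 # last instant at the high rate
  after <- raw$time_s > t0
  expected <- c_lo + (c_hi - c_lo) * exp(-(raw$time_s[after] - t0) / tau)
  expect_equal(raw$c_sample[after], expected, tolerance = 1e-9)
})

test_that("chamber model warns when sampling is slower than V/u", {
  flat <- as_gas_exchange_trace(
    tibble::tibble(time_s = seq(0, 200, 10), An = 25), basis = "area"
  )
  expect_warning(
    generate_raw_chamber_signals(flat, chamber_config(sampling_interval = 10)),
    "ill-conditioned"
  )
  expect_error(
    generate_raw_chamber_signals(convert_basis(flat, to = "fresh_weight"),
                                 chamber_config()),
    "area basis"
  )
})

test_that("zero-cv panels equal the template means, seeds reproduce exactly", {
  tmpl <- default_metabolite_templates("ML_to_LL")
  tmpl$cv <- 0
  p <- generate_metabolite_panel(tmpl, n_replicates = 3, seed = 5)
  by_rep <- tidyr::pivot_wider(p, names_from = "replicate",
                               values_from = "amount_nmol_gFW")
  expect_equal(by_rep$`1`, by_rep$`2`)
  expect_equal(by_rep$`1`, by_rep$`3`)

  tmpl2 <- default_metabolite_templates("ML_to_LL")
  a <- generate_metabolite_panel(tmpl2, n_replicates = 4, seed = 7)
  b <- generate_metabolite_panel(tmpl2, n_replicates = 4, seed = 7)
  expect_identical(a, b)
})

test_that("lognormal scatter has the configured mean and cv", {
  tmpl <- metabolite_template("DHAP", baseline = 200, target = 200, cv = 0.25)
  p <- generate_metabolite_panel(
    tmpl, times = c(0, 10), n_replicates = 4000, seed = 11,
    transition = "ML_to_LL"
  )
  x <- p$amount_nmol_gFW[p$time_s == 0]
  expect_equal(mean(x), 200, tolerance = 0.02)
  expect_equal(sd(x) / mean(x), 0.25, tolerance = 0.05)
})

test_that("default templates reproduce the DHAP drop and the summed pool rise", {
  st <- stoichiometry_table()
  tm <- default_metabolite_templates("ML_to_LL")
  tm$cv <- 0
  p <- generate_metabolite_panel(tm, n_replicates = 2, seed = 1,
                                 transition = "ML_to_LL", stoich = st)
  dhap <- subset(p, metabolite == "DHAP")
  drop <- mean(dhap$amount_nmol_gFW[dhap$time_s == 0]) -
    mean(dhap$amount_nmol_gFW[dhap$time_s == 15])
  expect_equal(drop, 108, tolerance = 0.02)

  tl <- default_metabolite_templates("LL_to_ML")
  tl$cv <- 0
  pl <- generate_metabolite_panel(tl, n_replicates = 2, seed = 1,
                                  transition = "LL_to_ML", stoich = st)
  pool <- sum_pool(
    pl, c("3PGA", "DHAP", "FBP", "F6P", "SBP", "S7P", "R5P", "Ru5P+Xu5P",
          "RuBP", "PEP", "pyruvate", "alanine", "aspartate"),
    "carbon", st
  )
  pool$trait <- "C_total"
  expect_equal(pool_delta(pool, 0, 1800)$delta, 7000, tolerance = 0.02)
})

test_that("panel generation validates names, times and replication", {
  tmpl <- metabolite_template("not-a-metabolite", 10, 10)
  expect_error(generate_metabolite_panel(tmpl), "unknown metabolite")
  good <- metabolite_template("DHAP", 10, 10)
  expect_error(generate_metabolite_panel(good, times = c(5, 10)), "time 0")
  expect_error(generate_metabolite_panel(good, n_replicates = 1), ">= 2")
})
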