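# Synthetic gas-exchange and metabolite data with the kinetic and noise
# structure of sudden irradiance-transition experiments on maize.

#' Construct a gas-exchange trace object
#'
#' A thin tibble subclass holding time-resolved net assimilation (`An`),
#' stomatal conductance (`gs`) and internal CO2 (`Ci`) with a declared rate
#' basis. Time is in seconds relative to the switch; the row at `time_s = 0`
#' is the pre-transition reference.
#'
#' @param data Data frame with columns `time_s`, `An` and optionally `gs`,
#'   `Ci`.
#' @param basis `"fresh_weight"` (nmol CO2 g-1 FW s-1) or `"area"`
#'   (umol CO2 m-2 s-1).
#' @param replicate_id Optional replicate label.
#' @return A `gas_exchange_trace` tibble.
#' @export
as_gas_exchange_trace <- function(data, basis = c("fresh_weight", "area"),
                                  replicate_id = NA_character_) {
  basis <- match.arg(basis)
  if (!all(c("time_s", "An") %in% names(data))) {
    stop_c4("a gas-exchange trace needs `time_s` and `An` columns")
  }
  if (is.unsorted(data$time_s, strictly = TRUE)) {
    stop_c4("`time_s` must be strictly increasing")
  }
  if (any(!is.finite(data$An))) stop_c4("`An` must be finite everywhere")
  out <- tibble::as_tibble(data)
  if (!"gs" %in% names(out)) out$gs <- NA_real_
  if (!"Ci" %in% names(out)) out$Ci <- NA_real_
  attr(out, "basis") <- basis
  attr(out, "replicate_id") <- replicate_id
  class(out) <- c("gas_exchange_trace", class(out))
  out
}

#' @export
print.gas_exchange_trace <- function(x, ...) {
  cat(sprintf("<gas_exchange_trace> %d samples, %.4g-%.4g s, basis: %s\n",
              nrow(x), min(x$time_s), max(x$time_s), attr(x, "basis")))
  NextMethod()
}

#' Basis of a gas-exchange trace
#' @param trace A `gas_exchange_trace`.
#' @return `"fresh_weight"` or `"area"`.
#' @export
trace_basis <- function(trace) attr(trace, "basis") %||% "area"

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- noiseless mean curves -------------------------------------------------

# Difference-of-exponentials trough/recovery pulse, normalised to peak 1 at
# s = s_peak and decayed to `end_value` at s = s_end. When the requested end
# value is at or below the floor reachable by this family, the gamma-limit
# shape (tau_r = tau_f = s_peak) is used, which decays fastest.
trough_pulse <- function(s, s_peak, s_end, end_value) {
  gamma_shape <- function(s) ifelse(s <= 0, 0, (s / s_peak) * exp(1 - s / s_peak))
  w_end_floor <- gamma_shape(s_end)
  if (end_value <= w_end_floor * (1 + 1e-6)) {
    return(gamma_shape(s))
  }
  # peak-time constraint: given tau_r find tau_f < tau_r with peak at s_peak
  tau_f_for <- function(tau_r) {
    peak_of <- function(tau_f) {
      tau_r * tau_f / (tau_r - tau_f) * log(tau_r / tau_f) - s_peak
    }
    stats::uniroot(peak_of, c(s_peak * 1e-6, tau_r * (1 - 1e-9)),
                   tol = 1e-10)$root
  }
  w_at <- function(s, tau_r, tau_f) {
    raw <- function(z) ifelse(z <= 0, 0, exp(-z / tau_r) - exp(-z / tau_f))
    raw(s) / raw(s_peak)
  }
  h <- function(tau_r) w_at(s_end, tau_r, tau_f_for(tau_r)) - end_value
  upper <- s_end * 50
  tau_r <- stats::uniroot(h, c(s_peak * (1 + 1e-6), upper), tol = 1e-10)$root
  w_at(s, tau_r, tau_f_for(tau_r))
}

# Noiseless mean A_n(t) for a scenario.
an_mean_curve <- function(scenario, t) {
  s <- t - scenario$t_lag
  if (scenario$direction == "ML_to_LL") {
    base <- scenario$A_final +
      (scenario$A_initial - scenario$A_final) *
        ifelse(s < 0, 1, 2^(-s / scenario$t_half_fast))
    if (scenario$trough_depth_frac > 0) {
      depth <- scenario$trough_depth_frac * abs(scenario$A_final)
      recov <- scenario$recovery_frac_of_delta *
        abs(scenario$A_initial - scenario$A_final)
      end_value <- max(0, 1 - recov / depth)
      w <- trough_pulse(
        pmax(s, 0),
        s_peak = scenario$t_trough - scenario$t_lag,
        s_end = scenario$t_end_recovery - scenario$t_lag,
        end_value = end_value
      )
      base <- base - depth * ifelse(s < 0, 0, w)
    }
    base
  } else {
    rise <- vapply(pmax(s, 0), function(z) {
      sum(scenario$phase_fractions *
            (1 - 2^(-z / scenario$phase_time_constants)))
    }, numeric(1))
    scenario$A_initial +
      (scenario$A_final - scenario$A_initial) * ifelse(s < 0, 0, rise)
  }
}

# Phenomenological stomatal conductance and internal CO2 courses. gs follows
# a single first-order lag (the experiments report only that it responds more
# slowly than A_n); Ci combines a settling exponential with a transient pulse
# matching the reported overshoot/undershoot timing.
gs_ci_curves <- function(scenario, t) {
  s <- pmax(t - scenario$t_lag, 0)
  if (scenario$direction == "ML_to_LL") {
    gs <- 0.12 + (0.25 - 0.12) * exp(-s / 120)
    ci <- 120 + (162 - 120) * (1 - exp(-s / 200)) +
      225 * (s / 30) * exp(1 - s / 30)
  } else {
    gs <- 0.25 + (0.12 - 0.25) * exp(-s / 150)
    ci <- 162 + (120 - 162) * (1 - exp(-s / 150)) -
      96 * (s / 50) * exp(1 - s / 50)
  }
  list(gs = gs, Ci = pmax(ci, 1))
}

#' Generate a synthetic net-assimilation trace
#'
#' Realises the noiseless response encoded by a [transition_scenario()] on a
#' uniform time grid and adds Gaussian measurement noise. The moderate-to-low
#' light response is a lagged exponential decay towards the low-light steady
#' state minus a difference-of-exponentials trough/recovery pulse; the
#' low-to-moderate response is a lagged sum of four saturating components.
#' Stomatal conductance and internal CO2 are filled in with phenomenological
#' first-order courses.
#'
#' @param scenario A [transition_scenario()].
#' @param duration Trace length, s (must exceed the scenario lag).
#' @param dt Sampling interval, s.
#' @param replicate_id Optional replicate label stored on the trace.
#' @return A `gas_exchange_trace` covering `0, dt, ..., duration`.
#' @examples
#' tr <- generate_an_trace(ml_ll_scenario(noise_sd = 0), duration = 300)
#' head(tr)
#' @export
generate_an_trace <- function(scenario, duration = 1800, dt = 1,
                              replicate_id = NA_character_) {
  if (!inherits(scenario, "transition_scenario")) {
    stop_c4("`scenario` must be a transition_scenario")
  }
  check_number(duration, "duration", min = scenario$t_lag, strict_min = TRUE)
  check_number(dt, "dt", min = 0, strict_min = TRUE)
  t <- seq(0, duration, by = dt)
  an <- an_mean_curve(scenario, t)
  aux <- gs_ci_curves(scenario, t)
  if (scenario$noise_sd > 0) {
    an <- with_seed(scenario$seed, an + rnorm(length(an), 0, scenario$noise_sd))
  }
  as_gas_exchange_trace(
    tibble::tibble(time_s = t, An = an, gs = aux$gs, Ci = aux$Ci),
    basis = scenario$basis,
    replicate_id = replicate_id
  )
}

# ---- forward chamber model -------------------------------------------------

#' Simulate raw analyzer signals for a known assimilation trace
#'
#' Forward model of an open gas-exchange chamber: the sample-cell CO2 mole
#' fraction obeys the first-order mass balance
#' \deqn{V \, dc_s/dt = u (c_r - c_s) - A S}
#' with molar flow \eqn{u}, chamber air content \eqn{V} (mol) and leaf area
#' \eqn{S}. The ODE is advanced with the exact exponential update over each
#' sampling interval (A held constant within a step), so at steady state
#' \eqn{c_s = c_r - A S / u}. Water channels are emitted as equal constants
#' (no transpiration dilution), and the true `gs`/`Ci` courses are carried
#' along for pass-through.
#'
#' @param true_trace A `gas_exchange_trace` on the area basis (umol m-2 s-1).
#' @param chamber A [chamber_config()].
#' @return A `raw_irga_series` tibble with columns `time_s`, `c_reference`,
#'   `c_sample`, `w_reference`, `w_sample` plus pass-through `gs`, `Ci`, and
#'   chamber metadata in attributes.
#' @export
generate_raw_chamber_signals <- function(true_trace, chamber) {
  if (!inherits(chamber, "chamber_config")) {
    stop_c4("`chamber` must be a chamber_config")
  }
  if (trace_basis(true_trace) != "area") {
    stop_c4("the forward chamber model needs a trace on the area basis; ",
            "use convert_basis() first")
  }
  u <- chamber$flow * 1e-6 # umol s-1 -> mol s-1
  V <- chamber$volume
  S <- chamber$leaf_area
  dt <- chamber$sampling_interval
  tau <- V / u
  if (dt >= tau) {
    warning(sprintf(
      "sampling interval (%.3g s) is not shorter than the chamber time constant V/u (%.3g s); the dynamic correction will be ill-conditioned",
      dt, tau
    ), call. = FALSE)
  }
  t <- seq(min(true_trace$time_s), max(true_trace$time_s), by = dt)
  A <- stats::approx(true_trace$time_s, true_trace$An, xout = t)$y
  c_r <- chamber$c_reference
  n <- length(t)
  c_s <- numeric(n)
  c_s[1] <- c_r - A[1] * S / u
  decay <- exp(-dt / tau)
  for (i in seq_len(n - 1L)) {
    c_eq <- c_r - A[i + 1L] * S / u
    c_s[i + 1L] <- c_eq + (c_s[i] - c_eq) * decay
  }
  out <- tibble::tibble(
    time_s = t,
    c_reference = c_r,
    c_sample = c_s,
    w_reference = 20,
    w_sample = 20,
    gs = if (sum(is.finite(true_trace$gs)) >= 2) {
      stats::approx(true_trace$time_s, true_trace$gs, xout = t)$y
    } else NA_real_,
    Ci = if (sum(is.finite(true_trace$Ci)) >= 2) {
      stats::approx(true_trace$time_s, true_trace$Ci, xout = t)$y
    } else NA_real_
  )
  attr(out, "flow") <- chamber$flow
  attr(out, "leaf_area") <- chamber$leaf_area
  attr(out, "chamber_volume") <- chamber$volume
  attr(out, "sampling_interval") <- dt
  class(out) <- c("raw_irga_series", class(out))
  out
}

# ---- metabolite panel ------------------------------------------------------

#' Construct a metabolite time-course template
#'
#' Phenomenological description of one metabolite's mean course across a
#' transition: a first-order relaxation from `baseline` towards `target` plus
#' a transient pulse of amplitude `transient_amplitude` peaking at
#' `transient_peak_time`, with multiplicative-lognormal replicate scatter of
#' coefficient of variation `cv`.
#'
#' @param name Metabolite identifier (must match the stoichiometry table).
#' @param baseline,target Steady-state amounts at the initial and final
#'   irradiance, nmol g-1 FW (both non-negative).
#' @param transient_amplitude Pulse amplitude, nmol g-1 FW (may be negative).
#' @param transient_peak_time Pulse peak time, s.
#' @param relax_time First-order relaxation time, s.
#' @param cv Replicate coefficient of variation in `[0, 1]`.
#' @return A one-row tibble of class `metabolite_template`.
#' @export
metabolite_template <- function(name, baseline, target,
                                transient_amplitude = 0,
                                transient_peak_time = 60,
                                relax_time = 120,
                                cv = 0.2) {
  check_number(baseline, "baseline", min = 0)
  check_number(target, "target", min = 0)
  check_number(cv, "cv", min = 0, max = 1)
  check_number(relax_time, "relax_time", min = 0, strict_min = TRUE)
  check_number(transient_peak_time, "transient_peak_time", min = 0,
               strict_min = TRUE)
  out <- tibble::tibble(
    metabolite = as.character(name), baseline = baseline, target = target,
    transient_amplitude = transient_amplitude,
    transient_peak_time = transient_peak_time,
    relax_time = relax_time, cv = cv
  )
  class(out) <- c("metabolite_template", class(out))
  out
}

# Mean amount at time t for one template row (vectorised over t).
template_mean <- function(tmpl, t) {
  m <- tmpl$target + (tmpl$baseline - tmpl$target) * exp(-t / tmpl$relax_time) +
    tmpl$transient_amplitude * (t / tmpl$transient_peak_time) *
      exp(1 - t / tmpl$transient_peak_time)
  pmax(m, 0)
}

#' Default metabolite templates for a transition
#'
#' Templates for the 36-metabolite panel used throughout the package,
#' calibrated to the reported dynamics: in the moderate-to-low transition DHAP
#' falls by ~108 nmol g-1 FW within 15 s; in the low-to-moderate transition
#' the summed carbon in the Calvin-Benson cycle, energy shuttle and CCM pools
#' rises by ~7000 nmol C g-1 FW over 1800 s. Everything else is
#' phenomenological (amounts and timings typical of maize leaves).
#'
#' @param direction `"ML_to_LL"` or `"LL_to_ML"`.
#' @return A tibble of template rows, one per metabolite.
#' @export
default_metabolite_templates <- function(direction = c("ML_to_LL", "LL_to_ML")) {
  direction <- match.arg(direction)
  # columns: metabolite, LL level, ML level, then per-direction transients
  # (amp, peak time) and relaxation time; cv last.
  spec <- list(
    #            name          LL     ML   amp.ml_ll tp.ml_ll rx.ml_ll amp.ll_ml tp.ll_ml rx.ll_ml  cv
    list("3PGA",          650,  1400,  -150, 200,  40,  -100,  10,  60, 0.20),
    list("DHAP",       132.34, 250.00,     0,  60,   6,     0,  60,  60, 0.20),
    list("FBP",            25,    35,     0, 100, 300,    25,  30,  80, 0.20),
    list("F6P",           150,   200,     0, 100, 120,     0,  60, 120, 0.20),
    list("SBP",            22,    28,     0, 100,  30,    10,  30,  80, 0.20),
    list("S7P",            75,   100,     0, 100,  60,     0,  60, 100, 0.20),
    list("R5P",            10,    15,     0, 100, 100,     0,  60,  60, 0.20),
    list("Ru5P+Xu5P",      15,    25,     0, 100, 100,     0,  60,  60, 0.20),
    list("RuBP",           55,    80,     0, 100, 400,    20,  60, 100, 0.20),
    list("ADPG",            6,    50,     0, 100,  60,    50,  20, 200, 0.25),
    list("UDPG",          120,   150,     0, 100, 300,   -30,  60, 250, 0.20),
    list("G6P",           300,   350,     0, 100, 300,   -80,  60, 200, 0.20),
    list("G1P",            20,    25,     0, 100, 300,     0,  60, 200, 0.20),
    list("PEP",           150,   400,   -40, 150, 150,   -60,   8, 150, 0.20),
    list("pyruvate",      300,   700,   -80, 250, 120,     0,  60, 300, 0.20),
    list("alanine",      2000,  2486,  -100, 250, 250,     0,  60, 400, 0.20),
    list("aspartate",    1500,  1550,   600, 900, 600,  -150, 120, 300, 0.20),
    list("malate",      25000, 25000,  -300, 300, 300,   500, 300, 300, 0.30),
    list("2PG",             4,     8,     0, 100,  10,     0,  60, 100, 0.25),
    list("glycolate",      15,    18,     0, 100, 100,     0,  60, 150, 0.25),
    list("glycine",       150,   300,     0, 100, 200,     0,  60, 300, 0.20),
    list("serine",        400,   450,     0, 100, 300,     0,  60, 300, 0.20),
    list("glycerate",      80,   120,     0, 100, 200,     0,  60, 200, 0.20),
    list("glutamate",    3500,  3400,     0, 100, 400,     0,  60, 400, 0.15),
    list("glutamine",     800,   820,     0, 100, 400,     0,  60, 400, 0.15),
    list("2OG",           110,   200,     0, 100, 400,     0,  60, 150, 0.20),
    list("fumarate",     2400,  1900,     0, 100, 500,     0,  60, 400, 0.25),
    list("citrate",      1500,  1450,     0, 100, 400,     0,  60, 400, 0.20),
    list("isocitrate",     60,    60,    -5, 120, 200,     5, 120, 200, 0.20),
    list("succinate",     300,   310,     0, 100, 300,     0,  60, 300, 0.20),
    list("sucrose",     12000, 13000,     0, 100, 700,     0,  60, 600, 0.15),
    list("glucose",      1500,  1550,     0, 100, 400,     0,  60, 400, 0.20),
    list("fructose",      900,   950,     0, 100, 400,     0,  60, 400, 0.20),
    list("raffinose",      50,    55,     0, 100, 500,     0,  60, 500, 0.25),
    list("maltose",        40,    42,     0, 100, 400,     0,  60, 400, 0.25),
    list("shikimate",      90,    90,     0, 100, 300,     0,  60, 300, 0.20)
  )
  rows <- lapply(spec, function(s) {
    if (direction == "ML_to_LL") {
      metabolite_template(
        name = s[[1]], baseline = s[[3]], target = s[[2]],
        transient_amplitude = s[[4]], transient_peak_time = s[[5]],
        relax_time = s[[6]], cv = s[[10]]
      )
    } else {
      metabolite_template(
        name = s[[1]], baseline = s[[2]], target = s[[3]],
        transient_amplitude = s[[7]], transient_peak_time = s[[8]],
        relax_time = s[[9]], cv = s[[10]]
      )
    }
  })
  dplyr::bind_rows(rows)
}

# DHAP in the ML_to_LL direction: baseline - mean(15 s) must be ~108
# nmol g-1 FW. With relax_time 6 s the drop by 15 s is
# (baseline - target) * (1 - exp(-15/6)); baseline/target above solve this.

#' Sampling times of the transition experiments
#'
#' The reference harvest grid: 0 (pre-switch) and 5, 10, 15, 30, 60, 120,
#' 300, 600, 1200, 1800 s after the switch.
#' @return Numeric vector of times, s.
#' @export
panel_times <- function() c(0, 5, 10, 15, 30, 60, 120, 300, 600, 1200, 1800)

#' Generate a replicated metabolite panel
#'
#' Draws replicate metabolite amounts around the template mean courses with
#' multiplicative-lognormal scatter: a replicate value is
#' \eqn{m \exp(\sigma Z - \sigma^2/2)} with \eqn{\sigma^2 = \log(1 + cv^2)},
#' so the expectation equals the template mean and the coefficient of
#' variation equals `cv`.
#'
#' @param templates Tibble of template rows (see
#'   [default_metabolite_templates()]).
#' @param times Sampling times, s; must include 0.
#' @param n_replicates Single integer or vector (one per time) of replicate
#'   counts; all must be >= 2.
#' @param seed Integer RNG seed.
#' @param transition Label stored in the panel (`"ML_to_LL"` or
#'   `"LL_to_ML"`).
#' @param stoich Stoichiometry table used to validate metabolite names.
#' @return A `metabolite_panel` tibble with columns `transition`, `time_s`,
#'   `replicate`, `metabolite`, `amount_nmol_gFW`.
#' @export
generate_metabolite_panel <- function(templates,
                                      times = panel_times(),
                                      n_replicates = 4L,
                                      seed = 1L,
                                      transition = c("ML_to_LL", "LL_to_ML"),
                                      stoich = stoichiometry_table()) {
  transition <- match.arg(transition)
  if (!0 %in% times) stop_c4("`times` must include the pre-switch time 0")
  if (length(n_replicates) == 1L) {
    n_replicates <- rep(as.integer(n_replicates), length(times))
  }
  if (length(n_replicates) != length(times)) {
    stop_c4("`n_replicates` must be length 1 or one entry per time point")
  }
  if (any(n_replicates < 2L)) stop_c4("each time point needs >= 2 replicates")
  unknown <- setdiff(templates$metabolite, stoich$metabolite)
  if (length(unknown)) {
    stop_c4("unknown metabolite(s) not in the stoichiometry table: ",
            paste(unknown, collapse = ", "))
  }
  grid <- tibble::tibble(time_s = times, n = n_replicates)
  panel <- with_seed(seed, {
    rows <- lapply(seq_len(nrow(templates)), function(i) {
      tmpl <- templates[i, ]
      m <- template_mean(tmpl, grid$time_s)
      sigma <- sqrt(log(1 + tmpl$cv^2))
      dplyr::bind_rows(lapply(seq_along(grid$time_s), function(j) {
        n <- grid$n[j]
        mult <- if (sigma > 0) exp(rnorm(n, 0, sigma) - sigma^2 / 2) else rep(1, n)
        tibble::tibble(
          transition = transition,
          time_s = grid$time_s[j],
          replicate = seq_len(n),
          metabolite = tmpl$metabolite,
          amount_nmol_gFW = m[j] * mult
        )
      }))
    })
    dplyr::bind_rows(rows)
  })
  panel <- dplyr::arrange(panel, .data$time_s, .data$replicate, .data$metabolite)
  as_metabolite_panel(panel)
}

#' Validate and class a metabolite panel
#'
#' @param data Data frame with columns `transition`, `time_s`, `replicate`,
#'   `metabolite`, `amount_nmol_gFW`.
#' @return A `metabolite_panel` tibble.
#' @export
as_metabolite_panel <- function(data) {
  need <- c("transition", "time_s", "replicate", "metabolite", "amount_nmol_gFW")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop_c4("panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(!is.na(data$amount_nmol_gFW) & data$amount_nmol_gFW < 0)
  if (length(bad)) {
    stop_c4(sprintf("negative amount at row %d (metabolite %s, t = %g s)",
                    bad[1], data$metabolite[bad[1]], data$time_s[bad[1]]))
  }
  out <- tibble::as_tibble(data)
  class(out) <- c("metabolite_panel", class(out))
  out
}
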