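#' Transition scenario for the synthetic assimilation generator
#'
#' A `transition_scenario` fixes every parameter of the noiseless net
#' assimilation (\eqn{A_n}) response to a step change in irradiance, plus the
#' replicate noise level and RNG seed. Two directions are supported:
#'
#' * `"ML_to_LL"` (moderate to low light): after a lag, \eqn{A_n} decays
#'   quasi-exponentially towards the low-light steady state, overshoots into a
#'   shallow trough and then partially recovers;
#' * `"LL_to_ML"`: after a lag, \eqn{A_n} rises as a sum of four saturating
#'   components whose amplitudes are fixed fractions of the overall rise.
#'
#' @param direction `"ML_to_LL"` or `"LL_to_ML"`.
#' @param A_initial,A_final Steady-state assimilation rates before and (as
#'   asymptote) after the switch, in the units of `basis`.
#' @param t_lag Delay (s) between the switch at `t = 0` and the first response.
#' @param t_half_fast Half-life (s) of the fast exponential component of the
#'   decay (`ML_to_LL` only).
#' @param trough_depth_frac Depth of the post-decay trough, as a fraction of
#'   `A_final` (`ML_to_LL` only); must lie in `[0, 0.5)`.
#' @param t_trough Time (s) of the trough minimum (`ML_to_LL` only).
#' @param recovery_frac_of_delta Rise from the trough to `t_end_recovery`,
#'   expressed as a fraction of `A_initial - A_final` (`ML_to_LL` only). Must
#'   not exceed the trough depth; the default recovers the full trough.
#' @param t_end_recovery Reference time (s) at which the recovery fraction is
#'   anchored; default 1800 s, the length of the observation window.
#' @param phase_fractions Four non-negative fractions summing to 1, the share
#'   of the overall rise carried by each saturating component
#'   (`LL_to_ML` only).
#' @param phase_time_constants Four half-lives (s), one per rise component.
#' @param noise_sd Additive Gaussian noise on the generated trace, in the
#'   units of `basis`.
#' @param basis `"fresh_weight"` (nmol CO2 g-1 FW s-1) or `"area"`
#'   (umol CO2 m-2 s-1).
#' @param seed Integer RNG seed used whenever the scenario is realised with
#'   noise.
#'
#' @return An object of class `transition_scenario`.
#' @seealso [ml_ll_scenario()], [ll_ml_scenario()], [generate_an_trace()]
#' @export
transition_scenario <- function(direction = c("ML_to_LL", "LL_to_ML"),
                                A_initial,
                                A_final,
                                t_lag = 0,
                                t_half_fast = NULL,
                                trough_depth_frac = 0,
                                t_trough = NULL,
                                recovery_frac_of_delta = NULL,
                                t_end_recovery = 1800,
                                phase_fractions = NULL,
                                phase_time_constants = NULL,
                                noise_sd = 0,
                                basis = c("fresh_weight", "area"),
                                seed = 1L) {
  direction <- match.arg(direction)
  basis <- match.arg(basis)
  check_number(A_initial, "A_initial")
  check_number(A_final, "A_final")
  if (A_initial == A_final) stop_c4("`A_initial` must differ from `A_final`")
  check_number(t_lag, "t_lag", min = 0)
  check_number(noise_sd, "noise_sd", min = 0)

  if (direction == "ML_to_LL") {
    check_number(t_half_fast, "t_half_fast", min = 0, strict_min = TRUE)
    check_number(trough_depth_frac, "trough_depth_frac", min = 0, max = 0.5 - 1e-12)
    if (trough_depth_frac > 0) {
      check_number(t_trough, "t_trough", min = t_lag, strict_min = TRUE)
      depth <- trough_depth_frac * abs(A_final)
      if (is.null(recovery_frac_of_delta)) {
        # full recovery of the trough by t_end_recovery
        recovery_frac_of_delta <- depth / abs(A_initial - A_final)
      }
      check_number(recovery_frac_of_delta, "recovery_frac_of_delta", min = 0)
      if (recovery_frac_of_delta * abs(A_initial - A_final) > depth + 1e-9) {
        stop_c4(
          "`recovery_frac_of_delta` implies a recovery larger than the trough ",
          "depth; reduce it or deepen `trough_depth_frac`"
        )
      }
    } else {
      t_trough <- NA_real_
      recovery_frac_of_delta <- 0
    }
  } else {
    if (is.null(phase_fractions) || is.null(phase_time_constants)) {
      stop_c4("LL_to_ML scenarios need `phase_fractions` and `phase_time_constants`")
    }
    if (length(phase_fractions) != 4L || any(!is.finite(phase_fractions))) {
      stop_c4("`phase_fractions` must be 4 finite numbers")
    }
    if (any(phase_fractions < 0)) stop_c4("`phase_fractions` must be >= 0")
    if (abs(sum(phase_fractions) - 1) > 1e-9) {
      stop_c4("`phase_fractions` must sum to 1 (within 1e-9)")
    }
    if (length(phase_time_constants) != 4L ||
        any(!is.finite(phase_time_constants)) ||
        any(phase_time_constants <= 0)) {
      stop_c4("`phase_time_constants` must be 4 positive numbers")
    }
  }

  structure(
    list(
      direction = direction,
      A_initial = A_initial,
      A_final = A_final,
      t_lag = t_lag,
      t_half_fast = t_half_fast,
      trough_depth_frac = trough_depth_frac,
      t_trough = t_trough,
      recovery_frac_of_delta = recovery_frac_of_delta,
      t_end_recovery = t_end_recovery,
      phase_fractions = phase_fractions,
      phase_time_constants = phase_time_constants,
      noise_sd = noise_sd,
      basis = basis,
      seed = as.integer(seed)
    ),
    class = "transition_scenario"
  )
}

#' @export
print.transition_scenario <- function(x, ...) {
  cat("<transition_scenario>", x$direction, "\n")
  cat(sprintf("  A: %.3g -> %.3g (%s basis), lag %.3g s\n",
              x$A_initial, x$A_final, x$basis, x$t_lag))
  if (x$direction == "ML_to_LL") {
    cat(sprintf("  decay half-life %.4g s; trough %.3g%% of A_final at %.4g s\n",
                x$t_half_fast, 100 * x$trough_depth_frac, x$t_trough))
  } else {
    cat(sprintf("  rise fractions %s; half-lives %s s\n",
                paste(signif(x$phase_fractions, 3), collapse = "/"),
                paste(signif(x$phase_time_constants, 3), collapse = "/")))
  }
  cat(sprintf("  noise sd %.3g, seed %d\n", x$noise_sd, x$seed))
  invisible(x)
}

# Half-life of the fast decay calibrated so that A_n at 15 s is 44% of the
# moderate-light rate (with lag 4 s, 135 -> 53 nmol g-1 FW s-1). Under this
# calibration A_n passes half of its initial value at ~11 s after the switch.
ml_ll_default_t_half <- function(A_initial = 135, A_final = 53,
                                 t_lag = 4, t_anchor = 15,
                                 frac_of_initial = 0.44) {
  r <- (frac_of_initial * A_initial - A_final) / (A_initial - A_final)
  -(t_anchor - t_lag) * log(2) / log(r)
}

#' Default moderate-to-low light scenario
#'
#' Steady states of 135 and 53 nmol CO2 g-1 FW s-1 (25 and 10 umol m-2 s-1 at
#' a specific leaf area of 0.0055 m2 g-1), a 4 s lag, a fast decay calibrated
#' so the rate at 15 s is 44% of the initial value (half of the initial value
#' is passed ~11 s after the switch), a trough 6% below the low-light steady
#' state at 250 s, and a slow recovery essentially complete by 1800 s.
#'
#' @param noise_sd Additive noise sd; the default is 2% of the steady-state
#'   difference.
#' @param seed RNG seed.
#' @param ... Overrides passed on to [transition_scenario()].
#' @return A `transition_scenario`.
#' @export
ml_ll_scenario <- function(noise_sd = 0.02 * (135 - 53), seed = 1L, ...) {
  args <- list(
    direction = "ML_to_LL",
    A_initial = 135,
    A_final = 53,
    t_lag = 4,
    t_half_fast = ml_ll_default_t_half(),
    trough_depth_frac = 0.06,
    t_trough = 250,
    noise_sd = noise_sd,
    basis = "fresh_weight",
    seed = seed
  )
  user <- list(...)
  args[names(user)] <- user
  do.call(transition_scenario, args)
}

#' Default low-to-moderate light scenario
#'
#' Steady states of 53 and 135 nmol CO2 g-1 FW s-1, a 5 s lag, and a rise made
#' of four saturating components carrying 49/0/31/20% of the overall increase:
#' a fast initial rise (complete by ~11-15 s), a silent component spanning the
#' plateau, a component saturating by ~90 s, and a slow final rise.
#'
#' @inheritParams ml_ll_scenario
#' @return A `transition_scenario`.
#' @export
ll_ml_scenario <- function(noise_sd = 0.02 * (135 - 53), seed = 1L, ...) {
  args <- list(
    direction = "LL_to_ML",
    A_initial = 53,
    A_final = 135,
    t_lag = 5,
    phase_fractions = c(0.49, 0.00, 0.31, 0.20),
    phase_time_constants = c(2, 6, 25, 400),
    noise_sd = noise_sd,
    basis = "fresh_weight",
    seed = seed
  )
  user <- list(...)
  args[names(user)] <- user
  do.call(transition_scenario, args)
}

#' Open gas-exchange chamber configuration
#'
#' Describes the chamber used by the forward signal simulator and the dynamic
#' correction: air volume (mol air equivalent), molar flow, leaf area, the
#' reference CO2 mole fraction and the logging interval.
#'
#' @param volume Chamber air content, mol air. The default corresponds to
#'   roughly 80 cm3 at 25 C and 1 atm.
#' @param flow Molar air flow, umol s-1 (instrument convention).
#' @param leaf_area Enclosed leaf area, m2.
#' @param c_reference CO2 mole fraction in the reference cell, umol mol-1.
#' @param sampling_interval Logging interval, s.
#' @return An object of class `chamber_config`.
#' @export
chamber_config <- function(volume = 3.3e-3,
                           flow = 600,
                           leaf_area = 6e-4,
                           c_reference = 400,
                           sampling_interval = 1) {
  check_number(volume, "volume", min = 0, strict_min = TRUE)
  check_number(flow, "flow", min = 0, strict_min = TRUE)
  check_number(leaf_area, "leaf_area", min = 0, strict_min = TRUE)
  check_number(c_reference, "c_reference", min = 0, strict_min = TRUE)
  check_number(sampling_interval, "sampling_interval", min = 0, strict_min = TRUE)
  structure(
    list(
      volume = volume, flow = flow, leaf_area = leaf_area,
      c_reference = c_reference, sampling_interval = sampling_interval
    ),
    class = "chamber_config"
  )
}

#' @export
print.chamber_config <- function(x, ...) {
  cat("<chamber_config>\n")
  cat(sprintf("  volume %.3g mol, flow %.3g umol s-1, leaf area %.3g m2\n",
              x$volume, x$flow, x$leaf_area))
  cat(sprintf("  reference CO2 %.4g umol mol-1, sampling %.3g s (tau = V/u = %.3g s)\n",
              x$c_reference, x$sampling_interval,
              x$volume / (x$flow * 1e-6)))
  invisible(x)
}
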