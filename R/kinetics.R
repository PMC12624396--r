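# Transition kinetics: lagged-exponential decay fits, four-component rise
# decomposition, trough detection, phase-integrated carbon budgets, pool-time
# equivalents and the triose-P energy budget.

new_kinetic_fit <- function(model, pars, rss, se = NULL, n = NA_integer_) {
  structure(
    c(list(model = model), pars, list(rss = rss, se = se, n = n)),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit>", x$model, "\n")
  if (x$model == "lagged_exponential_decay") {
    cat(sprintf("  A0 %.4g -> Ainf %.4g, lag %.4g s, t_half %.5g s\n",
                x$A0, x$Ainf, x$t_lag, x$t_half))
  } else {
    cat(sprintf("  A0 %.4g -> Ainf %.4g, lag %.4g s\n", x$A0, x$Ainf, x$t_lag))
    cat(sprintf("  amplitudes: %s (fractions %s)\n",
                paste(signif(x$amplitudes, 4), collapse = ", "),
                paste(signif(x$fractions, 3), collapse = "/")))
    cat(sprintf("  half-lives: %s s\n", paste(signif(x$tau, 4), collapse = ", ")))
  }
  cat(sprintf("  rss %.4g on %d samples\n", x$rss, x$n))
  invisible(x)
}

decay_basis <- function(t, lag, t_half) 2^(-pmax(t - lag, 0) / t_half)

#' Fit a lagged exponential decay
#'
#' Least-squares fit of
#' \deqn{A(t) = A_\infty + (A_0 - A_\infty) \, 2^{-(t - t_{lag})/t_{1/2}}}
#' (constant at \eqn{A_0} before the lag) to the decay part of a
#' moderate-to-low light trace. The fit uses variable projection (the two
#' amplitudes are solved linearly for each candidate lag/half-life) with five
#' deterministic half-life starts spanning 2-60 s, followed by a
#' Levenberg-Marquardt polish of all four parameters; ties are broken by
#' lowest residual then smallest half-life. Standard errors come from the
#' linearised covariance of the polished fit.
#'
#' @param trace A `gas_exchange_trace` (moderate-to-low shaped).
#' @param fit_window Length-2 numeric, s; the part of the trace to fit
#'   (default: the whole trace). Must contain >= 10 samples.
#' @return A `kinetic_fit` with elements `A0`, `Ainf`, `t_lag`, `t_half`,
#'   `rss`, `se`.
#' @export
fit_decay <- function(trace, fit_window = NULL) {
  df <- tibble::as_tibble(trace)[, c("time_s", "An")]
  df <- df[order(df$time_s), ]
  if (!is.null(fit_window)) {
    df <- df[df$time_s >= fit_window[1] & df$time_s <= fit_window[2], ]
  }
  t <- df$time_s
  y <- df$An
  if (length(y) < 10L) stop_c4("fit window must contain >= 10 samples")
  if (sd(y) < 1e-12 * max(1, abs(mean(y)))) {
    stop_c4("trace is constant over the fit window: no decay to fit")
  }

  rss_of <- function(par) {
    lag <- par[1]
    th <- exp(par[2])
    X <- cbind(1, decay_basis(t, lag, th))
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  lag0 <- min(t) + 0.05 * (max(t) - min(t))
  starts <- lapply(c(2, 5, 11, 30, 60), function(th) c(lag0, log(th)))
  best <- NULL
  for (s in starts) {
    opt <- optim(s, rss_of, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 2000))
    cand <- list(par = opt$par, value = opt$value)
    if (is.null(best) || cand$value < best$value - 1e-12 ||
        (abs(cand$value - best$value) <= 1e-12 &&
           exp(cand$par[2]) < exp(best$par[2]))) {
      best <- cand
    }
  }
  lag <- best$par[1]
  th <- exp(best$par[2])
  X <- cbind(1, decay_basis(t, lag, th))
  ab <- stats::lm.fit(X, y)$coefficients
  ainf <- ab[[1]]
  amp <- ab[[2]]

  # Levenberg-Marquardt polish of all four parameters
  polished <- tryCatch({
    fit <- minpack.lm::nlsLM(
      An ~ Ainf + amp * 2^(-pmax(time_s - lag, 0) / t_half),
      data = df,
      start = list(Ainf = ainf, amp = amp, lag = lag, t_half = th),
      lower = c(-Inf, -Inf, min(t), 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15)
    )
    cf <- coef(fit)
    se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) NULL)
    list(Ainf = cf[["Ainf"]], amp = cf[["amp"]], lag = cf[["lag"]],
         t_half = cf[["t_half"]], rss = sum(stats::residuals(fit)^2),
         se = se)
  }, error = function(e) NULL)
  if (!is.null(polished) && polished$rss <= best$value + 1e-12) {
    ainf <- polished$Ainf; amp <- polished$amp
    lag <- polished$lag; th <- polished$t_half
    rss <- polished$rss; se <- polished$se
  } else {
    rss <- best$value; se <- NULL
  }
  if (abs(amp) < 1e-10 * max(1, abs(ainf))) {
    stop_c4("no decay detected (amplitude ~ 0); best residual ", signif(rss, 4))
  }
  new_kinetic_fit(
    "lagged_exponential_decay",
    list(A0 = ainf + amp, Ainf = ainf, t_lag = lag, t_half = th),
    rss = rss, se = se, n = length(y)
  )
}

rise_basis <- function(t, lag, tau) {
  vapply(tau, function(tz) 1 - 2^(-pmax(t - lag, 0) / tz), numeric(length(t)))
}

#' Decompose a multiphasic rise into four saturating components
#'
#' Fits \deqn{A(t) = A_0 + \sum_{i=1}^{4} a_i (1 - 2^{-(t-t_{lag})/\tau_i})}
#' with non-negative amplitudes to a low-to-moderate light trace and reports
#' each component's amplitude as a fraction of the overall rise. Amplitudes
#' and the baseline are solved by non-negative least squares inside a
#' Nelder-Mead search over the lag and the four half-lives (variable
#' projection), from three deterministic start sets; components are reported
#' in order of increasing half-life.
#'
#' @param trace A `gas_exchange_trace` (low-to-moderate shaped).
#' @param fit_window Optional length-2 numeric, s.
#' @return A `kinetic_fit` with `A0`, `Ainf`, `t_lag`, `amplitudes`, `tau`,
#'   `fractions`, `rss`.
#' @export
decompose_rise <- function(trace, fit_window = NULL) {
  df <- tibble::as_tibble(trace)[, c("time_s", "An")]
  df <- df[order(df$time_s), ]
  if (!is.null(fit_window)) {
    df <- df[df$time_s >= fit_window[1] & df$time_s <= fit_window[2], ]
  }
  t <- df$time_s
  y <- df$An
  if (length(y) < 12L) stop_c4("fit window must contain >= 12 samples")
  if (sd(y) < 1e-12 * max(1, abs(mean(y)))) {
    stop_c4("trace is constant over the fit window: no rise to fit")
  }

  solve_amps <- function(lag, tau) {
    # amplitudes are sign-constrained, the baseline is free: alternate
    # non-negative least squares for a | b0 with the exact update for b0 | a
    # (coordinate descent on a convex problem)
    X <- rise_basis(t, lag, tau)
    b0 <- min(y)
    a <- rep(0, length(tau))
    for (it in 1:25) {
      a_new <- pracma::lsqnonneg(X, y - b0)$x
      b0_new <- mean(y - X %*% a_new)
      done <- max(abs(a_new - a), abs(b0_new - b0)) < 1e-12
      a <- a_new
      b0 <- b0_new
      if (done) break
    }
    resid <- y - b0 - X %*% a
    list(a = as.numeric(a), A0 = b0, rss = sum(resid^2))
  }
  rss_of <- function(par) {
    solve_amps(par[1], exp(par[2:5]))$rss
  }
  starts <- list(
    c(5, log(c(2, 6, 25, 400))),
    c(3, log(c(1, 10, 50, 300))),
    c(8, log(c(3, 8, 20, 600)))
  )
  best <- NULL
  for (s in starts) {
    opt <- optim(s, rss_of, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  # polish with a second restart from the best point
  opt <- optim(best$par, rss_of, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 5000))
  if (opt$value < best$value) best <- opt

  lag <- best$par[1]
  tau <- exp(best$par[2:5])
  sol <- solve_amps(lag, tau)
  ord <- order(tau)
  tau <- tau[ord]
  a <- sol$a[ord]
  total <- sum(a)
  if (total <= 0) stop_c4("no rise detected; best residual ", signif(sol$rss, 4))
  new_kinetic_fit(
    "multiphase_rise",
    list(A0 = sol$A0, Ainf = sol$A0 + total, t_lag = lag,
         amplitudes = a, tau = tau, fractions = a / total),
    rss = sol$rss, n = length(y)
  )
}

#' Locate the post-decay trough of a trace
#'
#' Finds the minimum of a moving-average-smoothed trace inside a search
#' window and reports its depth as a fraction of a reference steady state:
#' `depth_frac = (reference - A(t_trough)) / reference`. A minimum sitting on
#' the window boundary (monotone trace) yields a trough-absent result, not an
#' error.
#'
#' @param trace A `gas_exchange_trace`.
#' @param reference A [estimate_steady_state()] result (or a single number in
#'   the trace basis).
#' @param search_window Length-2 numeric, s.
#' @param smooth_window Samples in the centered moving average (default 21).
#' @return List with `present`, `t_trough`, `depth_frac`, `A_trough`.
#' @export
detect_trough <- function(trace, reference, search_window,
                          smooth_window = 21L) {
  ref <- if (inherits(reference, "steady_state_estimate")) {
    if (!is.null(reference$basis) && reference$basis != trace_basis(trace)) {
      stop_c4("reference basis (", reference$basis,
              ") differs from trace basis (", trace_basis(trace), ")")
    }
    reference$value
  } else {
    reference
  }
  sm <- smooth_centered(trace$An, smooth_window)
  sel <- which(trace$time_s >= search_window[1] &
                 trace$time_s <= search_window[2])
  if (length(sel) < 3L) stop_c4("search window too narrow")
  i_min <- sel[which.min(sm[sel])]
  # a genuine trough must sit strictly inside the window and be preceded by
  # a fall and followed by a rise larger than numerical noise
  tol <- max(1e-8, 1e-6 * abs(ref))
  fall_before <- sm[sel[1]] - sm[i_min]
  rise_after <- sm[sel[length(sel)]] - sm[i_min]
  if (i_min == sel[1] || i_min == sel[length(sel)] ||
      fall_before <= tol || rise_after <= tol) {
    return(list(present = FALSE, t_trough = NA_real_,
                depth_frac = NA_real_, A_trough = NA_real_))
  }
  list(
    present = TRUE,
    t_trough = trace$time_s[i_min],
    depth_frac = (ref - sm[i_min]) / ref,
    A_trough = sm[i_min]
  )
}

#' Default phase segmentation of a transition
#'
#' Named contiguous intervals covering `(0, duration]`, as delineated by the
#' trajectory PCA: 0-15, 15-120 and 120+ s for the moderate-to-low
#' transition; 0-5, 5-60 and 60+ s for the low-to-moderate transition.
#'
#' @param direction `"ML_to_LL"` or `"LL_to_ML"`.
#' @param duration End of the last phase, s.
#' @return A tibble `phase, t_start, t_end` of class `phase_segmentation`.
#' @export
phase_segmentation <- function(direction = c("ML_to_LL", "LL_to_ML"),
                               duration = 1800) {
  direction <- match.arg(direction)
  cuts <- if (direction == "ML_to_LL") c(0, 15, 120, duration) else
    c(0, 5, 60, duration)
  out <- tibble::tibble(
    phase = paste0("phase_", seq_len(length(cuts) - 1L)),
    t_start = cuts[-length(cuts)],
    t_end = cuts[-1]
  )
  class(out) <- c("phase_segmentation", class(out))
  out
}

#' Integrate the deviation of a trace from a reference over a phase
#'
#' Trapezoidal integral of `An - reference` over `[phase[1], phase[2]]` on
#' the native time grid (phase boundaries are included by linear
#' interpolation). The integral divided by the steady-state difference
#' `delta_an` gives the phase's carbon gain or loss as equivalent seconds of
#' that difference.
#'
#' @param trace A `gas_exchange_trace`.
#' @param reference A [estimate_steady_state()] result or single number
#'   (trace basis).
#' @param phase Length-2 numeric, s.
#' @param delta_an Steady-state difference used for the time-equivalent
#'   (same basis and units as the trace), > 0.
#' @return One-row tibble `t_start, t_end, integral, equivalent_seconds,
#'   sign` where `sign` is `"gain"` or `"loss"`.
#' @export
integrate_deviation <- function(trace, reference, phase, delta_an) {
  ref <- if (inherits(reference, "steady_state_estimate")) {
    if (!is.null(reference$basis) && reference$basis != trace_basis(trace)) {
      stop_c4("reference basis (", reference$basis,
              ") differs from trace basis (", trace_basis(trace), ")")
    }
    reference$value
  } else {
    reference
  }
  check_number(delta_an, "delta_an", min = 0, strict_min = TRUE)
  if (phase[1] >= phase[2]) stop_c4("`phase` must be [t_start, t_end]")
  if (phase[1] < min(trace$time_s) - 1e-9 ||
      phase[2] > max(trace$time_s) + 1e-9) {
    stop_c4("phase lies outside the trace")
  }
  inner <- trace$time_s > phase[1] & trace$time_s < phase[2]
  tt <- c(phase[1], trace$time_s[inner], phase[2])
  yy <- stats::approx(trace$time_s, trace$An, xout = tt)$y
  integral <- trapz_grid(tt, yy - ref)
  tibble::tibble(
    t_start = phase[1], t_end = phase[2],
    integral = integral,
    equivalent_seconds = integral / delta_an,
    sign = ifelse(integral >= 0, "gain", "loss")
  )
}

#' Phase-integrated carbon budget of a transition
#'
#' Applies [integrate_deviation()] to every phase of a segmentation.
#'
#' @inheritParams integrate_deviation
#' @param segmentation A [phase_segmentation()].
#' @return Tibble with one row per phase (`phase, t_start, t_end, integral,
#'   equivalent_seconds, sign`).
#' @export
carbon_budget <- function(trace, reference, segmentation, delta_an) {
  rows <- lapply(seq_len(nrow(segmentation)), function(i) {
    out <- integrate_deviation(
      trace, reference,
      c(segmentation$t_start[i], segmentation$t_end[i]), delta_an
    )
    dplyr::mutate(out, phase = segmentation$phase[i], .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' Express a pool change as seconds of photosynthesis
#'
#' `delta_C / rate`: the time for which net assimilation at `rate` fixes the
#' same amount of carbon as the pool change. E.g. a rise of 4760 nmol C g-1
#' FW against the low-light rate of 53 nmol CO2 g-1 FW s-1 is ~90 s.
#'
#' @param delta_C Pool change, nmol C g-1 FW.
#' @param rate Assimilation rate, nmol CO2 g-1 FW s-1 (> 0).
#' @return Seconds.
#' @export
pool_time_equivalent <- function(delta_C, rate) {
  check_number(rate, "rate", min = 0, strict_min = TRUE)
  delta_C / rate
}

#' Triose-phosphate energy budget of a transient
#'
#' Linear stoichiometric feasibility check: oxidation of DHAP to 3PGA
#' releases NADPH and ATP (default 1 each per triose-P), while fixing one
#' extra CO2 through the Calvin-Benson cycle costs NADPH and ATP (defaults 2
#' and 3). The budget compares supply from the observed DHAP decline with the
#' requirement of the observed excess CO2 fixation, per cofactor.
#'
#' @param dhap_decline Decline of DHAP, nmol g-1 FW (>= 0).
#' @param excess_co2 Extra CO2 fixed relative to steady state, nmol g-1 FW
#'   (>= 0).
#' @param stoichiometry Named list with `nadph_per_triose`, `atp_per_triose`,
#'   `nadph_per_co2`, `atp_per_co2` (all >= 0).
#' @return List of class `energy_budget` with supplied/required amounts and
#'   `feasibility_ratio` (named, NADPH and ATP; `NA` when the requirement is
#'   zero).
#' @export
energy_budget <- function(dhap_decline, excess_co2,
                          stoichiometry = list(nadph_per_triose = 1,
                                               atp_per_triose = 1,
                                               nadph_per_co2 = 2,
                                               atp_per_co2 = 3)) {
  check_number(dhap_decline, "dhap_decline", min = 0)
  check_number(excess_co2, "excess_co2", min = 0)
  for (nm in c("nadph_per_triose", "atp_per_triose", "nadph_per_co2",
               "atp_per_co2")) {
    check_number(stoichiometry[[nm]], nm, min = 0)
  }
  nadph_supplied <- dhap_decline * stoichiometry$nadph_per_triose
  atp_supplied <- dhap_decline * stoichiometry$atp_per_triose
  nadph_required <- excess_co2 * stoichiometry$nadph_per_co2
  atp_required <- excess_co2 * stoichiometry$atp_per_co2
  ratio <- c(
    NADPH = if (nadph_required > 0) nadph_supplied / nadph_required else NA_real_,
    ATP = if (atp_required > 0) atp_supplied / atp_required else NA_real_
  )
  structure(
    list(
      nadph_supplied = nadph_supplied, atp_supplied = atp_supplied,
      nadph_required = nadph_required, atp_required = atp_required,
      stoichiometry = stoichiometry, feasibility_ratio = ratio
    ),
    class = "energy_budget"
  )
}

#' @export
print.energy_budget <- function(x, ...) {
  cat("<energy_budget> (nmol g-1 FW)\n")
  cat(sprintf("  NADPH: supplied %.4g, required %.4g, ratio %.3g\n",
              x$nadph_supplied, x$nadph_required, x$feasibility_ratio[["NADPH"]]))
  cat(sprintf("  ATP:   supplied %.4g, required %.4g, ratio %.3g\n",
              x$atp_supplied, x$atp_required, x$feasibility_ratio[["ATP"]]))
  invisible(x)
}
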