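# Dynamic (non-steady-state) correction of open-chamber gas-exchange
# records, steady-state estimation and area <-> fresh-weight conversion.

#' Dynamically correct raw analyzer signals
#'
#' Inverts the open-chamber mass balance
#' \deqn{V \, dc_s/dt = u (c_r - c_s) - A S}
#' to recover the instantaneous assimilation rate from logged CO2 mole
#' fractions:
#' \deqn{A(t) = [u (c_r - c_s) - V \, dc_s/dt] / S.}
#' The storage term \eqn{V \, dc_s/dt} is what distinguishes this from the
#' conventional steady-state equation; it vanishes when the sample signal is
#' constant. The derivative is estimated by central differences on a
#' moving-average-smoothed signal. When water channels are present and
#' differ, the standard transpiration-dilution term
#' \eqn{- c_s E} with \eqn{E = u (w_s - w_r) / [S (1 - w_s)]} is applied.
#'
#' @param raw A `raw_irga_series` (see [generate_raw_chamber_signals()] or
#'   [read_raw_irga()]).
#' @param smoothing_window Samples in the centered moving average used before
#'   differentiating; must be >= 3 (odd; even values are incremented).
#' @return A `gas_exchange_trace` on the area basis. `gs` and `Ci` columns
#'   are passed through (smoothed with a wider window) when present in `raw`,
#'   otherwise `NA`.
#' @export
correct_dynamic <- function(raw, smoothing_window = 5L) {
  if (!inherits(raw, "raw_irga_series")) {
    stop_c4("`raw` must be a raw_irga_series")
  }
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 3L) {
    stop_c4("`smoothing_window` must be at least 3 samples")
  }
  t <- raw$time_s
  n <- length(t)
  if (n < 3L) stop_c4("need at least 3 samples")
  dts <- diff(t)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-6)) {
    stop_c4("time grid is not uniform (tolerance 1e-6 s); ",
            "resample the series onto a uniform grid first")
  }
  u <- attr(raw, "flow") * 1e-6 # umol s-1 -> mol s-1
  V <- attr(raw, "chamber_volume")
  S <- attr(raw, "leaf_area")
  if (is.null(u) || is.null(V) || is.null(S) || V <= 0 || u <= 0 || S <= 0) {
    stop_c4("raw series must carry positive flow, chamber_volume and leaf_area")
  }

  cs <- smooth_centered(raw$c_sample, smoothing_window)
  # central differences; one-sided at the ends
  dcs <- numeric(n)
  dcs[2:(n - 1L)] <- (cs[3:n] - cs[1:(n - 2L)]) / (2 * dt)
  dcs[1] <- (cs[2] - cs[1]) / dt
  dcs[n] <- (cs[n] - cs[n - 1L]) / dt

  an <- (u * (raw$c_reference - cs) - V * dcs) / S

  has_w <- all(c("w_reference", "w_sample") %in% names(raw)) &&
    any(is.finite(raw$w_sample - raw$w_reference) &
          raw$w_sample != raw$w_reference)
  if (has_w) {
    wr <- raw$w_reference / 1000 # mmol mol-1 -> mol mol-1
    ws <- raw$w_sample / 1000
    E <- u * (ws - wr) / (S * (1 - ws)) # mol m-2 s-1
    an <- an - cs * E
  }

  wide <- max(smoothing_window, 11L)
  gs <- if ("gs" %in% names(raw)) smooth_centered(raw$gs, wide) else NA_real_
  ci <- if ("Ci" %in% names(raw)) smooth_centered(raw$Ci, wide) else NA_real_

  as_gas_exchange_trace(
    tibble::tibble(time_s = t, An = an, gs = gs, Ci = ci),
    basis = "area"
  )
}

#' Estimate a steady-state rate over a time window
#'
#' Mean and standard deviation of `An` over `[window[1], window[2]]`, with a
#' non-stationarity flag raised when the magnitude of a fitted linear drift
#' across the window exceeds twice the residual standard deviation.
#'
#' @param trace A `gas_exchange_trace`.
#' @param window Length-2 numeric, seconds (inclusive); must contain at least
#'   10 samples.
#' @return A list of class `steady_state_estimate` with elements `value`,
#'   `sd`, `window`, `n`, `nonstationary`, `basis`.
#' @export
estimate_steady_state <- function(trace, window) {
  if (length(window) != 2L || window[1] >= window[2]) {
    stop_c4("`window` must be [t_start, t_end] with t_start < t_end")
  }
  sel <- trace$time_s >= window[1] & trace$time_s <= window[2]
  if (!any(sel)) stop_c4("window lies outside the trace")
  tt <- trace$time_s[sel]
  y <- trace$An[sel]
  if (length(y) < 10L) stop_c4("steady-state window must contain >= 10 samples")
  m <- mean(y)
  s <- sd(y)
  fit <- lm(y ~ tt)
  drift <- abs(coef(fit)[[2]]) * (max(tt) - min(tt))
  resid_sd <- sd(stats::residuals(fit))
  nonstat <- drift > 2 * max(resid_sd, .Machine$double.eps)
  structure(
    list(value = m, sd = s, window = window, n = length(y),
         nonstationary = nonstat, basis = trace_basis(trace)),
    class = "steady_state_estimate"
  )
}

#' @export
print.steady_state_estimate <- function(x, ...) {
  cat(sprintf(
    "<steady_state> %.4g (sd %.3g, n = %d) over %g-%g s [%s]%s\n",
    x$value, x$sd, x$n, x$window[1], x$window[2], x$basis,
    if (x$nonstationary) " NONSTATIONARY" else ""
  ))
  invisible(x)
}

#' Convert rates between area and fresh-weight bases
#'
#' Uses the specific leaf area (SLA, m2 g-1 FW):
#' `rate_fw [nmol g-1 FW s-1] = rate_area [umol m-2 s-1] * sla * 1000`.
#' The reference SLA for the study material is 0.0055 m2 g-1, under which
#' 25 umol m-2 s-1 converts to 137.5 nmol g-1 FW s-1.
#'
#' @param x A numeric vector of rates, or a `gas_exchange_trace`.
#' @param sla Specific leaf area, m2 g-1 FW (> 0).
#' @param to Target basis, `"fresh_weight"` or `"area"`.
#' @param from Basis of a numeric `x` (ignored for traces, which carry their
#'   basis).
#' @return Same shape as `x`, converted; traces keep `gs`/`Ci` untouched and
#'   get the new basis attribute.
#' @export
convert_basis <- function(x, sla = 0.0055, to = c("fresh_weight", "area"),
                          from = c("area", "fresh_weight")) {
  to <- match.arg(to)
  check_number(sla, "sla", min = 0, strict_min = TRUE)
  if (inherits(x, "gas_exchange_trace")) {
    from <- trace_basis(x)
    if (from == to) return(x)
    x$An <- convert_basis(x$An, sla = sla, to = to, from = from)
    attr(x, "basis") <- to
    return(x)
  }
  from <- match.arg(from)
  if (from == to) return(x)
  if (to == "fresh_weight") x * sla * 1000 else x / (sla * 1000)
}
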