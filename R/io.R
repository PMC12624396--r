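# File I/O (delimited tables with dialect auto-detection), scenario configs
# and the end-to-end pipeline.

detect_delim <- function(path) {
  lines <- readr::read_lines(path, n_max = 20)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop_c4("no data lines in ", path)
  header <- lines[1]
  counts <- vapply(c(",", "\t", ";"), function(d) {
    lengths(regmatches(header, gregexpr(d, header, fixed = TRUE)))
  }, integer(1))
  if (all(counts == 0)) stop_c4(
    "could not detect delimiter (comma/tab/semicolon) in ", path
  )
  c(",", "\t", ";")[which.max(counts)]
}

read_delim_auto <- function(path, mapping = NULL) {
  tab <- readr::read_delim(
    path, delim = detect_delim(path), comment = "#",
    show_col_types = FALSE, progress = FALSE, trim_ws = TRUE
  )
  if (!is.null(mapping)) {
    for (nm in names(mapping)) {
      src <- mapping[[nm]]
      if (!src %in% names(tab)) {
        stop_c4("mapped column `", src, "` not found in ", path)
      }
      names(tab)[names(tab) == src] <- nm
    }
  }
  tab
}

provenance_header <- function(seed = NULL, extra = NULL) {
  h <- c(
    sprintf("# c4dyn %s", as.character(utils::packageVersion("c4dyn"))),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)),
    extra
  )
  h
}

#' Read a gas-exchange trace table
#'
#' Expects columns `time_s`, `An`, optionally `gs`, `Ci`, `basis` (constant
#' column) and `replicate`; the delimiter (comma, tab or semicolon) is
#' auto-detected and `#` lines are ignored. A column-mapping config (named
#' list, target = source) adapts instrument export dialects.
#'
#' @param path File path.
#' @param mapping Optional named list mapping schema names to file columns.
#' @return A `gas_exchange_trace`.
#' @export
read_trace <- function(path, mapping = NULL) {
  tab <- read_delim_auto(path, mapping)
  need <- c("time_s", "An")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop_c4(path, ": missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  basis <- if ("basis" %in% names(tab)) {
    b <- unique(tab$basis)
    if (length(b) != 1L) stop_c4(path, ": `basis` column must be constant")
    b
  } else {
    "area"
  }
  rep_id <- if ("replicate" %in% names(tab)) {
    as.character(unique(tab$replicate))[1]
  } else {
    NA_character_
  }
  as_gas_exchange_trace(
    tab[, intersect(c("time_s", "An", "gs", "Ci"), names(tab))],
    basis = basis, replicate_id = rep_id
  )
}

#' Write a gas-exchange trace table
#'
#' @param trace A `gas_exchange_trace`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @param seed Optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, delim = ",", seed = NULL) {
  out <- tibble::as_tibble(trace)
  out$basis <- trace_basis(trace)
  readr::write_lines(provenance_header(seed), path)
  readr::write_delim(out, path, delim = delim, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a metabolite panel table
#'
#' Expects columns `transition, time_s, replicate, metabolite,
#' amount_nmol_gFW` (delimiter auto-detected, `#` comments allowed).
#' Negative amounts are rejected with the offending row; metabolite names are
#' validated against the stoichiometry table when one is supplied.
#'
#' @param path File path.
#' @param mapping Optional named list mapping schema names to file columns.
#' @param stoich A [stoichiometry_table()] for name validation, or `NULL` to
#'   skip.
#' @return A `metabolite_panel`.
#' @export
read_panel <- function(path, mapping = NULL, stoich = NULL) {
  tab <- read_delim_auto(path, mapping)
  need <- c("transition", "time_s", "replicate", "metabolite",
            "amount_nmol_gFW")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop_c4(path, ": missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(!is.na(tab$amount_nmol_gFW) & tab$amount_nmol_gFW < 0)
  if (length(bad)) {
    stop_c4(sprintf("%s: negative amount at data row %d (column amount_nmol_gFW)",
                    path, bad[1]))
  }
  if (!is.null(stoich)) {
    unknown <- setdiff(unique(tab$metabolite), stoich$metabolite)
    if (length(unknown)) {
      stop_c4(path, ": unknown metabolite(s) ",
              paste(unknown, collapse = ", "),
              "; accepted names: ", paste(stoich$metabolite, collapse = ", "))
    }
  }
  as_metabolite_panel(tab[, need])
}

#' Write a metabolite panel table
#'
#' @param panel A `metabolite_panel`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @param seed Optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, delim = ",", seed = NULL) {
  readr::write_lines(provenance_header(seed), path)
  readr::write_delim(tibble::as_tibble(panel), path, delim = delim,
                     append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read raw analyzer signals
#'
#' Expects columns `time_s, c_reference, c_sample` and optionally
#' `w_reference, w_sample, gs, Ci`; chamber metadata comes from the
#' `chamber` argument.
#'
#' @param path File path.
#' @param chamber A [chamber_config()].
#' @param mapping Optional column mapping (see [read_trace()]).
#' @return A `raw_irga_series`.
#' @export
read_raw_irga <- function(path, chamber, mapping = NULL) {
  tab <- read_delim_auto(path, mapping)
  need <- c("time_s", "c_reference", "c_sample")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop_c4(path, ": missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  out <- tibble::as_tibble(tab)
  attr(out, "flow") <- chamber$flow
  attr(out, "leaf_area") <- chamber$leaf_area
  attr(out, "chamber_volume") <- chamber$volume
  attr(out, "sampling_interval") <- chamber$sampling_interval
  class(out) <- c("raw_irga_series", class(out))
  out
}

#' Read a scenario from a flat key:value config file
#'
#' YAML with scalar keys matching the arguments of
#' [transition_scenario()] (list-valued fields like `phase_fractions` as YAML
#' sequences).
#'
#' @param path File path.
#' @return A `transition_scenario`.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(transition_scenario))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop_c4(path, ": unknown scenario field(s) ",
            paste(unknown, collapse = ", "))
  }
  do.call(transition_scenario, cfg)
}

# Cheap stable hash of a config list for provenance (not cryptographic).
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 251 + 1)) %%
            .Machine$integer.max)
}

#' Time at which assimilation first reaches a fraction of its initial value
#'
#' Linear interpolation of the first crossing; `NA` when the trace never
#' crosses. For the default moderate-to-low scenario the half-of-initial
#' time is ~11 s, the classic summary of the decay speed.
#'
#' @param trace A `gas_exchange_trace` (ideally noiseless).
#' @param fraction Fraction of the value at `time_s = 0` (default 0.5).
#' @return Time, s.
#' @export
time_to_fraction_of_initial <- function(trace, fraction = 0.5) {
  a0 <- trace$An[trace$time_s == 0]
  if (!length(a0)) a0 <- trace$An[1]
  target <- fraction * a0
  below <- if (a0 > target) trace$An <= target else trace$An >= target
  i <- which(below)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(trace$time_s[1])
  t1 <- trace$time_s[i - 1L]; t2 <- trace$time_s[i]
  y1 <- trace$An[i - 1L]; y2 <- trace$An[i]
  t1 + (target - y1) / (y2 - y1) * (t2 - t1)
}

#' Run the full synthetic-transition pipeline
#'
#' Chains every stage on synthetic data: scenario realisation, forward
#' chamber simulation and dynamic correction (round-trip), metabolite panel
#' generation, trait computation, kinetic fits, trough detection, phase
#' carbon budgets, pool deltas and time equivalents, trajectory PCA,
#' correlation analysis, segment t-tests and the paired recovery test.
#' Writes tidy tables plus a machine-readable `summary.json` to `out_dir`
#' and returns the summary invisibly. Deterministic given `seed`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving every random stage.
#' @param alpha Significance level for masks and stars.
#' @param sla Specific leaf area (m2 g-1 FW) for basis conversions.
#' @param duration Trace duration, s.
#' @param n_replicate_traces Replicate gas-exchange traces per transition.
#' @param ml_ll,ll_ml Scenario overrides (named lists passed to
#'   [ml_ll_scenario()] / [ll_ml_scenario()]).
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(out_dir, seed = 1L, alpha = 0.05, sla = 0.0055,
                         duration = 1800, n_replicate_traces = 5L,
                         ml_ll = list(), ll_ml = list()) {
  check_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  config <- list(seed = seed, alpha = alpha, sla = sla, duration = duration,
                 n_replicate_traces = n_replicate_traces,
                 ml_ll = ml_ll, ll_ml = ll_ml)
  stoich <- stoichiometry_table()
  summary <- list(
    package_version = as.character(utils::packageVersion("c4dyn")),
    seed = as.integer(seed), config_hash = config_hash(config)
  )

  for (dir_label in c("ML_to_LL", "LL_to_ML")) {
    message("stage: ", dir_label, " (simulate/correct/traits/kinetics/stats)")
    is_ml_ll <- dir_label == "ML_to_LL"
    overrides <- if (is_ml_ll) ml_ll else ll_ml
    make_scen <- if (is_ml_ll) ml_ll_scenario else ll_ml_scenario
    scen0 <- do.call(make_scen, c(list(seed = seed), overrides))

    # -- gas exchange: noiseless truth + replicate noisy traces
    truth <- generate_an_trace(
      do.call(make_scen, c(list(noise_sd = 0, seed = seed), overrides)),
      duration = duration
    )
    reps <- lapply(seq_len(n_replicate_traces), function(r) {
      generate_an_trace(
        do.call(make_scen, c(list(seed = seed + 1000L * r), overrides)),
        duration = duration, replicate_id = paste0("rep", r)
      )
    })
    write_trace(truth, file.path(out_dir, paste0("trace_", dir_label, ".csv")),
                seed = seed)

    # -- forward chamber + dynamic correction, checked on the step oracle
    # (a step at t = 100 s between the two steady states; error measured
    # outside a 2-sample boundary of the step, relative to its amplitude)
    area_truth <- convert_basis(truth, sla = sla, to = "area")
    a_hi <- convert_basis(ss_values(truth, pre = TRUE), sla, to = "area",
                          from = trace_basis(truth))
    a_lo <- convert_basis(ss_values(truth, pre = FALSE), sla, to = "area",
                          from = trace_basis(truth))
    step <- as_gas_exchange_trace(
      tibble::tibble(time_s = 0:300,
                     An = c(rep(a_hi, 100), rep(a_lo, 201))),
      basis = "area"
    )
    raw <- generate_raw_chamber_signals(step, chamber_config())
    corrected <- correct_dynamic(raw, smoothing_window = 3L)
    outside <- setdiff(seq(3, nrow(corrected) - 2L), 98:103)
    rt_err <- max(abs(corrected$An[outside] - step$An[outside])) /
      abs(a_hi - a_lo)
    raw_full <- generate_raw_chamber_signals(area_truth, chamber_config())
    write_trace(correct_dynamic(raw_full, smoothing_window = 3L),
                file.path(out_dir, paste0("corrected_", dir_label, ".csv")),
                seed = seed)

    # -- steady states and delta A_n
    ss_pre <- estimate_steady_state(
      rbind_pre(truth), window = c(-60, 0)
    )
    ss_end <- estimate_steady_state(truth, window = c(duration - 60, duration))
    delta_an <- abs(ss_pre$value - ss_end$value)

    # -- panel + traits
    n_rep <- if (is_ml_ll) 4L else c(10L, rep(4L, length(panel_times()) - 1L))
    panel <- generate_metabolite_panel(
      default_metabolite_templates(dir_label),
      n_replicates = n_rep, seed = seed + if (is_ml_ll) 1L else 2L,
      transition = dir_label, stoich = stoich
    )
    write_panel(panel, file.path(out_dir, paste0("panel_", dir_label, ".csv")),
                seed = seed)
    traits <- compute_traits(panel, stoich)
    readr::write_csv(traits,
                     file.path(out_dir, paste0("traits_", dir_label, ".csv")))

    # -- kinetics
    seg <- phase_segmentation(dir_label, duration)
    budget <- carbon_budget(truth, ss_end$value, seg, delta_an)
    readr::write_csv(budget,
                     file.path(out_dir, paste0("budget_", dir_label, ".csv")))
    dir_summary <- list(
      steady_initial = ss_pre$value,
      steady_final = ss_end$value,
      delta_an = delta_an,
      roundtrip_max_err_frac = rt_err,
      budget_equivalent_seconds = setNames(budget$equivalent_seconds,
                                           budget$phase)
    )
    if (is_ml_ll) {
      fit <- fit_decay(truth, fit_window = c(0, 60))
      trough <- detect_trough(truth, ss_end,
                              search_window = c(60, min(700, duration)))
      recovery <- if (duration >= 300) {
        paired_recovery_test(reps, window_a = c(250, 259),
                             window_b = c(duration - 9, duration))
      } else {
        tibble::tibble(p = NA_real_)
      }
      dhap <- pool_delta(
        dplyr::mutate(sum_pool(panel, "DHAP", "carbon", stoich),
                      trait = "DHAP_C", value = .data$value / 3),
        t_from = 0, t_to = 15
      )
      dir_summary <- c(dir_summary, list(
        t_half_fit = fit$t_half,
        t_lag_fit = fit$t_lag,
        t_half_of_initial = time_to_fraction_of_initial(truth, 0.5),
        frac_of_initial_10s = truth$An[truth$time_s == 10] / ss_pre$value,
        frac_of_initial_15s = truth$An[truth$time_s == 15] / ss_pre$value,
        trough_time = trough$t_trough,
        trough_depth_frac = trough$depth_frac,
        recovery_p = recovery$p,
        dhap_decline_0_15 = -dhap$delta
      ))
    } else {
      fit <- decompose_rise(truth)
      pools <- sum_pool(panel, c(pool_members(stoich, "CBC"),
                                 pool_members(stoich, "CCM")),
                        "carbon", stoich)
      pools$trait <- "C_CBC_shuttle_CCM"
      rise <- pool_delta(pools, t_from = 0, t_to = 1800)
      dir_summary <- c(dir_summary, list(
        phase_fractions = fit$fractions,
        pool_rise_C = rise$delta,
        pool_time_eq_final_s = pool_time_equivalent(rise$delta, ss_end$value),
        pool_time_eq_delta_s = pool_time_equivalent(rise$delta, delta_an)
      ))
    }

    # -- statistics
    pca <- pca_trajectory(panel, an_by_time = tibble::tibble(
      time_s = panel_times(),
      An = an_mean_curve(scen0, panel_times())
    ))
    tests <- segment_tests(panel, seg)
    readr::write_csv(tests,
                     file.path(out_dir, paste0("tests_", dir_label, ".csv")))
    dir_summary$pca_variance_pc1 <- pca$variance_explained[1]
    dir_summary$pca_variance_pc2 <- pca$variance_explained[2]
    summary[[dir_label]] <- dir_summary
  }

  message(sprintf("pipeline finished in %.1f s (seed %d, config %s)",
                  as.numeric(difftime(Sys.time(), t_start, units = "secs")),
                  seed, summary$config_hash))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

# Pre-switch reference value or final-window mean of a trace.
ss_values <- function(trace, pre = TRUE) {
  if (pre) {
    trace$An[trace$time_s == 0][1]
  } else {
    t_max <- max(trace$time_s)
    mean(trace$An[trace$time_s >= t_max - 60])
  }
}

# Extend a trace backwards with its pre-switch reference so a pre-transition
# steady-state window [-60, 0] has enough samples.
rbind_pre <- function(trace) {
  pre <- tibble::tibble(
    time_s = seq(-60, -1),
    An = trace$An[trace$time_s == 0],
    gs = trace$gs[trace$time_s == 0],
    Ci = trace$Ci[trace$time_s == 0]
  )
  as_gas_exchange_trace(rbind(pre, tibble::as_tibble(trace)),
                        basis = trace_basis(trace),
                        replicate_id = attr(trace, "replicate_id"))
}
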