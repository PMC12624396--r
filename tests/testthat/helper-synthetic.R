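# Shared fixtures, built in code.

noiseless_ml_ll <- function(duration = 1800, ...) {
  generate_an_trace(ml_ll_scenario(noise_sd = 0, ...), duration = duration)
}

noiseless_ll_ml <- function(duration = 1800, ...) {
  generate_an_trace(ll_ml_scenario(noise_sd = 0, ...), duration = duration)
}

# A minimal wide-format panel from a named list of per-metabolite amounts,
# replicated identically (used for hand-arithmetic oracles).
tiny_panel <- function(amounts, time_s = 0, replicate = 1,
                       transition = "ML_to_LL") {
  as_metabolite_panel(tibble::tibble(
    transition = transition,
    time_s = time_s,
    replicate = replicate,
    metabolite = names(amounts),
    amount_nmol_gFW = unname(unlist(amounts))
  ))
}

# Random positive panel over all 36 metabolites x several times/replicates.
random_panel <- function(seed = 1, times = c(0, 15, 120, 1800),
                         n_rep = 3, transition = "ML_to_LL") {
  st <- stoichiometry_table()
  grid <- expand.grid(
    time_s = times, replicate = seq_len(n_rep),
    metabolite = st$metabolite, stringsAsFactors = FALSE
  )
  set.seed(seed)
  grid$amount_nmol_gFW <- stats::runif(nrow(grid), 1, 1000)
  grid$transition <- transition
  attr(grid, "out.attrs") <- NULL
  as_metabolite_panel(tibble::as_tibble(grid)[, c(
    "transition", "time_s", "replicate", "metabolite", "amount_nmol_gFW"
  )])
}

# Gaussian null panel: every metabolite constant in expectation over time.
null_panel <- function(seed, n_met = 4, times = c(0, 5, 10, 15, 30, 60, 120,
                                                  300, 600, 1200),
                       n_rep = 30, mean = 100, sd = 10) {
  grid <- expand.grid(
    time_s = times, replicate = seq_len(n_rep),
    metabolite = paste0("m", seq_len(n_met)), stringsAsFactors = FALSE
  )
  set.seed(seed)
  grid$amount_nmol_gFW <- stats::rnorm(nrow(grid), mean, sd)
  grid$transition <- "ML_to_LL"
  attr(grid, "out.attrs") <- NULL
  as_metabolite_panel(tibble::as_tibble(grid))
}
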