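# Metabolic traits: diagnostic ratios and stoichiometry-weighted summed
# carbon / phosphate pools.

#' Metabolite stoichiometry and pool membership
#'
#' Per-metabolite carbon atoms, phosphate groups and pathway-pool membership
#' used to weight pool sums. Pools: `CBC` (Calvin-Benson cycle: 3PGA, DHAP,
#' FBP, F6P, SBP, S7P, R5P, Ru5P+Xu5P, RuBP), `energy_shuttle` (3PGA, DHAP),
#' `CBC_minus_shuttle` (the CBC without 3PGA and DHAP), `CCM` (PEP,
#' aspartate, pyruvate, alanine; malate is flagged `excluded_from_CCM`
#' because its photosynthetically active pool cannot be separated from large
#' inactive pools), `photorespiration` and `end_product`. ADPG is profiled
#' alongside the CBC but is not a member of the summed CBC pools.
#'
#' @param path Optional path to a user table with the same schema
#'   (`metabolite, carbon_atoms, phosphate_groups, pools,
#'   excluded_from_CCM`; pools separated by `;`).
#' @return A tibble of class `stoichiometry_table`.
#' @export
stoichiometry_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stoichiometry.csv", package = "c4dyn")
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("metabolite", "carbon_atoms", "phosphate_groups", "pools",
            "excluded_from_CCM")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop_c4("stoichiometry table missing column(s): ",
            paste(missing_cols, collapse = ", "))
  }
  tab$pools <- ifelse(is.na(tab$pools), "", tab$pools)
  pooled <- tab$pools != ""
  if (any(pooled & tab$carbon_atoms < 1)) {
    stop_c4("every pooled metabolite must have carbon_atoms >= 1")
  }
  class(tab) <- c("stoichiometry_table", class(tab))
  tab
}

# Members of a named pool, honouring the malate exclusion for CCM.
pool_members <- function(stoich, pool) {
  in_pool <- vapply(
    strsplit(stoich$pools, ";", fixed = TRUE),
    function(p) pool %in% p, logical(1)
  )
  if (pool == "CCM") in_pool <- in_pool & !stoich$excluded_from_CCM
  stoich$metabolite[in_pool]
}

ratio_definitions <- function() {
  list(
    "3PGA/DHAP" = list(num = "3PGA", den = "DHAP"),
    "FBP/F6P" = list(num = "FBP", den = "F6P"),
    "SBP/S7P" = list(num = "SBP", den = "S7P"),
    "pentoseP/RuBP" = list(num = c("R5P", "Ru5P+Xu5P"), den = "RuBP"),
    "RuBP/3PGA" = list(num = "RuBP", den = "3PGA"),
    "RuBP/2PG" = list(num = "RuBP", den = "2PG"),
    "pyruvate/alanine" = list(num = "pyruvate", den = "alanine"),
    "2OG/glutamate" = list(num = "2OG", den = "glutamate"),
    "3PGA/PEP" = list(num = "3PGA", den = "PEP")
  )
}

# Panel in wide (one row per transition/time/replicate) form.
panel_wide <- function(panel) {
  tidyr::pivot_wider(
    tibble::as_tibble(panel),
    id_cols = c("transition", "time_s", "replicate"),
    names_from = "metabolite", values_from = "amount_nmol_gFW"
  )
}

#' Compute diagnostic metabolite ratios per replicate
#'
#' Ratios indicative of the supply of NADPH and ATP (3PGA/DHAP), of
#' activation of the bisphosphatases (FBP/F6P, SBP/S7P), of RuBP regeneration
#' and use (pentoseP/RuBP with pentose-P = R5P + Ru5P+Xu5P, RuBP/3PGA,
#' RuBP/2PG), of the C4-acid decarboxylation balance (pyruvate/alanine), of
#' the amino shuttle (2OG/glutamate) and of CBC-to-CCM carbon transfer
#' (3PGA/PEP). Ratios are formed per replicate, never from means. A zero or
#' missing denominator yields `NA` (missing-flagged), never `Inf`.
#'
#' @param panel A `metabolite_panel`.
#' @return Tidy tibble `transition, time_s, replicate, trait, value`.
#' @export
compute_ratios <- function(panel) {
  wide <- panel_wide(panel)
  defs <- ratio_definitions()
  needed <- unique(unlist(lapply(defs, function(d) c(d$num, d$den))))
  absent <- setdiff(needed, names(wide))
  if (length(absent)) {
    stop_c4("panel lacks metabolite(s) needed for ratios: ",
            paste(absent, collapse = ", "))
  }
  rows <- lapply(names(defs), function(nm) {
    d <- defs[[nm]]
    num <- Reduce(`+`, lapply(d$num, function(m) wide[[m]]))
    den <- Reduce(`+`, lapply(d$den, function(m) wide[[m]]))
    val <- ifelse(is.na(den) | den == 0, NA_real_, num / den)
    tibble::tibble(
      transition = wide$transition, time_s = wide$time_s,
      replicate = wide$replicate, trait = nm, value = val
    )
  })
  dplyr::bind_rows(rows)
}

#' Sum a stoichiometry-weighted metabolite pool
#'
#' \eqn{\sum_i a_i x_i} over the pool members, where \eqn{x_i} is the amount
#' (nmol g-1 FW) and \eqn{a_i} the number of carbon atoms or phosphate
#' groups. Malate never contributes to the CCM sum.
#'
#' @param panel A `metabolite_panel`.
#' @param pool Pool name (see [stoichiometry_table()]), or a character vector
#'   of metabolite names for an ad-hoc pool.
#' @param weight `"carbon"` or `"phosphate"`.
#' @param stoich A [stoichiometry_table()].
#' @return Tibble `transition, time_s, replicate, value` (nmol C or nmol P
#'   g-1 FW).
#' @export
sum_pool <- function(panel, pool, weight = c("carbon", "phosphate"),
                     stoich = stoichiometry_table()) {
  weight <- match.arg(weight)
  members <- if (length(pool) == 1L && pool %in% unlist(strsplit(stoich$pools, ";"))) {
    pool_members(stoich, pool)
  } else {
    unknown <- setdiff(pool, stoich$metabolite)
    if (length(unknown)) {
      stop_c4("unknown metabolite(s) in ad-hoc pool: ",
              paste(unknown, collapse = ", "))
    }
    pool
  }
  if (!length(members)) stop_c4("pool `", pool, "` has no members")
  wide <- panel_wide(panel)
  absent <- setdiff(members, names(wide))
  if (length(absent)) {
    stop_c4("panel lacks pool member(s): ", paste(absent, collapse = ", "))
  }
  atoms <- stoich[[if (weight == "carbon") "carbon_atoms" else "phosphate_groups"]]
  names(atoms) <- stoich$metabolite
  val <- Reduce(`+`, lapply(members, function(m) atoms[[m]] * wide[[m]]))
  tibble::tibble(
    transition = wide$transition, time_s = wide$time_s,
    replicate = wide$replicate, value = val
  )
}

#' Compute the full trait table
#'
#' All diagnostic ratios plus the named stoichiometric sums: `C_CBC`,
#' `P_CBC`, `C_shuttle` (3PGA + DHAP), `C_CBC_minus_shuttle`, `C_CCM` and
#' `C_pyr_plus_ala`. By construction
#' `C_CBC = C_shuttle + C_CBC_minus_shuttle` holds exactly for every record.
#'
#' @inheritParams sum_pool
#' @return Tidy tibble `transition, time_s, replicate, trait, value`.
#' @export
compute_traits <- function(panel, stoich = stoichiometry_table()) {
  ratios <- compute_ratios(panel)
  sums <- list(
    C_CBC = sum_pool(panel, "CBC", "carbon", stoich),
    P_CBC = sum_pool(panel, "CBC", "phosphate", stoich),
    C_shuttle = sum_pool(panel, "energy_shuttle", "carbon", stoich),
    C_CBC_minus_shuttle = sum_pool(panel, "CBC_minus_shuttle", "carbon", stoich),
    C_CCM = sum_pool(panel, "CCM", "carbon", stoich),
    C_pyr_plus_ala = sum_pool(panel, c("pyruvate", "alanine"), "carbon", stoich)
  )
  sums <- dplyr::bind_rows(lapply(names(sums), function(nm) {
    dplyr::mutate(sums[[nm]], trait = nm, .before = "value")
  }))
  dplyr::bind_rows(ratios, sums)
}

#' Change of a trait between two time points
#'
#' Difference of replicate means, `mean(t_to) - mean(t_from)`, with the
#' standard error propagated as the root sum of squared standard errors of
#' the two means.
#'
#' @param traits Tidy trait table from [compute_traits()] or a pool sum from
#'   [sum_pool()] carrying a `trait` column (if absent, all rows are treated
#'   as one trait named `"value"`).
#' @param t_from,t_to Time points, s (must differ and be present).
#' @return Tibble `transition, trait, t_from, t_to, delta, se, n_from, n_to`.
#' @export
pool_delta <- function(traits, t_from, t_to) {
  if (t_from == t_to) stop_c4("`t_from` and `t_to` must differ")
  if (!"trait" %in% names(traits)) traits$trait <- "value"
  have <- unique(traits$time_s)
  if (!t_from %in% have || !t_to %in% have) {
    stop_c4("both time points must be present in the trait table")
  }
  summ <- traits |>
    dplyr::filter(.data$time_s %in% c(t_from, t_to)) |>
    dplyr::group_by(.data$transition, .data$trait, .data$time_s) |>
    dplyr::summarise(
      m = mean(.data$value, na.rm = TRUE),
      se = sd(.data$value, na.rm = TRUE) / sqrt(sum(is.finite(.data$value))),
      n = sum(is.finite(.data$value)),
      .groups = "drop"
    )
  from <- dplyr::filter(summ, .data$time_s == t_from)
  to <- dplyr::filter(summ, .data$time_s == t_to)
  joined <- dplyr::inner_join(
    from, to,
    by = c("transition", "trait"), suffix = c("_from", "_to")
  )
  tibble::tibble(
    transition = joined$transition,
    trait = joined$trait,
    t_from = t_from, t_to = t_to,
    delta = joined$m_to - joined$m_from,
    se = sqrt(joined$se_from^2 + joined$se_to^2),
    n_from = joined$n_from, n_to = joined$n_to
  )
}
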