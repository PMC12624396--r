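# Trajectory-level statistics: PCA on per-time-point means, correlation and
# clustering against A_n, time-zero and segment t-tests, the paired recovery
# test and per-transition linear regressions.

# Panel (long) -> matrix of per-time-point metabolite means, rows = times.
panel_time_means <- function(panel) {
  means <- panel |>
    dplyr::group_by(.data$time_s, .data$metabolite) |>
    dplyr::summarise(m = mean(.data$amount_nmol_gFW, na.rm = TRUE),
                     .groups = "drop")
  wide <- tidyr::pivot_wider(means, names_from = "metabolite",
                             values_from = "m")
  wide <- wide[order(wide$time_s), ]
  mat <- as.matrix(wide[, setdiff(names(wide), "time_s")])
  rownames(mat) <- wide$time_s
  mat
}

#' Trajectory PCA on per-time-point means
#'
#' Principal component analysis of the metabolite panel means at each time
#' point, with the mean net assimilation rate appended as one more variable.
#' Variables are centered and scaled to unit variance (amounts span orders of
#' magnitude); zero-variance variables are dropped with a warning. Loading
#' signs follow a deterministic convention: the largest-magnitude loading of
#' each component is positive.
#'
#' @param panel A `metabolite_panel`.
#' @param an_by_time Tibble `time_s, An` of mean assimilation at the panel
#'   time points (e.g. a noiseless trace evaluated there), or `NULL` to run
#'   on metabolites alone.
#' @return List of class `pca_result`: `scores` (tibble, time x component),
#'   `loadings` (tibble, variable x component), `variance_explained`
#'   (fraction per component), `scaled` (the scaled data matrix).
#' @export
pca_trajectory <- function(panel, an_by_time = NULL) {
  mat <- panel_time_means(panel)
  if (!is.null(an_by_time)) {
    an <- an_by_time[match(as.numeric(rownames(mat)), an_by_time$time_s), ]
    if (any(is.na(an$An))) {
      stop_c4("`an_by_time` must provide An at every panel time point")
    }
    mat <- cbind(mat, An = an$An)
  }
  if (nrow(mat) < 3L) stop_c4("need >= 3 time points for a trajectory PCA")
  vars <- apply(mat, 2, sd)
  if (any(vars == 0)) {
    warning("dropping zero-variance variable(s): ",
            paste(colnames(mat)[vars == 0], collapse = ", "), call. = FALSE)
    mat <- mat[, vars > 0, drop = FALSE]
  }
  pc <- prcomp(mat, center = TRUE, scale. = TRUE)
  # deterministic sign: largest |loading| per component positive
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      scores = tibble::as_tibble(pc$x) |>
        dplyr::mutate(time_s = as.numeric(rownames(mat)), .before = 1),
      loadings = tibble::as_tibble(pc$rotation) |>
        dplyr::mutate(variable = colnames(mat), .before = 1),
      variance_explained = ve,
      scaled = scale(mat)
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  ve <- x$variance_explained
  cat(sprintf("<pca_result> %d time points x %d variables\n",
              nrow(x$scores), nrow(x$loadings)))
  cat(sprintf("  variance explained: PC1 %.1f%%, PC2 %.1f%%\n",
              100 * ve[1], 100 * ve[2]))
  invisible(x)
}

# Long samples (time_s, replicate, variable, value) + An per time ->
# wide sample matrix including An.
samples_wide_with_an <- function(samples, an, exclude_time_zero = TRUE) {
  if (exclude_time_zero) samples <- dplyr::filter(samples, .data$time_s != 0)
  wide <- tidyr::pivot_wider(samples,
                             id_cols = c("time_s", "replicate"),
                             names_from = "variable", values_from = "value")
  if (!is.null(an)) {
    wide$An <- an$An[match(wide$time_s, an$time_s)]
  }
  wide
}

#' Pairwise Pearson correlations with hierarchical clustering
#'
#' Pearson correlation of every variable pair (metabolites, traits and the
#' assimilation rate) across individual samples at all time points after the
#' transition, time zero excluded. Two-sided p-values come from the t
#' distribution; variables are ordered by average-linkage hierarchical
#' clustering on the distance `1 - r` (ties between merge heights resolved by
#' the deterministic lexicographic order of `hclust`).
#'
#' @param samples Long tibble `time_s, replicate, variable, value` of
#'   per-replicate metabolite amounts and/or traits.
#' @param an Tibble `time_s, An` giving the assimilation rate attached to
#'   every sample of that time point, or `NULL` to omit `An`.
#' @param exclude_time_zero Drop the pre-transition samples (default `TRUE`).
#' @param alpha Significance level for the mask (default 0.05).
#' @return List of class `correlation_result`: `r`, `p` (matrices),
#'   `significant` (logical mask at `alpha`), `cluster_order` (variable
#'   permutation), `n` (samples used per pair), `alpha`.
#' @export
correlate_with_an <- function(samples, an = NULL, exclude_time_zero = TRUE,
                              alpha = 0.05) {
  wide <- samples_wide_with_an(samples, an, exclude_time_zero)
  mat <- as.matrix(wide[, setdiff(names(wide), c("time_s", "replicate"))])
  if (nrow(mat) < 4L) stop_c4("need >= 4 samples for correlations")
  vars <- colnames(mat)
  k <- length(vars)
  r <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1
  diag(p) <- 0
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      ok <- complete.cases(mat[, i], mat[, j])
      if (sum(ok) < 4L) next
      x <- mat[ok, i]
      y <- mat[ok, j]
      if (sd(x) == 0 || sd(y) == 0) next # constant variable: missing-flagged
      ct <- cor.test(x, y, method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  # average-linkage clustering on 1 - r; missing correlations get the
  # maximal distance so flagged variables cluster last
  d <- 1 - r
  d[is.na(d)] <- 2
  hc <- hclust(as.dist(d), method = "average")
  structure(
    list(
      r = r, p = p,
      significant = !is.na(p) & p < alpha & row(p) != col(p),
      cluster_order = vars[hc$order],
      hclust = hc,
      n = nrow(mat), alpha = alpha
    ),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  k <- ncol(x$r)
  n_sig <- sum(x$significant[upper.tri(x$significant)], na.rm = TRUE)
  cat(sprintf(
    "<correlation_result> %d variables, %d samples; %d/%d pairs significant at alpha = %g\n",
    k, x$n, n_sig, k * (k - 1) / 2, x$alpha
  ))
  invisible(x)
}

#' Time-zero and segment t-tests on a metabolite panel
#'
#' Two-sided unequal-variance (Welch) t-tests of each metabolite at each
#' post-transition time point against time zero, plus, for each phase
#' segment, a test of the samples at the segment end against those at the
#' segment start. No multiple-testing correction is applied by default,
#' matching the star conventions of the source analyses (`p_adjust = "BH"`
#' switches on Benjamini-Hochberg).
#'
#' @param panel A `metabolite_panel`.
#' @param segments A [phase_segmentation()] or `NULL` for time-zero tests
#'   only.
#' @param p_adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return Tidy tibble `metabolite, comparison, time_s, statistic, p, stars`;
#'   groups with fewer than 2 finite values yield `NA` (missing-flagged).
#' @export
segment_tests <- function(panel, segments = NULL, p_adjust = "none") {
  wide <- tibble::as_tibble(panel)
  mets <- unique(wide$metabolite)
  times <- sort(unique(wide$time_s))
  get_vals <- function(met, tp) {
    v <- wide$amount_nmol_gFW[wide$metabolite == met & wide$time_s == tp]
    v[is.finite(v)]
  }
  run_test <- function(a, b) {
    if (length(a) < 2L || length(b) < 2L || (sd(a) == 0 && sd(b) == 0)) {
      return(c(NA_real_, NA_real_))
    }
    tt <- t.test(a, b, var.equal = FALSE)
    c(unname(tt$statistic), tt$p.value)
  }
  rows <- list()
  for (met in mets) {
    base <- get_vals(met, 0)
    for (tp in setdiff(times, 0)) {
      res <- run_test(get_vals(met, tp), base)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        metabolite = met, comparison = "vs_time_zero", time_s = tp,
        statistic = res[1], p = res[2]
      )
    }
    if (!is.null(segments)) {
      for (i in seq_len(nrow(segments))) {
        t0 <- segments$t_start[i]
        t1 <- segments$t_end[i]
        in_seg <- times[times >= t0 & times <= t1]
        if (length(in_seg) < 2L) next
        res <- run_test(get_vals(met, max(in_seg)), get_vals(met, min(in_seg)))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          metabolite = met,
          comparison = paste0("segment_", t0, "_", t1),
          time_s = max(in_seg),
          statistic = res[1], p = res[2]
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (p_adjust != "none") out$p <- stats::p.adjust(out$p, method = p_adjust)
  out$stars <- stars_for_p(out$p)
  out
}

#' Paired t-test for the slow recovery of assimilation
#'
#' For each replicate trace, averages `An` over two windows (by default
#' 250-259 s, around the trough, and 1791-1800 s, the end of the transition)
#' and runs a paired two-sided t-test of the window means. Replicates not
#' covering both windows are dropped with a warning; fewer than 3 remaining
#' replicates is an error.
#'
#' @param traces List of `gas_exchange_trace` objects (one per replicate).
#' @param window_a,window_b Length-2 numeric windows, s.
#' @return Tidy one-row tibble `n, mean_a, mean_b, mean_diff, statistic, p,
#'   stars`.
#' @export
paired_recovery_test <- function(traces, window_a = c(250, 259),
                                 window_b = c(1791, 1800)) {
  win_mean <- function(tr, w) {
    sel <- tr$time_s >= w[1] & tr$time_s <= w[2]
    if (!any(sel)) return(NA_real_)
    mean(tr$An[sel])
  }
  a <- vapply(traces, win_mean, numeric(1), w = window_a)
  b <- vapply(traces, win_mean, numeric(1), w = window_b)
  ok <- is.finite(a) & is.finite(b)
  if (any(!ok)) {
    warning(sum(!ok), " replicate(s) dropped: window outside trace",
            call. = FALSE)
  }
  if (sum(ok) < 3L) stop_c4("need >= 3 replicates covering both windows")
  d <- b[ok] - a[ok]
  if (sd(d) == 0) {
    # degenerate but well-defined: identical shifts in every replicate
    stat <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
    pval <- if (mean(d) == 0) 1 else 0
  } else {
    tt <- t.test(b[ok], a[ok], paired = TRUE)
    stat <- unname(tt$statistic)
    pval <- tt$p.value
  }
  tibble::tibble(
    n = sum(ok),
    mean_a = mean(a[ok]), mean_b = mean(b[ok]),
    mean_diff = mean(d),
    statistic = stat, p = pval,
    stars = stars_for_p(pval)
  )
}

#' Linear regression of a variable on the assimilation rate
#'
#' Ordinary least squares of one metabolite or trait on `An` across
#' individual samples, time zero excluded, optionally restricted to a time
#' sub-range (e.g. 300-1800 s to isolate the slow recovery).
#'
#' @param samples Long tibble `time_s, replicate, variable, value`.
#' @param variable Name of the variable to regress.
#' @param an Tibble `time_s, An`.
#' @param time_range Optional length-2 numeric, s (inclusive).
#' @param exclude_time_zero Drop time-zero samples (default `TRUE`).
#' @return One-row tibble `variable, n, slope, slope_sign, r2, p`.
#' @export
regress_vs_an <- function(samples, variable, an, time_range = NULL,
                          exclude_time_zero = TRUE) {
  dat <- dplyr::filter(samples, .data$variable == !!variable)
  if (!nrow(dat)) stop_c4("variable `", variable, "` not found in samples")
  if (exclude_time_zero) dat <- dplyr::filter(dat, .data$time_s != 0)
  if (!is.null(time_range)) {
    dat <- dplyr::filter(dat, .data$time_s >= time_range[1],
                         .data$time_s <= time_range[2])
  }
  dat$An <- an$An[match(dat$time_s, an$time_s)]
  dat <- dat[complete.cases(dat$An, dat$value), ]
  if (nrow(dat) < 4L) stop_c4("need >= 4 samples for a regression")
  if (sd(dat$An) == 0) stop_c4("`An` is constant over the selected samples")
  fit <- lm(value ~ An, data = dat)
  sm <- summary(fit)
  slope <- coef(fit)[["An"]]
  tibble::tibble(
    variable = variable, n = nrow(dat),
    slope = slope,
    slope_sign = ifelse(slope >= 0, "positive", "negative"),
    r2 = sm$r.squared,
    p = sm$coefficients["An", "Pr(>|t|)"]
  )
}
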