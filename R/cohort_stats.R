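# Per-subject analysis across the four fitting techniques and cohort-level
# comparison: percentage changes between techniques, ANOVA with Tukey's
# post-hoc test across techniques, and paired t-tests between measured- and
# excess-derived wave intensity parameters. This stage is deliberately thin
# and delegates the inference to the standard stats routines; the substance
# of the package lies upstream in the decomposition.

#' Percentage change between two values
#'
#' `100 * (after - before) / before`, the convention used throughout the
#' cohort comparisons (e.g. "3 DOF to 2 DOF" means `before` is the 3-DOF
#' value).
#'
#' @param before,after numeric values; `before` must be non-zero.
#' @return percentage change.
#' @examples
#' percent_change(2.0, 1.24)  # -38
#' @export
percent_change <- function(before, after) {
  if (any(before == 0)) stop("'before' must be non-zero", call. = FALSE)
  100 * (after - before) / before
}

#' Analyse one subject under all fitting techniques
#'
#' Runs the full reservoir-wave pipeline on a single aligned beat pair for
#' each supplied fitting configuration: diastolic decay fit, systolic rate
#' solve, pressure and velocity decomposition, scalar hemodynamic parameters,
#' and wave intensity analysis on both measured and excess waveforms.
#'
#' @param P,U aligned single-beat pressure and velocity [waveform]s.
#' @param annotation a [beat_annotation] (detected with
#'   [detect_dicrotic_notch()] if omitted).
#' @param configs named list of [fit_config]s; default the four standard
#'   techniques.
#' @param rho blood density (kg/m^3); default 1050.
#' @param sg_window Savitzky-Golay window (samples) applied before the wave
#'   intensity analysis; default 9 (40 ms at 200 Hz). `NULL` disables
#'   smoothing.
#' @param subject_id optional identifier carried into the record.
#' @return an object of class `subject_record`: per-config list with elements
#'   `fit` (`reservoir_fit`), `split` (`velocity_split`), `params`
#'   (`hemodynamic_params`) and `wia_cmp` (from
#'   [compare_measured_vs_excess()]), plus `subject_id` and `annotation`.
#' @export
analyze_subject <- function(P, U, annotation = NULL,
                            configs = standard_fit_configs(),
                            rho = 1050, sg_window = 9L, subject_id = NA) {
  if (is.null(annotation)) annotation <- detect_dicrotic_notch(P)
  per_config <- lapply(configs, function(cf) {
    fit <- decompose_pressure(P, annotation, cf)
    Rbar <- mean_diastolic_resistance(P, U, annotation, fit$Pinf)
    split <- decompose_velocity(P, U, fit$Pinf, Rbar)
    params <- hemodynamic_params(fit, split, annotation)
    wia_cmp <- tryCatch(
      compare_measured_vs_excess(P, U, fit$Pex, split$Uex, annotation,
                                 rho = rho, sg_window = sg_window),
      error = function(e) NULL)
    list(fit = fit, split = split, params = params, wia_cmp = wia_cmp)
  })
  structure(list(subject_id = subject_id, annotation = annotation,
                 configs = per_config),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record: %s, %d fitting configs>\n",
              format(x$subject_id), length(x$configs)))
  invisible(x)
}

# scalar parameters extracted per config for the cohort table
record_row <- function(rec, config_name) {
  pc <- rec$configs[[config_name]]
  p <- pc$params
  out <- data.frame(
    subject_id = rec$subject_id, config = config_name,
    converged = pc$fit$converged,
    a = p$a, b = p$b, Pinf = p$Pinf, Pn_bar = p$Pn_bar,
    Prmax = p$Prmax, Pexmax = p$Pexmax, PRI = p$PRI, PEI = p$PEI,
    Urmax = p$Urmax, Uexmax = p$Uexmax, X2 = p$X2,
    stringsAsFactors = FALSE)
  if (!is.null(pc$wia_cmp)) {
    out$c_pu <- pc$wia_cmp$measured$c
    out$c_ex <- pc$wia_cmp$excess$c
    out$FCW_pu <- pc$wia_cmp$measured$FCW_area
    out$FCW_ex <- pc$wia_cmp$excess$FCW_area
    out$BCW_pu <- pc$wia_cmp$measured$BCW_area
    out$BCW_ex <- pc$wia_cmp$excess$BCW_area
    out$FEW_pu <- pc$wia_cmp$measured$FEW_area
    out$FEW_ex <- pc$wia_cmp$excess$FEW_area
  } else {
    out[c("c_pu", "c_ex", "FCW_pu", "FCW_ex", "BCW_pu", "BCW_ex",
          "FEW_pu", "FEW_ex")] <- NA_real_
  }
  out
}

#' Long-format cohort parameter table
#'
#' @param records list of `subject_record`s.
#' @return data frame with one row per (subject, config) and one column per
#'   scalar parameter.
#' @export
cohort_table <- function(records) {
  stopifnot(length(records) >= 1L)
  rows <- list()
  for (rec in records)
    for (nm in names(rec$configs))
      rows[[length(rows) + 1L]] <- record_row(rec, nm)
  do.call(rbind, rows)
}

#' Summarise a cohort across fitting techniques
#'
#' Computes per-parameter, per-configuration means and SDs; percentage changes
#' of the configuration means along the two design axes (3 DOF to 2 DOF
#' within each window; whole window to last-two-thirds within each DOF);
#' one-way ANOVA with Tukey's post-hoc test across the four configurations
#' for every parameter; and paired two-tailed t-tests between measured- and
#' excess-derived wave intensity parameters within each configuration.
#' Non-converged fits are excluded listwise per configuration, with the
#' exclusion count reported.
#'
#' @param records list of `subject_record`s (at least 3).
#' @param alpha significance level for the flags; default 0.05.
#' @return an object of class `cohort_summary`: list with `table` (the long
#'   per-subject table), `means` (parameter x config matrix of means), `sds`,
#'   `pct_change` (data frame of the design-axis percentage changes with
#'   Tukey-adjusted p-values and significance flags), `wia_paired` (paired
#'   t-test results, PU vs excess), `anova_p` (per-parameter ANOVA p-value),
#'   `n_excluded` and `alpha`.
#' @export
summarize_cohort <- function(records, alpha = 0.05) {
  if (length(records) < 3L)
    stop("need at least 3 complete subject records", call. = FALSE)
  tab <- cohort_table(records)
  n_excluded <- sum(!tab$converged)
  tab_ok <- tab[tab$converged, , drop = FALSE]
  pars <- c("a", "b", "Pinf", "Pn_bar", "Prmax", "Pexmax", "PRI", "PEI",
            "Urmax", "Uexmax", "X2", "c_ex", "FCW_ex", "BCW_ex", "FEW_ex")
  cfgs <- unique(tab$config)   # config order fixed by the records themselves
  means <- sapply(cfgs, function(cf)
    vapply(pars, function(p) mean(tab_ok[tab_ok$config == cf, p],
                                  na.rm = TRUE), numeric(1)))
  sds <- sapply(cfgs, function(cf)
    vapply(pars, function(p) stats::sd(tab_ok[tab_ok$config == cf, p],
                                       na.rm = TRUE), numeric(1)))

  anova_p <- rep(NA_real_, length(pars)); names(anova_p) <- pars
  tukey <- list()
  for (p in pars) {
    vals <- tab_ok[[p]]
    grp <- factor(tab_ok$config)
    if (length(unique(stats::na.omit(vals))) < 2L) next   # degenerate cohort
    fit <- stats::aov(vals ~ grp)
    anova_p[p] <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    tukey[[p]] <- stats::TukeyHSD(fit)$grp
  }

  axis_pairs <- list(
    c("3dof_whole", "2dof_whole"), c("3dof_last23", "2dof_last23"),
    c("3dof_whole", "3dof_last23"), c("2dof_whole", "2dof_last23"))
  pc_rows <- list()
  for (p in pars) {
    for (pr in axis_pairs) {
      if (!all(pr %in% cfgs)) next
      before <- means[p, pr[1L]]; after <- means[p, pr[2L]]
      pc <- if (is.finite(before) && before != 0)
        percent_change(before, after) else NA_real_
      padj <- NA_real_
      if (!is.null(tukey[[p]])) {
        key1 <- paste(pr[2L], pr[1L], sep = "-")
        key2 <- paste(pr[1L], pr[2L], sep = "-")
        rn <- rownames(tukey[[p]])
        hit <- match(key1, rn); if (is.na(hit)) hit <- match(key2, rn)
        if (!is.na(hit)) padj <- tukey[[p]][hit, "p adj"]
      }
      pc_rows[[length(pc_rows) + 1L]] <- data.frame(
        parameter = p, from = pr[1L], to = pr[2L],
        pct_change = pc, p_adj = padj,
        significant = !is.na(padj) && padj < alpha,
        stringsAsFactors = FALSE)
    }
  }
  pct_change <- do.call(rbind, pc_rows)

  wia_pairs <- list(c = c("c_pu", "c_ex"), FCW = c("FCW_pu", "FCW_ex"),
                    BCW = c("BCW_pu", "BCW_ex"), FEW = c("FEW_pu", "FEW_ex"))
  wp_rows <- list()
  for (cf in cfgs) {
    sub <- tab_ok[tab_ok$config == cf, , drop = FALSE]
    for (nm in names(wia_pairs)) {
      x <- sub[[wia_pairs[[nm]][1L]]]; y <- sub[[wia_pairs[[nm]][2L]]]
      ok <- stats::complete.cases(x, y)
      pval <- NA_real_
      if (sum(ok) >= 3L && stats::sd(x[ok] - y[ok]) > 0)
        pval <- stats::t.test(x[ok], y[ok], paired = TRUE)$p.value
      pct <- if (sum(ok) > 0L && is.finite(mean(y[ok])) && mean(y[ok]) != 0)
        percent_change(mean(y[ok]), mean(x[ok])) else NA_real_
      wp_rows[[length(wp_rows) + 1L]] <- data.frame(
        config = cf, parameter = nm, pct_pu_vs_ex = pct, p_value = pval,
        significant = !is.na(pval) && pval < alpha,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(table = tab, means = means, sds = sds,
                 pct_change = pct_change,
                 wia_paired = do.call(rbind, wp_rows),
                 anova_p = anova_p, n_excluded = n_excluded, alpha = alpha),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary: %d rows, %d non-converged excluded, alpha = %g>\n",
              nrow(x$table), x$n_excluded, x$alpha))
  cat("\nMean percentage changes along the design axes:\n")
  print(utils::head(x$pct_change, 12L), row.names = FALSE)
  cat("\nPU- vs excess-derived wave intensity (percentage difference):\n")
  print(x$wia_paired, row.names = FALSE)
  invisible(x)
}
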