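# Dual-stain live/dead quantification, growth-inhibition dose-response with
# 4PL IC50 fitting, and cytostatic-vs-cytotoxic mechanism classification.

#' Quantify live and dead cells in one well
#'
#' Dead cells are PI-gate positives. Live cells are either calcein-gate
#' positives (`live_mode = "calcein_gate"`; a cell positive for both stains
#' is counted dead — PI dominance — and tallied in `qc_double_positive`) or
#' total minus dead (`live_mode = "hoechst_subtraction"`, where the
#' partition live + dead = total holds exactly).
#'
#' @param cells cell table for the well.
#' @param pi_gate [define_gate()] object on the PI channel.
#' @param live_mode `"hoechst_subtraction"` or `"calcein_gate"`.
#' @param calcein_gate gate on the calcein channel (required for
#'   `"calcein_gate"` mode).
#' @param min_cells wells with fewer cells are flagged (`low_cell_count`)
#'   with a warning.
#' @return object of class `well_viability`: `n_dead`, `n_live`, `n_total`,
#'   `percent_dead`, `qc_double_positive`, `flags`.
#' @export
quantify_live_dead <- function(cells, pi_gate,
                               live_mode = c("hoechst_subtraction", "calcein_gate"),
                               calcein_gate = NULL, min_cells = 100) {
  live_mode <- match.arg(live_mode)
  n_total <- nrow(cells)
  if (n_total == 0L) stopf("empty cell table")
  dead <- gate_positive(cells, pi_gate)
  qc_double <- 0L
  if (live_mode == "calcein_gate") {
    if (is.null(calcein_gate)) stopf("calcein_gate required for live_mode = 'calcein_gate'")
    cal <- gate_positive(cells, calcein_gate)
    qc_double <- sum(cal & dead)
    n_live <- sum(cal & !dead)
  } else {
    n_live <- n_total - sum(dead)
  }
  flags <- character(0)
  if (n_total < min_cells) {
    flags <- "low_cell_count"
    warnf("only %d cells in well (min %d): viability statistics flagged",
          n_total, min_cells)
  }
  out <- list(n_dead = sum(dead), n_live = n_live, n_total = n_total,
              percent_dead = 100 * sum(dead) / n_total,
              qc_double_positive = qc_double,
              live_mode = live_mode, flags = flags)
  class(out) <- "well_viability"
  out
}

#' @export
print.well_viability <- function(x, ...) {
  cat(sprintf("well viability: %d total, %d dead (%.1f%%), %d live [%s]\n",
              x$n_total, x$n_dead, x$percent_dead, x$n_live, x$live_mode))
  invisible(x)
}

#' Growth percentage relative to untreated controls
#'
#' `100 * total cells (live + dead) / mean total cells of untreated wells`.
#'
#' @param treated a `well_viability` object or a bare total cell count.
#' @param untreated_mean_total mean total cell count of untreated wells.
#' @return growth percentage.
#' @export
growth_percent <- function(treated, untreated_mean_total) {
  n <- if (inherits(treated, "well_viability")) treated$n_total else treated
  if (untreated_mean_total <= 0) stopf("untreated mean total must be positive")
  100 * n / untreated_mean_total
}

# 4PL growth curve in concentration, parameterised by log10(ec50)
fourPL <- function(conc, top, bottom, log_ec50, hill) {
  bottom + (top - bottom) / (1 + (conc / 10^log_ec50)^hill)
}

#' Fit a four-parameter logistic dose-response and extract the IC50
#'
#' Fits growth percentage against log10 concentration with a 4PL curve
#' (top constrained <= 110, bottom >= -10, Hill slope free), using
#' Levenberg-Marquardt least squares. The zero-concentration wells anchor
#' the normalisation to 100% but are excluded from the log-scale fit. The
#' IC50 is the concentration at which the *fitted* curve crosses 50% growth;
#' when the curve never reaches 50% within the tested range the result is
#' reported as a bound (`"> cmax"`) and flagged as extrapolated.
#'
#' @param concentrations concentration per observation (uM); replicates are
#'   separate observations. May include 0 (ignored in the fit).
#' @param growth_percents growth percentage per observation.
#' @param percent_dead optional percent-dead per observation, used to
#'   evaluate the mechanism class at the reference concentration.
#' @param reference `"nearest_ic50"` (tested concentration closest to the
#'   fitted IC50 on the log scale) or a fixed concentration (uM).
#' @param monotone_tol warn when mean growth increases with concentration
#'   by more than this many percentage points (noise tolerance).
#' @return object of class `dose_response`: per-concentration mean growth,
#'   fitted parameters (`top`, `bottom`, `ec50`, `hill`), `ic50`,
#'   `ic50_label`, `extrapolated`, and — when `percent_dead` is given —
#'   `reference_concentration`, `percent_dead_at_reference`,
#'   `mechanism_class`.
#' @export
fit_ic50 <- function(concentrations, growth_percents, percent_dead = NULL,
                     reference = "nearest_ic50", monotone_tol = 15) {
  stopifnot(length(concentrations) == length(growth_percents))
  keep <- concentrations > 0
  conc <- concentrations[keep]
  growth <- growth_percents[keep]
  if (length(unique(conc)) < 4L)
    stopf("need >= 4 distinct non-zero concentrations (got %d)", length(unique(conc)))
  means <- tapply(growth, conc, mean)
  cs <- as.numeric(names(means))
  ord <- order(cs)
  if (any(diff(as.numeric(means)[ord]) > monotone_tol))
    warnf("growth increases with concentration beyond %g points: check data", monotone_tol)
  # multi-start Levenberg-Marquardt: midpoint start from the concentration
  # nearest the half-way response plus the log-range quartiles, crossed with
  # a few Hill slopes; keep the lowest-RSS fit
  mid0 <- log10(cs[ord][which.min(abs(as.numeric(means)[ord] -
                                        (max(growth) + min(growth)) / 2))])
  lo_c <- log10(min(conc)); hi_c <- log10(max(conc))
  starts <- expand.grid(hill = c(0.5, 1, 2, 4),
                        log_ec50 = unique(c(mid0, lo_c + (hi_c - lo_c) * c(0.25, 0.5, 0.75))))
  fit <- NULL
  last_err <- NULL
  for (k in seq_len(nrow(starts))) {
    cand <- tryCatch(
      minpack.lm::nlsLM(growth ~ fourPL(conc, top, bottom, log_ec50, hill),
                        start = list(top = min(110, max(growth)),
                                     bottom = max(-10, min(growth)),
                                     log_ec50 = starts$log_ec50[k],
                                     hill = starts$hill[k]),
                        lower = c(top = -10, bottom = -10,
                                  log_ec50 = lo_c - 3, hill = 0.05),
                        upper = c(top = 110, bottom = 110,
                                  log_ec50 = hi_c + 3, hill = 20),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) { last_err <<- conditionMessage(e); NULL })
    if (!is.null(cand) &&
        (is.null(fit) || sum(stats::resid(cand)^2) < sum(stats::resid(fit)^2)))
      fit <- cand
  }
  if (is.null(fit))
    stopf("4PL fit did not converge from any start (last error: %s)", last_err)
  cf <- as.list(stats::coef(fit))
  ec50 <- 10^cf$log_ec50
  cmax <- max(conc)
  # concentration where the fitted curve equals 50% growth
  ic50 <- NA_real_
  if (cf$top > 50 && cf$bottom < 50) {
    ratio <- (cf$top - cf$bottom) / (50 - cf$bottom) - 1
    if (ratio > 0) ic50 <- ec50 * ratio^(1 / cf$hill)
  }
  extrapolated <- is.na(ic50) || ic50 > cmax
  ic50_label <- if (extrapolated) paste0("> ", format(cmax)) else format(signif(ic50, 4))
  res <- list(concentrations = cs[ord],
              growth_percent = as.numeric(means)[ord],
              top = cf$top, bottom = cf$bottom, ec50 = ec50, hill = cf$hill,
              ic50 = ic50, ic50_label = ic50_label, extrapolated = extrapolated,
              fit = fit)
  if (!is.null(percent_dead)) {
    pd <- percent_dead[keep]
    pd_means <- tapply(pd, conc, mean, na.rm = TRUE)
    ref_conc <- if (identical(reference, "nearest_ic50")) {
      target <- if (!is.na(ic50)) ic50 else cmax
      cs[which.min(abs(log10(cs) - log10(target)))]
    } else as.numeric(reference)
    pd_ref <- as.numeric(pd_means[which.min(abs(log10(cs) - log10(ref_conc)))])
    res$reference_concentration <- ref_conc
    res$percent_dead_at_reference <- pd_ref
    res$mechanism_class <- classify_mechanism(pd_ref)
  }
  class(res) <- "dose_response"
  res
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("dose-response: IC50 %s uM (4PL top %.1f, bottom %.1f, hill %.2f)\n",
              x$ic50_label, x$top, x$bottom, x$hill))
  if (!is.null(x$mechanism_class))
    cat(sprintf("  %% dead at %.3g uM: %.1f -> %s\n", x$reference_concentration,
                x$percent_dead_at_reference, x$mechanism_class))
  invisible(x)
}

MECHANISM_CLASSES <- c("primarily cytostatic", "cytostatic >= cytotoxic",
                       "cytostatic <= cytotoxic", "mainly cytotoxic")

#' Classify a drug's mechanism from the percent of dead cells
#'
#' Four-bin step function of the percent dead at the reference
#' concentration: below 30% the growth inhibition is primarily cytostatic;
#' 30-50% cytostatic >= cytotoxic; 50-70% cytostatic <= cytotoxic; 70% and
#' above mainly cytotoxic. Lower bin bounds are closed (30 falls in the
#' second bin, 50 in the third, 70 in the fourth).
#'
#' @param percent_dead_at_reference percent dead in `[0, 100]` (vectorised).
#' @return factor with the four ordered mechanism classes.
#' @export
classify_mechanism <- function(percent_dead_at_reference) {
  x <- percent_dead_at_reference
  if (any(!is.finite(x)) || any(x < 0 | x > 100))
    stopf("percent dead must lie in [0, 100]")
  cut(x, breaks = c(-Inf, 30, 50, 70, Inf), right = FALSE,
      labels = MECHANISM_CLASSES)
}

#' Dose-response analysis of a simulated or measured plate
#'
#' Computes per-well viability and growth, then fits the 4PL curve and
#' classifies the mechanism. Expects a per-well cell-table list and a
#' layout with `well_id`, `concentration_uM`, `replicate`.
#'
#' @param cell_tables named list of cell tables, names matching
#'   `layout$well_id`.
#' @param layout data.frame with `well_id`, `concentration_uM`, `replicate`.
#' @param pi_gate gate on the PI channel.
#' @param live_mode passed to [quantify_live_dead()].
#' @param min_cells passed to [quantify_live_dead()].
#' @return a `dose_response` object (see [fit_ic50()]) plus a `wells`
#'   data.frame of per-well counts.
#' @export
plate_dose_response <- function(cell_tables, layout, pi_gate,
                                live_mode = "hoechst_subtraction",
                                min_cells = 10) {
  stopifnot(all(layout$well_id %in% names(cell_tables)))
  rows <- lapply(seq_len(nrow(layout)), function(i) {
    wid <- layout$well_id[i]
    if (nrow(cell_tables[[wid]]) == 0L) {
      # fully suppressed well: no cells segmented
      return(data.frame(well_id = wid, concentration_uM = layout$concentration_uM[i],
                        replicate = layout$replicate[i], n_total = 0L,
                        n_dead = 0L, percent_dead = NA_real_))
    }
    v <- quantify_live_dead(cell_tables[[wid]], pi_gate, live_mode = live_mode,
                            min_cells = min_cells)
    data.frame(well_id = wid, concentration_uM = layout$concentration_uM[i],
               replicate = layout$replicate[i], n_total = v$n_total,
               n_dead = v$n_dead, percent_dead = v$percent_dead)
  })
  wells <- do.call(rbind, rows)
  untreated <- wells$concentration_uM == 0
  if (!any(untreated)) stopf("no untreated (concentration 0) well in layout")
  base_total <- mean(wells$n_total[untreated])
  wells$growth_percent <- growth_percent(wells$n_total, base_total)
  res <- fit_ic50(wells$concentration_uM, wells$growth_percent,
                  percent_dead = wells$percent_dead)
  res$wells <- wells
  res
}
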