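# DNA-content cell-cycle analysis: histogram-based G1/G2 peak detection,
# window-based phase calling, and marker-by-phase cross-tabulation.

PHASES <- c("sub-G1", "G0/G1", "S", "G2/M", ">4N")

#' Fit a DNA-content histogram
#'
#' Locates the G0/G1 (2N) and G2/M (4N) peaks of the per-nucleus Hoechst
#' integrated-intensity distribution and derives closed phase windows
#' around them. The G1 peak is the leftmost prominent mode (at least 10% of
#' the tallest) of the kernel-smoothed histogram, so G2/M-arrested
#' populations keep their 2N anchor; the G2 peak is the strongest local mode between 1.6 and 2.4
#' times the G1 peak, falling back to exactly 2 x G1 (flagged) when no mode
#' exists there. Windows are `peak * (1 +/- window_halfwidth_frac)`; values
#' between the two windows are S phase, below the G1 window sub-G1, above
#' the G2 window >4N. The fit is flagged when the detected G2 peak falls
#' outside [1.8, 2.2] x G1.
#'
#' @param hoechst_intensities per-nucleus integrated DNA signal (a.u.).
#' @param bins number of histogram bins.
#' @param window_halfwidth_frac half-width of each phase window as a
#'   fraction of its peak position.
#' @param min_cells minimum number of cells required for a fit.
#' @param smooth_bins sd, in bins, of the Gaussian kernel used to smooth
#'   the histogram counts before mode detection.
#' @param s_bridge_correction correct the reported phase *fractions* for
#'   the S-phase plateau that runs underneath the G1 and G2 windows: its
#'   density is estimated from the inter-window gap and the corresponding
#'   mass reallocated from G0/G1 and G2/M to S (mass-conserving).
#'   Per-cell calls by [assign_phase()] are always the plain window
#'   lookup; only the summary fractions are corrected.
#' @return object of class `cell_cycle_fit`: `g1_peak`, `g2_peak`,
#'   `g1_window`, `g2_window`, `fractions` over
#'   sub-G1 / G0/G1 / S / G2/M / >4N, and `flags`.
#' @export
fit_dna_histogram <- function(hoechst_intensities, bins = 256,
                              window_halfwidth_frac = 0.15,
                              min_cells = 200, smooth_bins = 2,
                              s_bridge_correction = TRUE) {
  x <- hoechst_intensities[is.finite(hoechst_intensities)]
  if (length(x) < min_cells)
    stopf("need at least %d cells for a DNA-content fit (got %d)", min_cells, length(x))
  flags <- character(0)
  if (diff(range(x)) == 0) {
    g1 <- x[1]
    g2 <- 2 * g1
    flags <- "degenerate_distribution"
  } else {
    h <- graphics::hist(x, breaks = seq(min(x), max(x), length.out = bins + 1),
                        plot = FALSE)
    sm <- smooth_counts(h$counts, smooth_bins)
    # G1 = leftmost prominent mode (>= 10% of the tallest), so a
    # G2/M-arrested population with a dominant 4N peak is still anchored on
    # its 2N peak; plain argmax would misread the 4N peak as G1
    prominent <- which(local_maxima(sm) & sm >= 0.1 * max(sm))
    g1 <- h$mids[prominent[1]]
    in_win <- which(h$mids >= 1.6 * g1 & h$mids <= 2.4 * g1)
    g2 <- NA_real_
    if (length(in_win)) {
      modes <- in_win[local_maxima(sm)[in_win]]
      if (length(modes)) g2 <- h$mids[modes[which.max(sm[modes])]]
    }
    if (is.na(g2)) {
      g2 <- 2 * g1
      flags <- c(flags, "g2_fallback_2x")
    }
  }
  if (g2 < 1.8 * g1 || g2 > 2.2 * g1)
    flags <- c(flags, "g2_peak_outside_1.8_2.2_x_g1")
  w <- window_halfwidth_frac
  g1_win <- c(g1 * (1 - w), g1 * (1 + w))
  g2_win <- c(g2 * (1 - w), g2 * (1 + w))
  if (g1_win[2] >= g2_win[1]) flags <- c(flags, "windows_overlap")
  fit <- list(g1_peak = g1, g2_peak = g2,
              g1_window = g1_win, g2_window = g2_win,
              window_halfwidth_frac = w,
              bins = bins, n_cells = length(x),
              flags = flags)
  class(fit) <- "cell_cycle_fit"
  fit$s_bridge_correction <- isTRUE(s_bridge_correction)
  fit$fractions <- phase_fractions_of(x, fit, fit$s_bridge_correction)
  fit
}

# Gaussian smoothing of histogram counts; kernel sd in bins, zero -> identity.
smooth_counts <- function(counts, sd_bins) {
  if (sd_bins <= 0) return(counts)
  half <- max(1L, ceiling(3 * sd_bins))
  k <- stats::dnorm(-half:half, sd = sd_bins)
  k <- k / sum(k)
  n <- length(counts)
  padded <- c(rep(0, half), counts, rep(0, half))
  out <- stats::filter(padded, k, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

# logical vector: is position i a (weak) local maximum of v
local_maxima <- function(v) {
  n <- length(v)
  left <- c(-Inf, v[-n])
  right <- c(v[-1], -Inf)
  v >= left & v >= right & v > 0
}

phase_fractions_of <- function(x, fit, s_bridge_correction = TRUE) {
  phases <- assign_phase(x, fit)
  counts <- table(factor(phases, levels = PHASES))
  fr <- as.numeric(counts) / length(x)
  names(fr) <- PHASES
  if (s_bridge_correction) {
    # The S-phase DNA distribution is a plateau running from the G1 peak to
    # the G2 peak, so part of it falls inside the peak windows and would be
    # miscounted as G0/G1 or G2/M. Estimate the plateau density from the
    # inter-window gap and reallocate that mass back to S. Mass-conserving,
    # so fractions still sum to 1 exactly.
    gap_w <- fit$g2_window[1] - fit$g1_window[2]
    if (gap_w > 0) {
      dens <- fr[["S"]] / gap_w
      d1 <- min(dens * (fit$g1_window[2] - fit$g1_peak), fr[["G0/G1"]])
      d2 <- min(dens * (fit$g2_peak - fit$g2_window[1]), fr[["G2/M"]])
      fr[["G0/G1"]] <- fr[["G0/G1"]] - d1
      fr[["G2/M"]] <- fr[["G2/M"]] - d2
      fr[["S"]] <- fr[["S"]] + d1 + d2
    }
  }
  fr
}

#' @export
print.cell_cycle_fit <- function(x, ...) {
  cat(sprintf("cell_cycle_fit: G1 peak %.4g, G2 peak %.4g (ratio %.2f), windows +/- %.0f%%\n",
              x$g1_peak, x$g2_peak, x$g2_peak / x$g1_peak,
              100 * x$window_halfwidth_frac))
  print(round(100 * x$fractions, 1))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Plot a DNA-content histogram with its phase windows
#'
#' @param x a `cell_cycle_fit`.
#' @param intensities optional raw intensities to re-histogram.
#' @param ... passed to [graphics::hist()].
#' @export
plot.cell_cycle_fit <- function(x, intensities = NULL, ...) {
  if (!is.null(intensities)) {
    graphics::hist(intensities, breaks = x$bins, main = "DNA content",
                   xlab = "integrated Hoechst intensity (a.u.)", ...)
  } else {
    graphics::plot.new()
  }
  graphics::abline(v = c(x$g1_window, x$g2_window), lty = 2, col = "grey40")
  graphics::abline(v = c(x$g1_peak, x$g2_peak), col = c("red", "brown"))
  invisible(x)
}

#' Assign cell-cycle phases from DNA content
#'
#' Deterministic window lookup: values inside the closed G1 window are
#' G0/G1, inside the closed G2 window G2/M, strictly between the windows S,
#' below the G1 window sub-G1, above the G2 window >4N.
#'
#' @param intensity per-cell integrated Hoechst intensity (numeric vector).
#' @param fit a [fit_dna_histogram()] result.
#' @return character vector of phase labels.
#' @export
assign_phase <- function(intensity, fit) {
  stopifnot(inherits(fit, "cell_cycle_fit"))
  out <- rep("S", length(intensity))
  out[intensity < fit$g1_window[1]] <- "sub-G1"
  out[intensity >= fit$g1_window[1] & intensity <= fit$g1_window[2]] <- "G0/G1"
  out[intensity >= fit$g2_window[1] & intensity <= fit$g2_window[2]] <- "G2/M"
  out[intensity > fit$g2_window[2]] <- ">4N"
  out
}

#' Cross-tabulate marker positivity by cell-cycle phase
#'
#' Joint fractions over phase x marker status for one cell table, using the
#' table's Hoechst integrated intensity for phase calling and a gate for
#' positivity. Marginals are consistent with [percent_positive()] and with
#' the fit's phase fractions by construction.
#'
#' @param cells cell table with a `hoechst_integrated` column.
#' @param gate a [define_gate()] object for the marker channel.
#' @param fit a [fit_dna_histogram()] result.
#' @param three_phase_only renormalise over G0/G1, S and G2/M only
#'   (sub-G1 and >4N still reported, but excluded from the denominator).
#' @return object of class `marker_by_phase`: `joint` (2 x 5 fraction
#'   matrix, rows positive/negative), `phase_fractions`,
#'   `percent_positive`, `n_cells`.
#' @export
marker_by_phase <- function(cells, gate, fit, three_phase_only = FALSE) {
  if (nrow(cells) == 0L) stopf("empty cell table")
  if (!"hoechst_integrated" %in% names(cells))
    stopf("cell table has no 'hoechst_integrated' column")
  phase <- factor(assign_phase(cells$hoechst_integrated, fit), levels = PHASES)
  pos <- factor(ifelse(gate_positive(cells, gate), "positive", "negative"),
                levels = c("positive", "negative"))
  counts <- table(pos, phase)
  denom <- if (three_phase_only) sum(counts[, c("G0/G1", "S", "G2/M")]) else sum(counts)
  if (denom == 0L) stopf("no cells in the selected phases")
  joint <- counts / denom
  out <- list(joint = unclass(joint),
              phase_fractions = colSums(counts) / denom,
              percent_positive = 100 * sum(counts["positive", ]) / sum(counts),
              three_phase_only = three_phase_only,
              n_cells = nrow(cells))
  class(out) <- "marker_by_phase"
  out
}

#' @export
print.marker_by_phase <- function(x, ...) {
  cat(sprintf("marker-by-phase cross-tab over %d cells (%.1f%% positive)\n",
              x$n_cells, x$percent_positive))
  print(round(x$joint, 3))
  invisible(x)
}
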