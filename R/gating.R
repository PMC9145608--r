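# Flow-cytometry-like statistics on cell tables: control-anchored gates,
# % positive, fold changes, quadrant multiplexing, channel-overlap
# validation and replicate comparison.

#' Define a control-anchored gate on one channel
#'
#' The threshold is the empirical `q`-quantile of the integrated intensity of
#' the control cells (untreated, secondary-antibody-only; "CT") on that
#' channel. Cells strictly above the threshold are called positive, so a
#' degenerate control distribution gives 0% positive on the control itself.
#'
#' @param ct_cells cell table of pooled control wells.
#' @param channel channel name to gate on.
#' @param q quantile of the control distribution (default 0.99, i.e. a
#'   nominal 1% false-positive rate on control-like cells).
#' @param min_cells minimum control cells required.
#' @return object of class `gate`: channel, threshold (a.u.), `q`, number
#'   and identity of control cells used.
#' @export
define_gate <- function(ct_cells, channel, q = 0.99, min_cells = 100) {
  col <- int_col(channel)
  if (!col %in% names(ct_cells)) stopf("channel '%s' not present in cell table", channel)
  x <- ct_cells[[col]]
  if (length(x) < min_cells)
    stopf(paste0("only %d control cells for channel '%s' (need >= %d); ",
                 "pool additional CT wells"), length(x), channel, min_cells)
  g <- list(channel = channel,
            threshold = stats::quantile(x, q, names = FALSE),
            q = q,
            n_ct = length(x),
            source_wells = unique(as.character(ct_cells$well_id)))
  class(g) <- "gate"
  g
}

#' @export
print.gate <- function(x, ...) {
  cat(sprintf("gate on '%s': threshold %.4g a.u. (q = %g over %d CT cells)\n",
              x$channel, x$threshold, x$q, x$n_ct))
  invisible(x)
}

gate_positive <- function(cells, gate) {
  col <- int_col(gate$channel)
  if (!col %in% names(cells)) stopf("channel '%s' not present in cell table", gate$channel)
  cells[[col]] > gate$threshold   # strict: ties at the threshold are negative
}

#' Percent positive cells and mean intensity of positives
#'
#' @param cells cell table for one condition.
#' @param gate a [define_gate()] object.
#' @param condition condition label carried into the result.
#' @return object of class `marker_stats`: `condition`, `channel`,
#'   `n_cells`, `percent_positive`, and
#'   `mean_integrated_intensity_of_positives` (`NA` with `no_positives =
#'   TRUE` when nothing is gated in).
#' @export
percent_positive <- function(cells, gate, condition = NULL) {
  if (nrow(cells) == 0L) stopf("empty cell table")
  pos <- gate_positive(cells, gate)
  mii <- if (any(pos)) mean(cells[[int_col(gate$channel)]][pos]) else NA_real_
  s <- list(condition = condition %||% "unspecified",
            channel = gate$channel,
            n_cells = nrow(cells),
            percent_positive = 100 * mean(pos),
            mean_integrated_intensity_of_positives = mii,
            no_positives = !any(pos))
  class(s) <- "marker_stats"
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.marker_stats <- function(x, ...) {
  cat(sprintf("%s [%s]: %.1f%% positive of %d cells; mean intensity of positives %.4g\n",
              x$condition, x$channel, x$percent_positive, x$n_cells,
              x$mean_integrated_intensity_of_positives))
  invisible(x)
}

#' Fold change in percent positive, treated versus untreated
#'
#' Ratio of treated to untreated percent-positive (the marker-count fold
#' change). A zero untreated percentage is flagged with a warning and
#' returns `Inf` rather than failing silently.
#'
#' @param treated,untreated `marker_stats` objects (or bare percentages).
#' @return numeric ratio.
#' @export
fold_change <- function(treated, untreated) {
  pt <- if (inherits(treated, "marker_stats")) treated$percent_positive else treated
  pu <- if (inherits(untreated, "marker_stats")) untreated$percent_positive else untreated
  if (pu == 0) {
    warnf("untreated percent positive is 0: fold change undefined, returning Inf")
    return(Inf)
  }
  pt / pu
}

#' Quadrant analysis over 2-3 gated markers
#'
#' Assigns every cell to exactly one joint positivity combination (4 cells
#' for two markers, 8 for three) by the strict-threshold rule of each gate,
#' and reports the fraction of cells per combination plus the marginal
#' percent positive per marker.
#'
#' @param cells cell table.
#' @param gates list of [define_gate()] objects over distinct channels.
#' @return object of class `quadrant_result`: `combinations` (data.frame
#'   with one logical column per marker, `n` and `fraction`) and
#'   `marginals` (named percent-positive vector).
#' @export
quadrant_analysis <- function(cells, gates) {
  if (nrow(cells) == 0L) stopf("empty cell table")
  chans <- vapply(gates, function(g) g$channel, character(1))
  if (anyDuplicated(chans)) stopf("duplicate channels in gate set: %s",
                                  paste(chans[duplicated(chans)], collapse = ", "))
  pos <- vapply(gates, function(g) gate_positive(cells, g), logical(nrow(cells)))
  pos <- matrix(pos, nrow = nrow(cells), dimnames = list(NULL, chans))
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), length(chans)))
  names(combos) <- chans
  key <- apply(pos, 1, function(r) paste(ifelse(r, "+", "-"), collapse = ""))
  combo_key <- apply(combos, 1, function(r) paste(ifelse(r, "+", "-"), collapse = ""))
  counts <- table(factor(key, levels = combo_key))
  res <- cbind(combos,
               n = as.integer(counts),
               fraction = as.numeric(counts) / nrow(cells))
  rownames(res) <- combo_key
  out <- list(combinations = res,
              marginals = 100 * colMeans(pos),
              n_cells = nrow(cells))
  class(out) <- "quadrant_result"
  out
}

#' @export
print.quadrant_result <- function(x, ...) {
  cat(sprintf("quadrant analysis over %d cells, markers: %s\n", x$n_cells,
              paste(names(x$marginals), collapse = ", ")))
  print(x$combinations[, c("n", "fraction")])
  invisible(x)
}

#' Validate the absence of fluorescence overlap between channels
#'
#' For each single-stained control table (stained for exactly one marker),
#' computes the percent positive in every *other* marker's channel. The
#' check passes when every off-target percentage is at most `tolerance`
#' (default: the gates' nominal false-positive rate, `100 * (1 - q)`, plus
#' 2 percentage points).
#'
#' @param single_stain_tables named list of cell tables, one per marker,
#'   names matching gate channels.
#' @param gates list of [define_gate()] objects (one per marker).
#' @param tolerance maximal admissible off-target percent positive.
#' @return data.frame report (`stained_marker`, `measured_channel`,
#'   `percent_positive`, `tolerance`, `pass`) with attribute `pass` for the
#'   overall verdict; empty for an empty gate set.
#' @export
channel_overlap_check <- function(single_stain_tables, gates, tolerance = NULL) {
  chans <- vapply(gates, function(g) g$channel, character(1))
  if (length(gates) == 0L) {
    out <- data.frame(stained_marker = character(0), measured_channel = character(0),
                      percent_positive = numeric(0), tolerance = numeric(0),
                      pass = logical(0))
    attr(out, "pass") <- TRUE
    return(out)
  }
  missing <- setdiff(chans, names(single_stain_tables))
  if (length(missing))
    stopf("missing single-stain table(s) for: %s", paste(missing, collapse = ", "))
  if (is.null(tolerance))
    tolerance <- max(vapply(gates, function(g) 100 * (1 - g$q), numeric(1))) + 2
  rows <- NULL
  for (m in chans) {
    tab <- single_stain_tables[[m]]
    for (g in gates) {
      if (g$channel == m) next
      pp <- percent_positive(tab, g, condition = m)$percent_positive
      rows <- rbind(rows, data.frame(stained_marker = m,
                                     measured_channel = g$channel,
                                     percent_positive = pp,
                                     tolerance = tolerance,
                                     pass = pp <= tolerance))
    }
  }
  attr(rows, "pass") <- all(rows$pass)
  rows
}

#' Compare replicate statistics between two conditions
#'
#' Two-sided two-sample Student's t-test (equal variances), with
#' significance called at p < 0.01. Two constant groups with equal means
#' give p = 1 (no evidence of difference); constant groups with different
#' means give p = 0 (complete separation at zero variance).
#'
#' @param stats_a,stats_b numeric replicate values (>= 2 each).
#' @param alpha significance level.
#' @return list: `t_statistic`, `p_value`, `significant`, `alpha`.
#' @export
compare_replicates <- function(stats_a, stats_b, alpha = 0.01) {
  if (length(stats_a) < 2L || length(stats_b) < 2L)
    stopf("need at least 2 replicates per group")
  if (stats::sd(stats_a) == 0 && stats::sd(stats_b) == 0) {
    equal <- isTRUE(all.equal(mean(stats_a), mean(stats_b)))
    res <- list(t_statistic = if (equal) 0 else Inf,
                p_value = if (equal) 1 else 0)
  } else {
    tt <- stats::t.test(stats_a, stats_b, var.equal = TRUE)
    res <- list(t_statistic = unname(tt$statistic), p_value = tt$p.value)
  }
  res$significant <- res$p_value < alpha
  res$alpha <- alpha
  res
}

#' Serialize gates to YAML
#'
#' @param gates list of `gate` objects (or a single gate).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_gates_yaml <- function(gates, path) {
  if (inherits(gates, "gate")) gates <- list(gates)
  payload <- lapply(gates, function(g)
    list(channel = g$channel, threshold = as.numeric(g$threshold),
         method = "ct_quantile", q = g$q, n_ct = g$n_ct,
         source_wells = as.list(g$source_wells)))
  names(payload) <- vapply(gates, function(g) g$channel, character(1))
  yaml::write_yaml(payload, path)
  invisible(path)
}
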