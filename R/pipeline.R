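# Plate-layout handling, pipeline orchestration and report assembly.

#' Read a plate layout from YAML or CSV
#'
#' A layout describes every well of a plate: its address, condition role
#' (`treated`, `untreated`, `CT_secondary_only`, `positive_control`, or
#' `single_stain:<marker>`), drug, concentration (uM), replicate index, and
#' the plate-wide channel map (channel name -> stain/marker).
#'
#' YAML layouts have top-level keys `plate_id`, `channels` (map) and
#' `wells` (list of well records); CSV layouts hold the well table with the
#' channel map in columns `channel.<name>` of the first row.
#'
#' @param path file path (`.yaml`/`.yml` or `.csv`).
#' @return object of class `plate_layout`: `plate_id`, `channels`, `wells`
#'   (data.frame).
#' @export
read_plate_layout <- function(path) {
  if (!file.exists(path)) stopf("layout file not found: %s", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- tryCatch(yaml::read_yaml(path), error = function(e)
      stopf("could not parse layout YAML %s: %s", path, conditionMessage(e)))
    wells <- do.call(rbind, lapply(y$wells, function(w)
      data.frame(well_id = w$well_id %||% NA_character_,
                 role = w$role %||% "treated",
                 drug = w$drug %||% NA_character_,
                 concentration_uM = as.numeric(w$concentration_uM %||% NA),
                 replicate = as.integer(w$replicate %||% 1L))))
    layout <- list(plate_id = y$plate_id %||% "plate",
                   channels = y$channels %||% list(),
                   wells = wells)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    ch_cols <- grep("^channel\\.", names(df), value = TRUE)
    channels <- as.list(df[1, ch_cols, drop = FALSE])
    names(channels) <- sub("^channel\\.", "", ch_cols)
    layout <- list(plate_id = "plate", channels = channels,
                   wells = df[, setdiff(names(df), ch_cols), drop = FALSE])
  }
  class(layout) <- "plate_layout"
  layout
}

#' Build a plate layout in code
#'
#' @param wells data.frame with columns `well_id`, `role`, `drug`,
#'   `concentration_uM`, `replicate`.
#' @param channels named list mapping channel names to stains/markers.
#' @param plate_id plate identifier.
#' @return a `plate_layout` object.
#' @export
plate_layout <- function(wells, channels = list(), plate_id = "plate") {
  l <- list(plate_id = plate_id, channels = channels,
            wells = as.data.frame(wells))
  class(l) <- "plate_layout"
  l
}

#' Validate a plate layout
#'
#' Checks the structural invariants a pipeline run relies on and returns
#' every violation found (an empty character vector means the layout is
#' valid): unique well addresses, at least one untreated well per treated
#' drug series, and at least one CT (secondary-antibody-only) well when any
#' marker channel is to be gated.
#'
#' @param layout a `plate_layout` object.
#' @param gated_markers marker channels that will be gated (default: every
#'   non-structural channel in the layout's channel map).
#' @return character vector of violations.
#' @export
validate_layout <- function(layout, gated_markers = NULL) {
  stopifnot(inherits(layout, "plate_layout"))
  w <- layout$wells
  v <- character(0)
  if (is.null(w) || nrow(w) == 0L) return("layout has no wells")
  dup <- unique(w$well_id[duplicated(w$well_id)])
  if (length(dup))
    v <- c(v, sprintf("duplicate well address: %s", dup))
  drugs <- unique(w$drug[w$role == "treated" & !is.na(w$drug)])
  for (d in drugs) {
    if (!any(w$role == "untreated"))
      v <- c(v, sprintf("treated series '%s' has no untreated well", d))
  }
  if (is.null(gated_markers))
    gated_markers <- setdiff(unlist(layout$channels), c("hoechst", "pi", "calcein"))
  if (length(gated_markers) && !any(w$role == "CT_secondary_only"))
    v <- c(v, sprintf("marker gating requested (%s) but no CT_secondary_only well",
                      paste(gated_markers, collapse = ", ")))
  v
}

#' Run the full plate analysis pipeline
#'
#' Orchestrates segmentation, per-cell quantification, CT-anchored gating,
#' marker statistics with fold changes versus untreated, and optional
#' cell-cycle and quadrant analyses, producing one machine-readable report
#' bundle. Images are read from `image_root` in the TIFF dialect of
#' [write_well_images()]; alternatively, pre-simulated in-memory wells can
#' be supplied via `wells`. The run is deterministic given layout, images
#' and configuration, and the report logs every analysis parameter.
#'
#' @param layout a `plate_layout` object.
#' @param image_root directory of `<well>_<channel>.tif` images (ignored
#'   when `wells` is given).
#' @param wells optional named list of in-memory image sets (named lists of
#'   channel matrices), keyed by well id.
#' @param config list of analysis options: `seg` (arguments to
#'   [segment_nuclei()]), `gate_q` (CT quantile, default 0.99),
#'   `min_ct_cells` (default 100), `cell_cycle` (logical), `quadrant`
#'   (logical), `cycle_bins`, `window_halfwidth_frac`.
#' @param out_dir optional directory: writes per-cell CSV, gates YAML,
#'   per-condition stats CSV and a summary JSON.
#' @return report list: `cells` (full cell table), `gates`,
#'   `marker_stats` (per condition x marker data.frame), `fold_changes`,
#'   `cell_cycle`, `quadrant`, `config`, `n_wells`.
#' @export
run_pipeline <- function(layout, image_root = NULL, wells = NULL,
                         config = list(), out_dir = NULL) {
  stopifnot(inherits(layout, "plate_layout"))
  violations <- validate_layout(layout)
  if (length(violations))
    stopf("invalid layout:\n  %s", paste(violations, collapse = "\n  "))
  cfg <- utils::modifyList(list(seg = list(), gate_q = 0.99, min_ct_cells = 100,
                                cell_cycle = FALSE, quadrant = FALSE,
                                cycle_bins = 256, window_halfwidth_frac = 0.15),
                           config)
  w <- layout$wells
  channels <- names(layout$channels)
  markers <- setdiff(unlist(layout$channels), c("hoechst", "pi", "calcein"))
  marker_channels <- names(layout$channels)[unlist(layout$channels) %in% markers]

  # segment + quantify every well
  tables <- list()
  for (i in seq_len(nrow(w))) {
    wid <- w$well_id[i]
    imgs <- if (!is.null(wells)) wells[[wid]] else
      read_well_images(image_root, wid, channels)
    if (is.null(imgs)) stopf("no images for well %s", wid)
    tables[[wid]] <- quantify_well(imgs, well_id = wid, seg_params = cfg$seg)
  }
  cells <- do.call(rbind, tables)
  meta_cols <- intersect(c("role", "drug", "concentration_uM", "replicate"), names(w))
  cells <- merge(cells, w[, c("well_id", meta_cols)], by = "well_id", sort = FALSE)

  # CT-anchored gates, pooled over CT wells
  ct_wells <- w$well_id[w$role == "CT_secondary_only"]
  gates <- list()
  if (length(marker_channels)) {
    if (!length(ct_wells))
      stopf("gating requested but layout has no CT_secondary_only wells")
    ct_cells <- cells[cells$well_id %in% ct_wells, ]
    for (ch in marker_channels)
      gates[[ch]] <- define_gate(ct_cells, ch, q = cfg$gate_q,
                                 min_cells = cfg$min_ct_cells)
  }

  # per-condition marker statistics and fold changes vs untreated
  cond_of <- function(rows) {
    ifelse(rows$role == "treated" & !is.na(rows$drug),
           paste0(rows$drug, "@", rows$concentration_uM), rows$role)
  }
  cells$condition <- cond_of(cells)
  stats_rows <- NULL
  for (ch in names(gates)) {
    for (cond in unique(cells$condition)) {
      sub <- cells[cells$condition == cond, ]
      ms <- percent_positive(sub, gates[[ch]], condition = cond)
      stats_rows <- rbind(stats_rows, data.frame(
        condition = cond, channel = ch, n_cells = ms$n_cells,
        percent_positive = ms$percent_positive,
        mean_intensity_positives = ms$mean_integrated_intensity_of_positives))
    }
  }
  fold <- NULL
  if (!is.null(stats_rows) && "untreated" %in% stats_rows$condition) {
    for (ch in unique(stats_rows$channel)) {
      base <- stats_rows[stats_rows$condition == "untreated" &
                           stats_rows$channel == ch, ]
      for (cond in setdiff(unique(stats_rows$condition), "untreated")) {
        tr <- stats_rows[stats_rows$condition == cond & stats_rows$channel == ch, ]
        fc <- if (base$percent_positive > 0)
          tr$percent_positive / base$percent_positive else NA_real_
        fold <- rbind(fold, data.frame(condition = cond, channel = ch,
                                       fold_change_vs_untreated = fc))
      }
    }
  }

  cycle <- NULL
  if (isTRUE(cfg$cell_cycle)) {
    cycle <- lapply(split(cells, cells$condition), function(sub) {
      if (nrow(sub) < 200) return(NULL)
      fit_dna_histogram(sub$hoechst_integrated, bins = cfg$cycle_bins,
                        window_halfwidth_frac = cfg$window_halfwidth_frac)
    })
  }
  quad <- NULL
  if (isTRUE(cfg$quadrant) && length(gates) >= 2) {
    quad <- lapply(split(cells, cells$condition), quadrant_analysis,
                   gates = gates)
  }

  report <- list(plate_id = layout$plate_id, cells = cells, gates = gates,
                 marker_stats = stats_rows, fold_changes = fold,
                 cell_cycle = cycle, quadrant = quad,
                 config = cfg, n_wells = nrow(w))
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report bundle to disk
#'
#' Per-cell CSV, gates YAML, per-condition marker statistics CSV, and a
#' summary JSON (schema version in the header; no timestamps, so reruns are
#' byte-identical).
#'
#' @param report result of [run_pipeline()].
#' @param out_dir output directory.
#' @return invisibly, the summary JSON path.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
  if (length(report$gates))
    write_gates_yaml(report$gates, file.path(out_dir, "gates.yaml"))
  if (!is.null(report$marker_stats))
    utils::write.csv(report$marker_stats, file.path(out_dir, "marker_stats.csv"),
                     row.names = FALSE)
  summary <- list(schema_version = "1.0",
                  plate_id = report$plate_id,
                  n_wells = report$n_wells,
                  n_cells = nrow(report$cells),
                  gates = lapply(report$gates, function(g)
                    list(channel = g$channel, threshold = as.numeric(g$threshold),
                         q = g$q)),
                  config = report$config[c("gate_q", "min_ct_cells", "cycle_bins",
                                           "window_halfwidth_frac")],
                  marker_stats = report$marker_stats,
                  fold_changes = report$fold_changes)
  path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
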