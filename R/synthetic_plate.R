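# Synthetic plate generator: multi-channel well images with exact per-cell
# ground truth. Nuclei are rendered as truncated Gaussian spots whose discrete
# kernel is normalised to sum to one, so the ledger of integrated signals is
# exact by construction (up to later noise/background).

#' Construct simulation parameters for one well
#'
#' Bundles and validates every knob of the single-well generator: cell number,
#' image geometry, nucleus size, DNA-content model (bimodal 2N/4N with an
#' S-phase bridge), per-marker log-normal intensity mixtures, live/dead
#' staining, background, noise and channel bleed-through.
#'
#' Channels are `"hoechst"`, one channel per entry of `marker_models`, and —
#' when `viability_channels = TRUE` — `"pi"` and `"calcein"`. Intensities are
#' in arbitrary units (a.u.) matching 16-bit pixel counts when images are
#' written to TIFF.
#'
#' @param n_cells number of nuclei to place.
#' @param image_shape integer (rows, cols) of each channel image.
#' @param nucleus_radius named numeric `c(mean = , cv = )`: mean nucleus
#'   radius in pixels and its coefficient of variation.
#' @param g1_dna_intensity mean integrated Hoechst signal (a.u.) of a G0/G1
#'   (2N) cell; G2/M cells average twice this, S cells lie uniformly between.
#' @param dna_cv coefficient of variation of per-cell DNA signal around its
#'   phase mean.
#' @param phase_fractions probabilities over `c(g1 = , s = , g2m = )`; must
#'   sum to 1.
#' @param marker_models named list, one entry per marker channel, each a list
#'   with `positive_fraction`, `negative_mean`, `positive_mean` (a.u.) and
#'   `lognormal_sigma` (log-scale sd of both mixture components).
#' @param dead_fraction probability that a cell is dead (PI-positive,
#'   calcein-negative). Dead cells keep their Hoechst signal.
#' @param viability_channels render `"pi"` and `"calcein"` channels.
#' @param pi_mean,calcein_mean mean integrated signal (a.u.) of the positive
#'   population on the PI / calcein channel; negatives carry no spot.
#' @param stain_sigma log-normal sigma of the PI and calcein positives.
#' @param background_level constant background added to every pixel (a.u.).
#' @param noise_sd sd of additive Gaussian pixel noise (a.u.), applied after
#'   bleed-through mixing.
#' @param bleedthrough square channel mixing matrix (unit diagonal,
#'   non-negative entries) with dimnames equal to the channel names, or
#'   `NULL` for identity (no bleed-through).
#' @param seed integer seed; the simulation is fully deterministic given it.
#' @return object of class `well_sim_params`.
#' @export
well_sim_params <- function(n_cells = 200,
                            image_shape = c(512L, 512L),
                            nucleus_radius = c(mean = 8, cv = 0.1),
                            g1_dna_intensity = 20000,
                            dna_cv = 0.05,
                            phase_fractions = c(g1 = 0.6, s = 0.25, g2m = 0.15),
                            marker_models = list(),
                            dead_fraction = 0,
                            viability_channels = TRUE,
                            pi_mean = 10000,
                            calcein_mean = 10000,
                            stain_sigma = 0.25,
                            background_level = 100,
                            noise_sd = 5,
                            bleedthrough = NULL,
                            seed = 1L) {
  if (length(phase_fractions) != 3L)
    stopf("phase_fractions must have 3 entries (G0/G1, S, G2/M)")
  if (abs(sum(phase_fractions) - 1) > 1e-9)
    stopf("phase_fractions must sum to 1 (got %.12f)", sum(phase_fractions))
  if (any(phase_fractions < 0 | phase_fractions > 1))
    stopf("phase_fractions must lie in [0, 1]")
  if (dead_fraction < 0 || dead_fraction > 1)
    stopf("dead_fraction must lie in [0, 1]")
  for (m in names(marker_models)) {
    mm <- marker_models[[m]]
    need <- c("positive_fraction", "negative_mean", "positive_mean", "lognormal_sigma")
    if (!all(need %in% names(mm)))
      stopf("marker model '%s' must supply %s", m, paste(need, collapse = ", "))
    if (mm$positive_fraction < 0 || mm$positive_fraction > 1)
      stopf("marker '%s': positive_fraction must lie in [0, 1]", m)
    if (mm$positive_mean <= mm$negative_mean)
      stopf("marker '%s': positive_mean must exceed negative_mean", m)
  }
  channels <- c("hoechst", names(marker_models),
                if (viability_channels) c("pi", "calcein"))
  if (!is.null(bleedthrough)) {
    bleedthrough <- as.matrix(bleedthrough)
    if (nrow(bleedthrough) != length(channels) ||
        ncol(bleedthrough) != length(channels))
      stopf("bleedthrough must be %d x %d (channels: %s)",
            length(channels), length(channels), paste(channels, collapse = ", "))
    if (is.null(dimnames(bleedthrough)))
      dimnames(bleedthrough) <- list(channels, channels)
    if (any(bleedthrough < 0)) stopf("bleedthrough entries must be non-negative")
    if (any(abs(diag(bleedthrough) - 1) > 1e-12))
      stopf("bleedthrough must have a unit diagonal")
  }
  p <- list(n_cells = as.integer(n_cells),
            image_shape = as.integer(image_shape),
            nucleus_radius = nucleus_radius,
            g1_dna_intensity = g1_dna_intensity,
            dna_cv = dna_cv,
            phase_fractions = phase_fractions,
            marker_models = marker_models,
            dead_fraction = dead_fraction,
            viability_channels = isTRUE(viability_channels),
            pi_mean = pi_mean, calcein_mean = calcein_mean,
            stain_sigma = stain_sigma,
            background_level = background_level,
            noise_sd = noise_sd,
            bleedthrough = bleedthrough,
            channels = channels,
            seed = as.integer(seed))
  class(p) <- "well_sim_params"
  p
}

#' @export
print.well_sim_params <- function(x, ...) {
  cat(sprintf("well_sim_params: %d cells on %d x %d px, channels: %s\n",
              x$n_cells, x$image_shape[1], x$image_shape[2],
              paste(x$channels, collapse = ", ")))
  cat(sprintf("  phases (G0/G1, S, G2/M): %s; dead fraction %.2f; seed %d\n",
              paste(format(x$phase_fractions), collapse = ", "),
              x$dead_fraction, x$seed))
  invisible(x)
}

# Draw per-cell ground truth (phases, DNA signal, marker status and signals,
# viability) without placing cells. Assumes the RNG is already seeded.
draw_population <- function(params) {
  n <- params$n_cells
  phases <- c("G0/G1", "S", "G2/M")
  gt <- data.frame(cell = seq_len(n))
  if (n == 0L) {
    gt <- data.frame(cell = integer(0), phase = character(0),
                     dna_signal = numeric(0), viability = character(0),
                     pi_signal = numeric(0), calcein_signal = numeric(0))
    for (m in names(params$marker_models)) {
      gt[[paste0(m, "_positive")]] <- logical(0)
      gt[[paste0(m, "_signal")]] <- numeric(0)
    }
    return(gt)
  }
  gt$phase <- sample(phases, n, replace = TRUE, prob = params$phase_fractions)
  base <- params$g1_dna_intensity *
    ifelse(gt$phase == "G0/G1", 1,
           ifelse(gt$phase == "G2/M", 2, stats::runif(n, 1, 2)))
  jitter <- if (params$dna_cv > 0) pmax(stats::rnorm(n, 1, params$dna_cv), 0.05) else 1
  gt$dna_signal <- base * jitter
  gt$viability <- ifelse(stats::runif(n) < params$dead_fraction, "dead", "live")
  for (m in names(params$marker_models)) {
    mm <- params$marker_models[[m]]
    pos <- stats::runif(n) < mm$positive_fraction
    mu <- ifelse(pos, mm$positive_mean, mm$negative_mean)
    # meanlog chosen so the log-normal's arithmetic mean equals the stated mean
    sig <- mm$lognormal_sigma
    gt[[paste0(m, "_positive")]] <- pos
    gt[[paste0(m, "_signal")]] <- stats::rlnorm(n, log(mu) - sig^2 / 2, sig)
  }
  if (params$viability_channels) {
    sig <- params$stain_sigma
    dead <- gt$viability == "dead"
    gt$pi_signal <- ifelse(dead,
                           stats::rlnorm(n, log(params$pi_mean) - sig^2 / 2, sig), 0)
    gt$calcein_signal <- ifelse(dead, 0,
                                stats::rlnorm(n, log(params$calcein_mean) - sig^2 / 2, sig))
  } else {
    gt$pi_signal <- 0
    gt$calcein_signal <- 0
  }
  gt
}

#' Draw a ground-truth cell population without rendering images
#'
#' Samples per-cell phases, DNA signals, marker statuses/signals and
#' viability from the generative model of [well_sim_params()], skipping cell
#' placement and image rendering. Useful for testing table-level statistics
#' at population sizes far larger than an image could hold.
#'
#' @param params a `well_sim_params` object.
#' @return data.frame, one row per cell (the ground-truth ledger minus
#'   positions).
#' @export
sample_cell_population <- function(params) {
  stopifnot(inherits(params, "well_sim_params"))
  set.seed(params$seed)
  draw_population(params)
}

# Rejection-sample non-overlapping centers. Two cells i, j must satisfy
# dist >= max(2.2 * mean radius, 3 * max(radius_i, radius_j)): the first
# term keeps nuclei apart, the second keeps the 3-sigma truncation disks of
# their rendered spots disjoint on either side of the Voronoi bisector, so
# the per-cell signal ledger is exactly recoverable from the image.
place_cells <- function(n, shape, radii, mean_radius, max_tries_per_cell = 500) {
  margin <- ceiling(1.5 * max(radii, mean_radius)) + 1
  lo <- margin + 1
  hi_r <- shape[1] - margin
  hi_c <- shape[2] - margin
  if (n > 0 && (hi_r <= lo || hi_c <= lo))
    stopf("image %d x %d too small for nuclei of radius %.1f px",
          shape[1], shape[2], mean_radius)
  rows <- numeric(n); cols <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    prev <- seq_len(i - 1)
    for (try in seq_len(max_tries_per_cell)) {
      r <- stats::runif(1, lo, hi_r)
      cc <- stats::runif(1, lo, hi_c)
      if (i > 1L) {
        min_d <- pmax(2.2 * mean_radius, 3 * pmax(radii[prev], radii[i]))
        ok <- all((rows[prev] - r)^2 + (cols[prev] - cc)^2 >= min_d^2)
      } else ok <- TRUE
      if (ok) { rows[i] <- r; cols[i] <- cc; placed <- TRUE; break }
    }
    if (!placed) {
      d_typ <- max(2.2 * mean_radius, 3 * mean_radius)
      achievable <- floor(0.5 * (hi_r - lo) * (hi_c - lo) / d_typ^2)
      stopf(paste0("could not place %d non-overlapping nuclei in a %d x %d image ",
                   "(failed at cell %d); about %d cells are achievable at ",
                   "radius %.1f px"),
            n, shape[1], shape[2], i, achievable, mean_radius)
    }
  }
  cbind(row = rows, col = cols)
}

# Add one Gaussian spot (sigma = radius/2, truncated at 3 sigma, kernel
# normalised to total 1) of the given integrated amplitude into `img`.
render_spot <- function(img, center, radius, amplitude) {
  if (amplitude == 0) return(img)
  sigma <- radius / 2
  w <- ceiling(3 * sigma)
  r0 <- round(center[1]); c0 <- round(center[2])
  rr <- (r0 - w):(r0 + w)
  cc <- (c0 - w):(c0 + w)
  dr <- rr - center[1]
  dc <- cc - center[2]
  d2 <- outer(dr^2, dc^2, "+")
  k <- exp(-d2 / (2 * sigma^2))
  k[d2 > (3 * sigma)^2] <- 0
  k <- k / sum(k)
  keep_r <- rr >= 1 & rr <= nrow(img)
  keep_c <- cc >= 1 & cc <= ncol(img)
  img[rr[keep_r], cc[keep_c]] <- img[rr[keep_r], cc[keep_c]] +
    amplitude * k[keep_r, keep_c]
  img
}

#' Simulate one stained well
#'
#' Renders every channel of a well as 2D intensity images and returns them
#' together with the exact per-cell ground-truth ledger. Nuclei are
#' non-overlapping Gaussian spots (sigma = radius/2, truncated at 3 sigma);
#' the Hoechst spot of each cell integrates exactly to its DNA signal, marker
#' spots to the drawn log-normal mixture signals, and PI/calcein spots encode
#' live/dead exclusivity (dead: PI only; live: calcein only; Hoechst always).
#' Bleed-through mixing is applied channel-wise, then constant background and
#' additive Gaussian noise.
#'
#' @param params a [well_sim_params()] object.
#' @return list with elements `images` (named list of numeric matrices, class
#'   `well_images`), `truth` (data.frame ground truth, one row per cell) and
#'   `params`.
#' @export
simulate_well <- function(params) {
  stopifnot(inherits(params, "well_sim_params"))
  set.seed(params$seed)
  gt <- draw_population(params)
  n <- params$n_cells
  shape <- params$image_shape
  rad <- params$nucleus_radius
  radii <- if (n > 0) pmax(stats::rnorm(n, rad[["mean"]], rad[["cv"]] * rad[["mean"]]),
                           rad[["mean"]] * 0.3) else numeric(0)
  centers <- place_cells(n, shape, radii, rad[["mean"]])
  if (n > 0) {
    gt$center_row <- centers[, "row"]
    gt$center_col <- centers[, "col"]
    gt$radius_px <- radii
  } else {
    gt$center_row <- numeric(0); gt$center_col <- numeric(0)
    gt$radius_px <- numeric(0)
  }
  blank <- matrix(0, shape[1], shape[2])
  imgs <- stats::setNames(rep(list(blank), length(params$channels)), params$channels)
  signal_of <- function(ch, i) {
    switch(ch,
           hoechst = gt$dna_signal[i],
           pi = gt$pi_signal[i],
           calcein = gt$calcein_signal[i],
           gt[[paste0(ch, "_signal")]][i])
  }
  for (i in seq_len(n)) {
    ctr <- c(gt$center_row[i], gt$center_col[i])
    for (ch in params$channels)
      imgs[[ch]] <- render_spot(imgs[[ch]], ctr, radii[i], signal_of(ch, i))
  }
  if (!is.null(params$bleedthrough)) {
    M <- params$bleedthrough
    mixed <- imgs
    for (ch in params$channels) {
      acc <- blank
      for (src in params$channels)
        if (M[ch, src] != 0) acc <- acc + M[ch, src] * imgs[[src]]
      mixed[[ch]] <- acc
    }
    imgs <- mixed
  }
  for (ch in params$channels) {
    img <- imgs[[ch]] + params$background_level
    if (params$noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, params$noise_sd),
                          nrow(img), ncol(img))
    imgs[[ch]] <- img
  }
  class(imgs) <- c("well_images", class(imgs))
  list(images = imgs, truth = gt, params = params)
}

#' Convert a ground-truth ledger to a cell table
#'
#' Maps the generator's per-cell signals onto the column schema produced by
#' [apply_mask()] (`<channel>_integrated`), so gating, cell-cycle and
#' viability statistics can be exercised directly on ground truth,
#' independent of image rendering and segmentation.
#'
#' @param truth ground-truth data.frame from [simulate_well()] or
#'   [sample_cell_population()].
#' @param well_id well identifier stored in the table.
#' @return data.frame in cell-table schema.
#' @export
truth_to_cell_table <- function(truth, well_id = "SIM") {
  ct <- data.frame(well_id = rep(well_id, nrow(truth)),
                   cell_label = seq_len(nrow(truth)))
  ct$hoechst_integrated <- truth$dna_signal
  sig_cols <- grep("_signal$", names(truth), value = TRUE)
  for (sc in setdiff(sig_cols, "dna_signal")) {
    ch <- sub("_signal$", "", sc)
    ct[[int_col(ch)]] <- truth[[sc]]
  }
  ct
}

#' Construct a drug dose-response generative model
#'
#' Expected cells per well follow a four-parameter logistic inhibition curve
#' in concentration; the dead-cell fraction follows an independent logistic
#' (Hill) curve. Both are evaluated per well by [simulate_dose_plate()].
#'
#' @param ic50_true concentration (uM) at which growth inhibition reaches
#'   half of `max_inhibition`.
#' @param hill Hill slope of the inhibition curve.
#' @param max_inhibition maximal fractional reduction in cell number (1 =
#'   complete suppression at saturating dose).
#' @param ec50_dead,hill_dead,max_dead logistic parameters of the dead
#'   fraction versus concentration.
#' @param baseline_cells_per_well expected cells in an untreated well.
#' @param count_cv coefficient of variation of the realized per-well cell
#'   count around its expectation (plate-to-plate noise).
#' @return object of class `drug_response_model`.
#' @export
drug_response_model <- function(ic50_true = 1, hill = 2, max_inhibition = 1,
                                ec50_dead = 1, hill_dead = 2, max_dead = 0.8,
                                baseline_cells_per_well = 200,
                                count_cv = 0.1) {
  stopifnot(ic50_true > 0, hill > 0, max_inhibition >= 0, max_inhibition <= 1,
            ec50_dead > 0, hill_dead > 0, max_dead >= 0, max_dead <= 1)
  m <- list(ic50_true = ic50_true, hill = hill, max_inhibition = max_inhibition,
            ec50_dead = ec50_dead, hill_dead = hill_dead, max_dead = max_dead,
            baseline_cells_per_well = as.integer(baseline_cells_per_well),
            count_cv = count_cv)
  class(m) <- "drug_response_model"
  m
}

#' Expected cell number and dead fraction of the generative model
#'
#' @param model a [drug_response_model()].
#' @param conc concentration vector (uM).
#' @return data.frame with `conc`, `expected_cells`, `dead_fraction`.
#' @export
dose_response_expectation <- function(model, conc) {
  inhib <- ifelse(conc <= 0, 0,
                  model$max_inhibition * conc^model$hill /
                    (conc^model$hill + model$ic50_true^model$hill))
  dead <- ifelse(conc <= 0, 0,
                 model$max_dead * conc^model$hill_dead /
                   (conc^model$hill_dead + model$ec50_dead^model$hill_dead))
  data.frame(conc = conc,
             expected_cells = model$baseline_cells_per_well * (1 - inhib),
             dead_fraction = dead)
}

#' Simulate a dose-response plate of well images
#'
#' One well per concentration x replicate. The realized cell count of each
#' well is its expected count under the model times multiplicative Gaussian
#' noise of CV `model$count_cv`; the dead fraction follows the model's
#' logistic curve. Per-well seeds are derived from the master seed and the
#' well identifier with [well_seed()], so wells are reproducible in any
#' order.
#'
#' @param model a [drug_response_model()].
#' @param concentrations concentrations in uM; must include 0 (untreated).
#' @param replicates wells per concentration.
#' @param seed master seed.
#' @param base_params `well_sim_params` template for every well (its
#'   `n_cells`, `dead_fraction` and `seed` are overridden per well).
#' @return list with `wells` (named list of [simulate_well()] results),
#'   `layout` (data.frame: well_id, concentration_uM, replicate, n_cells,
#'   true dead fraction) and `model`.
#' @export
simulate_dose_plate <- function(model, concentrations, replicates = 3,
                                seed = 1L, base_params = well_sim_params()) {
  stopifnot(inherits(model, "drug_response_model"))
  if (any(concentrations < 0)) stopf("concentrations must be non-negative")
  if (!any(concentrations == 0))
    stopf("no untreated (concentration 0) well: growth normalization is undefined")
  exp_tab <- dose_response_expectation(model, concentrations)
  wells <- list()
  layout <- NULL
  for (ci in seq_along(concentrations)) {
    for (rep_i in seq_len(replicates)) {
      wid <- sprintf("%s%02d", LETTERS[ci], rep_i)
      ws <- well_seed(seed, wid)
      set.seed(ws)
      n_exp <- exp_tab$expected_cells[ci]
      n_real <- max(0L, as.integer(round(n_exp * (1 + stats::rnorm(1, 0, model$count_cv)))))
      p <- base_params
      p$n_cells <- n_real
      p$dead_fraction <- exp_tab$dead_fraction[ci]
      p$seed <- well_seed(ws, "cells")
      wells[[wid]] <- simulate_well(p)
      layout <- rbind(layout, data.frame(
        well_id = wid, concentration_uM = concentrations[ci],
        replicate = rep_i, n_cells = n_real,
        true_dead_fraction = exp_tab$dead_fraction[ci]))
    }
  }
  list(wells = wells, layout = layout, model = model)
}

#' Catalogue of packaged simulation scenarios
#'
#' Named generator parameterizations whose ground-truth fractions mirror
#' outcomes a DDR screen typically produces: a topoisomerase-II-poisoned
#' population arrested in G2/M (treated 66% vs untreated 22%), a
#' three-marker multiplex after topoisomerase-I inhibition (90% / 80% / 60%
#' positive for gH2AX / pATM / pATR), and a combined replicative-stress
#' scenario ("VOX": ATR inhibitor plus platinum) exercising multiplex and
#' cell-cycle readouts jointly. These are end-to-end smoke fixtures for
#' recovering the generator's own truth, not biological claims.
#'
#' @param name one of `"etoposide-treated"`, `"etoposide-untreated"`,
#'   `"SN38-multiplex"`, `"SN38-multiplex-untreated"`, `"VOX"`.
#' @param seed seed stored in the returned parameters.
#' @return a `well_sim_params` object.
#' @export
scenario_library <- function(name, seed = 1L) {
  marker3 <- function(fr) {
    lapply(stats::setNames(fr, names(fr)), function(f)
      list(positive_fraction = f, negative_mean = 500,
           positive_mean = 20000, lognormal_sigma = 0.4))
  }
  shape <- c(640L, 640L)     # room for 300 non-overlapping nuclei
  p <- switch(name,
    "etoposide-treated" = well_sim_params(
      n_cells = 300, image_shape = shape,
      phase_fractions = c(g1 = 0.24, s = 0.10, g2m = 0.66),
      marker_models = marker3(c(gH2AX = 0.85)), seed = seed),
    "etoposide-untreated" = well_sim_params(
      n_cells = 300, image_shape = shape,
      phase_fractions = c(g1 = 0.60, s = 0.18, g2m = 0.22),
      marker_models = marker3(c(gH2AX = 0.15)), seed = seed),
    "SN38-multiplex" = well_sim_params(
      n_cells = 300, image_shape = shape,
      marker_models = marker3(c(gH2AX = 0.90, pATM = 0.80, pATR = 0.60)),
      seed = seed),
    "SN38-multiplex-untreated" = well_sim_params(
      n_cells = 300, image_shape = shape,
      marker_models = marker3(c(gH2AX = 0.25, pATM = 0.25, pATR = 0.25)),
      seed = seed),
    "VOX" = well_sim_params(
      n_cells = 300, image_shape = shape,
      phase_fractions = c(g1 = 0.25, s = 0.45, g2m = 0.30),
      marker_models = marker3(c(gH2AX = 0.85, pATR = 0.70)), seed = seed),
    stopf("unknown scenario '%s'; available: %s", name,
          paste(c("etoposide-treated", "etoposide-untreated", "SN38-multiplex",
                  "SN38-multiplex-untreated", "VOX"), collapse = ", ")))
  p
}

#' Write a well's channel images as 16-bit TIFFs
#'
#' One single-channel grayscale TIFF per channel, named
#' `<well>_<channel>.tif`. Intensities are interpreted as 16-bit counts:
#' values are clipped to `[0, 65535]` and stored losslessly at integer
#' resolution.
#'
#' @param images named list of matrices (a `well_images` object).
#' @param dir output directory (created if needed).
#' @param well_id well identifier used in file names.
#' @return invisibly, the written file paths.
#' @export
write_well_images <- function(images, dir, well_id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (ch in names(images)) {
    path <- file.path(dir, sprintf("%s_%s.tif", well_id, ch))
    img <- pmin(pmax(round(images[[ch]]), 0), 65535) / 65535
    tiff::writeTIFF(img, path, bits.per.sample = 16L)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a well's channel images written by [write_well_images()]
#'
#' @param dir directory holding the TIFFs.
#' @param well_id well identifier.
#' @param channels channel names to read.
#' @return named list of matrices in a.u. (16-bit counts), class
#'   `well_images`.
#' @export
read_well_images <- function(dir, well_id, channels) {
  imgs <- list()
  for (ch in channels) {
    path <- file.path(dir, sprintf("%s_%s.tif", well_id, ch))
    if (!file.exists(path)) stopf("missing image file: %s", path)
    imgs[[ch]] <- tiff::readTIFF(path) * 65535
  }
  class(imgs) <- c("well_images", class(imgs))
  imgs
}

#' Write a ground-truth ledger and its parameters to disk
#'
#' Ground truth as CSV (one row per cell) and the generator parameters
#' echoed to YAML alongside.
#'
#' @param truth ground-truth data.frame.
#' @param params the `well_sim_params` used.
#' @param dir output directory.
#' @param well_id well identifier used in file names.
#' @return invisibly, the CSV path.
#' @export
write_ground_truth <- function(truth, params, dir, well_id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, sprintf("%s_truth.csv", well_id))
  utils::write.csv(truth, csv, row.names = FALSE)
  p <- params
  p$bleedthrough <- if (is.null(p$bleedthrough)) "identity" else
    apply(p$bleedthrough, 1, as.list, simplify = FALSE)
  p$phase_fractions <- as.list(p$phase_fractions)
  p$nucleus_radius <- as.list(p$nucleus_radius)
  class(p) <- NULL
  yaml::write_yaml(p, file.path(dir, sprintf("%s_params.yaml", well_id)))
  invisible(csv)
}
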