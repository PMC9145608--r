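test_that("an empty well renders background-only images and an empty ledger", {
  p <- well_sim_params(n_cells = 0, noise_sd = 0, background_level = 50, seed = 1)
  sim <- simulate_well(p)
  expect_equal(nrow(sim$truth), 0L)
  for (ch in p$channels)
    expect_true(all(sim$images[[ch]] == 50))
})

test_that("simulation is bit-identical for identical params and seed", {
  p <- pop_params(n = 60, seed = 42, image_shape = c(320L, 320L), noise_sd = 5)
  s1 <- simulate_well(p)
  s2 <- simulate_well(p)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$images, s2$images)
  s3 <- simulate_well(pop_params(n = 60, seed = 43, image_shape = c(320L, 320L),
                                 noise_sd = 5))
  expect_false(identical(s1$images$hoechst, s3$images$hoechst))
})

test_that("noiseless Hoechst image integrates exactly to the DNA ledger", {
  p <- well_sim_params(n_cells = 150, noise_sd = 0, background_level = 100, seed = 7)
  sim <- simulate_well(p)
  total <- sum(sim$images$hoechst - 100)
  expect_lt(abs(total - sum(sim$truth$dna_signal)) / sum(sim$truth$dna_signal),
            0.005)
})

test_that("degenerate phase distribution gives exactly the G1 intensity", {
  p <- well_sim_params(n_cells = 50, phase_fractions = c(1, 0, 0), dna_cv = 0,
                       g1_dna_intensity = 12345, seed = 3)
  pop <- sample_cell_population(p)
  expect_true(all(pop$phase == "G0/G1"))
  expect_true(all(pop$dna_signal == 12345))
})

test_that("bleed-through mixing is linear in the noiseless channel stack", {
  chans <- c("hoechst", "gH2AX", "pi", "calcein")
  M <- diag(4)
  dimnames(M) <- list(chans, chans)
  M["gH2AX", "hoechst"] <- 0.2    # 20% of Hoechst spills into the marker channel
  base <- list(n_cells = 40, noise_sd = 0, background_level = 0,
               dead_fraction = 0.3, seed = 9, image_shape = c(320L, 320L),
               marker_models = list(gH2AX = marker_model()))
  unmixed <- simulate_well(do.call(well_sim_params, base))
  mixed <- simulate_well(do.call(well_sim_params, c(base, list(bleedthrough = M))))
  expect_equal(mixed$images$gH2AX,
               0.2 * unmixed$images$hoechst + unmixed$images$gH2AX)
  expect_equal(mixed$images$hoechst, unmixed$images$hoechst)
})

test_that("malformed bleed-through matrices are rejected", {
  M <- diag(3); M[1, 2] <- -0.1
  expect_error(well_sim_params(bleedthrough = M, viability_channels = FALSE,
                               marker_models = list(g = marker_model(),
                                                    h = marker_model())),
               "non-negative")
  M2 <- diag(3) * 2
  expect_error(well_sim_params(bleedthrough = M2, viability_channels = FALSE,
                               marker_models = list(g = marker_model(),
                                                    h = marker_model())),
               "unit diagonal")
  expect_error(well_sim_params(bleedthrough = diag(2)), "must be 3 x 3")
})

test_that("parameter validation rejects inconsistent fractions and markers", {
  expect_error(well_sim_params(phase_fractions = c(0.5, 0.3, 0.3)), "sum to 1")
  expect_error(well_sim_params(dead_fraction = 1.2), "\\[0, 1\\]")
  expect_error(well_sim_params(marker_models = list(
    m = marker_model(positive_mean = 100, negative_mean = 500))),
    "must exceed")
})

test_that("realized phase, marker and viability counts follow their multinomials", {
  pvals_phase <- pvals_marker <- pvals_dead <- numeric(0)
  fr <- c(0.5, 0.3, 0.2)
  for (seed in 1:10) {
    pop <- sample_cell_population(pop_params(
      n = 600, seed = seed, phase_fractions = fr, dead_fraction = 0.25,
      markers = list(m = marker_model(positive_fraction = 0.4))))
    obs <- table(factor(pop$phase, levels = c("G0/G1", "S", "G2/M")))
    pvals_phase <- c(pvals_phase, stats::chisq.test(obs, p = fr)$p.value)
    pvals_marker <- c(pvals_marker, stats::binom.test(sum(pop$m_positive), 600,
                                                      0.4)$p.value)
    pvals_dead <- c(pvals_dead, stats::binom.test(sum(pop$viability == "dead"),
                                                  600, 0.25)$p.value)
  }
  expect_true(all(pvals_phase > 0.001))
  expect_true(all(pvals_marker > 0.001))
  expect_true(all(pvals_dead > 0.001))
})

test_that("live/dead staining is exclusive in the ledger", {
  pop <- sample_cell_population(pop_params(n = 500, seed = 5, dead_fraction = 0.4))
  dead <- pop$viability == "dead"
  expect_true(all(pop$pi_signal[dead] > 0))
  expect_true(all(pop$calcein_signal[dead] == 0))
  expect_true(all(pop$pi_signal[!dead] == 0))
  expect_true(all(pop$calcein_signal[!dead] > 0))
})

test_that("placement fails loudly when the requested density is unachievable", {
  p <- well_sim_params(n_cells = 500, image_shape = c(128L, 128L), seed = 1)
  expect_error(simulate_well(p), "achievable")
})

test_that("dose plate honours the inhibition and dead-fraction curves", {
  model <- drug_response_model(ic50_true = 1, hill = 1, max_inhibition = 1,
                               baseline_cells_per_well = 100, count_cv = 0)
  ex <- dose_response_expectation(model, c(0, 1))
  expect_equal(ex$expected_cells[1], 100)        # untreated = baseline
  expect_equal(ex$dead_fraction[1], 0)
  expect_equal(ex$expected_cells[2], 50)         # definition of the IC50
  expect_error(simulate_dose_plate(model, c(0.1, 1)), "untreated")
  expect_error(simulate_dose_plate(model, c(-1, 0)), "non-negative")
})

test_that("per-well seeds make wells reproducible independent of order", {
  model <- drug_response_model(baseline_cells_per_well = 40, count_cv = 0.1)
  bp <- well_sim_params(image_shape = c(256L, 256L), noise_sd = 2)
  p1 <- simulate_dose_plate(model, c(0, 1), replicates = 2, seed = 5,
                            base_params = bp)
  p2 <- simulate_dose_plate(model, c(0, 1), replicates = 2, seed = 5,
                            base_params = bp)
  expect_identical(p1$wells[["B02"]]$images, p2$wells[["B02"]]$images)
  expect_identical(p1$layout, p2$layout)
  expect_equal(well_seed(5, "B02"), well_seed(5, "B02"))
  expect_false(well_seed(5, "B02") == well_seed(5, "B01"))
})

test_that("scenario catalogue reproduces its stated ground-truth fractions", {
  expect_equal(scenario_library("etoposide-treated")$phase_fractions[[3]], 0.66)
  expect_equal(scenario_library("etoposide-untreated")$phase_fractions[[3]], 0.22)
  sn <- scenario_library("SN38-multiplex")
  expect_equal(vapply(sn$marker_models, `[[`, numeric(1), "positive_fraction"),
               c(gH2AX = 0.90, pATM = 0.80, pATR = 0.60))
  expect_error(scenario_library("nonesuch"), "unknown scenario")
})

test_that("TIFF round trip preserves intensities to 16-bit resolution", {
  p <- pop_params(n = 30, seed = 11, image_shape = c(256L, 256L), noise_sd = 3)
  sim <- simulate_well(p)
  dir <- withr::local_tempdir()
  write_well_images(sim$images, dir, "A01")
  expect_true(file.exists(file.path(dir, "A01_hoechst.tif")))
  back <- read_well_images(dir, "A01", p$channels)
  for (ch in p$channels)
    expect_lt(max(abs(back[[ch]] - pmin(pmax(round(sim$images[[ch]]), 0), 65535))),
              0.51)
  expect_error(read_well_images(dir, "A02", "hoechst"), "missing image")
})

test_that("ground truth and params serialize to CSV and YAML", {
  p <- pop_params(n = 20, seed = 2, image_shape = c(256L, 256L))
  sim <- simulate_well(p)
  dir <- withr::local_tempdir()
  write_ground_truth(sim$truth, p, dir, "A01")
  back <- read.csv(file.path(dir, "A01_truth.csv"))
  expect_equal(nrow(back), 20)
  expect_equal(back$dna_signal, sim$truth$dna_signal)
  y <- yaml::read_yaml(file.path(dir, "A01_params.yaml"))
  expect_equal(y$n_cells, 20)
})
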