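# shared fixture builders; everything is generated in code at test time

marker_model <- function(positive_fraction = 0.5, negative_mean = 500,
                         positive_mean = 20000, lognormal_sigma = 0.4) {
  list(positive_fraction = positive_fraction, negative_mean = negative_mean,
       positive_mean = positive_mean, lognormal_sigma = lognormal_sigma)
}

# population-scale params (no images rendered)
pop_params <- function(n = 2000, seed = 1, markers = list(gH2AX = marker_model()),
                       ...) {
  well_sim_params(n_cells = n, marker_models = markers, seed = seed, ...)
}

# a matching secondary-antibody-only control population: same marker
# channels, positive fraction forced to zero
ct_params <- function(params, n = 1000, seed = 1000) {
  p <- params
  p$n_cells <- as.integer(n)
  p$seed <- as.integer(seed)
  p$dead_fraction <- 0          # CT wells are healthy untreated cells
  p$marker_models <- lapply(p$marker_models, function(m) {
    m$positive_fraction <- 0
    m
  })
  p
}

# CT-anchored gate for one channel, built from a fresh control population
make_gate <- function(params, channel, q = 0.99, n_ct = 1000, seed = 1000) {
  ctp <- ct_params(params, n = n_ct, seed = seed)
  ct_tab <- truth_to_cell_table(sample_cell_population(ctp), well_id = "CT")
  define_gate(ct_tab, channel, q = q)
}

# brute-force percent positive: explicit per-record loop
brute_percent_positive <- function(cells, channel, threshold) {
  n_pos <- 0L
  for (i in seq_len(nrow(cells))) {
    if (cells[[paste0(channel, "_integrated")]][i] > threshold) n_pos <- n_pos + 1L
  }
  100 * n_pos / nrow(cells)
}

# random small cell table for oracle-equivalence checks
random_cell_table <- function(n, channels = c("a", "b"), seed = 1) {
  set.seed(seed)
  tab <- data.frame(well_id = rep("R", n), cell_label = seq_len(n))
  for (ch in channels)
    tab[[paste0(ch, "_integrated")]] <- rlnorm(n, log(1000), 1)
  tab
}
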