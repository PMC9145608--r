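test_that("a degenerate control distribution gates nothing", {
  ctt <- data.frame(well_id = "CT", m_integrated = rep(42, 200))
  g <- define_gate(ctt, "m")
  expect_equal(g$threshold, 42)
  expect_equal(percent_positive(ctt, g)$percent_positive, 0)  # strict >
})

test_that("quantile gates reproduce their nominal false-positive rate", {
  set.seed(101)
  ctt <- data.frame(well_id = "CT", m_integrated = rlnorm(10000, log(500), 0.4))
  g99 <- define_gate(ctt, "m", q = 0.99)
  fresh <- data.frame(well_id = "F", m_integrated = rlnorm(10000, log(500), 0.4))
  pp <- percent_positive(fresh, g99)$percent_positive
  expect_gt(pp, 0.5); expect_lt(pp, 1.6)     # ~1% within binomial CI
  g50 <- define_gate(ctt, "m", q = 0.5)
  pp50 <- percent_positive(fresh, g50)$percent_positive
  expect_gt(pp50, 48); expect_lt(pp50, 52)
})

test_that("too few control cells advises pooling CT wells", {
  ctt <- data.frame(well_id = "CT", m_integrated = rlnorm(50))
  expect_error(define_gate(ctt, "m"), "pool")
  expect_error(define_gate(ctt, "missing"), "not present")
})

test_that("percent positive equals the brute-force per-record count", {
  for (seed in 1:10) {
    tab <- random_cell_table(50 + seed * 7, seed = seed)
    thr <- quantile(tab$a_integrated, 0.6, names = FALSE)
    g <- list(channel = "a", threshold = thr, q = 0.6, n_ct = 0,
              source_wells = "x")
    class(g) <- "gate"
    expect_equal(percent_positive(tab, g)$percent_positive,
                 brute_percent_positive(tab, "a", thr))
  }
  expect_error(percent_positive(random_cell_table(0), list(channel = "a")),
               "empty")
})

test_that("raising the threshold never increases percent positive", {
  for (seed in 1:5) {
    tab <- random_cell_table(200, seed = seed)
    thr <- sort(runif(10, 100, 10000))
    pps <- vapply(thr, function(t) {
      g <- structure(list(channel = "a", threshold = t), class = "gate")
      percent_positive(tab, g)$percent_positive
    }, numeric(1))
    expect_true(all(diff(pps) <= 0))
  }
})

test_that("gate plus percent_positive recovers generator truth within 3 points", {
  params <- pop_params(n = 2000, markers = list(m = marker_model(0.5)))
  g <- make_gate(params, "m")
  for (seed in 1:5) {
    p <- params; p$seed <- seed
    pop <- sample_cell_population(p)
    tab <- truth_to_cell_table(pop)
    est <- percent_positive(tab, g)$percent_positive
    expect_lt(abs(est - 100 * mean(pop$m_positive)), 3)
  }
})

test_that("fold change matches treated/untreated ratios, with flagged zero", {
  expect_equal(fold_change(40, 20), 2)
  expect_equal(fold_change(33.3, 33.3), 1)
  # double-positive increase after topoisomerase-I inhibition: ~five-fold
  expect_equal(fold_change(74.4, 15.7), 4.74, tolerance = 0.001)
  expect_warning(fc <- fold_change(10, 0), "Inf")
  expect_true(is.infinite(fc))
})

test_that("quadrant fractions partition the population exactly", {
  tab <- random_cell_table(500, channels = c("a", "b", "c"), seed = 3)
  gates <- lapply(c("a", "b", "c"), function(ch)
    structure(list(channel = ch,
                   threshold = quantile(tab[[paste0(ch, "_integrated")]], 0.5,
                                        names = FALSE)),
              class = "gate"))
  qr <- quadrant_analysis(tab, gates)
  expect_equal(nrow(qr$combinations), 8)
  expect_equal(sum(qr$combinations$fraction), 1)
  # marginals equal independent per-marker percent positive
  for (i in 1:3) {
    pp <- percent_positive(tab, gates[[i]])$percent_positive
    expect_equal(unname(qr$marginals[gates[[i]]$channel]), pp)
    pos_combos <- qr$combinations[qr$combinations[[gates[[i]]$channel]], ]
    expect_equal(100 * sum(pos_combos$fraction), pp)
  }
  expect_error(quadrant_analysis(tab, gates[c(1, 1)]), "duplicate")
})

test_that("a single fully-positive marker occupies one quadrant", {
  tab <- data.frame(well_id = "w", m_integrated = rep(100, 50))
  g <- structure(list(channel = "m", threshold = 10), class = "gate")
  qr <- quadrant_analysis(tab, list(g))
  expect_equal(qr$combinations["+", "fraction"], 1)
  expect_equal(qr$combinations["-", "fraction"], 0)
})

test_that("independent markers give the product rule for double positives", {
  params <- pop_params(n = 10000, seed = 31,
                       markers = list(m1 = marker_model(0.5),
                                      m2 = marker_model(0.5)))
  pop <- sample_cell_population(params)
  tab <- truth_to_cell_table(pop)
  gates <- list(make_gate(params, "m1"), make_gate(params, "m2", seed = 1001))
  qr <- quadrant_analysis(tab, gates)
  expect_lt(abs(qr$combinations["++", "fraction"] - 0.25), 0.02)
})

test_that("channel overlap check flags bleed-through and passes clean data", {
  params <- pop_params(n = 1500, seed = 41,
                       markers = list(m1 = marker_model(1), m2 = marker_model(1)))
  gates <- list(make_gate(params, "m1"), make_gate(params, "m2", seed = 1001))
  # single-stain tables: marker present on its own channel, background on others
  single <- list()
  for (m in c("m1", "m2")) {
    p <- params
    other <- setdiff(c("m1", "m2"), m)
    p$marker_models[[other]]$positive_fraction <- 0
    p$seed <- 50 + match(m, c("m1", "m2"))
    single[[m]] <- truth_to_cell_table(sample_cell_population(p))
  }
  rep_ok <- channel_overlap_check(single, gates)
  expect_true(attr(rep_ok, "pass"))
  expect_true(all(rep_ok$percent_positive <= 3))  # ~1% false-positive floor
  # 20% spill of m1 signal into the m2 channel breaks the check
  single_bad <- single
  single_bad$m1$m2_integrated <- single_bad$m1$m2_integrated +
    0.2 * single_bad$m1$m1_integrated
  rep_bad <- channel_overlap_check(single_bad, gates)
  expect_false(attr(rep_bad, "pass"))
  expect_error(channel_overlap_check(single["m1"], gates), "m2")
  empty <- channel_overlap_check(list(), list())
  expect_equal(nrow(empty), 0)
  expect_true(attr(empty, "pass"))
})

test_that("replicate comparison matches the textbook Student's t-test", {
  a <- c(12.1, 14.3, 13.0); b <- c(21.4, 20.2, 22.9)
  res <- compare_replicates(a, b)
  # hand-computed pooled-variance t statistic
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(res$t_statistic, t_manual)
  expect_equal(res$p_value, 2 * pt(-abs(t_manual), 4))
  expect_true(res$significant)

  same <- compare_replicates(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  sep <- compare_replicates(c(0, 0.01, -0.01), c(10, 10.01, 9.99))
  expect_true(sep$significant)
  expect_error(compare_replicates(1, c(1, 2)), "replicates")
})

test_that("gates serialize to YAML with their provenance", {
  ctt <- data.frame(well_id = c("C1", "C2"), m_integrated = rlnorm(200))
  g <- define_gate(ctt, "m")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_gates_yaml(g, path)
  y <- yaml::read_yaml(path)
  expect_equal(y$m$channel, "m")
  expect_equal(y$m$threshold, unname(g$threshold))
  expect_equal(y$m$q, 0.99)
  expect_setequal(unlist(y$m$source_wells), c("C1", "C2"))
})
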