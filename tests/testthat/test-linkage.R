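test_that("a fully informative sibship with no recombinants pins theta at 0", {
  # father A/B at L1, C/D at L2; mother homozygous at both; 10 offspring all
  # carrying the A-C paternal gamete
  rows <- list(
    grow("fa", "f1", "father", "M", c(100, 102, 200, 202)),
    grow("mo", "f1", "mother", "F", c(110, 110, 210, 210)))
  for (i in 1:10)
    rows[[length(rows) + 1L]] <-
      grow(paste0("o", i), "f1", "offspring", "M", c(100, 110, 200, 210))
  d <- make_dataset(c("L1", "L2"), rows)
  e <- estimate_two_point(d, "L1", "L2")
  expect_identical(e$theta_m, 0)
  # with the phase summed (prior 1/2), the wrong-phase term vanishes at 0:
  # lnL(0) = log(1/2) + 10 log(1/2) while lnL(0.5) = 20 log(1/2), so the
  # drop to free recombination is 9 log 2
  l0 <- two_point_loglik(d, "L1", "L2", 0, 0.25)
  l5 <- two_point_loglik(d, "L1", "L2", 0.5, 0.25)
  expect_equal(l5 - l0, -9 * log(2), tolerance = 1e-10)
  expect_equal(e$lod_m, 9 * log(2) / log(10), tolerance = 1e-6)
})

test_that("the MLE tracks the recombinant count of an informative sibship", {
  rows <- list(
    grow("fa", "f1", "father", "M", c(100, 102, 200, 202)),
    grow("mo", "f1", "mother", "F", c(110, 110, 210, 210)))
  for (i in 1:8)
    rows[[length(rows) + 1L]] <-
      grow(paste0("p", i), "f1", "offspring", "M", c(100, 110, 200, 210))
  for (i in 1:2)
    rows[[length(rows) + 1L]] <-
      grow(paste0("r", i), "f1", "offspring", "F", c(100, 110, 202, 210))
  d <- make_dataset(c("L1", "L2"), rows)
  e <- estimate_two_point(d, "L1", "L2")
  # 2/10 recombinant; the phase-unknown mixture shifts the MLE from the
  # binomial 0.2 by < 0.005
  expect_lt(abs(e$theta_m - 0.2), 0.005)
  expect_true(is.na(e$theta_f))   # mother uninformative
  expect_equal(e$n_inf_m, 10L)
})

test_that("untyped offspring contribute nothing", {
  rows <- list(
    grow("fa", "f1", "father", "M", c(100, 102, 200, 202)),
    grow("mo", "f1", "mother", "F", c(110, 112, 210, 212)),
    grow("o1", "f1", "offspring", "M", c(NA, NA, NA, NA)))
  d <- make_dataset(c("L1", "L2"), rows)
  for (th in list(c(0, 0), c(0.3, 0.1), c(0.5, 0.5)))
    expect_equal(family_two_point_loglik(d, "f1", "L1", "L2", th[1], th[2]), 0)
})

test_that("family likelihood equals exhaustive phase/transmission enumeration", {
  set.seed(77)
  n_checked <- 0L
  for (seed in 1:12) {
    sim <- small_sim(seed, n_fam = 2, n_off = 3, null_freq = 0.15)
    for (fam in names(xy_families(sim$dataset))) {
      for (th in list(c(0, 0.4), c(0.21, 0.37), c(0.5, 0.5),
                      c(0.07, 0.05))) {
        a <- family_two_point_loglik(sim$dataset, fam, "A", "B",
                                     th[1], th[2])
        b <- oracle_family_loglik(sim$dataset, fam, "A", "B", th[1], th[2])
        expect_equal(a, b, tolerance = 1e-10)
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gte(n_checked, 80L)
})

test_that("the joint maximiser matches the 0.001-step grid oracle", {
  for (seed in c(3, 8, 15, 24, 33, 41, 52, 60, 71, 85)) {
    sim <- small_sim(seed, n_fam = 3, n_off = 5, null_freq = 0.1)
    e <- estimate_two_point(sim$dataset, "A", "B")
    g <- oracle_grid_mle(sim$dataset, "A", "B")
    if (!is.na(e$theta_m)) expect_lt(abs(e$theta_m - g[1]), 1e-3 + 1e-9)
    if (!is.na(e$theta_f)) expect_lt(abs(e$theta_f - g[2]), 1e-3 + 1e-9)
  }
})

test_that("estimates are symmetric under locus swap", {
  sim <- small_sim(5, n_fam = 4, n_off = 6)
  e1 <- estimate_two_point(sim$dataset, "A", "B")
  e2 <- estimate_two_point(sim$dataset, "B", "A")
  expect_equal(e1$theta_m, e2$theta_m, tolerance = 1e-6)
  expect_equal(e1$theta_f, e2$theta_f, tolerance = 1e-6)
  expect_equal(e1$lnL_max, e2$lnL_max, tolerance = 1e-8)
})

test_that("theta stays in [0, 0.5] and LOD is non-negative", {
  for (seed in 101:115) {
    sim <- small_sim(seed, n_fam = 2, n_off = 4, null_freq = 0.2)
    e <- tryCatch(estimate_two_point(sim$dataset, "A", "B"),
                  error = function(e) NULL)  # tiny sets can be uninformative
    if (is.null(e)) next
    for (v in c(e$theta_m, e$theta_f))
      if (!is.na(v)) { expect_gte(v, 0); expect_lte(v, 0.5) }
    for (v in c(e$lod_m, e$lod_f))
      if (!is.na(v)) expect_gte(v, 0)
  }
})

test_that("haldane map function and inverse round-trip", {
  th <- seq(0, 0.49, by = 0.007)
  expect_equal(haldane_theta(haldane_cM(th)), th, tolerance = 1e-9)
  expect_equal(haldane_cM(0.3), 45.81454, tolerance = 1e-5)
})

test_that("map ordering recovers additive three-locus structure", {
  pairs <- data.frame(locusA = c("A", "B", "A"), locusB = c("B", "C", "C"),
                      theta_m = 0, theta_f = c(0.1, 0.1, 0.2),
                      lod_m = 1, lod_f = 1, n_inf_m = 10L, n_inf_f = 10L,
                      stringsAsFactors = FALSE)
  sim <- small_sim(1, loci = c("A", "B", "C"))  # only for the container
  mp <- build_map(sim$dataset, loci = c("A", "B", "C"), pairs = pairs)
  expect_equal(mp$order, c("A", "B", "C"))
  expect_equal(mp$theta_f, c(0.1, 0.1))
  expect_equal(max(mp$pos_m), 0)
  expect_equal(max(mp$pos_f), 2 * haldane_cM(0.1))
})

test_that("six-locus marker order is recovered from simulated families", {
  th <- c(0.15, 0.2, 0.25, 0.2, 0.15)   # distinguishable adjacent intervals
  hits <- 0L
  for (r in 1:10) {
    sim <- simulate_pedigrees(pedigree_sim_config(
      species = "S", n_families = 40, offspring_mean = 12,
      loci = locus_def(sprintf("L%d", 1:6)), theta_f = th,
      n_adult_males = 0, n_adult_females = 0, seed = 300 + r))
    mp <- suppressWarnings(build_map(sim$dataset))
    ok <- identical(mp$order, sprintf("L%d", 1:6)) ||
      identical(mp$order, sprintf("L%d", 6:1))
    hits <- hits + ok
  }
  expect_gte(hits, 9L)
})

test_that("unlinked adjacent intervals are capped and flagged", {
  pairs <- data.frame(locusA = c("A", "B", "A"), locusB = c("B", "C", "C"),
                      theta_m = 0, theta_f = c(0.1, 0.5, NA),
                      lod_m = 1, lod_f = 1, n_inf_m = 10L, n_inf_f = 10L,
                      stringsAsFactors = FALSE)
  sim <- small_sim(1, loci = c("A", "B", "C"))
  expect_warning(mp <- build_map(sim$dataset, loci = c("A", "B", "C"),
                                 pairs = pairs), "capped")
  expect_true(any(mp$capped))
  expect_true(all(mp$theta_f <= 0.49))
})
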