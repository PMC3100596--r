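adults_dataset <- function(m_geno, f_geno, locus = "L1") {
  rows <- list()
  for (i in seq_along(m_geno))
    rows[[length(rows) + 1L]] <- grow(paste0("m", i), "", "adult", "M",
                                      m_geno[[i]])
  for (i in seq_along(f_geno))
    rows[[length(rows) + 1L]] <- grow(paste0("f", i), "", "adult", "F",
                                      f_geno[[i]])
  make_dataset(locus, rows)
}

test_that("G statistic matches direct arithmetic on a 3-allele table", {
  d <- adults_dataset(
    m_geno = list(c(100, 100), c(100, 102), c(100, 104)),
    f_geno = list(c(102, 104), c(104, 104), c(102, 102)))
  res <- sex_allele_freq_test(d, "L1", n_perm = 200, seed = 1)
  tab <- cbind(F = c(0, 3, 3), M = c(4, 1, 1))  # alleles 100, 102, 104
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  G_hand <- 2 * sum(ifelse(tab > 0, tab * log(tab / E), 0))
  expect_equal(res$G, G_hand, tolerance = 1e-12)
  expect_lt(res$p, 1)
})

test_that("identical allele distributions give G = 0 and p = 1", {
  g <- list(c(100, 102), c(100, 100), c(102, 102))
  res <- sex_allele_freq_test(adults_dataset(g, g), "L1",
                              n_perm = 100, seed = 1)
  expect_equal(res$G, 0)
  expect_equal(res$p, 1)
})

test_that("disjoint allele sets reach the minimum attainable p", {
  m <- replicate(10, c(100, 100), simplify = FALSE)
  f <- replicate(10, c(110, 110), simplify = FALSE)
  res <- sex_allele_freq_test(adults_dataset(m, f), "L1",
                              n_perm = 500, seed = 7)
  expect_equal(res$p, 1 / 501)
})

test_that("permutation p-values are super-uniform under exchangeability", {
  # males and females drawn from one pool: sex carries no information
  set.seed(123)
  pvals <- vapply(1:120, function(r) {
    g <- replicate(24, sample(c(100, 102, 104, 106), 2, replace = TRUE),
                   simplify = FALSE)
    d <- adults_dataset(g[1:12], g[13:24])
    sex_allele_freq_test(d, "L1", n_perm = 99, seed = r)$p
  }, 0)
  for (a in c(0.05, 0.1, 0.25))
    expect_lte(mean(pvals <= a), a + 3 * sqrt(a * (1 - a) / length(pvals)))
})

test_that("Y haplotype is read off a clean sibship", {
  rows <- list(
    grow("fa", "f1", "father", "M", c(100, 102)),
    grow("mo", "f1", "mother", "F", c(104, 104)))
  for (i in 1:5) rows[[length(rows) + 1L]] <-
    grow(paste0("s", i), "f1", "offspring", "M", c(100, 104))
  for (i in 1:5) rows[[length(rows) + 1L]] <-
    grow(paste0("d", i), "f1", "offspring", "F", c(102, 104))
  d <- make_dataset("L1", rows)
  y <- infer_y_from_family(d, "f1")
  expect_equal(y$calls$call, "100")
  expect_false(y$calls$inconsistent)
  expect_equal(y$calls$n_informative_sons, 5L)
})

test_that("sibship Y calls match simulator truth at every called locus", {
  for (seed in c(51, 62)) {
    sim <- small_sim(seed, n_fam = 20, n_off = 12,
                     loci = c("A", "B", "C"), null_freq = 0.1)
    fams <- names(xy_families(sim$dataset))
    for (fam in fams) {
      y <- infer_y_from_family(sim$dataset, fam)
      expect_false(any(y$calls$inconsistent))
      truth <- sim$truth$father_y[fam, ]
      for (li in seq_along(y$calls$locus)) {
        call <- y$calls$call[li]
        if (call %in% c("ambiguous", "untyped")) next
        want <- if (truth[li] == 0L) "*" else as.character(truth[li])
        expect_identical(call, want)
      }
    }
  }
})

test_that("a recombinant patriline raises an inconsistency flag", {
  # father X-allele leaking into a son (as after recombination in a
  # sex-reversed XY female) conflicts with his brothers
  rows <- list(
    grow("fa", "f1", "father", "M", c(100, 102)),
    grow("mo", "f1", "mother", "F", c(104, 106)))
  for (i in 1:4) rows[[length(rows) + 1L]] <-
    grow(paste0("s", i), "f1", "offspring", "M", c(100, 104))
  rows[[length(rows) + 1L]] <-
    grow("srev", "f1", "offspring", "M", c(102, 106))  # got the X allele
  d <- make_dataset("L1", rows)
  y <- infer_y_from_family(d, "f1")
  expect_true(y$calls$inconsistent)
  expect_equal(y$calls$call, "ambiguous")
})

test_that("population Y assignment counts planted haplotypes exactly", {
  # four Y haplotypes differing at the first locus only
  y_alleles <- c(100, 104, 108, 112)
  rows <- list()
  for (i in 1:12) {
    y1 <- y_alleles[(i - 1) %% 4 + 1]
    rows[[length(rows) + 1L]] <-
      grow(paste0("m", i), "", "adult", "M", c(y1, 90, 200, 210))
  }
  d <- make_dataset(c("LA", "LB"), rows)
  res <- assign_y_population(d, candidates = list(LA = y_alleles, LB = 200L))
  expect_equal(res$n_haplotypes, 4L)
  # homozygote for a candidate: called but flagged
  rows2 <- list(grow("m1", "", "adult", "M", c(200, 200)))
  d2 <- make_dataset("LB", rows2)
  r2 <- assign_y_population(d2, candidates = list(LB = 200L))
  expect_equal(r2$calls$LB, "200")
  expect_equal(r2$flags$LB, "uninformative-homozygote")
  # empty candidate set: all ambiguous
  r3 <- assign_y_population(d2, candidates = list(LB = integer(0)))
  expect_equal(r3$calls$LB, "ambiguous")
})

test_that("wildcard counting does not split on uncalled loci", {
  rows <- list(
    grow("m1", "", "adult", "M", c(100, 90, 200, 210)),
    grow("m2", "", "adult", "M", c(100, 90, NA, NA)),   # untyped at LB
    grow("m3", "", "adult", "M", c(104, 90, 200, 210)))
  d <- make_dataset(c("LA", "LB"), rows)
  res <- assign_y_population(d, candidates = list(LA = c(100L, 104L),
                                                  LB = 200L))
  expect_equal(res$n_haplotypes, 2L)  # m2 merges with m1
})
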