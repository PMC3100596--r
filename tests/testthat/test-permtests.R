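two_species_males <- function(geno_a, geno_b, locus = "L1") {
  rows <- list()
  for (i in seq_along(geno_a))
    rows[[length(rows) + 1L]] <- grow(paste0("a", i), "", "adult", "M",
                                      geno_a[[i]], species = "SpA")
  for (i in seq_along(geno_b))
    rows[[length(rows) + 1L]] <- grow(paste0("b", i), "", "adult", "M",
                                      geno_b[[i]], species = "SpB")
  make_dataset(locus, rows)
}

test_that("equal alleles everywhere give observed 0 and p 1", {
  d <- two_species_males(list(c(100, 100), c(100, 100)),
                         list(c(100, 100), c(100, 100)))
  res <- size_diff_test(d, loci = "L1", n_replicates = 200, seed = 1)
  expect_equal(res$observed_mean, 0)
  expect_true(all(res$null_means == 0))
  expect_equal(res$p, 1)
})

test_that("a forced cross-species pairing makes the null degenerate", {
  # pools {100} and {110}: every cross-species pair differs by exactly 10,
  # so the null distribution is a point mass at 10
  d <- two_species_males(list(c(100, 100), c(100, 100)),
                         list(c(110, 110)))
  res <- size_diff_test(d, loci = "L1", n_replicates = 300, seed = 2)
  expect_equal(res$null_sd, 0)
  expect_equal(res$null_mean, 10)
  expect_equal(res$observed_mean, 0)       # conspecific homozygotes
  expect_equal(res$p, 1 / 301)             # maximal X-Y similarity signal
})

test_that("simulated p matches full enumeration of the null on a toy dataset", {
  # one genotype slot, three alleles across two species: the null draws
  # allele 1 uniformly from the pool, allele 2 uniformly from the other
  # species' alleles
  d <- two_species_males(list(c(100, 104)), list(c(110, 110)))
  res <- size_diff_test(d, loci = "L1", n_replicates = 20000, seed = 3)
  pool <- data.frame(allele = c(100, 104, 110, 110),
                     species = c("SpA", "SpA", "SpB", "SpB"))
  probs <- diffs <- numeric(0)
  for (i in seq_len(nrow(pool))) {
    other <- which(pool$species != pool$species[i])
    for (j in other) {
      probs <- c(probs, (1 / nrow(pool)) * (1 / length(other)))
      diffs <- c(diffs, abs(pool$allele[i] - pool$allele[j]))
    }
  }
  p_exact <- sum(probs[diffs <= res$observed_mean + 1e-12])
  se <- sqrt(p_exact * (1 - p_exact) / res$n_replicates)
  expect_lt(abs(res$p - p_exact), 4 * se + 1 / res$n_replicates)
})

test_that("size test is invariant to shifting one locus by a constant", {
  d1 <- two_species_males(list(c(100, 104), c(102, 106)),
                          list(c(110, 112), c(108, 108)))
  d2 <- two_species_males(list(c(600, 604), c(602, 606)),
                          list(c(610, 612), c(608, 608)))
  r1 <- size_diff_test(d1, loci = "L1", n_replicates = 500, seed = 9)
  r2 <- size_diff_test(d2, loci = "L1", n_replicates = 500, seed = 9)
  expect_equal(r1$observed_mean, r2$observed_mean)
  expect_equal(r1$null_means, r2$null_means)
  expect_equal(r1$p, r2$p)
})

test_that("genotypes with null or missing alleles are excluded", {
  d <- two_species_males(list(c(100, 104), c(100, 0), c(NA, NA)),
                         list(c(110, 112)))
  res <- size_diff_test(d, loci = "L1", n_replicates = 100, seed = 1)
  expect_equal(res$n_pairs, 2L)  # the */NA genotypes dropped
})

test_that("cross-amplification exact formula matches hand enumeration", {
  # 2 loci x 1 species, z = 2 zeros, d_obs = 0: of the C(4,2) = 6
  # placements, 2 put both zeros in the same (locus, species) pair
  df <- data.frame(locus = c("L1", "L1", "L2", "L2"),
                   species = "S", gametolog = c("X", "Y", "X", "Y"),
                   amplified = c(0, 0, 1, 1))
  m <- crossamp_matrix(df)
  expect_equal(crossamp_exact(m), 1 / 3, tolerance = 1e-12)
  expect_equal(xylink:::crossamp_discordant(unclass(m)), 0)
})

test_that("degenerate matrices give p 1", {
  df <- expand.grid(locus = c("L1", "L2"), species = "S",
                    gametolog = c("X", "Y"), stringsAsFactors = FALSE)
  df$amplified <- 1
  res <- crossamp_test(crossamp_matrix(df), n_replicates = 10, seed = 1)
  expect_equal(res$observed_discordant, 0L)
  expect_equal(res$p_sim, 1)
  expect_equal(res$p_exact, 1)
})

test_that("simulated and exact cross-amplification p agree on random matrices", {
  set.seed(99)
  n_rep <- 4000L
  for (k in 1:12) {
    nl <- sample(3:6, 1); ns <- sample(2:3, 1)
    df <- expand.grid(locus = sprintf("L%d", 1:nl),
                      species = sprintf("S%d", 1:ns),
                      gametolog = c("X", "Y"), stringsAsFactors = FALSE)
    df$amplified <- 1
    z <- sample(1:(nl * ns), 1)
    df$amplified[sample(nrow(df), z)] <- 0
    m <- crossamp_matrix(df)
    res <- crossamp_test(m, n_replicates = n_rep, seed = k)
    pe <- res$p_exact
    se <- sqrt(max(pe * (1 - pe), 0) / n_rep)
    expect_lt(abs(res$p_sim - pe), 4 * se + 2 / n_rep)
  }
})

test_that("cross-amplification test is invariant to relabelling", {
  df <- expand.grid(locus = sprintf("L%d", 1:4), species = c("S1", "S2"),
                    gametolog = c("X", "Y"), stringsAsFactors = FALSE)
  df$amplified <- 1
  df$amplified[c(1, 6, 11)] <- 0
  m1 <- crossamp_matrix(df)
  df2 <- df
  df2$locus <- chartr("1234", "4321", df2$locus)    # permute locus names
  df2$species <- ifelse(df2$species == "S1", "S2", "S1")
  m2 <- crossamp_matrix(df2)
  expect_equal(crossamp_exact(m1), crossamp_exact(m2))
  r1 <- crossamp_test(m1, n_replicates = 500, seed = 5)
  r2 <- crossamp_test(m2, n_replicates = 500, seed = 5)
  expect_equal(r1$observed_discordant, r2$observed_discordant)
  expect_equal(r1$p_sim, r2$p_sim)
})
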