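aln <- function(...) {
  s <- c(...)
  stats::setNames(unname(s), names(s))
}

test_that("p and JC distances match their closed forms", {
  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("C", 10), rep("A", 90)), collapse = "")
  seqs <- c("S|X|1" = s1, "S|Y|1" = s2)
  dp <- pairwise_distance(seqs, "p")
  expect_equal(dp["S|X|1", "S|Y|1"], 0.1)
  dj <- pairwise_distance(seqs, "JC")
  expect_equal(round(dj["S|X|1", "S|Y|1"], 5), 0.10733)
  expect_equal(dj["S|X|1", "S|Y|1"], -0.75 * log(1 - 0.4 / 3),
               tolerance = 1e-12)
  expect_equal(diag(dj), c("S|X|1" = 0, "S|Y|1" = 0))
  # identical sequences
  expect_equal(pairwise_distance(c("S|X|1" = s1, "S|Y|2" = s1))[1, 2], 0)
})

test_that("gap handling: pairwise deletion, and no compared sites errors", {
  seqs <- c("S|X|1" = "AC-T", "S|Y|1" = "AC-A")
  expect_equal(pairwise_distance(seqs, "p")[1, 2], 1 / 3)
  seqs <- c("S|X|1" = "--AA", "S|Y|1" = "AA--")
  expect_error(pairwise_distance(seqs), "no compared sites")
})

test_that("saturated JC pairs are infinite and NJ refuses them", {
  s1 <- paste(rep("A", 40), collapse = "")
  s2 <- paste(rep("C", 40), collapse = "")
  s3 <- paste(rep("G", 40), collapse = "")
  d <- pairwise_distance(c("A|X|1" = s1, "B|X|1" = s2, "C|X|1" = s3), "JC")
  expect_true(all(is.infinite(d[upper.tri(d)])))
  expect_error(nj_tree(d), "non-finite")
})

test_that("neighbor joining inverts additive distance matrices", {
  set.seed(31)
  for (k in 1:50) {
    n <- sample(4:9, 1)
    tr <- ape::rtree(n, br = stats::runif(2 * n - 2, 0.05, 1))
    tr$tip.label <- make_tip_label("S", "X", seq_len(n))
    dm <- ape::cophenetic.phylo(tr)
    est <- nj_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(tr), est), 0,
                 ignore_attr = TRUE)
    expect_equal(sort(est$edge.length),
                 sort(ape::unroot(tr)$edge.length), tolerance = 1e-8)
  }
})

test_that("tip order does not change the NJ topology", {
  set.seed(7)
  tr <- ape::rtree(8, br = stats::runif(14, 0.05, 1))
  tr$tip.label <- make_tip_label("S", "X", 1:8)
  dm <- ape::cophenetic.phylo(tr)
  t1 <- nj_tree(dm)
  perm <- sample(8)
  t2 <- nj_tree(dm[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
})

test_that("bootstrap supports behave at the extremes and are stable", {
  # duplicated informative columns: one certain split
  base <- c("A|X|1" = "AAAA", "A|X|2" = "AAAA",
            "B|X|1" = "CCCC", "B|X|2" = "CCCC", "B|X|3" = "CCTT")
  tr1 <- bootstrap_support(base, B = 1, seed = 1, model = "p")
  expect_true(all(as.numeric(tr1$node.label) %in% c(0, 100)))
  tr <- bootstrap_support(base, B = 200, seed = 2, model = "p")
  lab <- parse_tip_labels(tr$tip.label)
  # the A|A vs B|B|B split is supported in every replicate
  expect_true(any(as.numeric(tr$node.label) == 100))

  # supports reproducible across seeds within Monte Carlo error
  sim <- simulate_genealogy(coal_sim_config("frozen_ancestral", seed = 5))
  seqs <- evolve_sequences(sim$tree, 2e-8, 400, seed = 6)
  b1 <- bootstrap_support(seqs, B = 1000, seed = 10)
  b2 <- bootstrap_support(seqs, B = 1000, seed = 11)
  expect_true(all(abs(as.numeric(b1$node.label) -
                        as.numeric(b2$node.label)) <= 5))
})

test_that("archetypal topologies are classified as in the scenario figures", {
  # every species' X and Y sister: species clustering
  t_sp <- ape::read.tree(text =
    "((Ha|X|1:1,Ha|Y|1:1):1,((Hi|X|1:1,Hi|Y|1:1):1,(Hm|X|1:1,Hm|Y|1:1):1):1);")
  r <- classify_clustering(t_sp, sister_species = c("Hi", "Hm"))
  expect_equal(r$verdict, "species_clustered")
  expect_true(all(r$species_monophyly))
  expect_equal(r$fitch_species, 2L)  # n_species - 1 when species-clustered

  # sister-group Y tips clade apart from X: gametolog clustering
  t_gam <- ape::read.tree(text =
    "(Ha|X|1:1,(Ha|Y|1:1,((Hi|Y|1:1,Hm|Y|1:1):1,(Hi|X|1:1,Hm|X|1:1):1):1):1);")
  r <- classify_clustering(t_gam, sister_species = c("Hi", "Hm"))
  expect_equal(r$verdict, "gametolog_clustered")
  expect_true(r$gametolog_clade)

  # scrambled: mixed
  t_mix <- ape::read.tree(text =
    "((Ha|X|1:1,Hi|Y|1:1):1,((Hi|X|1:1,Hm|Y|1:1):1,(Hm|X|1:1,Ha|Y|1:1):1):1);")
  r <- classify_clustering(t_mix, sister_species = c("Hi", "Hm"))
  expect_equal(r$verdict, "mixed")
})

test_that("classification is invariant to rooting and tip order", {
  t_gam <- ape::read.tree(text =
    "(Ha|X|1:1,(Ha|Y|1:1,((Hi|Y|1:1,Hm|Y|1:1):1,(Hi|X|1:1,Hm|X|1:1):1):1):1);")
  v0 <- classify_clustering(t_gam, sister_species = c("Hi", "Hm"))$verdict
  for (tip in c("Hi|X|1", "Hm|Y|1", "Ha|X|1")) {
    rr <- ape::root(t_gam, outgroup = tip, resolve.root = TRUE)
    expect_equal(classify_clustering(rr,
                                     sister_species = c("Hi", "Hm"))$verdict,
                 v0)
  }
  rot <- ape::rotateConstr(t_gam, sample(t_gam$tip.label))
  expect_equal(classify_clustering(rot,
                                   sister_species = c("Hi", "Hm"))$verdict,
               v0)
})

test_that("tips without proper gametolog labels are rejected", {
  t_bad <- ape::read.tree(text =
    "((Ha|unknown|1:1,Ha|Y|1:1):1,(Hi|X|1:1,Hi|Y|1:1):1);")
  expect_error(classify_clustering(t_bad), "unknown gametolog")
})
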