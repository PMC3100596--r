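# Independent oracles used across the suite. These re-derive expected values
# by direct enumeration / closed forms, sharing no code with the package
# internals they check.

# Brute-force two-point family log-likelihood: enumerate both parental
# phases (prior 1/4 over the four labelled phase combinations, which reduces
# to 1/2 per double-heterozygous parent) and all 16 transmission
# combinations per offspring, with plain-R genotype compatibility and the
# dropout-to-missing rule.
oracle_family_loglik <- function(dataset, family, A, B, tm, tf) {
  ind <- dataset$ind
  fam <- xy_families(dataset)[[family]]
  gg <- function(i, loc) c(ind[[paste0(loc, ".a1")]][i],
                           ind[[paste0(loc, ".a2")]][i])
  fill <- function(g) {
    W <- -1L
    if (is.na(g[1]) && is.na(g[2])) c(W, W)
    else if (is.na(g[2])) c(g[1], W)
    else if (is.na(g[1])) c(g[2], W)
    else g
  }
  compat1 <- function(t1, t2, o) {
    subs <- function(t) if (t == -1L) unique(c(o[!is.na(o)], 0L, 888888L)) else t
    for (x in subs(t1)) for (y in subs(t2)) {
      obs <- o[!is.na(o)]
      if (length(obs) == 0) return(TRUE)
      nn <- (x == 0L) + (y == 0L)
      ok <- if (nn == 2) all(obs == 0L)
      else if (nn == 1) {
        a <- if (x == 0L) y else x
        if (length(obs) == 1) obs %in% c(a, 0L)
        else (obs[1] == a && obs[2] == a) || all(sort(obs) == sort(c(a, 0L)))
      } else {
        if (length(obs) == 1) obs %in% c(x, y)
        else all(sort(obs) == sort(c(x, y)))
      }
      if (ok) return(TRUE)
    }
    FALSE
  }
  faA <- fill(gg(fam$father, A)); faB <- fill(gg(fam$father, B))
  moA <- fill(gg(fam$mother, A)); moB <- fill(gg(fam$mother, B))
  L <- 0
  for (fp in 1:2) for (mp in 1:2) {
    fhapB <- if (fp == 1) faB else rev(faB)
    mhapB <- if (mp == 1) moB else rev(moB)
    pf <- 1
    for (o in fam$offspring) {
      oA <- gg(o, A); oB <- gg(o, B)
      dropA <- !all(is.na(oA)) &&
        !any(sapply(1:2, function(i) sapply(1:2, function(k)
          compat1(faA[i], moA[k], oA))))
      dropB <- !all(is.na(oB)) &&
        !any(sapply(1:2, function(j) sapply(1:2, function(l)
          compat1(fhapB[j], mhapB[l], oB))))
      po <- 0
      for (i in 1:2) for (j in 1:2) for (k in 1:2) for (l in 1:2) {
        pr <- 0.5 * (if (i == j) 1 - tm else tm) *
              0.5 * (if (k == l) 1 - tf else tf)
        okA <- dropA || all(is.na(oA)) || compat1(faA[i], moA[k], oA)
        okB <- dropB || all(is.na(oB)) || compat1(fhapB[j], mhapB[l], oB)
        if (okA && okB) po <- po + pr
      }
      pf <- pf * po
    }
    L <- L + 0.25 * pf
  }
  log(L)
}

oracle_dataset_loglik <- function(dataset, A, B, tm, tf) {
  sum(vapply(names(xy_families(dataset)), function(f)
    oracle_family_loglik(dataset, f, A, B, tm, tf), 0))
}

# Exhaustive grid maximiser of the dataset log-likelihood (step 0.001).
oracle_grid_mle <- function(dataset, A, B, step = 0.001) {
  g <- seq(0, 0.5, by = step)
  gr <- expand.grid(tm = g, tf = g)
  ll <- two_point_loglik(dataset, A, B, gr$tm, gr$tf)
  as.numeric(gr[which.max(ll), ])
}

# small simulated dataset for oracle comparisons
small_sim <- function(seed, n_fam = 3, n_off = 4, loci = c("A", "B"),
                      theta_f = NULL, null_freq = 0.1) {
  if (is.null(theta_f)) theta_f <- stats::runif(length(loci) - 1, 0.05, 0.45)
  simulate_pedigrees(pedigree_sim_config(
    species = "S", n_families = n_fam, offspring_mean = n_off,
    loci = locus_def(loci), theta_f = theta_f,
    null_allele_freq = null_freq,
    n_adult_males = 0, n_adult_females = 0, seed = seed))
}

# hand construction of a dataset from explicit genotype rows
make_dataset <- function(loci, rows) {
  gc <- as.vector(rbind(paste0(loci, ".a1"), paste0(loci, ".a2")))
  ind <- do.call(rbind, lapply(rows, function(r) {
    stopifnot(length(r$g) == length(gc))
    df <- data.frame(id = r$id, family = r$family, role = r$role,
                     sex = r$sex, species = r$species,
                     population = r$species, stringsAsFactors = FALSE)
    for (j in seq_along(gc)) df[[gc[j]]] <- r$g[j]
    df
  }))
  xy_dataset(locus_def(loci), ind)
}

# shorthand for a genotype row
grow <- function(id, family, role, sex, g, species = "S") {
  list(id = id, family = family, role = role, sex = sex, species = species,
       g = as.integer(g))
}
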