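# Two-point sex-specific linkage machinery.
#
# The family likelihood sums over the unknown linkage phase of each
# double-heterozygous parent (prior 1/2 per phase, constant across the
# sibship) and over all parental transmissions consistent with each
# offspring's unphased genotype. Missing offspring alleles are marginalised;
# explicit null alleles are inheritable alleles; an offspring genotype that is
# incompatible with the face-value parental genotypes at a locus (suspected
# allelic dropout) is treated as missing at that locus.
#
# For speed the per-offspring likelihood is reduced at build time to a 2x2
# table of coefficients over the father/mother recombination indicators:
#   P(obs | phases, tm, tf) = sum_{rf, rm} C[rf, rm] tm^rf (1-tm)^(1-rf)
#                                          tf^rm (1-tf)^(1-rm)
# so evaluating the log-likelihood at any (tm, tf) — or over a whole grid —
# is a small matrix product.

fill_wild <- function(g) {
  if (is.na(g[1]) && is.na(g[2])) return(c(WILDCARD, WILDCARD))
  if (is.na(g[1])) return(c(g[2], WILDCARD))
  if (is.na(g[2])) return(c(g[1], WILDCARD))
  g
}

is_double_het <- function(gA, gB) {
  !anyNA(gA) && !anyNA(gB) && gA[1] != gA[2] && gB[1] != gB[2]
}

# Compatibility of each (father hap i, mother hap k) transmission with an
# observed offspring genotype at one locus; all-incompatible (dropout) or
# untyped loci become uninformative (all 1).
compat_matrix <- function(fal, mal, obs) {
  m <- matrix(0, 2, 2)
  for (i in 1:2) for (k in 1:2)
    m[i, k] <- as.numeric(pair_obs_compat(fal[i], mal[k], obs[1], obs[2]))
  if (all(m == 0)) m[] <- 1
  m
}

# Per-dataset cache of single-locus quantities: parental haplotype alleles
# (wildcard-filled), heterozygosity, and per-offspring 2x2 compatibility
# tables. Locus-pair structures are assembled from it, so computing all
# pairwise estimates touches each locus only once.
precompute_compat <- function(dataset, loci = NULL) {
  if (is.null(loci)) loci <- dataset$loci$name
  fams <- xy_families(dataset)
  # one matrix lookup instead of data.frame column access per genotype
  a1m <- vapply(loci, function(l) dataset$ind[[paste0(l, ".a1")]],
                integer(nrow(dataset$ind)))
  a2m <- vapply(loci, function(l) dataset$ind[[paste0(l, ".a2")]],
                integer(nrow(dataset$ind)))
  dim(a1m) <- dim(a2m) <- c(nrow(dataset$ind), length(loci))
  per_fam <- vector("list", length(fams))
  for (fi in seq_along(fams)) {
    fam <- fams[[fi]]
    het_f <- het_m <- logical(length(loci))
    cmat <- vector("list", length(loci))
    for (li in seq_along(loci)) {
      faL <- fill_wild(c(a1m[fam$father, li], a2m[fam$father, li]))
      moL <- fill_wild(c(a1m[fam$mother, li], a2m[fam$mother, li]))
      het_f[li] <- faL[1] != faL[2] && faL[1] != WILDCARD &&
        faL[2] != WILDCARD
      het_m[li] <- moL[1] != moL[2] && moL[1] != WILDCARD &&
        moL[2] != WILDCARD
      cm <- vector("list", length(fam$offspring))
      for (oi in seq_along(fam$offspring)) {
        o1 <- a1m[fam$offspring[oi], li]; o2 <- a2m[fam$offspring[oi], li]
        cm[oi] <- if (is.na(o1) && is.na(o2)) list(NULL)
                  else list(compat_matrix(faL, moL, c(o1, o2)))
      }
      cmat[[li]] <- cm
    }
    per_fam[[fi]] <- list(het_f = het_f, het_m = het_m,
                          cmat = cmat, n_off = length(fam$offspring))
  }
  list(loci = loci, per_fam = per_fam, fam_names = names(fams))
}

# Collapse the 16 transmission combinations into the 4x4 (phase combo,
# recombination combo) coefficient table using row/column swaps of the
# locus-B compatibility table.
combine_compat <- function(cA, cB0) {
  Co <- matrix(0, 4L, 4L)
  for (fp in 1:2) for (mp in 1:2) {
    pc <- fp + 2L * (mp - 1L)
    cB <- cB0
    if (fp == 2L) cB <- cB[2:1, , drop = FALSE]
    if (mp == 2L) cB <- cB[, 2:1, drop = FALSE]
    Co[pc, 1L] <- sum(cA * cB)                          # rf=0, rm=0
    Co[pc, 2L] <- sum(cA * cB[2:1, , drop = FALSE])     # rf=1, rm=0
    Co[pc, 3L] <- sum(cA * cB[, 2:1, drop = FALSE])     # rf=0, rm=1
    Co[pc, 4L] <- sum(cA * cB[2:1, 2:1, drop = FALSE])  # rf=1, rm=1
  }
  0.25 * Co
}

# Build the likelihood structure for one locus pair over all families.
build_pair_struct <- function(dataset, locusA, locusB, cache = NULL) {
  if (is.null(cache)) cache <- precompute_compat(dataset, c(locusA, locusB))
  ia <- match(locusA, cache$loci); ib <- match(locusB, cache$loci)
  if (is.na(ia)) stop("unknown locus: ", locusA)
  if (is.na(ib)) stop("unknown locus: ", locusB)
  C_list <- list(); fam_of_row <- integer(0)
  n_inf_m <- n_inf_f <- 0L
  ones <- matrix(1, 2, 2)
  for (fi in seq_along(cache$per_fam)) {
    pf <- cache$per_fam[[fi]]
    f_dhet <- pf$het_f[ia] && pf$het_f[ib]
    m_dhet <- pf$het_m[ia] && pf$het_m[ib]
    for (oi in seq_len(pf$n_off)) {
      cA <- pf$cmat[[ia]][[oi]]
      cB0 <- pf$cmat[[ib]][[oi]]
      if (!is.null(cA) && !is.null(cB0)) {
        if (f_dhet) n_inf_m <- n_inf_m + 1L
        if (m_dhet) n_inf_f <- n_inf_f + 1L
      }
      if (is.null(cA) && is.null(cB0)) next       # untyped at both loci
      allA1 <- is.null(cA) || all(cA == 1)
      allB1 <- is.null(cB0) || all(cB0 == 1)
      if (allA1 && allB1) next                    # uninformative row
      C_list[[length(C_list) + 1L]] <-
        combine_compat(if (is.null(cA)) ones else cA,
                       if (is.null(cB0)) ones else cB0)
      fam_of_row <- c(fam_of_row, fi)
    }
  }
  M <- length(C_list)
  n_fam <- length(cache$per_fam)
  if (M > 0L) {
    arr <- array(unlist(C_list), c(4L, 4L, M))       # [pc, rc, m]
    arr <- aperm(arr, c(3L, 1L, 2L))                 # [m, pc, rc]
    Cmat <- matrix(arr, M * 4L, 4L)                  # row = m + (pc-1)*M
    row_group <- rep(fam_of_row, times = 4L) +
      rep((0:3) * n_fam, each = M)
  } else {
    Cmat <- matrix(0, 0, 4L); row_group <- integer(0)
  }
  list(locusA = locusA, locusB = locusB, Cmat = Cmat,
       row_group = row_group, n_fam = n_fam, M = M,
       fam_names = cache$fam_names,
       n_inf_m = n_inf_m, n_inf_f = n_inf_f)
}

# Per-family log-likelihood at (tm[g], tf[g]) pairs -> matrix [n_fam_eff, G].
# Families contributing no informative row have lnL = 0 and are omitted;
# attr "fams" gives the family indices of the rows returned.
eval_loglik_by_family <- function(struct, tm, tf) {
  G <- length(tm)
  stopifnot(length(tf) == G)
  # tolerate optimiser finite-difference probes just outside the box
  tm <- pmin(pmax(tm, 0), 0.5)
  tf <- pmin(pmax(tf, 0), 0.5)
  if (struct$M == 0L) {
    out <- matrix(0, 0, G); attr(out, "fams") <- integer(0); return(out)
  }
  W <- rbind((1 - tm) * (1 - tf), tm * (1 - tf),
             (1 - tm) * tf, tm * tf)            # rc order 00,10,01,11
  P <- struct$Cmat %*% W                         # [M*4, G]
  LP <- log(P)
  S <- rowsum(LP, struct$row_group)              # groups sorted ascending
  gid <- sort(unique(struct$row_group))
  F_eff <- length(gid) %/% 4L
  arr <- array(S, c(F_eff, 4L, G))
  m12 <- pmax(arr[, 1L, , drop = FALSE], arr[, 2L, , drop = FALSE])
  m34 <- pmax(arr[, 3L, , drop = FALSE], arr[, 4L, , drop = FALSE])
  mx <- array(pmax(m12, m34), c(F_eff, G))
  tot <- exp(arr[, 1L, ] - mx) + exp(arr[, 2L, ] - mx) +
         exp(arr[, 3L, ] - mx) + exp(arr[, 4L, ] - mx)
  out <- mx + log(tot) + log(0.25)
  out[mx == -Inf] <- -Inf
  out <- matrix(out, F_eff, G)
  attr(out, "fams") <- gid[seq_len(F_eff)]
  out
}

eval_loglik <- function(struct, tm, tf) {
  fg <- eval_loglik_by_family(struct, tm, tf)
  if (nrow(fg) == 0L) return(rep(0, length(tm)))
  colSums(fg)
}

#' Two-point log-likelihood of one family
#'
#' Log-likelihood of a sibship at a pair of loci, as a function of the male
#' and female recombination fractions. Sums over unknown parental phases
#' (prior 1/2 each for a double-heterozygous parent) and over transmissions
#' consistent with each offspring's unphased genotype; missing data are
#' marginalised and null alleles treated as inheritable alleles.
#'
#' @param dataset an [xy_dataset].
#' @param family family id (a single name from [xy_families]).
#' @param locusA,locusB locus names.
#' @param theta_m,theta_f recombination fractions in `[0, 0.5]`; equal-length
#'   vectors are evaluated elementwise.
#' @return numeric vector of log-likelihoods.
#' @export
family_two_point_loglik <- function(dataset, family, locusA, locusB,
                                    theta_m, theta_f) {
  ind <- dataset$ind
  keep <- ind$family == family
  if (!any(keep)) stop("unknown family: ", family)
  sub <- xy_dataset(dataset$loci, ind[keep, , drop = FALSE])
  struct <- build_pair_struct(sub, locusA, locusB)
  eval_loglik(struct, theta_m, theta_f)
}

#' Two-point log-likelihood of a whole dataset
#'
#' Sum of [family_two_point_loglik] over all families.
#'
#' @inheritParams family_two_point_loglik
#' @return numeric vector of log-likelihoods.
#' @export
two_point_loglik <- function(dataset, locusA, locusB, theta_m, theta_f) {
  struct <- build_pair_struct(dataset, locusA, locusB)
  G <- length(theta_m)
  out <- numeric(G)
  chunk <- 5000L
  for (s in seq(1L, G, by = chunk)) {
    e <- min(s + chunk - 1L, G)
    out[s:e] <- eval_loglik(struct, theta_m[s:e], theta_f[s:e])
  }
  out
}

# maximise over the active thetas; snap near-boundary solutions exactly onto
# the boundary when the likelihood allows it
maximise_struct <- function(struct) {
  has_m <- struct$n_inf_m > 0L
  has_f <- struct$n_inf_f > 0L
  # cap -Inf (a boundary theta made a required recombinant impossible) so
  # box-constrained optimisers keep finite objective values
  f2 <- function(p) min(-eval_loglik(struct, p[1], p[2]), 1e10)
  if (has_m && has_f) {
    g <- seq(0, 0.5, by = 0.025)
    gr <- expand.grid(tm = g, tf = g)
    v <- eval_loglik(struct, gr$tm, gr$tf)
    p0 <- as.numeric(gr[which.max(v), ])
    opt <- stats::optim(p0, f2, method = "L-BFGS-B",
                        lower = c(0, 0), upper = c(0.5, 0.5),
                        control = list(factr = 1e4, pgtol = 1e-12))
    best <- opt$par; bl <- -opt$value
  } else if (has_m || has_f) {
    which_s <- if (has_m) 1L else 2L
    f1 <- function(x) {
      p <- c(0.25, 0.25); p[which_s] <- x; -f2(p)
    }
    opt <- stats::optimize(f1, c(0, 0.5), maximum = TRUE, tol = 1e-8)
    best <- c(0.25, 0.25); best[which_s] <- opt$maximum
    bl <- opt$objective
  } else {
    stop("no informative meioses for either sex at ",
         struct$locusA, " x ", struct$locusB)
  }
  # boundary snapping (also catches optimize() stopping short of 0 / 0.5)
  for (s in 1:2) {
    for (b in c(0, 0.5)) {
      cand <- best; cand[s] <- b
      lv <- -f2(cand)
      if (lv >= bl - 1e-9 && abs(best[s] - b) < 0.01) { best <- cand; bl <- lv }
    }
  }
  list(theta = best, lnL = bl, has_m = has_m, has_f = has_f)
}

#' Sex-specific two-point recombination estimate
#'
#' Jointly maximises the summed family log-likelihood over
#' `(theta_m, theta_f)` in `[0, 0.5]^2` and reports sex-specific LOD scores
#' `lod_s = log10 L(theta_hat) - log10 L(theta_hat with theta_s := 0.5)`.
#' When one sex has no informative meiosis (no parent of that sex doubly
#' heterozygous), its estimate and LOD are `NA`.
#'
#' @inheritParams family_two_point_loglik
#' @param cache optional precomputed compatibility cache (internal use by
#'   [estimate_all_pairs]).
#' @return object of class `two_point`: list with `locusA`, `locusB`,
#'   `theta_m`, `theta_f`, `lnL_max`, `lod_m`, `lod_f`, `n_inf_m`, `n_inf_f`.
#' @export
estimate_two_point <- function(dataset, locusA, locusB, cache = NULL) {
  struct <- build_pair_struct(dataset, locusA, locusB, cache = cache)
  fit <- maximise_struct(struct)
  lod <- c(NA_real_, NA_real_)
  th <- fit$theta
  for (s in 1:2) {
    if ((s == 1L && fit$has_m) || (s == 2L && fit$has_f)) {
      p <- th; p[s] <- 0.5
      lod[s] <- max(0, (fit$lnL - eval_loglik(struct, p[1], p[2])) / log(10))
    }
  }
  structure(list(locusA = locusA, locusB = locusB,
                 theta_m = if (fit$has_m) th[1] else NA_real_,
                 theta_f = if (fit$has_f) th[2] else NA_real_,
                 lnL_max = fit$lnL,
                 lod_m = lod[1], lod_f = lod[2],
                 n_inf_m = struct$n_inf_m, n_inf_f = struct$n_inf_f),
            class = "two_point")
}

#' @export
print.two_point <- function(x, ...) {
  cat(sprintf("<two_point> %s x %s  theta_m=%s (LOD %s, n=%d)  theta_f=%s (LOD %s, n=%d)\n",
              x$locusA, x$locusB,
              format(x$theta_m, digits = 4), format(x$lod_m, digits = 4),
              x$n_inf_m,
              format(x$theta_f, digits = 4), format(x$lod_f, digits = 4),
              x$n_inf_f))
  invisible(x)
}

#' All pairwise two-point estimates
#'
#' @param dataset an [xy_dataset].
#' @param loci character vector of loci (default all).
#' @return `data.frame` with one row per unordered locus pair.
#' @export
estimate_all_pairs <- function(dataset, loci = NULL) {
  if (is.null(loci)) loci <- dataset$loci$name
  cache <- precompute_compat(dataset, loci)
  out <- list()
  for (i in seq_along(loci)) for (j in seq_along(loci)) {
    if (j <= i) next
    e <- estimate_two_point(dataset, loci[i], loci[j], cache = cache)
    out[[length(out) + 1L]] <- data.frame(
      locusA = loci[i], locusB = loci[j],
      theta_m = e$theta_m, theta_f = e$theta_f,
      lod_m = e$lod_m, lod_f = e$lod_f,
      n_inf_m = e$n_inf_m, n_inf_f = e$n_inf_f,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Recombination-rate matrix (male above, female below the diagonal)
#'
#' Lays out pairwise estimates as a square matrix in the customary
#' supplementary-table format: male rates above the diagonal, female rates
#' below, `NA` where a rate could not be assessed.
#'
#' @param pairs output of [estimate_all_pairs].
#' @param loci locus order for rows/columns.
#' @return numeric matrix.
#' @export
recomb_rate_matrix <- function(pairs, loci = NULL) {
  if (is.null(loci)) loci <- unique(c(pairs$locusA, pairs$locusB))
  m <- matrix(NA_real_, length(loci), length(loci),
              dimnames = list(loci, loci))
  for (r in seq_len(nrow(pairs))) {
    i <- match(pairs$locusA[r], loci); j <- match(pairs$locusB[r], loci)
    m[min(i, j), max(i, j)] <- pairs$theta_m[r]
    m[max(i, j), min(i, j)] <- pairs$theta_f[r]
  }
  m
}
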