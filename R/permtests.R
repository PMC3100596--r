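# Two permutation tests of X-Y similarity.

#' Conspecific X-Y allelic size-difference test
#'
#' The observed statistic is the mean, over every male genotype with two
#' amplified alleles at the given sex-linked loci (homozygotes contribute 0;
#' genotypes containing a null or missing allele are excluded), of the
#' absolute size difference between the two alleles a male expresses. Each
#' null replicate redraws, for every such genotype slot at locus l, a pair of
#' alleles from the pooled typed-adult allele lists of locus l constrained to
#' come from two different species, and averages identically. Small observed
#' means (conspecific X and Y more similar than cross-species pairs) give
#' small one-tailed p: `p = (1 + #{null mean <= observed}) / (1 + n)`.
#'
#' @param dataset an [xy_dataset].
#' @param loci sex-linked loci to use (default: loci with
#'   `assumed_class == "sex_linked"`, or all loci if none are so annotated).
#' @param n_replicates number of null replicates.
#' @param seed integer seed.
#' @return object of class `size_diff_test`: `observed_mean`, `null_means`,
#'   `null_mean`, `null_sd`, `p`, `n_pairs`, `n_replicates`, `pair_counts`
#'   (per locus), `excluded_loci` (typed in fewer than two species).
#' @export
size_diff_test <- function(dataset, loci = NULL, n_replicates = 10000L,
                           seed = 1L) {
  if (is.null(loci)) {
    loci <- dataset$loci$name[dataset$loci$assumed_class == "sex_linked"]
    if (length(loci) == 0L) loci <- dataset$loci$name
  }
  ind <- dataset$ind
  males <- which(ind$sex == "M")
  if (length(unique(ind$species)) < 2L)
    stop("need at least two species for the cross-species null")
  obs_diffs <- numeric(0); slot_locus <- character(0)
  pools <- list()  # per locus: data.frame(allele, species) over typed adults
  excluded <- character(0)
  for (locus in loci) {
    a1 <- ind[[paste0(locus, ".a1")]]; a2 <- ind[[paste0(locus, ".a2")]]
    ok <- males[!is.na(a1[males]) & !is.na(a2[males]) &
                  a1[males] > 0L & a2[males] > 0L]
    al <- c(a1, a2); sp <- rep(ind$species, 2L)
    typed <- !is.na(al) & al > 0L
    pool <- data.frame(allele = al[typed], species = sp[typed],
                       stringsAsFactors = FALSE)
    if (length(unique(pool$species)) < 2L) {
      excluded <- c(excluded, locus)
      warning("locus ", locus, " typed in fewer than two species; excluded")
      next
    }
    pools[[locus]] <- pool
    obs_diffs <- c(obs_diffs, abs(a1[ok] - a2[ok]))
    slot_locus <- c(slot_locus, rep(locus, length(ok)))
  }
  n_pairs <- length(obs_diffs)
  if (n_pairs == 0L) stop("no male genotypes with two amplified alleles")
  observed <- mean(obs_diffs)
  set.seed(seed)
  # all replicates drawn at once: the first allele uniform over the pooled
  # typed alleles, the second uniform over the alleles of any other species
  null_means <- numeric(n_replicates)
  per_locus <- table(slot_locus)
  loc_names <- names(per_locus)
  for (locus in loc_names) {
    pool <- pools[[locus]]
    nslot <- per_locus[[locus]]
    D <- nslot * n_replicates
    i1 <- sample.int(nrow(pool), D, replace = TRUE)
    j <- integer(D)
    for (s in unique(pool$species)) {
      other <- which(pool$species != s)
      sel <- which(pool$species[i1] == s)
      if (length(sel))
        j[sel] <- other[sample.int(length(other), length(sel),
                                   replace = TRUE)]
    }
    d <- abs(pool$allele[i1] - pool$allele[j])
    null_means <- null_means +
      colSums(matrix(d, nslot, n_replicates))
  }
  null_means <- null_means / n_pairs
  structure(list(observed_mean = observed, null_means = null_means,
                 null_mean = mean(null_means), null_sd = stats::sd(null_means),
                 p = (1 + sum(null_means <= observed + 1e-12)) /
                     (1 + n_replicates),
                 n_pairs = n_pairs, n_replicates = n_replicates,
                 pair_counts = per_locus, excluded_loci = excluded),
            class = "size_diff_test")
}

#' @export
print.size_diff_test <- function(x, ...) {
  cat(sprintf(
    "<size_diff_test> observed %.3f bp over %d pairs; null %.3f bp (+/- %.3f SD); p = %s\n",
    x$observed_mean, x$n_pairs, x$null_mean, x$null_sd,
    format(x$p, digits = 4)))
  invisible(x)
}

#' Cross-amplification matrix
#'
#' Binary amplification success per (locus, species, gametolog).
#'
#' @param df `data.frame` with columns `locus`, `species`, `gametolog`
#'   (`"X"`/`"Y"`), `amplified` (0/1).
#' @return object of class `crossamp_matrix`: 3-d 0/1 array
#'   locus x species x gametolog.
#' @export
crossamp_matrix <- function(df) {
  stopifnot(all(c("locus", "species", "gametolog", "amplified") %in% names(df)))
  if (!all(df$gametolog %in% c("X", "Y"))) stop("gametolog must be X or Y")
  if (!all(df$amplified %in% c(0, 1))) stop("amplified must be 0/1")
  loci <- unique(df$locus); spp <- unique(df$species)
  a <- array(NA_real_, c(length(loci), length(spp), 2L),
             dimnames = list(loci, spp, c("X", "Y")))
  for (r in seq_len(nrow(df)))
    a[df$locus[r], df$species[r], df$gametolog[r]] <- df$amplified[r]
  if (anyNA(a)) stop("incomplete cross-amplification matrix")
  structure(a, class = "crossamp_matrix")
}

#' Read a cross-amplification matrix from CSV
#'
#' @param path CSV with columns `locus,species,gametolog,amplified`.
#' @return a [crossamp_matrix].
#' @export
read_crossamp <- function(path) {
  crossamp_matrix(utils::read.csv(path, stringsAsFactors = FALSE))
}

crossamp_discordant <- function(a) {
  sum(a[, , "X"] != a[, , "Y"])
}

#' Permutation test of X/Y cross-amplification concordance
#'
#' The statistic is the number of (locus, species) pairs whose X and Y
#' entries differ. The null places the observed number of zero entries
#' uniformly at random among all cells of the matrix; concordance as extreme
#' as observed (as few or fewer discordant pairs) gives
#' `p = (1 + #{stat <= observed}) / (1 + n_replicates)`.
#'
#' @param matrix a [crossamp_matrix].
#' @param n_replicates number of random placements.
#' @param seed integer seed.
#' @return object of class `crossamp_test`: `observed_discordant`, `p_sim`,
#'   `p_exact` (from [crossamp_exact]), `n_replicates`, `null_stats`.
#' @export
crossamp_test <- function(matrix, n_replicates = 100000L, seed = 1L) {
  a <- unclass(matrix)
  z <- sum(a == 0)
  n_cells <- length(a)
  if (z == 0 || z == n_cells) {
    return(structure(list(observed_discordant = crossamp_discordant(a),
                          p_sim = 1, p_exact = 1,
                          n_replicates = n_replicates,
                          null_stats = integer(0)),
                     class = "crossamp_test"))
  }
  obs <- crossamp_discordant(a)
  n_pairs <- n_cells %/% 2L
  set.seed(seed)
  stats_ <- integer(n_replicates)
  for (b in seq_len(n_replicates)) {
    cells <- sample.int(n_cells, z)
    # column-major layout: gametolog is the slowest dimension, so cell i and
    # cell i + n_pairs are the X and Y entries of the same (locus, species)
    pair_id <- (cells - 1L) %% n_pairs + 1L
    cnt <- tabulate(pair_id, n_pairs)
    stats_[b] <- sum(cnt == 1L)
  }
  structure(list(observed_discordant = obs,
                 p_sim = (1 + sum(stats_ <= obs)) / (1 + n_replicates),
                 p_exact = crossamp_exact(matrix),
                 n_replicates = n_replicates,
                 null_stats = stats_),
            class = "crossamp_test")
}

#' @export
print.crossamp_test <- function(x, ...) {
  cat(sprintf(
    "<crossamp_test> %d discordant (locus, species) pairs; p_sim = %s, p_exact = %s\n",
    x$observed_discordant, format(x$p_sim, digits = 4),
    format(x$p_exact, digits = 4)))
  invisible(x)
}

#' Exact tail probability for the cross-amplification null
#'
#' Under uniform placement of the `z` observed zeros among the `2P` cells
#' (`P` = loci x species pairs), the number of discordant pairs `D` equals
#' the number of pairs holding exactly one zero. This computes
#' `P(D <= d_obs)` by summing over the number `a` of fully-zero pairs and
#' `b = z - 2a` of half-zero pairs with `b <= d_obs`:
#' `sum C(P, a) C(P - a, b) 2^b / C(2P, z)`.
#'
#' @param matrix a [crossamp_matrix].
#' @return exact probability in `[0, 1]` (no `+1` correction).
#' @export
crossamp_exact <- function(matrix) {
  a <- unclass(matrix)
  z <- sum(a == 0)
  P <- length(a) %/% 2L
  if (z == 0 || z == length(a)) return(1)
  d_obs <- crossamp_discordant(a)
  total <- lchoose(2 * P, z)
  pr <- 0
  for (b in seq(z %% 2L, min(d_obs, z, P), by = 2L)) {
    af <- (z - b) / 2
    if (af > P - b) next
    pr <- pr + exp(lchoose(P, af) + lchoose(P - af, b) + b * log(2) - total)
  }
  min(max(pr, 0), 1)
}
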