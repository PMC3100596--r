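# Morton-style heterogeneity test of recombination fractions among groups.
#
# Per sex s:  Lambda_s = 2 [ sum_i max_{tm,tf} lnL_i
#                            - max_{theta_s} sum_i profile_i(theta_s) ]
# where profile_i maximises over the other sex's theta within group i.  The
# reference is chi-squared with k-1 df; because boundary MLEs (theta = 0)
# make that reference conservative, a permutation reference (families
# reallocated among groups, group sizes kept) is also available.
#
# All likelihoods are evaluated on a fixed (tm, tf) grid, which makes the
# family-level contributions reusable across permutations.

mtest_grid <- function(step = 0.005) {
  g <- seq(0, 0.5, by = step)
  list(g = g, n = length(g),
       tm = rep(g, times = length(g)), tf = rep(g, each = length(g)))
}

# Lambda for one sex from per-group summed grids (list of [n*n] vectors laid
# out tm-fastest).
lambda_from_grids <- function(group_grids, n, sex = c("m", "f")) {
  sex <- match.arg(sex)
  num <- 0; prof <- NULL
  for (Gi in group_grids) {
    m <- matrix(Gi, n, n)              # rows tm, cols tf
    num <- num + max(m)
    pi_ <- if (sex == "m") apply(m, 1, max) else apply(m, 2, max)
    prof <- if (is.null(prof)) pi_ else prof + pi_
  }
  max(0, 2 * (num - max(prof)))
}

#' Heterogeneity test of recombination fractions (Morton's M-test)
#'
#' Tests whether `k >= 2` groups (species, populations) share a common
#' recombination fraction at a locus pair, separately for each sex. The
#' statistic is the likelihood-ratio comparing per-group estimates to a
#' common estimate, with the other sex's fraction free within each group.
#' P-values come from the chi-squared distribution with `k - 1` df and,
#' optionally, from a permutation null that reallocates whole families among
#' groups keeping group sizes fixed.
#'
#' @param groups list of [xy_dataset] objects sharing locus definitions.
#' @param locusA,locusB locus names.
#' @param n_perm number of permutations (0 = chi-squared only; use >= 1000
#'   for a stable permutation p).
#' @param seed integer seed for the permutation null.
#' @param grid_step resolution of the likelihood grid over `[0, 0.5]`.
#' @return object of class `mtest`: for each sex a list with `statistic`,
#'   `df`, `p`, `p_perm` (`NA` without permutations), plus `k` and `n_perm`.
#'   A sex with no informative meioses in some group gets `NA` results.
#' @export
mtest <- function(groups, locusA, locusB, n_perm = 0L, seed = 1L,
                  grid_step = 0.005) {
  k <- length(groups)
  if (k < 1L) stop("need at least one group")
  gr <- mtest_grid(grid_step)
  fam_grids <- list(); group_of_fam <- integer(0)
  inf_m <- inf_f <- logical(k)
  for (i in seq_len(k)) {
    struct <- build_pair_struct(groups[[i]], locusA, locusB)
    inf_m[i] <- struct$n_inf_m > 0L; inf_f[i] <- struct$n_inf_f > 0L
    fg <- eval_loglik_by_family(struct, gr$tm, gr$tf)  # [F_eff, G]
    if (nrow(fg) > 0L) {
      for (r in seq_len(nrow(fg))) fam_grids[[length(fam_grids) + 1L]] <- fg[r, ]
      group_of_fam <- c(group_of_fam, rep(i, nrow(fg)))
    }
  }
  FG <- if (length(fam_grids)) do.call(cbind, fam_grids) else
    matrix(0, gr$n^2, 0)                               # [G, F]
  sum_groups <- function(assign) {
    lapply(seq_len(k), function(i) {
      cols <- which(assign == i)
      if (length(cols) == 0L) rep(0, nrow(FG))
      else if (length(cols) == 1L) FG[, cols]
      else rowSums(FG[, cols, drop = FALSE])
    })
  }
  res <- list(k = k, n_perm = n_perm, locusA = locusA, locusB = locusB)
  if (k == 1L) {
    one <- list(statistic = 0, df = 0L, p = 1, p_perm = NA_real_)
    res$m <- one; res$f <- one
    class(res) <- "mtest"
    return(res)
  }
  gg <- sum_groups(group_of_fam)
  lam_obs <- c(m = lambda_from_grids(gg, gr$n, "m"),
               f = lambda_from_grids(gg, gr$n, "f"))
  exceed <- c(m = 0L, f = 0L)
  if (n_perm > 0L && ncol(FG) > 0L) {
    set.seed(seed)
    for (b in seq_len(n_perm)) {
      perm <- sample(group_of_fam)
      gp <- sum_groups(perm)
      for (s in c("m", "f")) {
        if (lambda_from_grids(gp, gr$n, s) >= lam_obs[[s]] - 1e-12)
          exceed[[s]] <- exceed[[s]] + 1L
      }
    }
  }
  for (s in c("m", "f")) {
    ok <- if (s == "m") all(inf_m) else all(inf_f)
    if (!ok) {
      res[[s]] <- list(statistic = NA_real_, df = k - 1L, p = NA_real_,
                       p_perm = NA_real_)
    } else {
      res[[s]] <- list(
        statistic = lam_obs[[s]], df = k - 1L,
        p = stats::pchisq(lam_obs[[s]], k - 1L, lower.tail = FALSE),
        p_perm = if (n_perm > 0L) (1 + exceed[[s]]) / (1 + n_perm)
                 else NA_real_)
    }
  }
  class(res) <- "mtest"
  res
}

#' @export
print.mtest <- function(x, ...) {
  cat(sprintf("<mtest> %s x %s, k=%d groups\n", x$locusA, x$locusB, x$k))
  for (s in c("m", "f"))
    cat(sprintf("  %s: Lambda=%s df=%d p=%s p_perm=%s\n", s,
                format(x[[s]]$statistic, digits = 4), x[[s]]$df,
                format(x[[s]]$p, digits = 4),
                format(x[[s]]$p_perm, digits = 4)))
  invisible(x)
}

#' Haldane map function and its inverse
#'
#' `haldane_cM` converts a recombination fraction to a map distance
#' `d = -50 ln(1 - 2 theta)` in cM (no interference); `haldane_theta` is the
#' inverse.
#'
#' @param theta recombination fraction in `[0, 0.5)`.
#' @param d map distance in cM.
#' @return numeric vector.
#' @export
haldane_cM <- function(theta) -50 * log(1 - 2 * theta)

#' @rdname haldane_cM
#' @export
haldane_theta <- function(d) (1 - exp(-d / 50)) / 2

all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
  out
}

#' Build a sex-specific linkage map by exhaustive ordering
#'
#' Evaluates every locus order (up to reversal; at most 10 loci) and keeps
#' the one minimising the summed adjacent-interval female Haldane length.
#' Positions are cumulative Haldane distances in cM per sex. An adjacent
#' female fraction `>= 0.5` (or one that could not be estimated) is capped at
#' `theta = 0.49` and flagged. Ties between orders break lexicographically.
#'
#' @param dataset an [xy_dataset].
#' @param loci character vector of loci to map (default all; `<= 10`).
#' @param pairs optional precomputed [estimate_all_pairs] table.
#' @return object of class `linkage_map`: `order`, per-interval `theta_f`
#'   and `theta_m`, cumulative `pos_f`/`pos_m` (cM), the minimised
#'   `objective` (female map length, cM), `runner_up_gap`, and a `capped`
#'   flag per interval.
#' @export
build_map <- function(dataset, loci = NULL, pairs = NULL) {
  if (is.null(loci)) loci <- dataset$loci$name
  if (length(loci) < 2L) stop("need at least two loci")
  if (length(loci) > 10L) stop("exhaustive ordering supports at most 10 loci")
  if (is.null(pairs)) pairs <- estimate_all_pairs(dataset, loci)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  th_f <- stats::setNames(pairs$theta_f, key(pairs$locusA, pairs$locusB))
  th_m <- stats::setNames(pairs$theta_m, key(pairs$locusA, pairs$locusB))
  cap <- function(th) {
    capped <- is.na(th) | th >= 0.5
    th[capped] <- 0.49
    list(theta = th, capped = capped)
  }
  orders <- Filter(function(o) o[1] < o[length(o)], all_perms(sort(loci)))
  obj <- vapply(orders, function(o) {
    adj <- cap(th_f[key(o[-length(o)], o[-1])])
    sum(haldane_cM(adj$theta))
  }, 0)
  ord_str <- vapply(orders, paste, "", collapse = "|")
  best_i <- order(obj, ord_str)[1]
  best <- orders[[best_i]]
  runner_gap <- if (length(obj) > 1L) sort(obj)[2] - obj[best_i] else NA_real_
  adj_f <- cap(th_f[key(best[-length(best)], best[-1])])
  adj_m <- th_m[key(best[-length(best)], best[-1])]
  pos_f <- c(0, cumsum(haldane_cM(adj_f$theta)))
  pos_m <- c(0, cumsum(haldane_cM(adj_m)))
  if (any(adj_f$capped))
    warning("interval(s) with theta_f >= 0.5 or not estimable capped at 0.49")
  structure(list(order = best,
                 theta_f = unname(adj_f$theta), theta_m = unname(adj_m),
                 pos_f = unname(pos_f), pos_m = unname(pos_m),
                 objective = obj[best_i], runner_up_gap = runner_gap,
                 capped = unname(adj_f$capped), pairs = pairs),
            class = "linkage_map")
}

#' @export
print.linkage_map <- function(x, ...) {
  cat("<linkage_map> order:", paste(x$order, collapse = " - "), "\n")
  cat("  female length:", format(max(x$pos_f), digits = 5), "cM;",
      "male length:", format(max(x$pos_m), digits = 5), "cM\n")
  invisible(x)
}
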