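# Sex linkage from population samples and sibships.

# allele counts (rows = allele codes incl. "*" for null) x sex, from a set of
# individual rows; missing alleles dropped
allele_sex_counts <- function(dataset, rows, locus) {
  a1 <- dataset$ind[[paste0(locus, ".a1")]][rows]
  a2 <- dataset$ind[[paste0(locus, ".a2")]][rows]
  sex <- dataset$ind$sex[rows]
  al <- c(a1, a2); sx <- rep(sex, 2L)
  keep <- !is.na(al) & sx %in% c("M", "F")
  if (!any(keep)) return(table(factor(character()), factor(character())))
  table(allele = factor(al[keep]), sex = factor(sx[keep], levels = c("F", "M")))
}

g_statistic <- function(tab) {
  tab <- as.matrix(tab)
  if (sum(tab) == 0 || nrow(tab) < 2L || ncol(tab) < 2L) return(0)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  keep <- tab > 0
  2 * sum(tab[keep] * log(tab[keep] / E[keep]))
}

#' Test for sex differences in allele frequencies
#'
#' Computes the G statistic on the allele-count-by-sex table at a locus and
#' obtains its null distribution by permuting sex labels across individuals
#' (both alleles of an individual travel together, respecting their
#' within-individual dependence). Null alleles (`*`) count as an allele
#' class; missing alleles are dropped. The p-value uses the `+1` correction
#' and so never reports zero.
#'
#' @param dataset an [xy_dataset].
#' @param locus locus name.
#' @param n_perm number of sex-label permutations.
#' @param seed integer seed.
#' @param rows integer row indices of `dataset$ind` to use; default all
#'   non-offspring individuals (parents and unrelated adults) of known sex.
#' @return object of class `sex_freq_test`: `locus`, `table` (allele x sex
#'   counts), `freq` (per-sex frequencies), `G`, `p`, `n_perm`.
#' @export
sex_allele_freq_test <- function(dataset, locus, n_perm = 1000L, seed = 1L,
                                 rows = NULL) {
  if (!locus %in% dataset$loci$name) stop("unknown locus: ", locus)
  if (is.null(rows))
    rows <- which(dataset$ind$role != "offspring" & dataset$ind$sex != "U")
  sex <- dataset$ind$sex[rows]
  if (sum(sex == "M") < 2L || sum(sex == "F") < 2L)
    stop("need at least two typed individuals per sex")
  tab <- allele_sex_counts(dataset, rows, locus)
  G_obs <- g_statistic(tab)
  freq <- sweep(as.matrix(tab), 2L, pmax(colSums(tab), 1L), "/")
  if (nrow(tab) < 2L || G_obs == 0) {
    # monomorphic (or no sex contrast): degenerate
    return(structure(list(locus = locus, table = tab, freq = freq,
                          G = 0, p = 1, n_perm = n_perm),
                     class = "sex_freq_test"))
  }
  a1 <- dataset$ind[[paste0(locus, ".a1")]][rows]
  a2 <- dataset$ind[[paste0(locus, ".a2")]][rows]
  lev <- rownames(tab)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    sx <- sample(sex)
    al <- c(a1, a2); ss <- rep(sx, 2L)
    keep <- !is.na(al)
    tb <- table(factor(al[keep], levels = lev),
                factor(ss[keep], levels = c("F", "M")))
    if (g_statistic(tb) >= G_obs - 1e-12) hits <- hits + 1L
  }
  structure(list(locus = locus, table = tab, freq = freq, G = G_obs,
                 p = (1 + hits) / (1 + n_perm), n_perm = n_perm),
            class = "sex_freq_test")
}

#' @export
print.sex_freq_test <- function(x, ...) {
  cat(sprintf("<sex_freq_test> %s: G = %s, permutation p = %s (n_perm = %d)\n",
              x$locus, format(x$G, digits = 4), format(x$p, digits = 4),
              x$n_perm))
  invisible(x)
}

# Candidate paternal alleles for one offspring at one locus: the set of
# father-transmissible alleles p for which some mother-transmissible allele m
# makes (p, m) compatible with the observed offspring genotype.
paternal_candidates <- function(fg, mg, og) {
  ft <- transmissible_alleles(fg)
  mt <- transmissible_alleles(mg)
  ok <- logical(length(ft))
  for (i in seq_along(ft)) {
    for (m in mt) {
      if (pair_obs_compat(ft[i], m, og[1], og[2])) { ok[i] <- TRUE; break }
    }
  }
  ft[ok]
}

#' Reconstruct a father's Y haplotype from his sibship
#'
#' Assumes complete male linkage at the given loci (the caller asserts
#' `theta_m = 0`). Per locus, the paternal allele received by each offspring
#' is resolved by enumerating transmissions compatible with the mother's and
#' the offspring's genotypes; only offspring with an unambiguous paternal
#' allele are used. The allele received by all such sons and by no such
#' daughter is the Y call. Sons disagreeing among themselves, or a daughter
#' carrying the sons' allele, mark the locus `inconsistent` (possible
#' sex reversal, X-Y recombination, or scoring error) and the call
#' `ambiguous`.
#'
#' @param dataset an [xy_dataset].
#' @param family family id.
#' @param loci loci to call (default all).
#' @return object of class `y_haplotype`: `male` (father id), `provenance`
#'   `"sibship"`, and a `data.frame` `calls` with columns `locus`, `call`
#'   (allele size, `"*"` for a null, `"ambiguous"`, `"untyped"`),
#'   `inconsistent` (logical), `n_informative_sons`.
#' @export
infer_y_from_family <- function(dataset, family, loci = NULL) {
  if (is.null(loci)) loci <- dataset$loci$name
  fams <- xy_families(dataset)
  if (!family %in% names(fams)) stop("unknown family: ", family)
  fam <- fams[[family]]
  sex_o <- dataset$ind$sex[fam$offspring]
  calls <- data.frame(locus = loci, call = NA_character_,
                      inconsistent = FALSE, n_informative_sons = 0L,
                      stringsAsFactors = FALSE)
  for (li in seq_along(loci)) {
    locus <- loci[li]
    fg <- get_geno(dataset, fam$father, locus)
    if (is_untyped(fg)) { calls$call[li] <- "untyped"; next }
    mg <- get_geno(dataset, fam$mother, locus)
    son_alleles <- integer(0); dau_alleles <- integer(0)
    for (oi in seq_along(fam$offspring)) {
      og <- get_geno(dataset, fam$offspring[oi], locus)
      if (is_untyped(og)) next
      cand <- paternal_candidates(fg, mg, og)
      cand <- cand[cand != WILDCARD]
      if (length(cand) != 1L) next  # ambiguous transmission: skip
      if (sex_o[oi] == "M") son_alleles <- c(son_alleles, cand)
      else if (sex_o[oi] == "F") dau_alleles <- c(dau_alleles, cand)
    }
    if (length(son_alleles) == 0L) { calls$call[li] <- "ambiguous"; next }
    calls$n_informative_sons[li] <- length(son_alleles)
    y <- unique(son_alleles)
    # an apparent-homozygote father transmits the same allele on both
    # backgrounds, so daughters sharing it are no conflict
    father_hom <- !is.na(fg[1]) && !is.na(fg[2]) && fg[1] == fg[2]
    if (length(y) > 1L || (!father_hom && y %in% dau_alleles)) {
      calls$call[li] <- "ambiguous"
      calls$inconsistent[li] <- TRUE
    } else {
      calls$call[li] <- if (y == NULL_ALLELE) "*" else as.character(y)
    }
  }
  structure(list(male = dataset$ind$id[fam$father], provenance = "sibship",
                 calls = calls),
            class = "y_haplotype")
}

#' @export
print.y_haplotype <- function(x, ...) {
  cat("<y_haplotype>", x$male, "(", x$provenance, "):",
      paste(x$calls$call, collapse = " / "), "\n")
  invisible(x)
}

#' Assign Y haplotypes to population males from candidate Y alleles
#'
#' Given per-locus candidate Y allele sets (from sibship calls and/or
#' male-biased alleles flagged by [sex_allele_freq_test]), each male's Y call
#' at a locus is the unique genotype allele lying in the candidate set
#' (ambiguous if zero or two); a male homozygous for a candidate allele is
#' called but flagged uninformative. Distinct multilocus haplotypes are
#' counted with ambiguous loci as wildcards: two haplotypes differ only if
#' they conflict at a locus where both are called. Compatible call vectors
#' are merged greedily in male-id order, so the count is the number of
#' haplotypes the data force apart.
#'
#' @param dataset an [xy_dataset].
#' @param candidates named list (per locus) of integer candidate Y alleles
#'   (`0` = null).
#' @param males integer rows of `dataset$ind` (default: all adult males).
#' @return object of class `y_population`: `calls` (data.frame male x locus
#'   call strings), `flags`, `n_haplotypes`, `haplotypes` (merged
#'   representative patterns).
#' @export
assign_y_population <- function(dataset, candidates, males = NULL) {
  loci <- names(candidates)
  if (is.null(loci) || !all(loci %in% dataset$loci$name))
    stop("candidates must be a named list keyed by locus name")
  if (is.null(males))
    males <- which(dataset$ind$role == "adult" & dataset$ind$sex == "M")
  ids <- dataset$ind$id[males]
  call_m <- matrix(NA_character_, length(males), length(loci),
                   dimnames = list(ids, loci))
  flag_m <- matrix("", length(males), length(loci),
                   dimnames = list(ids, loci))
  for (j in seq_along(loci)) {
    cand <- candidates[[j]]
    for (i in seq_along(males)) {
      g <- get_geno(dataset, males[i], loci[j])
      if (is_untyped(g)) { call_m[i, j] <- "untyped"; next }
      if (length(cand) == 0L) { call_m[i, j] <- "ambiguous"; next }
      hit <- unique(g[!is.na(g) & g %in% cand])
      if (length(hit) == 1L) {
        call_m[i, j] <- if (hit == NULL_ALLELE) "*" else as.character(hit)
        if (!is.na(g[1]) && !is.na(g[2]) && g[1] == g[2])
          flag_m[i, j] <- "uninformative-homozygote"
      } else {
        call_m[i, j] <- "ambiguous"
      }
    }
  }
  # wildcard-tolerant distinct-haplotype count
  is_called <- function(v) !v %in% c("ambiguous", "untyped")
  compat <- function(a, b) {
    both <- is_called(a) & is_called(b)
    all(a[both] == b[both])
  }
  reps <- list()
  for (i in seq_len(nrow(call_m))) {
    v <- call_m[i, ]
    merged <- FALSE
    for (r in seq_along(reps)) {
      if (compat(reps[[r]], v)) {
        fill <- is_called(v) & !is_called(reps[[r]])
        reps[[r]][fill] <- v[fill]
        merged <- TRUE
        break
      }
    }
    if (!merged) reps[[length(reps) + 1L]] <- v
  }
  structure(list(calls = as.data.frame(call_m, stringsAsFactors = FALSE),
                 flags = as.data.frame(flag_m, stringsAsFactors = FALSE),
                 n_haplotypes = length(reps),
                 haplotypes = reps, provenance = "population"),
            class = "y_population")
}

#' @export
print.y_population <- function(x, ...) {
  cat("<y_population>", nrow(x$calls), "males,", x$n_haplotypes,
      "distinct Y haplotypes\n")
  invisible(x)
}
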