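# Distance-based gene-tree estimation and species-vs-gametolog clustering.

#' Pairwise distances from an alignment
#'
#' p-distance (mismatches over pairwise-complete sites, gaps deleted
#' pairwise) or its Jukes-Cantor transform
#' `d = -(3/4) ln(1 - (4/3) p)`. A pair with `p >= 0.75` gets an infinite JC
#' entry; a pair with no compared sites is an error.
#'
#' @param seqs named character vector of equal-length sequences over
#'   `A,C,G,T,-` (see [read_fasta]).
#' @param model `"p"` or `"JC"`.
#' @return symmetric numeric matrix with a `model` attribute.
#' @export
pairwise_distance <- function(seqs, model = c("JC", "p")) {
  model <- match.arg(model)
  if (length(unique(nchar(seqs))) != 1L) stop("unequal sequence lengths")
  n <- length(seqs)
  if (n < 2L) stop("need at least two sequences")
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- names(seqs)
  valid <- m %in% c("A", "C", "G", "T")
  dim(valid) <- dim(m)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- valid[i, ] & valid[j, ]
    nc <- sum(comp)
    if (nc == 0L)
      stop("no compared sites between '", names(seqs)[i], "' and '",
           names(seqs)[j], "'")
    p <- sum(m[i, comp] != m[j, comp]) / nc
    d[i, j] <- d[j, i] <- p
  }
  if (model == "JC") {
    jc <- d
    sat <- d >= 0.75
    jc[!sat] <- -0.75 * log(1 - (4 / 3) * d[!sat])
    jc[sat] <- Inf
    diag(jc) <- 0
    d <- jc
  }
  attr(d, "model") <- model
  d
}

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei neighbor joining via \pkg{ape}; negative branch
#' lengths are clamped to zero (flagged in attribute `clamped`). Infinite or
#' missing distances are an error.
#'
#' @param dm symmetric distance matrix (e.g. from [pairwise_distance]).
#' @return unrooted `phylo`.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("need at least three tips")
  off <- dm[upper.tri(dm)]
  if (any(!is.finite(off)))
    stop("non-finite distance entries (saturated JC pair?); cannot join")
  tr <- ape::nj(dm)
  clamped <- any(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- clamped
  tr
}

#' Bootstrap support for an alignment's NJ tree
#'
#' Resamples alignment columns with replacement `B` times, rebuilds the
#' distance + NJ tree, and reports for each internal edge of the original
#' tree the percentage of replicates containing the same bipartition.
#'
#' @param seqs named character vector of aligned sequences.
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @param model distance model, as in [pairwise_distance].
#' @return the NJ tree of the full alignment with `node.label` set to
#'   support percentages in `[0, 100]`.
#' @export
bootstrap_support <- function(seqs, B = 1000L, seed = 1L, model = "JC") {
  stopifnot(B >= 1L)
  base <- nj_tree(pairwise_distance(seqs, model))
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  L <- ncol(m)
  set.seed(seed)
  boots <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- sample.int(L, L, replace = TRUE)
    rs <- stats::setNames(apply(m[, cols, drop = FALSE], 1, paste,
                                collapse = ""), names(seqs))
    boots[[b]] <- nj_tree(pairwise_distance(rs, model))
  }
  class(boots) <- "multiPhylo"
  cnt <- ape::prop.clades(base, boots, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  base$node.label <- as.character(round(100 * cnt / B, 1))
  base
}

# is tip set `s` (character labels) one side of a bipartition of the tree?
is_bipartition <- function(tree, s) {
  tips <- tree$tip.label
  idx <- match(s, tips)
  stopifnot(!anyNA(idx))
  k <- length(idx); n <- length(tips)
  if (k <= 1L || k >= n - 1L) return(TRUE)
  parts <- ape::prop.part(tree)
  target <- sort(idx)
  comp <- sort(setdiff(seq_len(n), idx))
  for (p in parts) {
    sp <- sort(p)
    if (identical(sp, target) || identical(sp, comp)) return(TRUE)
  }
  FALSE
}

fitch_score <- function(tree, states) {
  lev <- unique(states)
  if (length(lev) < 2L) return(0L)
  dat <- phangorn::phyDat(matrix(states, ncol = 1,
                                 dimnames = list(names(states), NULL)),
                          type = "USER", levels = lev)
  as.integer(phangorn::parsimony(tree, dat, method = "fitch"))
}

#' Classify a gametolog tree as species- or gametolog-clustered
#'
#' Discriminates the expected genealogies of sex-linked markers: under
#' occasional X-Y recombination every species' X and Y alleles form a clade
#' (species clustering); when X-Y recombination stopped before the species
#' diverged, Y alleles cluster together apart from the X alleles (gametolog
#' clustering). All monophyly is evaluated as an unrooted bipartition test,
#' so the verdict does not depend on rooting or tip order.
#'
#' The verdict is `species_clustered` iff every species' pooled X and Y tips
#' are one side of a bipartition; else `gametolog_clustered` iff the pooled Y
#' tips of the designated sister-group species form a bipartition side apart
#' from their conspecific X tips; else `mixed`. Fitch parsimony change counts
#' for the species and gametolog tip characters are reported as continuous
#' scores for users wanting a different decision rule.
#'
#' @param tree a `phylo` whose tips parse as `species|gametolog|...` (see
#'   [parse_tip_labels]) with at least two species carrying both X and Y
#'   tips.
#' @param sister_species species forming the sister group for the gametolog
#'   test; default all species except `reference`.
#' @param reference the focal species; default the first species appearing
#'   among the tip labels.
#' @return object of class `clustering_result`: `species_monophyly` (named
#'   logical), `gametolog_clade` (logical), `fitch_species`,
#'   `fitch_gametolog`, `verdict`, `sister_species`.
#' @export
classify_clustering <- function(tree, sister_species = NULL,
                                reference = NULL) {
  lab <- parse_tip_labels(tree$tip.label)
  if (any(lab$gametolog == "unknown"))
    stop("tips with unknown gametolog label")
  spp <- unique(lab$species)
  has_both <- vapply(spp, function(s)
    all(c("X", "Y") %in% lab$gametolog[lab$species == s]), TRUE)
  if (sum(has_both) < 2L)
    stop("need at least two species with both X and Y tips")
  if (is.null(reference)) reference <- spp[1]
  if (is.null(sister_species)) sister_species <- setdiff(spp, reference)
  sp_mono <- vapply(spp, function(s)
    is_bipartition(tree, lab$label[lab$species == s]), TRUE)
  y_sister <- lab$label[lab$species %in% sister_species &
                          lab$gametolog == "Y"]
  x_sister_present <- any(lab$species %in% sister_species &
                            lab$gametolog == "X")
  gam_clade <- length(y_sister) >= 2L && x_sister_present &&
    is_bipartition(tree, y_sister)
  verdict <- if (all(sp_mono)) "species_clustered"
             else if (gam_clade) "gametolog_clustered"
             else "mixed"
  structure(list(species_monophyly = sp_mono,
                 gametolog_clade = gam_clade,
                 fitch_species = fitch_score(
                   tree, stats::setNames(lab$species, lab$label)),
                 fitch_gametolog = fitch_score(
                   tree, stats::setNames(lab$gametolog, lab$label)),
                 verdict = verdict,
                 sister_species = sister_species),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat("<clustering_result>", x$verdict,
      sprintf("(species monophyly: %d/%d; sister-Y clade: %s; Fitch species=%d, gametolog=%d)\n",
              sum(x$species_monophyly), length(x$species_monophyly),
              x$gametolog_clade, x$fitch_species, x$fitch_gametolog))
  invisible(x)
}
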