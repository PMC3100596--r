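# Structured-coalescent simulation of X/Y gametolog genealogies.
#
# Backwards in time, lineages live in per-species pools (X and Y, or a single
# autosomal pool). Within a pool of size N, k lineages coalesce at rate
# k(k-1)/(2N) per generation; each lineage switches pool at rate r (the
# X-Y exchange rate, modelling recombination in sex-reversed XY females).
# At a species-split time the daughter species' same-class pools merge.
# Above the root the scenario presets control the exchange rate; a strictly
# positive ancestral rate is required whenever two pools persist, otherwise
# the process could never find a common ancestor.

#' Configuration for the gametolog genealogy simulator
#'
#' Defaults follow a three-species system with a root split of 7.1 My and a
#' sister split of 5.4 My converted at a 2-year generation time, and an
#' X-to-Y pool size ratio of 3:1.
#'
#' @param scenario one of `"recombining_ancestral"` (occasional X-Y
#'   recombination throughout), `"frozen_ancestral"` (no exchange below the
#'   root), `"autosomal"` (a single pool per species), `"turnover_from_X"`
#'   (no exchange, but the reference species' Y lineages derive from its X
#'   pool at a recent time `t_turn`).
#' @param species species labels; `species[1]` is the reference (focal)
#'   species for `turnover_from_X`.
#' @param sister_species labels of the sister clade (default: all but the
#'   reference).
#' @param t_split_sister,t_root split times in generations
#'   (`t_root > t_split_sister > 0`).
#' @param n_x,n_y haploid lineage-pool sizes.
#' @param exchange_rate per-lineage per-generation pool-switch probability
#'   `r`; default set by the scenario (`10 / n_y` for
#'   `recombining_ancestral`, `0` otherwise).
#' @param r_anc exchange rate above the root for scenarios with `r = 0`
#'   below it (default `1 / n_y`); must be positive when two pools persist.
#' @param t_turn turnover time in generations (only `turnover_from_X`).
#' @param samples_per_pool tips sampled per (species, gametolog).
#' @param mu substitution rate per site per generation.
#' @param seq_length alignment length for [evolve_sequences].
#' @param seed integer seed.
#' @return a list of class `coal_sim_config`.
#' @export
coal_sim_config <- function(scenario = c("recombining_ancestral",
                                         "frozen_ancestral", "autosomal",
                                         "turnover_from_X"),
                            species = c("Ha", "Hi", "Hm"),
                            sister_species = NULL,
                            t_split_sister = 2.7e6,
                            t_root = 3.55e6,
                            n_x = 3e5, n_y = 1e5,
                            exchange_rate = NULL,
                            r_anc = NULL,
                            t_turn = 5e4,
                            samples_per_pool = 2L,
                            mu = 2e-8, seq_length = 1000L,
                            seed = 1L) {
  scenario <- match.arg(scenario)
  if (length(species) < 1L) stop("need at least one species")
  if (is.null(sister_species)) sister_species <- species[-1]
  if (!all(sister_species %in% species[-1]))
    stop("sister_species must be species other than the reference")
  if (!(t_root > t_split_sister && t_split_sister > 0))
    stop("need t_root > t_split_sister > 0")
  if (is.null(exchange_rate))
    exchange_rate <- switch(scenario,
                            recombining_ancestral = 10 / n_y,
                            0)
  if (exchange_rate < 0) stop("exchange_rate must be >= 0")
  if (scenario == "frozen_ancestral" && exchange_rate > 0)
    stop("frozen_ancestral fixes exchange_rate = 0 below the root")
  if (is.null(r_anc))
    r_anc <- if (scenario == "autosomal") 0 else max(exchange_rate, 1 / n_y)
  two_pools <- scenario != "autosomal"
  if (two_pools && r_anc <= 0)
    stop("non-terminating configuration: two pools persist above the root ",
         "with zero exchange rate")
  if (scenario == "turnover_from_X" &&
      !(t_turn > 0 && t_turn < t_split_sister))
    stop("t_turn must lie in (0, t_split_sister)")
  structure(list(scenario = scenario, species = species,
                 sister_species = sister_species,
                 t_split_sister = t_split_sister, t_root = t_root,
                 n_x = n_x, n_y = n_y,
                 exchange_rate = exchange_rate, r_anc = r_anc,
                 t_turn = t_turn,
                 samples_per_pool = as.integer(samples_per_pool),
                 mu = mu, seq_length = as.integer(seq_length),
                 seed = as.integer(seed)),
            class = "coal_sim_config")
}

#' Simulate a gametolog gene genealogy
#'
#' Runs the structured coalescent described in [coal_sim_config] and returns
#' the genealogy of the sampled X and Y lineages with branch lengths in
#' generations, plus the full event history as ground truth.
#'
#' @param config a [coal_sim_config].
#' @param seed optional seed overriding `config$seed`.
#' @return list with `tree` (an \pkg{ape} `phylo`, tips labelled
#'   `species|gametolog|i`) and `truth` (list: `switches` — one row per pool
#'   switch with `time`, `lineage` node id, `from`, `to`, and whether it
#'   happened above the root —, `coal_times`, `scenario`).
#' @export
simulate_genealogy <- function(config, seed = NULL) {
  stopifnot(inherits(config, "coal_sim_config"))
  set.seed(if (is.null(seed)) config$seed else seed)
  two_pools <- config$scenario != "autosomal"
  pools <- if (two_pools) c("X", "Y") else "A"
  pool_size <- c(X = config$n_x, Y = config$n_y, A = config$n_x + config$n_y)

  # tips
  tip_species <- character(0); tip_pool <- character(0); tip_lab <- character(0)
  for (sp in config$species) for (pl in pools) {
    gam <- if (two_pools) pl else "autosomal"
    for (i in seq_len(config$samples_per_pool)) {
      tip_species <- c(tip_species, sp)
      tip_pool <- c(tip_pool, pl)
      tip_lab <- c(tip_lab, make_tip_label(sp, gam, i))
    }
  }
  n_tip <- length(tip_lab)

  # active lineage state
  node <- seq_len(n_tip)        # node id carried by each active lineage
  sp <- tip_species
  pool <- tip_pool
  height <- rep(0, n_tip)       # height of the node at the base of lineage
  # turnover: the reference species' Y samples are a recently derived neo-Y;
  # they occupy an isolated pool until t_turn, when they join the X pool
  if (config$scenario == "turnover_from_X")
    pool[sp == config$species[1] & pool == "Y"] <- "neoY"

  merges <- list()   # (child1, child2, height)
  switches <- list() # (time, lineage, from, to)
  next_internal <- n_tip + 1L

  boundaries <- c(if (config$scenario == "turnover_from_X") config$t_turn,
                  config$t_split_sister, config$t_root, Inf)
  t <- 0
  r_now <- config$exchange_rate
  above_root <- FALSE
  bi <- 1L

  repeat {
    if (length(node) == 1L) break
    # event rates in the current epoch
    grp <- paste(sp, pool)
    ugrp <- unique(grp)
    coal_rate <- vapply(ugrp, function(g) {
      k <- sum(grp == g)
      pl <- sub("^.* ", "", g)
      ps <- if (pl == "neoY") pool_size[["Y"]] else pool_size[[pl]]
      k * (k - 1) / (2 * ps)
    }, 0)
    switchable <- two_pools & r_now > 0 & pool %in% c("X", "Y")
    sw_rate <- r_now * sum(switchable)
    R <- sum(coal_rate) + sw_rate
    nb <- boundaries[bi]
    dt <- if (R > 0) stats::rexp(1, R) else Inf
    if (t + dt >= nb) {
      t <- nb
      bi <- bi + 1L
      if (nb == Inf)
        stop("non-terminating configuration: no coalescence possible ",
             "above the root")
      if (config$scenario == "turnover_from_X" && nb == config$t_turn) {
        pool[pool == "neoY"] <- "X"
      } else if (nb == config$t_split_sister) {
        sp[sp %in% config$sister_species] <- "sister"
      } else if (nb == config$t_root) {
        sp[] <- "root"
        above_root <- TRUE
        if (two_pools) r_now <- config$r_anc
      }
      next
    }
    t <- t + dt
    u <- stats::runif(1, 0, R)
    if (u < sw_rate) {
      w <- which(switchable)
      i <- w[sample.int(length(w), 1L)]
      from <- pool[i]
      pool[i] <- if (from == "X") "Y" else "X"
      switches[[length(switches) + 1L]] <-
        data.frame(time = t, lineage = node[i], from = from, to = pool[i],
                   above_root = above_root, stringsAsFactors = FALSE)
    } else {
      u <- u - sw_rate
      gi <- which(cumsum(coal_rate) > u)[1]
      members <- which(grp == ugrp[gi])
      pair <- members[sample.int(length(members), 2L)]
      merges[[length(merges) + 1L]] <-
        list(c1 = node[pair[1]], c2 = node[pair[2]], h = t)
      node[pair[1]] <- next_internal
      height[pair[1]] <- t
      next_internal <- next_internal + 1L
      keep <- -pair[2]
      node <- node[keep]; sp <- sp[keep]; pool <- pool[keep]
      height <- height[keep]
    }
  }

  # assemble phylo: internal node created last is the root -> id n_tip + 1
  n_int <- length(merges)
  stopifnot(n_int == n_tip - 1L)
  remap <- function(id) ifelse(id <= n_tip, id,
                               n_tip + 1L + (n_tip + n_int - id))
  node_height <- numeric(n_tip + n_int)
  edge <- matrix(0L, 2L * n_int, 2L)
  elen <- numeric(2L * n_int)
  for (i in seq_len(n_int)) {
    m <- merges[[i]]
    pid <- remap(n_tip + i)
    node_height[pid] <- m$h
    for (j in 1:2) {
      cid <- remap(if (j == 1L) m$c1 else m$c2)
      edge[2L * (i - 1L) + j, ] <- c(pid, cid)
      elen[2L * (i - 1L) + j] <- m$h - node_height[cid]
    }
  }
  tree <- structure(list(edge = edge, edge.length = elen,
                         tip.label = tip_lab, Nnode = n_int),
                    class = "phylo")
  tree <- ape::reorder.phylo(tree, "cladewise")
  sw <- if (length(switches)) do.call(rbind, switches) else
    data.frame(time = numeric(0), lineage = integer(0),
               from = character(0), to = character(0),
               above_root = logical(0), stringsAsFactors = FALSE)
  if (nrow(sw)) sw$lineage <- remap(sw$lineage)
  list(tree = tree,
       truth = list(switches = sw,
                    coal_times = vapply(merges, `[[`, 0, "h"),
                    tip_pool = stats::setNames(tip_pool, tip_lab),
                    scenario = config$scenario))
}

#' Evolve sequences along a tree under Jukes-Cantor
#'
#' Site-independent JC69 evolution with a uniform random root sequence;
#' branch lengths are in generations and `mu` is the substitution rate per
#' site per generation, so a branch of length `t` carries `mu * t` expected
#' substitutions per site.
#'
#' @param tree a `phylo` with branch lengths in generations.
#' @param mu substitution rate per site per generation (`>= 0`).
#' @param L alignment length in bp.
#' @param seed integer seed.
#' @return named character vector of aligned sequences (names = tip labels).
#' @export
evolve_sequences <- function(tree, mu, L, seed = 1L) {
  stopifnot(mu >= 0, L >= 1)
  set.seed(seed)
  if (mu == 0) {
    root <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                  collapse = "")
    return(stats::setNames(rep(root, length(tree$tip.label)),
                           tree$tip.label))
  }
  sim <- phangorn::simSeq(tree, l = L, rate = mu)
  m <- toupper(as.character(sim))
  stats::setNames(apply(m, 1, paste, collapse = ""), rownames(m))
}
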