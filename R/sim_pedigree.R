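#' Configuration for the pedigree simulator
#'
#' Defaults emulate the study design this package targets: 111 families split
#' over three species, ~20 offspring each, six sex-linked microsatellites with
#' complete male linkage (`theta_m = 0`) and high female recombination
#' (`theta_f = 0.4` per interval), overlapping X and Y founder allele pools,
#' and a moderate null-allele frequency. The stepwise mutation rate defaults
#' to 0, the regime of proofread, Mendel-consistent genotype data.
#'
#' @param species character vector of species labels.
#' @param n_families families per species (recycled).
#' @param offspring_mean mean of the zero-truncated Poisson offspring count.
#' @param n_adult_males,n_adult_females unrelated adults sampled per species.
#' @param loci locus table from [locus_def].
#' @param theta_f,theta_m female/male recombination fraction per adjacent
#'   interval, each in `[0, 0.5]`, length `nrow(loci) - 1` (recycled).
#' @param x_pool,y_pool per-locus founder allele frequencies for the X and Y
#'   chromosome pools: lists (one element per locus) of named numeric vectors,
#'   names = allele sizes in bp, values summing to 1. Defaults give eight
#'   (X) / four (Y) overlapping equifrequent alleles per locus, typical of
#'   polymorphic microsatellites.
#' @param null_allele_freq per-locus probability that a founder allele is a
#'   null, in `[0, 1)` (recycled).
#' @param smm_mutation_rate per-meiosis per-locus stepwise mutation
#'   probability (one motif unit up or down, equiprobable).
#' @param seed integer seed used by [simulate_pedigrees].
#' @return a list of class `pedigree_sim_config`.
#' @export
pedigree_sim_config <- function(species = c("Ha", "Hi", "Hm"),
                                n_families = 37L,
                                offspring_mean = 20,
                                n_adult_males = 20L,
                                n_adult_females = 20L,
                                loci = locus_def(sprintf("L%02d", 1:6)),
                                theta_f = 0.4,
                                theta_m = 0,
                                x_pool = NULL,
                                y_pool = NULL,
                                null_allele_freq = 0.05,
                                smm_mutation_rate = 0,
                                seed = 1L) {
  nl <- nrow(loci)
  stopifnot(nl >= 1L)
  n_int <- max(nl - 1L, 0L)
  theta_f <- rep_len(theta_f, n_int)
  theta_m <- rep_len(theta_m, n_int)
  if (any(theta_f < 0 | theta_f > 0.5) || any(theta_m < 0 | theta_m > 0.5))
    stop("recombination fractions must lie in [0, 0.5]")
  null_allele_freq <- rep_len(null_allele_freq, nl)
  if (any(null_allele_freq < 0 | null_allele_freq >= 1))
    stop("null_allele_freq must lie in [0, 1)")
  if (smm_mutation_rate < 0 || smm_mutation_rate >= 1)
    stop("smm_mutation_rate must lie in [0, 1)")
  default_pool <- function(base, steps, motif) {
    a <- base + motif * steps
    stats::setNames(rep(1 / length(a), length(a)), a)
  }
  if (is.null(x_pool))
    x_pool <- lapply(seq_len(nl), function(i)
      default_pool(100L + 30L * (i - 1L), 0:7, loci$motif_length[i]))
  if (is.null(y_pool))
    y_pool <- lapply(seq_len(nl), function(i)
      default_pool(100L + 30L * (i - 1L), 2:5, loci$motif_length[i]))
  check_pool <- function(pool, what) {
    if (length(pool) != nl) stop(what, " must have one element per locus")
    for (p in pool) {
      if (abs(sum(p) - 1) > 1e-9)
        stop(what, " frequencies must sum to 1 within each locus")
      if (any(p < 0)) stop(what, " frequencies must be non-negative")
      if (anyNA(suppressWarnings(as.integer(names(p)))))
        stop(what, " allele names must be integer sizes")
    }
  }
  check_pool(x_pool, "x_pool"); check_pool(y_pool, "y_pool")
  structure(list(species = species,
                 n_families = rep_len(as.integer(n_families), length(species)),
                 offspring_mean = offspring_mean,
                 n_adult_males = rep_len(as.integer(n_adult_males), length(species)),
                 n_adult_females = rep_len(as.integer(n_adult_females), length(species)),
                 loci = loci, theta_f = theta_f, theta_m = theta_m,
                 x_pool = x_pool, y_pool = y_pool,
                 null_allele_freq = null_allele_freq,
                 smm_mutation_rate = smm_mutation_rate,
                 seed = as.integer(seed)),
            class = "pedigree_sim_config")
}

rtrunc_pois <- function(n, lambda) {
  out <- stats::rpois(n, lambda)
  while (any(out == 0L)) out[out == 0L] <- stats::rpois(sum(out == 0L), lambda)
  out
}

draw_hap <- function(pool, null_freq) {
  nl <- length(pool)
  hap <- integer(nl)
  for (i in seq_len(nl))
    hap[i] <- as.integer(sample(names(pool[[i]]), 1L, prob = pool[[i]]))
  is_null <- stats::runif(nl) < null_freq
  hap[is_null] <- NULL_ALLELE
  hap
}

# observed genotype from a true allele pair: double null amplifies nothing,
# a single null hides behind its partner (apparent homozygote)
observe_pair <- function(t1, t2) {
  if (t1 == NULL_ALLELE && t2 == NULL_ALLELE) return(c(NA_integer_, NA_integer_))
  if (t1 == NULL_ALLELE) return(c(t2, t2))
  if (t2 == NULL_ALLELE) return(c(t1, t1))
  c(min(t1, t2), max(t1, t2))
}

# vectorised observation of locus-wise allele pairs -> interleaved
# (a1, a2, a1, a2, ...) genotype vector
observe_vec <- function(pa, ma) {
  o1 <- pmin(pa, ma); o2 <- pmax(pa, ma)
  one_null <- o1 == NULL_ALLELE & o2 != NULL_ALLELE
  o1[one_null] <- o2[one_null]
  both_null <- o1 == NULL_ALLELE & o2 == NULL_ALLELE
  o1[both_null] <- NA_integer_; o2[both_null] <- NA_integer_
  as.vector(rbind(o1, o2))
}

# gamete from a two-haplotype parent: start in `start_hap` (1 or 2) at the
# first locus, switch haplotype across interval i with probability theta[i]
meiosis <- function(hap1, hap2, theta, start_hap) {
  nl <- length(hap1)
  state <- integer(nl)
  state[1] <- start_hap
  if (nl > 1L) {
    sw <- stats::runif(nl - 1L) < theta
    for (i in 2:nl) state[i] <- if (sw[i - 1L]) 3L - state[i - 1L] else state[i - 1L]
  }
  allele <- hap2
  pick1 <- state == 1L
  allele[pick1] <- hap1[pick1]
  list(allele = allele, state = state)
}

apply_smm <- function(allele, motif, rate) {
  hit <- stats::runif(length(allele)) < rate & allele != NULL_ALLELE
  if (any(hit)) {
    step <- sample(c(-1L, 1L), sum(hit), replace = TRUE)
    allele[hit] <- allele[hit] + step * motif[hit]
  }
  allele
}

#' Simulate pedigree genotype data with full ground truth
#'
#' Fathers carry one X-pool and one Y-pool haplotype, mothers two X-pool
#' haplotypes. Each meiosis recombines between adjacent loci with the
#' sex-appropriate recombination fraction; the sex-determining locus sits
#' immediately upstream of the first marker, so sons receive the paternal
#' gamete that starts on the Y background and daughters the one starting on
#' the X background. Null alleles are assigned at the founder stage and
#' inherited; genotypes are recorded as observed (a null hides behind its
#' partner allele, a double null is missing). Unrelated adults are drawn from
#' the same pools.
#'
#' @param config a [pedigree_sim_config].
#' @return list with elements `dataset` (an [xy_dataset]) and `truth`, a list
#'   holding founder haplotypes (`father_x`, `father_y`, `mother_x1`,
#'   `mother_x2`: matrices family x locus), per-offspring records
#'   (`offspring`: id, family, sex, transmitted alleles and background states
#'   per locus), and recombination events (`recomb`: one row per switch, with
#'   parent `"pat"`/`"mat"` and the 1-based interval index).
#' @export
simulate_pedigrees <- function(config) {
  stopifnot(inherits(config, "pedigree_sim_config"))
  set.seed(config$seed)
  loci <- config$loci
  nl <- nrow(loci)
  gc <- geno_cols(loci)
  nf_vec <- config$n_families

  ind_rows <- list()
  fam_ids <- character(0)
  father_x <- father_y <- mother_x1 <- mother_x2 <- NULL
  off_rec <- list()
  recomb <- list()
  tp_list <- list(); tm_list <- list(); bg_list <- list()

  mk_row <- function(id, family, role, sex, species, g) {
    list(meta = c(id, family, role, sex, species, species),
         g = as.integer(g))
  }

  for (si in seq_along(config$species)) {
    sp <- config$species[si]
    for (fj in seq_len(nf_vec[si])) {
      fam <- sprintf("%s.f%03d", sp, fj)
      fam_ids <- c(fam_ids, fam)
      fx <- draw_hap(config$x_pool, config$null_allele_freq)
      fy <- draw_hap(config$y_pool, config$null_allele_freq)
      mx1 <- draw_hap(config$x_pool, config$null_allele_freq)
      mx2 <- draw_hap(config$x_pool, config$null_allele_freq)
      father_x <- rbind(father_x, fx); father_y <- rbind(father_y, fy)
      mother_x1 <- rbind(mother_x1, mx1); mother_x2 <- rbind(mother_x2, mx2)
      ind_rows[[length(ind_rows) + 1L]] <-
        mk_row(paste0(fam, ".fa"), fam, "father", "M", sp, observe_vec(fx, fy))
      ind_rows[[length(ind_rows) + 1L]] <-
        mk_row(paste0(fam, ".mo"), fam, "mother", "F", sp, observe_vec(mx1, mx2))

      n_off <- rtrunc_pois(1L, config$offspring_mean)
      sexes <- sample(c("M", "F"), n_off, replace = TRUE)
      mat_starts <- sample(1:2, n_off, replace = TRUE)
      for (oj in seq_len(n_off)) {
        oid <- sprintf("%s.o%02d", fam, oj)
        sex <- sexes[oj]
        pat <- meiosis(fx, fy, config$theta_m,
                       start_hap = if (sex == "M") 2L else 1L)
        mat <- meiosis(mx1, mx2, config$theta_f, start_hap = mat_starts[oj])
        pa <- apply_smm(pat$allele, loci$motif_length, config$smm_mutation_rate)
        ma <- apply_smm(mat$allele, loci$motif_length, config$smm_mutation_rate)
        ind_rows[[length(ind_rows) + 1L]] <-
          mk_row(oid, fam, "offspring", sex, sp, observe_vec(pa, ma))
        off_rec[[length(off_rec) + 1L]] <-
          list(id = oid, family = fam, sex = sex)
        tp_list[[length(tp_list) + 1L]] <- pa
        tm_list[[length(tm_list) + 1L]] <- ma
        bg <- rep("X", nl); bg[pat$state == 2L] <- "Y"
        bg_list[[length(bg_list) + 1L]] <- bg
        if (nl > 1L) {
          psw <- which(diff(pat$state) != 0L)
          msw <- which(diff(mat$state) != 0L)
          if (length(psw) || length(msw))
            recomb[[length(recomb) + 1L]] <-
              list(oid = oid, fam = fam,
                   par = rep(c("pat", "mat"), c(length(psw), length(msw))),
                   interval = c(psw, msw))
        }
      }
    }
    # unrelated adults
    for (am in seq_len(config$n_adult_males[si])) {
      ax <- draw_hap(config$x_pool, config$null_allele_freq)
      ay <- draw_hap(config$y_pool, config$null_allele_freq)
      ind_rows[[length(ind_rows) + 1L]] <-
        mk_row(sprintf("%s.am%03d", sp, am), "", "adult", "M", sp,
               observe_vec(ax, ay))
    }
    for (af in seq_len(config$n_adult_females[si])) {
      a1 <- draw_hap(config$x_pool, config$null_allele_freq)
      a2 <- draw_hap(config$x_pool, config$null_allele_freq)
      ind_rows[[length(ind_rows) + 1L]] <-
        mk_row(sprintf("%s.af%03d", sp, af), "", "adult", "F", sp,
               observe_vec(a1, a2))
    }
  }

  meta <- do.call(rbind, lapply(ind_rows, `[[`, "meta"))
  gm <- do.call(rbind, lapply(ind_rows, `[[`, "g"))
  ind <- data.frame(id = meta[, 1], family = meta[, 2], role = meta[, 3],
                    sex = meta[, 4], species = meta[, 5],
                    population = meta[, 6], stringsAsFactors = FALSE)
  for (j in seq_along(gc)) ind[[gc[j]]] <- gm[, j]
  dataset <- xy_dataset(loci, ind)

  rn <- function(m) { rownames(m) <- fam_ids; colnames(m) <- loci$name; m }
  off <- data.frame(id = vapply(off_rec, `[[`, "", "id"),
                    family = vapply(off_rec, `[[`, "", "family"),
                    sex = vapply(off_rec, `[[`, "", "sex"),
                    stringsAsFactors = FALSE)
  mat_of <- function(lst) {
    m <- do.call(rbind, lst); rownames(m) <- off$id; colnames(m) <- loci$name; m
  }
  truth <- list(father_x = rn(father_x), father_y = rn(father_y),
                mother_x1 = rn(mother_x1), mother_x2 = rn(mother_x2),
                offspring = off,
                transmitted_pat = mat_of(tp_list),
                transmitted_mat = mat_of(tm_list),
                pat_background = mat_of(bg_list),
                recomb = if (length(recomb)) {
                  k <- lengths(lapply(recomb, `[[`, "interval"))
                  data.frame(
                    offspring = rep(vapply(recomb, `[[`, "", "oid"), k),
                    family = rep(vapply(recomb, `[[`, "", "fam"), k),
                    parent = unlist(lapply(recomb, `[[`, "par")),
                    interval = unlist(lapply(recomb, `[[`, "interval")),
                    stringsAsFactors = FALSE)
                } else data.frame(offspring = character(),
                                  family = character(),
                                  parent = character(),
                                  interval = integer(),
                                  stringsAsFactors = FALSE))
  list(dataset = dataset, truth = truth)
}
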