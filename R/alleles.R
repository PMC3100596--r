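# Allele coding used throughout the package.
#
# Genotypes are unordered pairs of integer codes:
#   > 0   allele size in bp
#   0     null (non-amplifying) allele, written "*" in genotype tables
#   NA    missing ("NA" in tables); a genotype with both alleles NA is untyped
# -1L is an internal wildcard ("could be anything") used when a parent is
# untyped at a locus; it never appears in stored data.

NULL_ALLELE <- 0L
WILDCARD <- -1L

#' @keywords internal
is_untyped <- function(g) is.na(g[1]) && is.na(g[2])

# Alleles a parent could transmit, given its *observed* genotype.  An apparent
# homozygote a/a may really be a/null (allelic dropout), so it can transmit
# the null too; a/* transmits a or null; fully or half missing genotypes
# contribute a wildcard.
transmissible_alleles <- function(g) {
  a1 <- g[1]; a2 <- g[2]
  if (is.na(a1) && is.na(a2)) return(WILDCARD)
  if (is.na(a1) || is.na(a2)) {
    a <- if (is.na(a1)) a2 else a1
    return(unique(c(a, WILDCARD)))
  }
  if (a1 == a2 && a1 > 0L) return(c(a1, NULL_ALLELE))
  unique(c(a1, a2))
}

# Is the true (transmitted) allele pair (t1, t2) consistent with the observed
# genotype (o1, o2)?  The observation model: a true null shows up either as an
# explicit "*" or by making its carrier an apparent homozygote for the other
# allele; a double null shows as */* or as a fully missing genotype; missing
# observed alleles are unconstrained.  No wildcards allowed here.
truepair_obs_compat <- function(t1, t2, o1, o2) {
  na1 <- is.na(o1); na2 <- is.na(o2)
  if (na1 && na2) return(TRUE)
  if (na1 || na2) {
    o <- if (na1) o2 else o1
    if (t1 == NULL_ALLELE && t2 == NULL_ALLELE) return(o == NULL_ALLELE)
    if (t1 == NULL_ALLELE || t2 == NULL_ALLELE) {
      a <- if (t1 == NULL_ALLELE) t2 else t1
      return(o == a || o == NULL_ALLELE)
    }
    return(o == t1 || o == t2)
  }
  if (t1 == NULL_ALLELE && t2 == NULL_ALLELE)
    return(o1 == NULL_ALLELE && o2 == NULL_ALLELE)
  if (t1 == NULL_ALLELE || t2 == NULL_ALLELE) {
    a <- if (t1 == NULL_ALLELE) t2 else t1
    return((o1 == a && o2 == a) ||
             (o1 == a && o2 == NULL_ALLELE) ||
             (o1 == NULL_ALLELE && o2 == a))
  }
  (o1 == t1 && o2 == t2) || (o1 == t2 && o2 == t1)
}

# Wildcard-tolerant wrapper: substitute each wildcard with a small covering
# set of values (each observed allele, the null, and a fresh size) and ask
# whether any substitution is compatible.
pair_obs_compat <- function(t1, t2, o1, o2) {
  if (t1 != WILDCARD && t2 != WILDCARD)
    return(truepair_obs_compat(t1, t2, o1, o2))
  subs <- function(t) {
    if (t == WILDCARD) {
      cand <- c(o1, o2)
      cand <- cand[!is.na(cand)]
      unique(c(cand, NULL_ALLELE, 999999999L))
    } else t
  }
  for (x in subs(t1)) for (y in subs(t2)) {
    if (truepair_obs_compat(x, y, o1, o2)) return(TRUE)
  }
  FALSE
}
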