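---
title: "Methods: sex-specific linkage, Y haplotypes, and X-Y recombination scenarios"
author: "xylink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-specific linkage, Y haplotypes, and X-Y recombination scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific question

Most cold-blooded vertebrates carry homomorphic sex chromosomes: X and Y
that are cytogenetically and genetically undifferentiated, in sharp contrast
with the decayed Y of mammals or W of birds. Two explanations compete.
Under *high turnover*, master sex-determining genes are replaced often
enough that no Y has time to degenerate. Under the *fountain-of-youth*
model, the same XY pair persists over long evolutionary times but is kept
young by occasional X-Y recombination, plausibly in sex-reversed XY females
(recombination patterns follow phenotypic, not genotypic, sex in several
ectotherms).

The two models leave different footprints in data that can be collected
from natural populations of a species group sharing one XY pair:

* **Sibship linkage**: if the XY pair is ancestral, the same markers are
  sex-linked, with zero male recombination, in all species.
* **Gene genealogies of gametologs** (the X- and Y-linked copies of a
  locus): with occasional X-Y recombination, alleles cluster by *species*;
  if recombination stopped before the species split, they cluster by
  *gametolog* (all Y alleles together).
* **X-Y similarity statistics**: allele-size differences between the two
  alleles a male expresses, and concordance of PCR cross-amplification
  failures between a species' X and Y.

`xylink` implements this entire inferential chain, together with a
pedigree simulator and a structured-coalescent simulator that provide
ground truth for every stage. The `analysis/` scripts run the chain as a
narrative pipeline on synthetic data.

## Data model

Genotypes are unordered pairs of allele sizes in bp. Two non-standard
states matter for microsatellites: a **null allele** (`*` in tables,
`0` internally) that fails to amplify, surfacing as apparent homozygosity
of its partner or, when homozygous, as a missing genotype; and **missing**
(`NA`). `validate_mendelian()` checks sibships under exactly this
observation model: an apparent homozygote may hide a null, so e.g. parents
`A/*` x `B/B` are compatible with an apparent `B/B` offspring.

The genotype table is a strict CSV (`id,family,role,sex,species,population`
then `<locus>.a1,<locus>.a2` per locus) because the original supplementary
genotype tables exist only as formatted documents; `*` and `NA` follow
their conventions. Locus metadata (motif length, inheritance class) is
supplied separately since the CSV cannot carry it.

## Two-point likelihood

For a locus pair and a family, the likelihood of `(theta_m, theta_f)` sums
over the unknown linkage phase of each double-heterozygous parent (prior
1/2 per phase, constant across the sibship — implemented as a uniform 1/4
prior over the four labelled phase combinations, which collapses correctly
for homozygous parents) and over the sixteen transmission combinations per
offspring, scoring each against the observed unphased genotype. Missing
alleles are marginalised; explicit nulls are inheritable alleles. An
offspring locus incompatible with the face-value parental genotypes
(suspected allelic dropout through a hidden null) is treated as missing at
that locus — a conservative choice that loses a little information but
introduces no bias.

At build time each offspring collapses to a 2x2 table of coefficients over
the parental recombination indicators, so the log-likelihood at any
`(theta_m, theta_f)` — or over a whole grid — is a small matrix product.
This makes the permutation M-test and the grid oracles cheap.

**Maximisation.** A coarse grid (step 0.025) seeds box-constrained
L-BFGS-B on `[0, 0.5]^2` (`factr = 1e4`); candidate boundary values are
then tested and adopted whenever they lose no likelihood, so complete
linkage yields `theta_m = 0` *exactly*. A sex with no informative meiosis
(no doubly heterozygous parent) gets `NA`, the convention used for
unassessable rates in recombination-matrix tables. LOD scores are
`log10 L(theta_hat) - log10 L(theta_hat with theta_s := 0.5)`.

**Precision limits.** With phase unknown, a sibship of size `n` with `r`
recombinants contributes `[theta^r (1-theta)^(n-r) + theta^(n-r)
(1-theta)^r] / 2`; as `theta -> 0.5` the two phase terms merge and the
per-family information vanishes. Consequences documented by the tests: the
MLE occasionally sits exactly at 0.5 when the truth is >= 0.42 at realistic
family counts, and single-study estimates near 0.5 have standard errors
around 0.03 even with 60 families of 20. Accuracy checks therefore use
means over replicate studies; multipoint likelihood (which would restore
precision) is deliberately out of scope.

## Heterogeneity (M-test)

For `k` groups and one sex, `Lambda = 2 [ sum_i max lnL_i - max_theta
sum_i profile_i(theta) ]`, the other sex's fraction being free within each
group, referred to chi-squared with `k - 1` df. Likelihoods are evaluated
on a fixed grid over `[0, 0.5]` (default step 0.005; the large replicate
studies in the tests use 0.01), making family contributions reusable
across permutations; the grid guarantees `Lambda >= 0` exactly. Because
boundary MLEs (`theta_m = 0`) make the chi-squared reference conservative,
a permutation reference — families reallocated among groups, group sizes
kept — is always available (`n_perm >= 1000` recommended). The test is
computed per sex and both are reported.

## Map construction

With at most ten loci, all orders (up to reversal) are scored by the
summed adjacent-interval female Haldane length `d = -50 ln(1 - 2 theta)`
cM, and the minimum wins; ties break lexicographically and the gap to the
runner-up is reported. An adjacent female fraction >= 0.5, or one that
could not be estimated, is capped at `theta = 0.49` and flagged rather
than made infinite. The male map length is the same sum over `theta_m`, so
complete male linkage gives a 0 cM male map. This two-point objective
reproduces the qualitative structure of multipoint maps but not their
likelihood ranking of near-tied orders.

## Sex linkage and Y haplotypes

Sex linkage is established twice over:

* `sex_allele_freq_test()` computes the G statistic on the allele-by-sex
  count table (nulls count as an allele class) and permutes sex labels
  across *individuals*, so the two alleles of one genotype travel
  together; the `+1`-corrected p never reports zero.
* `infer_y_from_family()` assumes complete male linkage, resolves each
  offspring's paternal allele by enumerating transmissions compatible with
  both parents, and calls the allele received by all unambiguous sons and
  no unambiguous daughter. Sons disagreeing, or a daughter carrying the
  sons' allele, flag the locus `inconsistent` — the expected footprint of
  a sex-reversal/recombination event or a scoring error. An
  apparent-homozygote father transmits the same size on both backgrounds,
  so daughters sharing it are exempt from the conflict rule; null Y
  alleles are callable (`*`).
* `assign_y_population()` intersects adult male genotypes with candidate Y
  alleles; distinct multilocus haplotypes are counted with ambiguous loci
  as wildcards, merging call vectors greedily in male-id order, so the
  count is the number of haplotypes the data force apart (a minimum, as
  such tables report).

## The two permutation tests

**Allelic size differences.** The statistic is the mean absolute size
difference between the two alleles a male expresses at the sex-linked
loci (homozygotes contribute 0; genotypes containing nulls or missing
alleles are excluded — "the two alleles expressed" is read as both
amplified). Each null replicate redraws every genotype slot as a pair of
alleles from that locus' pooled typed alleles of both sexes, constrained
to two different species, preserving per-locus-and-slot counts. Small
observed means are the X-Y-similarity signal; `p` is one-tailed with the
`+1` correction.

**Cross-amplification.** For a 0/1 amplification matrix over (locus,
species, gametolog), the statistic is the number of (locus, species) pairs
with discordant X/Y entries. The null places the observed number of zeros
uniformly among all cells (the matrix permutation is unconstrained — no
margins are fixed). `crossamp_exact()` provides the closed-form tail,
summing over `a` fully-zero and `b = z - 2a` half-zero pairs with
`b <= d_obs`: `sum C(P,a) C(P-a,b) 2^b / C(2P,z)`; the simulation must
agree with it within Monte Carlo error, which makes the permutation-scheme
choice auditable.

## Coalescent simulator

`simulate_genealogy()` runs a backwards-in-time structured coalescent in
units of generations. Within a species, each gametolog pool of size `N`
coalesces `k` lineages at rate `k(k-1)/(2N)` per generation; each lineage
switches pool at the exchange rate `r`, the model of X-Y recombination
through sex-reversed XY females; at a split time the daughter species'
same-class pools merge. Defaults and presets:

* Species tree `((Hi,Hm),Ha)` with splits of 5.4 and 7.1 My converted at a
  2-year generation time (`t_split_sister = 2.7e6`, `t_root = 3.55e6`
  generations). The source estimates carry wide intervals and no
  generation time, so both are configurable.
* Pool sizes `N_X : N_Y = 3e5 : 1e5`, the standard 3:1 effective-size
  ratio.
* `r` presets: 0 (frozen), `10/N_Y` ("occasional", the default for the
  recombining scenario), `1000/N_Y` ("frequent" — note the event-driven
  simulation then generates ~1e6 switch events per replicate at default
  sizes; use smaller `N` or shallower splits when exploring it).
* Above the root two pools must still coalesce, so scenarios with `r = 0`
  below the root use an ancestral rate `r_anc = 1/N_Y` (exchange predates
  the freeze by construction); a configuration whose pools can never merge
  is rejected before simulation. With `r_anc = 1/N`, the two surviving
  Y-pool root lineages coalesce before either switches with probability
  1/3 only, so *all-Y* monophyly is not guaranteed — the scenario
  classification therefore relies on the sister-species Y clade, which
  forms below the root and is insensitive to `r_anc` (tests that want
  near-certain all-Y monophyly set `r_anc` several orders smaller).
* `turnover_from_X` models a recent Y derived from the ancestral X in the
  focal species: its Y samples sit in an isolated neo-Y pool until
  `t_turn`, then join the X pool.

`evolve_sequences()` applies Jukes-Cantor evolution (uniform random root,
site-independent) with `mu` substitutions/site/generation, so a branch of
length `t` carries `mu t` expected substitutions; the default
`mu = 2e-8`, `L = 1000` gives between-species distances around 0.14 and
within-species diversity around 0.008 — comfortable for tree estimation
yet far from saturation.

## Tree estimation and classification

`pairwise_distance()` computes p-distances with pairwise gap deletion and
the JC transform `-(3/4) ln(1 - 4p/3)` (saturated pairs, `p >= 0.75`,
become infinite and refuse to enter NJ). `nj_tree()` is canonical
Saitou-Nei neighbor joining; negative branch lengths are clamped to zero
with a flag. `bootstrap_support()` resamples alignment columns and reports
bipartition frequencies as percentages. Externally estimated trees (e.g.
maximum-likelihood ones) enter the same classification through
`read_newick()`; tips carry `species|gametolog|individual[|clone]` labels.

`classify_clustering()` works on unrooted bipartitions, so rooting and tip
order cannot change the verdict: `species_clustered` iff every species'
pooled X and Y tips are one side of a bipartition; otherwise
`gametolog_clustered` iff the sister-group species' pooled Y tips form a
bipartition side apart from their conspecific X tips; otherwise `mixed`.
The sister group is a parameter because the turnover signature is
predicted only outside the focal species. No formal decision statistic
exists in this literature — trees are read by inspection — so the verdict
rule is one concrete formalisation, and Fitch parsimony change counts for
the species and gametolog characters are reported for users who prefer a
score-based rule.

## What the simulators do and do not emulate

The pedigree generator reproduces the study design (families of ~20,
three species, six sex-linked microsatellites, complete male linkage,
female fractions spanning 0.30-0.50, overlapping X/Y founder pools of 8/4
equifrequent alleles, 5% null alleles, optional single-step stepwise
mutation) and records full transmission truth. It does not model
genotyping error beyond nulls, population structure within species,
linkage disequilibrium among founder haplotypes, or multi-step mutation;
passing tests demonstrate correctness of the inference chain under the
stated model, not robustness to scoring artefacts. The coalescent
generator likewise omits demography beyond the species tree, gene
conversion (the turnover preset's relabelling is its only stand-in), and
recombination hot-spots.

## Numerical choices and test scales

Tolerances: boundary snapping accepts a likelihood loss of at most 1e-9;
the Haldane map function round-trips to 1e-9; grid-oracle equivalence is
asserted at 1e-3 in theta where the likelihood identifies a location, and
at the grid's maximum log-likelihood (1e-9) on flat ridges. The test suite
runs replicate studies at 3 x 20 families x 20 offspring (linkage regime,
100 M-test replicates), 3 x 10 x 10 (1,000-replicate type-I calibration),
40 families (Y-haplotype recovery), and 100 + 100 coalescent replicates at
the default deep-split parameters (scenario discrimination) — sizes chosen
to exercise the study scale while keeping the whole suite in the tens of
minutes on one core.

## Known limitations

* Two-point only: no multipoint likelihood, no interference (Kosambi), no
  sex-averaged maps.
* The phase-mixture MLE is noisy near `theta = 0.5` (see above); treat
  single-pair estimates there as "unlinked or nearly so".
* The population Y-haplotype count is a greedy minimum, order-dependent in
  principle (deterministic by male id) though exact on clean data.
* The exchange rate `r` is a free parameter: no quantitative sex-reversal
  rate is available to calibrate it, so scenario simulations explore preset
  magnitudes rather than an estimated value.
* ML tree search, substitution-model selection and molecular dating are
  out of scope; NJ on JC distances is the in-package estimator and
  externally produced trees are accepted as input.
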