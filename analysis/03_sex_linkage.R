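#!/usr/bin/env Rscript
# Stage 3 -- establish sex linkage: allele-frequency sex differences among
# adults, and non-recombining Y haplotypes from sibships and population
# samples.

library(xylink)

dir.create("results/sexlink", recursive = TRUE, showWarnings = FALSE)
d <- read_genotype_table("results/data/pedigree_genotypes.csv",
                         loci = locus_def(sprintf("L%d", 1:6),
                                          assumed_class = "sex_linked"))

## sex differences in allelic frequencies (adults only, per locus)
freq_rows <- list()
for (locus in d$loci$name) {
  res <- sex_allele_freq_test(d, locus, n_perm = 2000L, seed = 31L)
  freq_rows[[locus]] <- data.frame(locus = locus, G = res$G, p = res$p)
}
freq <- do.call(rbind, freq_rows)
write.csv(freq, "results/sexlink/sex_freq_tests.csv", row.names = FALSE)
message(sprintf(
  "Sex-frequency G tests: %d/%d loci significant at 0.05 (X and Y pools differ).",
  sum(freq$p <= 0.05), nrow(freq)))

## Y haplotypes from sibships
fams <- names(xy_families(d))
calls <- list()
for (fam in fams) {
  y <- infer_y_from_family(d, fam)
  calls[[fam]] <- data.frame(family = fam, male = y$male,
                             t(setNames(y$calls$call, y$calls$locus)),
                             inconsistent = sum(y$calls$inconsistent),
                             check.names = FALSE)
}
sib <- do.call(rbind, calls)
write.csv(sib, "results/sexlink/sibship_y_haplotypes.csv", row.names = FALSE)
message(sprintf(
  "Sibship analysis: Y haplotypes called for %d fathers; %d inconsistent locus calls.",
  nrow(sib), sum(sib$inconsistent)))

## population assignment from sibship-derived candidate alleles
cand <- lapply(d$loci$name, function(locus) {
  v <- sib[[locus]]
  v <- v[!v %in% c("ambiguous", "untyped")]
  as.integer(ifelse(v == "*", 0L, v))
})
names(cand) <- d$loci$name
for (sp in unique(d$ind$species)) {
  males <- which(d$ind$role == "adult" & d$ind$sex == "M" &
                   d$ind$species == sp)
  pop <- assign_y_population(d, cand, males = males)
  write.csv(cbind(male = rownames(pop$calls), pop$calls),
            sprintf("results/sexlink/population_y_%s.csv", sp),
            row.names = FALSE)
  message(sprintf("%s: >= %d distinct Y haplotypes among %d adult males.",
                  sp, pop$n_haplotypes, nrow(pop$calls)))
}
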