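#!/usr/bin/env Rscript
# Clone dynamics of balanced vs fate-biased progenitors.
#
# Solves the single-progenitor master equation at the clonal sampling
# times (1.5, 3, 6, 12 weeks) for a balanced wild-type-like population and
# a fate-biased mutant-like one, cross-checks against Gillespie
# simulation, and writes surviving-clone size statistics and extinction
# curves.

library(epiclone)
seed <- 101
dir.create("results", showWarnings = FALSE)

times <- c(1.5, 3, 6, 12)
genotypes <- list(balanced = sp_params(delta = 0),
                  biased = sp_params(delta = 0.25))

# for the biased genotype at 12 weeks ~8% of probability sits beyond the
# truncation; those clones are huge and certainly surviving, so the lumped
# boundary contributes to the conditional statistics as censored mass
stats <- do.call(rbind, lapply(names(genotypes), function(g) {
  s <- surviving_clone_size_stats(genotypes[[g]], times, n_max = 150,
                                  boundary_tol = 0.1)
  cbind(genotype = g, s)
}))
write.table(stats, "results/clone_size_stats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("surviving-clone mean basal size at 12 weeks: balanced ",
        round(stats$mean_basal[stats$genotype == "balanced" &
                                 stats$t == 12], 2), " cells, biased ",
        round(stats$mean_basal[stats$genotype == "biased" &
                                 stats$t == 12], 2), " cells")

ext <- data.frame(
  t = times,
  balanced = extinction_probability(genotypes$balanced, times, n_max = 80),
  biased = extinction_probability(genotypes$biased, times, n_max = 150,
                                  boundary_tol = 0.1))
write.table(ext, "results/extinction_curves.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("most balanced clones are lost by 12 weeks (extinction ",
        round(ext$balanced[4], 2), "); biased clones persist (",
        round(ext$biased[4], 2), ")")

# Monte-Carlo cross-check of the solver at 6 weeks
sim <- simulate_clone_final(genotypes$balanced, 6, 2e4, seed = seed)
bs <- basal_size_pmf(clone_size_pmf(genotypes$balanced, 6, n_max = 90))
emp <- tabulate(pmin(sim$n_p + sim$n_d, 91) + 1L, 92) / nrow(sim)
tv <- 0.5 * sum(abs(emp - c(bs$prob, attr(bs, "boundary_mass"))))
message("total-variation distance, master equation vs 2e4 Gillespie paths: ",
        signif(tv, 3))
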