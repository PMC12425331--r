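#!/usr/bin/env Rscript
# Validate the closed-form commute times against brute-force random
# walkers (first order), and compare non-backtracking (second-order)
# numerical commute times with the first-order analytic values.

suppressPackageStartupMessages(library(commutebrain))
dir.create("results/walks", showWarnings = FALSE, recursive = TRUE)

cn <- generate_connectome(connectome_spec(
  n_regions = 14, intra_density = 0.6, inter_density = 0.3,
  weight_log_mean = log(50), weight_log_sd = 0.5, length_decay = 60,
  bundle_degree_ratio = NA, seed = 2))

rep1 <- oracle_agreement(cn, n_walks = 1e4, seed = 11)
write_oracle_report(rep1, "results/walks/order1_agreement.tsv")
cat(sprintf(
  "Order-1 walkers: %.1f%% of %d pairs within |z| <= 3 of the closed form\n(1e4 walks per pair).\n",
  100 * rep1$fraction_within_3, nrow(rep1$pairs)))

ops <- build_operators(cn)
C <- commute_time(ops)$values
ij <- which(upper.tri(C), arr.ind = TRUE)
sim2 <- apply(ij, 1, function(p)
  simulate_commute(ops, p[1], p[2], 1000, seed = 13, order = 2)$mean_steps)
tab2 <- data.frame(i = ij[, 1], j = ij[, 2], analytic_order1 = C[ij],
                   simulated_order2 = sim2)
write.table(tab2, "results/walks/order2_vs_order1.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
rho2 <- spearman_correlation(sim2, C[ij])$rho
cat(sprintf(
  "Second-order (non-backtracking) commute times correlate with the\nfirst-order analytic values at Spearman rho = %.3f over %d pairs:\nmemory effects add little information at this scale.\n",
  rho2, nrow(ij)))
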