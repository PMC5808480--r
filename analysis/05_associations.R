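#!/usr/bin/env Rscript
# Stage 5: association statistics.
#
# (i) Planted-signal calibration of the destructive-bond detector on
# directly simulated stability tables (5 shifted bonds of 200 across 9
# variants); (ii) survival-time correlation against a stiffness value
# with a planted negative slope, plus the matching null; (iii) binned
# position-occupancy correlation and hypergeometric intersection
# between the destructive-bond residues and the stiffest residues of
# stage 4.
#
# Usage: Rscript analysis/05_associations.R [seed]

suppressPackageStartupMessages(library(enstab))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

# planted destructive-bond recovery
rec <- vapply(1:20, function(k) {
  pl <- simulate_sea_table(plant_spec(n_bonds = 200, n_variants = 9,
                                      planted_bonds = 5, delta = 0.4,
                                      background_sigma = 0.02,
                                      seed = seed * 100L + k))
  cs <- compute_deviations(pl$sea)
  det <- detect_destructive(cs, pl$truth$planted_variants, tail = 0.05)
  mean(pl$truth$planted_bonds %in% det$destructive_bonds)
}, 1)
message("planted-bond recovery over 20 seeds: ",
        round(100 * mean(rec), 1), "%")

# survival vs stiffness: planted slope and null
set.seed(seed)
kap <- stats::setNames(stats::runif(32, 1, 5), sprintf("M%02d", 1:32))
sigma <- 0.5 * stats::sd(kap) * sqrt(1 / 0.4^2 - 1)
planted <- vapply(1:50, function(k) {
  s <- simulate_survival(kap, a = 8, b = -0.5, sigma = sigma,
                         seed = seed * 200L + k)
  pearson(kap, s$table$years)$R
}, 1)
null_r <- vapply(1:50, function(k) {
  s <- simulate_survival(kap, a = 5, b = 0, sigma = 2,
                         seed = seed * 300L + k)
  abs(pearson(kap, s$table$years)$R)
}, 1)
message(sprintf("survival correlation: planted mean R = %.3f, null mean |R| = %.3f",
                mean(planted), mean(null_r)))
utils::write.table(
  data.frame(seed_index = 1:50, planted_R = planted, null_absR = null_r),
  "results/survival_correlations.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

# list comparison: destructive-bond residues vs stiffest residues
if (file.exists("results/destructive_residues.tsv") &&
    file.exists("results/stiffness_summary.tsv")) {
  dres <- utils::read.delim("results/destructive_residues.tsv",
                            stringsAsFactors = FALSE)
  stiff <- utils::read.delim("results/stiffness_summary.tsv",
                             stringsAsFactors = FALSE)
  n_res <- nrow(stiff)
  chains <- unique(dres$chain)
  subunit <- n_res / length(chains)
  pos_d <- dimer_position(dres$chain, dres$resno, chains = chains,
                          subunit_length = subunit)
  top <- stiff$residue[rank(-stiff$mean_stiffness) <= ceiling(n_res / 4)]
  top_chain <- sub("^.*\\.", "", top)
  top_resno <- as.integer(sub("\\..*$", "", top))
  pos_s <- dimer_position(top_chain, top_resno, chains = chains,
                          subunit_length = subunit)
  it <- intersection_test(pos_d, pos_s, universe_size = n_res)
  bc <- binned_position_correlation(pos_d, pos_s, universe = n_res)
  message(sprintf("destructive/stiff overlap: %d positions, p = %.3g; binned R = %.2f (p = %.3g)",
                  length(it$overlap), it$p, bc$R, bc$p))
  utils::write.table(
    data.frame(metric = c("overlap_size", "overlap_p", "binned_R",
                          "binned_p"),
               value = c(length(it$overlap), it$p, bc$R, bc$p)),
    "results/list_comparison.tsv", sep = "\t", quote = FALSE,
    row.names = FALSE)
} else {
  message("stage 3/4 outputs missing; list comparison not run")
}
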