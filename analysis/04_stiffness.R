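#!/usr/bin/env Rscript
# Stage 4: mechanical stiffness maps of the wild type.
#
# A C-alpha + metal-ion elastic network (8 A cutoff) gives pairwise
# effective spring constants kappa_ij from the full non-trivial mode
# spectrum. Reported: per-residue mean stiffness K-bar with its
# rightmost tail; the stiffness profile from the chain-A metal with its
# tail; the widest (maximin-stiffness) path between the two metal
# sites, i.e. the presumed route of mechanical impulse transmission;
# and a PDB copy with the site profile in the B-factor column for
# viewing.
#
# Usage: Rscript analysis/04_stiffness.R

suppressPackageStartupMessages(library(enstab))

manifest <- utils::read.delim("results/structures/manifest.tsv",
                              stringsAsFactors = FALSE)
wt <- read_pdb(manifest$path[1])
wt$id <- manifest$id[1]

cfg <- ensemble_config(node_policy = "calpha")
model <- build_elastic_model(wt, cfg)
modes <- compute_modes(model)
kappa <- pairwise_stiffness(modes)
message("stiffness matrix: ", nrow(kappa$kappa), " nodes, ",
        kappa$modes_used, " modes")

utils::write.table(
  data.frame(node = rownames(kappa$kappa), kappa$kappa,
             check.names = FALSE),
  "results/kappa_matrix.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

kbar <- mean_stiffness(kappa)
top_mean <- top_tail(kbar, 0.10)  # 24-residue toy: 10% tail ~ 2 residues
message("stiffest residues (10% tail of K-bar): ",
        paste(top_mean, collapse = ", "))

site <- "CU:A"
prof <- site_stiffness_profile(kappa, site)
metals <- rownames(kappa$kappa)[kappa$nodes$is_metal]
res_prof <- prof[!names(prof) %in% metals]
top_site <- top_tail(res_prof, 0.10)
message("stiffest residues to ", site, ": ",
        paste(top_site, collapse = ", "))

utils::write.table(
  data.frame(residue = names(kbar), mean_stiffness = kbar,
             site_stiffness = res_prof[names(kbar)]),
  "results/stiffness_summary.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

path <- transmission_path(kappa, "CU:A", "CU:B")
message("transmission path ", paste(path, collapse = "-"),
        " (bottleneck kappa ", signif(attr(path, "bottleneck"), 3), ")")
writeLines(paste(path, collapse = "-"), "results/transmission_path.txt")

write_stiffness_pdb(wt, res_prof, "results/wt_site_stiffness.pdb")

# stiffness of important positions vs the background kappa distribution
important <- paste0(4:6, ".A")  # the metal-coordinating positions
all_kappa <- kappa$kappa[upper.tri(kappa$kappa)]
all_kappa <- all_kappa[is.finite(all_kappa)]
rows <- lapply(setdiff(rownames(kappa$kappa), c(important, metals)),
               function(p) {
  sm <- site_mean_stiffness(kappa, p, important)
  ks <- ks_two_sample(sm$sample, all_kappa)
  data.frame(position = p, mean_kappa = sm$mean, ks_p = ks$p)
})
ks_tab <- do.call(rbind, rows)
ks_tab$fdr_rejected <- bh_fdr(stats::setNames(ks_tab$ks_p,
                                              ks_tab$position))$rejected
utils::write.table(ks_tab, "results/site_stiffness_tests.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sum(ks_tab$fdr_rejected), " of ", nrow(ks_tab),
        " positions differ from the background at 5% FDR")
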