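#!/usr/bin/env Rscript
# Stage 3: variant clustering and destructive hydrogen bonds.
#
# From the SEA table: (i) mean-shift clustering of structures by their
# SEA vectors (bandwidth from the k-NN quantile estimator) plus a
# hierarchical outlier ranking; (ii) per-variant deviations D^m from
# the wild type and per-bond contributions xi_j^m; (iii) the 9-bin
# contribution histogram (table H) with its S-bar summary; (iv)
# mean-shift selection of high-contribution variants and detection of
# destructive bonds as the rightmost 5% tail of the mean contribution
# distribution; (v) the residues forming those bonds.
#
# Usage: Rscript analysis/03_destructive_bonds.R

suppressPackageStartupMessages(library(enstab))

wt_id <- utils::read.delim("results/structures/manifest.tsv",
                           stringsAsFactors = FALSE)$id[1]
sea <- read_stability_table("results/sea.tsv", wt_column = wt_id)
message("SEA table: ", nrow(sea$values), " bonds x ", ncol(sea$values),
        " structures")

# clustering of structures by SEA vectors
pts <- t(sea$values)
bw <- estimate_bandwidth(pts)
cl <- mean_shift(pts, bw)
message("mean-shift: ", cl$n_clusters, " clusters at bandwidth ",
        round(bw, 3))
utils::write.table(
  data.frame(structure = rownames(pts), cluster = cl$labels),
  "results/sea_clusters.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
outliers <- rank_outliers_hierarchical(pts)
utils::write.table(outliers$ranking, "results/sea_outlier_ranking.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

# deviations, contributions, table H
contrib <- compute_deviations(sea)
h <- build_h_table(contrib)
utils::write.table(
  data.frame(variant = rownames(h$counts), h$counts, s_bar = h$s_bar,
             D = contrib$D[rownames(h$counts)], check.names = FALSE),
  "results/h_table.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

selected <- select_high_contribution_variants(h)
message("high-contribution variants: ",
        if (length(selected)) paste(selected, collapse = ", ") else "(none)")
if (length(selected) == 0) {
  message("single H-cluster; falling back to all variants for the tail scan")
  selected <- colnames(contrib$xi)
}

res <- detect_destructive(contrib, selected, tail = 0.05)
message(length(res$destructive_bonds), " destructive bonds at threshold ",
        signif(res$threshold, 3), "; explained fraction ",
        round(res$explained_fraction, 2))
utils::write.table(
  data.frame(bond = res$destructive_bonds,
             xi_bar = res$xi_bar[res$destructive_bonds],
             rank = seq_along(res$destructive_bonds)),
  "results/destructive_bonds.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

residues <- residues_of_bonds(res$destructive_bonds)
utils::write.table(residues, "results/destructive_residues.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("residues involved: ",
        paste(paste0(residues$resno, ".", residues$chain), collapse = ", "))
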