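#!/usr/bin/env Rscript
# Stage 1: build the study system.
#
# A two-chain helical dimer with one copper-like ion per chain stands in
# for a metalloprotein dimer; 35 variants are derived from it, a small
# minority with concentrated damage near hydrogen-bond partners (the
# structural analogue of destabilizing substitutions) and the rest with
# diffuse mild noise. Structures are written as PDB plus a manifest so
# later stages (and external tools) can consume them.
#
# Usage: Rscript analysis/01_build_structures.R [seed]

suppressPackageStartupMessages(library(enstab))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out_dir <- "results/structures"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

spec <- toy_spec(n_res_per_chain = 12, n_chains = 2,
                 metal_sites = list(list(chain = "A", residues = 4:6),
                                    list(chain = "B", residues = 4:6)))
wt <- make_toy_structure(spec)
message("wild type: ", nrow(wt$atoms), " atoms, chains ",
        paste(wt$chains, collapse = ","))

severe <- 1:6
manifest <- data.frame(id = character(0), path = character(0),
                       kind = character(0), seed = integer(0))
save_structure <- function(s, kind, sd_used) {
  p <- file.path(out_dir, paste0(s$id, ".pdb"))
  write_pdb(s, p)
  manifest <<- rbind(manifest, data.frame(id = s$id, path = p, kind = kind,
                                          seed = seed))
  invisible(p)
}
save_structure(wt, "wild_type", 0)

for (k in 1:35) {
  id <- sprintf("V%02d", k)
  if (k %in% severe) {
    v <- make_variant(wt, positions = c(5 + (k %% 3), 9 + (k %% 3)),
                      sigma = 1.2, seed = seed * 1000L + k, id = id)
    save_structure(v, "severe", 1.2)
  } else {
    v <- make_variant(wt, positions = 1:12, sigma = 0.08,
                      seed = seed * 1000L + k, id = id)
    save_structure(v, "mild", 0.08)
  }
}

utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote ", nrow(manifest), " structures and manifest to ", out_dir)
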