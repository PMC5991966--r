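#!/usr/bin/env Rscript
# Step 5: weighted re-scoring of the published virtual-screening hits.
# Inputs are the published per-structure Vina free energies and interaction
# counts shipped with the package; the score gives 80% weight to the
# (min-max normalized, negated) free energy and 20% to the interaction
# count. Rule-of-five descriptors are evaluated alongside.

suppressMessages(library(allostruct))
outdir <- "results/05_screening"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

hits <- load_scores(system.file("extdata/screening/vina_hits.csv",
                                package = "allostruct"))
cat("loaded", nrow(hits), "ligand-target-site records,",
    length(unique(hits$ligand)), "distinct ligands\n")

# per-ligand consensus record: the pose with the best (lowest) energy
best <- do.call(rbind, lapply(split(hits, hits$ligand), function(d)
  d[which.min(d$energy), ]))
ranked <- weighted_score(best)
write.csv(ranked, file.path(outdir, "rescored_consensus.csv"),
          row.names = FALSE)
cat("top 5 by weighted score:\n")
print(ranked[1:5, c("rank", "ligand", "target", "site", "energy",
                    "n_interactions", "weighted_score")], row.names = FALSE)

# per-target ranking (scores are only comparable within one list)
per_target <- do.call(rbind, lapply(split(hits, hits$target), weighted_score))
write.csv(per_target, file.path(outdir, "rescored_per_target.csv"),
          row.names = FALSE)

desc <- read.csv(system.file("extdata/screening/ligand_descriptors.csv",
                             package = "allostruct"))
desc <- desc[!duplicated(desc$ligand), ]
lip <- t(vapply(seq_len(nrow(desc)), function(i) {
  r <- lipinski(desc$donors[i], desc$acceptors[i], desc$mass[i], desc$logp[i])
  c(violations = r$violations, pass = as.integer(r$pass))
}, numeric(2)))
out <- cbind(desc, lip)
write.csv(out, file.path(outdir, "lipinski.csv"), row.names = FALSE)
cat(sum(out$pass), "of", nrow(out),
    "ligands pass the rule of five (<= 1 violation)\n")
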