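#!/usr/bin/env Rscript
# Hierarchical clustering of the simulated cohort: unsupervised on all
# retained miRNAs and supervised on the significant set, with the
# pair-cohesion statistic (a pair is cohesive when its primary and
# recurrent samples are direct siblings in the tree).
#
# Run analysis/04_mirna_de.R first.

library(medmir)

state <- readRDS("scratch/mirna_state.rds")
ex <- state$expr
dir.create("results", showWarnings = FALSE)

pm <- data.frame(pair_id = unique(ex$pair),
                 primary = names(ex$pair)[ex$role == "primary"],
                 recurrent = names(ex$pair)[ex$role == "recurrent"])

tree_all <- hierarchical_cluster(ex$expr, distance = "pearson",
                                 linkage = "average")
write_tree_newick(tree_all, "results/tree_unsupervised.nwk")
pc_all <- pair_cohesion(tree_all, pm)
cat(sprintf("unsupervised clustering: %d of %d pairs cluster together\n",
            pc_all$count, nrow(pm)))

sig <- state$de$mirna[state$de$significant]
if (length(sig) >= 2) {
  tree_sig <- hierarchical_cluster(ex$expr[rownames(ex$expr) %in% sig, ,
                                           drop = FALSE])
  write_tree_newick(tree_sig, "results/tree_supervised.nwk")
  pc_sig <- pair_cohesion(tree_sig, pm)
  cat(sprintf("supervised clustering (%d significant miRNAs): %d of %d pairs cohesive\n",
              length(sig), pc_sig$count, nrow(pm)))
}
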