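#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input the downstream stages consume.
#
# The stated world mirrors the survey and incubation designs: a 47-soil pH
# gradient (pH 3.48-8.74) carrying 425 phylotypes with Gaussian pH niches
# (bimodal narrow/broad breadths), and 30-day pH-shift incubations
# (native 6.0, shifts to 4.5 and 7.5; days 0/1/3/10/30; 3 replicates).
# Writes results/sim/.

library(phniche)

seed <- 20260918
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

grad <- gen_soil_gradient(gradient_scenario(), seed = seed)
write_tsv(unclass(grad$counts), "results/sim/gradient_counts.tsv",
          seed = seed)
write_tsv(grad$meta, "results/sim/gradient_meta.tsv", seed = seed)
write_tsv(grad$truth, "results/sim/gradient_truth.tsv", seed = seed)

cat(sprintf("gradient: %d phylotypes x %d soils, %.1f%% nonzero cells\n",
            nrow(grad$counts), ncol(grad$counts),
            100 * mean(grad$counts > 0)))

# the incubation needs classes; classify here once so stage 3 can rerun
# without recomputing stage 2 (stage 2 re-derives the same table)
cls <- classify_niche_breadth(grad$counts, grad$meta)
inc <- gen_incubation(incubation_scenario(), cls, seed = seed + 1)
for (cn in inc$conditions)
  for (r in seq_along(inc$dna[[cn]])) {
    write_tsv(inc$dna[[cn]][[r]],
              sprintf("results/sim/incubation_dna_%s_rep%d.tsv", cn, r),
              seed = seed + 1)
    write_tsv(inc$rna[[cn]][[r]],
              sprintf("results/sim/incubation_rna_%s_rep%d.tsv", cn, r),
              seed = seed + 1)
    write_tsv(data.frame(phylotype_id = names(inc$sip[[cn]][[r]]),
                         value = inc$sip[[cn]][[r]]),
              sprintf("results/sim/incubation_sip_%s_rep%d.tsv", cn, r),
              seed = seed + 1)
  }
cat(sprintf("incubation: %d conditions x %d replicates x %d timepoints\n",
            length(inc$conditions), length(inc$dna[[1]]),
            length(inc$timepoints)))

# phylogeny over the classified phylotypes for stages 4 and 5
tree <- gen_yule_tree(1, nrow(cls), seed = seed + 2)
tree$tip.label <- cls$phylotype_id
ape::write.tree(tree, "results/sim/phylogeny.nwk")
cat(sprintf("tree: %d tips, depth %.2f\n", length(tree$tip.label),
            max(ape::node.depth.edgelength(tree))))
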