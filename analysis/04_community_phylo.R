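#!/usr/bin/env Rscript
# Stage 4: phylogenetic community structure along the gradient and
# phylogenetic signal of the generalism trait.
#
# Per-soil abundance-weighted mpd is standardized against 999 richness
# nulls (ses.mpd; negative = phylogenetic clustering), ses.mpd is
# regressed on soil pH, and Blomberg's K with a 999-permutation test asks
# whether generalism is phylogenetically conserved. Reads results/sim/ and
# results/classification.tsv, writes results/.

library(phniche)

seed <- 20260918
counts <- read_abundance("results/sim/gradient_counts.tsv")
meta <- read_sample_meta("results/sim/gradient_meta.tsv")
tree <- read_tree("results/sim/phylogeny.nwk")
cls <- utils::read.delim("results/classification.tsv", comment.char = "#")

ses <- ses_mpd_table(counts, tree, n_null = 999, seed = seed)
write_tsv(ses, "results/ses_mpd.tsv", seed = seed)
cat(sprintf("ses.mpd over %d soils: mean %.3f, %d significantly clustered (p < 0.05, ses < 0)\n",
            nrow(ses), mean(ses$ses),
            sum(ses$p < 0.05 & ses$ses < 0)))

fit <- ses_mpd_vs_ph(ses$ses, meta$pH[match(ses$sample_id,
                                            meta$sample_id)])
cat(sprintf("ses.mpd ~ pH: slope %.3f, R2 = %.2f, F = %.1f, p = %.3g\n",
            fit$slope, fit$r_squared, fit$f_statistic, fit$p))
write_tsv(data.frame(slope = fit$slope, intercept = fit$intercept,
                     r_squared = fit$r_squared,
                     f_statistic = fit$f_statistic, p = fit$p),
          "results/ses_mpd_vs_ph.tsv", seed = seed)

trait <- stats::setNames(as.numeric(cls$nb_class == "generalist"),
                         cls$phylotype_id)
k <- blomberg_k(tree, trait, n_perm = 999, seed = seed)
cat(sprintf("Blomberg's K of generalism: K = %.3f, p = %.3g (%d perms)\n",
            k$K, k$p, k$n_perm))
write_tsv(data.frame(K = k$K, p = k$p, n_perm = k$n_perm),
          "results/phylosignal.tsv", seed = seed)
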