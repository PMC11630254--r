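#!/usr/bin/env Rscript
# Stage 3: growth, transcriptional activity, dormancy and diversity in the
# pH-shift incubations.
#
# Growth is the truncated day-30 minus day-0 DNA differential; RNA
# activity sums truncated successive-interval differentials; the SIP
# analogue is the end-point abundance of the replicating subset. Activities
# are summed per phenotype (replicates averaged after truncation), the
# combined dormancy+death fraction is the clipped complement of
# active/resident, and Shannon diversity is computed without rarefaction.
# Reads results/sim/ and results/classification.tsv, writes results/.

library(phniche)

cls <- utils::read.delim("results/classification.tsv", comment.char = "#")
conds <- c("pH4.5", "pH6.0", "pH7.5")
reps <- 1:3

pheno <- dorm <- div <- list()
for (cn in conds) {
  per_rep <- lapply(reps, function(r) {
    dna <- as.matrix(utils::read.delim(
      sprintf("results/sim/incubation_dna_%s_rep%d.tsv", cn, r),
      comment.char = "#", row.names = 1, check.names = FALSE))
    rna <- as.matrix(utils::read.delim(
      sprintf("results/sim/incubation_rna_%s_rep%d.tsv", cn, r),
      comment.char = "#", row.names = 1, check.names = FALSE))
    sip <- utils::read.delim(
      sprintf("results/sim/incubation_sip_%s_rep%d.tsv", cn, r),
      comment.char = "#")
    g <- growth(dna[, 1], dna[, ncol(dna)])
    ta <- transcriptional_activity(rna)$total
    list(growth = phenotype_sums(g, cls),
         transcription = phenotype_sums(ta, cls),
         replication = phenotype_sums(
           data.frame(phylotype_id = sip$phylotype_id, value = sip$value),
           cls),
         dormancy = dormancy_fraction(sum(sip$value), sum(dna[, ncol(dna)])),
         shannon_resident = shannon(dna[, ncol(dna)]),
         shannon_active = shannon(pmax(dna[, ncol(dna)] - dna[, 1], 0)))
  })
  for (m in c("growth", "transcription", "replication")) {
    avg <- rowMeans(sapply(per_rep, `[[`, m))
    pheno[[length(pheno) + 1]] <- data.frame(
      condition = cn, method = m, phenotype = names(avg), value = avg)
  }
  dorm[[length(dorm) + 1]] <- data.frame(
    condition = cn,
    dormancy = mean(vapply(per_rep, `[[`, numeric(1), "dormancy")))
  div[[length(div) + 1]] <- data.frame(
    condition = cn,
    shannon_resident = mean(vapply(per_rep, `[[`, numeric(1),
                                   "shannon_resident")),
    shannon_active = mean(vapply(per_rep, `[[`, numeric(1),
                                 "shannon_active")))
}
pheno <- do.call(rbind, pheno)
write_tsv(pheno, "results/phenotype_activity.tsv")
write_tsv(do.call(rbind, dorm), "results/dormancy.tsv")
write_tsv(do.call(rbind, div), "results/diversity.tsv")

cat("phenotype growth sums (replicate means, copies/g):\n")
print(reshape(pheno[pheno$method == "growth", -2],
              idvar = "phenotype", timevar = "condition",
              direction = "wide"), row.names = FALSE)

# who wins where: the gated comparison of specialist vs generalist growth
for (cn in conds) {
  g <- pheno[pheno$method == "growth" & pheno$condition == cn, ]
  s <- g$value[g$phenotype == "specialist"]
  gl <- g$value[g$phenotype == "generalist"]
  cat(sprintf("%s: specialists %s generalists (growth)\n", cn,
              if (s > gl) ">" else "<"))
}
cat("dormancy+death fraction per condition:\n")
print(do.call(rbind, dorm), row.names = FALSE)
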