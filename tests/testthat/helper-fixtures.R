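# Small fixtures shared across test files; all built in code.

fix_matrix <- function() {
  m <- rbind(
    p1 = c(0, 2, 5, 0),
    p2 = c(1, 1, 1, 1),
    p3 = c(0, 0, 3, 0),
    p4 = c(4, 0, 0, 2))
  colnames(m) <- paste0("s", 1:4)
  abundance_matrix(m, "absolute")
}

fix_meta <- function() {
  data.frame(sample_id = paste0("s", 1:4),
             pH = c(4.0, 5.5, 6.5, 8.0),
             qpcr_total = c(1e6, 2e6, 5e5, 3e6))
}

# balanced two-clade ultrametric tree with a deep split between the clades
fix_two_clade_tree <- function(n_per_clade = 8, deep = 10) {
  a <- gen_yule_tree(1, n_per_clade, seed = 1)
  a$tip.label <- paste0("a", seq_len(n_per_clade))
  b <- gen_yule_tree(1, n_per_clade, seed = 2)
  b$tip.label <- paste0("b", seq_len(n_per_clade))
  ha <- max(ape::node.depth.edgelength(a))
  hb <- max(ape::node.depth.edgelength(b))
  H <- max(ha, hb)
  txt <- sprintf("(%s:%.10g,%s:%.10g);",
                 sub(";$", "", ape::write.tree(a)), deep + H - ha,
                 sub(";$", "", ape::write.tree(b)), deep + H - hb)
  ape::read.tree(text = txt)
}
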