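test_that("relative abundances scale to qPCR totals and round-trip", {
  rel <- abundance_matrix(
    cbind(s1 = c(p1 = 0.5, p2 = 0.5), s2 = c(0.2, 0.8), s3 = c(0, 0)),
    "relative")
  tot <- c(s1 = 1e8, s2 = 1e6, s3 = 0)
  abs <- to_cell_abundance(rel, tot)
  expect_equal(abs["p1", "s1"], 5e7)
  expect_equal(unname(colSums(abs)), unname(tot))
  expect_equal(abs[, "s2"], c(p1 = 2e5, p2 = 8e5))
  expect_true(all(abs[, "s3"] == 0))
  # round trip: renormalizing recovers the relative matrix where total > 0
  renorm <- sweep(unclass(abs)[, 1:2], 2, colSums(abs)[1:2], `/`)
  expect_equal(renorm, unclass(rel)[, 1:2], tolerance = 1e-9)
  expect_error(to_cell_abundance(rel, tot[1:2]), "missing qPCR total")
  expect_error(to_cell_abundance(abs, tot), "relative")
})

test_that("growth truncates negative differentials to null", {
  g <- growth(c(a = 100, b = 100, c = 0), c(a = 160, b = 40, c = 0))
  expect_equal(g$value[match(c("a", "b", "c"), g$phylotype_id)],
               c(60, 0, 0))
  expect_true(all(g$value >= 0))
  expect_error(growth(c(a = 1), c(b = 1)), "same phylotypes")
})

test_that("transcriptional activity sums truncated interval differences", {
  m <- matrix(c(5, 9, 7, 12), 1, dimnames = list("p1", c(0, 1, 3, 10)))
  ta <- transcriptional_activity(m)
  expect_equal(ta$per_interval$value, c(4, 0, 5))
  expect_equal(ta$total$value, 9)
  dec <- matrix(c(9, 7, 4, 1), 1, dimnames = list("p1", c(0, 1, 3, 10)))
  expect_true(all(transcriptional_activity(dec)$per_interval$value == 0))
  const <- matrix(5, 1, 4, dimnames = list("p1", c(0, 1, 3, 10)))
  expect_equal(transcriptional_activity(const)$total$value, 0)
  expect_error(transcriptional_activity(m[, 1, drop = FALSE]),
               ">= 2 time points")
})

test_that("phenotype sums conserve the total exactly", {
  cls <- data.frame(phylotype_id = c("a", "b", "c", "d"),
                    nb_class = c("specialist", "generalist",
                                 "putative_specialist", "specialist"))
  act <- data.frame(phylotype_id = c("a", "b", "c", "d"),
                    value = c(10, 30, 2, 7))
  ps <- phenotype_sums(act, cls)
  expect_equal(unname(ps), c(17, 30, 2))
  expect_identical(sum(ps), sum(act$value))
  empty <- act[0, ]
  expect_equal(unname(phenotype_sums(empty, cls)), c(0, 0, 0))
  act$phylotype_id[1] <- "zz"
  expect_error(phenotype_sums(act, cls), "zz")
})

test_that("dormancy fraction is the clipped complement of active/resident", {
  expect_equal(dormancy_fraction(33, 100), 0.67)
  expect_equal(dormancy_fraction(100, 100), 0)
  expect_warning(d <- dormancy_fraction(150, 100), "clipped")
  expect_equal(d, 0)
  expect_error(dormancy_fraction(1, 0), "> 0")
})

test_that("Shannon index uses natural log over positive abundances", {
  expect_equal(shannon(rep(5, 4)), log(4))
  expect_equal(shannon(c(10, 0, 0)), 0)
  expect_equal(shannon(c(0.5, 0.25, 0.25)), 1.03972, tolerance = 1e-5)
  expect_error(shannon(c(0, 0)), "positive sum")
})

test_that("Bray-Curtis matches the formula and the vegan implementation", {
  expect_equal(bray_curtis(c(1, 2), c(1, 2)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 3)), 1)
  expect_equal(bray_curtis(c(1, 1), c(1, 3)), 1 / 3, tolerance = 1e-9)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  set.seed(9)
  m <- matrix(rpois(60, 8), 10, dimnames = list(paste0("p", 1:10),
                                                paste0("s", 1:6)))
  d <- bray_curtis_matrix(m)
  ref <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  expect_equal(unname(d), unname(ref), tolerance = 1e-12)
})

test_that("gated test picks Welch under met assumptions, Kruskal otherwise", {
  set.seed(11)
  a <- rnorm(30); b <- rnorm(30, 0.2)
  r <- gated_group_test(a, b)
  expect_identical(r$test_used, "welch")
  b_out <- c(rnorm(29), 40)  # extreme outlier breaks normality
  r2 <- gated_group_test(a, b_out)
  expect_identical(r2$test_used, "kruskal")
  expect_lt(r2$gates$shapiro_b, 0.05)
  r3 <- gated_group_test(1:10, 1:10)
  expect_gt(r3$p_value, 0.9)
  expect_error(gated_group_test(1:2, 1:5), "n >= 3")
})

test_that("gate selects Welch at about the (0.95)^3 rate on Gaussian pairs", {
  set.seed(202)
  n_rep <- 1000
  welch <- vapply(seq_len(n_rep), function(i)
    gated_group_test(rnorm(30), rnorm(30))$test_used == "welch",
    logical(1))
  expect_lt(abs(mean(welch) - 0.95^3), 0.03)
})

test_that("extreme-pH grouping uses the 5.0 / 8.5 bounds", {
  expect_identical(as.character(extreme_ph_split(c(4.2, 5.0, 6.5, 8.5))),
                   c("extreme", "extreme", "classical", "extreme"))
})

test_that("designed phenotype growth ranking is recovered from incubations", {
  cls <- data.frame(
    phylotype_id = sprintf("p%02d", 1:70),
    nb_class = rep(c("specialist", "generalist", "putative_specialist"),
                   c(30, 30, 10)))
  hits <- vapply(1:20, function(s) {
    inc <- gen_incubation(incubation_scenario(), cls, seed = s)
    sums <- sapply(c("pH4.5", "pH6.0"), function(cn) {
      per_rep <- sapply(seq_along(inc$dna[[cn]]), function(r) {
        m <- inc$dna[[cn]][[r]]
        g <- growth(m[, 1], m[, ncol(m)])
        phenotype_sums(g, cls)
      })
      rowMeans(per_rep)  # replicates averaged after activity computation
    })
    sums["specialist", "pH4.5"] > sums["generalist", "pH4.5"] &&
      sums["generalist", "pH6.0"] > sums["specialist", "pH6.0"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
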