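test_that("pH to [H+] conversion is the closed form and strictly decreasing", {
  expect_equal(ph_to_hplus(7), 1e-7)
  expect_equal(ph_to_hplus(0), 1)
  expect_equal(ph_to_hplus(4.5), 10^(-4.5), tolerance = 1e-12)
  ph <- seq(3, 9, by = 0.25)
  expect_true(all(diff(ph_to_hplus(ph)) < 0))
  expect_error(ph_to_hplus(NA_real_), "finite")
  expect_error(ph_to_hplus(Inf), "finite")
})

test_that("occupancy counts samples above the presence threshold", {
  m <- fix_matrix()
  expect_identical(unname(occupancy(m, "p1")), 2L)
  expect_identical(unname(occupancy(m, "p2")), 4L)
  expect_identical(unname(occupancy(m, "p3")), 1L)
  z <- abundance_matrix(rbind(p = c(a = 0, b = 0)), "absolute")
  expect_identical(unname(occupancy(z, "p")), 0L)
  expect_error(occupancy(m, "nope"), "unknown phylotype")
  # threshold is strict: values equal to it do not count
  expect_identical(unname(occupancy(m, "p2", presence_threshold = 1)), 0L)
})

test_that("B index reproduces the worked pH 5/7 value and the zero-variance case", {
  h <- ph_to_hplus(c(5, 7))
  # hand derivation: mu = 5.05e-6, sigma^2 = 4.9005e-11 (n-1 denominator),
  # B = (1/sqrt(2)) * 4.9005e-11 / 2.55025e-11 = 1.3587598
  expect_equal(niche_breadth_index(c(1, 1), h), 1.35876, tolerance = 1e-5)
  expect_equal(niche_breadth_index(c(1, 1), ph_to_hplus(c(6, 6))), 0)
  # abundances enter only through presence in unweighted mode
  expect_identical(niche_breadth_index(c(1, 1) * 10, h),
                   niche_breadth_index(c(1, 1), h))
  expect_identical(niche_breadth_index(c(3, 9), h),
                   niche_breadth_index(c(5, 1), h))
  expect_error(niche_breadth_index(c(1, 0), h), "putative-specialist")
  expect_error(niche_breadth_index(c(1, 1), c(1e-5, -1e-7)), "> 0")
})

test_that("B = 0 iff occupied [H+] identical, and grows as one sample moves away", {
  base <- rep(6, 5)
  expect_equal(niche_breadth_index(rep(1, 5), ph_to_hplus(base)), 0)
  shifts <- c(0.2, 0.5, 1, 2)
  b <- vapply(shifts, function(s)
    niche_breadth_index(rep(1, 5), ph_to_hplus(c(6 + s, base[-1]))),
    numeric(1))
  expect_true(all(b > 0))
  expect_true(all(diff(b) > 0))
})

test_that("abundance-weighted moments respond to weights", {
  h <- ph_to_hplus(c(5, 7))
  b_eq <- niche_breadth_index(c(1, 1), h, weighted = TRUE)
  b_sk <- niche_breadth_index(c(99, 1), h, weighted = TRUE)
  expect_false(isTRUE(all.equal(b_eq, b_sk)))
  # equal weights reduce to the unweighted value
  expect_equal(b_eq, niche_breadth_index(c(1, 1), h), tolerance = 1e-12)
})

test_that("median split follows the stated tie rule", {
  rec <- data.frame(phylotype_id = paste0("p", 1:4), n_j = 2L,
                    mu_hplus = 1, sigma2_hplus = 1,
                    B = c(0.1, 0.2, 0.3, 0.4))
  out <- classify_by_median(rec)
  expect_identical(as.character(out$nb_class),
                   c("specialist", "specialist", "generalist", "generalist"))
  # ties at the median go to specialist under the default "le" rule
  rec$B <- c(1, 2, 2, 3)
  out <- classify_by_median(rec)
  expect_identical(sum(out$nb_class == "specialist"), 3L)
  expect_identical(sum(out$nb_class == "generalist"), 1L)
  out_lt <- classify_by_median(rec, tie = "lt")
  expect_identical(sum(out_lt$nb_class == "specialist"), 1L)
  # all singletons: everything is a putative specialist, no cut-off needed
  singles <- data.frame(phylotype_id = c("a", "b"), n_j = 1L,
                        mu_hplus = 1, sigma2_hplus = NA_real_, B = NA_real_)
  expect_true(all(classify_by_median(singles)$nb_class ==
                    "putative_specialist"))
})

test_that("tie-free median split is balanced to within one", {
  set.seed(42)
  for (n in c(10, 11, 50, 61)) {
    rec <- data.frame(phylotype_id = seq_len(n), n_j = 2L, mu_hplus = 1,
                      sigma2_hplus = 1, B = stats::runif(n))
    out <- classify_by_median(rec)
    expect_lte(abs(sum(out$nb_class == "specialist") -
                     sum(out$nb_class == "generalist")), 1)
  }
})

test_that("range class uses the up-to-three-sites rule", {
  expect_identical(as.character(range_class(c(1, 3, 4, 10))),
                   c("endemic", "endemic", "cosmopolitan", "cosmopolitan"))
  expect_error(range_class(0), ">= 1")
})

test_that("classification is invariant to global abundance rescaling", {
  sim <- gen_soil_gradient(gradient_scenario(n_soils = 20,
                                             n_phylotypes = 60), seed = 3)
  cls1 <- suppressWarnings(classify_niche_breadth(sim$counts, sim$meta))
  scaled <- abundance_matrix(unclass(sim$counts) * 7.5, "absolute")
  cls2 <- suppressWarnings(classify_niche_breadth(scaled, sim$meta))
  expect_identical(cls1$n_j, cls2$n_j)
  expect_equal(cls1$B, cls2$B)
  expect_identical(as.character(cls1$nb_class), as.character(cls2$nb_class))
  expect_identical(as.character(cls1$range_class),
                   as.character(cls2$range_class))
})

test_that("narrow-niche phylotypes receive lower B than broad ones", {
  # AUC-style separation of B between the two designed breadth components,
  # among phylotypes with defined B, averaged over 10 seeds
  aucs <- vapply(1:10, function(s) {
    sim <- gen_soil_gradient(gradient_scenario(n_soils = 30,
                                               n_phylotypes = 120),
                             seed = s)
    tab <- niche_breadth_table(sim$counts, sim$meta)
    tab <- tab[!is.na(tab$B), ]
    comp <- sim$truth$component[match(tab$phylotype_id,
                                      sim$truth$phylotype_id)]
    if (length(unique(comp)) < 2) return(NA_real_)
    w <- stats::wilcox.test(tab$B[comp == "broad"],
                            tab$B[comp == "narrow"])$statistic
    unname(w / (sum(comp == "broad") * sum(comp == "narrow")))
  }, numeric(1))
  expect_gte(mean(aucs, na.rm = TRUE), 0.95)
})

test_that("index diagnostics tabulate candidates against the abundance rank", {
  sim <- gen_soil_gradient(gradient_scenario(n_soils = 25,
                                             n_phylotypes = 80), seed = 4)
  diag <- nb_index_diagnostics(sim$counts, sim$meta)
  expect_true(all(c("sd_hplus", "se_hplus", "B", "abund_rank") %in%
                    names(diag)))
  expect_identical(sort(names(attr(diag, "rank_correlations"))),
                   sort(c("sd_hplus", "se_hplus", "B")))
  expect_true(all(diag$B >= 0))
})
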