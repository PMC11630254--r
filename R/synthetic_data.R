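#' Scenario for a synthetic soil pH gradient survey
#'
#' Stated world for the gradient generator: 47 soils spanning pH
#' 3.48-8.74, 425 phylotypes with Gaussian niche response curves on the pH
#' axis whose breadths come from a bimodal narrow/broad mixture, lognormal
#' carrying abundances and multiplicative lognormal sampling noise, a
#' detection threshold, and per-soil lognormal qPCR totals.
#'
#' @param n_soils,ph_range,n_phylotypes Survey dimensions (defaults 47,
#'   c(3.48, 8.74), 425).
#' @param breadth_narrow,breadth_broad Niche breadths (pH units) of the two
#'   mixture components; defaults 0.35 and 1.5.
#' @param p_narrow Mixing proportion of the narrow component (default 0.5).
#' @param carrying_meanlog,carrying_sdlog Lognormal carrying abundance
#'   (expected counts at the niche optimum); defaults log(20) and 2.5, a
#'   wide rare-to-dominant spread under which a minority of phylotypes are
#'   detected in one soil only (putative specialists) and a few not at
#'   all.
#' @param noise_sdlog Multiplicative lognormal observation noise (default
#'   0.7).
#' @param detection_threshold Counts below this are unobserved (default 1).
#' @param qpcr_meanlog,qpcr_sdlog Per-soil lognormal total amoA copies
#'   g^-1; defaults log(1e7) and 0.8.
#' @return List of class `"gradient_scenario"`.
#' @export
gradient_scenario <- function(n_soils = 47, ph_range = c(3.48, 8.74),
                              n_phylotypes = 425,
                              breadth_narrow = 0.35, breadth_broad = 1.5,
                              p_narrow = 0.5,
                              carrying_meanlog = log(20),
                              carrying_sdlog = 2.5,
                              noise_sdlog = 0.7,
                              detection_threshold = 1,
                              qpcr_meanlog = log(1e7), qpcr_sdlog = 0.8) {
  if (breadth_narrow <= 0 || breadth_broad <= 0)
    stop("niche breadths must be > 0", call. = FALSE)
  structure(as.list(environment()), class = "gradient_scenario")
}

#' Generate a phylotype-by-soil abundance matrix along a pH gradient
#'
#' Expected abundance of phylotype j in soil s is
#' `carrying_j * exp(-(pH_s - optimum_j)^2 / (2 * breadth_j^2))`, with
#' multiplicative lognormal noise, thresholded to presence. Niche curves
#' are Gaussian on the pH scale so narrow/broad is interpretable in pH
#' units (set `hplus_scale = TRUE` to place them on the \[H+\] axis
#' instead and probe the index's scale sensitivity).
#'
#' @param scenario A [gradient_scenario()].
#' @param seed Integer seed; the output is a pure function of
#'   (scenario, seed).
#' @param hplus_scale Put Gaussian niches on the hydrogen-ion rather than
#'   the pH axis.
#' @return List with `counts` (absolute [abundance_matrix()]), `meta`
#'   (sample metadata data frame with `sample_id`, `pH`, `qpcr_total`) and
#'   `truth` (per-phylotype data frame: optimum, breadth, component,
#'   carrying abundance).
#' @export
gen_soil_gradient <- function(scenario = gradient_scenario(), seed = 1,
                              hplus_scale = FALSE) {
  stopifnot(inherits(scenario, "gradient_scenario"))
  set.seed(seed)
  sc <- scenario
  ph <- seq(sc$ph_range[1], sc$ph_range[2], length.out = sc$n_soils)
  soils <- sprintf("soil%02d", seq_len(sc$n_soils))
  phylo <- sprintf("p%03d", seq_len(sc$n_phylotypes))
  comp <- ifelse(stats::runif(sc$n_phylotypes) < sc$p_narrow,
                 "narrow", "broad")
  breadth <- ifelse(comp == "narrow", sc$breadth_narrow, sc$breadth_broad)
  optimum <- stats::runif(sc$n_phylotypes, sc$ph_range[1], sc$ph_range[2])
  carrying <- stats::rlnorm(sc$n_phylotypes, sc$carrying_meanlog,
                            sc$carrying_sdlog)
  axis_s <- if (hplus_scale) ph_to_hplus(ph) else ph
  axis_j <- if (hplus_scale) ph_to_hplus(optimum) else optimum
  bj <- if (hplus_scale) breadth * log(10) * ph_to_hplus(optimum) else breadth
  mu <- carrying * exp(-outer(axis_j, axis_s, `-`)^2 / (2 * bj^2))
  noise <- matrix(stats::rlnorm(length(mu), -sc$noise_sdlog^2 / 2,
                                sc$noise_sdlog),
                  nrow = nrow(mu))
  # Poisson count sampling on top of the lognormal environmental noise:
  # rare phylotypes drop out of most soils, as in real amplicon surveys
  counts <- matrix(stats::rpois(length(mu), mu * noise), nrow = nrow(mu))
  counts[counts < sc$detection_threshold] <- 0
  dimnames(counts) <- list(phylo, soils)
  qpcr <- stats::rlnorm(sc$n_soils, sc$qpcr_meanlog, sc$qpcr_sdlog)
  meta <- data.frame(sample_id = soils, pH = ph, qpcr_total = qpcr)
  truth <- data.frame(phylotype_id = phylo, optimum = optimum,
                      breadth = breadth, component = comp,
                      carrying = carrying)
  list(counts = abundance_matrix(counts, "absolute"), meta = meta,
       truth = truth)
}

#' Scenario for a synthetic pH-shift incubation experiment
#'
#' Stated world for the incubation generator: a native pH 6.0 soil either
#' maintained or shifted to pH 4.5 / 7.5, sampled at days 0, 1, 3, 10, 30
#' in 3 replicates. Each phenotype has a condition-dependent exponential
#' growth rate of its active fraction; the dormant fraction is inert.
#' Default growth rates (per day) encode the designed ranking: specialists
#' outgrow generalists after the acid shift (extreme condition), the
#' reverse at native pH 6.0 and after the alkaline shift; putative
#' specialists track specialists at reduced rate.
#'
#' @param timepoints Sampling days (default c(0, 1, 3, 10, 30)).
#' @param replicates Number of replicate microcosms (default 3).
#' @param growth_rates 3 x 3 matrix (rows specialist/generalist/
#'   putative_specialist, columns pH4.5/pH6.0/pH7.5) of per-day rates.
#' @param dormant_fraction Named per-condition inert fraction (defaults:
#'   native 0.4, perturbed 0.6, within the observed 32-67% range).
#' @param noise_sdlog Multiplicative lognormal observation noise on DNA
#'   (RNA uses twice this, matching its higher variability; default 0.3).
#' @param x0_meanlog,x0_sdlog Lognormal initial absolute abundances.
#' @return List of class `"incubation_scenario"`.
#' @export
incubation_scenario <- function(
    timepoints = c(0, 1, 3, 10, 30), replicates = 3,
    growth_rates = matrix(
      c(0.12, 0.02, 0.03,
        -0.02, 0.08, 0.10,
        0.08, 0.01, 0.01),
      nrow = 3, byrow = TRUE,
      dimnames = list(c("specialist", "generalist", "putative_specialist"),
                      c("pH4.5", "pH6.0", "pH7.5"))),
    dormant_fraction = c(pH4.5 = 0.6, pH6.0 = 0.4, pH7.5 = 0.6),
    noise_sdlog = 0.3,
    x0_meanlog = log(5e4), x0_sdlog = 1) {
  if (is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be strictly increasing", call. = FALSE)
  if (any(dormant_fraction < 0 | dormant_fraction > 1))
    stop("dormant fractions must be in [0, 1]", call. = FALSE)
  if (any(!is.finite(growth_rates)))
    stop("growth rates must be finite", call. = FALSE)
  structure(as.list(environment()), class = "incubation_scenario")
}

#' Generate incubation time series (DNA, RNA and SIP analogues)
#'
#' For each condition and replicate: DNA abundance of phylotype i at day t
#' is `d*x0 + (1-d)*x0*exp(r*t)` (dormant part inert, active part growing
#' at the phenotype's condition rate) times lognormal noise; the RNA
#' analogue is proportional to the active biomass with noisier
#' observation; the SIP analogue reports only the end-point abundance of
#' the active subset. Designed truths (active/dormant split, rates) are
#' returned for recovery tests.
#'
#' @param scenario An [incubation_scenario()].
#' @param classes Classification data frame from
#'   [classify_niche_breadth()]; every phylotype must be classified.
#' @param seed Integer seed.
#' @return List of class `"incubation_series"` with elements `dna`, `rna`
#'   (lists indexed by condition then replicate, each a phylotype x day
#'   matrix of absolute copies g^-1), `sip` (condition x replicate list of
#'   end-point active abundances), `conditions`, `timepoints`, and
#'   `truth`.
#' @export
gen_incubation <- function(scenario = incubation_scenario(), classes,
                           seed = 1) {
  stopifnot(inherits(scenario, "incubation_scenario"))
  set.seed(seed)
  sc <- scenario
  conds <- colnames(sc$growth_rates)
  need <- setdiff(conds, names(sc$dormant_fraction))
  if (length(need))
    stop("missing dormant fraction for condition(s): ",
         paste(need, collapse = ", "), call. = FALSE)
  ids <- classes$phylotype_id
  cls <- as.character(classes$nb_class)
  if (anyNA(cls) || !all(cls %in% rownames(sc$growth_rates)))
    stop("every phylotype must be classified", call. = FALSE)
  n <- length(ids)
  x0 <- stats::rlnorm(n, sc$x0_meanlog, sc$x0_sdlog)
  names(x0) <- ids
  days <- sc$timepoints
  noise <- function(sdlog, len)
    if (sdlog == 0) rep(1, len) else
      stats::rlnorm(len, -sdlog^2 / 2, sdlog)
  dna <- rna <- stats::setNames(vector("list", length(conds)), conds)
  sip <- stats::setNames(vector("list", length(conds)), conds)
  for (cn in conds) {
    d <- sc$dormant_fraction[[cn]]
    r <- sc$growth_rates[cls, cn]
    active0 <- (1 - d) * x0
    dna[[cn]] <- rna[[cn]] <- vector("list", sc$replicates)
    sip[[cn]] <- vector("list", sc$replicates)
    for (rep_i in seq_len(sc$replicates)) {
      act <- outer(seq_len(n), seq_along(days),
                   function(i, k) active0[i] * exp(r[i] * days[k]))
      tot <- d * x0 + act
      dmat <- tot * matrix(noise(sc$noise_sdlog, n * length(days)), n)
      rmat <- act * matrix(noise(2 * sc$noise_sdlog, n * length(days)), n)
      dimnames(dmat) <- dimnames(rmat) <- list(ids, days)
      dna[[cn]][[rep_i]] <- dmat
      rna[[cn]][[rep_i]] <- rmat
      sip_v <- act[, length(days)] * noise(sc$noise_sdlog, n)
      names(sip_v) <- ids
      sip[[cn]][[rep_i]] <- sip_v
    }
  }
  structure(list(dna = dna, rna = rna, sip = sip, conditions = conds,
                 timepoints = days,
                 truth = list(x0 = x0, classes = cls,
                              dormant_fraction = sc$dormant_fraction,
                              growth_rates = sc$growth_rates)),
            class = "incubation_series")
}

#' Brownian-motion traits on a tree
#'
#' Simulates a continuous trait from root value 0 with independent normal
#' increments of variance `sigma2 * branch length`, so tip covariances
#' equal `sigma2` times shared branch length.
#'
#' @param tree `phylo` with branch lengths.
#' @param sigma2 BM rate (> 0).
#' @param seed Optional integer seed.
#' @return Named numeric vector over tips.
#' @export
gen_bm_traits <- function(tree, sigma2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (sigma2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree needs branch lengths",
                                      call. = FALSE)
  ntot <- max(tree$edge)
  val <- numeric(ntot)
  ord <- rev(ape::postorder(tree))  # root-to-tip edge order
  for (e in ord) {
    p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
    val[c] <- val[p] + stats::rnorm(1, 0, sqrt(sigma2 *
                                                 tree$edge.length[e]))
  }
  stats::setNames(val[seq_along(tree$tip.label)], tree$tip.label)
}

#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' Crown-conditioned Yule process: starting from two lineages, epochs at
#' richness k last Exp(k * lambda), so the expected root-to-tip depth is
#' `sum_{k=2..n} 1/(lambda k)` (the final epoch at richness n is the
#' waiting time to the unobserved next speciation).
#'
#' @param lambda Speciation rate (> 0).
#' @param n_tips Number of tips (>= 2).
#' @param seed Optional integer seed.
#' @return Ultrametric `phylo`.
#' @export
gen_yule_tree <- function(lambda, n_tips, seed = NULL) {
  if (lambda <= 0 || n_tips < 2) stop("need lambda > 0 and n_tips >= 2",
                                      call. = FALSE)
  spec <- sse_model_spec("CR", 1)
  simulate_sse(c(lambda = lambda, mu = 0, q_ph = 0, q_range = 0),
               spec, n_tips, seed = seed, root_state = "ES")$tree
}
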