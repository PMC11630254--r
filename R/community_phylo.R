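#' Abundance-weighted mean pairwise phylogenetic distance
#'
#' \deqn{mpd = \sum_{i \ne j} w_i w_j d_{ij} / \sum_{i \ne j} w_i w_j}
#' over the taxa present in the community (abundance > 0).
#'
#' @param abund Named abundance vector; names must index `dist`.
#' @param dist Symmetric patristic distance matrix with zero diagonal
#'   (e.g. from `ape::cophenetic.phylo`).
#' @return Scalar mpd in tree-distance units.
#' @export
mpd_weighted <- function(abund, dist) {
  pres <- which(abund > 0)
  if (length(pres) < 2)
    stop("need >= 2 taxa with positive abundance", call. = FALSE)
  w <- abund[pres]
  d <- dist[names(abund)[pres], names(abund)[pres]]
  num <- drop(crossprod(w, d %*% w))       # diagonal of d is zero
  den <- sum(w)^2 - sum(w^2)
  num / den
}

#' Standardized effect size of mpd against richness nulls
#'
#' Compares the observed abundance-weighted mpd of a community with a null
#' distribution built by the "richness" algorithm: each null community
#' draws the same number of taxa uniformly without replacement from the
#' pool (all tree tips) and reassigns the observed abundance values to them
#' in random order. Negative ses means taxa are more closely related than
#' expected by chance (phylogenetic clustering).
#'
#' @param abund Named abundance vector over community taxa (zeros allowed);
#'   taxa absent from the tree are dropped with a warning.
#' @param tree Rooted `phylo` with branch lengths; its tips are the pool.
#' @param n_null Number of null communities (default 999).
#' @param seed Optional integer seed.
#' @param dist Optional precomputed patristic distance matrix over
#'   `tree$tip.label` (saves recomputation across many communities).
#' @return List of class `"ses_mpd"`: `mpd_obs`, `null_mean`, `null_sd`,
#'   `ses`, `p` (two-sided rank p with +1 correction), `n_null`.
#' @export
ses_mpd <- function(abund, tree, n_null = 999, seed = NULL, dist = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dist)) dist <- ape::cophenetic.phylo(tree)
  pool <- tree$tip.label
  drop <- setdiff(names(abund)[abund > 0], pool)
  if (length(drop)) {
    warning("taxa absent from tree dropped: ",
            paste(drop, collapse = ", "), " [code CP01]", call. = FALSE)
    abund <- abund[setdiff(names(abund), drop)]
  }
  comm <- abund[abund > 0]
  k <- length(comm)
  if (k < 2) stop("need >= 2 community taxa on the tree", call. = FALSE)
  if (k > length(pool)) stop("richness exceeds pool size", call. = FALSE)
  obs <- mpd_weighted(comm, dist)
  w <- unname(comm)
  dpool <- dist[pool, pool]
  nulls <- vapply(seq_len(n_null), function(i) {
    idx <- sample.int(length(pool), k)
    wi <- sample(w)
    d <- dpool[idx, idx]
    drop(crossprod(wi, d %*% wi)) / (sum(wi)^2 - sum(wi^2))
  }, numeric(1))
  m <- mean(nulls)
  s <- stats::sd(nulls)
  if (s <= 1e-12 * max(abs(m), 1))
    stop("degenerate null distribution (sd = 0); ses undefined",
         call. = FALSE)
  r <- sum(nulls <= obs) + 1
  p <- min(1, 2 * min(r, n_null + 1 - r) / (n_null + 1))
  structure(list(mpd_obs = obs, null_mean = m, null_sd = s,
                 ses = (obs - m) / s, p = p, n_null = n_null),
            class = "ses_mpd")
}

#' @export
print.ses_mpd <- function(x, ...) {
  cat(sprintf("ses.mpd: obs = %.4g, null = %.4g (sd %.3g), ses = %.3f, p = %.4g (%d nulls)\n",
              x$mpd_obs, x$null_mean, x$null_sd, x$ses, x$p, x$n_null))
  invisible(x)
}

#' ses.mpd for every sample of an abundance matrix
#'
#' @param mat Abundance matrix (phylotypes x samples).
#' @param tree Pool phylogeny.
#' @inheritParams ses_mpd
#' @return Data frame with one row per sample: `sample_id`, `mpd_obs`,
#'   `null_mean`, `null_sd`, `ses`, `p`. Samples with fewer than two taxa
#'   on the tree are skipped with a warning.
#' @export
ses_mpd_table <- function(mat, tree, n_null = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dist <- ape::cophenetic.phylo(tree)
  rows <- lapply(colnames(mat), function(s) {
    ab <- mat[, s]
    names(ab) <- rownames(mat)
    if (sum(names(ab)[ab > 0] %in% tree$tip.label) < 2) {
      warning("sample ", s, " has < 2 taxa on the tree; skipped ",
              "[code CP02]", call. = FALSE)
      return(NULL)
    }
    r <- suppressWarnings(ses_mpd(ab, tree, n_null = n_null, dist = dist))
    data.frame(sample_id = s, mpd_obs = r$mpd_obs, null_mean = r$null_mean,
               null_sd = r$null_sd, ses = r$ses, p = r$p)
  })
  do.call(rbind, rows)
}

#' Blomberg's K with a permutation test
#'
#' K is the observed ratio MSE0/MSE (mean squared trait error from the
#' phylogenetically corrected mean, over the GLS mean squared error under
#' the tree's variance-covariance structure) divided by its expectation
#' under Brownian motion, computed exactly from the tree VCV. K = 1 matches
#' the Brownian expectation; K << 1 indicates less phylogenetic signal than
#' BM. The p-value is the one-sided permutation quantile of the observed
#' MSE0/MSE among `n_perm` random tip-label permutations.
#'
#' @param tree Rooted `phylo` with branch lengths (>= 3 tips; polytomies
#'   allowed).
#' @param trait Named numeric vector over all tips, with positive variance.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return List of class `"phylosignal"`: `K`, `p`, `n_perm`.
#' @export
blomberg_k <- function(tree, trait, n_perm = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  if (n < 3) stop("need >= 3 tips", call. = FALSE)
  if (!all(tree$tip.label %in% names(trait)))
    stop("trait missing for tip(s): ",
         paste(setdiff(tree$tip.label, names(trait)), collapse = ", "),
         call. = FALSE)
  x <- trait[tree$tip.label]
  if (stats::var(x) == 0) stop("trait variance is zero", call. = FALSE)
  C <- ape::vcv.phylo(tree)
  Cinv <- solve(C)
  csum <- sum(Cinv)
  ratio <- function(xs) {
    # xs: matrix n x m of trait column(s)
    ahat <- colSums(Cinv %*% xs) / csum
    r <- sweep(xs, 2, ahat)
    mse0 <- colSums(r^2)
    mse <- colSums((Cinv %*% r) * r)
    mse0 / mse
  }
  obs <- ratio(matrix(x, ncol = 1))
  expect <- (sum(diag(C)) - n / csum) / (n - 1)
  K <- unname(obs / expect)
  perms <- matrix(0, n, n_perm)
  for (i in seq_len(n_perm)) perms[, i] <- sample(x)
  pr <- ratio(perms)
  p <- (sum(pr >= obs) + 1) / (n_perm + 1)
  structure(list(K = K, p = p, n_perm = n_perm), class = "phylosignal")
}

#' @export
print.phylosignal <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.3f, permutation p = %.4g (%d perms)\n",
              x$K, x$p, x$n_perm))
  invisible(x)
}

#' Simple regression of ses.mpd on soil pH
#'
#' Ordinary least-squares glue for relating community phylogenetic
#' relatedness to the pH gradient.
#'
#' @param ses Numeric vector of per-sample ses.mpd values.
#' @param ph Soil pH, same length (>= 3 pairs).
#' @return List with `slope`, `intercept`, `r_squared`, `f_statistic`, `p`,
#'   and the fitted `lm` object in `fit`.
#' @export
ses_mpd_vs_ph <- function(ses, ph) {
  if (length(ses) != length(ph) || length(ses) < 3)
    stop("need >= 3 paired observations", call. = FALSE)
  fit <- stats::lm(ses ~ ph)
  sm <- summary(fit)
  f <- sm$fstatistic
  p <- if (is.null(f)) NA_real_ else
    stats::pf(f[1], f[2], f[3], lower.tail = FALSE)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       f_statistic = unname(f[1]), p = unname(p), fit = fit)
}
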