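# Independent oracles. These deliberately avoid the code paths they check:
# matrix-exponential pruning for the Mk character likelihood, closed-form
# birth-death quantities, and brute-force double loops for mpd.

oracle_states <- c("ES", "CS", "EG", "CG")

# Mk character log-likelihood by expm pruning, with the same
# D-proportional ("obs") root weighting as the engine.
oracle_mk_loglik <- function(tree, states, Q) {
  P <- function(t) as.matrix(Matrix::expm(Q * t))
  m <- nrow(Q)
  ntip <- length(tree$tip.label)
  D <- matrix(NA_real_, m, ntip + tree$Nnode)
  for (i in seq_len(ntip)) {
    v <- rep(0, m)
    v[match(states[tree$tip.label[i]], oracle_states)] <- 1
    D[, i] <- v
  }
  tr <- stats::reorder(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    up <- P(tr$edge.length[e]) %*% D[, ch]
    D[, par] <- if (anyNA(D[, par])) up else D[, par] * up
  }
  root <- tr$edge[nrow(tr$edge), 1]
  d <- D[, root]
  log(sum(d^2) / sum(d))
}

# Closed-form single-state birth-death quantities (rho = 1)
oracle_bd_E <- function(lam, mu, t)
  mu * (1 - exp(-(lam - mu) * t)) / (lam - mu * exp(-(lam - mu) * t))

# D(t)/D(0) growth factor along a branch from the present
oracle_bd_h <- function(lam, mu, t)
  exp(-(lam - mu) * t) * (lam - mu)^2 / (lam - mu * exp(-(lam - mu) * t))^2

# Constant-rate birth-death tree log-likelihood matching the engine's
# conventions (node lambda factors, survival conditioning at the root).
oracle_bd_loglik <- function(tree, lam, mu) {
  dep <- ape::node.depth.edgelength(tree)
  H <- max(dep)
  height <- H - dep
  n <- length(tree$tip.label)
  ll <- 0
  for (e in seq_len(nrow(tree$edge)))
    ll <- ll + log(oracle_bd_h(lam, mu, height[tree$edge[e, 1]]) /
                     oracle_bd_h(lam, mu, height[tree$edge[e, 2]]))
  ll + (n - 1) * log(lam) - log(lam * (1 - oracle_bd_E(lam, mu, H))^2)
}

# Brute-force abundance-weighted mpd by explicit double loop
oracle_mpd <- function(abund, dist) {
  taxa <- names(abund)[abund > 0]
  num <- 0; den <- 0
  for (i in taxa) for (j in taxa) if (i != j) {
    num <- num + abund[i] * abund[j] * dist[i, j]
    den <- den + abund[i] * abund[j]
  }
  unname(num / den)
}

# Exhaustive richness-null ses for an equal-abundance community of size k
# (abundance assignment is then irrelevant, so subsets enumerate the null).
oracle_ses_exhaustive <- function(obs_taxa, dist, pool) {
  k <- length(obs_taxa)
  subs <- utils::combn(pool, k)
  vals <- apply(subs, 2, function(tx) {
    d <- dist[tx, tx]
    sum(d) / (k * (k - 1))
  })
  obs <- sum(dist[obs_taxa, obs_taxa]) / (k * (k - 1))
  list(ses = (obs - mean(vals)) / stats::sd(vals),
       null_mean = mean(vals), null_sd = stats::sd(vals), obs = obs)
}
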