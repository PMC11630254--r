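#' @useDynLib phniche, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Joint states: pH niche (Specialist/Generalist) x range (Endemic/
# Cosmopolitan). Order is fixed throughout the package.
.sse_states <- c("ES", "CS", "EG", "CG")
.sse_ph <- c(ES = "S", CS = "S", EG = "G", CG = "G")
.sse_range <- c(ES = "E", CS = "C", EG = "E", CG = "C")

#' Joint four-state classification of a phylotype
#'
#' Combines the pH niche-breadth class with the endemic/cosmopolitan range
#' class into one of ES (endemic specialist), CS (cosmopolitan specialist),
#' EG (endemic generalist), CG (cosmopolitan generalist). Putative
#' specialists (single-soil phylotypes) are treated as pH specialists.
#'
#' @param nb_class Character/factor in \{specialist, generalist,
#'   putative_specialist\}.
#' @param range_cls Character/factor in \{endemic, cosmopolitan\}.
#' @return Factor over ES, CS, EG, CG.
#' @export
classify_joint_state <- function(nb_class, range_cls) {
  nb <- as.character(nb_class)
  rg <- as.character(range_cls)
  if (!all(nb %in% c("specialist", "generalist", "putative_specialist")))
    stop("unknown niche-breadth class", call. = FALSE)
  if (!all(rg %in% c("endemic", "cosmopolitan")))
    stop("unknown range class", call. = FALSE)
  ph <- ifelse(nb == "generalist", "G", "S")  # putative -> specialist
  st <- ifelse(rg == "endemic",
               ifelse(ph == "S", "ES", "EG"),
               ifelse(ph == "S", "CS", "CG"))
  factor(st, levels = .sse_states)
}

#' Transition-rate structure of the four-state system
#'
#' Encodes which transitions among ES, CS, EG, CG are allowed and which
#' rates are shared, as an integer-indexed 4 x 4 matrix (0 = forbidden;
#' equal indices = shared parameter). Single moves change either the pH
#' niche state (S <-> G) or the range state (E <-> C); "dual" moves change
#' both at once (ES <-> CG and CS <-> EG).
#'
#' The six structures: M1 one symmetric pH rate + one symmetric range rate,
#' no dual moves; M2 = M1 plus dual moves; M3 asymmetric pH rates,
#' symmetric range, no dual; M4 symmetric pH, asymmetric range, no dual;
#' M5 both asymmetric, no dual; M6 both asymmetric plus dual moves.
#'
#' @param structure_id Integer 1..6.
#' @param dual_rate_shared If `TRUE` (default), dual moves (where allowed)
#'   share one rate; if `FALSE` they split by pH direction
#'   (specialist->generalist vs the reverse).
#' @return Integer matrix with `q_names` attribute naming the parameters.
#' @export
build_structure <- function(structure_id, dual_rate_shared = TRUE) {
  if (!structure_id %in% 1:6) stop("structure_id must be 1..6",
                                   call. = FALSE)
  q <- matrix(0L, 4, 4, dimnames = list(.sse_states, .sse_states))
  set <- function(from, to, id) q[from, to] <<- as.integer(id)
  # pH niche moves
  ph_moves <- list(SG = list(c("ES", "EG"), c("CS", "CG")),
                   GS = list(c("EG", "ES"), c("CG", "CS")))
  range_moves <- list(EC = list(c("ES", "CS"), c("EG", "CG")),
                      CE = list(c("CS", "ES"), c("CG", "EG")))
  dual_moves <- list(SG = list(c("ES", "CG"), c("CS", "EG")),
                     GS = list(c("CG", "ES"), c("EG", "CS")))
  apply_moves <- function(moves, id)
    for (mv in moves) set(mv[1], mv[2], id)
  nm <- character(0)
  add <- function(name) { nm <<- c(nm, name); length(nm) }
  if (structure_id %in% c(1, 2)) {
    i <- add("q_ph")
    apply_moves(c(ph_moves$SG, ph_moves$GS), i)
    i <- add("q_range")
    apply_moves(c(range_moves$EC, range_moves$CE), i)
  } else if (structure_id == 3) {
    apply_moves(ph_moves$SG, add("q_SG"))
    apply_moves(ph_moves$GS, add("q_GS"))
    i <- add("q_range")
    apply_moves(c(range_moves$EC, range_moves$CE), i)
  } else if (structure_id == 4) {
    i <- add("q_ph")
    apply_moves(c(ph_moves$SG, ph_moves$GS), i)
    apply_moves(range_moves$EC, add("q_EC"))
    apply_moves(range_moves$CE, add("q_CE"))
  } else {
    apply_moves(ph_moves$SG, add("q_SG"))
    apply_moves(ph_moves$GS, add("q_GS"))
    apply_moves(range_moves$EC, add("q_EC"))
    apply_moves(range_moves$CE, add("q_CE"))
  }
  if (structure_id %in% c(2, 6)) {
    if (dual_rate_shared) {
      i <- add("q_dual")
      apply_moves(c(dual_moves$SG, dual_moves$GS), i)
    } else {
      apply_moves(dual_moves$SG, add("q_dual_SG"))
      apply_moves(dual_moves$GS, add("q_dual_GS"))
    }
  }
  attr(q, "q_names") <- nm
  q
}

#' Construct one SSE model specification
#'
#' Three diversification modes over any of the six transition structures:
#' `"ETD"` (examined-trait-dependent: per-state speciation and extinction,
#' 4 lambda + 4 mu), `"CTD"` (concealed-trait-dependent: two hidden rate
#' classes A/B; lambda and mu depend only on the hidden state, examined
#' transitions are mirrored across the two hidden layers and one shared
#' rate switches the hidden state), and `"CR"` (constant rate: one lambda,
#' one mu).
#'
#' @param mode One of `"ETD"`, `"CTD"`, `"CR"`.
#' @param structure_id Transition structure 1..6 (see [build_structure()]).
#' @param dual_rate_shared Passed to [build_structure()].
#' @param rho Sampling fraction per examined state, recycled to 4
#'   (default 1).
#' @return Object of class `"sse_model_spec"` with fields `mode`,
#'   `structure_id`, `n_hidden`, `m` (number of joint states),
#'   `lambda_ids`, `mu_ids`, `q_ids`, `param_names`, `k`, `rho`,
#'   `state_names`.
#' @export
sse_model_spec <- function(mode = c("ETD", "CTD", "CR"), structure_id = 1,
                           dual_rate_shared = TRUE, rho = 1) {
  mode <- match.arg(mode)
  qs <- build_structure(structure_id, dual_rate_shared)
  q_names <- attr(qs, "q_names")
  n_hidden <- if (mode == "CTD") 2L else 1L
  m <- 4L * n_hidden
  state_names <- if (n_hidden == 1) .sse_states else
    c(paste0(.sse_states, "_A"), paste0(.sse_states, "_B"))
  rho <- rep_len(rho, 4)
  if (any(rho <= 0) || any(rho > 1))
    stop("sampling fractions must be in (0, 1]", call. = FALSE)

  if (mode == "ETD") {
    lam_names <- paste0("lambda_", .sse_states)
    mu_names <- paste0("mu_", .sse_states)
    lambda_ids <- 1:4
    mu_ids <- 5:8
    off <- 8L
  } else if (mode == "CR") {
    lam_names <- "lambda"; mu_names <- "mu"
    lambda_ids <- rep(1L, 4)
    mu_ids <- rep(2L, 4)
    off <- 2L
  } else {
    lam_names <- c("lambda_A", "lambda_B")
    mu_names <- c("mu_A", "mu_B")
    lambda_ids <- c(rep(1L, 4), rep(2L, 4))
    mu_ids <- c(rep(3L, 4), rep(4L, 4))
    off <- 4L
  }
  q_ids <- matrix(0L, m, m, dimnames = list(state_names, state_names))
  blk <- qs
  blk[blk > 0] <- blk[blk > 0] + off
  q_ids[1:4, 1:4] <- blk
  param_names <- c(lam_names, mu_names, q_names)
  if (mode == "CTD") {
    q_ids[5:8, 5:8] <- blk
    hid <- off + length(q_names) + 1L
    for (e in 1:4) {
      q_ids[e, e + 4] <- hid
      q_ids[e + 4, e] <- hid
    }
    param_names <- c(param_names, "q_hidden")
  }
  structure(list(mode = mode, structure_id = structure_id,
                 n_hidden = n_hidden, m = m,
                 lambda_ids = lambda_ids, mu_ids = mu_ids, q_ids = q_ids,
                 param_names = param_names, k = length(param_names),
                 rho = rho, state_names = state_names,
                 dual_rate_shared = dual_rate_shared),
            class = "sse_model_spec")
}

#' @export
print.sse_model_spec <- function(x, ...) {
  cat(sprintf("SSE model %s-M%d: %d joint states, %d free parameters\n",
              x$mode, x$structure_id, x$m, x$k))
  cat("  parameters:", paste(x$param_names, collapse = ", "), "\n")
  invisible(x)
}

#' The full 18-model set
#'
#' All combinations of the six transition structures with the three
#' diversification modes (ETD, CTD, CR). Free-parameter counts: ETD =
#' 8 + n_q, CTD = 5 + n_q, CR = 2 + n_q, with n_q = 2 (M1), 3 (M2 shared
#' dual, M3, M4), 4 (M5), 5 (M6 shared dual).
#'
#' @inheritParams sse_model_spec
#' @return Named list of 18 `sse_model_spec` objects
#'   (`ETD_M1` .. `CR_M6`).
#' @export
model_set <- function(dual_rate_shared = TRUE, rho = 1) {
  out <- list()
  for (mode in c("ETD", "CTD", "CR"))
    for (s in 1:6)
      out[[paste0(mode, "_M", s)]] <-
        sse_model_spec(mode, s, dual_rate_shared, rho)
  out
}

# Expand a parameter vector into per-joint-state lambda, mu and Q.
.sse_rates <- function(spec, params) {
  lambda <- params[spec$lambda_ids]
  mu <- params[spec$mu_ids]
  Q <- matrix(0, spec$m, spec$m,
              dimnames = dimnames(spec$q_ids))
  nz <- spec$q_ids > 0
  Q[nz] <- params[spec$q_ids[nz]]
  list(lambda = unname(lambda), mu = unname(mu), Q = Q)
}

# Tip initial conditions. states: named character vector tip -> examined
# state, comma-joined ambiguity sets, or NA (fully ambiguous).
.sse_tipD <- function(tree, states, spec) {
  tips <- tree$tip.label
  if (!all(tips %in% names(states)))
    stop("state missing for tip(s): ",
         paste(setdiff(tips, names(states)), collapse = ", "),
         call. = FALSE)
  st <- as.character(states[tips])
  m <- spec$m
  rho_joint <- rep(spec$rho, spec$n_hidden)
  examined <- rep(.sse_states, spec$n_hidden)
  D <- matrix(0, m, length(tips))
  for (i in seq_along(tips)) {
    if (is.na(st[i])) {
      set <- .sse_states
    } else {
      set <- strsplit(st[i], ",", fixed = TRUE)[[1]]
      if (!all(set %in% .sse_states))
        stop("unknown state '", st[i], "' for tip ", tips[i],
             call. = FALSE)
    }
    D[examined %in% set, i] <- rho_joint[examined %in% set]
  }
  list(D = D, E0 = 1 - rho_joint)
}

.check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object",
                                     call. = FALSE)
  if (!ape::is.binary(tree))
    stop("tree must be fully bifurcating (polytomies rejected)",
         call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree must have branch lengths", call. = FALSE)
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  spread <- diff(range(depths)) / max(depths)
  if (spread > 1e-6)
    warning("tree is not ultrametric (relative tip-depth spread ",
            signif(spread, 3), ") [code DV01]", call. = FALSE)
  invisible(TRUE)
}

#' SSE log-likelihood of a labeled phylogeny
#'
#' Pruning likelihood of the state-dependent speciation-extinction model:
#' tips are initialized with `D = rho` for compatible joint states (all
#' hidden layers of the observed examined state) and `E = 1 - rho`; E and D
#' are integrated numerically along each branch, daughter D vectors are
#' multiplied together with the state's speciation rate at each node, and
#' the root is treated with weights proportional to D (FitzJohn) and, by
#' default, conditioning on the survival of both crown lineages. D is
#' rescaled per branch with a log accumulator to avoid underflow.
#'
#' When every speciation rate is zero the engine drops the node speciation
#' factors and the survival conditioning, giving the plain continuous-time
#' Markov (Mk) character likelihood.
#'
#' @param tree Rooted, bifurcating, ultrametric `phylo`.
#' @param states Named vector tip -> examined state (`"ES"`, `"CS"`,
#'   `"EG"`, `"CG"`), comma-joined ambiguity sets, or `NA` for unknown.
#' @param spec An [sse_model_spec()].
#' @param params Nonnegative parameter vector of length `spec$k`.
#' @param root_weighting `"obs"` (weights proportional to D) or `"flat"`.
#' @param condition_surv Condition on survival of both crown lineages
#'   (default `TRUE`).
#' @param atol,rtol Absolute/relative ODE tolerances.
#' @param store Keep per-node/per-branch vectors (needed by
#'   [ancestral_states()]).
#' @return Log-likelihood in nats (`-Inf` for numerically infeasible
#'   parameters), with the stored vectors as attributes when
#'   `store = TRUE`.
#' @export
sse_loglik <- function(tree, states, spec, params,
                       root_weighting = c("obs", "flat"),
                       condition_surv = TRUE, atol = 1e-12, rtol = 1e-9,
                       store = FALSE) {
  root_weighting <- match.arg(root_weighting)
  .check_tree(tree)
  if (length(params) != spec$k)
    stop("expected ", spec$k, " parameters", call. = FALSE)
  if (any(params < 0) || any(!is.finite(params)))
    stop("parameters must be finite and >= 0", call. = FALSE)
  rates <- .sse_rates(spec, params)
  tip <- .sse_tipD(tree, states, spec)
  tr <- stats::reorder(tree, "postorder")
  res <- sse_loglik_cpp(tr$edge, tr$edge.length, length(tree$tip.label),
                        tip$D, tip$E0, rates$lambda, rates$mu, rates$Q,
                        if (root_weighting == "obs") 0L else 1L,
                        condition_surv, all(rates$lambda == 0),
                        atol, rtol, store)
  ll <- res$loglik
  if (store) {
    attr(ll, "vectors") <- res
    attr(ll, "edge") <- tr$edge
    attr(ll, "edge_length") <- tr$edge.length
  }
  ll
}

# Latin hypercube sample of n points in k dimensions on (0,1).
.lhs <- function(n, k) {
  matrix(vapply(seq_len(k),
                function(j) (sample.int(n) - stats::runif(n)) / n,
                numeric(n)),
         nrow = n, ncol = k)
}

# Heuristic central start: Yule-style lambda from tip count and total tree
# length, mu and q scaled from it.
.start_heuristic <- function(tree, spec) {
  n <- length(tree$tip.label)
  L <- sum(tree$edge.length)
  lam0 <- max((n - 2) / L, 1e-4)
  vals <- numeric(spec$k)
  names(vals) <- spec$param_names
  vals[grepl("^lambda", spec$param_names)] <- lam0
  vals[grepl("^mu", spec$param_names)] <- lam0 / 10
  vals[grepl("^q", spec$param_names)] <- lam0 / 5
  vals
}

#' Fit an SSE model by multi-start maximum likelihood
#'
#' Maximizes the likelihood over log-transformed parameters within
#' `[1e-8, 1e3]`, from `n_starts` starting points: one heuristic central
#' start (Yule-scaled) and the rest dispersed by a seeded Latin hypercube
#' over a log-box two orders of magnitude around it, to avoid local optima.
#'
#' @inheritParams sse_loglik
#' @param n_starts Number of optimizations (default 3).
#' @param seed Optional integer seed for the dispersed starts.
#' @param maxit Iteration cap per start.
#' @param ... Passed to [sse_loglik()] (e.g. `condition_surv`).
#' @return Object of class `"sse_fit"`: `spec`, `par` (named), `loglik`,
#'   `k`, `AIC`, `converged`, `starts` (per-start trace data frame), plus
#'   the tree/states needed for ancestral reconstruction.
#' @export
fit_model <- function(tree, states, spec, n_starts = 3, seed = NULL,
                      maxit = 2000, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  if (spec$k > n / 5)
    warning("model has ", spec$k, " free parameters for only ", n,
            " tips; estimates may be unidentifiable [code DV02]",
            call. = FALSE)
  lb <- log(1e-8); ub <- log(1e3)
  negll <- function(lp) {
    if (any(lp < lb) || any(lp > ub)) return(1e10)
    ll <- sse_loglik(tree, states, spec, exp(lp), ...)
    if (!is.finite(ll)) 1e10 else -ll
  }
  p0 <- .start_heuristic(tree, spec)
  starts <- matrix(log(p0), nrow = 1)
  if (n_starts > 1) {
    u <- .lhs(n_starts - 1, spec$k)
    disp <- sweep((u - 0.5) * 2 * log(100), 2, log(p0), `+`)
    starts <- rbind(starts, disp)
  }
  starts <- pmin(pmax(starts, lb), ub)
  best <- NULL
  trace <- data.frame(start = integer(0), loglik = numeric(0),
                      convergence = integer(0))
  for (s in seq_len(nrow(starts))) {
    opt <- try(stats::optim(starts[s, ], negll, method = "Nelder-Mead",
                            control = list(maxit = maxit,
                                           reltol = 1e-8)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    trace <- rbind(trace, data.frame(start = s, loglik = -opt$value,
                                     convergence = opt$convergence))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || best$value >= 1e10)
    stop("all optimization starts failed; traces:\n",
         paste(utils::capture.output(print(trace)), collapse = "\n"),
         call. = FALSE)
  par <- exp(best$par)
  names(par) <- spec$param_names
  ll <- -best$value
  hash <- paste(c(n, round(sum(tree$edge.length), 10),
                  as.character(states[sort(names(states))])),
                collapse = "|")
  structure(list(spec = spec, par = par, loglik = ll, k = spec$k,
                 AIC = 2 * spec$k - 2 * ll,
                 n_starts = n_starts, converged = best$convergence == 0,
                 starts = trace, data_hash = hash,
                 tree = tree, states = states,
                 loglik_args = list(...)),
            class = "sse_fit")
}

#' @export
print.sse_fit <- function(x, ...) {
  cat(sprintf("SSE fit %s-M%d: loglik = %.3f, k = %d, AIC = %.2f%s\n",
              x$spec$mode, x$spec$structure_id, x$loglik, x$k, x$AIC,
              if (x$converged) "" else " (not converged)"))
  print(signif(x$par, 4))
  invisible(x)
}

#' Rank fitted SSE models by AIC
#'
#' @param fits List of `sse_fit` objects fitted to the same tree and
#'   states (checked).
#' @return Data frame sorted by AIC (ties broken toward fewer parameters)
#'   with columns `model`, `mode`, `structure`, `k`, `loglik`, `AIC`,
#'   `delta_AIC`; the best fit is in the `"best"` attribute.
#' @export
compare_aic <- function(fits) {
  if (length(fits) < 2) stop("need >= 2 fits", call. = FALSE)
  hashes <- vapply(fits, `[[`, character(1), "data_hash")
  if (length(unique(hashes)) != 1)
    stop("fits were made on different data", call. = FALSE)
  nm <- names(fits)
  if (is.null(nm))
    nm <- vapply(fits, function(f)
      paste0(f$spec$mode, "_M", f$spec$structure_id), character(1))
  tab <- data.frame(
    model = nm,
    mode = vapply(fits, function(f) f$spec$mode, character(1)),
    structure = vapply(fits, function(f) f$spec$structure_id, numeric(1)),
    k = vapply(fits, `[[`, numeric(1), "k"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"))
  ord <- order(tab$AIC, tab$k)
  tab <- tab[ord, ]
  tab$delta_AIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  attr(tab, "best") <- fits[[ord[1]]]
  tab
}

#' Specialist/generalist transition-rate asymmetry of a fit
#'
#' Ratio of the fitted generalist-to-specialist pH transition rate to the
#' reverse rate. Structures with a single symmetric pH rate return 1.
#'
#' @param fit An `sse_fit`.
#' @return List with `ratio`, `q_GS`, `q_SG`.
#' @export
transition_asymmetry <- function(fit) {
  p <- fit$par
  if ("q_ph" %in% names(p))
    return(list(ratio = 1, q_GS = unname(p["q_ph"]),
                q_SG = unname(p["q_ph"])))
  list(ratio = unname(p["q_GS"] / p["q_SG"]),
       q_GS = unname(p["q_GS"]), q_SG = unname(p["q_SG"]))
}

#' Marginal ancestral state probabilities
#'
#' For each internal node, the marginal probability of each examined state:
#' the subtree partial likelihoods at the node are restricted to one
#' examined state (all hidden layers kept), re-propagated to the root along
#' the stored path (recombining with the stored sibling vectors and node
#' speciation factors), and the resulting root likelihoods (flat root
#' weights) are normalized. Hidden states are marginalized.
#'
#' @param fit A converged `sse_fit`.
#' @return Matrix (internal nodes x 4 examined states) of probabilities,
#'   rows summing to 1; rownames are ape node numbers.
#' @export
ancestral_states <- function(fit) {
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  spec <- fit$spec
  tree <- fit$tree
  args <- c(list(tree = tree, states = fit$states, spec = spec,
                 params = fit$par, store = TRUE), fit$loglik_args)
  ll <- do.call(sse_loglik, args)
  if (!is.finite(ll)) stop("non-finite likelihood at the optimum",
                           call. = FALSE)
  v <- attr(ll, "vectors")
  edge <- attr(ll, "edge")
  elen <- attr(ll, "edge_length")
  rates <- .sse_rates(spec, fit$par)
  char_only <- all(rates$lambda == 0)
  cond <- !char_only && !identical(fit$loglik_args$condition_surv, FALSE)
  m <- spec$m
  ntip <- length(tree$tip.label)
  root <- edge[nrow(edge), 1]
  child_edge <- integer(max(edge))
  child_edge[edge[, 2]] <- seq_len(nrow(edge))
  examined <- rep(.sse_states, spec$n_hidden)

  # returns log of the flat-weight root likelihood of the masked vector;
  # branch rescalings are tracked so masks remain comparable across states
  climb <- function(node, D) {
    logs <- 0
    while (node != root) {
      e <- child_edge[node]
      par <- edge[e, 1]
      sol <- sse_branch_solve_cpp(v$node_E[, node], D, rates$lambda,
                                  rates$mu, rates$Q, elen[e],
                                  1e-12, 1e-9)
      if (!sol$ok) return(-Inf)
      sibs <- setdiff(which(edge[, 1] == par), e)
      D <- sol$D
      for (se in sibs) D <- D * v$top_D[, se]
      if (par != root) {
        if (!char_only) D <- D * rates$lambda
      } else if (cond) {
        surv <- (1 - v$node_E[, root])^2
        D <- ifelse(surv > 1e-150, D / surv, 0)
      } else if (!char_only) {
        D <- D * rates$lambda
      }
      s <- sum(D)
      if (!is.finite(s) || s <= 0) return(-Inf)
      D <- D / s
      logs <- logs + log(s)
      node <- par
    }
    logs
  }

  internal <- (ntip + 1):(ntip + tree$Nnode)
  out <- matrix(NA_real_, length(internal), 4,
                dimnames = list(internal, .sse_states))
  for (node in internal) {
    logL <- rep(-Inf, 4)
    for (s in seq_along(.sse_states)) {
      Dmask <- v$node_D[, node]
      Dmask[examined != .sse_states[s]] <- 0
      if (all(Dmask == 0)) next
      logL[s] <- if (node == root) log(sum(Dmask)) else climb(node, Dmask)
    }
    L <- exp(logL - max(logL))   # flat root weights
    out[as.character(node), ] <- L / sum(L)
  }
  out
}

#' Simulate a phylogeny under a four-state SSE model
#'
#' Forward Gillespie birth-death simulation starting from two crown
#' lineages: each lineage speciates, goes extinct, or changes state at its
#' state's rates. The simulation stops at the moment the target number of
#' extant lineages is first reached plus one further waiting time drawn at
#' that richness (so the final epoch has the correct exponential length),
#' extinct lineages are pruned, and the surviving ultrametric tree and its
#' tip states are returned.
#'
#' @param params Parameter vector for `spec` (length `spec$k`).
#' @param spec An [sse_model_spec()].
#' @param n_tips Target number of surviving tips.
#' @param seed Optional integer seed.
#' @param root_state Joint state name to start from; default samples the
#'   stationary distribution of the transition matrix.
#' @param max_tries Retries when the clade dies before reaching `n_tips`.
#' @return List with `tree` (ultrametric `phylo`), `states` (named
#'   examined-state vector over tips), `joint_states`, and `root_state`.
#' @export
simulate_sse <- function(params, spec, n_tips, seed = NULL,
                         root_state = NULL, max_tries = 100) {
  if (!is.null(seed)) set.seed(seed)
  rates <- .sse_rates(spec, params)
  if (all(rates$lambda <= 0)) stop("need a positive speciation rate",
                                   call. = FALSE)
  m <- spec$m
  qrow <- rowSums(rates$Q)
  total_rate <- rates$lambda + rates$mu + qrow
  if (is.null(root_state)) {
    # stationary distribution of the transition CTMC (uniform fallback)
    G <- rates$Q - diag(qrow)
    A <- rbind(t(G), rep(1, m))
    pi <- try(qr.solve(A, c(rep(0, m), 1)), silent = TRUE)
    if (inherits(pi, "try-error") || any(!is.finite(pi)) || any(pi < -1e-8))
      pi <- rep(1 / m, m)
    pi <- pmax(pi, 0); pi <- pi / sum(pi)
  }
  for (try_i in seq_len(max_tries)) {
    rs <- if (is.null(root_state))
      sample.int(m, 1, prob = pi) else match(root_state, spec$state_names)
    if (is.na(rs)) stop("unknown root_state", call. = FALSE)
    nmax <- 4 * n_tips + 64
    parent <- integer(nmax); state <- integer(nmax)
    t_birth <- numeric(nmax); t_end <- rep(NA_real_, nmax)
    ended_by <- character(nmax)
    parent[1:2] <- 0L; state[1:2] <- rs; t_birth[1:2] <- 0
    nrec <- 2L
    alive <- c(1L, 2L)
    t <- 0
    ok <- FALSE
    for (ev in seq_len(1e6)) {
      rate_tot <- sum(total_rate[state[alive]])
      if (rate_tot <= 0) break
      dt <- stats::rexp(1, rate_tot)
      if (length(alive) == n_tips) {
        # stop just before the next event at target richness
        t <- t + dt
        ok <- TRUE
        break
      }
      t <- t + dt
      lin <- alive[sample.int(length(alive), 1,
                              prob = total_rate[state[alive]])]
      s <- state[lin]
      u <- stats::runif(1) * total_rate[s]
      if (u < rates$lambda[s]) {
        if (nrec + 2L > nmax) {
          nmax <- nmax * 2L
          length(parent) <- nmax; length(state) <- nmax
          length(t_birth) <- nmax
          t_end <- c(t_end, rep(NA_real_, nmax - length(t_end)))
          length(ended_by) <- nmax
        }
        t_end[lin] <- t; ended_by[lin] <- "spec"
        kids <- nrec + 1:2
        parent[kids] <- lin; state[kids] <- s; t_birth[kids] <- t
        nrec <- nrec + 2L
        alive <- c(setdiff(alive, lin), kids)
      } else if (u < rates$lambda[s] + rates$mu[s]) {
        t_end[lin] <- t; ended_by[lin] <- "ext"
        alive <- setdiff(alive, lin)
        if (length(alive) == 0) break
      } else {
        qcum <- cumsum(rates$Q[s, ])
        state[lin] <- findInterval(u - rates$lambda[s] - rates$mu[s],
                                   qcum, left.open = TRUE) + 1L
      }
    }
    if (!ok) next
    t_end[alive] <- t
    ended_by[alive] <- "tip"
    labels <- paste0("t", seq_len(nrec))
    children <- split(seq_len(nrec), factor(parent[seq_len(nrec)],
                                            levels = 0:nrec))
    nwk <- function(lin) {
      len <- t_end[lin] - t_birth[lin]
      kids <- children[[as.character(lin)]]
      if (is.null(kids) || length(kids) == 0)
        sprintf("%s:%.10g", labels[lin], len)
      else
        sprintf("(%s,%s):%.10g", nwk(kids[1]), nwk(kids[2]), len)
    }
    root_kids <- children[["0"]]
    txt <- sprintf("(%s,%s);", nwk(root_kids[1]), nwk(root_kids[2]))
    tree <- ape::read.tree(text = txt)
    extinct <- labels[seq_len(nrec)][ended_by[seq_len(nrec)] == "ext"]
    if (length(extinct))
      tree <- ape::drop.tip(tree, extinct)
    if (is.null(tree) || length(tree$tip.label) != n_tips) next
    joint <- spec$state_names[state[match(tree$tip.label, labels)]]
    names(joint) <- tree$tip.label
    exam <- substr(joint, 1, 2)
    names(exam) <- tree$tip.label
    return(list(tree = tree, states = exam, joint_states = joint,
                root_state = spec$state_names[rs]))
  }
  stop("clade went extinct before reaching ", n_tips, " tips in ",
       max_tries, " tries", call. = FALSE)
}
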