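# Independent brute-force oracles used to verify the LP/QP algorithms.
# These deliberately avoid the code paths they check: FVA enumeration uses
# plain per-reaction LPs, the minimal-superset search enumerates subsets,
# the QP oracle enumerates active sets with SVD pseudo-inverses, and the
# statistics oracles implement the textbook definitions directly.

# blocked set by exhaustive per-reaction min/max LPs
blocked_brute <- function(model, epsilon = 1e-4) {
  rng <- fva(model, objective_fraction = 0)
  rng$reaction_id[pmax(abs(rng$min), abs(rng$max)) < epsilon]
}

# is every reaction of the submodel able to carry |flux| >= epsilon?
submodel_consistent <- function(model, rxns, epsilon = 1e-4) {
  if (length(rxns) == 0) return(TRUE)
  sm <- submodel(model, rxns)
  length(blocked_brute(sm, epsilon)) == 0
}

# exact minimum size of a flux-consistent subnetwork containing the core
min_consistent_superset <- function(model, core, epsilon = 1e-4) {
  noncore <- setdiff(model$reaction_ids, core)
  for (k in 0:length(noncore)) {
    combos <- utils::combn(length(noncore), k, simplify = FALSE)
    for (cmb in combos) {
      cand <- c(core, noncore[cmb])
      if (submodel_consistent(model, cand, epsilon)) return(length(cand))
    }
  }
  Inf
}

# dense active-set enumeration for min ||Gv - y||^2 s.t. Sv = 0, lb<=v<=ub.
# Every variable is free, at its lower, or at its upper bound; the restricted
# equality-constrained least squares is solved by pseudo-inverse and the best
# feasible candidate wins.
qp_brute <- function(G, y, S, lb, ub) {
  n <- ncol(S)
  best <- Inf
  states <- expand.grid(rep(list(0:2), n))
  pinv <- function(M) {
    sv <- svd(M)
    pos <- sv$d > max(dim(M)) * max(sv$d, 0) * 1e-12
    if (!any(pos)) return(matrix(0, ncol(M), nrow(M)))
    sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  }
  for (r in seq_len(nrow(states))) {
    st <- as.integer(states[r, ])
    fixed <- which(st != 0)
    vals <- ifelse(st == 1, lb, ub)[fixed]
    C <- rbind(S, diag(n)[fixed, , drop = FALSE])
    c0 <- c(rep(0, nrow(S)), vals)
    v0 <- as.vector(pinv(C) %*% c0)
    if (max(abs(C %*% v0 - c0)) > 1e-7) next     # inconsistent active set
    qrC <- qr(t(C))
    rk <- qrC$rank
    v <- if (rk >= n) v0 else {
      Z <- qr.Q(qrC, complete = TRUE)[, (rk + 1):n, drop = FALSE]
      w <- as.vector(pinv(G %*% Z) %*% (y - G %*% v0))
      v0 + as.vector(Z %*% w)
    }
    if (any(v < lb - 1e-7) || any(v > ub + 1e-7)) next
    obj <- sum((y - as.vector(G %*% v))^2)
    if (obj < best) best <- obj
  }
  best
}

# textbook Benjamini-Hochberg step-up
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# hypergeometric tail by explicit log-combinatorics summation
hyper_tail_brute <- function(k, n, K, N, tail = "right") {
  term <- function(x) exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n))
  xs <- if (tail == "right") k:min(n, K) else 0:k
  sum(vapply(xs, term, numeric(1)))
}

# GPR truth-table evaluation by direct recursion on the rule text
gpr_eval_brute <- function(rule, present) {
  if (!nzchar(trimws(rule))) return(TRUE)
  expr <- gsub("\\bor\\b", "||", gsub("\\band\\b", "&&", tolower(rule)))
  genes <- gpr_genes(parse_gpr(rule))
  env <- new.env()
  for (g in genes) assign(tolower(g), tolower(g) %in% tolower(present), env)
  eval(parse(text = expr), env)
}

# shared small fixtures -------------------------------------------------------

# chain with a parallel futile cycle: pFBA must zero the cycle
futile_cycle_model <- function() {
  S <- rbind(A = c(-1, -1, 0, 1, -1),
             B = c(0, 1, -1, 0, 0),
             C = c(0, 0, 0, -1, 1))
  colnames(S) <- c("EX_a", "T1", "BIOMASS", "C1", "C2")
  metabolic_model(S, lb = c(-10, 0, 0, 0, 0), ub = rep(1000, 5),
                  objective_id = "BIOMASS", id = "futile")
}

# two routes from A to B: cheap (non-penalized) and expensive (penalized)
two_path_model <- function() {
  S <- rbind(A = c(-1, -1, -1, 0),
             B = c(0, 1, 1, -1))
  colnames(S) <- c("EX_a", "P1", "P2", "BIOMASS")
  metabolic_model(S, lb = c(-10, 0, 0, 0), ub = rep(1000, 4),
                  gpr = c("", "gmod", "glow", ""),
                  objective_id = "BIOMASS", id = "twopath")
}

random_fixture <- function(seed, ...) {
  make_toy_model(fixture_spec(seed = seed, ...))
}
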