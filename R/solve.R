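# Internal linear-programming interface.
#
# All flux optimizations in the package go through lp_solve(), a thin layer
# over pracma::linprog (Big-M simplex).  Variables are shifted to x = v - lb
# so the solver sees a nonnegative problem; every returned solution is
# verified against the steady-state and bound constraints before it is
# accepted, so a silently wrong simplex answer surfaces as status "failed"
# rather than as a bogus flux vector.

#' @keywords internal
with_fixed_rng <- function(expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(104729L)
  expr
}

#' @keywords internal
lp_solve <- function(obj, S, lb, ub, Aineq = NULL, bineq = NULL,
                     maximize = TRUE, maxiter = 5000L, tol = 1e-7) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n, ncol(S) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("lp_solve requires finite bounds; clip open bounds before solving")
  if (any(lb > ub + 1e-12))
    return(list(v = NULL, objective = NA_real_, status = "infeasible"))

  # shift x = v - lb >= 0
  rng <- ub - lb
  A <- diag(n)
  b <- rng
  if (!is.null(Aineq)) {
    A <- rbind(A, Aineq)
    b <- c(b, bineq - as.vector(Aineq %*% lb))
  }
  beq <- -as.vector(S %*% lb)
  cc <- if (maximize) -obj else obj

  # the simplex backend breaks degenerate pivot ties through the RNG; pin it
  # locally (and restore the caller's stream) so tied alternate optima are
  # resolved the same way on every call
  res <- with_fixed_rng(tryCatch(
    pracma::linprog(cc = cc, A = A, b = b, Aeq = S, beq = beq,
                    maxiter = maxiter),
    error = function(e) list(errno = -99, message = conditionMessage(e))))

  if (is.null(res$errno) || res$errno < 0 || is.null(res$x) || anyNA(res$x)) {
    status <- if (identical(res$errno, -3)) "unbounded" else "infeasible"
    return(list(v = NULL, objective = NA_real_, status = status,
                message = res$message))
  }
  v <- res$x[seq_len(n)] + lb
  # verify feasibility of the reported solution
  ok <- max(abs(S %*% v)) <= tol &&
    all(v >= lb - tol) && all(v <= ub + tol) &&
    (is.null(Aineq) || all(as.vector(Aineq %*% v) <= bineq + tol))
  if (!ok)
    return(list(v = NULL, objective = NA_real_, status = "failed"))
  list(v = v, objective = sum(obj * v), status = "optimal")
}

# Equality-constrained box-bounded least squares,
#   min ||G v - y||^2  s.t.  S v = 0, lb <= v <= ub.
# The slacks alpha = y - G v are eliminated, the reduced strictly convex QP
# (tiny ridge on the flux block, as Goldfarb-Idnani needs a positive-definite
# Hessian) is solved with quadprog::solve.QP, and the solution is then
# polished: with the active box constraints of the QP solution fixed, the
# remaining equality-constrained least-squares problem is solved exactly
# through the null space of the constraints, removing the ridge bias from the
# reported objective.
#' @keywords internal
qp_lsq_solve <- function(G, y, S, lb, ub, ridge = 1e-8) {
  n <- ncol(S)
  g <- nrow(G)
  stopifnot(ncol(G) == n, length(y) == g)
  scale <- max(1, sum(diag(crossprod(G))) / n)
  D <- 2 * crossprod(G) + diag(ridge * scale, n)
  dvec <- 2 * as.vector(crossprod(G, y))
  Amat <- t(rbind(S, diag(n), -diag(n)))
  bvec <- c(rep(0, nrow(S)), lb, -ub)
  sol <- tryCatch(
    quadprog::solve.QP(Dmat = D, dvec = dvec, Amat = Amat, bvec = bvec,
                       meq = nrow(S)),
    error = function(e) NULL)
  if (is.null(sol))
    return(list(v = NULL, alpha = NULL, objective = NA_real_,
                status = "infeasible"))
  v <- sol$solution
  tol <- 1e-7 * max(1, max(abs(ub)))
  act_lo <- which(v - lb < tol)
  act_hi <- which(ub - v < tol)
  Cmat <- rbind(S,
                diag(n)[act_lo, , drop = FALSE],
                diag(n)[act_hi, , drop = FALSE])
  c0 <- c(rep(0, nrow(S)), lb[act_lo], ub[act_hi])
  vp <- tryCatch(eq_constrained_ls(G, y, Cmat, c0), error = function(e) NULL)
  if (!is.null(vp) &&
      all(vp >= lb - tol) && all(vp <= ub + tol) &&
      sum((y - G %*% vp)^2) <= sum((y - G %*% v)^2) + 1e-9) {
    v <- pmin(pmax(vp, lb), ub)
  }
  alpha <- y - as.vector(G %*% v)
  list(v = v, alpha = alpha, objective = sum(alpha^2), status = "optimal")
}

# exact minimum of ||G v - y||^2 subject to C v = c0, via the null space of C
eq_constrained_ls <- function(G, y, Cmat, c0) {
  n <- ncol(Cmat)
  v0 <- as.vector(pracma::pinv(Cmat) %*% c0)
  qrC <- qr(t(Cmat))
  r <- qrC$rank
  if (r >= n) return(v0)
  Z <- qr.Q(qrC, complete = TRUE)[, (r + 1):n, drop = FALSE]
  GZ <- G %*% Z
  w <- as.vector(pracma::pinv(GZ) %*% (y - G %*% v0))
  v0 + as.vector(Z %*% w)
}
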