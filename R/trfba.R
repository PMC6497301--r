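# Expression-to-flux-bound constraints, the stepwise C sweep, growth-correlated
# reaction identification, QP slack consistency, and C calibration.
#
# For a scaling constant C and per-gene expression E_j, each covered gene j
# adds the constraint
#     sum_{i in R_j} v_i  <=  C * E_j
# over the irreversible-split network, where R_j is the set of (split)
# reactions whose GPR references gene j.  At C = 0 every gene-associated
# reaction is shut; as C grows the constraints relax monotonically until, at
# C_brk, the biomass optimum reaches the unconstrained value G_max.

#' Split reversible reactions into irreversible halves
#'
#' Every reaction with a negative lower bound is replaced by a forward and a
#' backward nonnegative reaction.  Used internally to give the expression
#' constraints a meaning over nonnegative flux sums.
#'
#' @param model a \code{metabolic_model}.
#' @return list with \code{S} (split stoichiometry), \code{ub} (split upper
#'   bounds), \code{orig} (index of the parent reaction per split column),
#'   \code{sign} (+1 forward, -1 backward) and \code{ids}.
#' @keywords internal
split_reversible <- function(model) {
  n <- length(model$reaction_ids)
  cols <- list(); orig <- integer(0); sgn <- integer(0); ids <- character(0)
  ub <- numeric(0)
  for (k in seq_len(n)) {
    if (model$ub[k] > 0 || model$lb[k] >= 0) {   # forward half
      cols[[length(cols) + 1L]] <- model$S[, k]
      orig <- c(orig, k); sgn <- c(sgn, 1L)
      ids <- c(ids, model$reaction_ids[k])
      ub <- c(ub, max(model$ub[k], 0))
    }
    if (model$lb[k] < 0) {                        # backward half
      cols[[length(cols) + 1L]] <- -model$S[, k]
      orig <- c(orig, k); sgn <- c(sgn, -1L)
      ids <- c(ids, paste0(model$reaction_ids[k], "_rev"))
      ub <- c(ub, -model$lb[k])
    }
  }
  S <- do.call(cbind, cols)
  colnames(S) <- ids
  list(S = S, ub = ub, orig = orig, sign = sgn, ids = ids)
}

#' Build expression-bound constraints on a model
#'
#' Constructs the irreversible-split copy of the model together with one
#' constraint row per expression-covered gene capping the summed flux of the
#' gene's associated reactions at \code{C * E_j}.  Genes absent from the
#' expression profile are left unconstrained.
#'
#' @param model a \code{metabolic_model}.
#' @param expr named nonnegative numeric vector: one sample's gene -> value.
#' @param C scaling constant ((mmol gDW^-1 hr^-1) per expression unit), >= 0.
#' @return an object of class \code{trfba_model}.
#' @export
build_trfba_model <- function(model, expr, C = 1) {
  stopifnot(C >= 0, !is.null(names(expr)))
  if (any(expr < 0)) stop("expression values must be >= 0")
  genes <- intersect(names(expr), model$gene_ids)
  if (length(genes) == 0) stop("expression covers no model gene")
  sp <- split_reversible(model)
  rg <- reaction_genes(model)
  G <- matrix(0, length(genes), ncol(sp$S),
              dimnames = list(genes, sp$ids))
  for (j in seq_along(genes)) {
    hit <- vapply(sp$orig, function(k) genes[j] %in% rg[[k]], logical(1))
    G[j, hit] <- 1
  }
  keep <- rowSums(G) > 0     # constraints need a nonempty reaction set
  structure(list(model = model, split = sp,
                 G = G[keep, , drop = FALSE],
                 E = expr[genes[keep]],
                 genes = genes[keep], C = C),
            class = "trfba_model")
}

#' @export
print.trfba_model <- function(x, ...) {
  cat(sprintf("<trfba_model> %s: %d split reactions, %d constrained genes, C = %g\n",
              x$model$id, length(x$split$ids), length(x$genes), x$C))
  invisible(x)
}

# FBA / pFBA on the split constrained model; returns merged original-space
# fluxes plus the growth value.
trfba_fba <- function(tm, C = tm$C, parsimonious = FALSE) {
  sp <- tm$split
  m <- tm$model
  ns <- ncol(sp$S)
  iobj <- which(sp$orig == match(m$objective_id, m$reaction_ids) & sp$sign == 1L)
  obj <- numeric(ns); obj[iobj] <- 1
  rhs <- C * tm$E
  res <- lp_solve(obj, sp$S, rep(0, ns), sp$ub, Aineq = tm$G, bineq = rhs,
                  maximize = TRUE)
  if (res$status != "optimal")
    return(list(growth = NA_real_, v = NULL, status = res$status))
  g <- res$objective
  if (parsimonious) {
    # all split fluxes are nonnegative, so the L1 stage is a plain LP
    row <- -obj
    res2 <- lp_solve(rep(1, ns), sp$S, rep(0, ns), sp$ub,
                     Aineq = rbind(tm$G, row),
                     bineq = c(rhs, -g * (1 - 1e-9)),
                     maximize = FALSE)
    if (res2$status == "optimal") res <- list(v = res2$v, status = "optimal")
  }
  vmerged <- stats::setNames(numeric(length(m$reaction_ids)), m$reaction_ids)
  for (k in seq_len(ns))
    vmerged[sp$orig[k]] <- vmerged[sp$orig[k]] + sp$sign[k] * res$v[k]
  list(growth = g, v = vmerged, v_split = res$v, status = "optimal")
}

#' Predicted growth under expression constraints
#'
#' @param tm a \code{trfba_model} from [build_trfba_model()].
#' @param C scaling constant (defaults to the one stored in \code{tm}).
#' @return biomass optimum (numeric scalar; \code{NA} if infeasible).
#' @export
trfba_growth <- function(tm, C = tm$C) {
  trfba_fba(tm, C)$growth
}

#' Find the breaking point C_brk
#'
#' The smallest C at which the expression constraints stop limiting growth:
#' constrained growth first reaches \code{(1 - tol)} times the unconstrained
#' optimum.  Located by bisection (growth is nondecreasing in C) to a
#' relative interval width of \code{rel_width}.
#'
#' @param model a \code{metabolic_model}.
#' @param expr named nonnegative expression vector.
#' @param tol relative growth tolerance, > 0.
#' @param rel_width relative bisection width for C_brk.
#' @return list with \code{C_brk} and \code{G_max} (unconstrained optimum).
#' @export
find_c_brk <- function(model, expr, tol = 1e-6, rel_width = 1e-3) {
  if (tol <= 0) stop("tol must be > 0")
  wt <- fba(model)
  if (wt$status != "optimal" || wt$objective_value <= 0)
    stop("unconstrained growth must be positive")
  G_max <- wt$objective_value
  target <- (1 - tol) * G_max
  tm <- build_trfba_model(model, expr, C = 1)
  hi <- 1
  it <- 0L
  while (isTRUE(trfba_growth(tm, hi) < target)) {
    hi <- hi * 2
    it <- it + 1L
    if (it > 60L)
      stop("growth stays below its unconstrained optimum at all tested C; ",
           "model and expression profile appear mismatched")
  }
  lo <- 0
  while ((hi - lo) > rel_width * hi) {
    mid <- (hi + lo) / 2
    if (isTRUE(trfba_growth(tm, mid) >= target)) hi <- mid else lo <- mid
  }
  list(C_brk = hi, G_max = G_max)
}

#' Stepwise C sweep
#'
#' Evaluates the expression-constrained model on a linear grid of
#' \code{n_steps} C values spanning [0, C_brk].  At each grid point the flux
#' vector is made unique by parsimonious FBA; optionally the per-gene slack
#' QP is solved and the count of near-zero slacks recorded.
#'
#' @param model a \code{metabolic_model}.
#' @param expr named nonnegative expression vector.
#' @param n_steps grid size (>= 2), default 500.
#' @param slacks also run the QP slack stage at each step.
#' @param slack_threshold threshold under which a slack counts as consistent.
#' @param c_brk optional precomputed [find_c_brk()] result.
#' @return an object of class \code{c_sweep}: list with \code{c_grid},
#'   \code{V} (reactions x steps flux matrix), \code{growth}, \code{A}
#'   (genes x steps slack matrix), \code{n_alpha}, \code{C_brk}, \code{G_max},
#'   \code{status} (per-step solver status).
#' @export
sweep_c <- function(model, expr, n_steps = 500, slacks = TRUE,
                    slack_threshold = 1e-6, c_brk = NULL) {
  stopifnot(n_steps >= 2)
  if (is.null(c_brk)) c_brk <- find_c_brk(model, expr)
  tm <- build_trfba_model(model, expr, C = 1)
  grid <- seq(0, c_brk$C_brk, length.out = n_steps)
  n <- length(model$reaction_ids)
  V <- matrix(NA_real_, n, n_steps, dimnames = list(model$reaction_ids, NULL))
  A <- if (slacks)
    matrix(NA_real_, length(tm$genes), n_steps,
           dimnames = list(tm$genes, NULL)) else NULL
  growth <- rep(NA_real_, n_steps)
  status <- rep("optimal", n_steps)
  for (s in seq_len(n_steps)) {
    sol <- trfba_fba(tm, grid[s], parsimonious = TRUE)
    status[s] <- sol$status
    if (sol$status != "optimal") next
    V[, s] <- sol$v
    growth[s] <- sol$growth
    if (slacks) {
      qp <- qp_slack_minimize(tm, grid[s])
      if (qp$status == "optimal") A[, s] <- qp$alpha else status[s] <- "qp_failed"
    }
  }
  n_alpha <- if (slacks)
    apply(A, 2, function(a) count_small_slacks(a, slack_threshold)) else NULL
  structure(list(c_grid = grid, V = V, growth = growth, A = A,
                 n_alpha = n_alpha, C_brk = c_brk$C_brk, G_max = c_brk$G_max,
                 slack_threshold = slack_threshold, status = status),
            class = "c_sweep")
}

#' @export
print.c_sweep <- function(x, ...) {
  cat(sprintf("<c_sweep> %d steps over [0, %.4g]; growth %.4g -> %.4g\n",
              length(x$c_grid), x$C_brk, x$growth[1],
              x$growth[length(x$growth)]))
  invisible(x)
}

#' Growth-correlated reactions of a C sweep
#'
#' Reactions whose pFBA flux is strongly rank-correlated (sign-agnostic
#' Spearman) with predicted growth along the sweep, after Benjamini-Hochberg
#' adjustment across all tested reactions.  Reactions with zero flux variance
#' are excluded (their correlation is undefined).
#'
#' @param sweep a \code{c_sweep} with >= 10 usable steps.
#' @param rho_min minimum |Spearman rho|.
#' @param alpha_fdr BH-adjusted q-value cutoff.
#' @return data.frame with columns \code{reaction_id}, \code{rho}, \code{p},
#'   \code{q}, restricted to the selected set.
#' @export
growth_correlated_reactions <- function(sweep, rho_min = 0.9,
                                        alpha_fdr = 0.05) {
  ok <- sweep$status == "optimal" | sweep$status == "qp_failed"
  ok <- ok & !is.na(sweep$growth)
  if (sum(ok) < 10) stop("sweep has fewer than 10 usable steps")
  g <- sweep$growth[ok]
  if (stats::sd(g) == 0)
    stop("growth is constant across the sweep; no growth signal to correlate")
  V <- sweep$V[, ok, drop = FALSE]
  keep <- apply(V, 1, stats::sd) > 0
  V <- V[keep, , drop = FALSE]
  if (nrow(V) == 0)
    return(data.frame(reaction_id = character(0), rho = numeric(0),
                      p = numeric(0), q = numeric(0)))
  stat <- t(apply(V, 1, function(vi) {
    ct <- suppressWarnings(stats::cor.test(vi, g, method = "spearman",
                                           exact = FALSE))
    c(rho = unname(ct$estimate), p = ct$p.value)
  }))
  q <- stats::p.adjust(stat[, "p"], method = "BH")
  res <- data.frame(reaction_id = rownames(V), rho = stat[, "rho"],
                    p = stat[, "p"], q = q, stringsAsFactors = FALSE,
                    row.names = NULL)
  res[abs(res$rho) >= rho_min & res$q < alpha_fdr, , drop = FALSE]
}

#' Minimize expression-flux slacks by quadratic programming
#'
#' Converts each gene's inequality into an equality with slack,
#' \eqn{\sum_{i \in R_j} v_i + \alpha_j = C E_j}, and minimizes
#' \eqn{\sum_j \alpha_j^2} over steady-state flux vectors within bounds.
#' Small \eqn{|\alpha_j|} means the network can match gene j's scaled
#' expression level exactly.
#'
#' @param x a \code{trfba_model}, or a \code{metabolic_model} (then
#'   \code{expr} is required).
#' @param C scaling constant.
#' @param expr expression vector when \code{x} is a plain model.
#' @return list with \code{alpha} (named per-gene slack), \code{v} (witness
#'   flux in the original reaction space), \code{objective}
#'   (\eqn{\sum \alpha^2}) and \code{status}.
#' @export
qp_slack_minimize <- function(x, C = NULL, expr = NULL) {
  tm <- if (inherits(x, "trfba_model")) x else build_trfba_model(x, expr, C = 1)
  if (is.null(C)) C <- tm$C
  sp <- tm$split
  res <- qp_lsq_solve(G = tm$G, y = C * tm$E, S = sp$S,
                      lb = rep(0, ncol(sp$S)), ub = sp$ub)
  if (res$status != "optimal")
    stop("slack QP infeasible; violated constraint set: steady state + bounds")
  m <- tm$model
  vmerged <- stats::setNames(numeric(length(m$reaction_ids)), m$reaction_ids)
  for (k in seq_along(sp$orig))
    vmerged[sp$orig[k]] <- vmerged[sp$orig[k]] + sp$sign[k] * res$v[k]
  list(alpha = stats::setNames(res$alpha, tm$genes), v = vmerged,
       objective = res$objective, status = res$status)
}

#' Count near-zero slacks
#'
#' The flux/expression consistency measure of a QP solution: the number of
#' slack variables with magnitude below the threshold (default 1e-6).
#'
#' @param alpha numeric slack vector.
#' @param threshold magnitude threshold.
#' @return integer count.
#' @export
count_small_slacks <- function(alpha, threshold = 1e-6) {
  stopifnot(all(is.finite(alpha)))
  sum(abs(alpha) < threshold)
}

#' Detect C_corr from the near-zero-slack series
#'
#' Fits piecewise-constant means to the \eqn{N_\alpha} series by binary
#' segmentation on the residual sum of squares and reports the grid C value
#' at the first detected change point (the first index of the new regime).
#' \code{which = "last"} instead reports the last change point, the
#' alternative reading of a "maximum shift point".
#'
#' @param n_alpha integer/numeric series of near-zero-slack counts.
#' @param c_grid C values matching the series.
#' @param penalty minimum RSS improvement to accept a split; by default a
#'   BIC-flavoured \code{2 * log(n) * sigma2} with a robust noise estimate
#'   from successive differences, so a noiseless step is always found.
#' @param which \code{"first"} or \code{"last"} change point.
#' @return list with \code{C_corr}, \code{index} (first index of the new
#'   regime) and \code{breakpoints} (all detected indices).
#' @export
detect_c_corr <- function(n_alpha, c_grid, penalty = NULL,
                          which = c("first", "last")) {
  which <- match.arg(which)
  n <- length(n_alpha)
  stopifnot(length(c_grid) == n)
  if (n < 4) stop("series too short for change-point detection")
  if (is.null(penalty)) {
    d <- diff(n_alpha)
    sigma2 <- (stats::mad(d, center = 0) / sqrt(2))^2
    penalty <- max(2 * log(n) * sigma2, 1e-9)
  }
  bps <- binseg_mean(n_alpha, penalty)
  if (length(bps) == 0)
    stop("no change point detected in the slack-count series; ",
         "fall back to C_opt (measured growth) or choose C manually")
  idx <- if (which == "first") min(bps) else max(bps)
  list(C_corr = c_grid[idx], index = idx, breakpoints = sort(bps))
}

# binary segmentation for changes in mean; returns first-index-of-new-regime
# breakpoints
binseg_mean <- function(x, penalty) {
  best_split <- function(lo, hi) {
    n <- hi - lo + 1
    if (n < 2) return(NULL)
    seg <- x[lo:hi]
    cs <- cumsum(seg); css <- cumsum(seg^2)
    tot <- css[n] - cs[n]^2 / n
    best <- NULL; bestgain <- 0
    for (k in 1:(n - 1)) {           # left = 1..k, right = k+1..n
      rssL <- css[k] - cs[k]^2 / k
      rssR <- (css[n] - css[k]) - (cs[n] - cs[k])^2 / (n - k)
      gain <- tot - rssL - rssR
      if (gain > bestgain + 1e-12) { bestgain <- gain; best <- k }
    }
    if (is.null(best) || bestgain <= penalty) return(NULL)
    list(k = lo + best - 1, gain = bestgain)
  }
  out <- integer(0)
  recurse <- function(lo, hi) {
    sp <- best_split(lo, hi)
    if (is.null(sp)) return(invisible())
    out <<- c(out, sp$k + 1L)        # first index of right segment
    recurse(lo, sp$k)
    recurse(sp$k + 1L, hi)
  }
  recurse(1L, length(x))
  out
}

#' Growth-calibrated scaling constant C_opt
#'
#' With measured growth available, the scaling constant is a linear function
#' of measured growth:
#' \deqn{C_{opt} = \frac{C_{brk}}{G_{max}} \times G_{measured}}
#'
#' @param C_brk breaking point from [find_c_brk()].
#' @param G_max unconstrained growth optimum (> 0).
#' @param G_measured measured growth rate (>= 0), hr^-1.
#' @return C_opt (same units as C_brk).
#' @export
compute_c_opt <- function(C_brk, G_max, G_measured) {
  if (any(G_max <= 0)) stop("G_max must be > 0")
  if (any(G_measured < 0)) stop("G_measured must be >= 0")
  (C_brk / G_max) * G_measured
}
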