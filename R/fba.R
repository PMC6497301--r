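# FBA family: flux balance analysis, parsimonious FBA, flux variability
# analysis, gene deletions.  All solve LPs over the steady-state polytope
# {v : S v = 0, lb <= v <= ub} via the internal lp_solve() wrapper.

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux through an objective reaction subject to
#' steady state \eqn{S v = 0} and flux bounds.  Infeasibility and
#' unboundedness are reported in the status, never silently mapped to zero.
#'
#' @param model a \code{metabolic_model}.
#' @param objective reaction id of the objective; the model's biomass reaction
#'   by default.
#' @param sense \code{"max"} or \code{"min"}.
#' @param extra_ineq,extra_rhs optional extra inequality constraints
#'   \eqn{A v \le b} over the reaction fluxes (used internally for fixed
#'   objective fractions and expression bounds).
#' @return an object of class \code{flux_distribution}: a list with
#'   \code{fluxes} (named vector), \code{objective_value} and \code{status}
#'   (\code{"optimal"}, \code{"infeasible"} or \code{"unbounded"}).
#' @examples
#' sol <- fba(example_chain_model())
#' sol$objective_value
#' @export
fba <- function(model, objective = model$objective_id,
                sense = c("max", "min"),
                extra_ineq = NULL, extra_rhs = NULL) {
  sense <- match.arg(sense)
  if (!objective %in% model$reaction_ids)
    stop("objective reaction ", sQuote(objective), " is not in the model")
  n <- length(model$reaction_ids)
  obj <- stats::setNames(numeric(n), model$reaction_ids)
  obj[objective] <- 1
  res <- lp_solve(obj, model$S, model$lb, model$ub,
                  Aineq = extra_ineq, bineq = extra_rhs,
                  maximize = (sense == "max"))
  flux_distribution(res, model)
}

flux_distribution <- function(res, model) {
  fl <- if (is.null(res$v)) NULL else stats::setNames(res$v, model$reaction_ids)
  structure(list(fluxes = fl, objective_value = res$objective,
                 status = res$status), class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("<flux_distribution> status %s, objective %s\n", x$status,
              format(x$objective_value)))
  invisible(x)
}

#' Parsimonious FBA
#'
#' Two-stage LP: first the biomass optimum is found, then the total flux
#' \eqn{\sum_i |v_i|} is minimized with the objective held at its optimum
#' (reversible reactions are split into nonnegative forward/backward halves,
#' so no integer variables are involved).  This picks a unique, thermodynamically
#' parsimonious representative among the alternate FBA optima.
#'
#' @inheritParams fba
#' @return a \code{flux_distribution}; \code{objective_value} is the biomass
#'   optimum (not the flux sum).
#' @export
pfba <- function(model, objective = model$objective_id,
                 extra_ineq = NULL, extra_rhs = NULL) {
  stage1 <- fba(model, objective, "max", extra_ineq, extra_rhs)
  if (stage1$status != "optimal") return(stage1)
  gstar <- stage1$objective_value

  n <- length(model$reaction_ids)
  # split v = p - m, p,m >= 0
  Sw <- cbind(model$S, -model$S)
  lbw <- rep(0, 2 * n)
  ubw <- c(pmax(model$ub, 0), pmax(-model$lb, 0))
  iobj <- match(objective, model$reaction_ids)
  # hold objective at its optimum: v_obj >= gstar * (1 - tol)
  row_obj <- numeric(2 * n); row_obj[iobj] <- -1; row_obj[n + iobj] <- 1
  Aw <- matrix(row_obj, 1)
  bw <- -gstar * (1 - 1e-9)
  if (!is.null(extra_ineq)) {
    Aw <- rbind(Aw, cbind(extra_ineq, -extra_ineq))
    bw <- c(bw, extra_rhs)
  }
  res <- lp_solve(rep(1, 2 * n), Sw, lbw, ubw, Aineq = Aw, bineq = bw,
                  maximize = FALSE)
  if (res$status != "optimal")
    return(structure(list(fluxes = NULL, objective_value = NA_real_,
                          status = res$status), class = "flux_distribution"))
  v <- res$v[seq_len(n)] - res$v[n + seq_len(n)]
  structure(list(fluxes = stats::setNames(v, model$reaction_ids),
                 objective_value = v[iobj], status = "optimal"),
            class = "flux_distribution")
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to the objective held at a
#' fraction of its optimum.  With \code{objective_fraction = 0} the objective
#' is unconstrained and reactions with \code{min = max = 0} are exactly the
#' blocked reactions.
#'
#' @param model a \code{metabolic_model}.
#' @param reactions reaction ids to analyze (all by default).
#' @param objective_fraction number in [0, 1].
#' @return data.frame with columns \code{reaction_id}, \code{min}, \code{max}.
#' @export
fva <- function(model, reactions = model$reaction_ids,
                objective_fraction = 0) {
  stopifnot(objective_fraction >= 0, objective_fraction <= 1)
  bad <- setdiff(reactions, model$reaction_ids)
  if (length(bad)) stop("unknown reaction(s): ", paste(bad, collapse = ", "))
  extra_ineq <- NULL; extra_rhs <- NULL
  if (objective_fraction > 0) {
    wt <- fba(model)
    if (wt$status != "optimal")
      stop("FVA with objective_fraction > 0 requires an optimal FBA solution")
    n <- length(model$reaction_ids)
    row <- numeric(n)
    row[match(model$objective_id, model$reaction_ids)] <- -1
    extra_ineq <- matrix(row, 1)
    extra_rhs <- -objective_fraction * wt$objective_value
  }
  lo <- hi <- numeric(length(reactions))
  for (k in seq_along(reactions)) {
    lo[k] <- fba(model, reactions[k], "min", extra_ineq, extra_rhs)$objective_value
    hi[k] <- fba(model, reactions[k], "max", extra_ineq, extra_rhs)$objective_value
  }
  data.frame(reaction_id = reactions, min = lo, max = hi,
             stringsAsFactors = FALSE)
}

#' Reactions disabled by a gene knockout
#'
#' A reaction is disabled when its GPR rule becomes unsatisfiable with the
#' given genes absent; reactions with empty rules are never disabled.
#'
#' @param model a \code{metabolic_model}.
#' @param genes character vector of knocked-out gene ids.
#' @return character vector of disabled reaction ids.
#' @export
knockout_reactions <- function(model, genes) {
  bad <- setdiff(genes, model$gene_ids)
  if (length(bad)) stop("unknown gene(s): ", paste(bad, collapse = ", "))
  hit <- vapply(seq_along(model$reaction_ids), function(k) {
    tr <- model$gpr_trees[[k]]
    length(gpr_genes(tr)) > 0 && !eval_gpr(tr, knocked_out = genes)
  }, logical(1))
  model$reaction_ids[hit]
}

#' Growth rate after a single-gene knockout
#'
#' Disables every reaction whose GPR evaluates false without the gene
#' (bounds fixed to zero) and re-runs FBA.  An infeasible knockout model is
#' reported as zero growth, the standard essentiality convention.
#'
#' @param model a \code{metabolic_model}.
#' @param gene a gene id.
#' @return biomass optimum after the knockout (numeric scalar).
#' @export
single_gene_deletion <- function(model, gene) {
  stopifnot(length(gene) == 1L)
  off <- knockout_reactions(model, gene)
  m <- model
  m$lb[off] <- 0
  m$ub[off] <- 0
  sol <- fba(m)
  if (sol$status != "optimal") 0 else sol$objective_value
}

#' Predicted essential genes
#'
#' A gene is essential when its knockout reduces the maximal growth rate by
#' more than \code{threshold} (relative drop), 1\% by default.
#'
#' @param model a \code{metabolic_model}.
#' @param threshold relative growth-drop threshold in [0, 1).
#' @param genes genes to test (all model genes by default).
#' @return character vector of essential gene ids.
#' @export
essential_genes <- function(model, threshold = 0.01,
                            genes = model$gene_ids) {
  wt <- fba(model)
  if (wt$status != "optimal" || wt$objective_value <= 0)
    stop("wild-type growth must be positive to define relative knockout drops")
  g0 <- wt$objective_value
  drop <- vapply(genes, function(g) (g0 - single_gene_deletion(model, g)) / g0,
                 numeric(1))
  genes[drop > threshold]
}
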