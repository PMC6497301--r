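# Expression discretization, core determination and FASTCORE-family
# subnetwork extraction.

#' Discretize expression z-scores into activity states
#'
#' Genes with z-scores above \code{hi} are \code{"core"} (confidently
#' expressed), below \code{lo} \code{"nonexpressed"}, and \code{"moderate"}
#' in between.  The defaults (5 and 0) are the conventional thresholds for
#' barcode-style z-scores.
#'
#' @param z named numeric vector of per-gene z-scores.
#' @param hi,lo thresholds.
#' @return named character vector of states; genes with \code{NaN}/\code{NA}
#'   z-scores are omitted with a warning.
#' @export
discretize_expression <- function(z, hi = 5, lo = 0) {
  stopifnot(!is.null(names(z)))
  bad <- !is.finite(z)
  if (any(bad)) {
    warning("omitting ", sum(bad), " gene(s) with non-finite z-scores")
    z <- z[!bad]
  }
  states <- ifelse(z > hi, "core", ifelse(z < lo, "nonexpressed", "moderate"))
  stats::setNames(states, names(z))
}

#' Core-reaction specification
#'
#' Bundles the three reaction sets driving extraction: \code{core} (must be
#' active in the output), \code{non_penalized} (free to include at no cost)
#' and \code{forced} (always included, e.g. the biomass reaction and its
#' support).
#'
#' @param core,non_penalized,forced character vectors of reaction ids.
#' @return an object of class \code{core_spec}.
#' @export
core_spec <- function(core = character(0), non_penalized = character(0),
                      forced = character(0)) {
  structure(list(core = unique(core),
                 non_penalized = unique(setdiff(non_penalized, core)),
                 forced = unique(forced)),
            class = "core_spec")
}

#' Map gene activity states to a core-reaction specification
#'
#' A reaction is core exactly when its GPR evaluates true with only the
#' core-state genes present; it is non-penalized when the rule is satisfied
#' once moderate genes are added.  Reactions without a GPR are never
#' expression-core.  The biomass reaction is appended to the forced set.
#'
#' @param model a \code{metabolic_model}.
#' @param states named character vector from [discretize_expression()].
#' @param force_biomass add the objective reaction to the forced set.
#' @return a \code{core_spec}.
#' @export
core_from_states <- function(model, states, force_biomass = TRUE) {
  covered <- intersect(names(states), model$gene_ids)
  if (length(covered) == 0) stop("states cover no model gene")
  core_genes <- names(states)[states == "core"]
  ok_genes <- names(states)[states %in% c("core", "moderate")]
  is_core <- is_soft <- logical(length(model$reaction_ids))
  for (k in seq_along(model$reaction_ids)) {
    tr <- model$gpr_trees[[k]]
    if (length(gpr_genes(tr)) == 0) next
    is_core[k] <- eval_gpr(tr, present = core_genes)
    is_soft[k] <- eval_gpr(tr, present = ok_genes)
  }
  core <- model$reaction_ids[is_core]
  if (length(core) == 0)
    warning("expression states produce an empty core set")
  core_spec(core = core,
            non_penalized = model$reaction_ids[is_soft & !is_core],
            forced = if (force_biomass) model$objective_id else character(0))
}

# LP-10: find a flux mode supporting all of K (v_K >= epsilon, in a scaled
# copy of the network) while minimizing the weighted L1 norm over the
# penalized set P.  Scaling pushes required fluxes far from the activation
# threshold so the L1 objective zeroes exactly the structurally unneeded
# penalized reactions.
lp10 <- function(model, K, P, epsilon, costs, scaling = 1e3) {
  n <- length(model$reaction_ids)
  np <- length(P)
  kidx <- match(K, model$reaction_ids)
  pidx <- match(P, model$reaction_ids)
  Sx <- cbind(model$S, matrix(0, nrow(model$S), np))
  big <- scaling * max(abs(model$lb), abs(model$ub), 1)
  lbx <- c(model$lb * scaling, rep(0, np))
  ubx <- c(model$ub * scaling, rep(big, np))
  lbx[kidx] <- pmax(lbx[kidx], epsilon * scaling)
  rows <- list()
  if (np) {
    A1 <- matrix(0, np, n + np)               #  v_i - z_i <= 0
    A1[cbind(seq_len(np), pidx)] <- 1
    A1[cbind(seq_len(np), n + seq_len(np))] <- -1
    A2 <- matrix(0, np, n + np)               # -v_i - z_i <= 0
    A2[cbind(seq_len(np), pidx)] <- -1
    A2[cbind(seq_len(np), n + seq_len(np))] <- -1
    Aineq <- rbind(A1, A2); bineq <- rep(0, 2 * np)
  } else {
    Aineq <- NULL; bineq <- NULL
  }
  obj <- c(numeric(n), costs[P])
  res <- lp_solve(obj, Sx, lbx, ubx, Aineq = Aineq, bineq = bineq,
                  maximize = FALSE)
  if (res$status != "optimal") return(NULL)
  stats::setNames(res$v[seq_len(n)], model$reaction_ids)
}

find_sparse_mode <- function(model, J, P, epsilon, costs, singleton) {
  if (length(J) == 0) return(character(0))
  Ji <- if (singleton) J[1] else J
  v1 <- lp7(model, Ji, epsilon)
  if (is.null(v1)) return(character(0))
  K <- intersect(Ji, flux_support(v1, epsilon))
  if (length(K) == 0) return(character(0))
  v2 <- lp10(model, K, P, epsilon, costs)
  if (is.null(v2)) return(character(0))
  flux_support(v2, epsilon)
}

#' FASTCORE context-specific subnetwork extraction
#'
#' Extracts a flux-consistent subnetwork containing every core reaction with
#' an approximately minimal number of non-core additions, via the iterative
#' LP-7 / LP-10 construction with direction flips for reversible core
#' reactions.  The input model must itself be flux-consistent.
#'
#' @param model a flux-consistent \code{metabolic_model}.
#' @param core character vector of core reaction ids, or a \code{core_spec}
#'   (forced reactions are added to the core; non-penalized reactions get
#'   zero inclusion cost).
#' @param epsilon flux-activation threshold shared with [fastcc()].
#' @param costs optional named per-reaction inclusion costs for non-core
#'   reactions (default 1, with 0 for a \code{core_spec}'s non-penalized set).
#' @return a \code{context_model} (a \code{metabolic_model} carrying
#'   provenance: parent model id, core specification, method label).
#' @examples
#' m <- example_chain_model()
#' cm <- fastcore(m, core = "T1")
#' cm$reaction_ids
#' @export
fastcore <- function(model, core, epsilon = 1e-4, costs = NULL) {
  validate_model(model)
  spec <- if (inherits(core, "core_spec")) core else core_spec(core = core)
  core_set <- union(spec$core, spec$forced)
  bad <- setdiff(core_set, model$reaction_ids)
  if (length(bad)) stop("core reaction(s) not in model: ",
                        paste(bad, collapse = ", "))
  if (is.null(costs)) {
    costs <- stats::setNames(rep(1, length(model$reaction_ids)),
                             model$reaction_ids)
    costs[spec$non_penalized] <- 0
  }
  if (length(core_set) == 0)
    return(new_context_model(model, character(0), spec, "fastcore", epsilon))

  N <- model$reaction_ids
  irr <- N[model$lb >= 0]
  work <- model
  flipped <- FALSE; singleton <- FALSE

  J <- intersect(core_set, irr)
  P <- setdiff(N, core_set)
  A <- find_sparse_mode(work, J, P, epsilon, costs, singleton = FALSE)
  missed <- setdiff(J, A)
  if (length(missed))
    stop("core contains blocked (inconsistent) irreversible reaction(s): ",
         paste(missed, collapse = ", "))
  J <- setdiff(core_set, A)
  while (length(J)) {
    P <- setdiff(P, A)
    supp <- find_sparse_mode(work, J, P, epsilon, costs, singleton)
    A <- union(A, supp)
    if (length(intersect(J, A))) {
      J <- setdiff(J, A)
      flipped <- FALSE
      singleton <- FALSE
    } else {
      Ji <- if (singleton) J[1] else J
      JiRev <- Ji[Ji %in% N[model$lb < 0]]
      if (flipped || length(JiRev) == 0) {
        if (singleton)
          stop("core contains blocked (inconsistent) reaction(s): ",
               paste(J[1], collapse = ", "))
        flipped <- FALSE
        singleton <- TRUE
      } else {
        work <- flip_reactions(work, JiRev)
        flipped <- TRUE
      }
    }
  }
  new_context_model(model, A, spec, "fastcore", epsilon)
}

#' Functionality-preserving FASTCORE variant
#'
#' A FASTCORE search tuned for context-model functionality: the biomass
#' reaction plus the support of one parsimonious-FBA solution are pre-seeded
#' (biomass forced into the core, its pFBA support made non-penalized),
#' moderate-state reactions carry zero inclusion cost and nonexpressed-state
#' reactions full cost.  The output therefore always contains the biomass
#' reaction and predicts positive growth whenever the parent model does.
#'
#' @param model a flux-consistent \code{metabolic_model} whose biomass is
#'   feasible.
#' @param core core reaction ids or a \code{core_spec} (e.g. growth-correlated
#'   reactions from [sweep_c()]).
#' @param states optional named gene-state vector from
#'   [discretize_expression()]; moderate-supported reactions become
#'   non-penalized.
#' @param epsilon flux-activation threshold.
#' @return a \code{context_model} containing the biomass reaction.
#' @export
fastcormics_modified <- function(model, core, states = NULL, epsilon = 1e-4) {
  validate_model(model)
  seed <- pfba(model)
  if (seed$status != "optimal" || seed$objective_value <= epsilon)
    stop("biomass is infeasible (or below epsilon) in the parent model")
  seed_support <- names(seed$fluxes)[abs(seed$fluxes) >= epsilon]

  spec <- if (inherits(core, "core_spec")) core else core_spec(core = core)
  soft <- spec$non_penalized
  if (!is.null(states)) {
    soft <- union(soft,
                  core_from_states(model, states, force_biomass = FALSE)$non_penalized)
  }
  spec <- core_spec(core = spec$core,
                    non_penalized = union(soft, seed_support),
                    forced = union(spec$forced, model$objective_id))
  cm <- fastcore(model, spec, epsilon = epsilon)
  cm$method <- "fastcormics_modified"
  cm
}

# ---- context models ---------------------------------------------------------

new_context_model <- function(parent, rxns, spec, method, epsilon,
                              C_used = NA_real_) {
  keep <- parent$reaction_ids[parent$reaction_ids %in% rxns]
  m <- submodel(parent, keep)
  m$parent_id <- parent$id
  m$core_used <- spec
  m$method <- method
  m$epsilon <- epsilon
  m$C_used <- C_used
  class(m) <- c("context_model", class(m))
  m
}

#' Extract a reaction subset of a model
#'
#' Keeps the named reactions, drops metabolites no longer touched, and
#' re-detects exchange reactions.  If the objective reaction is dropped the
#' submodel has no objective (\code{objective_id} is \code{NA}).
#'
#' @param model a \code{metabolic_model}.
#' @param rxns reaction ids to keep.
#' @return a \code{metabolic_model}.
#' @export
submodel <- function(model, rxns) {
  bad <- setdiff(rxns, model$reaction_ids)
  if (length(bad)) stop("unknown reaction(s): ", paste(bad, collapse = ", "))
  if (length(rxns) == 0) {
    return(metabolic_model(
      S = matrix(0, 0, 0), reaction_ids = character(0),
      metabolite_ids = character(0),
      lb = numeric(0), ub = numeric(0), gpr = character(0),
      gene_ids = character(0), objective_id = NA_character_,
      id = paste0(model$id, "_sub")))
  }
  keep <- model$reaction_ids %in% rxns
  S <- model$S[, keep, drop = FALSE]
  live <- rowSums(S != 0) > 0
  S <- S[live, , drop = FALSE]
  obj <- if (model$objective_id %in% colnames(S)) model$objective_id
         else NA_character_
  genes <- unique(unlist(lapply(model$gpr_trees[keep], gpr_genes)))
  metabolic_model(S = S, lb = model$lb[keep], ub = model$ub[keep],
                  gpr = model$gpr[keep],
                  gene_ids = genes,
                  objective_id = obj, id = paste0(model$id, "_sub"))
}

#' @export
print.context_model <- function(x, ...) {
  cat(sprintf("<context_model> %s from %s (%s): %d/%s reactions, C = %s\n",
              x$id, x$parent_id, x$method, length(x$reaction_ids),
              "parent", format(x$C_used)))
  NextMethod()
}

#' Write a context model with its provenance side-car
#'
#' The model itself goes to \code{path} in the JSON dialect; provenance
#' (parent id, method, core specification, epsilon, C) goes to
#' \code{<path>.provenance.json}.
#'
#' @param cm a \code{context_model}.
#' @param path output path for the model JSON.
#' @export
write_context_model <- function(cm, path) {
  write_model(cm, path, dialect = "json")
  prov <- list(parent = cm$parent_id, method = cm$method,
               epsilon = cm$epsilon, C_used = cm$C_used,
               core = as.list(unclass(cm$core_used)))
  jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
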