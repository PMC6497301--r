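# FASTCC flux-consistency testing.
#
# A reaction is blocked when it cannot carry |flux| >= epsilon in any steady
# state.  FASTCC finds the consistent set with a handful of support-maximizing
# LPs (the LP-7 construction) plus direction flips for reversible reactions,
# instead of the 2n LPs of exhaustive FVA.

# LP-7: find a flux vector maximizing the number of reactions in J with
# v_j >= epsilon.  Variables (v, z): max sum z, s.t. S v = 0, z_j <= v_j,
# 0 <= z <= epsilon, lb <= v <= ub.
lp7 <- function(model, J, epsilon) {
  n <- length(model$reaction_ids)
  k <- length(J)
  if (k == 0) return(NULL)
  jidx <- match(J, model$reaction_ids)
  Sx <- cbind(model$S, matrix(0, nrow(model$S), k))
  lbx <- c(model$lb, rep(0, k))
  ubx <- c(model$ub, rep(epsilon, k))
  Aineq <- matrix(0, k, n + k)
  Aineq[cbind(seq_len(k), n + seq_len(k))] <- 1
  Aineq[cbind(seq_len(k), jidx)] <- -1          # z_j - v_j <= 0
  obj <- c(numeric(n), rep(1, k))
  res <- lp_solve(obj, Sx, lbx, ubx, Aineq = Aineq, bineq = rep(0, k),
                  maximize = TRUE)
  if (res$status != "optimal") return(NULL)
  stats::setNames(res$v[seq_len(n)], model$reaction_ids)
}

flux_support <- function(v, epsilon) {
  names(v)[abs(v) >= 0.99 * epsilon]
}

flip_reactions <- function(model, rxns) {
  idx <- match(rxns, model$reaction_ids)
  model$S[, idx] <- -model$S[, idx]
  tmp <- model$lb[idx]
  model$lb[idx] <- -model$ub[idx]
  model$ub[idx] <- -tmp
  model
}

#' FASTCC flux-consistency test
#'
#' Partitions the reactions of a model into a flux-consistent set (each can
#' attain \code{|flux| >= epsilon} in some steady state) and a blocked set.
#' Reversible reactions are handled by the direction-flipping step of the
#' algorithm rather than by irreversible splitting.
#'
#' @param model a \code{metabolic_model}.
#' @param epsilon flux-activation threshold (mmol gDW^-1 hr^-1), > 0.
#' @return an object of class \code{consistency_report}: list with
#'   \code{consistent}, \code{blocked}, \code{epsilon}, and \code{witness}
#'   (a reaction-by-mode matrix of stored flux vectors in which every
#'   consistent reaction attains \code{|flux| >= epsilon} in at least one
#'   column).
#' @examples
#' rep <- fastcc(example_chain_model())
#' rep$blocked
#' @export
fastcc <- function(model, epsilon = 1e-4) {
  stopifnot(epsilon > 0)
  validate_model(model)
  N <- model$reaction_ids
  if (length(N) == 0)
    return(structure(list(consistent = character(0), blocked = character(0),
                          epsilon = epsilon,
                          witness = matrix(0, 0, 0)),
                     class = "consistency_report"))
  irr <- N[model$lb >= 0]
  work <- model
  flipsign <- stats::setNames(rep(1, length(N)), N)   # work flux -> original flux
  witnesses <- list()

  A <- character(0)
  v <- lp7(work, irr, epsilon)
  if (!is.null(v)) {
    A <- flux_support(v, epsilon)
    witnesses[[length(witnesses) + 1L]] <- v * flipsign
  }
  blocked <- setdiff(irr, A)                      # unsupported irreversible
  J <- setdiff(N, union(A, blocked))
  flipped <- FALSE; singleton <- FALSE
  while (length(J)) {
    Ji <- if (singleton) J[1] else J
    v <- lp7(work, Ji, epsilon)
    supp <- if (is.null(v)) character(0) else flux_support(v, epsilon)
    if (length(supp)) {
      A <- union(A, supp)
      witnesses[[length(witnesses) + 1L]] <- v * flipsign
    }
    if (length(intersect(J, A))) {
      J <- setdiff(J, A)
      flipped <- FALSE
      singleton <- FALSE
    } else {
      JiRev <- Ji[Ji %in% N[model$lb < 0]]
      if (flipped || length(JiRev) == 0) {
        flipped <- FALSE
        if (singleton) {
          blocked <- union(blocked, Ji)
          J <- setdiff(J, Ji)
        } else {
          singleton <- TRUE
        }
      } else {
        work <- flip_reactions(work, JiRev)
        flipsign[JiRev] <- -flipsign[JiRev]
        flipped <- TRUE
      }
    }
  }
  witness <- if (length(witnesses))
    do.call(cbind, lapply(witnesses, function(w) w[N])) else
    matrix(0, length(N), 0, dimnames = list(N, NULL))
  rownames(witness) <- N
  structure(list(consistent = intersect(N, A),
                 blocked = intersect(N, blocked),
                 epsilon = epsilon,
                 witness = witness),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("<consistency_report> %d consistent, %d blocked (epsilon %g)\n",
              length(x$consistent), length(x$blocked), x$epsilon))
  invisible(x)
}

#' Fraction of blocked reactions
#'
#' Runs FASTCC after either applying a medium (constrained state) or opening
#' every exchange bound symmetrically to \code{c(-open_bound, open_bound)}
#' (unconstrained state, the community convention).
#'
#' @param model a \code{metabolic_model}.
#' @param medium optional \code{medium_spec}; \code{NULL} selects the
#'   unconstrained state.
#' @param epsilon flux-activation threshold.
#' @param open_bound magnitude used to open exchanges when unconstrained.
#' @return fraction in [0, 1].
#' @export
blocked_fraction <- function(model, medium = NULL, epsilon = 1e-4,
                             open_bound = 1000) {
  m <- if (is.null(medium)) {
    ex <- model$exchange_ids
    model$lb[ex] <- -open_bound
    model$ub[ex] <- open_bound
    model
  } else apply_medium(model, medium)
  rep <- fastcc(m, epsilon)
  length(rep$blocked) / length(m$reaction_ids)
}

#' Write a consistency report as TSV
#' @param report a \code{consistency_report}.
#' @param path output path.
#' @export
write_consistency_tsv <- function(report, path) {
  rxns <- rownames(report$witness)
  wit <- vapply(rxns, function(r) {
    if (!r %in% report$consistent || ncol(report$witness) == 0) return(0)
    row <- report$witness[r, ]
    row[which.max(abs(row))]
  }, numeric(1))
  df <- data.frame(reaction_id = rxns,
                   status = ifelse(rxns %in% report$blocked, "blocked",
                                   "consistent"),
                   witness_flux = wit)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
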