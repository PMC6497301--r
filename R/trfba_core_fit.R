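#' Fit a context-specific metabolic model from expression data
#'
#' The full reconstruction pipeline for one sample:
#' \enumerate{
#'   \item apply the growth medium (if any) to the general model;
#'   \item locate the breaking point \code{C_brk} where the expression
#'     constraints stop limiting growth, and sweep the scaling constant C
#'     over [0, C_brk] with parsimonious-FBA fluxes and the per-gene QP
#'     slack stage at each step;
#'   \item identify growth-correlated reactions (strong sign-agnostic
#'     Spearman correlation between flux and predicted growth along the
#'     sweep, FDR-adjusted);
#'   \item feed that set as the core to the functionality-preserving
#'     FASTCORE variant ([fastcormics_modified()]) to extract a functional
#'     context model;
#'   \item calibrate C: with measured growth supplied, the growth-calibrated
#'     \code{C_opt = C_brk/G_max * G_measured}; otherwise the
#'     slack-consistency point \code{C_corr} (first sudden change in the
#'     near-zero-slack count series);
#'   \item constrain the extracted model with the expression bounds at the
#'     chosen C and predict growth.
#' }
#'
#' @param model a \code{metabolic_model} (the general input model).
#' @param expr one sample's named nonnegative expression vector.
#' @param medium optional \code{medium_spec}, applied before everything else.
#' @param growth_measured optional measured growth rate (hr^-1); switches
#'   calibration from C_corr to C_opt.
#' @param states optional gene activity states (from
#'   [discretize_expression()]) used to mark non-penalized reactions during
#'   extraction.
#' @param n_steps C-grid size for the sweep (default 500).
#' @param config a [default_config()] list carrying every other threshold.
#' @return an object of class \code{trfba_core}, with methods
#'   \code{print}, \code{summary}, \code{coef} (the calibrated constants),
#'   \code{predict} (growth at an arbitrary C) and \code{plot} (growth and
#'   slack-consistency profiles along the sweep).
#' @examples
#' \donttest{
#' fx <- make_fixture(fixture_spec(seed = 1, n_samples = 3))
#' fit <- trfba_core(fx$model, fx$expression[, 1],
#'                   growth_measured = fx$phenotype$growth[1], n_steps = 40)
#' coef(fit)
#' }
#' @export
trfba_core <- function(model, expr, medium = NULL, growth_measured = NULL,
                       states = NULL, n_steps = config$n_steps,
                       slacks = NULL, config = default_config()) {
  cl <- match.call()
  validate_model(model)
  if (!is.null(medium)) model <- apply_medium(model, medium)
  # the slack QP stage is only needed to calibrate C_corr; with measured
  # growth supplied the cheaper C_opt route is used
  if (is.null(slacks)) slacks <- is.null(growth_measured)

  cb <- find_c_brk(model, expr, tol = config$c_brk_tol,
                   rel_width = config$c_brk_rel_width)
  sw <- sweep_c(model, expr, n_steps = n_steps,
                slacks = slacks, slack_threshold = config$slack_threshold,
                c_brk = cb)
  gc <- growth_correlated_reactions(sw, rho_min = config$rho_min,
                                    alpha_fdr = config$alpha_fdr)
  if (nrow(gc) == 0)
    stop("pipeline stage growth_correlated_reactions: no reaction passed ",
         "the correlation filter")
  ctx <- tryCatch(
    fastcormics_modified(model, core = gc$reaction_id, states = states,
                         epsilon = config$epsilon),
    error = function(e) stop("pipeline stage extraction: ",
                             conditionMessage(e)))

  c_corr <- if (is.null(sw$n_alpha)) NA_real_ else tryCatch(
    detect_c_corr(sw$n_alpha, sw$c_grid,
                  which = config$changepoint_which)$C_corr,
    error = function(e) NA_real_)
  c_opt <- if (!is.null(growth_measured))
    compute_c_opt(cb$C_brk, cb$G_max, growth_measured) else NA_real_
  C_used <- if (!is.null(growth_measured)) c_opt else c_corr
  if (is.na(C_used))
    stop("pipeline stage calibration: no change point detected and no ",
         "measured growth supplied; pass growth_measured or choose C manually")

  tm_ctx <- build_trfba_model(ctx, expr, C = C_used)
  g_pred <- trfba_growth(tm_ctx)
  ctx$C_used <- C_used

  structure(list(
    context = ctx,
    sweep = sw,
    core = gc,
    C_brk = cb$C_brk, G_max = cb$G_max,
    C_corr = c_corr, C_opt = c_opt, C_used = C_used,
    growth_measured = if (is.null(growth_measured)) NA_real_
                      else growth_measured,
    growth_predicted = g_pred,
    expr_used = expr,
    config = config,
    call = cl), class = "trfba_core")
}

#' @export
print.trfba_core <- function(x, ...) {
  cat("Context-specific reconstruction (expression-constrained C sweep)\n")
  cat(sprintf("  parent: %s -> context: %d reactions (%d growth-correlated core)\n",
              x$context$parent_id, length(x$context$reaction_ids),
              nrow(x$core)))
  cat(sprintf("  C_brk %.4g, G_max %.4g; C_used %.4g (%s)\n",
              x$C_brk, x$G_max, x$C_used,
              if (!is.na(x$growth_measured)) "C_opt, growth-calibrated"
              else "C_corr, slack-consistency"))
  cat(sprintf("  predicted growth %.4g", x$growth_predicted))
  if (!is.na(x$growth_measured))
    cat(sprintf(" (measured %.4g)", x$growth_measured))
  cat("\n")
  invisible(x)
}

#' @export
summary.trfba_core <- function(object, ...) {
  out <- list(
    coef = coef(object),
    n_core = nrow(object$core),
    n_context = length(object$context$reaction_ids),
    n_parent = NA_integer_,
    growth_predicted = object$growth_predicted,
    growth_measured = object$growth_measured,
    relative_error = if (is.na(object$growth_measured)) NA_real_ else
      growth_error(object$growth_measured, object$growth_predicted),
    sweep_steps = length(object$sweep$c_grid))
  class(out) <- "summary.trfba_core"
  out
}

#' @export
print.summary.trfba_core <- function(x, ...) {
  cat("Calibrated constants:\n")
  print(x$coef)
  cat(sprintf("core %d reactions; context %d reactions; sweep %d steps\n",
              x$n_core, x$n_context, x$sweep_steps))
  cat(sprintf("predicted growth %.4g", x$growth_predicted))
  if (!is.na(x$growth_measured))
    cat(sprintf("; measured %.4g (relative error %.3g)",
                x$growth_measured, x$relative_error))
  cat("\n")
  invisible(x)
}

#' @export
coef.trfba_core <- function(object, ...) {
  c(C_brk = object$C_brk, G_max = object$G_max,
    C_corr = object$C_corr, C_opt = object$C_opt, C_used = object$C_used)
}

#' Predict growth at a scaling constant
#'
#' Re-solves the expression-constrained FBA on the extracted context model
#' (default) or the parent sweep model at the requested C.
#'
#' @param object a \code{trfba_core} fit.
#' @param C scaling constant (defaults to the calibrated \code{C_used}).
#' @param newdata optional replacement expression vector.
#' @param ... unused.
#' @return predicted growth rate (hr^-1).
#' @export
predict.trfba_core <- function(object, C = object$C_used, newdata = NULL,
                               ...) {
  expr <- if (is.null(newdata)) object$expr_used else newdata
  trfba_growth(build_trfba_model(object$context, expr, C = C))
}

#' @export
plot.trfba_core <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$sweep$c_grid, x$sweep$growth, type = "l",
                 xlab = "C", ylab = "predicted growth (1/hr)",
                 main = "growth vs C")
  graphics::abline(v = x$C_used, lty = 2)
  if (!is.null(x$sweep$n_alpha)) {
    graphics::plot(x$sweep$c_grid, x$sweep$n_alpha, type = "s",
                   xlab = "C", ylab = expression(N[alpha]),
                   main = "slack consistency")
    if (!is.na(x$C_corr)) graphics::abline(v = x$C_corr, lty = 2)
  }
  invisible(x)
}
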