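# Panel-level benchmark runner: applies each plugin to every sample of a
# fixture panel and fills the methods x 9 raw-statistic matrix consumed by
# score_methods().  Benchmarks, in the fixed column order:
#   1 growth rate            (mean relative error; lower better)
#   2 uptake/secretion rates (mean Spearman rho vs measured; higher better)
#   3 drug response          (mean Spearman rho vs IC50; higher better)
#   4 essential genes        (rank combination of mean -log10 enrichment p
#                             and fraction of significant samples; higher)
#   5 OG/TS enrichment       (rank combination of OG fold up, TS fold down)
#   6 blocked fraction       (mean over sample models; lower better)
#   7 resolution power       (within- minus between-type Jaccard; higher;
#                             subnetwork methods only)
#   8 robustness to missing data (extractors: -log10 pooled recovery p;
#                             bound-setters: -growth CV; higher better)
#   9 robustness to noise    (Spearman between noise level and growth
#                             deviation; higher better)

BENCHMARK_LABELS <- c("growth", "exchange", "drug", "essential", "og_ts",
                      "blocked", "resolution", "cv", "noise")
BENCHMARK_DIRECTION <- c(-1, 1, 1, 1, 1, -1, 1, 1, 1)

#' Run the benchmark panel for a set of method plugins
#'
#' Evaluates each plugin on every sample of a fixture set and assembles the
#' 9-benchmark raw matrix plus the rank-normalized score matrix and linkage
#' tree.  Partial failures (a plugin erroring on a sample or lacking a
#' capability) score 0 on the affected benchmark and are flagged, not fatal.
#'
#' @param plugins list of \code{method_plugin} objects.
#' @param fx a fixture set from [make_fixture()] (or a list with the same
#'   shape: \code{model}, \code{expression}, \code{phenotype}).
#' @param types sample type labels for resolution power; two alternating
#'   groups by default.
#' @param config a [default_config()].
#' @param n_noise_sets,cv_repeats sizes of the robustness analyses.
#' @return a \code{benchmark_report} (see [score_methods()]) with the
#'   per-method details in \code{$details}.
#' @export
run_benchmarks <- function(plugins, fx, types = NULL,
                           config = default_config(),
                           n_noise_sets = 20, cv_repeats = 15) {
  labels <- vapply(plugins, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("plugin labels must be unique")
  model <- fx$model; panel <- fx$expression; ph <- fx$phenotype
  ns <- ncol(panel)
  if (is.null(types)) types <- rep_len(c("typeA", "typeB"), ns)
  raw <- matrix(NA_real_, length(plugins), 9,
                dimnames = list(labels, BENCHMARK_LABELS))
  details <- list()
  ess_meta <- list(); ogts_meta <- list()

  for (pi in seq_along(plugins)) {
    pl <- plugins[[pi]]
    runs <- lapply(seq_len(ns), function(s) {
      tryCatch(pl$fn(model, panel[, s], NULL,
                     list(growth = unname(ph$growth[s]))),
               error = function(e) NULL)
    })
    ok <- !vapply(runs, is.null, logical(1))
    det <- list(failed_samples = sum(!ok))

    # 1: growth error
    gp <- vapply(runs, function(r) if (is.null(r)) NA_real_ else r$growth,
                 numeric(1))
    err <- growth_error(ph$growth[ok & !is.na(gp)], gp[ok & !is.na(gp)])
    raw[pi, "growth"] <- if (length(err)) mean(err) else NA_real_

    # 2: exchange-rate prediction (per metabolite across samples)
    ex <- rownames(ph$exchange_rates)
    rho_ex <- vapply(ex, function(e) {
      pred <- vapply(seq_len(ns), function(s) {
        r <- runs[[s]]
        if (is.null(r) || !e %in% r$model$exchange_ids ||
            is.na(r$model$objective_id)) return(NA_real_)
        tryCatch(predict_exchange_rate(r$model, e,
                                       config$growth_fraction),
                 error = function(err) NA_real_)
      }, numeric(1))
      # measured uptake (positive magnitude) mapped to the model's sign
      # convention (uptake = negative flux) before correlating
      meas <- -convert_uptake_rate(ph$exchange_rates[e, ], ph$cell_volume,
                                   config$volume_coefficient)
      if (sum(is.finite(pred)) < 3 || stats::sd(meas) == 0 ||
          stats::sd(pred, na.rm = TRUE) == 0) return(NA_real_)
      correlate(pred, meas)$rho
    }, numeric(1))
    raw[pi, "exchange"] <- if (any(is.finite(rho_ex)))
      mean(rho_ex, na.rm = TRUE) else NA_real_

    # 3: drug response: per-drug target capacity (sample-averaged) against
    # measured IC50; the fixture plants IC50 inversely rank-related to
    # capacity, so the benchmark statistic is the negated Spearman rho
    # (higher = better recovery of the planted order)
    cap <- vapply(seq_len(nrow(ph$drugs)), function(d) {
      tgt <- ph$drugs$target_reaction[d]
      v <- vapply(which(ok), function(s)
        simulate_drug_response(runs[[s]]$model, tgt,
                               config$biomass_fraction), numeric(1))
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    raw[pi, "drug"] <- if (sum(is.finite(cap)) >= 3)
      -correlate(cap, ph$drugs$ic50)$rho else NA_real_

    # 4: essential genes (per-sample enrichment of predictions in truth)
    pvals <- vapply(which(ok), function(s) {
      r <- runs[[s]]
      if (is.na(r$model$objective_id)) return(NA_real_)
      pred <- tryCatch(
        essential_genes(r$model, config$essentiality_threshold),
        error = function(e) character(0))
      if (length(pred) == 0) return(NA_real_)
      hypergeom_enrichment(length(intersect(pred, ph$essential)),
                           length(pred),
                           length(intersect(ph$essential, model$gene_ids)),
                           length(model$gene_ids), "right")
    }, numeric(1))
    ess_meta[[pi]] <- list(
      mean_neglogp = if (any(is.finite(pvals)))
        mean(-log10(pmax(pvals, 1e-300)), na.rm = TRUE) else NA_real_,
      frac_sig = if (any(is.finite(pvals)))
        mean(pvals < config$alpha_fdr, na.rm = TRUE) else NA_real_)

    # 5: OG/TS enrichment of the context models' gene content
    folds <- lapply(runs[ok], function(r) {
      genes <- r$model$gene_ids
      if (length(genes) == 0) return(NULL)
      list(og = og_ts_fold_enrichment(genes, ph$og, model$gene_ids,
                                      "right")$fold,
           ts = og_ts_fold_enrichment(genes, ph$ts, model$gene_ids,
                                      "left")$fold)
    })
    folds <- folds[!vapply(folds, is.null, logical(1))]
    ogts_meta[[pi]] <- list(
      og = if (length(folds)) mean(vapply(folds, `[[`, numeric(1), "og"),
                                   na.rm = TRUE) else NA_real_,
      ts = if (length(folds)) mean(vapply(folds, `[[`, numeric(1), "ts"),
                                   na.rm = TRUE) else NA_real_)

    # 6: blocked fraction of the produced models (unconstrained state)
    bf <- vapply(runs[ok], function(r)
      tryCatch(blocked_fraction(r$model, epsilon = config$epsilon,
                                open_bound = config$open_bound),
               error = function(e) NA_real_), numeric(1))
    raw[pi, "blocked"] <- if (any(is.finite(bf))) mean(bf, na.rm = TRUE)
    else NA_real_

    # 7: resolution power (subnetwork methods only)
    if (pl$produces_subnetwork && sum(ok) >= 2) {
      sets <- lapply(runs[ok], function(r) r$model$reaction_ids)
      raw[pi, "resolution"] <- resolution_power(sets, types[ok])$score
    }

    # 8: robustness to missing data
    cvres <- tryCatch({
      if (pl$produces_subnetwork) {
        core0 <- runs[[which(ok)[1]]]$model$reaction_ids
        cv <- cross_validate(
          method_plugin(pl$label, function(model, expr, medium, phenotype) {
            cm <- fastcormics_modified(model, phenotype$core)
            list(model = cm, growth = fba_growth_or_na(cm))
          }),
          model, panel[, which(ok)[1]],
          core = setdiff(core0, model$exchange_ids),
          k = 5, repeats = cv_repeats, mode = "core",
          seed = config$seed)
        -log10(pmax(cv$pooled_recovery_p, 1e-300))
      } else {
        cv <- cross_validate(pl, model, panel[, which(ok)[1]],
                             k = 5, repeats = cv_repeats,
                             mode = "expression", seed = config$seed)
        -cv$growth_cv
      }
    }, error = function(e) NA_real_)
    raw[pi, "cv"] <- cvres

    # 9: robustness to noise: growth deviation should track the noise level
    nz <- noise_series(panel[, which(ok)[1]], n_sets = n_noise_sets,
                       seed = config$seed)
    gnoise <- vapply(nz$profiles, function(e) {
      r <- tryCatch(pl$fn(model, e, NULL,
                          list(growth = unname(ph$growth[which(ok)[1]]))),
                    error = function(err) NULL)
      if (is.null(r)) NA_real_ else r$growth
    }, numeric(1))
    g0 <- gnoise[length(gnoise)]     # the original profile
    dev <- abs(gnoise - g0)
    raw[pi, "noise"] <- if (sum(is.finite(dev)) >= 3 &&
                            stats::sd(dev, na.rm = TRUE) > 0)
      -correlate(dev[is.finite(dev)],
                 nz$achieved_r[is.finite(dev)])$rho else 0
    details[[labels[pi]]] <- det
  }

  # benchmarks 4 and 5 combine two summaries by rank across methods
  raw[, "essential"] <- rank_combine(
    vapply(ess_meta, `[[`, numeric(1), "mean_neglogp"),
    vapply(ess_meta, `[[`, numeric(1), "frac_sig"))
  raw[, "og_ts"] <- rank_combine(
    vapply(ogts_meta, `[[`, numeric(1), "og"),
    -vapply(ogts_meta, `[[`, numeric(1), "ts"))

  rep <- score_methods(raw, BENCHMARK_DIRECTION)
  rep$details <- details
  rep
}

rank_combine <- function(a, b) {
  ra <- rank(a, na.last = FALSE); rb <- rank(b, na.last = FALSE)
  out <- ra + rb
  out[is.na(a) & is.na(b)] <- NA_real_
  out
}

fba_growth_or_na <- function(model) {
  if (is.na(model$objective_id)) return(NA_real_)
  sol <- fba(model)
  if (sol$status != "optimal") NA_real_ else sol$objective_value
}
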