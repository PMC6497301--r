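# Benchmark harness: five comparison tests (growth, exchange rates, drug
# response, essential genes, OG/TS/LOF enrichment), four consistency tests
# (blocked fraction, resolution power, robustness to missing data, robustness
# to noise), a rank-based scoring matrix and hierarchical clustering of
# methods.

#' Relative growth-prediction error
#'
#' \deqn{e = |growth_{exp} - growth_{pred}| / growth_{exp}}
#'
#' @param growth_exp observed growth rate (> 0).
#' @param growth_pred predicted growth rate.
#' @return relative error (vectorized).
#' @export
growth_error <- function(growth_exp, growth_pred) {
  if (any(growth_exp <= 0)) stop("observed growth must be > 0")
  abs(growth_exp - growth_pred) / growth_exp
}

#' Predicted uptake/secretion rate of an exchange reaction
#'
#' Maximizes the exchange flux while holding biomass at a fraction of its
#' optimum (default 90\%).  When the model was constrained with a
#' cell-specific medium, pass \code{reset_bound} (the general-medium uptake
#' magnitude) so the tested exchange's own measured bound does not constrain
#' its prediction.
#'
#' @param model a \code{metabolic_model} with positive growth.
#' @param exchange_id exchange reaction to predict.
#' @param growth_fraction fraction of maximal growth to maintain.
#' @param reset_bound optional general-medium uptake magnitude used to reset
#'   the tested exchange's lower bound before predicting.
#' @return predicted flux (negative = uptake, positive = secretion).
#' @export
predict_exchange_rate <- function(model, exchange_id, growth_fraction = 0.9,
                                  reset_bound = NULL) {
  if (!exchange_id %in% model$exchange_ids)
    stop(sQuote(exchange_id), " is not an exchange reaction")
  if (!is.null(reset_bound)) model$lb[exchange_id] <- -abs(reset_bound)
  wt <- fba(model)
  if (wt$status != "optimal" || wt$objective_value <= 0)
    stop("model must grow to predict exchange rates")
  n <- length(model$reaction_ids)
  row <- numeric(n)
  row[match(model$objective_id, model$reaction_ids)] <- -1
  sol <- fba(model, exchange_id, "max",
             extra_ineq = matrix(row, 1),
             extra_rhs = -growth_fraction * wt$objective_value)
  sol$objective_value
}

#' Spearman correlation with FDR adjustment over a batch
#'
#' For a single pair of vectors returns the exact-rank Spearman coefficient
#' (midranks for ties) and its p-value.  For matrices (one column per
#' metabolite/drug tested together) the p-values are Benjamini-Hochberg
#' adjusted across the batch.
#'
#' @param pred,meas numeric vectors (>= 3 paired finite values) or matrices
#'   with matching columns.
#' @return data.frame with columns \code{rho}, \code{p} and (for batches)
#'   \code{q}.
#' @export
correlate <- function(pred, meas) {
  if (is.matrix(pred)) {
    stopifnot(is.matrix(meas), ncol(pred) == ncol(meas))
    out <- do.call(rbind, lapply(seq_len(ncol(pred)), function(j)
      correlate(pred[, j], meas[, j])))
    out$q <- stats::p.adjust(out$p, method = "BH")
    rownames(out) <- colnames(pred)
    return(out)
  }
  ok <- is.finite(pred) & is.finite(meas)
  if (sum(ok) < 3) stop("need at least 3 paired finite values")
  ct <- suppressWarnings(stats::cor.test(pred[ok], meas[ok],
                                         method = "spearman"))
  data.frame(rho = unname(ct$estimate), p = ct$p.value)
}

#' Proxy drug-response statistic
#'
#' Maximal flux through the drug's target reaction with biomass bounded to a
#' fraction (default 50\%) of its optimum.  A target absent from the model, or
#' an infeasible bound, is reported as \code{NA} (non-predictable) rather than
#' an error, so panel-level correlations can skip it.  The statistic is
#' correlated against measured IC50 without sign flipping.
#'
#' @param model a \code{metabolic_model}.
#' @param target_reaction the drug's target reaction id.
#' @param biomass_fraction fraction of maximal growth fixed during the
#'   simulation.
#' @return predicted flux, or \code{NA} if non-predictable.
#' @export
simulate_drug_response <- function(model, target_reaction,
                                   biomass_fraction = 0.5) {
  if (!target_reaction %in% model$reaction_ids) return(NA_real_)
  wt <- fba(model)
  if (wt$status != "optimal" || wt$objective_value <= 0) return(NA_real_)
  n <- length(model$reaction_ids)
  iobj <- match(model$objective_id, model$reaction_ids)
  target <- biomass_fraction * wt$objective_value
  # pin biomass to the fraction of its optimum from both sides
  rows <- matrix(0, 2, n)
  rows[1, iobj] <- -1; rows[2, iobj] <- 1
  sol <- fba(model, target_reaction, "max",
             extra_ineq = rows,
             extra_rhs = c(-target * (1 - 1e-9), target * (1 + 1e-9)))
  if (sol$status != "optimal") return(NA_real_)
  sol$objective_value
}

#' Exact hypergeometric enrichment test
#'
#' Tail probability of drawing \code{hits_in_selection} annotated items in a
#' selection of \code{selection_size} from a universe of \code{universe_size}
#' containing \code{hits_in_universe} annotated items.
#'
#' @param hits_in_selection,selection_size,hits_in_universe,universe_size
#'   nonnegative integer counts, \code{k <= n <= N}, \code{K <= N}.
#' @param tail \code{"right"} (enrichment, \eqn{P(X \ge k)}) or \code{"left"}
#'   (depletion, \eqn{P(X \le k)}).
#' @return p-value.
#' @examples
#' hypergeom_enrichment(4, 4, 5, 10)   # 1/42
#' @export
hypergeom_enrichment <- function(hits_in_selection, selection_size,
                                 hits_in_universe, universe_size,
                                 tail = c("right", "left")) {
  tail <- match.arg(tail)
  k <- hits_in_selection; n <- selection_size
  K <- hits_in_universe; N <- universe_size
  if (k < 0 || k > n || n > N || K > N || k > K)
    stop("inconsistent hypergeometric counts")
  if (tail == "right")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  else
    stats::phyper(k, K, N - K, n, lower.tail = TRUE)
}

#' Fold enrichment of annotated genes in a predicted gene set
#'
#' The fraction of annotated genes among the predicted set divided by the
#' fraction among all model genes, with hypergeometric significance (right
#' tail for oncogene-style enrichment, left tail for tumor-suppressor/LOF
#' depletion).
#'
#' @param predicted_genes genes in the context model under evaluation
#'   (subset of \code{model_genes}).
#' @param annotated_set annotated genes (OG or TS/LOF list).
#' @param model_genes all genes of the input general model.
#' @param tail passed to [hypergeom_enrichment()].
#' @return list with \code{fold} and \code{p}; \code{fold} is \code{NA} for
#'   an empty predicted set.
#' @export
og_ts_fold_enrichment <- function(predicted_genes, annotated_set, model_genes,
                                  tail = c("right", "left")) {
  tail <- match.arg(tail)
  if (length(setdiff(predicted_genes, model_genes)))
    stop("predicted genes must be a subset of the model genes")
  ann_model <- intersect(annotated_set, model_genes)
  if (length(ann_model) == 0) stop("no annotated genes in the model")
  if (length(predicted_genes) == 0)
    return(list(fold = NA_real_, p = NA_real_))
  hits <- length(intersect(predicted_genes, ann_model))
  fold <- (hits / length(predicted_genes)) /
    (length(ann_model) / length(model_genes))
  p <- hypergeom_enrichment(hits, length(predicted_genes),
                            length(ann_model), length(model_genes), tail)
  list(fold = fold, p = p)
}

#' Jaccard similarity of two reaction sets
#'
#' \eqn{|A \cap B| / |A \cup B|}; two empty sets are defined as identical
#' (index 1) with a warning.
#'
#' @param setA,setB character vectors.
#' @return number in [0, 1].
#' @export
jaccard <- function(setA, setB) {
  u <- union(setA, setB)
  if (length(u) == 0) {
    warning("both sets empty; Jaccard index defined as 1")
    return(1)
  }
  length(intersect(setA, setB)) / length(u)
}

#' Resolution power of a set of context models
#'
#' Mean within-type pairwise Jaccard minus mean between-type pairwise
#' Jaccard of the models' reaction sets: a method that produces similar
#' models within a cancer type and distinct models across types scores high.
#'
#' @param sets named list of reaction-id sets (one per sample model).
#' @param types character vector of type labels matching \code{sets}.
#' @return list with \code{score}, \code{within}, \code{between}.
#' @export
resolution_power <- function(sets, types) {
  stopifnot(length(sets) == length(types), length(sets) >= 2)
  win <- c(); btw <- c()
  for (i in seq_along(sets)[-length(sets)]) {
    for (j in (i + 1):length(sets)) {
      jc <- jaccard(sets[[i]], sets[[j]])
      if (types[i] == types[j]) win <- c(win, jc) else btw <- c(btw, jc)
    }
  }
  w <- if (length(win)) mean(win) else NA_real_
  b <- if (length(btw)) mean(btw) else NA_real_
  list(score = w - b, within = w, between = b)
}

#' Method plugin for the benchmark harness
#'
#' A reconstruction method enters the harness through this contract: a
#' callable taking \code{(model, expr, medium, phenotype)} for one sample and
#' returning a list with \code{model} (the context or constrained model) and
#' \code{growth} (its predicted growth rate).  Capability flags say whether
#' the method extracts a subnetwork (needed for Jaccard-based tests) and
#' whether it requires phenotype data.
#'
#' @param label unique method label.
#' @param fn the callable.
#' @param produces_subnetwork,requires_phenotype capability flags.
#' @return an object of class \code{method_plugin}.
#' @export
method_plugin <- function(label, fn, produces_subnetwork = TRUE,
                          requires_phenotype = FALSE) {
  stopifnot(is.function(fn))
  structure(list(label = label, fn = fn,
                 produces_subnetwork = produces_subnetwork,
                 requires_phenotype = requires_phenotype),
            class = "method_plugin")
}

#' Built-in harness plugins
#'
#' \code{plugin_pfba()} keeps the (medium-constrained) general model and
#' predicts growth by parsimonious FBA: the baseline that uses no expression
#' data.  \code{plugin_trfba_core()} runs the full reconstruction pipeline
#' ([trfba_core()]).
#'
#' @param n_steps sweep grid size for the pipeline plugin (kept small in
#'   harness runs; the pipeline default is 500).
#' @return a \code{method_plugin}.
#' @export
plugin_pfba <- function() {
  method_plugin("pfba", function(model, expr, medium = NULL,
                                 phenotype = NULL) {
    m <- if (is.null(medium)) model else apply_medium(model, medium)
    sol <- pfba(m)
    list(model = m, growth = sol$objective_value)
  }, produces_subnetwork = FALSE)
}

#' @rdname plugin_pfba
#' @export
plugin_trfba_core <- function(n_steps = 60) {
  method_plugin("trfba_core", function(model, expr, medium = NULL,
                                       phenotype = NULL) {
    fit <- trfba_core(model, expr, medium = medium,
                      growth_measured = phenotype$growth,
                      n_steps = n_steps)
    list(model = fit$context, growth = fit$growth_predicted, fit = fit)
  }, produces_subnetwork = TRUE, requires_phenotype = FALSE)
}

#' Repeated k-fold cross-validation of a reconstruction method
#'
#' Removes a fraction of the method's input (core reactions for subnetwork
#' extractors, expression genes for bound-setting methods) in each fold and
#' measures how much of the removed input the method recovers in its output,
#' pooled into a hypergeometric recovery p-value.  For bound-setters the
#' variation of predicted growth across folds is recorded instead of
#' recovery.
#'
#' @param plugin a \code{method_plugin}, called as in the harness.
#' @param model parent \code{metabolic_model}.
#' @param expr one sample's named expression vector.
#' @param core input core reactions (removal target for extractors).
#' @param medium,phenotype passed through to the plugin.
#' @param k folds per repeat.
#' @param repeats number of repeats.
#' @param removal_fraction fraction removed per fold.
#' @param mode \code{"core"} or \code{"expression"}.
#' @param seed RNG seed.
#' @return an object of class \code{cv_report}: \code{n_models}
#'   (always \code{k * repeats}), per-fold table, pooled recovery p
#'   (\code{mode = "core"}), growth variation (\code{mode = "expression"}).
#' @export
cross_validate <- function(plugin, model, expr, core = NULL, medium = NULL,
                           phenotype = NULL, k = 5, repeats = 15,
                           removal_fraction = 0.2, mode = c("core", "expression"),
                           seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(plugin, "method_plugin"))
  if (mode == "core" && (is.null(core) || length(core) < k))
    stop("core-removal mode needs at least k input core reactions")
  pool <- if (mode == "core") core else names(expr)
  nrem <- max(1L, round(removal_fraction * length(pool)))
  set.seed(seed)
  rows <- list()
  for (r in seq_len(repeats)) {
    for (f in seq_len(k)) {
      removed <- sample(pool, nrem)
      if (mode == "core") {
        out <- tryCatch(
          plugin$fn(model, expr, medium, c(phenotype,
                                           list(core = setdiff(core, removed)))),
          error = function(e) NULL)
      } else {
        e2 <- expr[setdiff(names(expr), removed)]
        out <- tryCatch(plugin$fn(model, e2, medium, phenotype),
                        error = function(e) NULL)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_ = r, fold = f,
        failed = is.null(out),
        n_removed = nrem,
        n_recovered = if (is.null(out) || mode != "core") NA_integer_ else
          length(intersect(removed, out$model$reaction_ids)),
        model_size = if (is.null(out)) NA_integer_ else
          length(out$model$reaction_ids),
        growth = if (is.null(out)) NA_real_ else out$growth)
    }
  }
  folds <- do.call(rbind, rows)
  pooled_p <- NA_real_
  if (mode == "core") {
    ok <- !folds$failed
    hits <- sum(folds$n_recovered[ok])
    draws <- sum(folds$n_removed[ok])
    univ <- length(model$reaction_ids) * sum(ok)
    ann <- sum(folds$model_size[ok])
    if (sum(ok) > 0 && ann > 0)
      pooled_p <- hypergeom_enrichment(hits, draws,
                                       min(ann, univ), univ, "right")
  }
  g <- folds$growth[!is.na(folds$growth)]
  structure(list(n_models = as.integer(k) * as.integer(repeats),
                 folds = folds,
                 pooled_recovery_p = pooled_p,
                 growth_cv = if (length(g) > 1 && mean(g) > 0)
                   stats::sd(g) / mean(g) else NA_real_,
                 mode = mode),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d models (%s removal); pooled recovery p = %s; growth CV = %s\n",
              x$n_models, x$mode, format(x$pooled_recovery_p),
              format(x$growth_cv)))
  invisible(x)
}

#' Distribution-preserving noise series for an expression profile
#'
#' Generates \code{n_sets} perturbed copies of an expression vector by
#' partially shuffling its values (every copy is an exact permutation, so the
#' value distribution is preserved), targeting approximately evenly spaced
#' Spearman correlations to the original from near 0 up to exactly 1 (the
#' last set is the original).  The achieved correlation of each set is
#' reported.
#'
#' @param expr named nonnegative expression vector (>= 20 genes).
#' @param n_sets number of perturbed profiles.
#' @param seed RNG seed.
#' @return list with \code{profiles} (list of named vectors) and
#'   \code{achieved_r} (decreasing in noise; \code{achieved_r[n_sets] == 1}).
#' @export
noise_series <- function(expr, n_sets = 20, seed = 1L) {
  n <- length(expr)
  stopifnot(n >= 20, !is.null(names(expr)))
  set.seed(seed)
  # candidate perturbations: several scramble patterns x all prefix lengths;
  # each candidate is an exact permutation of the values.  Retry patterns
  # whose full shuffle stays correlated so the series can reach ~0.
  n_pat <- 12L
  pats <- list()
  while (length(pats) < n_pat) {
    ord <- sample(n); rot <- sample(n)
    r_full <- stats::cor(expr, shuffle_prefix(expr, ord, rot, n),
                         method = "spearman")
    if (length(pats) > 0 || abs(r_full) < 0.1)
      pats[[length(pats) + 1L]] <- list(ord = ord, rot = rot)
  }
  cand <- do.call(rbind, lapply(seq_along(pats), function(pi) {
    r <- vapply(0:n, function(L)
      stats::cor(expr, shuffle_prefix(expr, pats[[pi]]$ord, pats[[pi]]$rot, L),
                 method = "spearman"), numeric(1))
    data.frame(pat = pi, L = 0:n, r = r)
  }))
  targets <- seq(1, 0, length.out = n_sets)
  pick <- integer(n_sets)
  prev_r <- Inf
  for (i in seq_len(n_sets)) {
    # keep the series monotone: only candidates at or below the previous level
    ok <- which(cand$r <= prev_r + 1e-12)
    pick[i] <- ok[which.min(abs(cand$r[ok] - targets[i]))]
    prev_r <- cand$r[pick[i]]
  }
  pick[1] <- which(cand$pat == 1 & cand$L == 0)   # target 1 -> the original
  profiles <- lapply(pick, function(k)
    shuffle_prefix(expr, pats[[cand$pat[k]]]$ord, pats[[cand$pat[k]]]$rot,
                   cand$L[k]))
  achieved <- cand$r[pick]
  # reported noisiest-first
  o <- order(achieved)
  list(profiles = profiles[o], achieved_r = achieved[o])
}

shuffle_prefix <- function(expr, ord, rot, L) {
  if (L < 2) return(expr)
  idx <- ord[seq_len(L)]
  perm <- rot[rot <= L]               # a fixed permutation of 1..L
  out <- expr
  out[idx] <- expr[idx[perm]]
  out
}

#' Score and cluster benchmarked methods
#'
#' Rank-normalizes each benchmark column to [0, 1] (direction-aware: the best
#' method gets 1 whether "best" means lowest error or highest enrichment),
#' then clusters the methods by average-linkage hierarchical clustering on
#' the Euclidean distance between score rows.
#'
#' @param raw numeric matrix, methods x benchmarks (rownames = method
#'   labels); \code{NA} means the benchmark was not attempted and scores 0.
#' @param direction vector of +1 (higher is better) / -1 (lower is better)
#'   per benchmark.
#' @return an object of class \code{benchmark_report}: \code{raw},
#'   \code{scores}, \code{tree} (an \code{hclust}, \code{NULL} for < 3
#'   methods), \code{flags} (logical matrix of missing entries).
#' @export
score_methods <- function(raw, direction = rep(1, ncol(raw))) {
  stopifnot(is.matrix(raw), nrow(raw) >= 2,
            length(direction) == ncol(raw))
  flags <- is.na(raw)
  scores <- raw
  for (j in seq_len(ncol(raw))) {
    x <- raw[, j] * direction[j]
    r <- rank(x, na.last = FALSE, ties.method = "average")
    sc <- if (max(r) == min(r)) rep(0.5, length(r)) else
      (r - min(r)) / (max(r) - min(r))
    sc[is.na(raw[, j])] <- 0
    scores[, j] <- sc
  }
  if (all(apply(scores, 2, function(s) length(unique(s)) == 1)))
    warning("all methods scored identically; clustering is degenerate")
  tree <- if (nrow(scores) >= 3)
    stats::hclust(stats::dist(scores, method = "euclidean"),
                  method = "average") else NULL
  structure(list(raw = raw, scores = scores, tree = tree, flags = flags),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> %d methods x %d benchmarks\n",
              nrow(x$scores), ncol(x$scores)))
  print(round(x$scores, 3))
  invisible(x)
}

#' Serialize a benchmark report
#'
#' Scores go to \code{scores.tsv}, details (raw statistics and flags) to
#' \code{details.json}, and the method linkage tree to \code{tree.nwk}
#' (Newick).
#'
#' @param report a \code{benchmark_report}.
#' @param dir output directory (created if needed).
#' @export
write_benchmark_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(method = rownames(report$scores), report$scores,
                   check.names = FALSE)
  utils::write.table(df, file.path(dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(raw = as.data.frame(report$raw),
                            methods = rownames(report$raw),
                            missing = as.data.frame(report$flags)),
                       file.path(dir, "details.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$tree)) {
    phy <- ape::as.phylo(report$tree)
    ape::write.tree(phy, file.path(dir, "tree.nwk"))
  }
  invisible(dir)
}
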