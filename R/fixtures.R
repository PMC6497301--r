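# Deterministic synthetic fixtures: toy flux-consistent networks with GPRs
# and a biomass reaction, correlated expression panels with a planted
# growth-limiting gene per sample, and phenotype tables generated from
# planted ground truth.  Everything is a pure function of the fixture
# specification, so the same spec reproduces byte-identical fixtures.

#' Fixture specification
#'
#' @param seed RNG seed (all fixture randomness flows from it).
#' @param n_pathways number of parallel pathways between substrate and
#'   biomass precursor.
#' @param pathway_length reactions per pathway.
#' @param frac_gene_associated fraction of internal pathway reactions
#'   carrying a GPR.
#' @param n_samples expression-panel size.
#' @param cor_target target mean pairwise Spearman correlation between
#'   samples (the high-correlation regime of real cell-line panels).
#' @param n_blocked planted dead-end (blocked) reactions.
#' @param uptake_max substrate uptake bound (mmol gDW^-1 hr^-1).
#' @param reversible_fraction fraction of pathway reactions made reversible.
#' @param cell_volume planted cell volume (fL cell^-1) for exchange-rate
#'   back-conversion.
#' @param essential_noise number of spurious genes added to the phenotype
#'   essential-gene list.
#' @return a list of class \code{fixture_spec}.
#' @export
fixture_spec <- function(seed = 1L, n_pathways = 2L, pathway_length = 3L,
                         frac_gene_associated = 0.8, n_samples = 20L,
                         cor_target = 0.9, n_blocked = 0L, uptake_max = 10,
                         reversible_fraction = 0.25, cell_volume = 430,
                         essential_noise = 0L) {
  stopifnot(n_pathways >= 1, pathway_length >= 1, n_samples >= 1,
            cor_target > 0, cor_target <= 1)
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a toy metabolic model with planted structure
#'
#' Builds a flux-consistent network: one substrate exchange, a shared
#' gene-associated transport step (the planted growth bottleneck), parallel
#' linear pathways with mixed AND/OR GPRs feeding a biomass reaction, and a
#' secretion exchange.  Optionally a planted set of dead-end reactions of
#' known identity (the blocked-set ground truth).
#'
#' @param spec a [fixture_spec()].
#' @return a \code{metabolic_model}; the planted truth is attached as
#'   attributes \code{blocked_truth} (reaction ids) and
#'   \code{bottleneck_gene}.
#' @export
make_toy_model <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  P <- spec$n_pathways; L <- spec$pathway_length
  mets <- c("sub_e", "sub_c", "bm_pre", "bm_e")
  rxn <- list()  # each: id, mets (named coefs), lb, ub, gpr
  add <- function(id, coefs, lb, ub, gpr = "")
    rxn[[length(rxn) + 1L]] <<- list(id = id, coefs = coefs, lb = lb,
                                     ub = ub, gpr = gpr)
  add("EX_sub", c(sub_e = -1), -spec$uptake_max, 1000)
  add("T0", c(sub_e = -1, sub_c = 1), 0, 1000, gpr = "gT0")
  gidx <- 0L
  for (p in seq_len(P)) {
    prev <- "sub_c"
    for (l in seq_len(L)) {
      mid <- if (l == L) "bm_pre" else sprintf("m_%d_%d", p, l)
      if (!mid %in% mets) mets <- c(mets, mid)
      gpr <- ""
      if (stats::runif(1) < spec$frac_gene_associated) {
        gidx <- gidx + 1L
        kind <- sample(c("single", "or", "and"), 1,
                       prob = c(0.5, 0.3, 0.2))
        if (kind == "single") {
          gpr <- sprintf("g%d", gidx)
        } else {
          gidx <- gidx + 1L
          op <- if (kind == "or") "or" else "and"
          gpr <- sprintf("(g%d %s g%d)", gidx - 1L, op, gidx)
        }
      }
      rev <- stats::runif(1) < spec$reversible_fraction
      add(sprintf("R_%d_%d", p, l), stats::setNames(c(-1, 1), c(prev, mid)),
          if (rev) -1000 else 0, 1000, gpr = gpr)
      prev <- mid
    }
  }
  add("BIOMASS", c(bm_pre = -1, bm_e = 1), 0, 1000)
  add("EX_bm", c(bm_e = -1), 0, 1000)
  blocked <- character(0)
  if (spec$n_blocked > 0) {
    for (b in seq_len(spec$n_blocked)) {
      dm <- sprintf("dead_%d", b)
      mets <- c(mets, dm)
      id <- sprintf("D_%d", b)
      add(id, stats::setNames(c(-1, 1), c("sub_c", dm)), 0, 1000)
      blocked <- c(blocked, id)
    }
  }
  ids <- vapply(rxn, `[[`, character(1), "id")
  S <- matrix(0, length(mets), length(rxn), dimnames = list(mets, ids))
  for (r in rxn) S[names(r$coefs), r$id] <- r$coefs
  m <- metabolic_model(
    S = S,
    lb = vapply(rxn, `[[`, numeric(1), "lb"),
    ub = vapply(rxn, `[[`, numeric(1), "ub"),
    gpr = vapply(rxn, `[[`, character(1), "gpr"),
    objective_id = "BIOMASS",
    id = sprintf("toy_seed%d", spec$seed))
  attr(m, "blocked_truth") <- blocked
  attr(m, "bottleneck_gene") <- "gT0"
  m
}

#' Generate a correlated expression panel with planted bottlenecks
#'
#' Each gene gets a shared baseline; samples are noisy copies of the
#' baseline, with the noise level calibrated so the mean pairwise Spearman
#' correlation between samples lands within 0.05 of the target.  The planted
#' growth-limiting gene receives a sample-specific low value far below every
#' other gene, so the expression bound on its reaction is the growth
#' bottleneck at small C.
#'
#' @param model a model from [make_toy_model()].
#' @param spec the same [fixture_spec()].
#' @return numeric matrix genes x samples; planted per-sample bottleneck
#'   expression as attribute \code{bottleneck_expr}; achieved mean pairwise
#'   Spearman as attribute \code{achieved_cor}.
#' @export
make_expression_panel <- function(model, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  genes <- model$gene_ids
  if (length(genes) == 0) stop("model has no genes")
  bkg <- attr(model, "bottleneck_gene")
  set.seed(spec$seed + 1000L)
  base <- stats::runif(length(genes), 20, 60)
  names(base) <- genes
  ns <- spec$n_samples
  # increasing with sample index, matching the planted C* order so growth
  # stays monotone in the planted constant
  bott <- seq(0.5, 2.5, length.out = ns)

  panel_at <- function(sdlog) {
    set.seed(spec$seed + 2000L)
    E <- vapply(seq_len(ns), function(s)
      base * stats::rlnorm(length(base), 0, sdlog), numeric(length(base)))
    E <- matrix(E, nrow = length(base),
                dimnames = list(genes, sprintf("S%02d", seq_len(ns))))
    if (!is.null(bkg) && bkg %in% genes) E[bkg, ] <- bott
    E
  }
  mean_cor <- function(E) {
    if (ncol(E) < 2) return(1)
    cc <- stats::cor(E, method = "spearman")
    mean(cc[upper.tri(cc)])
  }
  if (ns == 1) return(structure(panel_at(0.1), bottleneck_expr = bott,
                                achieved_cor = 1))
  lo <- 1e-3; hi <- 3
  for (it in 1:40) {
    mid <- sqrt(lo * hi)
    if (mean_cor(panel_at(mid)) > spec$cor_target) lo <- mid else hi <- mid
  }
  # few genes make the achievable correlations coarse; take the better
  # bracket endpoint
  sd_best <- if (abs(mean_cor(panel_at(lo)) - spec$cor_target) <=
                 abs(mean_cor(panel_at(hi)) - spec$cor_target)) lo else hi
  E <- panel_at(sd_best)
  ach <- mean_cor(E)
  if (abs(ach - spec$cor_target) > 0.05)
    stop(sprintf("cannot reach target correlation %.2f with %d genes (got %.2f)",
                 spec$cor_target, length(genes), ach))
  structure(E, bottleneck_expr = bott, achieved_cor = ach)
}

#' Generate phenotype tables from planted ground truth
#'
#' Measured growth is the model's own expression-constrained growth at a
#' planted per-sample scaling constant C*, so growth-calibration recovery is
#' exact by construction.  Exchange rates are back-converted through the
#' volume scaling with a planted cell volume (so re-conversion returns the
#' planted bound).  Essential genes come from exhaustive single-gene
#' deletion (plus optional labeled noise), drug targets from the biomass
#' path with IC50 inversely rank-related to target flux capacity, and OG/TS
#' gene sets are planted as growth-supporting vs dead-end genes.
#'
#' @param model a model from [make_toy_model()].
#' @param panel an expression panel from [make_expression_panel()].
#' @param spec the same [fixture_spec()].
#' @return a list of class \code{phenotype_data}: \code{growth} (named,
#'   hr^-1), \code{c_star} (planted constants), \code{exchange_rates}
#'   (fmol cell^-1 hr^-1, uptake positive), \code{cell_volume},
#'   \code{essential}, \code{drugs} (data.frame), \code{og}, \code{ts}.
#' @export
make_phenotypes <- function(model, panel, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  ns <- ncol(panel)
  set.seed(spec$seed + 3000L)
  c_star <- seq(0.5, 4, length.out = ns)
  growth <- vapply(seq_len(ns), function(s) {
    tm <- build_trfba_model(model, panel[, s], C = c_star[s])
    trfba_growth(tm)
  }, numeric(1))
  names(growth) <- names(c_star) <- colnames(panel)

  # measured per-cell exchange rates back-converted from the growth-linked
  # uptake flux at the planted C* (the chain stoichiometry ties substrate
  # uptake to growth one-to-one), so re-conversion recovers the planted flux
  ex <- setdiff(model$exchange_ids, "EX_bm")
  vol <- spec$cell_volume
  exchange_rates <- matrix(rep(growth, each = length(ex)) * vol / 4.3,
                           length(ex), ns,
                           dimnames = list(ex, colnames(panel)))

  ess <- essential_genes(model)
  if (spec$essential_noise > 0) {
    extra <- sample(setdiff(model$gene_ids, ess),
                    min(spec$essential_noise,
                        length(setdiff(model$gene_ids, ess))))
    ess <- c(ess, extra)
  }

  # drug targets on the biomass path; IC50 decreasing in flux capacity
  path <- names(which(abs(pfba(model)$fluxes) > 1e-6))
  targets <- utils::head(setdiff(path, model$exchange_ids), 3)
  fv <- vapply(targets, function(r) fba(model, r, "max")$objective_value,
               numeric(1))
  drugs <- data.frame(drug = sprintf("drug%d", seq_along(targets)),
                      target_reaction = targets,
                      ic50 = max(fv) + 1 - rank(fv),
                      stringsAsFactors = FALSE)

  live_genes <- unique(unlist(reaction_genes(model)[path]))
  og <- utils::head(live_genes, max(1L, length(live_genes) %/% 2L))
  dead <- setdiff(model$gene_ids, live_genes)
  ts <- if (length(dead)) dead else utils::tail(model$gene_ids, 1)

  structure(list(growth = growth, c_star = c_star,
                 exchange_rates = exchange_rates, cell_volume = vol,
                 essential = ess, drugs = drugs, og = og, ts = ts),
            class = "phenotype_data")
}

#' Generate a complete fixture set
#'
#' Convenience wrapper running [make_toy_model()],
#' [make_expression_panel()] and [make_phenotypes()] from one spec.
#'
#' @param spec a [fixture_spec()].
#' @return list with \code{model}, \code{expression}, \code{phenotype},
#'   \code{spec}.
#' @export
make_fixture <- function(spec = fixture_spec()) {
  model <- make_toy_model(spec)
  panel <- make_expression_panel(model, spec)
  phen <- make_phenotypes(model, panel, spec)
  list(model = model, expression = panel, phenotype = phen, spec = spec)
}

#' Write a fixture set to disk
#'
#' Model as JSON and SBML, expression as TSV, phenotypes as one TSV per
#' table.
#'
#' @param fx a fixture set from [make_fixture()].
#' @param dir output directory.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_model(fx$model, file.path(dir, "model.json"))
  write_model(fx$model, file.path(dir, "model.xml"), dialect = "sbml")
  write_expression_tsv(fx$expression, file.path(dir, "expression.tsv"))
  ph <- fx$phenotype
  utils::write.table(
    data.frame(sample = names(ph$growth), growth = ph$growth,
               c_star = ph$c_star),
    file.path(dir, "growth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(exchange_id = rownames(ph$exchange_rates),
               ph$exchange_rates, cell_volume = ph$cell_volume,
               check.names = FALSE),
    file.path(dir, "exchange_rates.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeLines(ph$essential, file.path(dir, "essential_genes.txt"))
  utils::write.table(ph$drugs, file.path(dir, "drugs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(ph$og, file.path(dir, "oncogenes.txt"))
  writeLines(ph$ts, file.path(dir, "tumor_suppressors.txt"))
  invisible(dir)
}
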