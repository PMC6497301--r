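#' Construct a genome-scale metabolic model
#'
#' The container at the base of every operation in the package: a
#' stoichiometric matrix, per-reaction flux bounds (mmol gDW^-1 hr^-1), GPR
#' rules, a biomass objective, and the derived exchange-reaction set.
#' Exchange reactions are detected structurally as the columns of S with a
#' single nonzero entry; by convention negative exchange flux is uptake and
#' positive flux is secretion.
#'
#' @param S numeric metabolite-by-reaction stoichiometric matrix.
#' @param lb,ub numeric lower/upper flux bounds, one per reaction.
#' @param reaction_ids,metabolite_ids character identifiers; taken from the
#'   dimnames of \code{S} when omitted.
#' @param gpr character vector of GPR rule strings (\code{""} for none), one
#'   per reaction.
#' @param gene_ids character vector of gene identifiers; defaults to the union
#'   of genes referenced by the rules.
#' @param objective_id identifier of the biomass (objective) reaction.
#' @param id optional model identifier.
#' @return an object of class \code{metabolic_model}.
#' @examples
#' m <- example_chain_model()
#' m
#' fba(m)$objective_value
#' @export
metabolic_model <- function(S, lb, ub, reaction_ids = colnames(S),
                            metabolite_ids = rownames(S),
                            gpr = rep("", ncol(S)), gene_ids = NULL,
                            objective_id, id = "model") {
  S <- as.matrix(S)
  n <- ncol(S)
  if (is.null(reaction_ids) || is.null(metabolite_ids))
    stop("reaction and metabolite identifiers are required")
  if (length(lb) != n || length(ub) != n || length(gpr) != n)
    stop("lb, ub and gpr must have one entry per reaction")
  if (anyDuplicated(reaction_ids)) stop("duplicated reaction identifiers")
  if (anyDuplicated(metabolite_ids)) stop("duplicated metabolite identifiers")
  dimnames(S) <- list(metabolite_ids, reaction_ids)
  lb <- as.numeric(lb); ub <- as.numeric(ub)
  names(lb) <- names(ub) <- reaction_ids
  names(gpr) <- reaction_ids
  trees <- lapply(gpr, parse_gpr)
  used <- unique(unlist(lapply(trees, gpr_genes)))
  if (is.null(gene_ids)) gene_ids <- used
  missing_genes <- setdiff(used, gene_ids)
  if (length(missing_genes))
    stop("GPR rules reference unknown gene(s): ",
         paste(missing_genes, collapse = ", "))
  # NA objective marks a (sub)model without a biomass reaction
  if (!is.na(objective_id) && !objective_id %in% reaction_ids)
    stop("objective reaction ", sQuote(objective_id), " is not in the model")
  if (any(lb > ub))
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(reaction_ids[lb > ub], collapse = ", "))
  m <- structure(list(
    id = id,
    S = S,
    lb = lb, ub = ub,
    reaction_ids = reaction_ids,
    metabolite_ids = metabolite_ids,
    gene_ids = gene_ids,
    gpr = gpr,
    gpr_trees = trees,
    objective_id = objective_id,
    exchange_ids = detect_exchanges(S)
  ), class = "metabolic_model")
  m
}

detect_exchanges <- function(S) {
  nz <- colSums(S != 0)
  colnames(S)[nz == 1]
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s: %d metabolites, %d reactions, %d genes\n",
              x$id, length(x$metabolite_ids), length(x$reaction_ids),
              length(x$gene_ids)))
  cat(sprintf("  objective: %s; exchanges: %d\n",
              x$objective_id, length(x$exchange_ids)))
  invisible(x)
}

#' Genes referenced by each reaction's GPR
#' @param model a \code{metabolic_model}.
#' @return named list, reaction id -> character vector of gene ids.
#' @export
reaction_genes <- function(model) {
  lapply(model$gpr_trees, gpr_genes)
}

#' Validate a metabolic model's invariants
#'
#' Checks dimension agreement, bound ordering, objective membership, GPR gene
#' coverage and exchange detection.  Called by the readers; exported so user
#' code can re-check a hand-edited model.
#'
#' @param model a \code{metabolic_model}.
#' @return \code{model}, invisibly; errors on violation.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  n <- length(model$reaction_ids)
  if (ncol(model$S) != n || length(model$lb) != n || length(model$ub) != n ||
      length(model$gpr) != n)
    stop("inconsistent dimensions in model")
  if (any(model$lb > model$ub)) stop("lb > ub in model")
  if (!is.na(model$objective_id) &&
      !model$objective_id %in% model$reaction_ids)
    stop("objective reaction missing")
  used <- unique(unlist(lapply(model$gpr_trees, gpr_genes)))
  if (length(setdiff(used, model$gene_ids)))
    stop("GPR references gene absent from gene_ids")
  if (!setequal(model$exchange_ids, detect_exchanges(model$S)))
    stop("exchange_ids out of step with S")
  invisible(model)
}

# ---- JSON dialect -----------------------------------------------------------

#' Read a metabolic model from disk
#'
#' Two dialects are supported: a JSON dialect (keys \code{metabolites},
#' \code{genes}, \code{reactions} with \code{id}, \code{mets}, \code{lb},
#' \code{ub}, \code{gpr}, and \code{objective}) for which write/read
#' round-trips are bit-exact, and SBML Level 3 with the FBC package, read
#' semantically (stoichiometry, bounds, GPR association trees, objective).
#'
#' @param path file path.
#' @param dialect \code{"json"} or \code{"sbml"}; guessed from the file
#'   extension by default.
#' @return a validated \code{metabolic_model}.
#' @export
read_model <- function(path, dialect = c("auto", "json", "sbml")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  if (!file.exists(path)) stop("model file not found: ", path)
  m <- if (dialect == "json") read_model_json(path) else read_model_sbml(path)
  validate_model(m)
}

read_model_json <- function(path) {
  j <- jsonlite::read_json(path)
  req <- c("metabolites", "reactions", "objective")
  miss <- setdiff(req, names(j))
  if (length(miss))
    stop("model JSON is missing element(s): ", paste(miss, collapse = ", "))
  mets <- unlist(j$metabolites)
  rxns <- j$reactions
  rids <- vapply(rxns, function(r) r$id, character(1))
  S <- matrix(0, length(mets), length(rxns),
              dimnames = list(mets, rids))
  for (r in rxns) {
    for (mid in names(r$mets)) {
      if (!mid %in% mets)
        stop("reaction ", r$id, " references unknown metabolite ", mid)
      S[mid, r$id] <- as.numeric(r$mets[[mid]])
    }
  }
  metabolic_model(
    S = S,
    lb = vapply(rxns, function(r) as.numeric(r$lb), numeric(1)),
    ub = vapply(rxns, function(r) as.numeric(r$ub), numeric(1)),
    gpr = vapply(rxns, function(r) if (is.null(r$gpr)) "" else r$gpr,
                 character(1)),
    gene_ids = if (is.null(j$genes)) NULL else unlist(j$genes),
    objective_id = j$objective,
    id = if (is.null(j$id)) tools::file_path_sans_ext(basename(path)) else j$id)
}

#' Write a metabolic model to disk
#'
#' @param model a \code{metabolic_model}.
#' @param path output file path.
#' @param dialect \code{"json"} (lossless round-trip) or \code{"sbml"}
#'   (Level 3 + FBC, semantically equivalent round-trip).
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path, dialect = c("auto", "json", "sbml")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  if (dialect == "json") write_model_json(model, path)
  else write_model_sbml(model, path)
  invisible(path)
}

write_model_json <- function(model, path) {
  rxns <- lapply(model$reaction_ids, function(rid) {
    col <- model$S[, rid]
    nz <- col[col != 0]
    list(id = rid,
         mets = as.list(nz),
         lb = unname(model$lb[rid]),
         ub = unname(model$ub[rid]),
         gpr = unname(model$gpr[rid]))
  })
  j <- list(id = model$id,
            metabolites = as.list(model$metabolite_ids),
            genes = as.list(model$gene_ids),
            reactions = rxns,
            objective = model$objective_id)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# ---- SBML Level 3 + FBC -----------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in ", path,
                                           ": ", conditionMessage(e)))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  model_node <- xml2::xml_find_first(doc, "./s:model", ns)
  if (inherits(model_node, "xml_missing")) stop("SBML file has no <model>")

  params <- xml2::xml_find_all(model_node, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  sp <- xml2::xml_find_all(model_node, ".//s:listOfSpecies/s:species", ns)
  mets <- xml2::xml_attr(sp, "id")
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% c("true", "1")
  mets <- mets[!boundary]

  gps <- xml2::xml_find_all(model_node,
                            ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gene_ids <- xml2::xml_attr(gps, "id")
  if (all(is.na(gene_ids))) gene_ids <- xml2::xml_attr(gps, "fbc:id")
  gene_label <- xml2::xml_attr(gps, "label")
  if (all(is.na(gene_label))) gene_label <- xml2::xml_attr(gps, "fbc:label")
  gmap <- stats::setNames(ifelse(is.na(gene_label), gene_ids, gene_label),
                          gene_ids)

  rx <- xml2::xml_find_all(model_node, ".//s:listOfReactions/s:reaction", ns)
  if (length(rx) == 0) stop("SBML file has no reactions")
  rids <- xml2::xml_attr(rx, "id")
  S <- matrix(0, length(mets), length(rx), dimnames = list(mets, rids))
  lb <- ub <- numeric(length(rx))
  gpr <- character(length(rx))
  for (k in seq_along(rx)) {
    node <- rx[[k]]
    for (sr in xml2::xml_find_all(node, "./s:listOfReactants/s:speciesRef", ns)) {
      mid <- xml2::xml_attr(sr, "species")
      if (mid %in% mets)
        S[mid, k] <- S[mid, k] - as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(node, "./s:listOfProducts/s:speciesRef", ns)) {
      mid <- xml2::xml_attr(sr, "species")
      if (mid %in% mets)
        S[mid, k] <- S[mid, k] + as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    lbref <- xml2::xml_attr(node, "lowerFluxBound")
    if (is.na(lbref)) lbref <- xml2::xml_attr(node, "fbc:lowerFluxBound")
    ubref <- xml2::xml_attr(node, "upperFluxBound")
    if (is.na(ubref)) ubref <- xml2::xml_attr(node, "fbc:upperFluxBound")
    lb[k] <- if (!is.na(lbref) && lbref %in% names(pval)) pval[[lbref]] else -1000
    ub[k] <- if (!is.na(ubref) && ubref %in% names(pval)) pval[[ubref]] else 1000
    ga <- xml2::xml_find_first(node, "./fbc:geneProductAssociation/*", ns)
    gpr[k] <- if (inherits(ga, "xml_missing")) "" else sbml_gpa_to_rule(ga, gmap)
  }

  obj <- xml2::xml_find_first(
    model_node,
    ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (inherits(obj, "xml_missing"))
    stop("SBML model declares no flux objective")
  objective_id <- xml2::xml_attr(obj, "reaction")
  if (is.na(objective_id)) objective_id <- xml2::xml_attr(obj, "fbc:reaction")

  metabolic_model(S = S, lb = lb, ub = ub, gpr = gpr,
                  gene_ids = unname(gmap),
                  objective_id = objective_id,
                  id = xml2::xml_attr(model_node, "id"))
}

sbml_gpa_to_rule <- function(node, gmap) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    return(if (ref %in% names(gmap)) gmap[[ref]] else ref)
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, sbml_gpa_to_rule, character(1), gmap = gmap)
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

write_model_sbml <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
                   'fbc:required="false">'), SBML_NS, FBC_NS),
    sprintf('  <model id="%s" fbc:strict="true">', sid(model$id)),
    '    <listOfSpecies>',
    sprintf('      <species id="%s" constant="false" hasOnlySubstanceUnits="false" boundaryCondition="false"/>',
            sid(model$metabolite_ids)),
    '    </listOfSpecies>',
    '    <listOfParameters>')
  bnd <- sort(unique(c(model$lb, model$ub)))
  bid <- stats::setNames(sprintf("bnd_%d", seq_along(bnd)),
                         vapply(bnd, function(x) format(x, digits = 17),
                                character(1)))
  lines <- c(lines,
    sprintf('      <parameter id="%s" value="%s" constant="true"/>',
            bid, names(bid)),
    '    </listOfParameters>',
    '    <fbc:listOfGeneProducts>',
    sprintf('      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
            sid(model$gene_ids), esc(model$gene_ids)),
    '    </fbc:listOfGeneProducts>',
    '    <listOfReactions>')
  for (k in seq_along(model$reaction_ids)) {
    rid <- model$reaction_ids[k]
    col <- model$S[, k]
    reac <- col[col < 0]; prod <- col[col > 0]
    lines <- c(lines, sprintf(
      '      <reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      sid(rid), tolower(model$lb[k] < 0),
      bid[[format(model$lb[k], digits = 17)]],
      bid[[format(model$ub[k], digits = 17)]]))
    if (length(reac))
      lines <- c(lines, '        <listOfReactants>',
        sprintf('          <speciesRef species="%s" stoichiometry="%s" constant="true"/>',
                sid(names(reac)), format(-unname(reac), digits = 17)),
        '        </listOfReactants>')
    if (length(prod))
      lines <- c(lines, '        <listOfProducts>',
        sprintf('          <speciesRef species="%s" stoichiometry="%s" constant="true"/>',
                sid(names(prod)), format(unname(prod), digits = 17)),
        '        </listOfProducts>')
    if (nzchar(model$gpr[k]))
      lines <- c(lines, '        <fbc:geneProductAssociation>',
                 gpa_xml(model$gpr_trees[[k]], sid, indent = 10),
                 '        </fbc:geneProductAssociation>')
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines,
    '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
            sid(model$objective_id)),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>',
    '</sbml>')
  writeLines(lines, path)
}

gpa_xml <- function(tree, sid, indent) {
  pad <- strrep(" ", indent)
  rec <- function(node, pad) {
    if (node$op == "gene")
      return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>',
                     pad, sid(node$gene)))
    tag <- if (node$op == "and") "fbc:and" else "fbc:or"
    c(sprintf("%s<%s>", pad, tag),
      unlist(lapply(node$args, rec, pad = paste0(pad, "  "))),
      sprintf("%s</%s>", pad, tag))
  }
  rec(unclass(tree), pad)
}

# ---- medium -----------------------------------------------------------------

#' Define a growth medium
#'
#' A medium maps exchange reactions to maximum uptake magnitudes
#' (mmol gDW^-1 hr^-1, all nonnegative).  Applying it sets the exchange lower
#' bound to minus the magnitude (negative flux = uptake).
#'
#' @param uptake named numeric vector, exchange reaction id -> maximum uptake
#'   magnitude (>= 0).
#' @param cell_specific logical flag distinguishing a cell-specific medium
#'   (derived from measured exchange rates) from the general medium.
#' @return an object of class \code{medium_spec}.
#' @export
medium_spec <- function(uptake, cell_specific = FALSE) {
  stopifnot(is.numeric(uptake), !is.null(names(uptake)))
  if (any(uptake < 0)) stop("uptake magnitudes must be >= 0")
  structure(list(uptake = uptake, cell_specific = cell_specific),
            class = "medium_spec")
}

#' Fill missing rates of a cell-specific medium from the general medium
#'
#' Exchange reactions present in the general medium but unmeasured in the
#' cell-specific one keep their general-medium uptake rate.
#'
#' @param specific,general \code{medium_spec} objects.
#' @return a combined cell-specific \code{medium_spec}.
#' @export
fill_medium <- function(specific, general) {
  stopifnot(inherits(specific, "medium_spec"), inherits(general, "medium_spec"))
  extra <- general$uptake[setdiff(names(general$uptake),
                                  names(specific$uptake))]
  medium_spec(c(specific$uptake, extra), cell_specific = TRUE)
}

#' Apply a medium to a model
#'
#' For each exchange reaction keyed in the medium the lower flux bound is set
#' to minus the uptake magnitude; unkeyed exchanges and all internal reactions
#' are untouched.  The input model is not modified.
#'
#' @param model a \code{metabolic_model}.
#' @param medium a \code{medium_spec}.
#' @return a new constrained \code{metabolic_model}.
#' @export
apply_medium <- function(model, medium) {
  stopifnot(inherits(model, "metabolic_model"), inherits(medium, "medium_spec"))
  keys <- names(medium$uptake)
  bad <- setdiff(keys, model$exchange_ids)
  if (length(bad))
    stop("medium keys are not exchange reactions: ",
         paste(bad, collapse = ", "))
  out <- model
  out$lb[keys] <- -medium$uptake[keys]
  out$ub[keys] <- pmax(out$ub[keys], out$lb[keys])
  out
}

# ---- unit conversions -------------------------------------------------------

#' Convert a measured per-cell exchange rate to model units
#'
#' Measured exchange rates (fmol cell^-1 hr^-1) are scaled to flux-bound units
#' (mmol gDW^-1 hr^-1) through the cell volume and a cell-specific-volume
#' coefficient:
#' \deqn{v = coefficient \times C_{met} / V_c}
#' with the coefficient in mL gDW^-1 (default 4.3, an experimentally
#' determined mammalian-cell value; other cell types differ) and the cell
#' volume \eqn{V_c} in fL cell^-1.
#'
#' @param C_met measured exchange rate, fmol cell^-1 hr^-1 (uptake positive).
#' @param V_c cell volume, fL cell^-1 (> 0).
#' @param coefficient cell-specific volume, mL gDW^-1.
#' @return flux bound magnitude, mmol gDW^-1 hr^-1.
#' @examples
#' convert_uptake_rate(100, 430)   # 1.0
#' @export
convert_uptake_rate <- function(C_met, V_c, coefficient = 4.3) {
  if (any(V_c <= 0)) stop("cell volume V_c must be > 0")
  coefficient * C_met / V_c
}

#' Convert doubling time to specific growth rate
#'
#' @param dt doubling time in hours (> 0).
#' @return growth rate mu = ln(2)/dt, hr^-1.
#' @export
doubling_time_to_growth <- function(dt) {
  if (any(dt <= 0)) stop("doubling time must be > 0")
  log(2) / dt
}

# ---- tabular IO -------------------------------------------------------------

#' Read a gene-by-sample expression table
#'
#' TSV with a header row; first column gene identifiers, remaining columns one
#' per sample.  Values must be nonnegative.
#'
#' @param path file path.
#' @return numeric matrix, genes x samples.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  if (any(mat < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  mat
}

#' Write an expression matrix as TSV
#' @param expr genes x samples numeric matrix.
#' @param path output path.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a medium table
#'
#' TSV with columns \code{exchange_id} and \code{uptake}.
#' @param path file path.
#' @param cell_specific flag passed to [medium_spec()].
#' @return a \code{medium_spec}.
#' @export
read_medium_tsv <- function(path, cell_specific = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  medium_spec(stats::setNames(as.numeric(df$uptake), df$exchange_id),
              cell_specific = cell_specific)
}

#' Per-gene z-scores of an expression matrix
#'
#' A plain (x - mean)/sd transform across samples for each gene, provided as a
#' clearly-labeled stand-in for platform-specific normalization pipelines;
#' externally computed z-scores can be supplied anywhere the package accepts
#' them.
#'
#' @param expr genes x samples numeric matrix.
#' @return matrix of z-scores with the same shape (NaN where sd is 0).
#' @export
expression_zscores <- function(expr) {
  mu <- rowMeans(expr)
  sd <- apply(expr, 1, stats::sd)
  sweep(sweep(expr, 1, mu, "-"), 1, sd, "/")
}
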