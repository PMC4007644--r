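# In-memory representation of constraint-based metabolic models.
#
# A model holds metabolites, reactions (stoichiometry, flux bounds in
# mmol/gAFDW/h, GPR, subsystem) and a designated biomass reaction.  The gene
# list is always the union of GPR leaves.  Exchange reactions are boundary
# reactions touching exactly one metabolite; their lower bound caps uptake.

#' Construct a reaction
#'
#' @param id,name Reaction identifier and display name.
#' @param stoich Named numeric vector: metabolite id -> signed coefficient
#'   (reactants negative, products positive).
#' @param lb,ub Lower/upper flux bounds (mmol/gAFDW/h).
#' @param gpr A [gpr][gpr_gene] expression; default empty (no association).
#' @param subsystem Subsystem label, e.g. `"Energy Metabolism"`.
#' @return An object of class `reaction`.
#' @export
reaction <- function(id, stoich, lb = 0, ub = 1000, gpr = gpr_empty(),
                     name = id, subsystem = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.numeric(stoich), length(stoich) >= 1L, !is.null(names(stoich)),
            all(nzchar(names(stoich))), !anyDuplicated(names(stoich)))
  if (!is.numeric(lb) || !is.numeric(ub) || lb > ub)
    stop("reaction ", id, ": invalid bounds [", lb, ", ", ub, "]")
  if (!inherits(gpr, "gpr")) stop("reaction ", id, ": gpr must be a gpr expression")
  structure(
    list(id = id, name = name, stoich = stoich, lb = as.numeric(lb),
         ub = as.numeric(ub), gpr = gpr, subsystem = subsystem),
    class = "reaction"
  )
}

#' Construct a metabolic model
#'
#' @param id Model identifier (e.g. `"iMR1_799"`).
#' @param metabolites Data frame with columns `id`, `name`, `compartment`
#'   and optionally `formula`.
#' @param reactions List of [reaction()] objects.
#' @param biomass_id Id of the biomass reaction; must be among `reactions`.
#' @return An object of class `metabolic_model`.  The gene list is derived
#'   from the GPRs.
#' @export
metabolic_model <- function(id, metabolites, reactions, biomass_id) {
  stopifnot(is.character(id), length(id) == 1L)
  stopifnot(is.data.frame(metabolites), all(c("id", "compartment") %in% names(metabolites)))
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"formula" %in% names(metabolites)) metabolites$formula <- NA_character_
  metabolites <- metabolites[, c("id", "name", "compartment", "formula")]
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  if (any(!nzchar(metabolites$compartment)))
    stop("metabolites with empty compartment: ",
         paste(metabolites$id[!nzchar(metabolites$compartment)], collapse = ", "))
  stopifnot(is.list(reactions), length(reactions) >= 1L)
  rids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(rids))
    stop("duplicate reaction ids: ", paste(unique(rids[duplicated(rids)]), collapse = ", "))
  names(reactions) <- rids
  unknown <- setdiff(unique(unlist(lapply(reactions, function(r) names(r$stoich)))),
                     metabolites$id)
  if (length(unknown) > 0L)
    stop("stoichiometry references unknown metabolites: ", paste(unknown, collapse = ", "))
  if (!biomass_id %in% rids)
    stop("biomass reaction '", biomass_id, "' not among reactions")
  model <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         genes = sort(unique(unlist(lapply(reactions, function(r) gpr_genes(r$gpr))))),
         biomass_id = biomass_id),
    class = "metabolic_model"
  )
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  ex <- length(exchange_reactions(x))
  gpr <- sum(!vapply(x$reactions, function(r) is_gpr_empty(r$gpr), logical(1)))
  cat("<metabolic_model> ", x$id, "\n",
      "  metabolites: ", nrow(x$metabolites), "\n",
      "  reactions:   ", length(x$reactions),
      " (", gpr, " with GPR, ", ex, " exchange)\n",
      "  genes:       ", length(x$genes), "\n",
      "  biomass:     ", x$biomass_id, "\n", sep = "")
  invisible(x)
}

#' Is a reaction a boundary-reaction candidate?
#'
#' Exchange (boundary) reactions touch exactly one metabolite; this checks
#' only that necessary condition.  Use [exchange_reactions()] to identify a
#' model's true exchanges, which additionally requires the metabolite to
#' sit in a boundary compartment (or an `EX_` id), so that single-metabolite
#' internal reactions (biomass sinks, maintenance demands) are not
#' mistaken for exchanges.
#'
#' @param rxn A [reaction()].
#' @return Logical scalar.
#' @export
is_exchange <- function(rxn) length(rxn$stoich) == 1L

#' Ids of a model's exchange reactions
#'
#' @param model A [metabolic_model()].
#' @param compartments Compartment ids (lower-cased) counted as boundary;
#'   reactions with an `EX_` id prefix qualify regardless.
#' @return Character vector of reaction ids.
#' @export
exchange_reactions <- function(model,
                               compartments = c("e", "b", "extracellular",
                                                "extraorganism",
                                                "extra_organism")) {
  comp_of <- stats::setNames(tolower(model$metabolites$compartment),
                             model$metabolites$id)
  names(model$reactions)[vapply(model$reactions, function(r) {
    if (length(r$stoich) != 1L) return(FALSE)
    grepl("^EX_", r$id) || comp_of[[names(r$stoich)]] %in% compartments
  }, logical(1))]
}

reaction_ids <- function(model) names(model$reactions)

#' Apply gene deletions to a model
#'
#' Every reaction whose GPR evaluates inactive under the deletions has both
#' flux bounds set to zero; everything else (including reactions with no
#' gene association) is untouched.  Gene ids not present in the model are
#' silently no-ops.  The input model is not modified.
#'
#' @param model A [metabolic_model()].
#' @param deleted_genes Character vector of gene ids to knock out.
#' @return A new model with blocked reactions closed.
#' @export
apply_gene_deletions <- function(model, deleted_genes) {
  if (length(deleted_genes) == 0L) return(model)
  closed <- closed_reactions(model, deleted_genes)
  for (rid in closed) {
    model$reactions[[rid]]$lb <- 0
    model$reactions[[rid]]$ub <- 0
  }
  model
}

# Reaction ids whose GPR is inactivated by the deletions.  Only reactions
# whose GPR mentions a deleted gene can change state.
closed_reactions <- function(model, deleted_genes) {
  deleted_genes <- intersect(deleted_genes, model$genes)
  if (length(deleted_genes) == 0L) return(character())
  cand <- names(model$reactions)[vapply(
    model$reactions,
    function(r) !is_gpr_empty(r$gpr) && length(intersect(gpr_genes(r$gpr), deleted_genes)) > 0L,
    logical(1)
  )]
  cand[!vapply(cand, function(rid) evaluate_gpr(model$reactions[[rid]]$gpr, deleted_genes),
               logical(1))]
}

#' Content difference between two models
#'
#' Reaction and gene ids lost and gained in `other` relative to
#' `reference`.  With an ortholog table, gene identity is taken through
#' ortholog groups (a reference gene is "lost" only if no ortholog group
#' member of it is in `other`); without one, raw ids are compared.
#'
#' @param reference,other [metabolic_model()] objects.
#' @param table Optional [ortholog_table()] for cross-strain gene identity.
#' @param reference_strain,other_strain Strain ids in `table` for the two
#'   models (required when `table` is given).
#' @return A list of class `model_diff` with character vectors
#'   `reactions_lost`, `reactions_gained`, `genes_lost`, `genes_gained`.
#' @export
model_diff <- function(reference, other, table = NULL,
                       reference_strain = NULL, other_strain = NULL) {
  out <- list(
    reactions_lost = setdiff(reaction_ids(reference), reaction_ids(other)),
    reactions_gained = setdiff(reaction_ids(other), reaction_ids(reference))
  )
  if (is.null(table)) {
    out$genes_lost <- setdiff(reference$genes, other$genes)
    out$genes_gained <- setdiff(other$genes, reference$genes)
  } else {
    stopifnot(!is.null(reference_strain), !is.null(other_strain))
    gref <- gene_groups(table, reference_strain)[reference$genes]
    goth <- gene_groups(table, other_strain)[other$genes]
    out$genes_lost <- reference$genes[is.na(gref) | !(gref %in% goth)]
    out$genes_gained <- other$genes[is.na(goth) | !(goth %in% gref)]
  }
  structure(out, class = "model_diff")
}

#' @export
print.model_diff <- function(x, ...) {
  cat("<model_diff>\n",
      "  reactions lost:   ", length(x$reactions_lost), "\n",
      "  reactions gained: ", length(x$reactions_gained), "\n",
      "  genes lost:       ", length(x$genes_lost), "\n",
      "  genes gained:     ", length(x$genes_gained), "\n", sep = "")
  invisible(x)
}

#' Shared-content (Venn) table over a set of models
#'
#' For every non-empty subset of models, counts the reactions and genes
#' present in exactly that subset.  Reaction identity is by reaction id and
#' exchange reactions are excluded from the reaction counts; gene identity
#' is by ortholog group when a table is supplied, by raw id otherwise.
#'
#' @param models Named list of [metabolic_model()] objects (names are used
#'   as column labels; model ids are used if unnamed).
#' @param table Optional [ortholog_table()].
#' @param strains Strain ids in `table`, one per model (required with `table`).
#' @return A data frame with one logical membership column per model plus
#'   `n_reactions` and `n_genes`, one row per exclusive Venn region; region
#'   counts sum to the union sizes (stored in attributes `union_reactions`
#'   and `union_genes`).
#' @export
shared_content <- function(models, table = NULL, strains = NULL) {
  stopifnot(length(models) >= 1L)
  labels <- names(models)
  if (is.null(labels)) labels <- vapply(models, function(m) m$id, character(1))
  rxn_sets <- lapply(models, function(m) setdiff(reaction_ids(m), exchange_reactions(m)))
  if (is.null(table)) {
    gene_sets <- lapply(models, function(m) m$genes)
  } else {
    stopifnot(length(strains) == length(models))
    gene_sets <- Map(function(m, s) {
      grp <- gene_groups(table, s)[m$genes]
      # genes with no ortholog group keep their own id as a singleton key
      ifelse(is.na(grp), paste0("gene:", m$genes), grp)
    }, models, strains)
  }
  n <- length(models)
  region <- function(sets, member) {
    inside <- Reduce(intersect, sets[member])
    if (any(!member)) inside <- setdiff(inside, Reduce(union, sets[!member]))
    length(inside)
  }
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), n))[-(2^n), , drop = FALSE]
  names(grid) <- labels
  grid$n_reactions <- apply(grid[, seq_len(n), drop = FALSE], 1L,
                            function(m) region(rxn_sets, as.logical(m)))
  grid$n_genes <- apply(grid[, seq_len(n), drop = FALSE], 1L,
                        function(m) region(gene_sets, as.logical(m)))
  rownames(grid) <- NULL
  attr(grid, "union_reactions") <- length(Reduce(union, rxn_sets))
  attr(grid, "union_genes") <- length(Reduce(union, gene_sets))
  grid
}
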