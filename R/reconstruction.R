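# Template-based strain-model derivation and core-model construction.
#
# A strain model is derived from a template by translating every GPR
# through the ortholog table: template genes map to the OR of their
# co-orthologs in the target strain, reactions whose translated GPR cannot
# be satisfied are removed, and reactions with no gene association (and all
# exchanges, and the biomass reaction) are carried over unchanged.
#
# The core model keeps GPR reactions still supported after restricting to
# genes conserved in every strain, non-GPR reactions only when essential
# for growth on a reference condition, and reactions that are essential but
# supported only by non-conserved genes as flagged isozyme exceptions.

#' Derive a strain-specific model from a template
#'
#' @param template A [metabolic_model()] for the template strain.
#' @param table An [ortholog_table()] containing both strains.
#' @param target_strain Strain to derive a model for.
#' @param template_strain Strain id of the template in `table` (default:
#'   first strain of the table).
#' @param id Id for the derived model.
#' @return A list with elements `model` (the derived [metabolic_model()])
#'   and `report`: `removed_reactions` (data frame of reaction id and the
#'   template genes lacking orthologs), `retained_non_gpr` (ids of carried
#'   non-GPR reactions) and `conflicts` (empty; see
#'   [detect_growth_conflicts()]).
#' @export
derive_strain_model <- function(template, table, target_strain,
                                template_strain = table$strains[[1]],
                                id = paste0(template$id, "_", target_strain)) {
  stopifnot(template_strain %in% table$strains)
  if (!target_strain %in% table$strains)
    stop("target strain '", target_strain, "' absent from ortholog table")
  mapping <- ortholog_mapping(table, template_strain, target_strain)

  reactions <- list()
  removed <- list()
  retained_non_gpr <- character()
  exch <- exchange_reactions(template)
  for (rid in reaction_ids(template)) {
    r <- template$reactions[[rid]]
    if (is_gpr_empty(r$gpr) || rid %in% exch || rid == template$biomass_id) {
      # always carried over: non-GPR reactions, exchanges, biomass (curated
      # biomass edits are a user-supplied override, not computed here)
      if (is_gpr_empty(r$gpr) && !(rid %in% exch) && rid != template$biomass_id)
        retained_non_gpr <- c(retained_non_gpr, rid)
      if (!is_gpr_empty(r$gpr) && rid != template$biomass_id) {
        tg <- gpr_translate(r$gpr, mapping)
        r$gpr <- if (is.null(tg)) gpr_empty() else tg
      }
      reactions[[rid]] <- r
      next
    }
    tg <- gpr_translate(r$gpr, mapping)
    if (is.null(tg)) {
      missing <- gpr_genes(r$gpr)[vapply(gpr_genes(r$gpr),
                                         function(g) length(mapping[[g]] %||% character()) == 0L,
                                         logical(1))]
      removed[[length(removed) + 1L]] <- data.frame(
        reaction = rid, missing_genes = paste(missing, collapse = ","))
      next
    }
    r$gpr <- tg
    reactions[[rid]] <- r
  }
  used <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
  mets <- template$metabolites[template$metabolites$id %in% used, , drop = FALSE]
  model <- metabolic_model(id, mets, reactions, template$biomass_id)
  report <- list(
    removed_reactions = if (length(removed) > 0L) do.call(rbind, removed)
                        else data.frame(reaction = character(), missing_genes = character()),
    retained_non_gpr = retained_non_gpr,
    conflicts = data.frame(condition = character(), observed = logical(),
                           predicted = logical())
  )
  list(model = model, report = report)
}

# Named list: template gene -> functional co-orthologs in the target strain.
ortholog_mapping <- function(table, from_strain, to_strain) {
  from_groups <- gene_groups(table, from_strain)
  to_members <- functional_members(table, to_strain)
  out <- lapply(from_groups, function(grp) to_members[[grp]] %||% character())
  stats::setNames(out, names(from_groups))
}

#' Compare model growth predictions to observed phenotypes
#'
#' Flags conditions where FBA disagrees with an experimental growth
#' observation; such conflicts are candidates for manual gap-filling (not
#' automated here).
#'
#' @param model A [metabolic_model()].
#' @param observations Data frame with columns `carbon`, `acceptor`
#'   (optionally `nitrogen`) and logical `observed`.
#' @param config A [medium_config()].
#' @return Data frame of conflicting rows with an added `predicted` column.
#' @export
detect_growth_conflicts <- function(model, observations, config = medium_config()) {
  if (nrow(observations) == 0L)
    return(cbind(observations, predicted = logical()))
  if (!"nitrogen" %in% names(observations)) observations$nitrogen <- "nh4"
  observations$predicted <- vapply(seq_len(nrow(observations)), function(i) {
    cond <- growth_condition(observations$carbon[i], observations$acceptor[i],
                             observations$nitrogen[i])
    tryCatch(deletion_grows(model, character(), cond, config),
             strainflux_not_representable = function(e) FALSE)
  }, logical(1))
  observations[observations$predicted != observations$observed, , drop = FALSE]
}

#' Build a core model across a set of strains
#'
#' Starting from the template: (1) GPR reactions are kept when their GPR,
#' restricted to genes whose ortholog group is conserved in all strains,
#' still evaluates active; (2) reactions dropped in step 1 are pruned back
#' to the subset essential in the core context -- each candidate is removed
#' (in lexicographic order, iterating to a fixed point) whenever the model
#' still grows without it -- and the survivors are retained with their
#' original, non-conserved GPRs and flagged as isozyme exceptions;
#' (3) non-GPR reactions are pruned the same way, so only those essential
#' for growth under `condition` remain.  The deterministic fixed-point
#' order makes the result independent of strain order.  Exchanges and
#' biomass are carried over.
#'
#' @param template A [metabolic_model()].
#' @param table An [ortholog_table()] covering all strains.
#' @param strains Strains defining conservation (default: all in `table`).
#' @param condition Reference [growth_condition()] the core must support
#'   (conventionally aerobic growth on pyruvate).
#' @param template_strain Strain id of the template in `table`.
#' @param config A [medium_config()].
#' @param id Id for the core model.
#' @return A list with `model`, `retained_non_gpr` (essential non-GPR
#'   reaction ids kept), and `isozyme_exceptions` (essential reactions
#'   retained despite non-conserved GPRs).
#' @export
build_core_model <- function(template, table, strains = table$strains,
                             condition = growth_condition("pyr", "o2"),
                             template_strain = table$strains[[1]],
                             config = medium_config(), id = "Core") {
  conserved <- conserved_groups(table, strains)
  grp <- gene_groups(table, template_strain)
  conserved_genes <- names(grp)[grp %in% conserved]
  non_conserved <- setdiff(template$genes, conserved_genes)

  keep <- list()
  dropped_gpr <- character()
  non_gpr_candidates <- character()
  exch <- exchange_reactions(template)
  for (rid in reaction_ids(template)) {
    r <- template$reactions[[rid]]
    if (rid %in% exch || rid == template$biomass_id) {
      keep[[rid]] <- r
      next
    }
    if (is_gpr_empty(r$gpr)) {
      non_gpr_candidates <- c(non_gpr_candidates, rid)
      keep[[rid]] <- r
      next
    }
    pruned <- gpr_prune(r$gpr, non_conserved)
    if (is.null(pruned)) {
      dropped_gpr <- c(dropped_gpr, rid)
      keep[[rid]] <- r  # candidate isozyme exception, pruned below
    } else {
      r$gpr <- pruned
      keep[[rid]] <- r
    }
  }

  build <- function(rxn_list) {
    used <- unique(unlist(lapply(rxn_list, function(r) names(r$stoich))))
    metabolic_model(id, template$metabolites[template$metabolites$id %in% used, ,
                                             drop = FALSE],
                    rxn_list, template$biomass_id)
  }
  # remove the lexicographically first non-essential candidate, repeating
  # until every remaining candidate is essential in the current context
  prune_fixed_point <- function(keep, candidates) {
    candidates <- sort(candidates)
    repeat {
      dropped_one <- FALSE
      for (rid in candidates) {
        trial <- keep[names(keep) != rid]
        grows <- is_growth(maximize_growth(set_medium(build(trial), condition,
                                                      config)))
        if (grows) {
          keep <- trial
          candidates <- setdiff(candidates, rid)
          dropped_one <- TRUE
          break
        }
      }
      if (!dropped_one) return(list(keep = keep, retained = candidates))
    }
  }

  # (2) non-conserved GPR reactions survive only if essential in the core
  # context (isozyme exceptions); (3) same rule for non-GPR reactions
  step2 <- prune_fixed_point(keep, dropped_gpr)
  isozyme_exceptions <- step2$retained
  step3 <- prune_fixed_point(step2$keep, non_gpr_candidates)
  keep <- step3$keep
  candidates <- step3$retained

  core <- build(keep)
  sol <- maximize_growth(set_medium(core, condition, config))
  if (!is_growth(sol)) {
    blocked <- blocked_biomass_components(core, condition, config)
    stop("core model cannot grow under ", format_condition(condition),
         "; blocked biomass components: ", paste(blocked, collapse = ", "))
  }
  list(model = core, retained_non_gpr = candidates,
       isozyme_exceptions = isozyme_exceptions)
}

# Biomass substrates that cannot be produced (per-component sink FBA).
blocked_biomass_components <- function(model, condition, config = medium_config(),
                                       deleted_genes = character()) {
  m <- set_medium(apply_gene_deletions(model, deleted_genes), condition, config)
  bm <- m$reactions[[m$biomass_id]]$stoich
  components <- names(bm)[bm < 0]
  blocked <- character()
  for (met in components) {
    if (!component_producible(m, met)) blocked <- c(blocked, met)
  }
  blocked
}

# Maximize a demand sink for one metabolite on a medium-applied model.
component_producible <- function(prepared, met, threshold = 1e-6) {
  sink_id <- ".sink"
  prepared$reactions[[sink_id]] <- reaction(sink_id, stats::setNames(-1, met),
                                            lb = 0, ub = 1000)
  sol <- maximize_growth(prepared, objective_id = sink_id)
  sol$status == "optimal" && !is.na(sol$objective) && sol$objective > threshold
}
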