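# Gene-aligned comparison of model pairs (CONGA-style).
#
# Two models are aligned at the gene level through the ortholog table.
# Candidate deletions are ortholog groups shared by both models; the search
# reports every minimal deletion set (size <= k) for which exactly one
# model grows, annotated with the biomass-flux difference and classified as
# a biomass, metabolic and/or genetic difference.  The default engine is
# exhaustive enumeration with memoized FBA, which serves as ground truth.

#' Align two models' genes through an ortholog table
#'
#' @param model_a,model_b [metabolic_model()] objects.
#' @param table An [ortholog_table()] containing both strains.
#' @param strain_a,strain_b Strain ids of the two models in `table`.
#' @return An object of class `gene_alignment`: `shared_groups` (ortholog
#'   groups with functional members in both models), `unique_a`,
#'   `unique_b` (gene ids present in only one model, through the table),
#'   and per-model group membership maps.  Pseudogenes count as absent.
#' @export
align_genes <- function(model_a, model_b, table, strain_a, strain_b) {
  for (s in c(strain_a, strain_b))
    if (!s %in% table$strains) stop("strain '", s, "' absent from ortholog table")
  grp_a <- gene_groups(table, strain_a)
  grp_b <- gene_groups(table, strain_b)
  # groups whose member genes actually occur in each model
  in_a <- unique(grp_a[names(grp_a) %in% model_a$genes])
  in_b <- unique(grp_b[names(grp_b) %in% model_b$genes])
  shared <- sort(intersect(in_a, in_b))
  structure(
    list(shared_groups = shared,
         unique_a = sort(model_a$genes[!(grp_a[model_a$genes] %in% in_b) |
                                         is.na(grp_a[model_a$genes])]),
         unique_b = sort(model_b$genes[!(grp_b[model_b$genes] %in% in_a) |
                                         is.na(grp_b[model_b$genes])]),
         groups_a = grp_a, groups_b = grp_b,
         strain_a = strain_a, strain_b = strain_b),
    class = "gene_alignment"
  )
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat("<gene_alignment> ", x$strain_a, " vs ", x$strain_b, ": ",
      length(x$shared_groups), " shared groups, ",
      length(x$unique_a), " / ", length(x$unique_b), " unique genes\n", sep = "")
  invisible(x)
}

# Member genes of one ortholog group that are present in a model.
group_members_in_model <- function(model, groups_map, group) {
  genes <- names(groups_map)[groups_map %in% group]
  intersect(genes, model$genes)
}

#' Find ortholog deletion sets that separate two models
#'
#' Enumerates all deletion sets over shared ortholog groups (sizes 1..`k`)
#' after which exactly one model grows under the condition, i.e. the
#' deletions maximize the biomass-flux difference down to lethality in one
#' network.  Reported sets are minimal: size-2 sets containing a reported
#' single are excluded.  FBA calls are memoized per model by the set of
#' reactions a deletion closes.
#'
#' @param model_a,model_b [metabolic_model()] objects; both wildtypes must
#'   grow under `condition`.
#' @param condition A [growth_condition()].
#' @param table An [ortholog_table()].
#' @param strain_a,strain_b Strain ids of the models in `table`.
#' @param k Maximum deletion-set size, 1 or 2.
#' @param config A [medium_config()].
#' @param threshold Growth threshold.
#' @return A list of `conga_result` objects, each with `deletion_set`
#'   (ortholog group ids), `grows_a`, `grows_b`, `objective_a`,
#'   `objective_b`, `flux_difference` and (after
#'   [classify_difference()]) `classifications`.
#' @export
find_deletion_sets <- function(model_a, model_b, condition, table,
                               strain_a, strain_b, k = 1,
                               config = medium_config(), threshold = 1e-6) {
  stopifnot(k %in% c(1, 2))
  aln <- align_genes(model_a, model_b, table, strain_a, strain_b)
  cache_a <- fba_cache(model_a, condition, config)
  cache_b <- fba_cache(model_b, condition, config)
  wt_a <- growth_objective_after(cache_a, character())
  wt_b <- growth_objective_after(cache_b, character())
  if (wt_a <= threshold || wt_b <= threshold) {
    dead <- c(model_a$id, model_b$id)[c(wt_a, wt_b) <= threshold]
    stop("wildtype(s) not growing under ", format_condition(condition), ": ",
         paste(dead, collapse = ", "))
  }
  test_set <- function(groups) {
    del_a <- unique(unlist(lapply(groups, group_members_in_model,
                                  model = model_a, groups_map = aln$groups_a)))
    del_b <- unique(unlist(lapply(groups, group_members_in_model,
                                  model = model_b, groups_map = aln$groups_b)))
    obj_a <- growth_objective_after(cache_a, del_a)
    obj_b <- growth_objective_after(cache_b, del_b)
    grows_a <- obj_a > threshold
    grows_b <- obj_b > threshold
    if (grows_a == grows_b) return(NULL)
    structure(
      list(deletion_set = groups, condition = condition,
           grows_a = grows_a, grows_b = grows_b,
           model_a = model_a$id, model_b = model_b$id,
           deleted_genes_a = del_a, deleted_genes_b = del_b,
           objective_a = obj_a, objective_b = obj_b,
           flux_difference = abs(obj_a - obj_b),
           classifications = NULL),
      class = "conga_result"
    )
  }
  results <- Filter(Negate(is.null), lapply(aln$shared_groups,
                                            function(g) test_set(g)))
  if (k == 2) {
    # minimality: a pair may not contain any group already lethal on its own
    # (in either model); that excludes all supersets of reported singles
    lethal_any <- aln$shared_groups[vapply(aln$shared_groups, function(g) {
      del_a <- group_members_in_model(model_a, aln$groups_a, g)
      del_b <- group_members_in_model(model_b, aln$groups_b, g)
      growth_objective_after(cache_a, del_a) <= threshold ||
        growth_objective_after(cache_b, del_b) <= threshold
    }, logical(1))]
    cand <- setdiff(aln$shared_groups, lethal_any)
    if (length(cand) >= 2) {
      for (p in utils::combn(sort(cand), 2, simplify = FALSE)) {
        r <- test_set(p)
        if (!is.null(r)) results[[length(results) + 1L]] <- r
      }
    }
  }
  results
}

#' @export
print.conga_result <- function(x, ...) {
  cat("<conga_result> delete {", paste(x$deletion_set, collapse = ", "), "}: ",
      x$model_a, ifelse(x$grows_a, " grows", " lethal"), ", ",
      x$model_b, ifelse(x$grows_b, " grows", " lethal"),
      "; flux difference ", signif(x$flux_difference, 4),
      if (!is.null(x$classifications))
        paste0(" [", paste(x$classifications, collapse = ", "), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Classify why a deletion set separates two models
#'
#' With the non-growing model written N and the growing model G, the checks
#' are applied in order: **genetic** if some reaction disabled by the
#' deletions in N is present in G but remains active there (the GPR
#' survives through extra isozymes or subunits); **biomass** if every
#' biomass component of N made unproducible by the deletions is absent
#' from G's biomass composition; **metabolic** otherwise (the same
#' reactions are disabled in both networks and G reroutes around them, or
#' the blocked components sit in both biomass equations).  Genetic and
#' biomass can co-occur; every result receives at least one label.
#' Unproducibility is operationalized as per-component sink FBA under the
#' deletion.
#'
#' @param result A `conga_result` from [find_deletion_sets()].
#' @param model_a,model_b The two models the result was computed on.
#' @param config A [medium_config()].
#' @param threshold Growth threshold.
#' @return The result with its `classifications` field set (subset of
#'   `c("genetic", "biomass", "metabolic")`).
#' @export
classify_difference <- function(result, model_a, model_b,
                                config = medium_config(), threshold = 1e-6) {
  if (result$grows_a == result$grows_b)
    stop("conga_result contract violated: both models have the same growth outcome")
  if (result$grows_a) {
    g_model <- model_a; n_model <- model_b
    g_del <- result$deleted_genes_a; n_del <- result$deleted_genes_b
  } else {
    g_model <- model_b; n_model <- model_a
    g_del <- result$deleted_genes_b; n_del <- result$deleted_genes_a
  }
  labels <- character()

  # (1) genetic: a reaction closed in N survives in G under the deletions
  closed_n <- closed_reactions(n_model, n_del)
  for (rid in closed_n) {
    if (rid %in% reaction_ids(g_model) &&
        evaluate_gpr(g_model$reactions[[rid]]$gpr, g_del)) {
      labels <- c(labels, "genetic")
      break
    }
  }

  # (2) biomass: every component of N's biomass blocked by the deletion is
  # absent from G's biomass composition
  cond <- result$condition
  blocked_wt <- blocked_biomass_components(n_model, cond, config)
  blocked_del <- blocked_biomass_components(n_model, cond, config, n_del)
  newly_blocked <- setdiff(blocked_del, blocked_wt)
  if (length(newly_blocked) > 0L) {
    g_bm <- g_model$reactions[[g_model$biomass_id]]$stoich
    g_components <- names(g_bm)[g_bm < 0]
    if (!any(newly_blocked %in% g_components)) labels <- c(labels, "biomass")
  }

  # (3) metabolic: neither of the above explains the difference
  if (length(labels) == 0L) labels <- "metabolic"
  result$classifications <- labels
  result
}

#' Unique lethal ortholog groups per model across a model set
#'
#' Runs pairwise deletion-set searches over every ordered model pair and
#' groups the results by the non-growing model: a group counts for model M
#' if deleting it is lethal in M but viable in at least one other model.
#' Counts are deduplicated by ortholog group and split by difference
#' classification (a group may carry several labels across pairs).
#'
#' @param models Named list of [metabolic_model()] objects (>= 2), all
#'   growing under `condition`; models whose wildtype does not grow are
#'   excluded with a message.
#' @param table An [ortholog_table()].
#' @param strains Strain ids, one per model.
#' @param condition A [growth_condition()].
#' @param k Maximum deletion-set size (single-gene summaries use 1).
#' @param config A [medium_config()].
#' @return A list with `counts` (data frame: model, n_unique_lethal,
#'   n_genetic, n_biomass, n_metabolic) and `details` (data frame of
#'   model, group, labels).
#' @export
summarize_unique_lethal <- function(models, table, strains,
                                    condition = growth_condition("pyr", "o2"),
                                    k = 1, config = medium_config()) {
  stopifnot(length(models) >= 2L, length(strains) == length(models))
  labels <- names(models)
  if (is.null(labels)) labels <- vapply(models, function(m) m$id, character(1))
  growing <- vapply(models, function(m)
    tryCatch(deletion_grows(m, character(), condition, config),
             strainflux_not_representable = function(e) FALSE), logical(1))
  if (any(!growing))
    message("excluded (wildtype not growing under ", format_condition(condition),
            "): ", paste(labels[!growing], collapse = ", "))
  idx <- which(growing)
  rows <- list()
  for (i in idx) {
    for (j in idx) {
      if (i >= j) next
      res <- find_deletion_sets(models[[i]], models[[j]], condition, table,
                                strains[i], strains[j], k = k, config = config)
      for (r in res) {
        r <- classify_difference(r, models[[i]], models[[j]], config)
        loser <- if (r$grows_a) labels[j] else labels[i]
        rows[[length(rows) + 1L]] <- data.frame(
          model = loser, group = paste(r$deletion_set, collapse = "+"),
          labels = paste(sort(unique(r$classifications)), collapse = ","))
      }
    }
  }
  details <- if (length(rows) > 0L) do.call(rbind, rows)
             else data.frame(model = character(), group = character(),
                             labels = character())
  counts <- do.call(rbind, lapply(labels[idx], function(m) {
    d <- details[details$model == m, , drop = FALSE]
    groups <- unique(d$group)
    lab_of <- function(g) unlist(strsplit(d$labels[d$group == g], ","))
    data.frame(model = m, n_unique_lethal = length(groups),
               n_genetic = sum(vapply(groups, function(g) "genetic" %in% lab_of(g), logical(1))),
               n_biomass = sum(vapply(groups, function(g) "biomass" %in% lab_of(g), logical(1))),
               n_metabolic = sum(vapply(groups, function(g) "metabolic" %in% lab_of(g), logical(1))))
  }))
  list(counts = counts, details = details)
}

#' Map deletion-set results to metabolic subsystems
#'
#' For each result, collects the reactions (in either model) whose GPR
#' mentions a deleted gene and tallies unique reactions per subsystem.
#'
#' @param results List of `conga_result` objects.
#' @param models Named list of the models the results were computed on
#'   (matched by model id).
#' @return Data frame: `subsystem`, `n_reactions`, sorted by count.
#' @export
map_to_subsystems <- function(results, models) {
  if (length(results) == 0L)
    return(data.frame(subsystem = character(), n_reactions = integer()))
  by_id <- stats::setNames(models, vapply(models, function(m) m$id, character(1)))
  seen <- character()  # "model|reaction" keys
  subsys <- character()
  for (r in results) {
    for (side in c("a", "b")) {
      m <- by_id[[r[[paste0("model_", side)]]]]
      if (is.null(m)) next
      del <- r[[paste0("deleted_genes_", side)]]
      for (rid in reaction_ids(m)) {
        rxn <- m$reactions[[rid]]
        if (is_gpr_empty(rxn$gpr)) next
        if (length(intersect(gpr_genes(rxn$gpr), del)) == 0L) next
        key <- paste0(m$id, "|", rid)
        if (key %in% seen) next
        seen <- c(seen, key)
        subsys <- c(subsys, if (nzchar(rxn$subsystem)) rxn$subsystem else "(unassigned)")
      }
    }
  }
  tab <- sort(table(subsys), decreasing = TRUE)
  data.frame(subsystem = names(tab), n_reactions = as.integer(tab),
             row.names = NULL)
}
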