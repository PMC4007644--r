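# Seeded generators for synthetic strain families.
#
# The generators build toy constraint-based models that exercise every
# pipeline stage without external data: a template network with exchanges,
# respiration with several electron acceptors, precursor biosynthesis with
# singleton/complex/isozyme GPRs and an ATP-maintenance demand; a
# multi-strain family obtained by group-wise gene loss recorded in an
# ortholog table; planted biomass/genetic/metabolic pair differences with
# known expected deletion sets; and simulated mutant-fitness z-scores whose
# ground truth is the model's own FBA essentiality.  All generators are
# pure functions of (spec, seed).

#' Specification for a synthetic strain family
#'
#' Defaults are chosen so the family is large enough to contain isozymes,
#' enzyme complexes and redundant pathways, yet small enough that
#' exhaustive single- and double-deletion enumeration stays cheap.
#'
#' @param n_strains Number of strains (template included).
#' @param n_precursors Biomass precursors in the template (>= 3).
#' @param n_extra_reactions Seeded redundant two-step pathways added on top
#'   of the deterministic backbone.
#' @param gene_loss_prob Per-gene probability that a non-template strain
#'   loses a non-essential gene.
#' @param pseudogene_prob Probability that a loss is recorded as a
#'   pseudogene fragment (`^` in the table) rather than an absent gene.
#' @param isozyme_fraction Probability that a pathway reaction receives an
#'   isozyme-pair (OR) GPR instead of a singleton.
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @return A list of class `family_spec`.
#' @export
family_spec <- function(n_strains = 4, n_precursors = 4, n_extra_reactions = 8,
                        gene_loss_prob = 0.15, pseudogene_prob = 0.3,
                        isozyme_fraction = 0.25, seed = 1) {
  stopifnot(n_strains >= 2, n_precursors >= 3,
            gene_loss_prob >= 0, gene_loss_prob <= 1,
            pseudogene_prob >= 0, pseudogene_prob <= 1,
            isozyme_fraction >= 0, isozyme_fraction <= 1)
  structure(
    list(n_strains = n_strains, n_precursors = n_precursors,
         n_extra_reactions = n_extra_reactions,
         gene_loss_prob = gene_loss_prob, pseudogene_prob = pseudogene_prob,
         isozyme_fraction = isozyme_fraction, seed = seed,
         condition = growth_condition("pyr", "o2")),
    class = "family_spec"
  )
}

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a synthetic template model
#'
#' The deterministic backbone takes up pyruvate, oxidizes it to acetate
#' with NADH formation, respires NADH on oxygen, nitrate or fumarate, and
#' assembles biomass from ATP plus `n_precursors` precursors synthesized
#' from pyruvate (with ammonia, phosphate and sulfate feeding individual
#' precursors).  An ATP-maintenance demand carries a positive lower bound
#' until a medium is applied.  Seeded decoration adds redundant two-step
#' routes to precursors other than the first (the first precursor's sole
#' pathway and the pyruvate transporter are reserved as planted-difference
#' targets).  Wildtype growth on the spec's condition (aerobic pyruvate)
#' is checked before returning.
#'
#' @param spec A [family_spec()].
#' @return A [metabolic_model()] with attribute `condition`.
#' @export
generate_template <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, generate_template_impl(spec))
}

generate_template_impl <- function(spec) {
  P <- spec$n_precursors
  ext <- c("pyr", "ac", "o2", "no3", "fum", "nh4", "pi", "so4", "h2o", "h", "co2")
  mets <- data.frame(
    id = c(paste0(ext, "_e"),
           paste0(c("pyr", "ac", "o2", "no3", "fum", "nh4", "pi", "so4", "co2",
                    "atp", "nadh"), "_c"),
           sprintf("prec%d_c", seq_len(P))),
    compartment = c(rep("e", length(ext)), rep("c", 11 + P))
  )
  mets$name <- sub("_[ec]$", "", mets$id)

  gene_counter <- 0L
  next_gene <- function() {
    gene_counter <<- gene_counter + 1L
    sprintf("g%03d", gene_counter)
  }
  single <- function() gpr_gene(next_gene())
  iso_pair <- function() gpr_or(gpr_gene(next_gene()), gpr_gene(next_gene()))
  complex_pair <- function() gpr_and(gpr_gene(next_gene()), gpr_gene(next_gene()))
  maybe_iso <- function() if (stats::runif(1) < spec$isozyme_fraction) iso_pair() else single()

  rxns <- list()
  add <- function(r) rxns[[r$id]] <<- r
  for (x in ext)
    add(reaction(paste0("EX_", x), stats::setNames(-1, paste0(x, "_e")),
                 lb = -1000, ub = 1000, subsystem = "Exchange"))
  add(reaction("T_pyr", c(pyr_e = -1, pyr_c = 1), gpr = single(),
               subsystem = "Transport"))
  add(reaction("T_o2", c(o2_e = -1, o2_c = 1), gpr = single(),
               subsystem = "Transport"))
  add(reaction("T_no3", c(no3_e = -1, no3_c = 1), gpr = single(),
               subsystem = "Transport"))
  add(reaction("T_fum", c(fum_e = -1, fum_c = 1), gpr = single(),
               subsystem = "Transport"))
  add(reaction("T_nh4", c(nh4_e = -1, nh4_c = 1), gpr = single(),
               subsystem = "Transport"))
  add(reaction("T_pi", c(pi_e = -1, pi_c = 1), gpr = single(),
               subsystem = "Transport"))
  add(reaction("T_so4", c(so4_e = -1, so4_c = 1), gpr = single(),
               subsystem = "Transport"))
  add(reaction("T_ac", c(ac_c = -1, ac_e = 1), subsystem = "Transport"))
  add(reaction("T_co2", c(co2_c = -1, co2_e = 1), subsystem = "Transport"))
  add(reaction("GLY", c(pyr_c = -1, ac_c = 1, nadh_c = 1, co2_c = 1),
               gpr = complex_pair(), subsystem = "Central Metabolism"))
  add(reaction("RES_O2", c(nadh_c = -1, o2_c = -0.5, atp_c = 2),
               gpr = single(), subsystem = "Energy Metabolism"))
  add(reaction("RES_NO3", c(nadh_c = -1, no3_c = -1, atp_c = 1.5),
               gpr = single(), subsystem = "Energy Metabolism"))
  add(reaction("RES_FUM", c(nadh_c = -1, fum_c = -1, atp_c = 1),
               gpr = maybe_iso(), subsystem = "Energy Metabolism"))
  add(reaction("ATPM", c(atp_c = -1), lb = 2, ub = 1000,
               name = "ATP maintenance", subsystem = "Energy Metabolism"))
  for (i in seq_len(P)) {
    st <- c(-1, -1, 1)
    names(st) <- c("pyr_c", "atp_c", sprintf("prec%d_c", i))
    if (i %% 2L == 1L) st <- c(st, nh4_c = -0.5)
    if (i %% 4L == 2L) st <- c(st, pi_c = -0.2)
    if (i %% 4L == 3L) st <- c(st, so4_c = -0.1)
    gpr <- if (i == 1L) single()            # reserved: sole route, singleton
           else if (i %% 3L == 0L) complex_pair()
           else maybe_iso()
    add(reaction(sprintf("PS%d", i), st, gpr = gpr,
                 subsystem = "Biosynthesis"))
  }
  bm <- stats::setNames(rep(-1, P + 1L), c(sprintf("prec%d_c", seq_len(P)), "atp_c"))
  add(reaction("BIOMASS", bm, name = "Biomass assembly", subsystem = "Biomass"))

  # redundant decoration routes: pyr -> intermediate -> precursor (never prec1)
  extra_mets <- character()
  for (j in seq_len(spec$n_extra_reactions)) {
    target <- sample(2:P, 1)
    int_id <- sprintf("int%02d_c", j)
    extra_mets <- c(extra_mets, int_id)
    st1 <- c(-1, -1, 1)
    names(st1) <- c("pyr_c", "atp_c", int_id)
    st2 <- c(-1, 1)
    names(st2) <- c(int_id, sprintf("prec%d_c", target))
    add(reaction(sprintf("ALT%02da", j), st1, gpr = maybe_iso(),
                 subsystem = "Alternative Pathways"))
    add(reaction(sprintf("ALT%02db", j), st2, gpr = maybe_iso(),
                 subsystem = "Alternative Pathways"))
  }
  if (length(extra_mets) > 0L)
    mets <- rbind(mets, data.frame(id = extra_mets, compartment = "c",
                                   name = sub("_c$", "", extra_mets)))

  model <- metabolic_model("template", mets, rxns, "BIOMASS")
  attr(model, "condition") <- spec$condition
  if (!deletion_grows(model, character(), spec$condition))
    stop("generated template does not grow on its designated condition")
  model
}

#' Generate a strain family and its ortholog table
#'
#' Each template gene founds one ortholog group (`og_<gene>`).  Non-template
#' strains lose non-essential genes independently with the spec's loss
#' probability (essential genes, determined by single-deletion FBA on the
#' designated condition, are conserved in every strain); a fraction of the
#' losses are recorded as pseudogene fragments instead of absences.  Strain
#' models are produced with [derive_strain_model()], so generator and
#' deriver agree by construction, and any strain left unable to grow has
#' lost groups restored (in group order) until it grows.
#'
#' @param template Model from [generate_template()].
#' @param spec The same [family_spec()].
#' @return A list with `models` (named list, template strain `S1` first),
#'   `table` (the [ortholog_table()]), `strains` and `condition`.
#' @export
generate_family <- function(template, spec) {
  with_seed(spec$seed + 1L, generate_family_impl(template, spec))
}

generate_family_impl <- function(template, spec) {
  strains <- sprintf("S%d", seq_len(spec$n_strains))
  cond <- spec$condition
  protected <- unlist(essential_genes(template, cond))
  members <- list(data.frame(group = paste0("og_", template$genes),
                             strain = strains[1], gene = template$genes,
                             pseudo = FALSE))
  for (s in strains[-1]) {
    lost <- !(template$genes %in% protected) &
      stats::runif(length(template$genes)) < spec$gene_loss_prob
    as_pseudo <- lost & stats::runif(length(template$genes)) < spec$pseudogene_prob
    keep <- !lost | as_pseudo
    if (any(keep))
      members[[length(members) + 1L]] <- data.frame(
        group = paste0("og_", template$genes[keep]), strain = s,
        gene = paste0(s, "_", template$genes[keep]),
        pseudo = as_pseudo[keep])
  }
  table <- ortholog_table(strains, do.call(rbind, members))

  build <- function(s) derive_strain_model(template, table, s,
                                           template_strain = strains[1],
                                           id = s)$model
  models <- list()
  for (s in strains) {
    m <- build(s)
    # viability repair: restore lost groups (deterministic order) until the
    # strain grows on the designated condition
    restorable <- sort(setdiff(paste0("og_", template$genes),
                               names(functional_members(table, s))))
    while (!deletion_grows(m, character(), cond) && length(restorable) > 0L) {
      g <- restorable[1L]
      restorable <- restorable[-1L]
      mem <- table$members
      mem <- mem[!(mem$strain == s & mem$group == g), , drop = FALSE]
      mem <- rbind(mem, data.frame(group = g, strain = s,
                                   gene = paste0(s, "_", sub("^og_", "", g)),
                                   pseudo = FALSE))
      table <- ortholog_table(table$strains, mem)
      m <- build(s)
    }
    models[[s]] <- m
  }
  list(models = models, table = table, strains = strains, condition = cond)
}

#' Plant a known difference between two family models
#'
#' Modifies a pair of strain models so that a specific shared ortholog
#' group, when deleted from both, is lethal in model B only, for a known
#' reason:
#'
#' * `"genetic"` - model A gains an isozyme (a new A-only gene) for the
#'   pyruvate transporter, so deleting the transporter's shared group
#'   closes the reaction in B but not in A;
#' * `"biomass"` - both models gain a synthesis reaction for a new
#'   compound under a new shared group, and the compound is added to B's
#'   biomass only;
#' * `"metabolic"` - model A gains a two-step bypass (A-only gene) around
#'   the first precursor's sole synthesis reaction, whose shared gene
#'   group becomes the deletion target.
#'
#' @param model_a,model_b Two strain models from one family.
#' @param table The family's [ortholog_table()].
#' @param strain_a,strain_b Their strain ids.
#' @param type `"genetic"`, `"biomass"` or `"metabolic"`.
#' @return A list with the modified `model_a`, `model_b`, `table`, the
#'   `deletion_set` (one ortholog group id) the pair comparison must
#'   report, and `expected` (`grows_a = TRUE`, `grows_b = FALSE`,
#'   `label = type`).
#' @export
plant_difference <- function(model_a, model_b, table, strain_a, strain_b, type) {
  type <- match.arg(type, c("genetic", "biomass", "metabolic"))
  rebuild <- function(m) metabolic_model(m$id, m$metabolites, m$reactions, m$biomass_id)
  add_member <- function(table, group, strain, gene) {
    ortholog_table(table$strains,
                   rbind(table$members,
                         data.frame(group = group, strain = strain,
                                    gene = gene, pseudo = FALSE)))
  }
  shared_gene_group <- function(rid) {
    ga <- gpr_genes(model_a$reactions[[rid]]$gpr)[1]
    unname(gene_groups(table, strain_a)[ga])
  }
  if (type == "genetic") {
    target <- shared_gene_group("T_pyr")
    iso <- paste0(strain_a, "_iso_pyrT")
    model_a$reactions[["T_pyr"]]$gpr <-
      gpr_or(model_a$reactions[["T_pyr"]]$gpr, gpr_gene(iso))
    model_a <- rebuild(model_a)
    table <- add_member(table, "og_planted_genetic", strain_a, iso)
  } else if (type == "biomass") {
    target <- "og_planted_biomass"
    for (side in c("a", "b")) {
      m <- if (side == "a") model_a else model_b
      gene <- paste0(get(paste0("strain_", side)), "_gbio")
      m$metabolites <- rbind(m$metabolites,
                             data.frame(id = "bcomp_c", name = "bcomp",
                                        compartment = "c", formula = NA_character_))
      m$reactions[["BSYN"]] <- reaction("BSYN", c(pyr_c = -1, atp_c = -1, bcomp_c = 1),
                                        gpr = gpr_gene(gene),
                                        subsystem = "Biosynthesis")
      if (side == "b")
        m$reactions[[m$biomass_id]]$stoich <-
          c(m$reactions[[m$biomass_id]]$stoich, bcomp_c = -0.1)
      assign(paste0("model_", side), rebuild(m))
      table <- add_member(table, target, get(paste0("strain_", side)), gene)
    }
  } else {
    target <- shared_gene_group("PS1")
    gene <- paste0(strain_a, "_galt")
    model_a$metabolites <- rbind(model_a$metabolites,
                                 data.frame(id = "altm_c", name = "altm",
                                            compartment = "c", formula = NA_character_))
    model_a$reactions[["ALTP1a"]] <- reaction("ALTP1a", c(pyr_c = -1, atp_c = -1, altm_c = 1),
                                              gpr = gpr_gene(gene),
                                              subsystem = "Alternative Pathways")
    model_a$reactions[["ALTP1b"]] <- reaction("ALTP1b", c(altm_c = -1, prec1_c = 1),
                                              gpr = gpr_gene(gene),
                                              subsystem = "Alternative Pathways")
    model_a <- rebuild(model_a)
    table <- add_member(table, "og_planted_metabolic", strain_a, gene)
  }
  list(model_a = model_a, model_b = model_b, table = table,
       deletion_set = target, type = type,
       expected = list(grows_a = TRUE, grows_b = FALSE, label = type))
}

#' Simulate mutant-fitness z-scores from a model's own essentiality
#'
#' For every gene and condition the ground truth is taken from
#' single-deletion FBA; replicate z-scores are then drawn from
#' `Normal(0, noise_sd)` for growing mutants and `Normal(-6, noise_sd)`
#' for non-growing ones, so the conventional cutoff of -3.5 sits between
#' the two modes.
#'
#' @param model A [metabolic_model()] growing on every condition.
#' @param conditions Named list of [growth_condition()]s; names are the
#'   condition ids of the records.
#' @param noise_sd Standard deviation of the fitness noise.
#' @param n_replicates Replicate experiments per condition.
#' @param seed Integer seed.
#' @param config A [medium_config()].
#' @return Data frame `gene`, `experiment`, `condition`, `z`, with the
#'   ground-truth calls in attribute `truth` (data frame `gene`,
#'   `condition`, `grows`).
#' @export
simulate_fitness <- function(model, conditions, noise_sd = 1, n_replicates = 3,
                             seed = 1, config = medium_config()) {
  stopifnot(length(conditions) >= 1L, !is.null(names(conditions)))
  with_seed(seed, {
    rows <- vector("list", length(conditions))
    truth <- vector("list", length(conditions))
    for (ci in seq_along(conditions)) {
      cname <- names(conditions)[ci]
      cache <- fba_cache(model, conditions[[ci]], config)
      if (growth_objective_after(cache, character()) <= 1e-6)
        stop("model does not grow under condition '", cname, "'")
      grows <- vapply(model$genes, function(g)
        growth_objective_after(cache, g) > 1e-6, logical(1))
      truth[[ci]] <- data.frame(gene = model$genes, condition = cname,
                                grows = unname(grows))
      z <- stats::rnorm(length(model$genes) * n_replicates,
                        mean = rep(ifelse(grows, 0, -6), each = n_replicates),
                        sd = noise_sd)
      rows[[ci]] <- data.frame(
        gene = rep(model$genes, each = n_replicates),
        experiment = paste0(cname, "_rep", rep(seq_len(n_replicates),
                                               length(model$genes))),
        condition = cname,
        z = z)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- do.call(rbind, truth)
    out
  })
}

#' Knockout growth predictions for a set of conditions
#'
#' Single-gene deletion predictions from FBA, in the form consumed by
#' [evaluate_predictions()].
#'
#' @inheritParams simulate_fitness
#' @return Data frame `gene`, `condition`, `predicted`.
#' @export
knockout_predictions <- function(model, conditions, config = medium_config()) {
  stopifnot(!is.null(names(conditions)))
  do.call(rbind, lapply(names(conditions), function(cname) {
    cache <- fba_cache(model, conditions[[cname]], config)
    data.frame(gene = model$genes, condition = cname,
               predicted = vapply(model$genes, function(g)
                 growth_objective_after(cache, g) > 1e-6, logical(1)))
  }))
}
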