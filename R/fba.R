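# Flux balance analysis.
#
# FBA maximizes flux through the biomass reaction subject to steady-state
# mass balance S v = 0 and flux bounds lb <= v <= ub.  The LP is solved by
# an internal two-phase dense simplex with Bland's anti-cycling rule, on
# the shifted variables x = v - lb >= 0 (all bounds in these models are
# finite).  FBA systems are small here but highly degenerate (many zero
# right-hand sides); the general-purpose simplex routines on CRAN fail on
# them, hence the dedicated implementation.

#' Describe a growth condition
#'
#' A growth condition names the carbon source, terminal electron acceptor
#' and nitrogen source to be opened in the medium.  `NA` means the nutrient
#' class is withheld (e.g. no electron acceptor for fermentative growth).
#'
#' @param carbon Carbon-source compound name, or `NA` for none.
#' @param acceptor Electron-acceptor compound name, or `NA` for none.
#' @param nitrogen Nitrogen-source compound name (default ammonia, `"nh4"`).
#' @return An object of class `growth_condition` with an `aerobic`
#'   convenience flag (`TRUE` iff the acceptor is oxygen).
#' @export
growth_condition <- function(carbon, acceptor = NA, nitrogen = "nh4") {
  structure(
    list(carbon = carbon, acceptor = acceptor, nitrogen = nitrogen,
         aerobic = isTRUE(tolower(acceptor) %in% c("o2", "oxygen"))),
    class = "growth_condition"
  )
}

#' @export
print.growth_condition <- function(x, ...) {
  cat("<growth_condition> ", format_condition(x), "\n", sep = "")
  invisible(x)
}

format_condition <- function(cond) {
  paste0("carbon=", ifelse(is.na(cond$carbon), "none", cond$carbon),
         ", acceptor=", ifelse(is.na(cond$acceptor), "none", cond$acceptor),
         ", nitrogen=", cond$nitrogen)
}

#' Medium conventions for growth simulations
#'
#' Bounds follow the usual comparative-simulation convention: the named
#' carbon source and electron acceptor are capped at 10 mmol/gAFDW/h uptake;
#' phosphate, sulfate, water and protons (and ammonia, when it is the
#' nitrogen source) are freely available at 1000; every exchange may secrete
#' at up to 1000; and both growth- and non-growth-associated ATP maintenance
#' demands are set to zero, since maintenance values are unknown for most
#' strains being compared.
#'
#' @param uptake_bound Uptake cap for carbon source and electron acceptor.
#' @param free_bound Uptake cap for freely available inorganic nutrients.
#' @param secretion_bound Upper bound on every exchange flux.
#' @param free_compounds Compound names always open for uptake (skipped
#'   silently when a model has no matching exchange).
#' @param default_nitrogen Compound treated as the default nitrogen source.
#' @param atpm_pattern Case-insensitive regex identifying ATP-maintenance
#'   reactions by id or name; their lower bounds are set to zero.
#' @return A named list of medium settings.
#' @export
medium_config <- function(uptake_bound = 10, free_bound = 1000,
                          secretion_bound = 1000,
                          free_compounds = c("pi", "so4", "h2o", "h"),
                          default_nitrogen = "nh4",
                          atpm_pattern = "atp[_ ]?m|maintenance") {
  list(uptake_bound = uptake_bound, free_bound = free_bound,
       secretion_bound = secretion_bound, free_compounds = free_compounds,
       default_nitrogen = default_nitrogen, atpm_pattern = atpm_pattern)
}

#' Find the exchange reaction for a compound
#'
#' Matches `compound` (case-insensitively) against each exchange reaction's
#' metabolite id (with and without a compartment suffix such as `_e` or
#' `[e]`), metabolite name, and the reaction id without an `EX_` prefix.
#'
#' @param model A [metabolic_model()].
#' @param compound Compound name, e.g. `"pyruvate"` or `"o2"`.
#' @return The exchange reaction id, or `NA_character_` if no match.
#' @export
find_exchange_reaction <- function(model, compound) {
  key <- tolower(compound)
  mets <- model$metabolites
  for (rid in exchange_reactions(model)) {
    rxn <- model$reactions[[rid]]
    mid <- names(rxn$stoich)
    comp <- mets$compartment[match(mid, mets$id)]
    mname <- mets$name[match(mid, mets$id)]
    cands <- c(mid,
               sub(paste0("_", comp, "$"), "", mid),
               sub("\\[[^][]+\\]$", "", mid),
               mname,
               sub("^EX_", "", rid),
               sub(paste0("_", comp, "$"), "", sub("^EX_", "", rid)))
    if (key %in% tolower(cands)) return(rid)
  }
  NA_character_
}

not_representable <- function(model, compound) {
  stop(structure(
    class = c("strainflux_not_representable", "error", "condition"),
    list(message = paste0("compound '", compound, "' has no exchange reaction in model ",
                          model$id),
         call = sys.call(-1))
  ))
}

#' Apply a growth condition to a model's exchange bounds
#'
#' Closes all uptake, then opens the condition's carbon source and electron
#' acceptor at the uptake bound, the configured free nutrients and the
#' nitrogen source at the free bound, sets every exchange's upper bound to
#' the secretion bound, and zeroes ATP-maintenance lower bounds.  Applying
#' the same condition twice is idempotent.
#'
#' @param model A [metabolic_model()].
#' @param condition A [growth_condition()].
#' @param config A [medium_config()].
#' @return A new model with medium bounds applied.
#' @export
set_medium <- function(model, condition, config = medium_config()) {
  stopifnot(inherits(condition, "growth_condition"))
  for (rid in exchange_reactions(model)) {
    model$reactions[[rid]]$lb <- 0
    model$reactions[[rid]]$ub <- config$secretion_bound
  }
  open <- function(compound, bound, required) {
    if (is.na(compound)) return(invisible())
    rid <- find_exchange_reaction(model, compound)
    if (is.na(rid)) {
      if (required) not_representable(model, compound)
      return(invisible())
    }
    model$reactions[[rid]]$lb <<- -bound
    invisible()
  }
  for (cmp in config$free_compounds) open(cmp, config$free_bound, required = FALSE)
  open(condition$nitrogen, config$free_bound, required = TRUE)
  if (!identical(tolower(condition$nitrogen), tolower(config$default_nitrogen))) {
    # ammonia is closed unless it is the nitrogen source
    rid <- find_exchange_reaction(model, config$default_nitrogen)
    if (!is.na(rid)) model$reactions[[rid]]$lb <- 0
  }
  open(condition$carbon, config$uptake_bound, required = TRUE)
  open(condition$acceptor, config$uptake_bound, required = TRUE)
  # zero growth- and non-growth-associated ATP maintenance demands
  for (rid in reaction_ids(model)) {
    rxn <- model$reactions[[rid]]
    if (grepl(config$atpm_pattern, rxn$id, ignore.case = TRUE) ||
        grepl(config$atpm_pattern, rxn$name, ignore.case = TRUE)) {
      if (rxn$lb > 0) model$reactions[[rid]]$lb <- 0
    }
  }
  model
}

#' Stoichiometric matrix of a model
#'
#' @param model A [metabolic_model()].
#' @return Dense numeric matrix, metabolites by reactions.
#' @export
stoichiometric_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), length(model$reactions),
              dimnames = list(model$metabolites$id, reaction_ids(model)))
  for (rid in reaction_ids(model)) {
    st <- model$reactions[[rid]]$stoich
    S[names(st), rid] <- st
  }
  S
}

model_bounds <- function(model) {
  list(lb = vapply(model$reactions, function(r) r$lb, numeric(1)),
       ub = vapply(model$reactions, function(r) r$ub, numeric(1)))
}

#' Maximize flux through the biomass reaction
#'
#' Solves the FBA linear program for a model whose medium bounds are
#' already set.  The optimal objective is unique even when the flux vector
#' is degenerate; downstream code asserts only objectives.
#'
#' @param model A [metabolic_model()] with medium applied.
#' @param objective_id Reaction whose flux to maximize (default biomass).
#' @return An object of class `flux_solution`: `status` (`"optimal"` or
#'   `"infeasible"`), `objective`, and named `fluxes`.
#' @export
maximize_growth <- function(model, objective_id = model$biomass_id) {
  S <- stoichiometric_matrix(model)
  bnd <- model_bounds(model)
  obj <- as.numeric(reaction_ids(model) == objective_id)
  sol <- solve_lp(obj, S, bnd$lb, bnd$ub)
  if (sol$status != "optimal")
    return(structure(list(status = sol$status, objective = NA_real_,
                          fluxes = NULL, model_id = model$id),
                     class = "flux_solution"))
  structure(list(status = "optimal", objective = sol$objective,
                 fluxes = stats::setNames(sol$v, reaction_ids(model)),
                 model_id = model$id),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> ", x$model_id, ": ", x$status,
      if (x$status == "optimal") paste0(", objective = ", signif(x$objective, 6)),
      "\n", sep = "")
  invisible(x)
}

# Maximize obj'v s.t. S v = 0, lb <= v <= ub (finite bounds), by two-phase
# dense simplex on the shifted variables x = v - lb >= 0.  Bland's rule
# guarantees termination on the highly degenerate systems FBA produces.
solve_lp <- function(obj, S, lb, ub) {
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp requires finite flux bounds")
  n <- length(obj)
  me <- nrow(S)
  beq <- as.vector(-S %*% lb)
  Aeq <- unname(S)
  neg <- beq < 0
  if (any(neg)) {
    Aeq[neg, ] <- -Aeq[neg, , drop = FALSE]
    beq[neg] <- -beq[neg]
  }
  # standard form: [x slacks artificials]; bound rows x_i + s_i = ub_i - lb_i
  # (slack basis), equality rows Aeq x + a_r = beq (artificial basis)
  A <- rbind(cbind(diag(n), diag(n), matrix(0, n, me)),
             cbind(Aeq, matrix(0, me, n), diag(me)))
  b <- c(ub - lb, beq)
  basis <- c(n + seq_len(n), 2L * n + seq_len(me))
  art <- 2L * n + seq_len(me)

  ph1 <- simplex_core(A, b, cost = c(rep(0, 2L * n), rep(1, me)), basis,
                      allowed = seq_len(2L * n + me))
  if (ph1$value > 1e-7) return(list(status = "infeasible"))
  A <- ph1$A; b <- ph1$b; basis <- ph1$basis
  # drive any artificial still basic (at zero) out of the basis; an all-zero
  # row marks a redundant constraint and is dropped
  drop_rows <- integer()
  for (i in which(basis %in% art)) {
    row <- A[i, seq_len(2L * n)]
    j <- which(abs(row) > 1e-9)
    if (length(j) == 0L) {
      drop_rows <- c(drop_rows, i)
      next
    }
    j <- j[1L]
    piv <- A[i, j]
    A[i, ] <- A[i, ] / piv
    b[i] <- b[i] / piv
    other <- setdiff(seq_len(nrow(A)), i)
    f <- A[other, j]
    A[other, ] <- A[other, , drop = FALSE] - outer(f, A[i, ])
    b[other] <- b[other] - f * b[i]
    basis[i] <- j
  }
  if (length(drop_rows) > 0L) {
    A <- A[-drop_rows, , drop = FALSE]
    b <- b[-drop_rows]
    basis <- basis[-drop_rows]
  }
  ph2 <- simplex_core(A, b, cost = c(-obj, rep(0, n + me)), basis,
                      allowed = seq_len(2L * n))
  x <- numeric(2L * n + me)
  x[ph2$basis] <- ph2$b
  v <- x[seq_len(n)] + lb
  list(status = "optimal", objective = sum(obj * v), v = v)
}

# Full-tableau simplex minimizing cost'z over A z = b, z >= 0, from a given
# feasible basis.  Entering columns are restricted to `allowed` (used to bar
# artificials in phase 2).  Bland's smallest-index rule for both the
# entering and leaving choice prevents cycling.
simplex_core <- function(A, b, cost, basis, allowed, tol = 1e-9,
                         maxit = 100000L) {
  m <- nrow(A)
  for (it in seq_len(maxit)) {
    cb <- cost[basis]
    # reduced costs; basis columns of the maintained tableau are unit vectors
    r <- cost - as.vector(crossprod(A, cb))
    r[basis] <- 0
    cand <- allowed[r[allowed] < -tol]
    if (length(cand) == 0L) {
      return(list(A = A, b = b, basis = basis, value = sum(cb * b)))
    }
    j <- min(cand)
    col <- A[, j]
    pos <- which(col > tol)
    if (length(pos) == 0L) stop("LP is unbounded")
    ratios <- b[pos] / col[pos]
    best <- pos[ratios <= min(ratios) + tol]
    i <- best[which.min(basis[best])]
    # pivot on (i, j)
    piv <- A[i, j]
    A[i, ] <- A[i, ] / piv
    b[i] <- b[i] / piv
    other <- setdiff(seq_len(m), i)
    f <- A[other, j]
    A[other, ] <- A[other, , drop = FALSE] - outer(f, A[i, ])
    b[other] <- b[other] - f * b[i]
    b[b < 0 & b > -1e-11] <- 0
    basis[i] <- j
  }
  stop("simplex iteration limit reached")
}

#' Mass-balance residual of a flux solution
#'
#' @param model The model the solution was computed on.
#' @param solution A `flux_solution` from [maximize_growth()].
#' @return Max-norm of `S v` over metabolites.
#' @export
mass_balance_residual <- function(model, solution) {
  stopifnot(solution$status == "optimal")
  max(abs(stoichiometric_matrix(model) %*% solution$fluxes[reaction_ids(model)]))
}

#' Classify a flux solution as growth or no growth
#'
#' Growth means the model attains a biomass flux above the numeric
#' threshold; the threshold guards against solver noise around zero.
#'
#' @param solution A `flux_solution`.
#' @param threshold Minimum biomass flux counted as growth (default `1e-6`).
#' @return Logical scalar.
#' @export
is_growth <- function(solution, threshold = 1e-6) {
  solution$status == "optimal" && !is.na(solution$objective) &&
    solution$objective > threshold
}

#' Does a deletion mutant grow under a condition?
#'
#' Composes [apply_gene_deletions()], [set_medium()], [maximize_growth()]
#' and [is_growth()].
#'
#' @param model A [metabolic_model()].
#' @param deleted_genes Character vector of gene ids (may be empty).
#' @param condition A [growth_condition()].
#' @param config A [medium_config()].
#' @param threshold Growth threshold passed to [is_growth()].
#' @return Logical scalar.
#' @export
deletion_grows <- function(model, deleted_genes, condition,
                           config = medium_config(), threshold = 1e-6) {
  m <- set_medium(apply_gene_deletions(model, deleted_genes), condition, config)
  is_growth(maximize_growth(m), threshold)
}

# Memoized growth testing ----------------------------------------------------
#
# Deletion outcomes depend on the model only through the set of reactions
# closed by the GPRs, so FBA results are cached by that signature.  A
# "prepared" model has its medium already applied.

fba_cache <- function(model, condition, config = medium_config()) {
  prepared <- set_medium(model, condition, config)
  env <- new.env(parent = emptyenv())
  list(model = prepared, memo = env)
}

growth_objective_after <- function(cache, deleted_genes) {
  closed <- closed_reactions(cache$model, deleted_genes)
  key <- paste0("k:", paste(sort(closed), collapse = "|"))
  if (!is.null(cache$memo[[key]])) return(cache$memo[[key]])
  m <- cache$model
  for (rid in closed) {
    m$reactions[[rid]]$lb <- 0
    m$reactions[[rid]]$ub <- 0
  }
  sol <- maximize_growth(m)
  obj <- if (sol$status == "optimal") sol$objective else 0
  cache$memo[[key]] <- obj
  obj
}

#' Essential gene sets of a model under a condition
#'
#' Enumerates all minimal gene sets of the requested size whose deletion
#' abolishes growth.  Size-2 results exclude supersets of lethal singles,
#' so every reported set is minimal.  FBA calls are memoized by the set of
#' reactions the deletion closes.
#'
#' @param model A [metabolic_model()].
#' @param condition A [growth_condition()]; the wildtype must grow under it.
#' @param set_size 1 (single knockouts) or 2 (double knockouts).
#' @param config A [medium_config()].
#' @param threshold Growth threshold.
#' @return List of character vectors (each a lethal gene set).
#' @export
essential_genes <- function(model, condition, set_size = 1,
                            config = medium_config(), threshold = 1e-6) {
  stopifnot(set_size %in% c(1, 2))
  cache <- fba_cache(model, condition, config)
  if (growth_objective_after(cache, character()) <= threshold)
    stop("wildtype of ", model$id, " does not grow under ",
         format_condition(condition), "; essentiality is undefined")
  genes <- model$genes
  lethal1 <- genes[vapply(genes, function(g)
    growth_objective_after(cache, g) <= threshold, logical(1))]
  if (set_size == 1) return(lapply(lethal1, identity))
  viable <- setdiff(genes, lethal1)
  out <- list()
  if (length(viable) >= 2) {
    pairs <- utils::combn(sort(viable), 2, simplify = FALSE)
    for (p in pairs) {
      if (growth_objective_after(cache, p) <= threshold)
        out[[length(out) + 1L]] <- p
    }
  }
  out
}
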