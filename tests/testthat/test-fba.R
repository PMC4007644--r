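test_that("a linear chain attains the analytic uptake-limited optimum", {
  m <- toy_chain_model(uptake = 10)
  sol <- maximize_growth(m)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective, 10, tolerance = 1e-9)
  # all exchanges closed: no growth
  m$reactions$EX_A$lb <- 0
  expect_equal(maximize_growth(m)$objective, 0, tolerance = 1e-9)
})

test_that("optimal solutions satisfy mass balance and bounds", {
  fam <- default_family()
  cond <- fam$condition
  for (m in fam$models) {
    prepared <- set_medium(m, cond)
    sol <- maximize_growth(prepared)
    expect_identical(sol$status, "optimal")
    expect_lt(mass_balance_residual(prepared, sol), 1e-6)
    for (rid in names(prepared$reactions)) {
      r <- prepared$reactions[[rid]]
      expect_gte(sol$fluxes[[rid]], r$lb - 1e-6)
      expect_lte(sol$fluxes[[rid]], r$ub + 1e-6)
    }
  }
})

test_that("set_medium applies the comparative-simulation bound conventions", {
  fam <- default_family()
  m <- set_medium(fam$template, growth_condition("pyr", "o2"))
  expect_identical(m$reactions$EX_pyr$lb, -10)
  expect_identical(m$reactions$EX_o2$lb, -10)
  expect_identical(m$reactions$EX_nh4$lb, -1000)
  expect_identical(m$reactions$EX_pi$lb, -1000)
  expect_identical(m$reactions$EX_so4$lb, -1000)
  expect_identical(m$reactions$EX_h2o$lb, -1000)
  expect_identical(m$reactions$EX_h$lb, -1000)
  # non-condition nutrients closed for uptake, everything open for secretion
  expect_identical(m$reactions$EX_no3$lb, 0)
  expect_identical(m$reactions$EX_ac$lb, 0)
  expect_true(all(vapply(exchange_reactions(m),
                         function(r) m$reactions[[r]]$ub == 1000, logical(1))))
  # ATP maintenance demands zeroed
  expect_identical(m$reactions$ATPM$lb, 0)
  # idempotence
  expect_identical(set_medium(m, growth_condition("pyr", "o2")), m)
  # no carbon source: nothing to grow on
  m0 <- set_medium(fam$template, growth_condition(NA, "o2"))
  expect_equal(maximize_growth(m0)$objective, 0, tolerance = 1e-9)
  # unmappable compounds are not representable
  expect_error(set_medium(fam$template, growth_condition("unobtainium", "o2")),
               class = "strainflux_not_representable")
})

test_that("is_growth applies the numeric threshold", {
  sol <- function(obj) structure(list(status = "optimal", objective = obj),
                                 class = "flux_solution")
  expect_false(is_growth(sol(0)))
  expect_true(is_growth(sol(0.5)))
  expect_false(is_growth(sol(1e-9)))
  expect_false(is_growth(structure(list(status = "infeasible",
                                        objective = NA_real_),
                                   class = "flux_solution")))
})

test_that("FBA objective matches the naive scipy LP oracle on seeded toy models", {
  set.seed(101)
  models <- list()
  for (s in 1:12) {
    spec <- family_spec(n_precursors = sample(3:5, 1),
                        n_extra_reactions = sample(3:10, 1), seed = 100 + s)
    tpl <- generate_template(spec)
    prepared <- set_medium(tpl, spec$condition)
    models[[length(models) + 1L]] <- prepared
    # also a random deletion mutant of the same template
    del <- sample(tpl$genes, sample(1:4, 1))
    models[[length(models) + 1L]] <-
      set_medium(apply_gene_deletions(tpl, del), spec$condition)
  }
  ours <- vapply(models, function(m) maximize_growth(m)$objective, numeric(1))
  oracle <- scipy_fba_objectives(models)
  expect_length(oracle, length(models))
  expect_false(anyNA(oracle))
  expect_lt(max(abs(ours - oracle)), 1e-6)
})

test_that("deletion monotonicity and carbon-uptake scaling hold", {
  fam <- default_family()
  cond <- fam$condition
  model <- fam$models$S2
  prepared <- set_medium(model, cond)
  set.seed(5)
  for (rep in 1:10) {
    d1 <- sample(model$genes, sample(0:4, 1))
    d2 <- union(d1, sample(model$genes, sample(1:4, 1)))
    o1 <- maximize_growth(apply_gene_deletions(prepared, d1))$objective
    o2 <- maximize_growth(apply_gene_deletions(prepared, d2))$objective
    expect_lte(o2, o1 + 1e-6)
  }
  # doubling carbon uptake at most doubles the objective
  base <- maximize_growth(prepared)$objective
  doubled <- prepared
  doubled$reactions$EX_pyr$lb <- 2 * doubled$reactions$EX_pyr$lb
  expect_lte(maximize_growth(doubled)$objective, 2 * base + 1e-6)
})

test_that("deletion_grows reproduces wildtype calls and ignores unknown genes", {
  fam <- default_family()
  cond <- fam$condition
  m <- fam$models$S2
  expect_true(deletion_grows(m, character(), cond))
  expect_identical(deletion_grows(m, "absent_gene", cond),
                   deletion_grows(m, character(), cond))
})

test_that("essential gene enumeration matches the brute-force loop", {
  fam <- default_family()
  cond <- fam$condition
  model <- fam$models$S2
  ours <- essential_genes(model, cond)
  brute <- brute_force_essential(model, cond)
  expect_setequal(unlist(ours), unlist(brute))
})

test_that("double-deletion enumeration finds exactly the planted isozyme pair", {
  iso <- toy_isozyme_model()
  # the toy's only exchange is its carbon source, which also stands in as
  # the nitrogen source so the medium is representable
  cond <- growth_condition("A", NA, "A")
  singles <- essential_genes(iso, cond, set_size = 1)
  expect_setequal(unlist(singles), "g1")
  doubles <- essential_genes(iso, cond, set_size = 2)
  expect_identical(doubles, list(c("g2a", "g2b")))
  # a model with only GPR-free reactions has no essential genes
  chain <- toy_chain_model()
  chain$reactions$CONV$gpr <- gpr_empty()
  chain <- metabolic_model("nc", chain$metabolites, chain$reactions, "BIOMASS")
  expect_length(essential_genes(chain, growth_condition("A", NA, "A")), 0)
  # essentiality is undefined when the wildtype does not grow
  dead <- toy_chain_model()
  dead$reactions$CONV$ub <- 0
  expect_error(essential_genes(dead, growth_condition("A", NA, "A")),
               "does not grow")
})
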