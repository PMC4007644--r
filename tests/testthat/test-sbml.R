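# The same model must survive write_sbml -> read_sbml with identical ids,
# bounds, GPR truth tables and biomass designation, and the reader must
# also accept the legacy Level 2 notes dialect.

model_contents_equal <- function(a, b) {
  expect_setequal(names(b$reactions), names(a$reactions))
  expect_setequal(b$metabolites$id, a$metabolites$id)
  expect_setequal(b$genes, a$genes)
  expect_identical(b$biomass_id, a$biomass_id)
  for (rid in names(a$reactions)) {
    ra <- a$reactions[[rid]]; rb <- b$reactions[[rid]]
    expect_identical(rb$lb, ra$lb)
    expect_identical(rb$ub, ra$ub)
    expect_identical(rb$subsystem, ra$subsystem)
    expect_identical(sort(names(rb$stoich)), sort(names(ra$stoich)))
    expect_equal(rb$stoich[names(ra$stoich)], ra$stoich)
    genes <- gpr_genes(ra$gpr)
    expect_setequal(gpr_genes(rb$gpr), genes)
    # GPR equality as truth tables, not tree shape
    if (length(genes) > 0 && length(genes) <= 10) {
      for (k in 0:length(genes)) {
        del <- genes[seq_len(k)]
        expect_identical(evaluate_gpr(rb$gpr, del), evaluate_gpr(ra$gpr, del))
      }
    }
  }
}

test_that("fbc SBML round-trips a synthetic model exactly", {
  fam <- default_family()
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(fam$template, path)
  model_contents_equal(fam$template, read_sbml(path))
})

test_that("bounds of (-1000, 1000) and GPR-free reactions survive round-trip", {
  m <- toy_chain_model()
  m$reactions$EX_A$lb <- -1000
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  m2 <- read_sbml(path)
  expect_identical(m2$reactions$EX_A$lb, -1000)
  expect_identical(m2$reactions$EX_A$ub, 1000)
  # no gene association emitted for GPR-free reactions
  raw <- readLines(path)
  expect_false(any(grepl("geneProductAssociation", raw[grepl("EX_A|BIOMASS",
                                                             raw)])))
  expect_true(is_gpr_empty(m2$reactions$BIOMASS$gpr))
})

test_that("a hand-built fbc fixture parses to the expected structure", {
  fix <- metabolic_model(
    "fix5",
    data.frame(id = c("A_e", "B_c", "C_c"), compartment = c("e", "c", "c")),
    list(
      reaction("EX_A", c(A_e = -1), lb = -10),
      reaction("R1", c(A_e = -1, B_c = 1),
               gpr = gpr_or(gpr_and(gpr_gene("g1"), gpr_gene("g2")),
                            gpr_gene("g3"))),
      reaction("R2", c(B_c = -1, C_c = 1)),
      reaction("R3", c(C_c = -1, B_c = 1), lb = -5),
      reaction("growth_biomass", c(C_c = -1))
    ),
    "growth_biomass"
  )
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(fix, path)
  m <- read_sbml(path)
  expect_length(m$reactions, 5)
  expect_identical(exchange_reactions(m), "EX_A")
  expect_identical(m$reactions$R1$gpr,
                   gpr_or(gpr_and(gpr_gene("g1"), gpr_gene("g2")),
                          gpr_gene("g3")))
  expect_identical(m$biomass_id, "growth_biomass")
})

test_that("legacy Level 2 notes dialect is read (bounds, GPR, boundary species)", {
  legacy <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    '<model id="legacy">',
    '<listOfSpecies>',
    '<species id="M_a_e" name="acetate" compartment="e"/>',
    '<species id="M_a_b" name="acetate" compartment="b" boundaryCondition="true"/>',
    '<species id="M_b_c" name="bmet" compartment="c"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="EX_a" reversible="true">',
    '<listOfReactants><speciesReference species="M_a_e" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="M_a_b" stoichiometry="1"/></listOfProducts>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="-10"/><parameter id="UPPER_BOUND" value="1000"/>',
    '</listOfParameters></kineticLaw>',
    '</reaction>',
    '<reaction id="R1" reversible="false">',
    '<notes><body xmlns="http://www.w3.org/1999/xhtml">',
    '<p>GENE_ASSOCIATION: (g1 and g2) or g3</p>',
    '<p>SUBSYSTEM: Transport</p>',
    '</body></notes>',
    '<listOfReactants><speciesReference species="M_a_e" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="M_b_c" stoichiometry="1"/></listOfProducts>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="0"/><parameter id="UPPER_BOUND" value="999"/>',
    '</listOfParameters></kineticLaw>',
    '</reaction>',
    '<reaction id="Biomass_core" reversible="false">',
    '<listOfReactants><speciesReference species="M_b_c" stoichiometry="1"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions>',
    '</model>',
    '</sbml>'
  )
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(legacy, path)
  m <- read_sbml(path)
  # boundary species dropped: EX_a becomes a one-metabolite exchange
  expect_identical(exchange_reactions(m), "EX_a")
  expect_false("M_a_b" %in% m$metabolites$id)
  expect_identical(m$reactions$EX_a$lb, -10)
  expect_identical(m$reactions$R1$ub, 999)
  expect_identical(m$reactions$R1$gpr,
                   gpr_or(gpr_and(gpr_gene("g1"), gpr_gene("g2")),
                          gpr_gene("g3")))
  expect_identical(m$reactions$R1$subsystem, "Transport")
  # biomass found by the default id pattern
  expect_identical(m$biomass_id, "Biomass_core")
})

test_that("biomass identification fails loudly on ambiguity or absence", {
  m <- toy_chain_model()
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  # strip the objective block so the pattern is the only route
  raw <- readLines(path)
  raw <- raw[!grepl("Objective|fluxObjective", raw)]
  path2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(raw, path2)
  expect_error(read_sbml(path2, biomass_pattern = "no_such_thing"),
               "no biomass reaction")
  expect_error(read_sbml(path2, biomass_pattern = "EX_A|BIOMASS"), "ambiguous")
  expect_identical(read_sbml(path2)$biomass_id, "BIOMASS")
})
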