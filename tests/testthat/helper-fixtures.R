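# Shared fixtures: tiny hand-built models and a default synthetic family.

# Linear chain: EX_A (uptake cap 10) -> A, A -> B, biomass consumes B 1:1.
# Analytic optimum equals the uptake bound.
toy_chain_model <- function(uptake = 10) {
  metabolic_model(
    "chain",
    data.frame(id = c("A_e", "B_c"), compartment = c("e", "c")),
    list(
      reaction("EX_A", c(A_e = -1), lb = -uptake, ub = 1000),
      reaction("CONV", c(A_e = -1, B_c = 1), gpr = gpr_gene("g1")),
      reaction("BIOMASS", c(B_c = -1))
    ),
    "BIOMASS"
  )
}

# Isozyme pair: either g2a or g2b suffices for the second step, so only the
# double deletion {g2a, g2b} (and the single {g1}) abolishes growth.
toy_isozyme_model <- function() {
  metabolic_model(
    "iso",
    data.frame(id = c("A_e", "B_c", "C_c"), compartment = c("e", "c", "c")),
    list(
      reaction("EX_A", c(A_e = -1), lb = -10, ub = 1000),
      reaction("S1", c(A_e = -1, B_c = 1), gpr = gpr_gene("g1")),
      reaction("S2x", c(B_c = -1, C_c = 1), gpr = gpr_gene("g2a")),
      reaction("S2y", c(B_c = -1, C_c = 1), gpr = gpr_gene("g2b")),
      reaction("BIOMASS", c(C_c = -1))
    ),
    "BIOMASS"
  )
}

# One shared synthetic family per test run (generation is seeded, so this
# is reproducible; caching avoids regenerating it in every test block).
family_env <- new.env(parent = emptyenv())
default_family <- function(seed = 7) {
  key <- paste0("fam", seed)
  if (is.null(family_env[[key]])) {
    spec <- family_spec(seed = seed)
    tpl <- generate_template(spec)
    fam <- generate_family(tpl, spec)
    fam$template <- tpl
    fam$spec <- spec
    family_env[[key]] <- fam
  }
  family_env[[key]]
}
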