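test_that("self-derivation returns the template unchanged with an empty report", {
  fam <- default_family()
  out <- derive_strain_model(fam$template, fam$table, "S1",
                             template_strain = "S1", id = fam$template$id)
  expect_identical(names(out$model$reactions), names(fam$template$reactions))
  expect_identical(out$model$genes, fam$template$genes)
  expect_identical(nrow(out$report$removed_reactions), 0L)
  for (rid in names(fam$template$reactions))
    expect_identical(deparse_gpr(out$model$reactions[[rid]]$gpr),
                     deparse_gpr(fam$template$reactions[[rid]]$gpr))
})

test_that("derivation removes reactions whose genes lack orthologs, with reasons", {
  fam <- default_family()
  tpl <- fam$template
  # plant a clean loss: remove one singleton-GPR reaction's gene from S2
  singleton_rxns <- Filter(function(rid) {
    g <- tpl$reactions[[rid]]$gpr
    g$op == "gene" && sum(vapply(tpl$reactions, function(r)
      g$gene %in% gpr_genes(r$gpr), logical(1))) == 1
  }, names(tpl$reactions))
  rid <- singleton_rxns[[1]]
  gene <- tpl$reactions[[rid]]$gpr$gene
  members <- fam$table$members
  members <- members[!(members$strain == "S2" &
                         members$group == paste0("og_", gene)), ]
  tab <- ortholog_table(fam$strains, members)
  out <- derive_strain_model(tpl, tab, "S2", template_strain = "S1")
  expect_true(rid %in% out$report$removed_reactions$reaction)
  expect_false(rid %in% names(out$model$reactions))
  expect_identical(
    out$report$removed_reactions$missing_genes[
      out$report$removed_reactions$reaction == rid], gene)
  # derived reaction set is always a subset of the template's
  expect_true(all(names(out$model$reactions) %in% names(tpl$reactions)))
})

test_that("losing one isozyme keeps the reaction with the surviving gene", {
  tpl <- metabolic_model(
    "t",
    data.frame(id = c("A_e", "B_c"), compartment = c("e", "c")),
    list(reaction("EX_A", c(A_e = -1), lb = -10),
         reaction("R", c(A_e = -1, B_c = 1),
                  gpr = gpr_or(gpr_gene("ga"), gpr_gene("gb"))),
         reaction("BM", c(B_c = -1))),
    "BM"
  )
  tab <- ortholog_table(
    c("T", "X"),
    data.frame(group = c("og1", "og1", "og2"),
               strain = c("T", "X", "T"),
               gene = c("ga", "X_ga", "gb"),
               pseudo = FALSE)
  )
  out <- derive_strain_model(tpl, tab, "X", template_strain = "T")
  expect_true("R" %in% names(out$model$reactions))
  expect_identical(out$model$reactions$R$gpr, gpr_gene("X_ga"))
  expect_identical(nrow(out$report$removed_reactions), 0L)
})

test_that("growth conflicts are flagged against observations", {
  fam <- default_family()
  m <- fam$models$S1
  obs <- data.frame(carbon = c("pyr", "pyr", "ac"),
                    acceptor = c("o2", "no3", "o2"),
                    observed = c(TRUE, TRUE, TRUE))
  conflicts <- detect_growth_conflicts(m, obs)
  # the template grows on pyruvate with either acceptor but not on acetate
  expect_identical(conflicts$carbon, "ac")
  expect_false(conflicts$predicted)
  expect_identical(nrow(detect_growth_conflicts(m, obs[0, ])), 0L)
  # unrepresentable compounds predict no growth rather than erroring
  obs2 <- data.frame(carbon = "unobtainium", acceptor = "o2", observed = FALSE)
  expect_identical(nrow(detect_growth_conflicts(m, obs2)), 0L)
})

test_that("core construction keeps conserved GPRs and only essential non-GPR reactions", {
  fam <- default_family()
  core <- build_core_model(fam$template, fam$table, condition = fam$condition,
                           template_strain = "S1")
  m <- core$model
  # the core grows on the construction condition
  expect_true(deletion_grows(m, character(), fam$condition))
  # every retained non-GPR (non-exchange) reaction is individually essential
  for (rid in core$retained_non_gpr) {
    dropped <- m
    dropped$reactions[[rid]]$lb <- 0
    dropped$reactions[[rid]]$ub <- 0
    expect_false(deletion_grows(dropped, character(), fam$condition),
                 label = paste("reaction", rid, "should be essential"))
  }
  # core genes = intersection of per-strain memberships (template gene ids),
  # plus genes of flagged isozyme exceptions only
  conserved <- sub("^og_", "", conserved_groups(fam$table))
  exception_genes <- unlist(lapply(core$isozyme_exceptions, function(rid)
    gpr_genes(fam$template$reactions[[rid]]$gpr)))
  expect_true(all(setdiff(m$genes, exception_genes) %in% conserved))
  # reaction set is a subset of the template's
  expect_true(all(names(m$reactions) %in% names(fam$template$reactions)))
})

test_that("core growth capabilities are a subset of the template's", {
  fam <- default_family()
  core <- build_core_model(fam$template, fam$table, condition = fam$condition,
                           template_strain = "S1")
  carbons <- c("pyr", "ac")
  acceptors <- c("o2", "no3", "fum")
  both <- growth_phenotype_matrix(list(template = fam$template,
                                       core = core$model),
                                  carbons, acceptors)
  expect_true(all(both$layers[, , "core"] <= both$layers[, , "template"]))
})

test_that("all-conserved table reduces the core to template minus non-essential non-GPR", {
  fam <- default_family()
  # a table where S1's genes are conserved everywhere (every strain keeps all)
  members <- do.call(rbind, lapply(fam$strains, function(s)
    data.frame(group = paste0("og_", fam$template$genes), strain = s,
               gene = if (s == "S1") fam$template$genes
                      else paste0(s, "_", fam$template$genes),
               pseudo = FALSE)))
  tab <- ortholog_table(fam$strains, members)
  core <- build_core_model(fam$template, tab, condition = fam$condition,
                           template_strain = "S1")
  expect_length(core$isozyme_exceptions, 0)
  expect_setequal(core$model$genes, fam$template$genes)
  dropped <- setdiff(names(fam$template$reactions), names(core$model$reactions))
  # everything dropped was a non-essential reaction with no gene association
  for (rid in dropped)
    expect_true(is_gpr_empty(fam$template$reactions[[rid]]$gpr))
})

test_that("core construction is invariant to strain order", {
  fam <- default_family()
  a <- build_core_model(fam$template, fam$table, strains = fam$strains,
                        condition = fam$condition, template_strain = "S1")
  b <- build_core_model(fam$template, fam$table, strains = rev(fam$strains),
                        condition = fam$condition, template_strain = "S1")
  expect_identical(names(a$model$reactions), names(b$model$reactions))
  expect_identical(a$model$genes, b$model$genes)
})
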