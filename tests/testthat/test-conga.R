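test_that("gene alignment partitions genes through the ortholog table", {
  fam <- default_family()
  # identical models: everything shared
  aln <- align_genes(fam$models$S2, fam$models$S2, fam$table, "S2", "S2")
  expect_length(aln$unique_a, 0)
  expect_length(aln$unique_b, 0)
  expect_length(aln$shared_groups, length(fam$models$S2$genes))
  # across strains: shared count equals the table intersection restricted
  # to genes actually present in the models
  aln2 <- align_genes(fam$models$S2, fam$models$S3, fam$table, "S2", "S3")
  g2 <- gene_groups(fam$table, "S2")
  g3 <- gene_groups(fam$table, "S3")
  manual <- intersect(unique(g2[names(g2) %in% fam$models$S2$genes]),
                      unique(g3[names(g3) %in% fam$models$S3$genes]))
  expect_setequal(aln2$shared_groups, manual)
  # the three parts cover both gene sets
  covered_a <- c(aln2$unique_a,
                 names(g2)[g2 %in% aln2$shared_groups])
  expect_setequal(intersect(covered_a, fam$models$S2$genes), fam$models$S2$genes)
  expect_error(align_genes(fam$models$S2, fam$models$S3, fam$table, "S2", "S9"),
               "absent")
})

test_that("deletion-set enumeration agrees with brute force for k = 1 and 2", {
  fam <- default_family()
  cond <- fam$condition
  a <- fam$models$S2
  b <- fam$models$S4
  for (k in 1:2) {
    ours <- find_deletion_sets(a, b, cond, fam$table, "S2", "S4", k = k)
    keys <- vapply(ours, function(r) paste(r$deletion_set, collapse = "+"),
                   character(1))
    brute <- brute_force_conga(a, b, cond, fam$table, "S2", "S4", k = k)
    # brute-force separating sets, reduced to minimal ones
    sep <- brute[brute$grows_a != brute$grows_b, , drop = FALSE]
    singles_any_lethal <- brute$set[brute$size == 1 &
                                      (!brute$grows_a | !brute$grows_b)]
    minimal <- vapply(seq_len(nrow(sep)), function(i) {
      if (sep$size[i] == 1) return(TRUE)
      parts <- strsplit(sep$set[i], "+", fixed = TRUE)[[1]]
      !any(parts %in% singles_any_lethal)
    }, logical(1))
    expect_setequal(keys, sep$set[minimal])
    # outcomes and flux differences are coherent
    for (r in ours) {
      expect_true(xor(r$grows_a, r$grows_b))
      expect_gt(r$flux_difference, 1e-6)
    }
  }
  # identical models yield no separating sets
  expect_length(find_deletion_sets(a, a, cond, fam$table, "S2", "S2", k = 1), 0)
})

test_that("swapping the model roles mirrors the result set", {
  fam <- default_family()
  cond <- fam$condition
  ab <- find_deletion_sets(fam$models$S2, fam$models$S4, cond, fam$table,
                           "S2", "S4", k = 1)
  ba <- find_deletion_sets(fam$models$S4, fam$models$S2, cond, fam$table,
                           "S4", "S2", k = 1)
  key <- function(rs) sort(vapply(rs, function(r)
    paste(r$deletion_set, collapse = "+"), character(1)))
  expect_identical(key(ab), key(ba))
  for (r in ab) {
    m <- ba[[which(key(ba) == paste(r$deletion_set, collapse = "+"))[1]]]
    expect_identical(r$grows_a, m$grows_b)
    expect_identical(r$grows_b, m$grows_a)
  }
})

test_that("planted differences are found and correctly classified", {
  fam <- default_family()
  cond <- fam$condition
  for (type in c("genetic", "biomass", "metabolic")) {
    pl <- plant_difference(fam$models$S2, fam$models$S3, fam$table,
                           "S2", "S3", type)
    res <- find_deletion_sets(pl$model_a, pl$model_b, cond, pl$table,
                              "S2", "S3", k = 1)
    hit <- Filter(function(r) identical(r$deletion_set, pl$deletion_set), res)
    expect_length(hit, 1)
    r <- classify_difference(hit[[1]], pl$model_a, pl$model_b)
    expect_identical(r$grows_a, pl$expected$grows_a)
    expect_identical(r$grows_b, pl$expected$grows_b)
    expect_true(pl$expected$label %in% r$classifications)
    # metabolic is the fallback: never co-assigned with an explained case
    if (type != "metabolic") expect_false("metabolic" %in% r$classifications)
  }
})

test_that("every separating set receives at least one classification", {
  fam <- default_family()
  cond <- fam$condition
  # a planted pair guarantees at least one separating set; any natural
  # differences between the strains ride along
  pl <- plant_difference(fam$models$S1, fam$models$S4, fam$table,
                         "S1", "S4", "genetic")
  res <- find_deletion_sets(pl$model_a, pl$model_b, cond, pl$table,
                            "S1", "S4", k = 1)
  expect_gte(length(res), 1)
  for (r in res) {
    cls <- classify_difference(r, pl$model_a, pl$model_b)$classifications
    expect_gte(length(cls), 1)
    expect_true(all(cls %in% c("genetic", "biomass", "metabolic")))
  }
  # a result with equal growth flags violates the contract
  fake <- res[[1]]
  fake$grows_b <- fake$grows_a
  expect_error(classify_difference(fake, pl$model_a, pl$model_b), "contract")
})

test_that("unique-lethal summaries match hand enumeration on a planted triple", {
  fam <- default_family()
  cond <- fam$condition
  pl <- plant_difference(fam$models$S2, fam$models$S3, fam$table,
                         "S2", "S3", "genetic")
  models <- list(S2 = pl$model_a, S3 = pl$model_b, S4 = fam$models$S4)
  summ <- summarize_unique_lethal(models, pl$table, c("S2", "S3", "S4"),
                                  cond, k = 1)
  # hand enumeration: lethal singles per model over shared groups
  shared_all <- Reduce(intersect, lapply(c("S2", "S3", "S4"), function(s) {
    g <- gene_groups(pl$table, s)
    unique(g[names(g) %in% models[[match(s, c("S2", "S3", "S4"))]]$genes])
  }))
  lethal <- function(m, s, grp) {
    g <- gene_groups(pl$table, s)
    del <- intersect(names(g)[g %in% grp], m$genes)
    !deletion_grows(m, del, cond)
  }
  for (mi in seq_along(models)) {
    s <- c("S2", "S3", "S4")[mi]
    expected <- sum(vapply(shared_all, function(grp) {
      mine <- lethal(models[[mi]], s, grp)
      others <- vapply(seq_along(models)[-mi], function(oj)
        lethal(models[[oj]], c("S2", "S3", "S4")[oj], grp), logical(1))
      mine && any(!others)
    }, logical(1)))
    got <- summ$counts$n_unique_lethal[summ$counts$model == s]
    expect_gte(got, expected)  # pairwise search may add pair-specific groups
    # the planted genetic difference lands on S3
    if (s == "S3")
      expect_true(pl$deletion_set %in%
                    summ$details$group[summ$details$model == "S3"])
  }
  # identical models have nothing unique
  summ0 <- summarize_unique_lethal(list(A = fam$models$S2, B = fam$models$S2),
                                   fam$table, c("S2", "S2"), cond, k = 1)
  expect_true(all(summ0$counts$n_unique_lethal == 0))
})

test_that("subsystem mapping tallies unique reactions touched by deletions", {
  fam <- default_family()
  cond <- fam$condition
  expect_identical(nrow(map_to_subsystems(list(), fam$models)), 0L)
  pl <- plant_difference(fam$models$S2, fam$models$S3, fam$table,
                         "S2", "S3", "genetic")
  res <- find_deletion_sets(pl$model_a, pl$model_b, cond, pl$table,
                            "S2", "S3", k = 1)
  hit <- Filter(function(r) identical(r$deletion_set, pl$deletion_set), res)
  tab <- map_to_subsystems(hit, list(pl$model_a, pl$model_b))
  # the planted target is the pyruvate transporter in both models
  expect_identical(tab$subsystem, "Transport")
  expect_identical(tab$n_reactions, 2L)
})
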