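# Independent oracles the implementation is checked against.  These stay
# deliberately naive and share no code with the package internals.

# Brute-force GPR evaluation: render the tree as an R logical expression
# and eval() it with per-gene truth values.
gpr_to_expression <- function(gpr) {
  if (is.null(gpr) || gpr$op == "empty") return("TRUE")
  if (gpr$op == "gene") return(sprintf("`%s`", gpr$gene))
  op <- if (gpr$op == "and") " & " else " | "
  paste0("(", paste(vapply(gpr$args, gpr_to_expression, character(1)),
                    collapse = op), ")")
}

eval_gpr_oracle <- function(gpr, deleted) {
  genes <- gpr_genes(gpr)
  env <- as.list(stats::setNames(!(genes %in% deleted), genes))
  isTRUE(eval(parse(text = gpr_to_expression(gpr)), envir = env))
}

# Random GPR tree with at most max_leaves leaves.
random_gpr <- function(max_leaves = 8) {
  genes <- sprintf("g%d", seq_len(sample(max_leaves, 1)))
  build <- function(pool) {
    if (length(pool) == 1) return(gpr_gene(pool))
    split_at <- sample(length(pool) - 1, 1)
    op <- sample(c(gpr_and, gpr_or), 1)[[1]]
    op(build(pool[seq_len(split_at)]), build(pool[-seq_len(split_at)]))
  }
  build(sample(genes))
}

# Naive LP oracle: an independently coded matrix-form FBA (split variables
# v = p - m, p, m >= 0; bounds as inequality rows) solved by scipy's HiGHS
# backend through the python interpreter.  Problems are batched into one
# interpreter call.  Returns a numeric vector of objectives (NA where the
# oracle reports infeasibility).
scipy_fba_objectives <- function(models) {
  probs <- lapply(models, function(m) {
    S <- stoichiometric_matrix(m)
    list(S = unname(S),
         lb = unname(vapply(m$reactions, function(r) r$lb, numeric(1))),
         ub = unname(vapply(m$reactions, function(r) r$ub, numeric(1))),
         c = as.numeric(colnames(S) == m$biomass_id))
  })
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  jsonlite::write_json(probs, fin, digits = NA, auto_unbox = FALSE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    "probs = json.load(open(sys.argv[1]))",
    "out = []",
    "for p in probs:",
    "    S = np.array(p['S']); lb = np.array(p['lb']); ub = np.array(p['ub'])",
    "    c = np.array(p['c']); n = len(c)",
    "    # split variables: v = pos - neg, pos, neg >= 0",
    "    Aeq = np.hstack([S, -S])",
    "    Aub = np.vstack([np.hstack([np.eye(n), -np.eye(n)]),",
    "                     np.hstack([-np.eye(n), np.eye(n)])])",
    "    bub = np.concatenate([ub, -lb])",
    "    cc = np.concatenate([-c, c])  # linprog minimizes",
    "    r = linprog(cc, A_ub=Aub, b_ub=bub, A_eq=Aeq,",
    "                b_eq=np.zeros(S.shape[0]), bounds=(0, None), method='highs')",
    "    out.append(-r.fun if r.status == 0 else None)",
    "json.dump(out, open(sys.argv[2], 'w'))"
  ), script)
  status <- system2("python", c(script, fin, fout))
  if (status != 0) stop("python LP oracle failed")
  vals <- jsonlite::fromJSON(fout)
  vapply(vals, function(v) if (is.null(v)) NA_real_ else as.numeric(v), numeric(1))
}

# Brute-force essentiality: plain loops over deletion_grows, no caching.
brute_force_essential <- function(model, condition, set_size = 1) {
  grows <- function(del) deletion_grows(model, del, condition)
  singles <- Filter(function(g) !grows(g), model$genes)
  if (set_size == 1) return(lapply(singles, identity))
  viable <- setdiff(model$genes, singles)
  out <- list()
  if (length(viable) >= 2) {
    for (p in utils::combn(sort(viable), 2, simplify = FALSE)) {
      if (!grows(p)) out[[length(out) + 1L]] <- p
    }
  }
  out
}

# Brute-force deletion-set comparison over shared ortholog groups: direct
# enumeration with fresh FBA per call.  Returns a data frame keyed by the
# deletion set with both growth outcomes.
brute_force_conga <- function(model_a, model_b, condition, table,
                              strain_a, strain_b, k = 1) {
  ga <- gene_groups(table, strain_a)
  gb <- gene_groups(table, strain_b)
  shared <- sort(intersect(unique(ga[names(ga) %in% model_a$genes]),
                           unique(gb[names(gb) %in% model_b$genes])))
  members <- function(map, model, groups)
    intersect(names(map)[map %in% groups], model$genes)
  outcome <- function(groups) {
    c(a = deletion_grows(model_a, members(ga, model_a, groups), condition),
      b = deletion_grows(model_b, members(gb, model_b, groups), condition))
  }
  sets <- lapply(shared, identity)
  if (k == 2 && length(shared) >= 2)
    sets <- c(sets, utils::combn(shared, 2, simplify = FALSE))
  rows <- lapply(sets, function(s) {
    o <- outcome(s)
    data.frame(set = paste(s, collapse = "+"), size = length(s),
               grows_a = o[["a"]], grows_b = o[["b"]])
  })
  do.call(rbind, rows)
}

# Independent confusion-matrix tally for fitness evaluation.
confusion_oracle <- function(predictions, calls) {
  n <- 0L; agree <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_len(nrow(calls))) {
    if (calls$call[i] == "undetermined") next
    j <- which(predictions$gene == calls$gene[i] &
                 predictions$condition == calls$condition[i])
    if (length(j) == 0) next
    n <- n + 1L
    pred <- predictions$predicted[j]
    obs <- calls$call[i] == "growth"
    if (pred == obs) agree <- agree + 1L
    else if (pred) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(n = n, accuracy = 100 * agree / n, fp = 100 * fp / n, fn = 100 * fn / n)
}
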