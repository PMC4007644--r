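# Growth-phenotype matrices over carbon x electron-acceptor grids, binary
# gene-content matrices, and hierarchical clustering of models.

#' Predicted growth phenotypes over a condition grid
#'
#' Runs FBA for every model under every (carbon source, electron acceptor)
#' pair; all models see identical exchange constraints.  A compound a model
#' cannot exchange scores 0 (no growth) and is recorded in the log rather
#' than treated as missing, matching a union-condition simulation design.
#'
#' @param models Named list of [metabolic_model()] objects.
#' @param carbon_sources,electron_acceptors Character vectors of compound
#'   names (rows and columns of the matrix).
#' @param nitrogen Nitrogen source for every condition.
#' @param config A [medium_config()].
#' @param threshold Growth threshold.
#' @return An object of class `phenotype_matrix`: `layers` (3-d 0/1 array,
#'   carbon x acceptor x model), `counts` (per-cell number of growing
#'   models) and `log` (data frame of non-representable compound events).
#' @export
growth_phenotype_matrix <- function(models, carbon_sources, electron_acceptors,
                                    nitrogen = "nh4", config = medium_config(),
                                    threshold = 1e-6) {
  stopifnot(length(carbon_sources) >= 1L, length(electron_acceptors) >= 1L)
  labels <- names(models)
  if (is.null(labels)) labels <- vapply(models, function(m) m$id, character(1))
  layers <- array(0L, dim = c(length(carbon_sources), length(electron_acceptors),
                              length(models)),
                  dimnames = list(carbon_sources, electron_acceptors, labels))
  log <- list()
  for (k in seq_along(models)) {
    for (i in seq_along(carbon_sources)) {
      for (j in seq_along(electron_acceptors)) {
        cond <- growth_condition(carbon_sources[i], electron_acceptors[j], nitrogen)
        grows <- tryCatch(
          deletion_grows(models[[k]], character(), cond, config, threshold),
          strainflux_not_representable = function(e) {
            log[[length(log) + 1L]] <<- data.frame(
              model = labels[k], carbon = carbon_sources[i],
              acceptor = electron_acceptors[j], message = conditionMessage(e))
            FALSE
          })
        layers[i, j, k] <- as.integer(grows)
      }
    }
  }
  structure(
    list(layers = layers, counts = apply(layers, c(1, 2), sum),
         log = if (length(log) > 0L) do.call(rbind, log)
               else data.frame(model = character(), carbon = character(),
                               acceptor = character(), message = character())),
    class = "phenotype_matrix"
  )
}

#' @export
print.phenotype_matrix <- function(x, ...) {
  d <- dim(x$layers)
  cat("<phenotype_matrix> ", d[1], " carbon sources x ", d[2],
      " electron acceptors x ", d[3], " models\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Per-model binary condition profiles from a phenotype matrix
#'
#' Flattens the carbon x acceptor grid into one row per condition pair with
#' one 0/1 column per model, the form consumed by [cluster_models()].
#'
#' @param pheno A `phenotype_matrix`.
#' @return Integer matrix, condition pairs by models.
#' @export
phenotype_profiles <- function(pheno) {
  d <- dim(pheno$layers)
  out <- matrix(as.integer(pheno$layers), nrow = d[1] * d[2], ncol = d[3])
  rownames(out) <- as.vector(outer(dimnames(pheno$layers)[[1]],
                                   dimnames(pheno$layers)[[2]], paste, sep = "|"))
  colnames(out) <- dimnames(pheno$layers)[[3]]
  out
}

#' Binary gene-content matrix over models
#'
#' Entry 1 iff the ortholog group (or raw gene id, without a table) has a
#' functional member among the model's genes.  Rows identical across all
#' models can optionally be dropped for display; identical coordinates
#' contribute nothing to euclidean distances, so clustering is unaffected.
#'
#' @param models Named list of [metabolic_model()] objects (>= 2).
#' @param table Optional [ortholog_table()].
#' @param strains Strain ids in `table`, one per model.
#' @param drop_invariant Drop rows identical across all models?
#' @return Integer 0/1 matrix, ortholog groups (or genes) by models.
#' @export
gene_content_matrix <- function(models, table = NULL, strains = NULL,
                                drop_invariant = FALSE) {
  stopifnot(length(models) >= 2L)
  labels <- names(models)
  if (is.null(labels)) labels <- vapply(models, function(m) m$id, character(1))
  if (is.null(table)) {
    keys <- lapply(models, function(m) m$genes)
  } else {
    stopifnot(length(strains) == length(models))
    keys <- Map(function(m, s) {
      grp <- gene_groups(table, s)[m$genes]
      unique(ifelse(is.na(grp), paste0("gene:", m$genes), grp))
    }, models, strains)
  }
  rows <- sort(unique(unlist(keys)))
  mat <- vapply(keys, function(k) as.integer(rows %in% k),
                integer(length(rows)))
  dimnames(mat) <- list(rows, labels)
  if (drop_invariant) {
    keep <- apply(mat, 1L, function(r) length(unique(r)) > 1L)
    mat <- mat[keep, , drop = FALSE]
  }
  mat
}

#' Hierarchically cluster models on binary profiles
#'
#' Computes euclidean distances between model columns and agglomerates with
#' the requested linkage (average by default; only the distance metric is
#' pinned by convention, so the linkage is exposed).  Columns are taken in
#' lexicographic order of model id so merge-order ties break
#' deterministically.
#'
#' @param binary_matrix Numeric/integer matrix, features by models (>= 2
#'   model columns).
#' @param method Linkage passed to [stats::hclust()].
#' @return An object of class `cluster_result`: `dist` (the distance
#'   matrix), `hclust`, `leaf_order` (labels left to right), `first_merge`
#'   (labels joined at the lowest height) and `newick` (the dendrogram with
#'   branch lengths).
#' @export
cluster_models <- function(binary_matrix, method = "average") {
  if (is.null(dim(binary_matrix)) || ncol(binary_matrix) < 2L)
    stop("clustering needs at least two model columns")
  binary_matrix <- binary_matrix[, order(colnames(binary_matrix)), drop = FALSE]
  d <- stats::dist(t(binary_matrix), method = "euclidean")
  hc <- stats::hclust(d, method = method)
  labels <- colnames(binary_matrix)
  first <- labels[-hc$merge[1, ]]
  phy <- ape::as.phylo(hc)
  structure(
    list(dist = d, hclust = hc, leaf_order = labels[hc$order],
         first_merge = sort(first),
         newick = ape::write.tree(phy)),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", length(x$leaf_order), " models\n",
      "  leaf order:  ", paste(x$leaf_order, collapse = ", "), "\n",
      "  first merge: ", paste(x$first_merge, collapse = " + "), "\n",
      "  newick:      ", x$newick, "\n", sep = "")
  invisible(x)
}

#' Height at which two models first join one cluster
#'
#' Reads the cophenetic distance between two leaves off the dendrogram;
#' useful for topology assertions such as "A merges with B before C".
#'
#' @param result A `cluster_result`.
#' @param a,b Model labels.
#' @return Numeric merge height.
#' @export
merge_height <- function(result, a, b) {
  cd <- as.matrix(stats::cophenetic(result$hclust))
  cd[a, b]
}
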