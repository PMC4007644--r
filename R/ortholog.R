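# Ortholog tables: strain-by-group gene membership.
#
# The table aligns genes across strains.  Each group maps a strain to zero
# or more member genes; a trailing "^" on a member marks a pseudogene
# (a gene fragment), which is recorded but excluded from functional
# membership everywhere downstream.

#' Construct an ortholog table
#'
#' @param strains Character vector of strain ids.
#' @param members Data frame with columns `group`, `strain`, `gene`,
#'   `pseudo` (logical).
#' @return An object of class `ortholog_table`.
#' @export
ortholog_table <- function(strains, members) {
  stopifnot(is.character(strains), length(strains) >= 1L, !anyDuplicated(strains))
  stopifnot(is.data.frame(members),
            all(c("group", "strain", "gene", "pseudo") %in% names(members)))
  members <- members[, c("group", "strain", "gene", "pseudo")]
  bad <- setdiff(unique(members$strain), strains)
  if (length(bad) > 0L)
    stop("members reference unknown strains: ", paste(bad, collapse = ", "))
  dup <- members[duplicated(members[, c("strain", "gene")]), , drop = FALSE]
  if (nrow(dup) > 0L)
    stop("gene(s) in more than one group for a strain: ",
         paste(unique(paste0(dup$strain, ":", dup$gene)), collapse = ", "))
  rownames(members) <- NULL
  structure(list(strains = strains, members = members), class = "ortholog_table")
}

#' @export
print.ortholog_table <- function(x, ...) {
  cat("<ortholog_table> ", length(unique(x$members$group)), " groups x ",
      length(x$strains), " strains (", sum(x$members$pseudo),
      " pseudogene entries)\n", sep = "")
  invisible(x)
}

#' Functional members of ortholog groups for one strain
#'
#' @param table An [ortholog_table()].
#' @param strain Strain id.
#' @return Named list: group id -> character vector of non-pseudogene member
#'   genes for that strain (groups with no functional member are absent).
#' @export
functional_members <- function(table, strain) {
  stopifnot(strain %in% table$strains)
  m <- table$members
  m <- m[m$strain == strain & !m$pseudo, , drop = FALSE]
  split(m$gene, m$group)
}

# Named character vector: gene id -> group id (functional members only).
gene_groups <- function(table, strain) {
  m <- table$members
  m <- m[m$strain == strain & !m$pseudo, , drop = FALSE]
  stats::setNames(m$group, m$gene)
}

#' Ortholog groups with a functional member in every listed strain
#'
#' @param table An [ortholog_table()].
#' @param strains Strain ids (default: all strains in the table).
#' @return Character vector of group ids.
#' @export
conserved_groups <- function(table, strains = table$strains) {
  per <- lapply(strains, function(s) names(functional_members(table, s)))
  sort(Reduce(intersect, per))
}

#' Read an ortholog table from a delimited file
#'
#' Expected layout: a header line of strain ids (optionally preceded by a
#' `group` column naming the groups), then one row per ortholog group.  A
#' cell holds zero or more gene ids separated by `member_delim`; `-` or an
#' empty cell means the strain has no member.  A trailing `^` marks a
#' pseudogene.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @param member_delim Delimiter between co-ortholog members within a cell.
#' @return An [ortholog_table()].
#' @export
read_ortholog_table <- function(path, sep = "\t", member_delim = ",") {
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "", comment.char = "")
  has_group_col <- tolower(names(raw)[1]) == "group"
  if (has_group_col) {
    groups <- raw[[1]]
    raw <- raw[, -1, drop = FALSE]
  } else {
    groups <- sprintf("og_%04d", seq_len(nrow(raw)))
  }
  if (anyDuplicated(groups))
    stop("duplicate group ids in ", path)
  strains <- names(raw)
  rows <- list()
  for (j in seq_along(strains)) {
    for (i in seq_len(nrow(raw))) {
      cell <- trimws(raw[i, j])
      if (cell == "" || cell == "-") next
      genes <- trimws(strsplit(cell, member_delim, fixed = TRUE)[[1]])
      genes <- genes[nzchar(genes)]
      pseudo <- grepl("\\^$", genes)
      rows[[length(rows) + 1L]] <- data.frame(
        group = groups[i], strain = strains[j],
        gene = sub("\\^$", "", genes), pseudo = pseudo
      )
    }
  }
  members <- do.call(rbind, rows)
  dup <- which(duplicated(members[, c("strain", "gene")]))
  if (length(dup) > 0L) {
    bad <- members[dup[1], ]
    stop("duplicate gene '", bad$gene, "' for strain '", bad$strain,
         "' (group ", bad$group, ") in ", path)
  }
  ortholog_table(strains, members)
}

#' Write an ortholog table to a delimited file
#'
#' Inverse of [read_ortholog_table()]; pseudogenes are written with a
#' trailing `^`, absent strains as `-`, and a leading `group` column is
#' always emitted.
#'
#' @param table An [ortholog_table()].
#' @param path Output file path.
#' @param sep,member_delim As in [read_ortholog_table()].
#' @return Invisibly, `path`.
#' @export
write_ortholog_table <- function(table, path, sep = "\t", member_delim = ",") {
  m <- table$members
  groups <- sort(unique(m$group))
  cells <- matrix("-", nrow = length(groups), ncol = length(table$strains),
                  dimnames = list(groups, table$strains))
  m$tag <- ifelse(m$pseudo, paste0(m$gene, "^"), m$gene)
  for (g in groups) {
    for (s in unique(m$strain[m$group == g])) {
      cells[g, s] <- paste(m$tag[m$group == g & m$strain == s], collapse = member_delim)
    }
  }
  out <- data.frame(group = groups, cells, check.names = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
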