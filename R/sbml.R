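# SBML read/write.
#
# Reads both modern SBML Level 3 + fbc (flux bounds as parameters, gene
# associations as fbc:geneProductAssociation trees) and the legacy Level 2
# COBRA dialect (bounds in kineticLaw parameters, GPR strings and subsystem
# labels in notes, boundary species on exchange reactions).  Always writes
# Level 3 + fbc version 2.  Parsing is built on xml2; the SBML semantics
# layer lives here.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Read a metabolic model from SBML
#'
#' @param path Path to an SBML file (Level 3 + fbc, or Level 2 with
#'   COBRA-style notes).
#' @param biomass_pattern Case-insensitive regex used to identify the
#'   biomass reaction by id or name when the file's fbc objective does not
#'   designate one.  Ambiguity or absence of a candidate is an error that
#'   lists the offending reaction ids.
#' @return A [metabolic_model()].
#' @export
read_sbml <- function(path, biomass_pattern = "biomass") {
  doc <- xml2::read_xml(path)
  model_node <- xml_first(doc, "model")
  if (is.null(model_node)) stop("not an SBML file (no <model> element): ", path)
  model_id <- attr_or(model_node, "id", "model")

  # gene products (fbc): map SId -> label
  gp_nodes <- xml_all(doc, "geneProduct")
  gp_label <- character()
  for (gp in gp_nodes) {
    gid <- xml2::xml_attr(gp, "id")
    lab <- xml2::xml_attr(gp, "label")
    gp_label[gid] <- if (!is.na(lab) && nzchar(lab)) lab else gid
  }

  # species; legacy boundary species are dropped from the network
  sp_nodes <- xml_all(doc, "species")
  if (length(sp_nodes) == 0L) stop("SBML file has no species: ", path)
  sp_id <- vapply(sp_nodes, xml2::xml_attr, character(1), "id")
  sp_name <- vapply(sp_nodes, attr_or, character(1), "name", "")
  sp_comp <- vapply(sp_nodes, attr_or, character(1), "compartment", "c")
  sp_formula <- vapply(sp_nodes, attr_or, character(1), "chemicalFormula", NA_character_)
  sp_boundary <- vapply(sp_nodes, attr_or, character(1), "boundaryCondition", "false") == "true"
  boundary_ids <- sp_id[sp_boundary]
  metabolites <- data.frame(
    id = sp_id[!sp_boundary],
    name = ifelse(nzchar(sp_name[!sp_boundary]), sp_name[!sp_boundary], sp_id[!sp_boundary]),
    compartment = sp_comp[!sp_boundary],
    formula = sp_formula[!sp_boundary]
  )

  # flux-bound parameters (fbc dialect): global listOfParameters
  par_nodes <- xml_all(model_node, "parameter")
  par_value <- numeric()
  for (p in par_nodes) {
    pid <- xml2::xml_attr(p, "id")
    if (!is.na(pid)) par_value[pid] <- as.numeric(xml2::xml_attr(p, "value"))
  }

  rxn_nodes <- xml_all(doc, "reaction")
  if (length(rxn_nodes) == 0L) stop("SBML file has no reactions: ", path)
  reactions <- vector("list", length(rxn_nodes))
  for (i in seq_along(rxn_nodes)) {
    reactions[[i]] <- parse_sbml_reaction(rxn_nodes[[i]], par_value, gp_label,
                                          boundary_ids, path)
  }
  reactions <- Filter(Negate(is.null), reactions)

  biomass_id <- sbml_objective_reaction(doc)
  if (is.null(biomass_id)) {
    rids <- vapply(reactions, function(r) r$id, character(1))
    rnames <- vapply(reactions, function(r) r$name, character(1))
    hits <- rids[grepl(biomass_pattern, rids, ignore.case = TRUE) |
                 grepl(biomass_pattern, rnames, ignore.case = TRUE)]
    if (length(hits) == 0L)
      stop("no biomass reaction matches pattern '", biomass_pattern, "' in ",
           path, "; reaction ids: ", paste(utils::head(rids, 50), collapse = ", "))
    if (length(hits) > 1L)
      stop("biomass pattern '", biomass_pattern, "' is ambiguous in ", path,
           ": ", paste(hits, collapse = ", "))
    biomass_id <- hits
  }
  metabolic_model(model_id, metabolites, reactions, biomass_id)
}

parse_sbml_reaction <- function(node, par_value, gp_label, boundary_ids, path) {
  rid <- xml2::xml_attr(node, "id")
  rname <- attr_or(node, "name", rid)
  stoich <- numeric()
  for (side in c("listOfReactants", "listOfProducts")) {
    sign <- if (side == "listOfReactants") -1 else 1
    for (sr in xml_all(xml_first(node, side), "speciesReference")) {
      sp <- xml2::xml_attr(sr, "species")
      if (sp %in% boundary_ids) next
      coef <- as.numeric(attr_or(sr, "stoichiometry", "1"))
      stoich[sp] <- (if (is.na(stoich[sp])) 0 else stoich[sp]) + sign * coef
    }
  }
  stoich <- stoich[stoich != 0]
  if (length(stoich) == 0L) {
    warning("reaction ", rid, " touches only boundary species; dropped (", path, ")")
    return(NULL)
  }

  # bounds: fbc parameter references, else legacy kineticLaw parameters
  lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
  ub_ref <- xml2::xml_attr(node, "upperFluxBound")
  if (!is.na(lb_ref) || !is.na(ub_ref)) {
    lb <- if (!is.na(lb_ref)) par_value[[lb_ref]] else -1000
    ub <- if (!is.na(ub_ref)) par_value[[ub_ref]] else 1000
  } else {
    kl <- xml_first(node, "kineticLaw")
    lb <- NA_real_; ub <- NA_real_
    if (!is.null(kl)) {
      for (p in c(xml_all(kl, "parameter"), xml_all(kl, "localParameter"))) {
        pid <- toupper(attr_or(p, "id", attr_or(p, "name", "")))
        if (pid == "LOWER_BOUND") lb <- as.numeric(xml2::xml_attr(p, "value"))
        if (pid == "UPPER_BOUND") ub <- as.numeric(xml2::xml_attr(p, "value"))
      }
    }
    if (is.na(lb) || is.na(ub)) {
      rev <- attr_or(node, "reversible", "true") == "true"
      if (is.na(lb)) lb <- if (rev) -1000 else 0
      if (is.na(ub)) ub <- 1000
    }
  }

  notes <- sbml_notes_fields(node)
  gpr <- sbml_reaction_gpr(node, gp_label, notes)
  reaction(id = rid, name = rname, stoich = stoich, lb = lb, ub = ub,
           gpr = gpr, subsystem = notes[["SUBSYSTEM"]] %||% "")
}

# fbc:geneProductAssociation tree, else a GENE_ASSOCIATION notes string.
sbml_reaction_gpr <- function(node, gp_label, notes) {
  gpa <- xml_first(node, "geneProductAssociation")
  if (!is.null(gpa)) {
    kids <- xml2::xml_children(gpa)
    if (length(kids) == 0L) return(gpr_empty())
    return(parse_fbc_assoc(kids[[1]], gp_label))
  }
  txt <- notes[["GENE_ASSOCIATION"]] %||% notes[["GENE ASSOCIATION"]]
  if (is.null(txt)) return(gpr_empty())
  parse_gpr(txt)
}

parse_fbc_assoc <- function(node, gp_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- xml2::xml_attr(node, "geneProduct")
    lab <- gp_label[gid]
    return(gpr_gene(if (is.na(lab)) gid else unname(lab)))
  }
  args <- lapply(xml2::xml_children(node), parse_fbc_assoc, gp_label)
  if (nm == "and") do.call(gpr_and, args)
  else if (nm == "or") do.call(gpr_or, args)
  else stop("unexpected element in gene association: ", nm)
}

# "KEY: value" fields from a reaction's notes body.
sbml_notes_fields <- function(node) {
  notes <- xml_first(node, "notes")
  if (is.null(notes)) return(list())
  out <- list()
  for (p in xml_all(notes, "p")) {
    txt <- trimws(xml2::xml_text(p))
    m <- regmatches(txt, regexec("^([A-Za-z_ ]+):\\s*(.*)$", txt))[[1]]
    if (length(m) == 3L && nzchar(trimws(m[3]))) out[[trimws(m[2])]] <- trimws(m[3])
  }
  # some files use <html:p>, others bare text lines
  if (length(out) == 0L) {
    for (line in strsplit(xml2::xml_text(notes), "\n")[[1]]) {
      m <- regmatches(trimws(line), regexec("^([A-Za-z_ ]+):\\s*(.*)$", trimws(line)))[[1]]
      if (length(m) == 3L && nzchar(trimws(m[3]))) out[[trimws(m[2])]] <- trimws(m[3])
    }
  }
  out
}

sbml_objective_reaction <- function(doc) {
  objs <- xml_all(doc, "listOfObjectives")
  if (length(objs) == 0L) return(NULL)
  active <- xml2::xml_attr(objs[[1]], "activeObjective")
  for (obj in xml_all(objs[[1]], "objective")) {
    if (!is.na(active) && !identical(xml2::xml_attr(obj, "id"), active)) next
    fo <- xml_first(obj, "fluxObjective")
    if (!is.null(fo)) return(xml2::xml_attr(fo, "reaction"))
  }
  NULL
}

#' Write a metabolic model to SBML (Level 3 + fbc v2)
#'
#' Flux bounds are emitted as shared global parameters, gene associations
#' as `fbc:geneProductAssociation` trees (omitted for reactions with no
#' gene association), the biomass reaction as the active maximization
#' objective, and subsystems in reaction notes.  Output is byte-for-byte
#' deterministic for a given model.
#'
#' @param model A [metabolic_model()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  sid <- function(x) {
    x <- gsub("[^A-Za-z0-9_]", "_", x)
    ifelse(grepl("^[A-Za-z_]", x), x, paste0("x_", x))
  }
  num <- function(x) formatC(x, format = "g", digits = 17)

  bounds <- sort(unique(c(vapply(model$reactions, function(r) r$lb, numeric(1)),
                          vapply(model$reactions, function(r) r$ub, numeric(1)))))
  bnd_id <- stats::setNames(sprintf("bnd_%d", seq_along(bounds) - 1L), num(bounds))

  gene_sid <- stats::setNames(sid(paste0("G_", model$genes)), model$genes)

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="', SBML_CORE_NS, '" xmlns:fbc="', SBML_FBC_NS,
           '" level="3" version="1" fbc:required="false">'),
    paste0('  <model id="', esc(sid(model$id)), '" name="', esc(model$id),
           '" fbc:strict="false">'),
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" constant="true"/>',
            esc(sid(sort(unique(model$metabolites$compartment))))),
    '    </listOfCompartments>',
    '    <listOfSpecies>'
  )
  mets <- model$metabolites
  for (i in seq_len(nrow(mets))) {
    formula <- if (!is.na(mets$formula[i]) && nzchar(mets$formula[i]))
      paste0(' fbc:chemicalFormula="', esc(mets$formula[i]), '"') else ""
    lines <- c(lines, sprintf(
      '      <species id="%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"%s/>',
      esc(sid(mets$id[i])), esc(mets$name[i]), esc(sid(mets$compartment[i])), formula))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>',
             sprintf('      <parameter id="%s" value="%s" constant="true"/>',
                     unname(bnd_id), names(bnd_id)),
             '    </listOfParameters>', '    <listOfReactions>')
  for (rid in reaction_ids(model)) {
    r <- model$reactions[[rid]]
    lines <- c(lines, sprintf(
      '      <reaction id="%s" name="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      esc(sid(r$id)), esc(r$name), tolower(r$lb < 0),
      bnd_id[[num(r$lb)]], bnd_id[[num(r$ub)]]))
    if (nzchar(r$subsystem)) {
      lines <- c(lines,
        '        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
        sprintf('          <p>SUBSYSTEM: %s</p>', esc(r$subsystem)),
        '        </body></notes>')
    }
    for (side in c(-1, 1)) {
      part <- r$stoich[sign(r$stoich) == side]
      if (length(part) == 0L) next
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      lines <- c(lines, sprintf('        <%s>', tag),
                 sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         esc(sid(names(part))), num(abs(part))),
                 sprintf('        </%s>', tag))
    }
    if (!is_gpr_empty(r$gpr)) {
      lines <- c(lines, '        <fbc:geneProductAssociation>',
                 fbc_assoc_lines(r$gpr, gene_sid, indent = 10L),
                 '        </fbc:geneProductAssociation>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines,
    '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
            esc(sid(model$biomass_id))),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>')
  if (length(model$genes) > 0L) {
    lines <- c(lines, '    <fbc:listOfGeneProducts>',
               sprintf('      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
                       unname(gene_sid), esc(model$genes)),
               '    </fbc:listOfGeneProducts>')
  }
  lines <- c(lines, '  </model>', '</sbml>')
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

fbc_assoc_lines <- function(gpr, gene_sid, indent) {
  pad <- strrep(" ", indent)
  if (gpr$op == "gene")
    return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="%s"/>', pad, gene_sid[[gpr$gene]]))
  tag <- paste0("fbc:", gpr$op)
  c(sprintf("%s<%s>", pad, tag),
    unlist(lapply(gpr$args, fbc_assoc_lines, gene_sid, indent + 2L)),
    sprintf("%s</%s>", pad, tag))
}

# xml2 helpers: namespace-agnostic lookup by local element name.
xml_all <- function(node, name) {
  if (is.null(node)) return(list())
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
}

xml_first <- function(node, name) {
  if (is.null(node)) return(NULL)
  out <- xml2::xml_find_first(node, sprintf(".//*[local-name()='%s']", name))
  if (inherits(out, "xml_missing") || length(out) == 0L) NULL else out
}

attr_or <- function(node, name, default) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else v
}

`%||%` <- function(a, b) if (is.null(a)) b else a
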