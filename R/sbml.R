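## SBML Level 3 Version 1 + fbc version 2 import/export, built on xml2.
## Covers the subset constraint-based models need: compartments, species
## with charge and chemical formula, reactions with flux-bound parameters
## and gene-product associations, and the active objective. Round-trips
## preserve ids, formulas, charges, bounds, gene-association strings and
## the objective exactly.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

num_attr <- function(x) sprintf("%.17g", x)

sbml_bound_value <- function(chr) {
  if (chr == "INF") Inf else if (chr == "-INF") -Inf else as.numeric(chr)
}

## parse a gene-association string into nested fbc XML nodes
gpr_to_xml <- function(parent, s) {
  toks <- regmatches(s, gregexpr("\\(|\\)|[^()\\s]+", s, perl = TRUE))[[1]]
  pos <- 1L
  parse_expr <- function() {
    terms <- list(parse_term())
    ops <- character(0)
    while (pos <= length(toks) && toks[pos] %in% c("and", "or")) {
      ops <- c(ops, toks[pos]); pos <<- pos + 1L
      terms <- c(terms, list(parse_term()))
    }
    if (!length(ops)) return(terms[[1]])
    if (length(unique(ops)) > 1L) {
      stop("mixed and/or without parentheses in gene association: ", s)
    }
    list(op = ops[1], args = terms)
  }
  parse_term <- function() {
    if (toks[pos] == "(") {
      pos <<- pos + 1L
      e <- parse_expr()
      if (pos > length(toks) || toks[pos] != ")") {
        stop("unbalanced parentheses in gene association: ", s)
      }
      pos <<- pos + 1L
      e
    } else {
      g <- toks[pos]; pos <<- pos + 1L
      list(gene = g)
    }
  }
  emit <- function(node, e) {
    if (!is.null(e$gene)) {
      xml2::xml_add_child(node, "fbc:geneProductRef",
                          "fbc:geneProduct" = paste0("G_", e$gene))
    } else {
      sub <- xml2::xml_add_child(node, paste0("fbc:", e$op))
      for (a in e$args) emit(sub, a)
    }
  }
  e <- parse_expr()
  if (pos <= length(toks)) stop("trailing tokens in gene association: ", s)
  gpa <- xml2::xml_add_child(parent, "fbc:geneProductAssociation")
  emit(gpa, e)
  invisible(gpa)
}

xml_to_gpr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    sub("^G_", "", xml2::xml_attr(node, "geneProduct"))
  } else if (nm %in% c("and", "or")) {
    parts <- vapply(xml2::xml_children(node), xml_to_gpr, character(1))
    paste0("(", paste(parts, collapse = paste0(" ", nm, " ")), ")")
  } else {
    stop("unexpected node in gene association: ", nm)
  }
}

#' Write a model as SBML (Level 3, fbc v2)
#'
#' @param model a [metabolic_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_CORE_NS, "xmlns:fbc" = SBML_FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = model$id,
                             "fbc:strict" = "true")

  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (i in seq_along(model$compartments)) {
    xml2::xml_add_child(loc, "compartment",
                        id = names(model$compartments)[i],
                        name = unname(model$compartments[i]),
                        constant = "true")
  }

  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(
      los, "species", id = paste0("M_", m$id), name = m$name,
      compartment = m$compartment, hasOnlySubstanceUnits = "false",
      boundaryCondition = "false", constant = "false",
      "fbc:charge" = num_attr(m$charge))
    if (!is.na(m$formula)) {
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
    }
  }

  ## flux-bound parameters, one per distinct value
  bounds <- unlist(lapply(model$reactions,
                          function(r) c(r$lower_bound, r$upper_bound)))
  vals <- sort(unique(bounds))
  pid <- stats::setNames(sprintf("fb_%d", seq_along(vals)), num_attr(vals))
  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  for (v in vals) {
    xml2::xml_add_child(lop, "parameter", id = pid[[num_attr(v)]],
                        value = if (is.finite(v)) num_attr(v)
                                else if (v > 0) "INF" else "-INF",
                        constant = "true", "sboTerm" = "SBO:0000625")
  }

  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    rn <- xml2::xml_add_child(
      lor, "reaction", id = paste0("R_", r$id), name = r$name,
      reversible = if (r$lower_bound < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = pid[[num_attr(r$lower_bound)]],
      "fbc:upperFluxBound" = pid[[num_attr(r$upper_bound)]])
    if (!is.na(r$subsystem)) {
      notes <- xml2::xml_add_child(rn, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(body, "p", paste0("SUBSYSTEM: ", r$subsystem))
    }
    neg <- r$stoichiometry[r$stoichiometry < 0]
    pos <- r$stoichiometry[r$stoichiometry > 0]
    if (length(neg)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (j in seq_along(neg)) {
        xml2::xml_add_child(lre, "speciesReference",
                            species = paste0("M_", names(neg)[j]),
                            stoichiometry = num_attr(-neg[[j]]),
                            constant = "true")
      }
    }
    if (length(pos)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (j in seq_along(pos)) {
        xml2::xml_add_child(lpr, "speciesReference",
                            species = paste0("M_", names(pos)[j]),
                            stoichiometry = num_attr(pos[[j]]),
                            constant = "true")
      }
    }
    if (!is.na(r$gene_association) && nzchar(r$gene_association)) {
      gpr_to_xml(rn, r$gene_association)
    }
  }

  loo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                             "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  for (i in seq_along(model$objective)) {
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
                        "fbc:reaction" = paste0("R_",
                                                names(model$objective)[i]),
                        "fbc:coefficient" = num_attr(model$objective[[i]]))
  }

  genes <- model_genes(model)
  if (length(genes)) {
    lgp <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in genes) {
      xml2::xml_add_child(lgp, "fbc:geneProduct", "fbc:id" = paste0("G_", g),
                          "fbc:label" = g)
    }
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read an SBML (Level 3, fbc v2) model
#'
#' @param path path to an SBML file.
#' @return a [metabolic_model()].
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_CORE_NS, fbc = SBML_FBC_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (is.na(xml2::xml_name(mdl))) stop("no <model> element found in ", path)

  cps <- xml2::xml_find_all(mdl, "./s:listOfCompartments/s:compartment", ns)
  compartments <- stats::setNames(
    vapply(cps, function(x) {
      nm <- xml2::xml_attr(x, "name")
      if (is.na(nm)) xml2::xml_attr(x, "id") else nm
    }, character(1)),
    vapply(cps, xml2::xml_attr, character(1), "id"))

  sps <- xml2::xml_find_all(mdl, "./s:listOfSpecies/s:species", ns)
  mets <- lapply(sps, function(x) {
    charge <- xml2::xml_attr(x, "charge")
    if (is.na(charge)) charge <- "0"
    nm <- xml2::xml_attr(x, "name")
    id <- sub("^M_", "", xml2::xml_attr(x, "id"))
    metabolite(id,
               name = if (is.na(nm)) id else nm,
               formula = {
                 f <- xml2::xml_attr(x, "chemicalFormula")
                 if (is.na(f)) NA_character_ else f
               },
               charge = as.numeric(charge),
               compartment = xml2::xml_attr(x, "compartment"))
  })

  pars <- xml2::xml_find_all(mdl, "./s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(
    vapply(pars, function(x) sbml_bound_value(xml2::xml_attr(x, "value")),
           numeric(1)),
    vapply(pars, xml2::xml_attr, character(1), "id"))

  rns <- xml2::xml_find_all(mdl, "./s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rns, function(x) {
    id <- sub("^R_", "", xml2::xml_attr(x, "id"))
    sref <- function(xp, sign) {
      refs <- xml2::xml_find_all(x, xp, ns)
      if (!length(refs)) return(stats::setNames(numeric(0), character(0)))
      stats::setNames(
        sign * as.numeric(vapply(refs, xml2::xml_attr, character(1),
                                 "stoichiometry")),
        sub("^M_", "", vapply(refs, xml2::xml_attr, character(1), "species")))
    }
    st <- c(sref("./s:listOfReactants/s:speciesReference", -1),
            sref("./s:listOfProducts/s:speciesReference", 1))
    gpa <- xml2::xml_find_first(x, "./fbc:geneProductAssociation", ns)
    gpr <- if (is.na(xml2::xml_name(gpa))) NA_character_ else {
      xml_to_gpr(xml2::xml_child(gpa))
    }
    note <- xml2::xml_find_first(
      x, "./s:notes//*[starts-with(text(), 'SUBSYSTEM: ')]", ns)
    subsys <- if (is.na(xml2::xml_name(note))) NA_character_ else {
      sub("^SUBSYSTEM: ", "", xml2::xml_text(note))
    }
    nm <- xml2::xml_attr(x, "name")
    reaction(id, st,
             lower_bound = pval[[xml2::xml_attr(x, "lowerFluxBound")]],
             upper_bound = pval[[xml2::xml_attr(x, "upperFluxBound")]],
             name = if (is.na(nm)) id else nm,
             gene_association = gpr, subsystem = subsys)
  })

  fobj <- xml2::xml_find_all(
    mdl, "./fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  objective <- stats::setNames(
    as.numeric(vapply(fobj, xml2::xml_attr, character(1), "coefficient")),
    sub("^R_", "", vapply(fobj, xml2::xml_attr, character(1), "reaction")))

  metabolic_model(mets, rxns, objective = objective,
                  compartments = compartments,
                  id = xml2::xml_attr(mdl, "id"))
}
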