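# SBML Level 3 + FBC IO -------------------------------------------------------
#
# Flux bounds are carried as FBC bound parameters, GPRs as gene-product
# associations, and the objective as an FBC flux objective. Reaction kinds
# (internal/transport/exchange/objective) travel in a notes block, the
# conventional place for tool-specific annotation. Aggregate
# pseudo-metabolites may carry fractional charges/formula counts; these are
# written as-is (technically outside strict FBC, documented behaviour).

.sbml_core_ns <- "http://www.sbml.org/sbml/level3/version1/core"
.sbml_fbc_ns <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_mangle <- function(x) gsub("[^A-Za-z0-9_]", "__", x)

write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  num <- function(x) vapply(x, function(v) sprintf("%.15g", v), "")
  L <- character(0)
  add <- function(...) L <<- c(L, paste0(...))

  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<sbml xmlns="', .sbml_core_ns, '" xmlns:fbc="', .sbml_fbc_ns,
      '" level="3" version="1" fbc:required="false">')
  add('  <model id="', sbml_mangle(model$id), '" name="', esc(model$id),
      '" fbc:strict="true">')

  comps <- unique(model$mets$compartment)
  add('    <listOfCompartments>')
  for (cm in comps) {
    add('      <compartment id="', sbml_mangle(cm), '" constant="true"/>')
  }
  add('    </listOfCompartments>')

  add('    <listOfSpecies>')
  for (i in seq_len(nrow(model$mets))) {
    m <- model$mets[i, ]
    s <- paste0('      <species id="M_', sbml_mangle(m$id), '" name="',
                esc(m$name), '" compartment="', sbml_mangle(m$compartment),
                '" hasOnlySubstanceUnits="false" boundaryCondition="false"',
                ' constant="false" fbc:charge="', num(m$charge), '"')
    if (nzchar(m$formula)) {
      s <- paste0(s, ' fbc:chemicalFormula="', m$formula, '"')
    }
    add(s, "/>")
  }
  add('    </listOfSpecies>')

  bounds <- sort(unique(c(model$rxns$lb, model$rxns$ub)))
  bname <- stats::setNames(paste0("bnd_", seq_along(bounds)), num(bounds))
  add('    <listOfParameters>')
  for (b in bounds) {
    add('      <parameter id="', bname[[num(b)]], '" value="', num(b),
        '" constant="true"/>')
  }
  add('    </listOfParameters>')

  gpr_xml <- function(ast, indent) {
    pad <- strrep(" ", indent)
    if (!is.null(ast$gene)) {
      return(paste0(pad, '<fbc:geneProductRef fbc:geneProduct="G_',
                    sbml_mangle(ast$gene), '"/>'))
    }
    tag <- if (ast$op == "and") "fbc:and" else "fbc:or"
    c(paste0(pad, "<", tag, ">"),
      unlist(lapply(ast$args, gpr_xml, indent = indent + 2)),
      paste0(pad, "</", tag, ">"))
  }

  add('    <listOfReactions>')
  for (i in seq_len(nrow(model$rxns))) {
    r <- model$rxns[i, ]
    st <- model$stoich[[r$id]]
    add('      <reaction id="R_', sbml_mangle(r$id), '" name="', esc(r$name),
        '" reversible="', if (r$lb < 0) "true" else "false",
        '" fast="false" fbc:lowerFluxBound="', bname[[num(r$lb)]],
        '" fbc:upperFluxBound="', bname[[num(r$ub)]], '">')
    add('        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
        '<p>kind: ', r$kind, '</p></body></notes>')
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      add('        <listOfReactants>')
      for (k in seq_along(reac)) {
        add('          <speciesReference species="M_',
            sbml_mangle(names(reac)[k]), '" stoichiometry="',
            num(-reac[[k]]), '" constant="true"/>')
      }
      add('        </listOfReactants>')
    }
    if (length(prod)) {
      add('        <listOfProducts>')
      for (k in seq_along(prod)) {
        add('          <speciesReference species="M_',
            sbml_mangle(names(prod)[k]), '" stoichiometry="',
            num(prod[[k]]), '" constant="true"/>')
      }
      add('        </listOfProducts>')
    }
    ast <- parse_gpr(r$gpr)
    if (!is.null(ast)) {
      add('        <fbc:geneProductAssociation>')
      add(gpr_xml(ast, 10L))
      add('        </fbc:geneProductAssociation>')
    }
    add('      </reaction>')
  }
  add('    </listOfReactions>')

  add('    <fbc:listOfObjectives fbc:activeObjective="obj">')
  add('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
  add('        <fbc:listOfFluxObjectives>')
  add('          <fbc:fluxObjective fbc:reaction="R_',
      sbml_mangle(model$objective_id), '" fbc:coefficient="1"/>')
  add('        </fbc:listOfFluxObjectives>')
  add('      </fbc:objective>')
  add('    </fbc:listOfObjectives>')

  if (length(model$genes)) {
    add('    <fbc:listOfGeneProducts>')
    for (g in model$genes) {
      add('      <fbc:geneProduct fbc:id="G_', sbml_mangle(g),
          '" fbc:label="', esc(g), '"/>')
    }
    add('    </fbc:listOfGeneProducts>')
  }
  add('  </model>')
  add('</sbml>')
  writeLines(L, path)
  invisible(model)
}

read_model_sbml <- function(path, objective_id = NULL) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("SBML parse failure in ", path, ": ", conditionMessage(e))
  })
  ns <- c(c = .sbml_core_ns, fbc = .sbml_fbc_ns)
  mdl <- xml2::xml_find_first(doc, "./c:model", ns)
  if (inherits(mdl, "xml_missing")) stop("no <model> element in ", path)
  att <- function(node, name, default = NULL) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) default else v
  }

  # gene products: id -> label
  gp_nodes <- xml2::xml_find_all(mdl, ".//fbc:geneProduct", ns)
  gp_label <- stats::setNames(
    vapply(gp_nodes, function(n) {
      lbl <- att(n, "label")
      if (is.null(lbl)) sub("^G_", "", att(n, "id", "")) else lbl
    }, ""),
    vapply(gp_nodes, function(n) att(n, "id", ""), ""))

  par_nodes <- xml2::xml_find_all(mdl, "./c:listOfParameters/c:parameter", ns)
  par_val <- stats::setNames(
    vapply(par_nodes, function(n) as.numeric(att(n, "value", "NA")), 0),
    vapply(par_nodes, function(n) att(n, "id", ""), ""))

  sp_nodes <- xml2::xml_find_all(mdl, "./c:listOfSpecies/c:species", ns)
  mets <- lapply(sp_nodes, function(n) {
    id <- sub("^M_", "", att(n, "id", ""))
    metabolite(id, att(n, "name", id), att(n, "chemicalFormula", ""),
               as.numeric(att(n, "charge", "0")),
               att(n, "compartment", "c"))
  })

  parse_assoc <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- att(node, "geneProduct", "")
      lbl <- if (ref %in% names(gp_label)) gp_label[[ref]] else
        sub("^G_", "", ref)
      return(lbl)
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, parse_assoc, "")
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }

  rx_nodes <- xml2::xml_find_all(mdl, "./c:listOfReactions/c:reaction", ns)
  rxns <- lapply(rx_nodes, function(n) {
    id <- sub("^R_", "", att(n, "id", ""))
    sto <- c()
    for (sr in xml2::xml_find_all(n, "./c:listOfReactants/c:speciesReference", ns)) {
      sto[sub("^M_", "", att(sr, "species", ""))] <-
        -as.numeric(att(sr, "stoichiometry", "1"))
    }
    for (sr in xml2::xml_find_all(n, "./c:listOfProducts/c:speciesReference", ns)) {
      sto[sub("^M_", "", att(sr, "species", ""))] <-
        as.numeric(att(sr, "stoichiometry", "1"))
    }
    lbp <- att(n, "lowerFluxBound"); ubp <- att(n, "upperFluxBound")
    lb <- if (!is.null(lbp) && lbp %in% names(par_val)) par_val[[lbp]] else
      if (identical(att(n, "reversible", "true"), "true")) -1000 else 0
    ub <- if (!is.null(ubp) && ubp %in% names(par_val)) par_val[[ubp]] else 1000
    assoc <- xml2::xml_find_first(n, "./fbc:geneProductAssociation", ns)
    gpr <- if (inherits(assoc, "xml_missing")) "" else {
      s <- parse_assoc(xml2::xml_children(assoc)[[1]])
      sub("^\\((.*)\\)$", "\\1", s)
    }
    notes <- xml2::xml_find_first(n, "./c:notes", ns)
    kind <- NULL
    if (!inherits(notes, "xml_missing")) {
      txt <- xml2::xml_text(notes)
      mk <- regmatches(txt, regexec("kind:\\s*(\\w+)", txt))[[1]]
      if (length(mk) == 2L) kind <- mk[2]
    }
    reaction(id, sto, att(n, "name", id), lb, ub, gpr, kind)
  })

  genes <- unname(gp_label)
  obj <- objective_id
  if (is.null(obj)) {
    fo <- xml2::xml_find_first(mdl, ".//fbc:fluxObjective", ns)
    if (!inherits(fo, "xml_missing")) {
      obj <- sub("^R_", "", att(fo, "reaction", ""))
    }
  }
  if (is.null(obj)) {
    stop("no flux objective in ", path, "; pass objective_id")
  }
  metabolic_model(mets, rxns, genes = if (length(genes)) genes else NULL,
                  objective_id = obj,
                  id = att(mdl, "name", att(mdl, "id", basename(path))))
}
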