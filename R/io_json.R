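# COBRA-style JSON IO ---------------------------------------------------------
#
# The JSON dialect mirrors the community COBRA schema (id / name /
# metabolites / lower_bound / upper_bound / gene_reaction_rule keys), so
# models exported by the usual toolchains load directly. A `kind` key is
# written per reaction (extra keys are permitted by the schema); on read it
# is honoured when present and otherwise inferred (single-metabolite
# reactions are exchanges).

#' Read a metabolic model
#'
#' @param path file path.
#' @param format `"json"`, `"sbml"`, or `"auto"` (by file extension:
#'   `.json` vs `.xml`/`.sbml`).
#' @param objective_id optional objective override when the file does not
#'   mark one.
#' @return a [metabolic_model()].
#' @export
read_model <- function(path, format = c("auto", "json", "sbml"),
                       objective_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "sbml"
  }
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format,
         json = read_model_json(path, objective_id),
         sbml = read_model_sbml(path, objective_id))
}

#' Write a metabolic model
#'
#' @param model a [metabolic_model()].
#' @param path output path.
#' @param format `"json"`, `"sbml"`, or `"auto"` (by extension).
#' @return invisibly, the model.
#' @export
write_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "sbml"
  }
  switch(format,
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(model)
}

read_model_json <- function(path, objective_id = NULL) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("JSON parse failure in ", path, ": ",
                         conditionMessage(e))
                  })
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    stop("not a COBRA-style model JSON (missing 'metabolites'/'reactions'): ",
         path)
  }
  num_or <- function(x, default) if (is.null(x)) default else as.numeric(x)
  chr_or <- function(x, default) {
    if (is.null(x) || is.na(x)) default else as.character(x)
  }
  mets <- lapply(doc$metabolites, function(m) {
    comp <- chr_or(m$compartment, sub("^.*_([a-zA-Z0-9]+)$", "\\1", m$id))
    metabolite(m$id, chr_or(m$name, m$id), chr_or(m$formula, ""),
               num_or(m$charge, 0), comp)
  })
  obj_from_coef <- character(0)
  rxns <- lapply(doc$reactions, function(r) {
    st <- unlist(r$metabolites)
    if (is.null(st) || !length(st)) {
      stop("reaction ", r$id, " has empty stoichiometry in ", path)
    }
    if (!is.null(r$objective_coefficient) &&
        as.numeric(r$objective_coefficient) != 0) {
      obj_from_coef <<- c(obj_from_coef, r$id)
    }
    reaction(r$id, st, chr_or(r$name, r$id),
             lb = num_or(r$lower_bound, -1000),
             ub = num_or(r$upper_bound, 1000),
             gpr = chr_or(r$gene_reaction_rule, ""),
             kind = if (!is.null(r$kind)) r$kind else NULL)
  })
  genes <- if (!is.null(doc$genes)) {
    vapply(doc$genes, function(g) as.character(g$id), "")
  } else NULL
  obj <- objective_id
  if (is.null(obj)) {
    if (!length(obj_from_coef)) {
      stop("no objective reaction marked in ", path,
           " (no nonzero objective_coefficient); pass objective_id")
    }
    obj <- obj_from_coef[[1]]
  }
  metabolic_model(mets, rxns, genes = genes, objective_id = obj,
                  id = chr_or(doc$id, basename(path)))
}

write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$mets)), function(i) {
    m <- model$mets[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment,
                charge = m$charge)
    if (nzchar(m$formula)) out$formula <- m$formula
    out
  })
  rxns <- lapply(seq_len(nrow(model$rxns)), function(i) {
    r <- model$rxns[i, ]
    out <- list(id = r$id, name = r$name,
                metabolites = as.list(model$stoich[[r$id]]),
                lower_bound = r$lb, upper_bound = r$ub, kind = r$kind)
    if (nzchar(r$gpr)) out$gene_reaction_rule <- r$gpr
    if (r$id == model$objective_id) out$objective_coefficient <- 1
    out
  })
  genes <- lapply(model$genes, function(g) list(id = g, name = g))
  doc <- list(id = model$id, version = "1", metabolites = mets,
              reactions = rxns, genes = genes)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(model)
}
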