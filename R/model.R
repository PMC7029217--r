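# Stoichiometric model container ----------------------------------------------

#' Create a metabolite record
#'
#' @param id unique metabolite id (by convention `<name>_<compartment>`).
#' @param name human-readable name.
#' @param formula elemental formula string (`""` = unknown).
#' @param charge formal charge; integer for real metabolites, but aggregate
#'   pseudo-metabolites (the symbiosis product) may carry a fractional
#'   coefficient-weighted charge.
#' @param compartment compartment id: `"c"` (cytosol) or `"e"`
#'   (extracellular / plant interface) in the models shipped here.
#' @return a `metabolite_record` list.
#' @export
metabolite <- function(id, name = id, formula = "", charge = 0L,
                       compartment = "c") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!nzchar(compartment)) stop("metabolite ", id, ": empty compartment")
  parse_formula(formula)  # validates
  structure(list(id = id, name = name, formula = formula,
                 charge = as.numeric(charge), compartment = compartment),
            class = "metabolite_record")
}

#' Create a reaction record
#'
#' @param id unique reaction id.
#' @param stoichiometry named numeric vector, metabolite id -> signed
#'   coefficient (negative = consumed).
#' @param name human-readable name.
#' @param lb,ub flux bounds in mmol/gDW/h.
#' @param gpr gene-protein-reaction rule string (`""` = none).
#' @param kind one of `"internal"`, `"transport"`, `"exchange"`,
#'   `"objective"`; `NULL` infers `"exchange"` for single-metabolite
#'   reactions and `"internal"` otherwise.
#' @return a `reaction_record` list.
#' @export
reaction <- function(id, stoichiometry, name = id, lb = -1000, ub = 1000,
                     gpr = "", kind = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(stoichiometry) || is.null(names(stoichiometry)) ||
      !length(stoichiometry)) {
    stop("reaction ", id, ": stoichiometry must be a non-empty named numeric vector")
  }
  if (anyDuplicated(names(stoichiometry))) {
    stop("reaction ", id, ": duplicated metabolite in stoichiometry")
  }
  if (!is.finite(lb) || !is.finite(ub)) stop("reaction ", id, ": bounds must be finite")
  if (lb > ub) stop("reaction ", id, ": lower_bound > upper_bound")
  if (is.null(kind)) {
    kind <- if (length(stoichiometry) == 1L) "exchange" else "internal"
  }
  kind <- match.arg(kind, c("internal", "transport", "exchange", "objective"))
  if (kind == "exchange" && length(stoichiometry) != 1L) {
    stop("reaction ", id, ": exchange reactions touch exactly one metabolite")
  }
  gpr <- deparse_gpr(parse_gpr(gpr))  # validate + normalize
  structure(list(id = id, name = name, stoichiometry = stoichiometry,
                 lb = as.numeric(lb), ub = as.numeric(ub),
                 gpr = gpr, kind = kind),
            class = "reaction_record")
}

#' Assemble a metabolic model
#'
#' Validates referential integrity: every stoichiometry key must resolve to
#' a declared metabolite, every GPR gene must be in the gene list, and the
#' objective id must name a reaction.
#'
#' @param metabolites list of [metabolite()] records.
#' @param reactions list of [reaction()] records.
#' @param genes character vector of gene ids; defaults to the union of all
#'   genes appearing in GPRs. Extra genes (present in the genome but in no
#'   GPR) are allowed.
#' @param objective_id id of the objective reaction.
#' @param id model name.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, genes = NULL,
                            objective_id, id = "model") {
  met_ids <- vapply(metabolites, `[[`, "", "id")
  if (anyDuplicated(met_ids)) {
    stop("duplicated metabolite id(s): ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  }
  rxn_ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rxn_ids)) {
    stop("duplicated reaction id(s): ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  }
  gpr_all <- character(0)
  for (r in reactions) {
    dangling <- setdiff(names(r$stoichiometry), met_ids)
    if (length(dangling)) {
      stop("reaction ", r$id, " references undeclared metabolite(s): ",
           paste(dangling, collapse = ", "))
    }
    gpr_all <- c(gpr_all, gpr_genes(parse_gpr(r$gpr)))
  }
  gpr_all <- unique(gpr_all)
  if (is.null(genes)) {
    genes <- gpr_all
  } else {
    missing <- setdiff(gpr_all, genes)
    if (length(missing)) {
      stop("GPR gene(s) not in the declared gene list: ",
           paste(missing, collapse = ", "))
    }
  }
  if (!objective_id %in% rxn_ids) {
    stop("objective_id '", objective_id, "' does not name a reaction")
  }
  mets <- data.frame(
    id = met_ids,
    name = vapply(metabolites, `[[`, "", "name"),
    formula = vapply(metabolites, `[[`, "", "formula"),
    charge = vapply(metabolites, function(m) as.numeric(m$charge), 0),
    compartment = vapply(metabolites, `[[`, "", "compartment"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  rxns <- data.frame(
    id = rxn_ids,
    name = vapply(reactions, `[[`, "", "name"),
    lb = vapply(reactions, function(r) r$lb, 0),
    ub = vapply(reactions, function(r) r$ub, 0),
    gpr = vapply(reactions, `[[`, "", "gpr"),
    kind = vapply(reactions, `[[`, "", "kind"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  stoich <- lapply(reactions, `[[`, "stoichiometry")
  names(stoich) <- rxn_ids
  structure(list(id = id, mets = mets, rxns = rxns, stoich = stoich,
                 genes = sort(genes), objective_id = objective_id),
            class = "metabolic_model")
}

#' Dense stoichiometric matrix S of a model
#'
#' Rows are metabolites (model order), columns reactions (model order);
#' `S[i, j]` is the coefficient of metabolite i in reaction j.
#'
#' @param model a `metabolic_model`.
#' @param drop_exchanges drop exchange and objective-sink columns (the
#'   "internal" matrix used by the stoichiometric-consistency check).
#' @return numeric matrix with dimnames.
#' @export
stoich_matrix <- function(model, drop_exchanges = FALSE) {
  keep <- rep(TRUE, nrow(model$rxns))
  if (drop_exchanges) keep <- !(model$rxns$kind %in% c("exchange", "objective"))
  rids <- model$rxns$id[keep]
  S <- matrix(0, nrow(model$mets), length(rids),
              dimnames = list(model$mets$id, rids))
  for (j in seq_along(rids)) {
    st <- model$stoich[[rids[j]]]
    S[names(st), j] <- st
  }
  S
}

#' Set flux bounds of one reaction
#'
#' @param model a `metabolic_model`.
#' @param id reaction id.
#' @param lb,ub new bounds; `NULL` leaves a bound unchanged.
#' @return the modified model.
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  i <- match(id, model$rxns$id)
  if (is.na(i)) stop("no reaction '", id, "' in model")
  if (!is.null(lb)) model$rxns$lb[i] <- lb
  if (!is.null(ub)) model$rxns$ub[i] <- ub
  if (model$rxns$lb[i] > model$rxns$ub[i]) {
    stop("reaction ", id, ": lower_bound > upper_bound")
  }
  model
}

# rebuild constructor-style record lists from the packed representation
met_records <- function(model) {
  lapply(seq_len(nrow(model$mets)), function(i) {
    with(model$mets[i, ], metabolite(id, name, formula, charge, compartment))
  })
}

rxn_records <- function(model) {
  lapply(seq_len(nrow(model$rxns)), function(i) {
    r <- model$rxns[i, ]
    reaction(r$id, model$stoich[[r$id]], r$name, r$lb, r$ub, r$gpr, r$kind)
  })
}

#' Ids of exchange reactions
#' @param model a `metabolic_model`.
#' @return character vector.
#' @export
exchange_ids <- function(model) model$rxns$id[model$rxns$kind == "exchange"]

# single metabolite touched by an exchange reaction
exchange_metabolite <- function(model, rxn_id) names(model$stoich[[rxn_id]])[1L]

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model '", x$id, "'\n", sep = "")
  cat("  metabolites: ", nrow(x$mets),
      "  (", paste(sprintf("%s: %d", names(table(x$mets$compartment)),
                           as.integer(table(x$mets$compartment))),
                   collapse = ", "), ")\n", sep = "")
  kinds <- table(x$rxns$kind)
  cat("  reactions:   ", nrow(x$rxns),
      "  (", paste(sprintf("%s: %d", names(kinds), as.integer(kinds)),
                   collapse = ", "), ")\n", sep = "")
  cat("  genes:       ", length(x$genes), "\n", sep = "")
  cat("  objective:   ", x$objective_id, "\n", sep = "")
  invisible(x)
}

#' @export
summary.metabolic_model <- function(object, ...) {
  print(object)
  rng <- range(c(object$rxns$lb, object$rxns$ub))
  cat("  bound range: [", rng[1], ", ", rng[2], "]\n", sep = "")
  nogpr <- sum(!nzchar(object$rxns$gpr) &
                 !(object$rxns$kind %in% c("exchange", "objective")))
  cat("  internal/transport reactions without GPR: ", nogpr, "\n", sep = "")
  invisible(object)
}
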