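# Symbiosis objective ---------------------------------------------------------
#
# Nitrogen-fixing bacteroids do not grow, so a biomass objective is wrong;
# instead the FBA objective is a "symbiosis reaction" aggregating what an
# effective bacteroid must make and deliver: storage polymers (PHB,
# glycogen), amino acids, fixed ammonium, and cofactor demands. The
# composition is expressed in mmol of component per g of symbiosis product
# and is scaled so the pseudo-product has a molecular weight of exactly
# 1 g/mmol: one unit of objective flux then corresponds to 1 g of product
# per gDW per h, which makes yields directly comparable across models.

#' Construct a symbiosis composition table
#'
#' @param component character vector of component metabolite ids.
#' @param coefficient positive coefficients, mmol component per g product.
#' @param formula elemental formula strings of the components.
#' @param charge formal charges of the components.
#' @return object of class `symbiosis_composition` (a data.frame).
#' @export
symbiosis_composition <- function(component, coefficient, formula, charge) {
  stopifnot(length(component) == length(coefficient),
            length(component) == length(formula),
            length(component) == length(charge))
  if (!length(component)) stop("empty symbiosis composition")
  if (any(coefficient <= 0)) stop("composition coefficients must be > 0")
  if (anyDuplicated(component)) stop("duplicated composition component")
  lapply(formula, parse_formula)
  out <- data.frame(component = component, coefficient = as.numeric(coefficient),
                    formula = formula, charge = as.numeric(charge),
                    stringsAsFactors = FALSE)
  class(out) <- c("symbiosis_composition", "data.frame")
  out
}

#' Read / write a composition TSV
#'
#' Columns: `component_id`, `coefficient_mmol_per_g`, `formula`, `charge`.
#'
#' @param path file path.
#' @return a `symbiosis_composition`.
#' @export
read_composition <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("component_id", "coefficient_mmol_per_g", "formula", "charge")
  if (!all(need %in% names(d))) {
    stop("composition TSV must have columns: ", paste(need, collapse = ", "))
  }
  symbiosis_composition(d$component_id, d$coefficient_mmol_per_g,
                        d$formula, d$charge)
}

#' @rdname read_composition
#' @param composition a `symbiosis_composition`.
#' @export
write_composition <- function(composition, path) {
  utils::write.table(
    data.frame(component_id = composition$component,
               coefficient_mmol_per_g = composition$coefficient,
               formula = composition$formula, charge = composition$charge),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(composition)
}

#' Molecular weight of the symbiosis product implied by a composition
#'
#' @param composition a `symbiosis_composition`.
#' @return `sum(coefficient * MW(component))` in g/mmol; 1 after scaling.
#' @export
composition_product_mw <- function(composition) {
  mw <- vapply(composition$formula, function(f) molecular_weight(f) / 1000, 0)
  sum(composition$coefficient * mw)
}

#' Scale a composition to unit product molecular weight
#'
#' Multiplies all coefficients by the single scalar that makes
#' `sum(coefficient * MW) = 1` g/mmol exactly, preserving relative
#' proportions. Errors if any component formula is unknown.
#'
#' @param composition a `symbiosis_composition`.
#' @return the scaled composition.
#' @export
scale_to_unit_molecular_weight <- function(composition) {
  if (any(!nzchar(composition$formula))) {
    stop("cannot scale: component(s) with unknown formula: ",
         paste(composition$component[!nzchar(composition$formula)],
               collapse = ", "))
  }
  composition$coefficient <- composition$coefficient /
    composition_product_mw(composition)
  composition
}

#' Add the symbiosis objective reaction to a model
#'
#' Adds (i) the pseudo-metabolite `symbiosis_product_c`, whose formula and
#' charge are the coefficient-weighted sums over the composition, (ii) the
#' symbiosis reaction consuming the components and producing one product --
#' elementally and charge balanced by construction -- and (iii) the product
#' sink, which becomes the model objective.
#'
#' @param model a [metabolic_model()].
#' @param composition a scaled `symbiosis_composition` (see
#'   [scale_to_unit_molecular_weight()]); every component must be a model
#'   metabolite.
#' @param reaction_id,sink_id,product_id ids for the added parts.
#' @return the extended model with `objective_id` set to the sink.
#' @export
build_symbiosis_reaction <- function(model, composition,
                                     reaction_id = "SYMBIOSIS",
                                     sink_id = "SK_symbiosis_product",
                                     product_id = "symbiosis_product_c") {
  if (!inherits(composition, "symbiosis_composition")) {
    stop("composition must be a symbiosis_composition")
  }
  missing <- setdiff(composition$component, model$mets$id)
  if (length(missing)) {
    stop("composition component(s) absent from model: ",
         paste(missing, collapse = ", "))
  }
  if (abs(composition_product_mw(composition) - 1) > 1e-9) {
    stop("composition is not scaled to unit product MW; ",
         "run scale_to_unit_molecular_weight() first")
  }
  fml <- weighted_formula_sum(lapply(composition$formula, parse_formula),
                              composition$coefficient)
  chg <- sum(composition$coefficient * composition$charge)
  product <- metabolite(product_id, "symbiosis product",
                        deparse_formula(fml), chg, compartment = "c")
  st <- c(stats::setNames(-composition$coefficient, composition$component),
          stats::setNames(1, product_id))
  rx <- reaction(reaction_id, st, name = "symbiosis reaction",
                 lb = 0, ub = 1000, kind = "internal")
  sink <- reaction(sink_id, stats::setNames(-1, product_id),
                   name = "symbiosis product sink", lb = 0, ub = 1000,
                   kind = "objective")
  metabolic_model(c(met_records(model), list(product)),
                  c(rxn_records(model), list(rx, sink)),
                  genes = model$genes, objective_id = sink_id,
                  id = model$id)
}

#' Rescale symbiosis reactions for cross-model yield comparison
#'
#' Yields from different reconstructions are only comparable if one unit of
#' objective flux moves the same total mass through each symbiosis
#' reaction. Each model's symbiosis reaction is rescaled so that one flux
#' unit consumes exactly 1 g of components, and the product formula/charge
#' are recomputed accordingly.
#'
#' @param models list of [metabolic_model()]s, each containing a symbiosis
#'   reaction named by `reaction_id` whose component formulas are known.
#' @param reaction_id,product_id ids of the symbiosis reaction and product.
#' @return list of rescaled models.
#' @export
rescale_for_cross_model_comparison <- function(models,
                                               reaction_id = "SYMBIOSIS",
                                               product_id = "symbiosis_product_c") {
  lapply(models, function(model) {
    if (!reaction_id %in% model$rxns$id) {
      stop("model '", model$id, "' lacks a symbiosis reaction '",
           reaction_id, "'")
    }
    st <- model$stoich[[reaction_id]]
    comp <- st[names(st) != product_id]
    if (any(comp >= 0)) stop("symbiosis reaction has non-consumed components")
    idx <- match(names(comp), model$mets$id)
    mw <- vapply(model$mets$formula[idx],
                 function(f) molecular_weight(f) / 1000, 0)
    mass <- sum(-comp * mw)           # g moved per unit flux
    sc <- 1 / mass
    newst <- c(comp * sc, stats::setNames(1, product_id))
    model$stoich[[reaction_id]] <- newst
    fml <- weighted_formula_sum(lapply(model$mets$formula[idx], parse_formula),
                                -comp * sc)
    pidx <- match(product_id, model$mets$id)
    model$mets$formula[pidx] <- deparse_formula(fml)
    model$mets$charge[pidx] <- sum(-comp * sc * model$mets$charge[idx])
    model
  })
}

#' Symbiosis yields from a flux solution
#'
#' Uptake is any exchange reaction with negative flux. The carbon yield is
#' the objective flux (g product/gDW/h for the unit-MW objective) divided
#' by total carbon uptake (mmol C/gDW/h); the nitrogen yield is analogous;
#' `c_to_n` is their ratio, the "C/N" column of the cross-model and
#' cross-condition yield tables.
#'
#' @param model the [metabolic_model()] the solution belongs to.
#' @param fit an optimal [solve_fba()] result.
#' @param tol fluxes with magnitude below `tol` are treated as zero.
#' @return object of class `yield_summary`.
#' @export
compute_symbiosis_yields <- function(model, fit, tol = 1e-9) {
  if (fit$status != "optimal") stop("flux solution is ", fit$status)
  ex <- exchange_ids(model)
  fml <- lapply(model$mets$formula, parse_formula)
  names(fml) <- model$mets$id
  upt_c <- 0; upt_n <- 0
  for (id in ex) {
    v <- fit$fluxes[[id]]
    if (v >= -tol) next
    met <- exchange_metabolite(model, id)
    f <- fml[[met]]
    if (!length(f) && !nzchar(model$mets$formula[match(met, model$mets$id)])) {
      stop("uptake metabolite ", met, " has unknown formula; ",
           "yields undefined")
    }
    upt_c <- upt_c + abs(v) * (if ("C" %in% names(f)) f[["C"]] else 0)
    upt_n <- upt_n + abs(v) * (if ("N" %in% names(f)) f[["N"]] else 0)
  }
  if (upt_c <= tol) stop("undefined yield: zero carbon uptake")
  if (upt_n <= tol) stop("undefined yield: zero nitrogen uptake")
  cy <- fit$objective_value / upt_c
  ny <- fit$objective_value / upt_n
  structure(list(carbon_yield = cy, nitrogen_yield = ny, c_to_n = cy / ny,
                 carbon_uptake = upt_c, nitrogen_uptake = upt_n,
                 objective = fit$objective_value),
            class = "yield_summary")
}

#' @export
print.yield_summary <- function(x, ...) {
  cat("Symbiosis yields\n")
  cat("  product flux:   ", format(x$objective, digits = 4),
      " g/gDW/h\n", sep = "")
  cat("  carbon yield:   ", format(x$carbon_yield, digits = 4),
      " g/mmol C  (uptake ", format(x$carbon_uptake, digits = 4),
      " mmol C/gDW/h)\n", sep = "")
  cat("  nitrogen yield: ", format(x$nitrogen_yield, digits = 4),
      " g/mmol N  (uptake ", format(x$nitrogen_uptake, digits = 4),
      " mmol N/gDW/h)\n", sep = "")
  cat("  C/N:            ", format(x$c_to_n, digits = 4), "\n", sep = "")
  invisible(x)
}
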