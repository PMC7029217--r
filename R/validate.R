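# Model-quality validation battery -------------------------------------------
#
# Re-implements the consistency checks a reconstruction is expected to pass
# before simulation: elemental and charge balance of internal reactions,
# stoichiometric consistency (existence of a strictly positive conserved
# mass vector), and detection of energy-generating cycles that would let
# the model make ATP from nothing.

.validator_tol <- 1e-6

#' Elemental and charge balance of internal reactions
#'
#' For every non-exchange, non-objective reaction computes the per-element
#' residual `sum(coeff * count)` and the charge residual; a reaction is
#' balanced iff all residuals are exactly zero. The generic side group `R`
#' is carried as a pseudo-element and must cancel like any other. Reactions
#' touching a metabolite with unknown (empty) formula are marked
#' `"unchecked"`.
#'
#' @param model a [metabolic_model()].
#' @return object of class `balance_report`: data.frame with columns `id`,
#'   `status` (`balanced`/`unbalanced`/`unchecked`), `charge_residual`,
#'   `element_residuals` (list column of named numeric vectors).
#' @export
check_mass_charge_balance <- function(model) {
  fml <- lapply(model$mets$formula, parse_formula)
  names(fml) <- model$mets$id
  charge <- stats::setNames(model$mets$charge, model$mets$id)
  unknown <- model$mets$id[!vapply(fml, length, 0L) &
                             !nzchar(model$mets$formula)]
  check <- !(model$rxns$kind %in% c("exchange", "objective"))
  ids <- model$rxns$id[check]
  status <- character(length(ids))
  cres <- numeric(length(ids))
  eres <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    st <- model$stoich[[ids[k]]]
    mets <- names(st)
    if (any(mets %in% unknown)) {
      status[k] <- "unchecked"; cres[k] <- NA_real_
      eres[[k]] <- stats::setNames(numeric(0), character(0))
      next
    }
    res <- weighted_formula_sum(fml[mets], unname(st))
    cr <- sum(charge[mets] * st)
    eres[[k]] <- res
    cres[k] <- cr
    status[k] <- if (all(abs(res) < .validator_tol) &&
                     abs(cr) < .validator_tol) "balanced" else "unbalanced"
  }
  out <- data.frame(id = ids, status = status, charge_residual = cres,
                    stringsAsFactors = FALSE)
  out$element_residuals <- eres
  class(out) <- c("balance_report", "data.frame")
  out
}

#' Stoichiometric consistency
#'
#' A model is stoichiometrically consistent iff there is a strictly positive
#' molecular-mass vector `m` conserved by every internal reaction,
#' `t(S_int) %*% m = 0`. The existence test is posed as a linear
#' feasibility problem with `m >= 1` (scale-invariant closure of `m > 0`).
#' When inconsistent, the witness set is found by maximising the support of
#' a conservable mass vector in a single LP: metabolites that cannot carry
#' positive mass in any conserved vector are the unconserved ones.
#'
#' @param model a [metabolic_model()]; exchanges and the objective sink are
#'   excluded from `S_int`.
#' @return list with `consistent` (logical) and `unconserved_metabolites`
#'   (character vector, empty when consistent).
#' @export
check_stoichiometric_consistency <- function(model) {
  Si <- stoich_matrix(model, drop_exchanges = TRUE)
  if (ncol(Si) == 0L) {
    warning("model has no internal reactions; trivially consistent")
    return(list(consistent = TRUE, unconserved_metabolites = character(0)))
  }
  nm <- nrow(Si)
  # feasibility: t(Si) m = 0, 1 <= m <= 1e6
  res <- solve_lp(rep(0, nm), t(Si), rep(0, ncol(Si)), "=",
                  lb = rep(1, nm), ub = rep(1e6, nm))
  if (res$status == "optimal") {
    return(list(consistent = TRUE, unconserved_metabolites = character(0)))
  }
  # max-support LP: max sum(z), z <= m, 0 <= z <= 1, t(Si) m = 0, m >= 0
  A <- rbind(cbind(t(Si), matrix(0, ncol(Si), nm)),
             cbind(diag(nm), -diag(nm)))          # m - z >= 0
  rhs <- c(rep(0, ncol(Si)), rep(0, nm))
  sense <- c(rep("=", ncol(Si)), rep(">=", nm))
  obj <- c(rep(0, nm), rep(1, nm))
  sup <- solve_lp(obj, A, rhs, sense,
                  lb = rep(0, 2 * nm), ub = c(rep(1e6, nm), rep(1, nm)),
                  maximize = TRUE)
  if (sup$status != "optimal") stop("support LP is ", sup$status)
  m <- sup$x[seq_len(nm)]
  bad <- model$mets$id[m <= .validator_tol]
  list(consistent = FALSE, unconserved_metabolites = bad)
}

#' Detect energy-generating cycles
#'
#' Closes every exchange (and objective-sink) bound to `[0, 0]`, adds an
#' energy-dissipation reaction (by default ATP hydrolysis,
#' `atp + h2o -> adp + pi + h`), and maximises its flux. Any positive
#' optimum means the network can regenerate its energy currency from
#' nothing -- an energy-generating cycle, a reconstruction artifact that
#' inflates yields.
#'
#' @param model a [metabolic_model()].
#' @param dissipation named numeric stoichiometry of the dissipation
#'   reaction over metabolite ids; the default names the ATP couple in the
#'   `_c` compartment.
#' @param tol flux above which the cycle counts as detected.
#' @return list with `egc_detected` (logical), `dissipation_flux`, and
#'   `witness` (ids of internal reactions carrying flux in the cycle).
#' @export
detect_energy_generating_cycles <- function(model,
    dissipation = c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
    tol = .validator_tol) {
  missing <- setdiff(names(dissipation), model$mets$id)
  if (length(missing)) {
    stop("dissipation metabolite(s) absent from model: ",
         paste(missing, collapse = ", "))
  }
  closed <- model
  shut <- closed$rxns$kind %in% c("exchange", "objective")
  closed$rxns$lb[shut] <- 0
  closed$rxns$ub[shut] <- 0
  diss <- reaction("EGC_dissipation__", dissipation, lb = 0, ub = 1000,
                   kind = "internal")
  probe <- metabolic_model(
    metabolites = met_records(closed),
    reactions = c(rxn_records(closed), list(diss)),
    genes = closed$genes,
    objective_id = "EGC_dissipation__",
    id = paste0(closed$id, "_egc_probe"))
  fit <- solve_fba(probe)
  flux <- if (fit$status == "optimal") fit$objective_value else 0
  witness <- character(0)
  if (flux > tol) {
    v <- fit$fluxes
    witness <- setdiff(names(v)[abs(v) > tol], "EGC_dissipation__")
  }
  list(egc_detected = flux > tol, dissipation_flux = flux, witness = witness)
}

#' Run the full model-quality battery
#'
#' @param model a [metabolic_model()].
#' @param dissipation passed to [detect_energy_generating_cycles()]; `NULL`
#'   skips the EGC probe (e.g. for models without an ATP couple).
#' @return object of class `validation_report`.
#' @export
validate_model <- function(model,
    dissipation = c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1)) {
  bal <- check_mass_charge_balance(model)
  cons <- check_stoichiometric_consistency(model)
  egc <- if (!is.null(dissipation)) {
    detect_energy_generating_cycles(model, dissipation)
  } else {
    list(egc_detected = FALSE, dissipation_flux = NA_real_,
         witness = character(0))
  }
  structure(list(model_id = model$id, balance = bal, consistency = cons,
                 egc = egc,
                 ok = all(bal$status == "balanced") && cons$consistent &&
                      !egc$egc_detected),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report for '", x$model_id, "'\n", sep = "")
  tab <- table(factor(x$balance$status,
                      levels = c("balanced", "unbalanced", "unchecked")))
  cat("  mass/charge balance: ", tab[["balanced"]], " balanced, ",
      tab[["unbalanced"]], " unbalanced, ", tab[["unchecked"]],
      " unchecked\n", sep = "")
  cat("  stoichiometric consistency: ",
      if (x$consistency$consistent) "consistent" else
        paste0("INCONSISTENT (", length(x$consistency$unconserved_metabolites),
               " unconserved metabolites)"), "\n", sep = "")
  cat("  energy-generating cycle: ",
      if (isTRUE(x$egc$egc_detected)) "DETECTED" else "none", "\n", sep = "")
  cat("  overall: ", if (x$ok) "PASS" else "FAIL", "\n", sep = "")
  invisible(x)
}

#' Write a validation report to disk
#'
#' Writes a per-reaction residual TSV (`reaction`, `element`, `residual`;
#' charge rows use the pseudo-element `"charge"`) and a YAML summary.
#'
#' @param report a `validation_report`.
#' @param tsv,yaml output file paths (`NULL` skips one of them).
#' @return invisibly, the report.
#' @export
write_validation_report <- function(report, tsv = NULL, yaml = NULL) {
  if (!is.null(tsv)) {
    rows <- list()
    for (k in seq_len(nrow(report$balance))) {
      id <- report$balance$id[k]
      er <- report$balance$element_residuals[[k]]
      if (length(er)) {
        rows[[length(rows) + 1L]] <- data.frame(
          reaction = id, element = names(er), residual = unname(er),
          stringsAsFactors = FALSE)
      }
      cr <- report$balance$charge_residual[k]
      if (!is.na(cr) && abs(cr) > .validator_tol) {
        rows[[length(rows) + 1L]] <- data.frame(
          reaction = id, element = "charge", residual = cr,
          stringsAsFactors = FALSE)
      }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(reaction = character(0), element = character(0),
                 residual = numeric(0))
    utils::write.table(out, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(yaml)) {
    tab <- table(factor(report$balance$status,
                        levels = c("balanced", "unbalanced", "unchecked")))
    yaml::write_yaml(list(
      model = report$model_id,
      balanced = as.integer(tab[["balanced"]]),
      unbalanced = as.integer(tab[["unbalanced"]]),
      unchecked = as.integer(tab[["unchecked"]]),
      stoichiometrically_consistent = report$consistency$consistent,
      unconserved_metabolites = as.list(report$consistency$unconserved_metabolites),
      egc_detected = isTRUE(report$egc$egc_detected),
      overall_pass = report$ok), yaml)
  }
  invisible(report)
}
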