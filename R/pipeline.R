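# Pipeline orchestration ------------------------------------------------------
#
# Function equivalents of the command-line workflow: validate a model,
# analyse it under the standard nitrogen-fixation condition, and build /
# compare / dissect condition-specific models from two expression profiles.
# All randomness flows from explicit seed arguments; reruns with the same
# inputs produce byte-identical outputs.

sigfig <- function(x, digits = 4) signif(x, digits)

#' Validate a model and write the report
#'
#' @param model a [metabolic_model()].
#' @param out_dir output directory (created if needed); `NULL` writes
#'   nothing.
#' @param dissipation passed to [validate_model()].
#' @return the [validate_model()] report (its `ok` field is the pipeline
#'   pass/fail signal).
#' @export
run_validation <- function(model, out_dir = NULL,
    dissipation = c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1)) {
  rep <- validate_model(model, dissipation)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_validation_report(rep,
                            tsv = file.path(out_dir, "validation_residuals.tsv"),
                            yaml = file.path(out_dir, "validation_summary.yaml"))
  }
  rep
}

#' Standard-condition analysis: FBA, FVA, shadow prices, knockout screen
#'
#' @param model a [metabolic_model()] with symbiosis objective.
#' @param condition condition list applied before analysis (`NULL` = use
#'   the model's bounds as-is).
#' @param out_dir output directory; `NULL` writes nothing.
#' @param fva_fraction fraction of optimum for the FVA table.
#' @param essential_cutoff,partial_tolerance passed to
#'   [classify_symbiotic_genes()].
#' @return list with `fit`, `yields`, `fva`, `shadow`, `classified`.
#' @export
run_analysis <- function(model, condition = standard_condition(),
                         out_dir = NULL, fva_fraction = 0,
                         essential_cutoff = 0.05, partial_tolerance = 0.01) {
  m <- if (is.null(condition)) model else
    apply_standard_condition(model, condition)
  fit <- solve_fba(m)
  if (fit$status != "optimal") {
    stop("standard-condition FBA is ", fit$status,
         "; check the condition bounds")
  }
  if (fit$objective_value <= 1e-9) {
    message("optimum is zero under this condition; ",
            "yields and knockout ratios are undefined")
    return(list(fit = fit, yields = NULL, fva = NULL, shadow = NULL,
                classified = NULL))
  }
  yields <- compute_symbiosis_yields(m, fit)
  fva <- flux_variability(m, fva_fraction)
  shadow <- shadow_prices(m)
  classified <- classify_symbiotic_genes(single_gene_deletion(m),
                                         essential_cutoff, partial_tolerance)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(
      data.frame(condition = if (is.null(condition)) "as-is" else condition$name,
                 carbon_yield = sigfig(yields$carbon_yield),
                 nitrogen_yield = sigfig(yields$nitrogen_yield),
                 c_to_n = sigfig(yields$c_to_n)),
      file.path(out_dir, "yields.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    jsonlite::write_json(unclass(yields),
                         file.path(out_dir, "yields.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.table(
      data.frame(reaction_id = names(fit$fluxes),
                 flux = sigfig(unname(fit$fluxes))),
      file.path(out_dir, "fluxes.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(reaction_id = fva$id, min = sigfig(fva$min),
                 max = sigfig(fva$max)),
      file.path(out_dir, "fva.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(metabolite_id = names(shadow$prices),
                 shadow_price = sigfig(unname(shadow$prices))),
      file.path(out_dir, "shadow_prices.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_knockout_report(classified,
                          tsv = file.path(out_dir, "knockouts.tsv"),
                          yaml = file.path(out_dir, "knockout_summary.yaml"))
  }
  list(fit = fit, yields = yields, fva = fva, shadow = shadow,
       classified = classified)
}

#' Condition-specific models, joint flux fit, and sensitivity analysis
#'
#' Builds E-Flux condition models from two expression profiles, computes
#' per-condition yields, fits both flux distributions jointly with 1-norm
#' minimisation, and runs the evolutionary sensitivity analysis from the
#' lower-yield condition toward the higher-yield one.
#'
#' @param model a [metabolic_model()] with symbiosis objective.
#' @param profiles list of exactly two [expression_profile()]s.
#' @param condition nutrient condition applied before the baseline FVA.
#' @param out_dir output directory; `NULL` writes nothing.
#' @param n_runs,seed,stall_limit sensitivity parameters (see
#'   [evolutionary_sensitivity()]).
#' @param frequency_threshold determinant cutoff.
#' @param normalizer passed to [eflux_bounds()].
#' @return list with `yields` (per condition), `models`, `joint`,
#'   `runs`, `determinants`, `start_condition`.
#' @export
run_conditions <- function(model, profiles,
                           condition = standard_condition(),
                           out_dir = NULL, n_runs = 100L, seed = 1L,
                           stall_limit = NULL, frequency_threshold = 0.9,
                           normalizer = "shared_max") {
  if (length(profiles) != 2L) {
    stop("exactly two expression profiles (two conditions) are required")
  }
  cn <- unname(vapply(profiles, `[[`, "", "condition"))
  names(profiles) <- cn
  m_std <- if (is.null(condition)) model else
    apply_standard_condition(model, condition)
  baseline <- flux_variability(m_std, 0)
  scores <- lapply(profiles, function(p) reaction_expression_scores(m_std, p))
  bnds <- eflux_bounds(m_std, scores, baseline, normalizer = normalizer)
  cms <- lapply(cn, function(nm) build_condition_model(m_std, bnds[[nm]], nm))
  names(cms) <- cn
  fits <- lapply(cms, solve_fba)
  for (nm in cn) {
    if (fits[[nm]]$status != "optimal") {
      stop("condition '", nm, "' model is ", fits[[nm]]$status)
    }
  }
  yields <- lapply(cn, function(nm) compute_symbiosis_yields(cms[[nm]],
                                                             fits[[nm]]))
  names(yields) <- cn
  joint <- joint_min_norm_fluxes(cms[[1]], cms[[2]])

  cy <- vapply(yields, `[[`, 0, "carbon_yield")
  low <- cn[which.min(cy)]; high <- cn[which.max(cy)]
  if (low == high) { low <- cn[1]; high <- cn[2] }
  runs <- evolutionary_sensitivity(m_std, bnds[[low]], bnds[[high]],
                                   n_runs = n_runs, seed = seed,
                                   stall_limit = stall_limit)
  det <- summarize_determinants(runs, frequency_threshold)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(
      data.frame(condition = cn,
                 carbon_yield = sigfig(vapply(yields, `[[`, 0, "carbon_yield")),
                 nitrogen_yield = sigfig(vapply(yields, `[[`, 0, "nitrogen_yield")),
                 c_to_n = sigfig(vapply(yields, `[[`, 0, "c_to_n")),
                 objective = sigfig(vapply(yields, `[[`, 0, "objective"))),
      file.path(out_dir, "condition_yields.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    jsonlite::write_json(lapply(yields, unclass),
                         file.path(out_dir, "condition_yields.json"),
                         auto_unbox = TRUE, digits = NA)
    for (nm in cn) {
      write_condition_bounds(bnds[[nm]],
        file.path(out_dir, paste0("bounds_", nm, ".tsv")))
      v <- if (nm == cn[1]) joint$A$fluxes else joint$B$fluxes
      utils::write.table(
        data.frame(reaction_id = names(v), flux = sigfig(unname(v))),
        file.path(out_dir, paste0("fluxes_", nm, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_determinant_tsv(det, file.path(out_dir, "determinants.tsv"))
    write_sensitivity_jsonl(runs, file.path(out_dir, "sensitivity_runs.jsonl"))
  }
  list(yields = yields, models = cms, joint = joint, runs = runs,
       determinants = det, start_condition = low)
}
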