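# Reproduction of the published bacteroid analysis ----------------------------

#' Analyse a published bacteroid reconstruction
#'
#' Runs the full standard-condition analysis on a genome-scale bacteroid
#' model obtained separately (the deposited reconstruction is distributed
#' as a COBRA-style JSON in the authors' repository; it is not bundled
#' here). Reports the parsed model statistics -- the loader reports what it
#' parses and hard-codes nothing -- together with the symbiosis yields and
#' the symbiotic-gene classification counts.
#'
#' @param path path to the downloaded model (JSON or SBML).
#' @param format passed to [read_model()].
#' @param condition optional condition list applied before analysis. The
#'   deposited model ships with its in-silico nitrogen-fixation bounds
#'   already set, so the default (`NULL`) analyses it as-is.
#' @param essential_cutoff,partial_tolerance classification thresholds.
#' @return list with `model`, `stats` (reactions/metabolites/genes),
#'   `fit`, `yields`, `classified`, `counts`.
#' @export
analyze_published_model <- function(path, format = "auto", condition = NULL,
                                    essential_cutoff = 0.05,
                                    partial_tolerance = 0.01) {
  model <- read_model(path, format)
  if (!is.null(condition)) model <- apply_standard_condition(model, condition)
  stats <- c(reactions = nrow(model$rxns), metabolites = nrow(model$mets),
             genes = length(model$genes))
  fit <- solve_fba(model)
  if (fit$status != "optimal") {
    stop("FBA on the published model is ", fit$status,
         "; are the condition bounds present?")
  }
  yields <- compute_symbiosis_yields(model, fit)
  classified <- classify_symbiotic_genes(single_gene_deletion(model),
                                         essential_cutoff, partial_tolerance)
  list(model = model, stats = stats, fit = fit, yields = yields,
       classified = classified, counts = attr(classified, "counts"))
}
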