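# Single-gene deletion screen -------------------------------------------------

#' Single-gene deletion screen
#'
#' For every gene, reactions whose GPR evaluates to inactive under that
#' deletion have their bounds set to `[0, 0]`; the mutant FBA optimum is
#' divided by the wild-type optimum to give the symbiotic rate ratio.
#' Reactions catalysed by isozymes (an `or` of genes) survive single
#' deletions. Genes that appear in no GPR are reported with ratio 1 and
#' flagged as outside the model's reaction scope. The model is restored
#' between genes; the input model is never modified.
#'
#' @param model a [metabolic_model()] with its objective set (e.g. the
#'   symbiosis sink) and condition bounds applied.
#' @param genes genes to screen; defaults to all model genes.
#' @return object of class `knockout_screen`: data.frame with columns
#'   `gene`, `ratio`, `affected_reactions` (comma-separated ids),
#'   `in_scope`; attribute `wild_type_optimum`.
#' @export
single_gene_deletion <- function(model, genes = model$genes) {
  wt <- solve_fba(model)
  if (wt$status != "optimal") {
    stop("wild-type FBA is ", wt$status)
  }
  if (wt$objective_value <= 1e-9) {
    stop("wild-type optimum is zero: knockout ratios undefined")
  }
  asts <- lapply(model$rxns$gpr, parse_gpr)
  gene_rxns <- lapply(asts, gpr_genes)
  S <- stoich_matrix(model)
  obj <- as.numeric(model$rxns$id == model$objective_id)
  b0 <- rep(0, nrow(S))
  lb0 <- model$rxns$lb; ub0 <- model$rxns$ub

  ratio <- numeric(length(genes))
  affected <- character(length(genes))
  in_scope <- logical(length(genes))
  for (k in seq_along(genes)) {
    g <- genes[k]
    touches <- which(vapply(gene_rxns, function(x) g %in% x, NA))
    if (!length(touches)) {
      ratio[k] <- 1; affected[k] <- ""; in_scope[k] <- FALSE
      next
    }
    in_scope[k] <- TRUE
    off <- touches[!vapply(asts[touches], evaluate_gpr, NA,
                           deleted_genes = g)]
    if (!length(off)) {
      ratio[k] <- 1; affected[k] <- ""
      next
    }
    lb <- lb0; ub <- ub0
    lb[off] <- 0; ub[off] <- 0
    res <- solve_lp(obj, S, b0, "=", lb, ub, maximize = TRUE)
    mut <- if (res$status == "optimal") res$objective else 0
    ratio[k] <- max(0, mut / wt$objective_value)
    affected[k] <- paste(model$rxns$id[off], collapse = ",")
  }
  out <- data.frame(gene = genes, ratio = ratio,
                    affected_reactions = affected, in_scope = in_scope,
                    stringsAsFactors = FALSE)
  attr(out, "wild_type_optimum") <- wt$objective_value
  class(out) <- c("knockout_screen", "data.frame")
  out
}

#' Classify knockout results into symbiotic-gene categories
#'
#' A gene is *essential* when its symbiotic rate ratio falls below
#' `essential_cutoff` (0.05: the deletion abolishes nitrogen fixation for
#' practical purposes); *partial* when the ratio shows any other reduction
#' beyond solver noise (`ratio < 1 - partial_tolerance`); *nonessential*
#' otherwise. Essential plus partial genes together are the symbiotic
#' genes.
#'
#' @param results a [single_gene_deletion()] screen.
#' @param essential_cutoff rate-ratio cutoff for essentiality.
#' @param partial_tolerance guard band so LP noise is not labelled a
#'   partial effect.
#' @return object of class `symbiotic_classification`: the screen with a
#'   `label` column plus a `counts` attribute (named integer vector:
#'   `symbiotic`, `essential`, `partial`, `nonessential`).
#' @export
classify_symbiotic_genes <- function(results, essential_cutoff = 0.05,
                                     partial_tolerance = 0.01) {
  stopifnot(inherits(results, "knockout_screen"))
  lab <- ifelse(results$ratio < essential_cutoff, "essential",
                ifelse(results$ratio < 1 - partial_tolerance, "partial",
                       "nonessential"))
  out <- results
  out$label <- lab
  counts <- c(symbiotic = sum(lab != "nonessential"),
              essential = sum(lab == "essential"),
              partial = sum(lab == "partial"),
              nonessential = sum(lab == "nonessential"))
  attr(out, "counts") <- counts
  attr(out, "essential_cutoff") <- essential_cutoff
  attr(out, "partial_tolerance") <- partial_tolerance
  class(out) <- c("symbiotic_classification", class(results))
  out
}

#' @export
print.symbiotic_classification <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat("Symbiotic-gene classification (", nrow(x), " genes screened)\n",
      sep = "")
  cat("  symbiotic (ratio < 1): ", cnt[["symbiotic"]], "\n", sep = "")
  cat("    essential (ratio < ", attr(x, "essential_cutoff"), "): ",
      cnt[["essential"]], "\n", sep = "")
  cat("    partial effect:      ", cnt[["partial"]], "\n", sep = "")
  cat("  nonessential:          ", cnt[["nonessential"]], "\n", sep = "")
  invisible(x)
}

#' Write a knockout screen to TSV / its summary to YAML
#'
#' @param classified a [classify_symbiotic_genes()] result.
#' @param tsv,yaml output paths (`NULL` skips).
#' @export
write_knockout_report <- function(classified, tsv = NULL, yaml = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(
      data.frame(gene_id = classified$gene,
                 ratio = signif(classified$ratio, 4),
                 label = classified$label,
                 reactions_disabled = classified$affected_reactions),
      tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(yaml)) {
    yaml::write_yaml(as.list(attr(classified, "counts")), yaml)
  }
  invisible(classified)
}
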