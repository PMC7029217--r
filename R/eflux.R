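# E-Flux transcriptome integration --------------------------------------------
#
# E-Flux assumes maximum enzymatic capacity is proportional to transcript
# abundance: each reaction's flux bounds are the unconstrained FVA envelope
# scaled by the reaction's expression activity relative to the global
# maximum. Using one normaliser shared by both conditions keeps the two
# condition-specific models on a common capacity scale, so their yields are
# directly comparable.

#' Construct an expression profile
#'
#' @param condition condition name.
#' @param values named numeric vector, gene id -> normalized expression.
#'   Values must be `>= 0` or exactly `-1`, the sentinel for "no data".
#' @return object of class `expression_profile`.
#' @export
expression_profile <- function(condition, values) {
  if (is.null(names(values)) || !length(values)) {
    stop("expression values must be a non-empty named vector")
  }
  if (anyNA(values)) stop("NA/NaN in expression profile '", condition, "'")
  bad <- values < 0 & values != -1
  if (any(bad)) {
    stop("negative expression (other than the -1 sentinel) for gene(s): ",
         paste(names(values)[bad], collapse = ", "))
  }
  structure(list(condition = condition, values = values),
            class = "expression_profile")
}

#' Read an expression TSV (`gene_id <tab> value`)
#'
#' @param path file path; must have columns `gene_id` and `value`.
#' @param condition condition name; defaults to the file name.
#' @return an [expression_profile()].
#' @export
read_expression_tsv <- function(path, condition = NULL) {
  if (is.null(condition)) {
    condition <- sub("\\.[^.]*$", "", basename(path))
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "value") %in% names(d))) {
    stop("expression TSV must have columns gene_id and value: ", path)
  }
  expression_profile(condition, stats::setNames(d$value, d$gene_id))
}

#' @rdname read_expression_tsv
#' @param profile an `expression_profile`.
#' @export
write_expression_tsv <- function(profile, path) {
  utils::write.table(
    data.frame(gene_id = names(profile$values),
               value = unname(profile$values)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(profile)
}

#' Reaction activity scores from gene expression
#'
#' Maps gene scores onto reactions through the GPR rules: `and` takes the
#' minimum over scored subunits, `or` the sum over scored isozymes; the
#' `-1` sentinel propagates only when no child of a node has data. Orphan
#' reactions (empty GPR) score `-1`.
#'
#' @param model a [metabolic_model()].
#' @param profile an [expression_profile()].
#' @return named numeric vector, reaction id -> score (or -1).
#' @export
reaction_expression_scores <- function(model, profile) {
  vapply(seq_len(nrow(model$rxns)), function(i) {
    gpr_expression_score(parse_gpr(model$rxns$gpr[i]), profile$values)
  }, 0) |> stats::setNames(model$rxns$id)
}

#' E-Flux condition-specific bounds
#'
#' For each condition the relative activity of a reaction is its score
#' divided by the shared normaliser (by default the maximum finite score
#' across all reactions of *both* conditions); both sides of the baseline
#' FVA envelope are scaled toward zero by that factor. A score of `-1`
#' (no data: orphan reactions, exchanges, genes without measurements)
#' leaves the reaction's nutrient-condition bounds unchanged -- the
#' envelope itself is not imposed, because FVA minima/maxima encode fluxes
#' forced by couplings to other reactions' full capacity and would
#' contradict the scaled-down bounds of the scored reactions. A score of 0
#' closes the reaction.
#'
#' @param model a [metabolic_model()].
#' @param scores_by_condition named list of score vectors from
#'   [reaction_expression_scores()], one per condition.
#' @param baseline an [flux_variability()] result computed on the
#'   unconstrained model at `fraction_of_optimum = 0`.
#' @param normalizer `"shared_max"` (default; cross-condition comparable)
#'   or `"per_condition_max"` (each condition normalised by its own
#'   maximum, available for sensitivity checks).
#' @return named list of `condition_bounds` data.frames (`id`, `lb`, `ub`).
#' @export
eflux_bounds <- function(model, scores_by_condition, baseline,
                         normalizer = c("shared_max", "per_condition_max")) {
  normalizer <- match.arg(normalizer)
  stopifnot(inherits(baseline, "fva_result"))
  all_scores <- unlist(scores_by_condition)
  finite <- all_scores[all_scores >= 0]
  if (!length(finite)) stop("no constraining information: every score is -1")
  shared_max <- max(finite)
  if (shared_max <= 0) stop("no constraining information: all scores are 0")
  base <- baseline[match(model$rxns$id, baseline$id), ]
  lapply(scores_by_condition, function(sc) {
    sc <- sc[model$rxns$id]
    nmax <- if (normalizer == "shared_max") shared_max else max(sc[sc >= 0])
    r <- ifelse(sc < 0, 1, sc / nmax)
    lb <- ifelse(sc < 0, model$rxns$lb, base$min * r)
    ub <- ifelse(sc < 0, model$rxns$ub, base$max * r)
    out <- data.frame(id = model$rxns$id, lb = lb, ub = ub,
                      stringsAsFactors = FALSE)
    class(out) <- c("condition_bounds", "data.frame")
    out
  })
}

#' Apply condition bounds to a model
#'
#' Returns a copy of the model with the listed reactions' bounds replaced.
#' Reactions absent from `bounds` are untouched, so exchange bounds of the
#' nutrient condition survive unless the bounds table overrides them (an
#' exchange only acquires expression-scaled bounds through the GPR of an
#' associated transporter).
#'
#' @param model a [metabolic_model()].
#' @param bounds a `condition_bounds` data.frame (`id`, `lb`, `ub`).
#' @param condition optional condition name appended to the model id.
#' @return the condition-specific model.
#' @export
build_condition_model <- function(model, bounds, condition = NULL) {
  if (nrow(bounds)) {
    i <- match(bounds$id, model$rxns$id)
    if (anyNA(i)) {
      stop("bounds reference unknown reaction(s): ",
           paste(bounds$id[is.na(i)], collapse = ", "))
    }
    if (any(bounds$lb > bounds$ub)) stop("condition bounds with lb > ub")
    model$rxns$lb[i] <- bounds$lb
    model$rxns$ub[i] <- bounds$ub
  }
  if (!is.null(condition)) model$id <- paste0(model$id, "_", condition)
  model
}

#' @rdname build_condition_model
#' @param path TSV path (`reaction_id`, `lb`, `ub`).
#' @export
write_condition_bounds <- function(bounds, path) {
  utils::write.table(
    data.frame(reaction_id = bounds$id, lb = bounds$lb, ub = bounds$ub),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(bounds)
}
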