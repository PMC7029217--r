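# Flux balance analysis -------------------------------------------------------

#' Flux balance analysis
#'
#' Maximises (or minimises) the flux of the model's objective reaction
#' subject to steady-state mass balance `S v = 0` and the flux bounds.
#' Metabolite duals (shadow prices) are reported with the sign convention
#' that a positive price means the optimal objective would increase if one
#' extra unit of the metabolite were made available per hour.
#'
#' @param model a [metabolic_model()].
#' @param maximize logical; the symbiosis objective is maximised.
#' @return an object of class `fba_fit`: list with `status`,
#'   `objective_value`, `fluxes` (named by reaction), `duals` (named by
#'   metabolite), `objective_id`.
#' @export
solve_fba <- function(model, maximize = TRUE) {
  if (any(model$rxns$lb > model$rxns$ub)) {
    bad <- model$rxns$id[model$rxns$lb > model$rxns$ub]
    stop("lower_bound > upper_bound for reaction(s): ",
         paste(bad, collapse = ", "))
  }
  S <- stoich_matrix(model)
  obj <- as.numeric(model$rxns$id == model$objective_id)
  res <- solve_lp(obj, S, rep(0, nrow(S)), "=",
                  lb = model$rxns$lb, ub = model$rxns$ub,
                  maximize = maximize)
  duals <- if (res$status == "optimal") -res$y else res$y
  structure(list(status = res$status,
                 objective_value = res$objective,
                 fluxes = stats::setNames(res$x, model$rxns$id),
                 duals = stats::setNames(duals, model$mets$id),
                 objective_id = model$objective_id,
                 maximize = maximize),
            class = "fba_fit")
}

#' @export
print.fba_fit <- function(x, ...) {
  cat("FBA solution (", if (x$maximize) "max" else "min", " ",
      x$objective_id, ")\n", sep = "")
  cat("  status:    ", x$status, "\n", sep = "")
  if (x$status == "optimal") {
    cat("  objective: ", format(x$objective_value, digits = 6), "\n", sep = "")
    nz <- sum(abs(x$fluxes) > 1e-9)
    cat("  reactions with nonzero flux: ", nz, " / ", length(x$fluxes),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.fba_fit <- function(object, ...) object$fluxes

#' Flux variability analysis
#'
#' For each reaction, the minimum and maximum flux compatible with the
#' objective being at least `fraction_of_optimum` times its FBA optimum.
#'
#' @param model a [metabolic_model()].
#' @param fraction_of_optimum number in `[0, 1]`; 0 (the default used when
#'   deriving E-Flux baseline envelopes) leaves the objective free.
#' @return object of class `fva_result`: data.frame with columns `id`,
#'   `min`, `max`, plus attributes `fraction_of_optimum` and `optimum`.
#' @export
flux_variability <- function(model, fraction_of_optimum = 0) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  wt <- solve_fba(model)
  if (wt$status != "optimal") {
    stop("flux_variability: wild-type FBA is ", wt$status)
  }
  S <- stoich_matrix(model)
  n <- ncol(S)
  obj_row <- as.numeric(model$rxns$id == model$objective_id)
  A <- rbind(S, obj_row)
  rhs <- c(rep(0, nrow(S)), fraction_of_optimum * wt$objective_value)
  sense <- c(rep("=", nrow(S)), ">=")
  mn <- mx <- numeric(n)
  for (j in seq_len(n)) {
    cc <- numeric(n); cc[j] <- 1
    lo <- solve_lp(cc, A, rhs, sense, model$rxns$lb, model$rxns$ub,
                   maximize = FALSE)
    hi <- solve_lp(cc, A, rhs, sense, model$rxns$lb, model$rxns$ub,
                   maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("flux_variability: subproblem for ", model$rxns$id[j],
           " is ", lo$status, "/", hi$status)
    }
    mn[j] <- lo$objective; mx[j] <- hi$objective
  }
  out <- data.frame(id = model$rxns$id, min = mn, max = mx,
                    stringsAsFactors = FALSE)
  attr(out, "fraction_of_optimum") <- fraction_of_optimum
  attr(out, "optimum") <- wt$objective_value
  class(out) <- c("fva_result", "data.frame")
  out
}

#' Shadow prices and rate-limiting exchange metabolites
#'
#' Solves the FBA problem and reports the dual value of every metabolite's
#' mass-balance constraint: the marginal change of the optimal objective per
#' unit of additional availability of that metabolite. Metabolites touched
#' by an exchange reaction whose absolute price exceeds `tol` are flagged
#' rate-limiting. When the optimum is primal-degenerate the duals need not
#' be unique; a warning is issued and the solver's returned dual reported.
#'
#' @param model a [metabolic_model()].
#' @param tol threshold for calling a price nonzero.
#' @return list with `prices` (named numeric), `rate_limiting` (data.frame
#'   of exchanged metabolites with `|price| > tol`), and the `fit`.
#' @export
shadow_prices <- function(model, tol = 1e-6) {
  fit <- solve_fba(model)
  if (fit$status != "optimal") stop("shadow_prices: FBA is ", fit$status)
  S <- stoich_matrix(model)
  n_active <- sum(pmin(abs(fit$fluxes - model$rxns$lb),
                       abs(model$rxns$ub - fit$fluxes)) < 1e-9)
  if (n_active > ncol(S) - qr(S)$rank) {
    warning("degenerate optimum: shadow prices may be non-unique")
  }
  ex <- exchange_ids(model)
  ex_met <- vapply(ex, function(id) exchange_metabolite(model, id), "")
  pr <- fit$duals[ex_met]
  rl <- data.frame(exchange = ex, metabolite = ex_met, price = unname(pr),
                   stringsAsFactors = FALSE, row.names = NULL)
  rl <- rl[abs(rl$price) > tol, , drop = FALSE]
  rl <- rl[order(-abs(rl$price)), , drop = FALSE]
  list(prices = fit$duals, rate_limiting = rl, fit = fit)
}

#' Joint two-condition 1-norm-minimised flux fit
#'
#' Fixes each model's objective at its own FBA optimum (to within 1e-6
#' relative) and then minimises the summed 1-norm of both flux vectors in a
#' single LP, the standard way to obtain comparable, parsimonious flux
#' distributions for two conditions. Both models must share the same
#' reaction id space.
#'
#' @param modelA,modelB two [metabolic_model()]s with identical reaction ids.
#' @return list of two `fba_fit` objects (fluxes from the joint fit; duals
#'   from each model's own FBA solve), plus `total_norm`.
#' @export
joint_min_norm_fluxes <- function(modelA, modelB) {
  if (!identical(modelA$rxns$id, modelB$rxns$id)) {
    stop("models do not share a reaction id space")
  }
  fitA <- solve_fba(modelA); fitB <- solve_fba(modelB)
  if (fitA$status != "optimal") stop("model A FBA is ", fitA$status)
  if (fitB$status != "optimal") stop("model B FBA is ", fitB$status)

  build_part <- function(model, fit) {
    lb <- model$rxns$lb; ub <- model$rxns$ub
    i <- match(model$objective_id, model$rxns$id)
    opt <- fit$objective_value
    lb[i] <- max(lb[i], opt - max(1e-6 * abs(opt), 1e-9))
    list(S = stoich_matrix(model), lb = lb, ub = ub)
  }
  pa <- build_part(modelA, fitA); pb <- build_part(modelB, fitB)
  n <- nrow(modelA$rxns)
  mA <- nrow(pa$S); mB <- nrow(pb$S)
  # variables: vA (n), vB (n), tA (n), tB (n); t_j >= |v_j|
  zero <- function(r, c) matrix(0, r, c)
  A <- rbind(
    cbind(pa$S, zero(mA, n), zero(mA, n), zero(mA, n)),
    cbind(zero(mB, n), pb$S, zero(mB, n), zero(mB, n)),
    cbind(-diag(n), zero(n, n), diag(n), zero(n, n)),   # tA - vA >= 0
    cbind(diag(n), zero(n, n), diag(n), zero(n, n)),    # tA + vA >= 0
    cbind(zero(n, n), -diag(n), zero(n, n), diag(n)),
    cbind(zero(n, n), diag(n), zero(n, n), diag(n))
  )
  rhs <- c(rep(0, mA + mB), rep(0, 4 * n))
  sense <- c(rep("=", mA + mB), rep(">=", 4 * n))
  tmaxA <- pmax(abs(pa$lb), abs(pa$ub))
  tmaxB <- pmax(abs(pb$lb), abs(pb$ub))
  lb <- c(pa$lb, pb$lb, rep(0, 2 * n))
  ub <- c(pa$ub, pb$ub, tmaxA, tmaxB)
  obj <- c(rep(0, 2 * n), rep(1, 2 * n))
  res <- solve_lp(obj, A, rhs, sense, lb, ub, maximize = FALSE)
  if (res$status != "optimal") stop("joint 1-norm fit is ", res$status)
  vA <- stats::setNames(res$x[seq_len(n)], modelA$rxns$id)
  vB <- stats::setNames(res$x[n + seq_len(n)], modelB$rxns$id)
  outA <- fitA; outA$fluxes <- vA
  outB <- fitB; outB$fluxes <- vB
  list(A = outA, B = outB, total_norm = res$objective)
}
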